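#' Genotype-by-population contingency table
#'
#' A 3 x k table of joint probability estimates p_ij for genotype category
#' i (reference-allele dosage 0, 1, 2) and population j, with its
#' marginals. This is the object on which the Lancaster estimator of
#' independence is evaluated.
#'
#' @param p numeric 3 x k matrix of non-negative joint probabilities
#'   summing to 1 (within 1e-12).
#' @param population_names optional k population names.
#' @return An object of class `geno_pop_table` with elements `p`,
#'   `row_marginals` (genotype marginals p_i+), `col_marginals`
#'   (population marginals p_+j) and `population_names`.
#' @export
geno_pop_table <- function(p, population_names = NULL) {
  p <- as.matrix(p)
  if (nrow(p) != 3L || ncol(p) < 1L) {
    stop("table must be 3 genotype rows by k >= 1 population columns")
  }
  if (any(p < 0)) stop("joint probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop("joint probabilities must sum to 1")
  population_names <- population_names %||% colnames(p) %||%
    paste0("pop", seq_len(ncol(p)))
  dimnames(p) <- list(c("0", "1", "2"), population_names)
  structure(list(
    p = p,
    row_marginals = rowSums(p),
    col_marginals = colSums(p),
    population_names = population_names
  ), class = "geno_pop_table")
}

#' Build the genotype-by-population table from observed genotypes
#'
#' Joint probabilities are estimated by simple counting, p_ij = n_ij / n,
#' where n_ij is the number of individuals with dosage i in population j.
#' Missing genotypes are dropped (complete-case counting), so n is the
#' number of non-missing calls at the marker.
#'
#' @param codes per-sample reference-allele dosages at one marker
#'   (0, 1, 2 or NA).
#' @param labels per-sample population names.
#' @return A [geno_pop_table()].
#' @export
build_genotype_contingency <- function(codes, labels) {
  stopifnot(length(codes) == length(labels))
  pops <- sort(unique(as.character(labels)))
  if (length(pops) < 2L) stop("need at least two populations")
  keep <- !is.na(codes)
  n_by_pop <- vapply(pops, function(p) sum(keep & labels == p), numeric(1))
  if (any(n_by_pop == 0)) {
    stop("degenerate-population error: no non-missing genotypes in ",
         paste(pops[n_by_pop == 0], collapse = ", "))
  }
  counts <- table(factor(codes[keep], levels = 0:2),
                  factor(labels[keep], levels = pops))
  geno_pop_table(unclass(counts) / sum(counts), pops)
}

#' Build the expected genotype-by-population table from allele frequencies
#'
#' Under Hardy-Weinberg equilibrium a population with reference-allele
#' frequency f_j and c_j individuals is expected to carry
#' c_j (1 - f_j)^2, 2 c_j f_j (1 - f_j) and c_j f_j^2 individuals of
#' dosage 0, 1 and 2 respectively. Fractional expected counts are kept;
#' dividing by n = sum(c_j) yields the joint probability estimates.
#'
#' @param f reference-allele frequency per population, in [0, 1].
#' @param c_counts individuals per population (positive).
#' @return A [geno_pop_table()].
#' @export
expected_contingency_from_freq <- function(f, c_counts) {
  stopifnot(length(f) == length(c_counts), all(f >= 0), all(f <= 1),
            all(c_counts > 0))
  n0 <- c_counts * (1 - f)^2
  n1 <- 2 * c_counts * f * (1 - f)
  n2 <- c_counts * f^2
  p <- rbind(n0, n1, n2) / sum(c_counts)
  geno_pop_table(p, names(f))
}

#' Lancaster estimator of independence for one table
#'
#' Computes theta^2 = sum_ij p_ij^2 / (p_i+ p_+j) - 1, a chi-square-type
#' measure of dependence between genotype category and population
#' membership: 0 when the two are independent, and at most
#' min(m, k) - 1 where m is the number of genotype categories (3) and k
#' the number of populations. Cells whose row or column marginal is zero
#' necessarily have p_ij = 0 and contribute nothing.
#'
#' @param table a [geno_pop_table()].
#' @return A list of class `lei_score` with `value`, `m_effective` (number
#'   of genotype categories with positive marginal) and `k`.
#' @export
theta_squared <- function(table) {
  stopifnot(inherits(table, "geno_pop_table"))
  p <- table$p
  rm_ <- table$row_marginals
  cm <- table$col_marginals
  denom <- outer(rm_, cm)
  ok <- denom > 0
  value <- sum(p[ok]^2 / denom[ok]) - 1
  structure(list(value = value,
                 m_effective = sum(rm_ > 0),
                 k = length(cm)),
            class = "lei_score")
}

# Internal constructor for ranking tables shared by all scorers.
new_ranking <- function(method, marker_ids, score, chrom = NULL, bp = NULL) {
  df <- data.frame(
    marker_id = as.character(marker_ids),
    chrom = if (is.null(chrom)) rep("0", length(marker_ids)) else
      as.character(chrom),
    bp = if (is.null(bp)) seq_along(marker_ids) else as.integer(bp),
    method = method,
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  class(df) <- c("marker_ranking", "data.frame")
  rank_markers(df)
}

# Vectorized theta^2 across markers given dosage-count arrays.
# n0, n1, n2: L x k matrices of (possibly fractional) genotype counts.
theta_squared_from_counts <- function(n0, n1, n2) {
  n <- n0 + n1 + n2              # L x k per-population totals
  ntot <- rowSums(n)
  r0 <- rowSums(n0) / ntot       # row marginals p_i+
  r1 <- rowSums(n1) / ntot
  r2 <- rowSums(n2) / ntot
  cm <- n / ntot                 # column marginals p_+j
  acc <- numeric(nrow(n0))
  rows <- list(list(n0, r0), list(n1, r1), list(n2, r2))
  for (row in rows) {
    pij <- row[[1]] / ntot
    ri <- row[[2]]
    den <- ri * cm
    term <- ifelse(den > 0, pij^2 / den, 0)
    acc <- acc + rowSums(term)
  }
  acc - 1
}

#' LEI scores from individual-level genotypes
#'
#' For every marker, estimates theta^2 from the observed genotype-by-
#' population counts (complete-case over missing calls) and returns a
#' ranked score table. Larger scores indicate markers whose genotype
#' distribution differs more strongly across the reference populations.
#'
#' @param g a labeled [genotype_matrix()] with at least two populations.
#' @return A `marker_ranking` data frame (marker_id, chrom, bp, method,
#'   score, rank).
#' @export
lei_geno_scores <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- g$population_labels
  if (is.null(labels)) stop("population labels are required")
  pops <- sort(unique(labels))
  if (length(pops) < 2L) stop("need at least two populations")
  L <- ncol(g$codes)
  k <- length(pops)
  n0 <- n1 <- n2 <- matrix(0, L, k)
  for (j in seq_len(k)) {
    sub <- g$codes[labels == pops[j], , drop = FALSE]
    n0[, j] <- colSums(sub == 0L, na.rm = TRUE)
    n1[, j] <- colSums(sub == 1L, na.rm = TRUE)
    n2[, j] <- colSums(sub == 2L, na.rm = TRUE)
  }
  npop <- n0 + n1 + n2
  if (any(npop == 0)) {
    bad <- which(rowSums(npop == 0) > 0)[1]
    stop("degenerate-population error: marker ", g$marker_ids[bad],
         " has a population with no non-missing genotypes")
  }
  new_ranking("LEI_Geno", g$marker_ids,
              theta_squared_from_counts(n0, n1, n2), g$chrom, g$bp)
}

#' LEI scores from population allele frequencies
#'
#' The summary-level variant: per-marker theta^2 evaluated on the
#' Hardy-Weinberg expected genotype counts implied by the population
#' reference-allele frequencies and sample sizes, so no individual-level
#' genotypes are needed.
#'
#' @param ft a [pop_freq_table()].
#' @return A `marker_ranking` data frame.
#' @export
lei_freq_scores <- function(ft) {
  stopifnot(inherits(ft, "pop_freq_table"))
  f <- ft$f
  cc <- matrix(ft$c_counts, nrow(f), ncol(f), byrow = TRUE)
  n0 <- cc * (1 - f)^2
  n1 <- 2 * cc * f * (1 - f)
  n2 <- cc * f^2
  new_ranking("LEI_Freq", ft$marker_ids,
              theta_squared_from_counts(n0, n1, n2), ft$chrom, ft$bp)
}

#' Global FST scores from population allele frequencies
#'
#' Nei-style multi-population fixation index per marker:
#' FST = (H_T - H_S) / H_T, with H_S the sample-size-weighted mean of the
#' within-population expected heterozygosities 2 f_j (1 - f_j) and
#' H_T = 2 fbar (1 - fbar) the total expected heterozygosity at the
#' weighted mean frequency fbar. Markers with H_T = 0 (monomorphic
#' overall) score 0.
#'
#' @param ft a [pop_freq_table()] with k >= 2 populations.
#' @return A `marker_ranking` data frame.
#' @export
global_fst_scores <- function(ft) {
  stopifnot(inherits(ft, "pop_freq_table"),
            length(ft$population_names) >= 2L)
  w <- ft$c_counts / sum(ft$c_counts)
  fbar <- drop(ft$f %*% w)
  hs <- drop((2 * ft$f * (1 - ft$f)) %*% w)
  ht <- 2 * fbar * (1 - fbar)
  score <- ifelse(ht > 0, (ht - hs) / ht, 0)
  new_ranking("FST", ft$marker_ids, score, ft$chrom, ft$bp)
}

#' Rank markers by score
#'
#' Assigns ranks 1..L in decreasing score order. Ties are broken
#' deterministically by genomic position (chrom, then bp ascending) and
#' finally by marker id, so repeated runs produce identical rankings.
#'
#' @param ranking a `marker_ranking` data frame with a `score` column.
#' @return The same data frame with its `rank` column (re)populated.
#' @export
rank_markers <- function(ranking) {
  stopifnot(inherits(ranking, "marker_ranking"),
            all(is.finite(ranking$score)))
  ord <- order(-ranking$score, ranking$chrom, ranking$bp,
               ranking$marker_id, method = "radix")
  ranking$rank <- integer(nrow(ranking))
  ranking$rank[ord] <- seq_len(nrow(ranking))
  ranking
}

#' Top-N marker ids of a ranking
#'
#' @param ranking a `marker_ranking` data frame.
#' @param n how many markers to return.
#' @return Character vector of the `n` best-ranked marker ids, in rank
#'   order.
#' @export
top_markers <- function(ranking, n) {
  stopifnot(n >= 1, n <= nrow(ranking))
  ranking$marker_id[order(ranking$rank)][seq_len(n)]
}
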