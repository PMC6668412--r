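#' Two-way mosaic simulation parameters
#'
#' Parameters of the Poisson-switch mosaic model: each admixed chromosome
#' draws its own second-panel ancestry probability theta1 from a
#' Beta(alpha, beta) distribution, then walks along the marker map
#' resampling ancestry at each inter-marker gap with probability
#' 1 - exp(-g * l), where g is the number of generations since admixture
#' and l is the gap in units of 10^8 bp (an approximation of genetic
#' distance). The defaults (g = 8, Beta(12, 3), 200 chromosomes) emulate
#' an African-American-like admixture history with a mean second-panel
#' proportion of 80%.
#'
#' @param g generations since admixture (> 0).
#' @param alpha,beta Beta shape parameters for the per-chromosome
#'   ancestry probability.
#' @param n_chromosomes number of admixed chromosomes to simulate (even;
#'   chromosomes are paired into diploid individuals).
#' @param seed integer seed controlling all randomness.
#' @return A list of class `two_way_params`.
#' @export
two_way_params <- function(g = 8, alpha = 12, beta = 3,
                           n_chromosomes = 200, seed = 1) {
  stopifnot(g >= 0, alpha > 0, beta > 0, n_chromosomes %% 2 == 0,
            n_chromosomes >= 2)
  structure(list(g = g, alpha = alpha, beta = beta,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "two_way_params")
}

#' Three-way block-mosaic simulation parameters
#'
#' Each admixed chromosome is partitioned into consecutive fixed-length
#' windows (100 kb by default, anchored at position 1); every window's
#' ancestry is drawn independently from the mixing proportions. The
#' defaults (0.6, 0.3, 0.1) emulate a three-way admixed cohort dominated
#' by the first ancestry.
#'
#' @param proportions length-K mixing probabilities summing to 1.
#' @param block_bp window length in base pairs.
#' @param n_chromosomes number of admixed chromosomes (even).
#' @param seed integer seed.
#' @return A list of class `three_way_params`.
#' @export
three_way_params <- function(proportions = c(0.6, 0.3, 0.1),
                             block_bp = 100000L, n_chromosomes = 200,
                             seed = 1) {
  stopifnot(all(proportions >= 0), abs(sum(proportions) - 1) < 1e-8,
            block_bp >= 1, n_chromosomes %% 2 == 0, n_chromosomes >= 2)
  structure(list(proportions = proportions,
                 block_bp = as.integer(block_bp),
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "three_way_params")
}

#' Generate differentiated synthetic reference panels
#'
#' Download-free stand-in for real reference panels: ancestral allele
#' frequencies are drawn uniformly on [0.05, 0.95]; each population's
#' frequency is drawn from the Balding-Nichols distribution
#' Beta(p (1 - F) / F, (1 - p) (1 - F) / F) around the ancestral frequency
#' p at differentiation F; haplotype alleles are Bernoulli draws at the
#' population frequency (1 = reference allele). Marker positions increase
#' strictly with uniform random gaps in [500, 5000] bp.
#'
#' @param k number of populations.
#' @param n_markers number of biallelic markers (shared map).
#' @param n_haplotypes haplotypes per population (>= 2).
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param seed integer seed.
#' @param chrom chromosome name for the shared map.
#' @return A list of class `reference_panels` with elements `panels`
#'   (list of k `haplotype_panel` objects), `ancestral_freq` and
#'   `pop_freq` (the true L x k Balding-Nichols frequencies).
#' @export
generate_reference_panels <- function(k, n_markers, n_haplotypes, fst,
                                      seed = 1, chrom = "1") {
  stopifnot(k >= 1, n_markers >= 1, n_haplotypes >= 2, fst > 0, fst < 1)
  with_seed(seed, {
    bp <- cumsum(round(stats::runif(n_markers, 500, 5000)))
    p <- stats::runif(n_markers, 0.05, 0.95)
    pop_names <- paste0("POP", seq_len(k))
    pop_freq <- matrix(NA_real_, n_markers, k,
                       dimnames = list(NULL, pop_names))
    panels <- vector("list", k)
    shape <- (1 - fst) / fst
    for (j in seq_len(k)) {
      fj <- stats::rbeta(n_markers, p * shape, (1 - p) * shape)
      pop_freq[, j] <- fj
      hap <- matrix(stats::rbinom(n_haplotypes * n_markers, 1L,
                                  rep(fj, each = n_haplotypes)),
                    n_haplotypes, n_markers)
      panels[[j]] <- structure(list(
        population_name = pop_names[j],
        chrom = rep(chrom, n_markers),
        bp = as.integer(bp),
        ref_allele = rep("A", n_markers),
        alt_allele = rep("C", n_markers),
        haplotypes = hap
      ), class = "haplotype_panel")
    }
    names(panels) <- pop_names
    structure(list(panels = panels, ancestral_freq = p,
                   pop_freq = pop_freq, fst = fst, seed = seed),
              class = "reference_panels")
  })
}

#' Allele-frequency table of a set of reference panels
#'
#' Builds the summary-level [pop_freq_table()] that a consortium would
#' publish for the panels: per-marker reference-allele frequencies and the
#' panel sample sizes (haplotypes / 2 individuals).
#'
#' @param panels a list of `haplotype_panel` objects sharing a marker map,
#'   or a `reference_panels` object.
#' @param use `"realized"` (frequencies observed in the haplotypes, the
#'   default: what real summary data would contain) or `"true"` (the
#'   generating Balding-Nichols frequencies; only available for a
#'   `reference_panels` object).
#' @return A [pop_freq_table()].
#' @export
panel_freq_table <- function(panels, use = c("realized", "true")) {
  use <- match.arg(use)
  rp <- NULL
  if (inherits(panels, "reference_panels")) {
    rp <- panels
    panels <- panels$panels
  }
  check_shared_map(panels)
  L <- length(panels[[1]]$bp)
  marker_ids <- paste0("snp", seq_len(L))
  pop_names <- vapply(panels, `[[`, character(1), "population_name")
  cc <- vapply(panels, function(p) max(1L, nrow(p$haplotypes) %/% 2L),
               integer(1))
  if (use == "true") {
    if (is.null(rp)) stop("true frequencies require a reference_panels object")
    f <- rp$pop_freq
  } else {
    f <- vapply(panels, function(p) colMeans(p$haplotypes), numeric(L))
  }
  pop_freq_table(marker_ids, pop_names, f, cc,
                 chrom = panels[[1]]$chrom, bp = panels[[1]]$bp)
}

check_shared_map <- function(panels) {
  stopifnot(length(panels) >= 2)
  ref <- panels[[1]]
  for (p in panels[-1]) {
    if (!identical(p$bp, ref$bp) || !identical(p$chrom, ref$chrom)) {
      stop("map error: panels do not share an identical marker map")
    }
  }
  invisible(TRUE)
}

# Assemble an admixed_cohort from per-chromosome haplotype/ancestry lists.
build_cohort <- function(panels, hap_rows, anc_rows, params, seed,
                         theta1 = NULL, n_resample = NULL,
                         hap_choice = NULL) {
  k <- length(panels)
  pop_names <- vapply(panels, `[[`, character(1), "population_name")
  n_chrom <- length(hap_rows)
  L <- length(panels[[1]]$bp)
  n <- n_chrom %/% 2L
  pairing <- matrix(sample.int(n_chrom), nrow = 2L)  # random pairing
  codes <- matrix(0L, n, L)
  local_anc <- array(NA_integer_, dim = c(2L, n, L))
  for (i in seq_len(n)) {
    c1 <- pairing[1, i]
    c2 <- pairing[2, i]
    codes[i, ] <- hap_rows[[c1]] + hap_rows[[c2]]
    local_anc[1, i, ] <- anc_rows[[c1]]
    local_anc[2, i, ] <- anc_rows[[c2]]
  }
  true_q <- matrix(0, n, k, dimnames = list(paste0("ind", seq_len(n)),
                                            pop_names))
  copy1 <- matrix(local_anc[1, , ], nrow = n)
  copy2 <- matrix(local_anc[2, , ], nrow = n)
  for (j in seq_len(k)) {
    true_q[, j] <- (rowMeans(copy1 == j) + rowMeans(copy2 == j)) / 2
  }
  g <- genotype_matrix(codes, paste0("ind", seq_len(n)),
                       paste0("snp", seq_len(L)),
                       panels[[1]]$chrom, panels[[1]]$bp,
                       panels[[1]]$ref_allele, panels[[1]]$alt_allele)
  structure(list(
    genotypes = g,
    local_ancestry = local_anc,
    true_q = true_q,
    population_names = pop_names,
    provenance = list(params = unclass(params), seed = seed,
                      theta1 = theta1, n_resample = n_resample,
                      hap_choice = hap_choice, pairing = pairing)
  ), class = "admixed_cohort")
}

#' Simulate a two-way admixed cohort
#'
#' Builds mosaic chromosomes from a pair of phased reference panels. For
#' each chromosome: draw theta1 ~ Beta(alpha, beta) (the probability of
#' second-panel ancestry), draw one haplotype from each panel, assign the
#' first marker to the second panel with probability theta1, and at each
#' subsequent marker resample the ancestry with probability
#' 1 - exp(-g * l) (l = bp gap / 10^8); resampled ancestry is again
#' second-panel with probability theta1, so it may stay unchanged. The
#' allele at each marker is copied from the current ancestral haplotype.
#' Chromosomes are randomly paired into diploid individuals. The returned
#' truth is the realized per-individual marker fraction of each ancestry
#' (averaged over the two chromosome copies); the drawn theta1 values are
#' kept in the provenance.
#'
#' @param panel_a,panel_b `haplotype_panel` objects on the same marker map;
#'   `panel_b` plays the role of the high-proportion ancestry under the
#'   default Beta(12, 3).
#' @param params a [two_way_params()] object.
#' @return An object of class `admixed_cohort` with elements `genotypes`,
#'   `local_ancestry` (2 x n x L array of panel indices), `true_q` and
#'   `provenance`.
#' @export
simulate_two_way <- function(panel_a, panel_b, params = two_way_params()) {
  stopifnot(inherits(params, "two_way_params"))
  panels <- list(panel_a, panel_b)
  check_shared_map(panels)
  bp <- panel_a$bp
  L <- length(bp)
  lgap <- diff(bp) / 1e8
  p_resample <- 1 - exp(-params$g * lgap)
  with_seed(params$seed, {
    hap_rows <- anc_rows <- vector("list", params$n_chromosomes)
    theta1 <- numeric(params$n_chromosomes)
    n_resample <- integer(params$n_chromosomes)
    hap_choice <- matrix(0L, params$n_chromosomes, 2L)
    for (cidx in seq_len(params$n_chromosomes)) {
      th <- stats::rbeta(1, params$alpha, params$beta)
      theta1[cidx] <- th
      ia <- sample.int(nrow(panel_a$haplotypes), 1L)
      ib <- sample.int(nrow(panel_b$haplotypes), 1L)
      hap_choice[cidx, ] <- c(ia, ib)
      resample <- if (L > 1L) stats::runif(L - 1L) < p_resample else logical(0)
      n_resample[cidx] <- sum(resample)
      seg <- cumsum(c(TRUE, resample))
      # ancestry of each segment is an independent Bernoulli(theta1) draw
      seg_anc <- stats::rbinom(seg[L], 1L, th)
      anc <- seg_anc[seg] + 1L  # 1 = panel_a, 2 = panel_b
      hap <- ifelse(anc == 2L, panel_b$haplotypes[ib, ],
                    panel_a$haplotypes[ia, ])
      hap_rows[[cidx]] <- as.integer(hap)
      anc_rows[[cidx]] <- anc
    }
    build_cohort(panels, hap_rows, anc_rows, params, params$seed,
                 theta1 = theta1, n_resample = n_resample,
                 hap_choice = hap_choice)
  })
}

#' Simulate a three-way admixed cohort
#'
#' Builds block-mosaic chromosomes from three phased reference panels.
#' Each chromosome is partitioned into consecutive `block_bp` windows
#' anchored at position 1; the ancestry of every window is drawn
#' independently from `proportions`; one haplotype is drawn at random from
#' each panel and the allele at every marker is copied from the window's
#' ancestral haplotype. Chromosomes are randomly paired into diploid
#' individuals and the realized per-individual marker fractions are
#' recorded as the truth.
#'
#' @param panels a list of three `haplotype_panel` objects on the same map
#'   (or a `reference_panels` object with three panels).
#' @param params a [three_way_params()] object.
#' @return An `admixed_cohort`; see [simulate_two_way()].
#' @export
simulate_three_way <- function(panels, params = three_way_params()) {
  stopifnot(inherits(params, "three_way_params"))
  if (inherits(panels, "reference_panels")) panels <- panels$panels
  stopifnot(length(panels) == length(params$proportions))
  check_shared_map(panels)
  k <- length(panels)
  bp <- panels[[1]]$bp
  L <- length(bp)
  block <- (bp - 1L) %/% params$block_bp
  block_id <- match(block, unique(block))
  n_blocks <- max(block_id)
  with_seed(params$seed, {
    hap_rows <- anc_rows <- vector("list", params$n_chromosomes)
    hap_choice <- matrix(0L, params$n_chromosomes, k)
    for (cidx in seq_len(params$n_chromosomes)) {
      idx <- vapply(panels, function(p)
        sample.int(nrow(p$haplotypes), 1L), integer(1))
      hap_choice[cidx, ] <- idx
      block_anc <- sample.int(k, n_blocks, replace = TRUE,
                              prob = params$proportions)
      anc <- block_anc[block_id]
      hap <- integer(L)
      for (j in seq_len(k)) {
        sel <- anc == j
        if (any(sel)) hap[sel] <- panels[[j]]$haplotypes[idx[j], sel]
      }
      hap_rows[[cidx]] <- hap
      anc_rows[[cidx]] <- anc
    }
    build_cohort(panels, hap_rows, anc_rows, params, params$seed,
                 hap_choice = hap_choice)
  })
}

#' Reconstruct cohort genotypes from the recorded ancestry paths
#'
#' Conservation check: every simulated allele must be traceable to exactly
#' one source haplotype. Re-copies alleles from the panels using the
#' recorded local ancestry, haplotype choices and pairing, and returns the
#' reconstructed dosage matrix (which must equal `cohort$genotypes$codes`).
#'
#' @param cohort an `admixed_cohort`.
#' @param panels the panels the cohort was simulated from.
#' @return An integer dosage matrix.
#' @export
regenerate_genotypes <- function(cohort, panels) {
  if (inherits(panels, "reference_panels")) panels <- panels$panels
  pairing <- cohort$provenance$pairing
  choice <- cohort$provenance$hap_choice
  la <- cohort$local_ancestry
  n <- dim(la)[2]
  L <- dim(la)[3]
  codes <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    for (copy in 1:2) {
      chrom_idx <- pairing[copy, i]
      anc <- la[copy, i, ]
      for (j in seq_along(panels)) {
        sel <- anc == j
        if (any(sel)) {
          codes[i, sel] <- codes[i, sel] +
            panels[[j]]$haplotypes[choice[chrom_idx, j], sel]
        }
      }
    }
  }
  codes
}

#' Diploid reference genotypes from haplotype panels
#'
#' Pairs consecutive haplotypes of each panel into individuals and returns
#' a labeled [genotype_matrix()] of the reference populations, the
#' individual-level companion of [panel_freq_table()]. Useful for the
#' genotype-based rankers, which need labeled reference genotypes.
#'
#' @param panels a list of `haplotype_panel` objects sharing a marker map,
#'   or a `reference_panels` object.
#' @return A [genotype_matrix()] with population labels.
#' @export
panel_genotypes <- function(panels) {
  if (inherits(panels, "reference_panels")) panels <- panels$panels
  check_shared_map(panels)
  L <- length(panels[[1]]$bp)
  codes <- NULL
  ids <- labels <- character(0)
  for (p in panels) {
    h <- nrow(p$haplotypes) %/% 2L * 2L
    blk <- p$haplotypes[seq(1, h, by = 2), , drop = FALSE] +
      p$haplotypes[seq(2, h, by = 2), , drop = FALSE]
    codes <- rbind(codes, blk)
    ids <- c(ids, paste0(p$population_name, "_", seq_len(h %/% 2L)))
    labels <- c(labels, rep(p$population_name, h %/% 2L))
  }
  genotype_matrix(codes, ids, paste0("snp", seq_len(L)),
                  panels[[1]]$chrom, panels[[1]]$bp,
                  panels[[1]]$ref_allele, panels[[1]]$alt_allele,
                  population_labels = labels)
}
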