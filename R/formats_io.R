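#' Construct a genotype matrix
#'
#' The central genotype container: an `n` samples by `L` markers integer
#' matrix of reference-allele dosages (0, 1, 2; `NA` = missing) together
#' with the marker map and optional per-sample population labels. Markers
#' are sorted by (chromosome, position) on construction.
#'
#' @param codes integer matrix, samples x markers; entries in {0, 1, 2, NA},
#'   counting copies of the reference allele.
#' @param sample_ids character vector, one id per row of `codes`.
#' @param marker_ids character vector, one id per column of `codes`.
#' @param chrom per-marker chromosome names.
#' @param bp per-marker 1-based positions, strictly increasing within a
#'   chromosome.
#' @param ref_allele,alt_allele per-marker single-character alleles.
#' @param population_labels optional per-sample population names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, sample_ids, marker_ids, chrom, bp,
                            ref_allele = NULL, alt_allele = NULL,
                            population_labels = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  n <- nrow(codes)
  L <- ncol(codes)
  if (length(sample_ids) != n || length(marker_ids) != L) {
    stop("genotype codes dimensions do not match sample/marker ids")
  }
  stopifnot(length(chrom) == L, length(bp) == L)
  bad <- codes[!is.na(codes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (!is.null(population_labels) && length(population_labels) != n) {
    stop("labeling error: population_labels length does not match samples")
  }
  ref_allele <- ref_allele %||% rep("N", L)
  alt_allele <- alt_allele %||% rep("N", L)
  ord <- order(as.character(chrom), bp, method = "radix")
  for (ch in unique(chrom[ord])) {
    b <- bp[ord][chrom[ord] == ch]
    if (anyDuplicated(b)) stop("duplicate bp position on chromosome ", ch)
  }
  g <- structure(list(
    codes = codes[, ord, drop = FALSE],
    sample_ids = as.character(sample_ids),
    marker_ids = as.character(marker_ids)[ord],
    chrom = as.character(chrom)[ord],
    bp = as.integer(bp)[ord],
    ref_allele = as.character(ref_allele)[ord],
    alt_allele = as.character(alt_allele)[ord],
    population_labels = if (is.null(population_labels)) NULL else
      as.character(population_labels)
  ), class = "genotype_matrix")
  dimnames(g$codes) <- list(g$sample_ids, g$marker_ids)
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers", nrow(x$codes),
              ncol(x$codes)))
  if (!is.null(x$population_labels)) {
    tb <- table(x$population_labels)
    cat(sprintf("; populations: %s",
                paste(sprintf("%s (%d)", names(tb), tb), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Subset a genotype matrix to a set of markers
#'
#' @param g a [genotype_matrix()].
#' @param marker_ids markers to keep; all must be present.
#' @return A `genotype_matrix` restricted to the requested markers
#'   (re-sorted by genomic position).
#' @export
subset_markers <- function(g, marker_ids) {
  idx <- match(marker_ids, g$marker_ids)
  if (anyNA(idx)) {
    stop("unknown marker ids: ",
         paste(utils::head(marker_ids[is.na(idx)], 5), collapse = ", "))
  }
  genotype_matrix(g$codes[, idx, drop = FALSE], g$sample_ids,
                  g$marker_ids[idx], g$chrom[idx], g$bp[idx],
                  g$ref_allele[idx], g$alt_allele[idx], g$population_labels)
}

#' Read genotypes from VCF or a PLINK-style text table
#'
#' For VCF input, only diploid GT fields of biallelic SNP records are used;
#' multi-allelic and non-SNP records are skipped and the skip count is
#' reported via `message()`. Dosages count copies of the VCF REF allele.
#' The PLINK-style text table is tab-separated with a header row
#' `IID <marker ids...>` and one row per sample; genotype entries are
#' reference-allele dosages (`NA` or -9 = missing). An optional first
#' comment line `#COUNTED=ALT` declares that the stored dosages count the
#' ALT allele, in which case they are flipped to the reference orientation
#' on read.
#'
#' @param path input file.
#' @param format `"vcf"` or `"plink_text"`.
#' @param labels_path optional two-column tab-separated file (sample id,
#'   population name; no header) covering every sample.
#' @return A [genotype_matrix()] sorted by (chrom, bp).
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"),
                           labels_path = NULL) {
  format <- match.arg(format)
  g <- switch(format,
    vcf = read_genotypes_vcf(path),
    plink_text = read_genotypes_plink_text(path)
  )
  if (!is.null(labels_path)) {
    lab <- read_labels(labels_path)
    miss <- setdiff(g$sample_ids, names(lab))
    if (length(miss)) {
      stop("labeling error: no population label for samples: ",
           paste(miss, collapse = ", "))
    }
    g$population_labels <- unname(lab[g$sample_ids])
  }
  g
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message("read_genotypes: skipped ", n_skip,
            " multi-allelic or non-SNP record(s)")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")  # markers x samples
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  # reference-allele dosage = number of '0' alleles in the GT string
  code_gt <- function(v) {
    out <- rep(NA_integer_, length(v))
    ok <- !is.na(v) & !grepl(".", v, fixed = TRUE)
    alleles <- strsplit(v[ok], "[/|]")
    bad <- vapply(alleles, function(a) length(a) != 2L ||
                    !all(a %in% c("0", "1")), logical(1))
    if (any(bad)) stop("parse error: malformed GT field '",
                       v[ok][bad][1], "'")
    out[ok] <- vapply(alleles, function(a) sum(a == "0"), integer(1))
    out
  }
  codes <- apply(gt, 2, code_gt)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  codes <- t(codes)  # samples x markers
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(codes, colnames(gt), ids, fix[, "CHROM"],
                  as.integer(fix[, "POS"]), ref, alt)
}

read_genotypes_plink_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  counted <- "REF"
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("^#COUNTED=(REF|ALT)$", first))[[1]]
    if (length(m) != 2L) stop("parse error: bad header comment: ", first)
    counted <- m[2]
    skip <- 1L
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"))
  if (colnames(tab)[1] != "IID") {
    stop("parse error: first column of PLINK-style table must be IID")
  }
  codes <- as.matrix(tab[, -1, drop = FALSE])
  if (counted == "ALT") codes <- 2L - codes
  genotype_matrix(codes, tab$IID, colnames(tab)[-1],
                  chrom = rep("0", ncol(codes)), bp = seq_len(ncol(codes)))
}

read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  stats::setNames(as.character(tab$population), tab$sample)
}

#' Write genotypes to VCF or a PLINK-style text table
#'
#' The inverse of [read_genotypes()]: writing then reading reproduces the
#' dosage codes exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"plink_text"`.
#' @param labels_path optional path; when given and `g` carries population
#'   labels, a two-column sample-to-population file is written alongside.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "plink_text"),
                            labels_path = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    ref <- ifelse(g$ref_allele == "N", "A", g$ref_allele)
    alt <- ifelse(g$alt_allele == "N", "C", g$alt_allele)
    gt_of <- c("1/1", "0/1", "0/0")  # dosage 0, 1, 2 of the REF allele
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", g$sample_ids), collapse = "\t")
    )
    body <- vapply(seq_along(g$marker_ids), function(j) {
      gts <- ifelse(is.na(g$codes[, j]), "./.", gt_of[g$codes[, j] + 1L])
      paste(c(g$chrom[j], g$bp[j], g$marker_ids[j], ref[j], alt[j], ".",
              "PASS", ".", "GT", gts), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#COUNTED=REF", con)
    writeLines(paste(c("IID", g$marker_ids), collapse = "\t"), con)
    for (i in seq_along(g$sample_ids)) {
      writeLines(paste(c(g$sample_ids[i], g$codes[i, ]), collapse = "\t"), con)
    }
  }
  if (!is.null(labels_path) && !is.null(g$population_labels)) {
    utils::write.table(
      data.frame(g$sample_ids, g$population_labels),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct a population allele-frequency table
#'
#' Summary-level input: per-marker reference-allele frequency in each of
#' `k` reference populations together with the population sample sizes
#' (individual counts).
#'
#' @param marker_ids character vector of L marker ids.
#' @param population_names character vector of k unique population names.
#' @param f numeric L x k matrix of reference-allele frequencies in [0, 1].
#' @param c_counts integer vector of k population sample sizes (>= 1).
#' @param chrom,bp optional per-marker map (used when writing).
#' @return An object of class `pop_freq_table`.
#' @export
pop_freq_table <- function(marker_ids, population_names, f, c_counts,
                           chrom = NULL, bp = NULL) {
  f <- as.matrix(f)
  if (anyDuplicated(population_names)) {
    stop("population names must be unique")
  }
  if (nrow(f) != length(marker_ids) || ncol(f) != length(population_names)) {
    stop("frequency matrix dimensions do not match markers x populations")
  }
  if (any(f < 0 | f > 1, na.rm = FALSE) || anyNA(f)) {
    stop("range error: allele frequencies must lie in [0, 1]")
  }
  if (length(c_counts) != length(population_names) || any(c_counts < 1)) {
    stop("population sample sizes must be positive, one per population")
  }
  dimnames(f) <- list(marker_ids, population_names)
  structure(list(
    marker_ids = as.character(marker_ids),
    population_names = as.character(population_names),
    f = f,
    c_counts = as.integer(round(c_counts)),
    chrom = if (is.null(chrom)) rep("0", length(marker_ids)) else
      as.character(chrom),
    bp = if (is.null(bp)) seq_along(marker_ids) else as.integer(bp)
  ), class = "pop_freq_table")
}

#' @export
print.pop_freq_table <- function(x, ...) {
  cat(sprintf("pop_freq_table: %d markers x %d populations (%s)\n",
              length(x$marker_ids), length(x$population_names),
              paste(x$population_names, collapse = ", ")))
  invisible(x)
}

#' Read a stratified allele-frequency table
#'
#' Parses the PLINK `.frq.strat` dialect: a whitespace- or tab-separated
#' table with header columns CHR, SNP, CLST, A1, A2, MAF, NCHROBS and one
#' row per marker x population. The A1 frequency is taken as the
#' reference-allele frequency; the per-population individual count is
#' recovered as NCHROBS / 2 rounded half up (a warning is raised when
#' NCHROBS is odd). Every marker must be present in every population.
#'
#' @param path input file.
#' @return A [pop_freq_table()].
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("CHR", "SNP", "CLST", "A1", "A2", "MAF", "NCHROBS")
  if (!all(need %in% colnames(tab))) {
    stop("parse error: missing columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  }
  if (any(tab$MAF < 0 | tab$MAF > 1)) {
    bad <- tab$SNP[tab$MAF < 0 | tab$MAF > 1][1]
    stop("range error: frequency outside [0, 1] at marker ", bad)
  }
  pops <- unique(tab$CLST)
  snps <- unique(tab$SNP)
  counts <- table(tab$SNP)
  if (any(counts != length(pops))) {
    stop("completeness error: marker(s) missing for some population: ",
         paste(utils::head(names(counts)[counts != length(pops)], 5),
               collapse = ", "))
  }
  if (any(tab$NCHROBS %% 2 != 0)) {
    warning("odd NCHROBS encountered; individual counts rounded half up")
  }
  f <- matrix(NA_real_, length(snps), length(pops),
              dimnames = list(snps, pops))
  f[cbind(match(tab$SNP, snps), match(tab$CLST, pops))] <- tab$MAF
  c_counts <- vapply(pops, function(p) {
    obs <- tab$NCHROBS[tab$CLST == p]
    floor(stats::median(obs) / 2 + 0.5)
  }, numeric(1))
  first <- !duplicated(tab$SNP)
  map <- tab[first, ][match(snps, tab$SNP[first]), ]
  pft <- pop_freq_table(snps, pops, f, c_counts, chrom = map$CHR,
                        bp = if ("BP" %in% colnames(tab)) map$BP else NULL)
  pft
}

#' Write a stratified allele-frequency table
#'
#' Writes the `.frq.strat` dialect read by [read_freq_table()].
#'
#' @param ft a [pop_freq_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(ft, path) {
  k <- length(ft$population_names)
  L <- length(ft$marker_ids)
  out <- data.frame(
    CHR = rep(ft$chrom, each = k),
    SNP = rep(ft$marker_ids, each = k),
    CLST = rep(ft$population_names, times = L),
    A1 = "A", A2 = "C",
    MAF = as.vector(t(ft$f)),
    NCHROBS = rep(2L * ft$c_counts, times = L)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ancestry-proportion matrix
#'
#' Writes the whitespace-separated `.Q` convention: one row per individual,
#' K columns of ancestry proportions. Every row must lie on the simplex.
#'
#' @param q numeric n x K matrix; rows sum to 1 within 1e-8 and entries are
#'   non-negative.
#' @param path output file.
#' @param digits decimal places written; the conventional 6 by default.
#'   Use 17 for lossless round-trips.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(q, path, digits = 6) {
  q <- as.matrix(q)
  if (!is_simplex_rows(q, tol = 1e-8)) {
    stop("contract error: Q rows must be non-negative and sum to 1")
  }
  fmt <- paste0("%.", digits, "f")
  if (digits > 8) fmt <- paste0("%.", digits, "g")
  lines <- apply(q, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ancestry-proportion matrix
#'
#' @param path a whitespace-separated file, one row per individual.
#' @return A numeric matrix, one column per ancestry.
#' @export
read_q_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write a marker ranking table
#'
#' Tab-separated columns marker_id, chrom, bp, method, score, rank,
#' ordered by rank.
#'
#' @param ranking a ranking produced by [rank_markers()] or any of the
#'   scoring functions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "marker_ranking"))
  out <- ranking[order(ranking$rank),
                 c("marker_id", "chrom", "bp", "method", "score", "rank")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker ranking table written by [write_ranking()]
#'
#' @param path input file.
#' @return A `marker_ranking` data frame.
#' @export
read_ranking <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(tab) <- c("marker_ranking", "data.frame")
  tab
}
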