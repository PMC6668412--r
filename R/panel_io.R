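#' Write a phased haplotype panel as plain text
#'
#' Simple tab-separated panel format: a comment line naming the
#' population, a header, and one row per marker with the map columns
#' (chrom, bp, ref, alt) followed by one 0/1 column per haplotype
#' (1 = reference allele). Phase is preserved, unlike genotype formats.
#'
#' @param panel a `haplotype_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#population=", panel$population_name), con)
  h <- nrow(panel$haplotypes)
  writeLines(paste(c("chrom", "bp", "ref", "alt", paste0("h", seq_len(h))),
                   collapse = "\t"), con)
  body <- paste(panel$chrom, panel$bp, panel$ref_allele, panel$alt_allele,
                apply(t(panel$haplotypes), 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a phased haplotype panel written by [write_haplotype_panel()]
#'
#' @param path input file.
#' @return A `haplotype_panel`.
#' @export
read_haplotype_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#population=(.+)$", first))[[1]]
  if (length(m) != 2L) stop("parse error: missing #population line")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  hap <- t(as.matrix(tab[, -(1:4), drop = FALSE]))
  storage.mode(hap) <- "integer"
  dimnames(hap) <- NULL
  if (nrow(hap) < 2L) stop("panel must contain at least 2 haplotypes")
  structure(list(
    population_name = m[2],
    chrom = tab$chrom,
    bp = tab$bp,
    ref_allele = tab$ref,
    alt_allele = tab$alt,
    haplotypes = hap
  ), class = "haplotype_panel")
}

#' Write the realized truth of a simulated cohort
#'
#' Tab-separated table: individual id followed by one true ancestry
#' proportion column per population.
#'
#' @param cohort an `admixed_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  out <- data.frame(individual = rownames(cohort$true_q),
                    cohort$true_q, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#'
#' @param path input file.
#' @return A numeric matrix of true ancestry proportions with individual
#'   ids as row names.
#' @export
read_truth <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  q <- as.matrix(tab[, -1, drop = FALSE])
  rownames(q) <- tab[[1]]
  q
}
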