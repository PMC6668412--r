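# Shared fixtures and independent oracles, all built in code.

# Naive double-loop evaluation of theta^2 on a 3 x k joint table; the
# reference oracle against which the vectorized implementations are
# checked. Kept deliberately scalar.
naive_theta2 <- function(p) {
  rm_ <- rowSums(p)
  cm <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (rm_[i] > 0 && cm[j] > 0) s <- s + p[i, j]^2 / (rm_[i] * cm[j])
    }
  }
  unname(s - 1)
}

# A random 3 x k joint probability table (rows genotype 0/1/2).
random_joint_table <- function(k = 3) {
  p <- matrix(stats::rexp(3 * k), 3, k)
  p / sum(p)
}

# A tiny labeled genotype matrix with planted differentiation: markers
# diff1..diff<d> have population-specific frequencies, the rest share one.
planted_genotypes <- function(n_per_pop = 20, n_null = 30, n_diff = 5,
                              pops = c("A", "B", "C"), seed = 1,
                              diff_freqs = NULL) {
  k <- length(pops)
  if (is.null(diff_freqs)) {
    diff_freqs <- matrix(0.5, n_diff, k)
    for (m in seq_len(n_diff)) {
      diff_freqs[m, ] <- 0.05 + 0.9 * (seq_len(k) - 1) / (k - 1)
      if (m %% 2 == 0) diff_freqs[m, ] <- rev(diff_freqs[m, ])
    }
  }
  withr::with_seed(seed, {
    labels <- rep(pops, each = n_per_pop)
    n <- length(labels)
    L <- n_null + n_diff
    codes <- matrix(0L, n, L)
    for (j in seq_len(n_null)) {
      codes[, j] <- stats::rbinom(n, 2, 0.5)
    }
    for (m in seq_len(n_diff)) {
      f <- diff_freqs[m, match(labels, pops)]
      codes[, n_null + m] <- stats::rbinom(n, 2, f)
    }
    ids <- c(sprintf("null%03d", seq_len(n_null)),
             sprintf("diff%03d", seq_len(n_diff)))
    genotype_matrix(codes, paste0("s", seq_len(n)), ids,
                    chrom = rep("1", L), bp = seq_len(L) * 1000L,
                    population_labels = labels)
  })
}

# Writes a small VCF: 3 samples, 2 biallelic SNPs, optionally plus one
# triallelic record.
write_tiny_vcf <- function(path, triallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "0/1", "0/0", sep = "\t")
  )
  if (triallelic) {
    lines <- c(lines,
      paste("1", "300", "rs3", "A", "G,T", ".", "PASS", ".", "GT",
            "0/1", "1/2", "0/0", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Writes a stratified allele-frequency table in the .frq.strat dialect.
write_tiny_frq_strat <- function(path, snps = c("rs1"),
                                 pops = c("A", "B"),
                                 maf = matrix(c(0.9, 0.1), 1),
                                 nchrobs = c(100, 100),
                                 drop_last_row = FALSE) {
  rows <- c(paste("CHR", "SNP", "CLST", "A1", "A2", "MAF", "NCHROBS",
                  sep = "\t"))
  for (i in seq_along(snps)) {
    for (j in seq_along(pops)) {
      rows <- c(rows, paste("1", snps[i], pops[j], "A", "C",
                            maf[i, j], nchrobs[j], sep = "\t"))
    }
  }
  if (drop_last_row) rows <- rows[-length(rows)]
  writeLines(rows, path)
  path
}

# Genotypes of n individuals drawn with admixture proportions q (n x K)
# from per-population frequencies f (L x K): each of the two alleles picks
# an ancestry from q, then a Bernoulli(f) allele.
admixed_draws <- function(q, f, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(q)
    L <- nrow(f)
    p_ref <- q %*% t(f)  # n x L probability a random allele is reference
    codes <- matrix(stats::rbinom(n * L, 2, as.vector(p_ref)), n, L)
    genotype_matrix(codes, paste0("i", seq_len(n)),
                    paste0("snp", seq_len(L)),
                    chrom = rep("1", L), bp = seq_len(L) * 1000L)
  })
}
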