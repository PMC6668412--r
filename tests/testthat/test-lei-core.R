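test_that("genotype contingency tables count complete cases", {
  tb <- build_genotype_contingency(c(0, 0, 2, 2), c("A", "A", "B", "B"))
  expect_equal(unname(tb$p),
               matrix(c(0.5, 0, 0, 0, 0, 0.5), 3, 2), tolerance = 1e-15)
  expect_equal(unname(tb$row_marginals), unname(rowSums(tb$p)))
  expect_equal(unname(tb$col_marginals), unname(colSums(tb$p)))

  # identical genotype distributions: all mass on dosage 1, theta^2 = 0
  tb1 <- build_genotype_contingency(c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(tb1$row_marginals[2]), 1)
  expect_equal(theta_squared(tb1)$value, 0, tolerance = 1e-12)

  # missing genotypes are dropped from the denominator
  tbm <- build_genotype_contingency(c(0, NA, 2, 2), c("A", "A", "B", "B"))
  expect_equal(unname(tbm$p), cbind(c(1, 0, 0), c(0, 0, 2)) / 3,
               tolerance = 1e-15)

  expect_error(
    build_genotype_contingency(c(NA, NA, 0, 1), c("A", "A", "B", "B")),
    "degenerate-population")
})

test_that("HWE expected tables match the product formulas", {
  # fixed alleles concentrate all mass on the homozygote rows
  tb <- expected_contingency_from_freq(c(0, 1), c(50, 50))
  expect_equal(unname(tb$p), matrix(c(0.5, 0, 0, 0, 0, 0.5), 3, 2),
               tolerance = 1e-15)
  # single population at f = 0.5: expected counts (25, 50, 25)
  tb2 <- expected_contingency_from_freq(0.5, 100)
  expect_equal(unname(tb2$p[, 1]), c(0.25, 0.5, 0.25), tolerance = 1e-15)
  # hand evaluation of the three product formulas at f = (0.9, 0.1)
  tb3 <- expected_contingency_from_freq(c(0.9, 0.1), c(50, 50))
  expect_equal(unname(tb3$p * 100),
               cbind(c(0.5, 9, 40.5), c(40.5, 9, 0.5)), tolerance = 1e-12)
})

test_that("theta^2 attains its bound, vanishes under independence, and matches the oracle", {
  # one genotype exclusive to each of three equal populations: the maximum
  diag_tb <- geno_pop_table(diag(3) / 3)
  expect_equal(theta_squared(diag_tb)$value, 2, tolerance = 1e-12)

  # identical distribution in every population: independence
  p <- matrix(rep(c(0.2, 0.5, 0.3) / 2, 2), 3, 2)
  expect_equal(theta_squared(geno_pop_table(p))$value, 0, tolerance = 1e-12)

  # frozen value computed with the naive double-loop oracle
  tb <- expected_contingency_from_freq(c(0.9, 0.1), c(50, 50))
  expect_equal(theta_squared(tb)$value, 0.780487804878049,
               tolerance = 1e-12)
  expect_equal(theta_squared(tb)$value, naive_theta2(tb$p),
               tolerance = 1e-14)
})

test_that("vectorized theta^2 equals the naive double loop on random tables", {
  # absolute comparison: near-independent tables compute theta^2 as
  # S - 1 with S ~ 1, so a relative criterion would amplify benign
  # last-bit cancellation noise
  withr::with_seed(7, {
    for (rep in 1:1000) {
      k <- sample(2:5, 1)
      p <- random_joint_table(k)
      expect_lt(abs(theta_squared(geno_pop_table(p))$value - naive_theta2(p)),
                1e-12)
    }
  })
})

test_that("theta^2 respects its bound and symmetries", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      k <- sample(2:4, 1)
      p <- random_joint_table(k)
      v <- theta_squared(geno_pop_table(p))$value
      expect_gte(v, -1e-12)
      expect_lte(v, min(3, k) - 1 + 1e-9)
      # invariance under population permutation and allele flip (0 <-> 2)
      perm <- sample(k)
      expect_equal(theta_squared(geno_pop_table(p[, perm]))$value, v,
                   tolerance = 1e-12)
      expect_equal(theta_squared(geno_pop_table(p[3:1, ]))$value, v,
                   tolerance = 1e-12)
    }
  })
})

test_that("genotype-based LEI scores markers as specified", {
  codes <- cbind(mono = rep(1L, 8),
                 full = c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L))
  g <- genotype_matrix(codes, paste0("s", 1:8), colnames(codes),
                       chrom = c("1", "1"), bp = c(10L, 20L),
                       population_labels = rep(c("A", "B"), each = 4))
  rk <- lei_geno_scores(g)
  expect_equal(rk$score[rk$marker_id == "mono"], 0, tolerance = 1e-12)
  # dosage 0 exclusive to A, dosage 2 exclusive to B: min(2, 2) - 1 = 1
  expect_equal(rk$score[rk$marker_id == "full"], 1, tolerance = 1e-12)

  # permuting sample order leaves scores unchanged
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  gp <- genotype_matrix(codes[perm, ], paste0("s", 1:8)[perm],
                        colnames(codes), chrom = c("1", "1"),
                        bp = c(10L, 20L),
                        population_labels = rep(c("A", "B"), each = 4)[perm])
  expect_equal(lei_geno_scores(gp)$score, rk$score, tolerance = 1e-12)
})

test_that("frequency-based LEI scores markers as specified", {
  ft <- pop_freq_table(
    c("same", "fixed", "strong"), c("P1", "P2"),
    rbind(c(0.3, 0.3), c(1, 0), c(0.9, 0.1)), c(50, 50))
  rk <- lei_freq_scores(ft)
  sc <- stats::setNames(rk$score, rk$marker_id)
  expect_equal(unname(sc["same"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc["fixed"]), 1, tolerance = 1e-12)
  expect_equal(unname(sc["strong"]), 0.780487804878049, tolerance = 1e-12)
})

test_that("genotype and frequency LEI agree on exactly-HWE counts", {
  # counts chosen so HWE expected counts are integers: f = 0.5 with c = 4
  # (1, 2, 1) and f = 0.25 with c = 16 (9, 6, 1)
  codes_a <- c(0L, 1L, 1L, 2L)                     # pop A, f = 0.5
  codes_b <- c(rep(0L, 9), rep(1L, 6), rep(2L, 1)) # pop B, f = 0.25
  codes <- matrix(c(codes_a, codes_b), ncol = 1)
  g <- genotype_matrix(codes, paste0("s", 1:20), "m1", "1", 100L,
                       population_labels = rep(c("A", "B"), c(4, 16)))
  ft <- pop_freq_table("m1", c("A", "B"), matrix(c(0.5, 0.25), 1), c(4, 16))
  expect_equal(lei_geno_scores(g)$score, lei_freq_scores(ft)$score,
               tolerance = 1e-12)
})

test_that("LEI from genotypes and from frequencies agree on differentiated panels", {
  rp <- generate_reference_panels(3, 2000, 100, fst = 0.15, seed = 31)
  geno <- lei_geno_scores(panel_genotypes(rp))
  freq <- lei_freq_scores(panel_freq_table(rp))
  expect_gte(stats::cor(geno$score, freq$score), 0.95)
})

test_that("global FST scores follow the heterozygosity partition", {
  ft <- pop_freq_table(
    c("same", "fixed", "strong", "monomorphic"), c("P1", "P2"),
    rbind(c(0.3, 0.3), c(1, 0), c(0.9, 0.1), c(0, 0)), c(50, 50))
  sc <- stats::setNames(global_fst_scores(ft)$score, ft$marker_ids)
  expect_equal(unname(sc["same"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc["fixed"]), 1, tolerance = 1e-12)
  # hand evaluation: H_S = 0.18, H_T = 0.5
  expect_equal(unname(sc["strong"]), 0.64, tolerance = 1e-12)
  expect_equal(unname(sc["monomorphic"]), 0)
})

test_that("ranking is deterministic, position-tied and idempotent", {
  df <- data.frame(marker_id = c("m1", "m2", "m3"),
                   chrom = "1", bp = c(100L, 200L, 300L),
                   method = "test", score = c(0.2, 0.9, 0.5))
  class(df) <- c("marker_ranking", "data.frame")
  rk <- rank_markers(df)
  expect_equal(rk$rank, c(3L, 1L, 2L))

  # equal scores: earlier genomic position wins
  df$score <- c(0.5, 0.5, 0.9)
  rk2 <- rank_markers(df)
  expect_equal(rk2$rank, c(2L, 3L, 1L))

  expect_identical(rank_markers(rk2), rk2)
})
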