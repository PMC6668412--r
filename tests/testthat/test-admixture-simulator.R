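test_that("Balding-Nichols panels match their target differentiation", {
  rp <- generate_reference_panels(3, 5000, 100, fst = 0.15, seed = 41)
  expect_true(all(rp$pop_freq >= 0 & rp$pop_freq <= 1))
  expect_true(all(diff(rp$panels[[1]]$bp) >= 500 &
                  diff(rp$panels[[1]]$bp) <= 5000))
  # Multi-locus FST on realized panel frequencies recovers the target.
  # Plain Nei G_ST divides the between-population variance by k rather
  # than k - 1 and so has expectation F(1 - 1/k)/(1 - F/k), about 0.105
  # here; the small-k-corrected moment estimator below is unbiased for
  # the drift parameter: F = var_pop(f) / (p(1 - p)), estimated per
  # marker with s2 = sum((f - fbar)^2)/(k - 1) and
  # p(1 - p) = fbar(1 - fbar) + s2/k, then pooled as a ratio of sums.
  ft <- panel_freq_table(rp)
  k <- ncol(ft$f)
  fbar <- rowMeans(ft$f)
  s2 <- rowSums((ft$f - fbar)^2) / (k - 1)
  fst_hat <- sum(s2) / sum(fbar * (1 - fbar) + s2 / k)
  expect_lt(abs(fst_hat - 0.15), 0.03)
})

test_that("vanishing differentiation gives panels at the ancestral frequency", {
  rp <- generate_reference_panels(2, 1000, 10, fst = 1e-6, seed = 42)
  expect_lt(max(abs(rp$pop_freq - rp$ancestral_freq)), 0.02)
})

test_that("no generations since admixture means single-ancestry chromosomes", {
  rp <- generate_reference_panels(2, 300, 20, fst = 0.15, seed = 43)
  coh <- simulate_two_way(rp$panels[[1]], rp$panels[[2]],
                          two_way_params(g = 0, n_chromosomes = 20,
                                         seed = 44))
  for (copy in 1:2) {
    la <- matrix(coh$local_ancestry[copy, , ], nrow = dim(coh$local_ancestry)[2])
    expect_true(all(apply(la, 1, function(x) length(unique(x))) == 1L))
  }
  # per-chromosome ancestry fraction is then 0 or 1
  expect_true(all(coh$true_q %in% c(0, 0.5, 1)))
})

test_that("huge switch rates decorrelate ancestry along the chromosome", {
  rp <- generate_reference_panels(2, 10000, 10, fst = 0.15, seed = 45)
  coh <- simulate_two_way(rp$panels[[1]], rp$panels[[2]],
                          two_way_params(g = 1e9, alpha = 2, beta = 2,
                                         n_chromosomes = 4, seed = 46))
  for (copy in 1:2) {
    for (i in seq_len(dim(coh$local_ancestry)[2])) {
      anc <- coh$local_ancestry[copy, i, ]
      if (stats::sd(anc) > 0) {
        L <- length(anc)
        expect_lt(abs(stats::cor(anc[-1], anc[-L])), 0.05)
      }
    }
  }
})

test_that("default two-way simulation realizes ~80% second-panel ancestry", {
  rp <- generate_reference_panels(2, 5000, 100, fst = 0.15, seed = 47)
  coh <- simulate_two_way(rp$panels[[1]], rp$panels[[2]],
                          two_way_params(seed = 48))
  expect_lt(abs(mean(coh$true_q[, 2]) - 0.80), 0.03)
})

test_that("two-way resampling events match their Poisson expectation", {
  rp <- generate_reference_panels(2, 5000, 10, fst = 0.15, seed = 49)
  coh <- simulate_two_way(rp$panels[[1]], rp$panels[[2]],
                          two_way_params(seed = 50))
  p <- 1 - exp(-8 * diff(rp$panels[[1]]$bp) / 1e8)
  expected <- sum(p)
  se <- sqrt(sum(p * (1 - p)) / 200)
  obs <- mean(coh$provenance$n_resample)
  expect_lt(abs(obs - expected), 3 * se)
  # and the expectation itself approaches g * D / 1e8
  D <- diff(range(rp$panels[[1]]$bp))
  expect_lt(abs(expected - 8 * D / 1e8) / (8 * D / 1e8), 0.01)
})

test_that("degenerate three-way proportions copy a single panel", {
  rp <- generate_reference_panels(3, 500, 10, fst = 0.15, seed = 51)
  coh <- simulate_three_way(rp, three_way_params(proportions = c(1, 0, 0),
                                                 n_chromosomes = 10,
                                                 seed = 52))
  expect_true(all(coh$local_ancestry == 1L))
  expect_equal(unname(coh$true_q),
               matrix(rep(c(1, 0, 0), each = 5), 5), tolerance = 1e-15)
})

test_that("three-way ancestry switches only at block boundaries", {
  rp <- generate_reference_panels(3, 3000, 10, fst = 0.15, seed = 53)
  params <- three_way_params(n_chromosomes = 10, seed = 54)
  coh <- simulate_three_way(rp, params)
  bp <- rp$panels[[1]]$bp
  block <- (bp - 1) %/% params$block_bp
  for (copy in 1:2) {
    la <- matrix(coh$local_ancestry[copy, , ],
                 nrow = dim(coh$local_ancestry)[2])
    changes <- la[, -1, drop = FALSE] != la[, -ncol(la), drop = FALSE]
    same_block <- matrix(rep(diff(block) == 0, each = nrow(la)),
                         nrow = nrow(la))
    expect_false(any(changes & same_block))
  }
})

test_that("default three-way simulation realizes the stated proportions", {
  rp <- generate_reference_panels(3, 20000, 100, fst = 0.15, seed = 55)
  coh <- simulate_three_way(rp, three_way_params(seed = 56))
  expect_true(all(abs(colMeans(coh$true_q) - c(0.6, 0.3, 0.1)) < 0.03))
})

test_that("simulations are deterministic and internally consistent", {
  rp <- generate_reference_panels(2, 800, 20, fst = 0.15, seed = 57)
  params <- two_way_params(n_chromosomes = 30, seed = 58)
  coh <- simulate_two_way(rp$panels[[1]], rp$panels[[2]], params)
  coh2 <- simulate_two_way(rp$panels[[1]], rp$panels[[2]], params)
  expect_identical(coh$genotypes$codes, coh2$genotypes$codes)
  expect_identical(coh$true_q, coh2$true_q)
  expect_identical(coh$local_ancestry, coh2$local_ancestry)

  # true_q equals the marker-average of local-ancestry indicators
  n <- dim(coh$local_ancestry)[2]
  for (j in 1:2) {
    frac <- (rowMeans(matrix(coh$local_ancestry[1, , ], nrow = n) == j) +
             rowMeans(matrix(coh$local_ancestry[2, , ], nrow = n) == j)) / 2
    expect_equal(unname(coh$true_q[, j]), frac, tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(coh$true_q) - 1) < 1e-12))

  # every allele traces back to its recorded source haplotype
  expect_identical(regenerate_genotypes(coh, rp), unname(coh$genotypes$codes))

  rp3 <- generate_reference_panels(3, 800, 20, fst = 0.15, seed = 59)
  coh3 <- simulate_three_way(rp3, three_way_params(n_chromosomes = 30,
                                                   seed = 60))
  expect_identical(regenerate_genotypes(coh3, rp3),
                   unname(coh3$genotypes$codes))

  # mismatched maps are rejected
  rp_alt <- generate_reference_panels(2, 800, 20, fst = 0.15, seed = 61)
  expect_error(simulate_two_way(rp$panels[[1]], rp_alt$panels[[2]], params),
               "map error")
})
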