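test_that("genotypes follow Binomial(2, maf) and are reproducible", {
  x <- simulate_genotypes(2000, 0.3, seed = 11)
  expect_true(all(x %in% 0:2))
  expect_identical(x, simulate_genotypes(2000, 0.3, seed = 11))
  # allele frequency within 3 binomial standard errors
  expect_lt(abs(mean(x) / 2 - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 2000)))

  # genotype class frequencies match the Hardy-Weinberg proportions
  xl <- simulate_genotypes(1e6, 0.3, seed = 12)
  freqs <- tabulate(xl + 1L, 3) / 1e6
  expect_true(all(abs(freqs - c(0.49, 0.42, 0.09)) < 0.005))

  # degenerate maf: essentially no minor alleles
  expect_true(all(simulate_genotypes(100, 1e-9, seed = 1) == 0L))

  expect_error(simulate_genotypes(100, 0.6), "maf")
  expect_error(simulate_genotypes(100, 0), "maf")
  expect_error(simulate_genotypes(1, 0.3), "n")
})

test_that("model configurations reproduce the four canned designs at M = 16", {
  c1 <- build_model_config(1, 16, 0.1)
  expect_equal(c1$lambda, rep(0.1, 16))
  expect_equal(c1$gamma, matrix(1, 16, 1))
  expect_equal(c1$d, rep(1, 16))
  expect_equal(c1$R, 1L)

  c2 <- build_model_config(2, 16, 0)
  expect_equal(c2$lambda, rep(0, 16))
  expect_equal(c2$R, 2L)
  expect_equal(c2$gamma[, 1], c(rep(1, 8), rep(0, 8)))
  expect_equal(c2$gamma[, 2], c(rep(0, 8), rep(1, 8)))

  c3 <- build_model_config(3, 16, 0.2)
  expect_equal(c3$lambda,
               c(rep(0, 8), rep(-0.2, 3), rep(0.2, 4), rep(-0.2, 1)))
  expect_equal(c3$d, rep(c(0.5, 1, 1.5, 2), 4))
  blk <- c(1, 1, 1, -1)
  expect_equal(c3$gamma[1:4, 1], blk)
  expect_equal(c3$gamma[13:16, 4], blk)
  expect_equal(rowSums(c3$gamma != 0), rep(1, 16))

  c4 <- build_model_config(4, 16, 0.1)
  # increasing-effect block has mean effect exactly beta
  expect_equal(mean(c4$lambda[5:8]), 0.1)
  expect_equal(c4$lambda[1:4], rep(0, 4))
  expect_equal(c4$lambda[9:16], c(rep(-0.1, 3), rep(0.1, 4), -0.1))
  expect_equal(c4$gamma[5:8, 2], rep(1, 4))
  expect_equal(c4$gamma[1:4, 1], blk)
  expect_equal(c4$d, c3$d)

  expect_error(build_model_config(2, 15, 0), "even")
  expect_error(build_model_config(3, 20, 0), "divisible by 16")
  expect_error(build_model_config(4, 24, 0), "divisible by 16")
})

test_that("factor model produces the stated correlation structure", {
  n <- 50000
  x <- simulate_genotypes(n, 0.3, seed = 21)

  # one factor: every pairwise correlation equals c^2
  Y1 <- simulate_phenotypes(build_model_config(1, 16, 0, c2 = 0.5,
                                               rho_c2 = 0.1), x, seed = 22)
  S1 <- cor(Y1)
  off <- S1[upper.tri(S1)]
  expect_true(all(abs(off - 0.5) < 0.01 + 3 * sd(off)))
  expect_lt(abs(mean(off) - 0.5), 0.01)

  # two factors: cross-block correlation equals rho * c^2
  Y2 <- simulate_phenotypes(build_model_config(2, 16, 0, c2 = 0.5,
                                               rho_c2 = 0.1), x, seed = 23)
  S2 <- cor(Y2)
  expect_lt(abs(mean(S2[1:8, 9:16]) - 0.1), 0.01)
  expect_lt(abs(mean(S2[1:8, 1:8][upper.tri(diag(8))]) - 0.5), 0.01)

  # no factor contribution: independent unit-variance columns
  Y0 <- simulate_phenotypes(build_model_config(1, 8, 0, c2 = 0, rho_c2 = 0),
                            x, seed = 24)
  S0 <- cor(Y0)
  expect_lt(max(abs(S0[upper.tri(S0)])), 0.02)

  # marginal variances are 1 for the unit-scaling designs
  expect_true(all(abs(apply(Y1, 2, var) - 1) < 0.03))
  expect_true(all(abs(apply(Y2, 2, var) - 1) < 0.03))

  # mixed-sign loadings: within-block correlation is +/- c^2 with the sign
  # given by the product of the two loadings
  Y3 <- simulate_phenotypes(build_model_config(3, 16, 0, c2 = 0.5,
                                               rho_c2 = 0.1), x, seed = 25)
  S3 <- cor(Y3)
  expect_lt(abs(S3[1, 2] - 0.5), 0.015)   # + * +
  expect_lt(abs(S3[1, 4] + 0.5), 0.015)   # + * -
})

test_that("phenotype simulation is seed-deterministic and leaves the caller's RNG alone", {
  cfg <- build_model_config(2, 8, 0.1)
  x <- simulate_genotypes(200, 0.3, seed = 5)
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  Y1 <- simulate_phenotypes(cfg, x, seed = 6)
  expect_identical(rnorm(1), before)
  Y2 <- simulate_phenotypes(cfg, x, seed = 6)
  expect_identical(Y1, Y2)
})

test_that("phenotype scaling standardizes columns and is idempotent", {
  expect_equal(as.numeric(scale_phenotypes(cbind(c(1, 2, 3)))), c(-1, 0, 1))

  set.seed(31)
  Y <- matrix(rnorm(500, mean = 3, sd = 4), 100, 5)
  Z <- scale_phenotypes(Y)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-8)
  expect_lt(max(abs(scale_phenotypes(Z) - Z)), 1e-12)
  expect_true(attr(Z, "scaled"))

  Y[, 2] <- 7
  colnames(Y) <- paste0("P", 1:5)
  expect_error(scale_phenotypes(Y), "P2")
})
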