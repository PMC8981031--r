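test_that("MANOVA reduces to the univariate F test for one phenotype", {
  d <- make_dataset(model_id = 1, M = 1, beta = 0.2, n = 300, seed = 10)
  res <- manova_test(d$Ys, d$x)
  fit <- summary(lm(d$Ys[, 1] ~ d$x))
  expect_equal(res$p_value, unname(pf(fit$fstatistic[1], 1, 298,
                                      lower.tail = FALSE)), tolerance = 1e-10)
  expect_equal(res$statistic, unname(fit$fstatistic[1]), tolerance = 1e-8)
})

test_that("Wilks' lambda matches the explicit determinant oracle", {
  set.seed(11)
  n <- 20
  Y <- matrix(rnorm(n * 3), n, 3)
  x <- rbinom(n, 2, 0.4)
  res <- manova_test(Y, x)
  fit <- lm(Y ~ x)
  E <- crossprod(resid(fit))
  H <- crossprod(fitted(fit) - matrix(colMeans(Y), n, 3, byrow = TRUE))
  lam <- det(E) / det(E + H)
  expect_equal(res$detail$wilks_lambda, lam, tolerance = 1e-10)
  Fo <- (1 - lam) / lam * (n - 3 - 1) / 3
  expect_equal(res$statistic, Fo, tolerance = 1e-10)
  expect_equal(res$p_value, pf(Fo, 3, n - 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("MANOVA is invariant to invertible linear recoding of the block", {
  d <- make_dataset(model_id = 2, M = 4, beta = 0.1, n = 400, seed = 12)
  A <- matrix(c(1, 0.5, 0.2, 0, 0, 2, 1, 0, 0, 0, 1, -1, 0, 0, 0, 3), 4, 4)
  p1 <- manova_test(d$Ys, d$x)$p_value
  p2 <- manova_test(d$Ys %*% A, d$x)$p_value
  expect_lt(abs(p1 - p2), 1e-8)

  expect_false(manova_test(d$Ys, rep(1, 400))$available)
})

test_that("proportional-odds fit maximizes the ordered-logit likelihood", {
  d <- make_dataset(model_id = 1, M = 2, beta = 0.15, n = 200, seed = 13)
  res <- multiphen_test(d$Ys, d$x)
  expect_true(res$available)
  ll_oracle <- maximize_ordlogit(d$Ys, d$x)
  expect_gte(res$detail$loglik, ll_oracle - 1e-6)
  expect_lt(abs(res$detail$loglik - ll_oracle), 1e-5)

  # null log-likelihood has the closed multinomial form
  cnt <- tabulate(d$x + 1L, 3)
  expect_equal(res$detail$loglik_null, sum(cnt * log(cnt / 200)))

  # LRT is invariant to phenotype order
  res2 <- multiphen_test(d$Ys[, 2:1], d$x)
  expect_equal(res$statistic, res2$statistic, tolerance = 1e-6)

  # missing genotype class: unavailable, mirroring the NA convention
  x2 <- d$x; x2[x2 == 2L] <- 1L
  expect_false(multiphen_test(d$Ys, x2)$available)
})

test_that("null reversed-regression LRT has the chi-square mean", {
  m <- 2
  n <- 300
  reps <- 2000
  cfg <- build_model_config(1, m, 0, c2 = 0.3, rho_c2 = 0)
  stats <- vapply(seq_len(reps), function(r) {
    x <- simulate_genotypes(n, 0.3, seed = 7000 + r)
    Y <- simulate_phenotypes(cfg, x, seed = 8000 + r)
    res <- multiphen_test(scale_phenotypes(Y), x)
    if (res$available) res$statistic else NA_real_
  }, numeric(1))
  stats <- stats[!is.na(stats)]
  expect_lt(abs(mean(stats) - m), 3 * sqrt(2 * m / length(stats)) + 0.05)
})

test_that("a strong monotone effect beats its own permutation", {
  cfg <- build_model_config(1, 1, 0.6, c2 = 0.3, rho_c2 = 0)
  wins <- vapply(1:100, function(r) {
    x <- simulate_genotypes(200, 0.3, seed = 100 + r)
    Y <- scale_phenotypes(simulate_phenotypes(cfg, x, seed = 300 + r))
    set.seed(500 + r)
    xs <- sample(x)
    multiphen_test(Y, x)$p_value < multiphen_test(Y, xs)$p_value
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("univariate p-values follow the closed-form t transform", {
  d <- make_dataset(model_id = 1, M = 5, beta = 0.1, n = 150, seed = 14)
  p <- univariate_pvalues(d$Ys, d$x)
  r <- drop(cor(d$Ys, d$x))
  t_oracle <- r * sqrt((150 - 2) / (1 - r^2))
  expect_equal(p, 2 * pt(-abs(t_oracle), 148), tolerance = 1e-10)
  # and each equals the per-phenotype regression t test
  pv_lm <- vapply(1:5, function(j)
    summary(lm(d$Ys[, j] ~ d$x))$coefficients[2, 4], numeric(1))
  expect_equal(unname(p), unname(pv_lm), tolerance = 1e-10)

  # duplicated phenotype gives an identical p-value
  p2 <- univariate_pvalues(cbind(d$Ys[, 1], d$Ys[, 1]), d$x)
  expect_equal(p2[1], p2[2])
})

test_that("null univariate p-values are uniform", {
  set.seed(15)
  x <- simulate_genotypes(200, 0.3, seed = 16)
  Y <- matrix(rnorm(200 * 2000), 200, 2000)
  p <- univariate_pvalues(Y, x)
  expect_lt(suppressWarnings(ks.test(p, "punif"))$statistic, 0.05)
})

test_that("p-value correlation map is anchored and matches fresh simulation", {
  expect_equal(pvalue_correlation(diag(2))[1, 2], 0)
  expect_equal(pvalue_correlation(matrix(1, 2, 2))[1, 2], 1)
  R <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(pvalue_correlation(R),
               pvalue_correlation(abs(R)))  # even in r

  # fresh finite-sample Monte Carlo at r = 0.5: null genotype, bivariate
  # normal phenotypes, correlate the two univariate association p-values
  set.seed(17)
  n <- 500; B <- 20000
  x <- matrix(rbinom(n * B, 2, 0.3), n, B)
  Y1 <- matrix(rnorm(n * B), n, B)
  Y2 <- 0.5 * Y1 + sqrt(1 - 0.25) * matrix(rnorm(n * B), n, B)
  cs <- function(m) sweep(m, 2, colMeans(m))
  xc <- cs(x); y1c <- cs(Y1); y2c <- cs(Y2)
  r1 <- colSums(xc * y1c) / sqrt(colSums(xc^2) * colSums(y1c^2))
  r2 <- colSums(xc * y2c) / sqrt(colSums(xc^2) * colSums(y2c^2))
  pv <- function(r) 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  mc <- cor(pv(r1), pv(r2))
  expect_lt(abs(pvalue_correlation(matrix(c(1, .5, .5, 1), 2))[1, 2] - mc),
            0.02)
})

test_that("effective number of tests follows the eigenvalue-excess formula", {
  e5 <- effective_number(diag(5))
  expect_equal(e5$me_total, 5)
  expect_equal(e5$me_partial, 1:5)

  ones <- matrix(1, 5, 5)
  expect_equal(effective_number(ones)$me_total, 1)

  set.seed(18)
  A <- matrix(rnorm(40), 10, 4)
  R <- cor(A)
  e <- effective_number(R)
  expect_equal(e$me_total, me_by_svd(R), tolerance = 1e-10)
  expect_true(all(e$me_partial >= 1 - 1e-12))
  expect_true(all(e$me_partial <= seq_len(4) + 1e-12))
  expect_equal(e$me_partial[4], e$me_total)
})

test_that("extended-Simes combination reduces correctly at the extremes", {
  d <- make_dataset(model_id = 1, M = 4, beta = 0.15, n = 300, seed = 19)

  # single phenotype: the univariate p-value itself
  r1 <- tates_test(d$Ys[, 1, drop = FALSE], d$x)
  expect_equal(r1$p_value, univariate_pvalues(d$Ys[, 1, drop = FALSE], d$x)[1])

  # exactly orthogonal phenotypes: Simes' rule exactly
  Q <- qr.Q(qr(sweep(d$Y, 2, colMeans(d$Y))))
  Yorth <- scale_phenotypes(Q)
  p_uni <- sort(univariate_pvalues(Yorth, d$x))
  simes <- min(ncol(Yorth) * p_uni / seq_along(p_uni))
  expect_equal(tates_test(Yorth, d$x)$p_value, simes, tolerance = 1e-10)

  # fully duplicated phenotypes: collapses to the single univariate p-value
  Ydup <- scale_phenotypes(matrix(d$Y[, 1], 300, 4))
  pd <- tates_test(Ydup, d$x)$p_value
  pu <- univariate_pvalues(d$Ys[, 1, drop = FALSE], d$x)[1]
  expect_lt(abs(pd - pu) / pu, 0.10)
})

test_that("combined p-value sits between the minimum and Bonferroni bounds", {
  set.seed(20)
  for (i in 1:15) {
    d <- make_dataset(model_id = sample(1:2, 1), M = 8,
                      beta = runif(1, 0, 0.2), n = 250, seed = 400 + i)
    p_uni <- univariate_pvalues(d$Ys, d$x)
    pt <- tates_test(d$Ys, d$x)$p_value
    expect_gte(pt + 1e-12, min(p_uni))
    expect_lte(pt, min(1, 8 * min(p_uni)) + 1e-12)
  }
})

test_that("clustered pipeline composes exactly from its stages", {
  d <- make_dataset(model_id = 2, M = 16, beta = 0.1, n = 500, seed = 21)
  res <- run_method("manova", "hcdc", d$Y, d$x)

  dend <- agglomerate(scale_phenotypes(d$Y), "hcdc")
  K <- choose_k(dend)
  Yr <- representative_phenotypes(scale_phenotypes(d$Y),
                                  cut_dendrogram(dend, K))
  expect_equal(res$p_value, manova_test(Yr, d$x)$p_value, tolerance = 1e-14)
  expect_equal(res$K, as.integer(K))

  # forcing all singletons reproduces the unclustered analysis
  res_all <- run_method("tates", "hcdc", d$Y, d$x, K = 16)
  res_none <- run_method("tates", "none", d$Y, d$x)
  expect_equal(res_all$p_value, res_none$p_value, tolerance = 1e-12)
})

test_that("null p-values are uniform for MANOVA and MultiPhen; TATES is
           tail-calibrated but body-conservative under correlation", {
  n_reps <- 400
  cells <- expand.grid(method = c("manova", "multiphen", "tates"),
                       clustering = "none", stringsAsFactors = FALSE)
  s <- estimate_type1(1, N = 500, M = 8, n_reps = n_reps, cells = cells,
                      master_seed = 22)
  for (j in c("manova", "multiphen")) {
    p <- s$pvalues[, j]
    expect_lt(suppressWarnings(ks.test(p[!is.na(p)], "punif"))$statistic,
              0.07)
  }
  ## the extended-Simes combination is calibrated only in the rejection
  ## region: with positively correlated phenotypes its null p-values are
  ## stochastically larger than uniform in the body of the distribution,
  ## while the tail rejection rate stays near nominal
  pt <- s$pvalues[, "tates"]
  ci <- mc_confidence_interval(0.05, n_reps)
  expect_gte(mean(pt < 0.05), ci[1] - 0.02)
  expect_lte(mean(pt < 0.05), ci[2] + 0.02)
  expect_gt(median(pt), 0.5)    # conservative body
  expect_gt(mean(pt), 0.5)
})
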