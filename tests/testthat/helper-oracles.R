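# Independent brute-force oracles used across tests.

# ordered-logit (proportional odds) log-likelihood, written directly from the
# cumulative-probability definition; used for independent numerical
# maximization of the likelihood
ordlogit_loglik <- function(zeta, beta, X, y) {
  eta <- drop(as.matrix(X) %*% beta)
  F1 <- plogis(zeta[1] - eta)
  F2 <- plogis(zeta[2] - eta)
  pr <- cbind(F1, F2 - F1, 1 - F2)
  sum(log(pr[cbind(seq_along(y), y + 1L)]))
}

maximize_ordlogit <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  nll <- function(par) {
    zeta <- c(par[1], par[1] + exp(par[2]))
    -ordlogit_loglik(zeta, par[-(1:2)], X, y)
  }
  cum <- cumsum(tabulate(y + 1L, 3))[1:2] / length(y)
  start <- c(qlogis(cum[1]), log(qlogis(cum[2]) - qlogis(cum[1])), rep(0, p))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  -opt$value
}

# pearson correlation from hand-expanded sums
pearson_by_sums <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}

# effective number of tests recomputed through an svd (eigenvalues of a
# symmetric PSD matrix equal its singular values up to sign handling)
me_by_svd <- function(R) {
  ev <- svd(R)$d * sign(diag(t(svd(R)$u) %*% svd(R)$v))
  nrow(R) - sum(pmax(ev - 1, 0))
}

# small simulated phenotype/genotype set shared by several tests
make_dataset <- function(model_id = 2, M = 16, beta = 0, c2 = 0.5,
                         rho_c2 = 0.1, n = 500, seed = 42) {
  cfg <- build_model_config(model_id, M, beta, c2, rho_c2)
  x <- simulate_genotypes(n, 0.3, seed = seed)
  Y <- simulate_phenotypes(cfg, x, seed = seed + 1)
  list(x = x, Y = Y, Ys = scale_phenotypes(Y), cfg = cfg)
}
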