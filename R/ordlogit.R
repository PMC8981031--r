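## Proportional-odds (cumulative logit) model for a 3-level ordinal genotype.
##
## P(x <= j | Y) = logistic(zeta_j - Y beta), j = 0, 1, with zeta_0 < zeta_1.
## Fitted by Fisher scoring on the expected information, with step halving,
## and a BFGS fallback on the rare non-converged fit. The null
## (intercepts-only) log-likelihood has the closed multinomial form.

fit_proportional_odds <- function(X, y, tol = 1e-8, maxit = 100L) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  counts <- tabulate(y + 1L, nbins = 3L)
  if (any(counts == 0L))
    stop("genotype must take all three values 0, 1, 2", call. = FALSE)
  ## start at the null fit
  cum <- cumsum(counts)[1:2] / n
  theta <- c(qlogis(cum), rep(0, p))
  i0 <- y == 0L; i1 <- y == 1L; i2 <- y == 2L

  loglik <- function(theta) {
    eta <- drop(X %*% theta[-(1:2)])
    F1 <- plogis(theta[1L] - eta); F2 <- plogis(theta[2L] - eta)
    pr <- cbind(F1, F2 - F1, 1 - F2)
    pr[pr < 1e-300] <- 1e-300
    sum(log(pr[cbind(seq_len(n), y + 1L)]))
  }

  ll <- loglik(theta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    z1 <- theta[1L]; z2 <- theta[2L]; beta <- theta[-(1:2)]
    eta <- drop(X %*% beta)
    F1 <- plogis(z1 - eta); F2 <- plogis(z2 - eta)
    f1 <- F1 * (1 - F1); f2 <- F2 * (1 - F2)
    p0 <- pmax(F1, 1e-12); p1 <- pmax(F2 - F1, 1e-12); p2 <- pmax(1 - F2, 1e-12)

    ## score in coordinates (z1, z2, eta_i)
    geta <- numeric(n)
    gz1 <- sum(f1[i0] / p0[i0]) - sum(f1[i1] / p1[i1])
    gz2 <- sum(f2[i1] / p1[i1]) - sum(f2[i2] / p2[i2])
    geta[i0] <- -f1[i0] / p0[i0]
    geta[i1] <- (f1[i1] - f2[i1]) / p1[i1]
    geta[i2] <- f2[i2] / p2[i2]
    U <- c(gz1, gz2, drop(crossprod(X, geta)))

    ## expected information: sum_j (dpi_j)(dpi_j)^T / pi_j per observation,
    ## with dpi in (z1, z2, eta): v0 = (f1, 0, -f1), v1 = (-f1, f2, f1 - f2),
    ## v2 = (0, -f2, f2)
    w11 <- f1^2 / p0 + f1^2 / p1
    w12 <- -f1 * f2 / p1
    w22 <- f2^2 / p1 + f2^2 / p2
    w1e <- -f1^2 / p0 - f1 * (f1 - f2) / p1
    w2e <- f2 * (f1 - f2) / p1 - f2^2 / p2
    wee <- f1^2 / p0 + (f1 - f2)^2 / p1 + f2^2 / p2

    I <- matrix(0, p + 2L, p + 2L)
    I[1L, 1L] <- sum(w11); I[1L, 2L] <- I[2L, 1L] <- sum(w12)
    I[2L, 2L] <- sum(w22)
    I[1L, -(1:2)] <- I[-(1:2), 1L] <- drop(crossprod(X, w1e))
    I[2L, -(1:2)] <- I[-(1:2), 2L] <- drop(crossprod(X, w2e))
    I[-(1:2), -(1:2)] <- crossprod(X, X * wee)

    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step)) break
    ## step halving: keep the cutpoints ordered and the likelihood ascending
    lam <- 1
    repeat {
      cand <- theta + lam * step
      if (cand[1L] < cand[2L]) {
        ll_new <- loglik(cand)
        if (ll_new >= ll - 1e-12) break
      }
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta; ll_new <- ll; break }
    }
    moved <- abs(ll_new - ll)
    theta <- cand
    ll_prev <- ll
    ll <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }

  if (!converged) {
    ## derivative-free restart: reparametrize the second cutpoint as
    ## z1 + exp(delta) so ordering is unconstrained
    nll <- function(par) {
      th <- c(par[1L], par[1L] + exp(par[2L]), par[-(1:2)])
      -loglik(th)
    }
    start <- c(theta[1L], log(max(theta[2L] - theta[1L], 1e-3)), theta[-(1:2)])
    opt <- tryCatch(
      stats::optim(start, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value >= ll - 1e-6) {
      theta <- c(opt$par[1L], opt$par[1L] + exp(opt$par[2L]), opt$par[-(1:2)])
      ll <- -opt$value
      converged <- TRUE
    }
  }

  list(zeta = theta[1:2], beta = theta[-(1:2)], loglik = ll,
       loglik_null = sum(counts * log(counts / n)), converged = converged)
}
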