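## Association tests between a phenotype block and one genetic variant.

new_assoc_result <- function(method, statistic = NA_real_, df = NULL,
                             p_value = NA_real_, available = TRUE,
                             detail = NULL, K = NA_integer_) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, available = available,
                 detail = detail, K = K),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("%s: not available (%s)\n", x$method,
                if (is.null(x$detail)) "see detail" else x$detail))
  } else {
    cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n", x$method,
                x$statistic, paste(signif(x$df, 6), collapse = ", "),
                x$p_value))
  }
  invisible(x)
}

#' MANOVA association test of a phenotype block with one variant
#'
#' Multivariate regression of the M' phenotypes on the additively coded
#' genotype (0/1/2). Tests that all M' regression coefficients are zero via
#' Wilks' lambda = det(E) / det(E + H); with a single predictor the exact
#' transform \eqn{F = \frac{1-\Lambda}{\Lambda}\,\frac{N - M' - 1}{M'}} has an
#' F distribution on (M', N - M' - 1) degrees of freedom. (With one
#' predictor all four classical MANOVA statistics coincide.)
#'
#' @param Y Numeric matrix, N x M' phenotypes.
#' @param x Genotype vector of length N.
#' @return An `"assoc_result"`; `available = FALSE` when the genotype is
#'   constant.
#' @export
manova_test <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (length(x) != n) stop("`x` must match rows of `Y`", call. = FALSE)
  if (n <= m + 2) stop("need N > M' + 2", call. = FALSE)
  if (stats::var(x) == 0)
    return(new_assoc_result("manova", available = FALSE,
                            detail = "constant genotype"))
  xc <- x - mean(x)
  Yc <- sweep(Y, 2L, colMeans(Y), `-`)
  sxx <- sum(xc^2)
  bhat <- crossprod(Yc, xc) / sxx           # M' x 1
  H <- tcrossprod(bhat) * sxx
  Tm <- crossprod(Yc)
  E <- Tm - H
  detE <- det(E); detT <- det(Tm)
  if (!is.finite(detE) || !is.finite(detT) || detT <= 0 || detE <= 0) {
    dg <- sqrt(diag(Tm))
    R <- Tm / tcrossprod(dg)
    bad <- colnames(Y)[colSums(abs(R - diag(m)) > 1 - 1e-8) > 1]
    stop("singular phenotype cross-product matrix",
         if (length(bad)) paste0("; collinear phenotypes: ",
                                 paste(bad, collapse = ", ")) else "",
         call. = FALSE)
  }
  lambda <- detE / detT
  Fstat <- (1 - lambda) / lambda * (n - m - 1) / m
  p <- pf(Fstat, m, n - m - 1, lower.tail = FALSE)
  new_assoc_result("manova", statistic = Fstat, df = c(m, n - m - 1),
                   p_value = p, detail = list(wilks_lambda = lambda))
}

#' Reversed-regression (proportional odds) association test
#'
#' The genotype (0/1/2) is modeled as an ordinal response of all M'
#' phenotypes jointly in a proportional-odds logistic regression; the test is
#' the likelihood-ratio statistic \eqn{2(\ell_{full} - \ell_{null})} against
#' the intercepts-only null, referred to a chi-square distribution with M'
#' degrees of freedom.
#'
#' The test is reported unavailable (mirroring the "NA" convention for this
#' method) when the genotype does not take all three values 0, 1, 2, or when
#' the fit does not converge.
#'
#' @inheritParams manova_test
#' @return An `"assoc_result"` with the LRT statistic and the fitted
#'   log-likelihoods in `detail`.
#' @export
multiphen_test <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (length(x) != n) stop("`x` must match rows of `Y`", call. = FALSE)
  if (n <= m + 2) stop("need N > M' + 2", call. = FALSE)
  if (length(unique(x)) < 3L)
    return(new_assoc_result("multiphen", available = FALSE,
                            detail = "genotype does not take all three values 0, 1, 2"))
  fit <- tryCatch(fit_proportional_odds(Y, as.integer(x)),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(new_assoc_result("multiphen", available = FALSE,
                            detail = "proportional-odds fit did not converge"))
  lrt <- 2 * (fit$loglik - fit$loglik_null)
  p <- pchisq(lrt, df = m, lower.tail = FALSE)
  new_assoc_result("multiphen", statistic = lrt, df = m, p_value = p,
                   detail = list(loglik = fit$loglik,
                                 loglik_null = fit$loglik_null,
                                 beta = fit$beta))
}

#' Per-phenotype univariate association p-values
#'
#' Simple linear regression of each phenotype on the additively coded
#' genotype; two-sided t-test of the slope, computed in closed form from the
#' phenotype-genotype correlation r via
#' \eqn{t = r\sqrt{(N-2)/(1-r^2)}} on N - 2 degrees of freedom.
#'
#' @inheritParams manova_test
#' @return Numeric vector of M' p-values.
#' @export
univariate_pvalues <- function(Y, x) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (length(x) != n) stop("`x` must match rows of `Y`", call. = FALSE)
  if (stats::var(x) == 0) stop("constant genotype", call. = FALSE)
  r <- drop(cor(Y, x))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

## Coefficients of the shipped map from phenotype correlation to the
## correlation of the two univariate association p-values: a monotone odd
## polynomial g(|r|) = a1|r| + a3|r|^3 + a5|r|^5 + a7|r|^7 with g(1) = 1
## enforced.  Produced by calibrate_pvalue_correlation(); regenerate with
## that function if the calibration scheme changes.
.pcorr_coef <- c(0.081959534513, 1.211983496682, -1.027347430702,
                 0.733404399508)

#' Map phenotype correlations to univariate p-value correlations
#'
#' Under the null, the univariate association z-statistics of two phenotypes
#' with correlation r against the same variant are (asymptotically)
#' bivariate normal with correlation r; the correlation of the resulting
#' two-sided p-values is a smooth even function of r. This map is shipped as
#' a monotone odd polynomial in |r| calibrated by simulation
#' (see [calibrate_pvalue_correlation()]); it is applied elementwise to turn
#' a phenotype correlation matrix into the p-value correlation matrix used
#' for the effective number of tests.
#'
#' @param pheno_corr M' x M' phenotype correlation matrix.
#' @return M' x M' p-value correlation matrix with unit diagonal, entries
#'   clipped to `[0, 1]`.
#' @export
pvalue_correlation <- function(pheno_corr) {
  R <- as.matrix(pheno_corr)
  a <- abs(R)
  out <- .pcorr_coef[1] * a + .pcorr_coef[2] * a^3 +
    .pcorr_coef[3] * a^5 + .pcorr_coef[4] * a^7
  out <- pmin(pmax(out, 0), 1)
  out[a >= 1 - 1e-12] <- 1
  diag(out) <- 1
  out
}

#' Recalibrate the p-value correlation map
#'
#' Simulates, for each grid value of the phenotype correlation r, a large
#' number of null bivariate-normal association z-score pairs with
#' correlation r, converts them to two-sided p-values, and records the
#' sample correlation of the p-value pairs. A polynomial
#' a1|r| + a3|r|^3 + a5|r|^5 + a7|r|^7 is then least-squares fitted with the
#' endpoint constraint g(1) = 1 (g(0) = 0 holds by construction).
#'
#' This is a maintenance utility: the package ships the frozen coefficients
#' used by [pvalue_correlation()].
#'
#' @param grid Grid of correlations in `[0, 1]`.
#' @param n_draws Monte Carlo draws per grid point (>= 1e5 recommended).
#' @param seed Optional seed.
#' @return Named numeric vector of the four coefficients, with the grid
#'   estimates in attribute `calibration`.
#' @export
calibrate_pvalue_correlation <- function(grid = seq(0, 1, by = 0.1),
                                         n_draws = 2e5, seed = NULL) {
  est <- with_seed(seed, vapply(grid, function(r) {
    z1 <- rnorm(n_draws)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_draws)
    cor(2 * pnorm(-abs(z1)), 2 * pnorm(-abs(z2)))
  }, numeric(1)))
  ## substitute a7 = 1 - a1 - a3 - a5 to enforce g(1) = 1
  X <- cbind(grid - grid^7, grid^3 - grid^7, grid^5 - grid^7)
  a <- qr.solve(X, est - grid^7)
  coefs <- c(a1 = a[1], a3 = a[2], a5 = a[3], a7 = 1 - sum(a))
  structure(coefs, calibration = data.frame(r = grid, pcorr = est))
}

#' Effective number of independent tests from a correlation matrix
#'
#' The eigenvalue-excess form: \eqn{M_e = M' - \sum_{\lambda_i > 1}
#' (\lambda_i - 1)} over the eigenvalues of the correlation matrix. When an
#' ordering of the variables is supplied (e.g. by ascending univariate
#' p-value), the partial effective numbers \eqn{M_e(j)} are computed the same
#' way on the leading j x j submatrix of the reordered matrix.
#'
#' @param corr Correlation matrix.
#' @param order Optional permutation of `1:M'` giving the variable ordering
#'   for the partial numbers (defaults to the given order).
#' @return List with `me_total` and the length-M' vector `me_partial`.
#' @export
effective_number <- function(corr, order = NULL) {
  R <- as.matrix(corr)
  m <- nrow(R)
  if (is.null(order)) order <- seq_len(m)
  R <- R[order, order, drop = FALSE]
  me_of <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    nrow(S) - sum(pmax(ev - 1, 0))
  }
  me_partial <- vapply(seq_len(m), function(j)
    if (j == 1L) 1 else me_of(R[seq_len(j), seq_len(j), drop = FALSE]),
    numeric(1))
  list(me_total = me_partial[m], me_partial = me_partial)
}

#' Extended-Simes combination of univariate p-values
#'
#' Sorts the per-phenotype univariate p-values ascending and reports
#' \eqn{p = \min_j M_e\,p_{(j)} / M_e(j)} (capped at 1), where the effective
#' numbers \eqn{M_e} and \eqn{M_e(j)} are computed from the p-value
#' correlation matrix derived from the phenotype correlations
#' ([pvalue_correlation()], [effective_number()]). With mutually independent
#' phenotypes this reduces exactly to Simes' rule; with fully duplicated
#' phenotypes it collapses to the single univariate p-value.
#'
#' @inheritParams manova_test
#' @return An `"assoc_result"`; `detail` carries the sorted univariate
#'   p-values and the effective numbers.
#' @export
tates_test <- function(Y, x) {
  Y <- as.matrix(Y)
  if (stats::var(x) == 0)
    return(new_assoc_result("tates", available = FALSE,
                            detail = "constant genotype"))
  p_uni <- univariate_pvalues(Y, x)
  m <- ncol(Y)
  if (m == 1L)
    return(new_assoc_result("tates", statistic = p_uni, df = 1,
                            p_value = p_uni,
                            detail = list(p_sorted = p_uni, me_total = 1)))
  ord <- order(p_uni)
  pc <- pvalue_correlation(cor(Y))
  me <- effective_number(pc, order = ord)
  p_sorted <- p_uni[ord]
  p_tates <- min(1, min(me$me_total * p_sorted / me$me_partial))
  new_assoc_result("tates", statistic = p_tates, df = me$me_total,
                   p_value = p_tates,
                   detail = list(p_sorted = p_sorted,
                                 me_total = me$me_total,
                                 me_partial = me$me_partial))
}

#' Run an association test with optional phenotype clustering
#'
#' The two-step pipeline: standardize the phenotypes; if a clustering scheme
#' is requested, build the dendrogram ([agglomerate()]), choose the number of
#' clusters by the largest-height-drop rule ([choose_k()]), cut, and form the
#' representative phenotypes (within-cluster means); then apply the requested
#' test to the representative (or, with `clustering = "none"`, the scaled
#' original) phenotypes. The nine method combinations are the 3 x 3 grid of
#' test and clustering scheme.
#'
#' @param method `"manova"`, `"multiphen"`, or `"tates"`.
#' @param clustering `"none"`, `"hcm"`, or `"hcdc"`.
#' @param Y Raw phenotype matrix, N x M.
#' @param x Genotype vector.
#' @param K Optional manual override of the number of clusters.
#' @param abs_pearson Passed to [agglomerate()] for the HCDC scheme.
#' @return An `"assoc_result"` whose `K` field records the number of
#'   phenotypes actually tested.
#' @examples
#' cfg <- build_model_config(2, M = 16, beta = 0.2, c2 = 0.5, rho_c2 = 0.1)
#' x <- simulate_genotypes(1000, 0.3, seed = 1)
#' Y <- simulate_phenotypes(cfg, x, seed = 2)
#' run_method("manova", "hcdc", Y, x)
#' @export
run_method <- function(method = c("manova", "multiphen", "tates"),
                       clustering = c("none", "hcm", "hcdc"),
                       Y, x, K = NULL, abs_pearson = FALSE) {
  method <- match.arg(method)
  clustering <- match.arg(clustering)
  Y <- as.matrix(Y)
  Ys <- if (is_scaled(Y)) Y else scale_phenotypes(Y)
  if (clustering == "none") {
    Yt <- Ys
    Kt <- ncol(Ys)
  } else {
    dend <- agglomerate(Ys, method = clustering, abs_pearson = abs_pearson)
    Kt <- if (is.null(K)) choose_k(dend) else as.integer(K)
    part <- cut_dendrogram(dend, Kt)
    Yt <- representative_phenotypes(Ys, part)
  }
  test <- switch(method, manova = manova_test, multiphen = multiphen_test,
                 tates = tates_test)
  res <- test(Yt, x)
  res$K <- as.integer(Kt)
  res$method <- if (clustering == "none") method else
    paste(clustering, method, sep = "_")
  res
}
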