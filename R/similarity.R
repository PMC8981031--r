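## Between-cluster similarity measures.
##
## The size-dependent scheme uses three correlation coefficients, chosen by
## the sizes (M1, M2) of the two disjoint phenotype clusters:
##   1 vs 1   -> Pearson correlation,
##   1 vs >1  -> multiple correlation (singleton regressed on the group),
##   >1 vs >1 -> first canonical correlation.
## All three depend on the data only through the phenotype correlation
## matrix, so internal kernels operate on correlation submatrices; the
## exported functions accept raw data columns.

#' Pearson correlation between two phenotypes
#'
#' @param y1,y2 Numeric vectors of equal length >= 3, neither constant.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("`y1` and `y2` must have equal length",
                                     call. = FALSE)
  if (length(y1) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(y1) == 0 || sd(y2) == 0)
    stop("constant input: Pearson correlation undefined", call. = FALSE)
  cor(y1, y2)
}

## kernel: squared multiple correlation of variable `yi` on variables `gi`,
## from a correlation (or covariance) matrix C. Falls back to a pseudoinverse
## when the predictor block is numerically singular.
mcor2_from_corr <- function(C, yi, gi) {
  s <- C[gi, yi, drop = FALSE]
  Cgg <- C[gi, gi, drop = FALSE]
  r2 <- tryCatch(drop(crossprod(s, solve(Cgg, s))) / C[yi, yi],
                 error = function(e) NA_real_)
  warned <- FALSE
  if (is.na(r2) || !is.finite(r2)) {
    warned <- TRUE
    sv <- svd(Cgg)
    pos <- sv$d > max(sv$d) * 1e-10
    pinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    r2 <- drop(crossprod(s, pinv %*% s)) / C[yi, yi]
  }
  structure(min(1, max(0, r2)), degenerate = warned)
}

## kernel: first canonical correlation between variable sets g1 and g2 from a
## correlation (or covariance) matrix C. Collinear columns within a block are
## dropped before the eigen solve.
ccor_from_corr <- function(C, g1, g2) {
  drop_collinear <- function(g) {
    B <- C[g, g, drop = FALSE]
    qrB <- qr(B)
    if (qrB$rank < length(g)) g[qrB$pivot[seq_len(qrB$rank)]] else g
  }
  warned <- length(drop_collinear(g1)) < length(g1) ||
    length(drop_collinear(g2)) < length(g2)
  g1 <- drop_collinear(g1); g2 <- drop_collinear(g2)
  C11 <- C[g1, g1, drop = FALSE]
  C22 <- C[g2, g2, drop = FALSE]
  C12 <- C[g1, g2, drop = FALSE]
  K <- solve(C11, C12) %*% solve(C22, t(C12))
  ev <- eigen(K, only.values = TRUE)$values
  rho2 <- max(Re(ev))
  structure(sqrt(min(1, max(0, rho2))), degenerate = warned)
}

#' Multiple correlation of one phenotype with a group of phenotypes
#'
#' The square root of the coefficient of determination from the least-squares
#' projection of `y` onto an intercept plus the columns of `group`. Used as
#' the between-cluster similarity when one cluster is a singleton.
#'
#' @param y Numeric vector (the singleton phenotype).
#' @param group Numeric matrix, n x k, the phenotypes of the other cluster.
#' @return Multiple correlation R in `[0, 1]`. A rank-deficient `group` is
#'   handled by a pseudoinverse and flagged via attribute `degenerate`.
#' @export
multiple_correlation <- function(y, group) {
  group <- as.matrix(group)
  n <- length(y)
  if (nrow(group) != n) stop("`y` and `group` must have matching rows",
                             call. = FALSE)
  if (n <= ncol(group) + 1)
    stop("need n > k + 1 observations", call. = FALSE)
  C <- stats::cov(cbind(y, group))
  r2 <- mcor2_from_corr(C, 1L, 1L + seq_len(ncol(group)))
  structure(sqrt(r2), degenerate = attr(r2, "degenerate"))
}

#' First canonical correlation between two groups of phenotypes
#'
#' Largest canonical correlation, i.e. the square root of the largest
#' eigenvalue of \eqn{\Sigma_{11}^{-1}\Sigma_{12}\Sigma_{22}^{-1}\Sigma_{21}}
#' formed from the sample covariance blocks. Used as the between-cluster
#' similarity when both clusters contain more than one phenotype.
#'
#' @param group1,group2 Numeric matrices with the same number of rows.
#' @return First canonical correlation in `[0, 1]`, clipped against
#'   floating-point overshoot; rank deficiency within a block drops the
#'   collinear columns and sets attribute `degenerate`.
#' @export
canonical_correlation <- function(group1, group2) {
  group1 <- as.matrix(group1); group2 <- as.matrix(group2)
  n <- nrow(group1)
  if (nrow(group2) != n) stop("groups must have matching rows", call. = FALSE)
  if (n <= ncol(group1) + ncol(group2) + 1)
    stop("need n > k1 + k2 + 1 observations", call. = FALSE)
  C <- stats::cov(cbind(group1, group2))
  ccor_from_corr(C, seq_len(ncol(group1)),
                 ncol(group1) + seq_len(ncol(group2)))
}

#' Size-dependent similarity between two disjoint phenotype clusters
#'
#' Dispatches on the cluster sizes: Pearson correlation for two singletons,
#' multiple correlation when exactly one cluster is a singleton (the
#' singleton is the regression response), and the first canonical
#' correlation when both clusters contain several phenotypes. Symmetric in
#' its two index sets.
#'
#' @param g1,g2 Integer vectors of column indices into `Y`; must be disjoint.
#' @param Y Phenotype matrix (standardization does not change the value).
#' @param abs_pearson If `TRUE`, the singleton-singleton rule returns the
#'   absolute Pearson correlation, making it comparable with the two
#'   intrinsically nonnegative rules. Default `FALSE` (signed).
#' @return Similarity value; in `[-1, 1]` for two singletons (signed rule),
#'   otherwise in `[0, 1]`.
#' @export
hcdc_similarity <- function(g1, g2, Y, abs_pearson = FALSE) {
  if (length(intersect(g1, g2)) > 0)
    stop("clusters must be disjoint", call. = FALSE)
  if (length(g1) < 1 || length(g2) < 1)
    stop("clusters must be non-empty", call. = FALSE)
  S <- cor(Y[, sort(unique(c(g1, g2))), drop = FALSE])
  idx <- sort(unique(c(g1, g2)))
  i1 <- match(g1, idx); i2 <- match(g2, idx)
  hcdc_similarity_corr(S, i1, i2, abs_pearson = abs_pearson)
}

## kernel form on a precomputed phenotype correlation matrix
hcdc_similarity_corr <- function(S, g1, g2, abs_pearson = FALSE) {
  m1 <- length(g1); m2 <- length(g2)
  if (m1 == 1L && m2 == 1L) {
    r <- S[g1, g2]
    if (abs_pearson) abs(r) else r
  } else if (m1 == 1L) {
    as.numeric(sqrt(mcor2_from_corr(S, g1, g2)))
  } else if (m2 == 1L) {
    as.numeric(sqrt(mcor2_from_corr(S, g2, g1)))
  } else {
    as.numeric(ccor_from_corr(S, g1, g2))
  }
}

#' Average-linkage similarity between two clusters
#'
#' The uniform competitor rule: the arithmetic mean of the cross-cluster
#' entries of the phenotype correlation matrix, regardless of cluster sizes.
#'
#' @param g1,g2 Disjoint integer index sets.
#' @param S M x M phenotype correlation matrix.
#' @return Mean of the `length(g1) * length(g2)` cross entries of `S`.
#' @export
hcm_similarity <- function(g1, g2, S) {
  if (length(intersect(g1, g2)) > 0)
    stop("clusters must be disjoint", call. = FALSE)
  mean(S[g1, g2])
}
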