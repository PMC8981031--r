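#' Simulate genotypes at a single variant under Hardy-Weinberg equilibrium
#'
#' Minor-allele counts for `n` unrelated individuals are drawn independently
#' from Binomial(2, `maf`), the genotype distribution implied by
#' Hardy-Weinberg equilibrium at a biallelic variant.
#'
#' @param n Number of individuals (>= 2).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return Integer vector of length `n` with entries in {0, 1, 2} and
#'   attribute `maf`.
#' @examples
#' x <- simulate_genotypes(2000, maf = 0.3, seed = 1)
#' table(x)
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf <= 0 || maf > 0.5)
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  x <- with_seed(seed, rbinom(as.integer(n), 2L, maf))
  structure(as.integer(x), maf = maf)
}

#' Build a factor-model configuration for phenotype simulation
#'
#' Constructs the effect vector `lambda`, factor-loading matrix `gamma`, and
#' variance-scaling diagonal `d` of the factor model
#' \deqn{y = \lambda x + d\,c\,\gamma f + d\sqrt{1-c^2}\,\varepsilon,}
#' where \eqn{f \sim MVN(0, (1-\rho)I + \rho 1 1^T)} and \eqn{\varepsilon} is
#' standard normal, for one of four canned designs:
#'
#' * **Model 1** - one factor loading on all phenotypes; the variant affects
#'   every phenotype equally: R = 1, lambda = beta * 1.
#' * **Model 2** - two equal factor blocks; the variant affects only the
#'   second block: R = 2, lambda = (0, ..., 0, beta, ..., beta).
#' * **Model 3** - four factor blocks with mixed-sign loadings
#'   (3M/16 entries at +1 then M/16 at -1 per block); the variant affects the
#'   last two blocks with opposing directions, and `d` tiles
#'   (8/M) * (1, ..., M/4) so phenotype variances differ within a block.
#' * **Model 4** - as Model 3 but the second block loads uniformly (+1) and
#'   carries a linearly increasing effect (2 beta / (M/4 + 1)) * (1, ..., M/4),
#'   whose mean is exactly beta; the variant affects the last three blocks.
#'
#' The within-factor phenotypic correlation is `c2` and the between-factor
#' correlation is `rho_c2`, achieved by setting the factor correlation to
#' `rho = rho_c2 / c2` (taken as 0 when both are 0).
#'
#' @param model_id One of 1, 2, 3, 4.
#' @param M Number of phenotypes. Model 2 requires `M` even; Models 3 and 4
#'   require `M` divisible by 16.
#' @param beta Genetic effect size (0 under the null).
#' @param c2 Within-factor correlation, in `[0, 1)`.
#' @param rho_c2 Between-factor correlation, in `[0, c2]`.
#' @return An object of class `"factor_model_config"`: a list with elements
#'   `model_id`, `M`, `R`, `beta`, `c2`, `rho_c2`, `rho`, `lambda`, `gamma`
#'   (M x R), and `d` (length M).
#' @examples
#' cfg <- build_model_config(2, M = 16, beta = 0.1, c2 = 0.5, rho_c2 = 0.1)
#' cfg$lambda
#' @export
build_model_config <- function(model_id, M, beta, c2 = 0.5, rho_c2 = 0.1) {
  if (!model_id %in% 1:4) stop("`model_id` must be 1, 2, 3 or 4", call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("`M` must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  if (model_id == 2 && M %% 2L != 0L)
    stop("Model 2 requires an even number of phenotypes M", call. = FALSE)
  if (model_id %in% 3:4 && M %% 16L != 0L)
    stop(sprintf("Model %d requires M divisible by 16", model_id), call. = FALSE)
  if (!is.numeric(c2) || c2 < 0 || c2 >= 1)
    stop("`c2` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(rho_c2) || rho_c2 < 0 || rho_c2 > c2)
    stop("`rho_c2` must lie in [0, c2]", call. = FALSE)
  rho <- if (c2 == 0) 0 else rho_c2 / c2
  if (rho >= 1) stop("implied factor correlation rho = rho_c2/c2 must be < 1",
                     call. = FALSE)

  mixed_block <- function(m) c(rep(1, 3 * m / 4), rep(-1, m / 4)) # length m
  bdiag_cols <- function(blocks) {
    R <- length(blocks)
    g <- matrix(0, sum(lengths(blocks)), R)
    at <- 0L
    for (r in seq_len(R)) {
      g[at + seq_along(blocks[[r]]), r] <- blocks[[r]]
      at <- at + length(blocks[[r]])
    }
    g
  }

  if (model_id == 1L) {
    R <- 1L
    lambda <- rep(beta, M)
    gamma <- matrix(1, M, 1L)
    d <- rep(1, M)
  } else if (model_id == 2L) {
    R <- 2L
    half <- M %/% 2L
    lambda <- c(rep(0, half), rep(beta, half))
    gamma <- bdiag_cols(list(rep(1, half), rep(1, half)))
    d <- rep(1, M)
  } else if (model_id == 3L) {
    R <- 4L
    q <- M %/% 4L
    blk <- mixed_block(q)
    lambda <- c(rep(0, M / 2), rep(-beta, 3 * M / 16), rep(beta, M / 4),
                rep(-beta, M / 16))
    gamma <- bdiag_cols(rep(list(blk), 4L))
    d <- rep((8 / M) * seq_len(q), 4L)
  } else {
    R <- 4L
    q <- M %/% 4L
    blk <- mixed_block(q)
    lambda <- c(rep(0, q), (2 * beta / (q + 1)) * seq_len(q),
                rep(-beta, 3 * M / 16), rep(beta, M / 4), rep(-beta, M / 16))
    gamma <- bdiag_cols(list(blk, rep(1, q), blk, blk))
    d <- rep((8 / M) * seq_len(q), 4L)
  }
  structure(
    list(model_id = as.integer(model_id), M = M, R = R, beta = beta,
         c2 = c2, rho_c2 = rho_c2, rho = rho,
         lambda = lambda, gamma = gamma, d = d),
    class = "factor_model_config")
}

#' @export
print.factor_model_config <- function(x, ...) {
  cat(sprintf("Factor model %d: M = %d phenotypes, R = %d factor(s)\n",
              x$model_id, x$M, x$R))
  cat(sprintf("  beta = %g, c2 = %g, rho*c2 = %g (rho = %g)\n",
              x$beta, x$c2, x$rho_c2, x$rho))
  invisible(x)
}

#' Simulate multi-phenotype data from a factor-model configuration
#'
#' For each individual i, the M phenotypes are
#' \eqn{y_i = \lambda x_i + d\,c\,\gamma f_i + d\sqrt{1-c^2}\,\varepsilon_i}
#' with an independent factor vector \eqn{f_i \sim MVN(0,(1-\rho)I+\rho11^T)}
#' and independent standard-normal errors. The compound-symmetric factor
#' vector is generated as \eqn{f = \sqrt{\rho}\,u\,1 + \sqrt{1-\rho}\,z} with
#' scalar u and i.i.d. z. Output phenotypes are unscaled.
#'
#' @param config A `"factor_model_config"` from [build_model_config()].
#' @param x Genotype vector (minor-allele counts) of length N.
#' @param seed Optional integer seed (local to this call).
#' @return N x M numeric matrix with column names `P1 ... PM` and attribute
#'   `scaled = FALSE`.
#' @examples
#' cfg <- build_model_config(1, M = 4, beta = 0, c2 = 0.5, rho_c2 = 0.1)
#' Y <- simulate_phenotypes(cfg, simulate_genotypes(500, 0.3, seed = 1), seed = 2)
#' round(cor(Y), 2)
#' @export
simulate_phenotypes <- function(config, x, seed = NULL) {
  if (!inherits(config, "factor_model_config"))
    stop("`config` must come from build_model_config()", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  M <- config$M; R <- config$R
  cc <- sqrt(config$c2)
  Y <- with_seed(seed, {
    u <- rnorm(n)
    Z <- matrix(rnorm(n * R), n, R)
    f <- sqrt(config$rho) * u + sqrt(1 - config$rho) * Z
    E <- matrix(rnorm(n * M), n, M)
    latent <- f %*% t(config$gamma) * cc + E * sqrt(1 - config$c2)
    outer(as.numeric(x), config$lambda) +
      sweep(latent, 2L, config$d, `*`)
  })
  colnames(Y) <- paste0("P", seq_len(M))
  attr(Y, "scaled") <- FALSE
  Y
}

#' Standardize each phenotype to mean 0 and unit sample standard deviation
#'
#' Column-wise z-scoring with the sample (n-1) standard deviation. Every
#' phenotype must be standardized before representative phenotypes (cluster
#' means) are formed, so that each trait contributes on a common scale.
#'
#' @param Y Numeric matrix (individuals x phenotypes).
#' @return Matrix of the same shape with attribute `scaled = TRUE`.
#' @examples
#' scale_phenotypes(cbind(a = c(1, 2, 3)))
#' @export
scale_phenotypes <- function(Y) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("phenotype matrix contains missing values", call. = FALSE)
  s <- apply(Y, 2L, sd)
  if (any(s == 0)) {
    bad <- colnames(Y)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("constant phenotype column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Z <- sweep(sweep(Y, 2L, colMeans(Y), `-`), 2L, s, `/`)
  attr(Z, "scaled") <- TRUE
  Z
}

## internal: TRUE when columns are (numerically) mean 0, sd 1
is_scaled <- function(Y) {
  isTRUE(attr(Y, "scaled")) ||
    (max(abs(colMeans(Y))) < 1e-8 && max(abs(apply(Y, 2L, sd) - 1)) < 1e-6)
}
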