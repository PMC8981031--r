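## Monte Carlo harness: type-I error and power of the nine method cells.

default_cells <- function() {
  expand.grid(method = c("manova", "multiphen", "tates"),
              clustering = c("none", "hcm", "hcdc"),
              stringsAsFactors = FALSE)
}

cell_labels <- function(cells) {
  ifelse(cells$clustering == "none", cells$method,
         paste(cells$clustering, cells$method, sep = "_"))
}

#' Normal-approximation Monte Carlo confidence band for a rejection rate
#'
#' The band \eqn{\alpha \pm z_{(1+level)/2}\sqrt{\alpha(1-\alpha)/n}} within
#' which an empirical type-I error estimate from `n_reps` replicates is
#' expected to fall when the true rate equals the nominal level. At 10,000
#' replicates the 95% bands for nominal 0.05 and 0.01 are (0.0457, 0.0543)
#' and (0.008, 0.012) after rounding.
#'
#' @param alpha_nominal Nominal level in (0, 1).
#' @param n_reps Number of Monte Carlo replicates.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' round(mc_confidence_interval(0.05, 10000), 4)
#' @export
mc_confidence_interval <- function(alpha_nominal, n_reps, level = 0.95) {
  if (alpha_nominal <= 0 || alpha_nominal >= 1)
    stop("`alpha_nominal` must lie in (0, 1)", call. = FALSE)
  if (n_reps <= 0) stop("`n_reps` must be positive", call. = FALSE)
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(alpha_nominal * (1 - alpha_nominal) / n_reps)
  c(lower = alpha_nominal - half, upper = alpha_nominal + half)
}

## internal engine: one simulated dataset per replicate, evaluated by every
## requested cell, so method comparisons are paired. Returns an n_reps x
## n_cells matrix of p-values (NA where a cell was unavailable).
run_simulation_grid <- function(model_id, N, M, beta, c2, rho_c2, maf,
                                n_reps, cells = default_cells(),
                                master_seed = 1L, abs_pearson = FALSE) {
  cfg <- build_model_config(model_id, M, beta, c2, rho_c2)
  labels <- cell_labels(cells)
  seeds <- spawn_seeds(master_seed, 2L * n_reps)
  P <- matrix(NA_real_, n_reps, nrow(cells), dimnames = list(NULL, labels))
  need <- unique(cells$clustering)
  for (r in seq_len(n_reps)) {
    x <- simulate_genotypes(N, maf, seed = seeds[2L * r - 1L])
    Y <- simulate_phenotypes(cfg, x, seed = seeds[2L * r])
    Ys <- scale_phenotypes(Y)
    blocks <- list(none = Ys)
    for (cl in setdiff(need, "none")) {
      dend <- agglomerate(Ys, method = cl, abs_pearson = abs_pearson)
      part <- cut_dendrogram(dend, choose_k(dend))
      blocks[[cl]] <- representative_phenotypes(Ys, part)
    }
    for (i in seq_len(nrow(cells))) {
      Yt <- blocks[[cells$clustering[i]]]
      res <- switch(cells$method[i],
                    manova = manova_test(Yt, x),
                    multiphen = multiphen_test(Yt, x),
                    tates = tates_test(Yt, x))
      P[r, i] <- if (res$available) res$p_value else NA_real_
    }
  }
  P
}

summarize_rates <- function(P, alphas, settings) {
  labels <- colnames(P)
  rows <- do.call(rbind, lapply(seq_along(labels), function(i) {
    ok <- !is.na(P[, i])
    n_eff <- sum(ok)
    do.call(rbind, lapply(alphas, function(a) {
      ci <- mc_confidence_interval(min(max(a, 1e-12), 1 - 1e-12), max(n_eff, 1))
      data.frame(cell = labels[i], alpha = a,
                 rate = mean(P[ok, i] < a),
                 n_eff = n_eff, n_unavailable = sum(!ok),
                 ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(rates = rows, settings = settings, pvalues = P),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Simulation summary: model %d, N = %d, M = %d, beta = %g, c2 = %g, rho*c2 = %g, MAF = %g, %d replicates\n",
              s$model_id, s$N, s$M, s$beta, s$c2, s$rho_c2, s$maf, s$n_reps))
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Estimate type-I error rates of the method grid by simulation
#'
#' Generates `n_reps` null datasets (genetic effect forced to zero) under the
#' chosen factor model, runs every requested method/clustering cell on the
#' same data per replicate, and reports rejection proportions at each nominal
#' level together with the matching Monte Carlo confidence band. Replicates
#' where a cell is unavailable (e.g. a genotype class missing for the
#' reversed ordinal regression) are excluded from that cell's denominator and
#' counted.
#'
#' @param model_id,N,M,c2,rho_c2,maf Simulation design; see
#'   [build_model_config()] and [simulate_genotypes()].
#' @param n_reps Number of replicates.
#' @param alphas Nominal levels at which rejection is tallied.
#' @param cells Data frame with columns `method` and `clustering`
#'   (default: the full 3 x 3 grid).
#' @param master_seed Integer seed; each replicate draws its own derived
#'   seeds so the run is fully reproducible.
#' @param abs_pearson Passed to the HCDC similarity rule.
#' @return A `"simulation_summary"`: rejection rates (`$rates`), the
#'   per-replicate p-values (`$pvalues`), and the echoed settings.
#' @export
estimate_type1 <- function(model_id, N = 2000, M = 16, c2 = 0.5,
                           rho_c2 = 0.1, maf = 0.3, n_reps = 2000,
                           alphas = c(0.01, 0.05), cells = default_cells(),
                           master_seed = 1L, abs_pearson = FALSE) {
  P <- run_simulation_grid(model_id, N, M, beta = 0, c2 = c2,
                           rho_c2 = rho_c2, maf = maf, n_reps = n_reps,
                           cells = cells, master_seed = master_seed,
                           abs_pearson = abs_pearson)
  summarize_rates(P, alphas,
                  list(model_id = model_id, N = N, M = M, beta = 0, c2 = c2,
                       rho_c2 = rho_c2, maf = maf, n_reps = n_reps,
                       master_seed = master_seed))
}

#' Estimate power of the method grid over a grid of effects or correlations
#'
#' One `"simulation_summary"` per grid point; within each replicate all cells
#' share the same dataset. Exactly one of `beta_grid` or `c2_grid` should
#' have length > 1; scalar settings are recycled.
#'
#' @inheritParams estimate_type1
#' @param beta_grid Genetic effect sizes (> 0 for power).
#' @param c2_grid Within-factor correlations.
#' @param alpha Significance level at which power is tallied.
#' @return List of `"simulation_summary"` objects, one per grid point, named
#'   by the varying parameter.
#' @export
estimate_power <- function(model_id, N = 2000, M = 16, beta_grid = 0.1,
                           c2_grid = 0.5, rho_c2 = 0.1, maf = 0.3,
                           n_reps = 400, alpha = 0.05,
                           cells = default_cells(), master_seed = 1L,
                           abs_pearson = FALSE) {
  grid <- expand.grid(beta = beta_grid, c2 = c2_grid)
  seeds <- spawn_seeds(master_seed, nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    P <- run_simulation_grid(model_id, N, M, beta = grid$beta[i],
                             c2 = grid$c2[i], rho_c2 = rho_c2, maf = maf,
                             n_reps = n_reps, cells = cells,
                             master_seed = seeds[i],
                             abs_pearson = abs_pearson)
    summarize_rates(P, alpha,
                    list(model_id = model_id, N = N, M = M,
                         beta = grid$beta[i], c2 = grid$c2[i],
                         rho_c2 = rho_c2, maf = maf, n_reps = n_reps,
                         master_seed = seeds[i]))
  })
  names(out) <- if (length(unique(grid$beta)) > 1)
    paste0("beta=", grid$beta) else paste0("c2=", grid$c2)
  out
}
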