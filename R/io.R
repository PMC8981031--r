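## File input/output, covariate adjustment, and the end-to-end pipeline.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a phenotype, genotype, or covariate matrix from delimited text
#'
#' Accepts tab- or comma-delimited files with a header row whose first column
#' holds the individual id. Genotype files may also use the PLINK `.raw`
#' dialect (columns `FID IID PAT MAT SEX PHENOTYPE` followed by per-variant
#' dosages; `IID` is taken as the id). Rows with any missing value among the
#' data columns are dropped (complete-case handling) with a message giving
#' the count.
#'
#' @param path File path.
#' @param kind One of `"pheno"`, `"geno"`, `"covar"`.
#' @return Numeric matrix with ids as row names. Categorical covariate
#'   columns are dummy-coded against their first level.
#' @export
read_matrix <- function(path, kind = c("pheno", "geno", "covar")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(df) < 2) stop("expected an id column plus data columns in ", path,
                         call. = FALSE)
  plink_raw <- identical(toupper(names(df)[1:2]), c("FID", "IID")) &&
    ncol(df) >= 7 && all(toupper(names(df)[3:6]) == c("PAT", "MAT", "SEX",
                                                      "PHENOTYPE"))
  if (kind == "geno" && plink_raw) {
    ids <- as.character(df[[2L]])
    dat <- df[, -(1:6), drop = FALSE]
  } else {
    ids <- as.character(df[[1L]])
    dat <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1L]
    stop(sprintf("duplicate id '%s' at data line %d of %s", ids[dup], dup,
                 path), call. = FALSE)
  }
  if (kind == "covar") {
    ## dummy-code character/factor covariates against the first level
    is_cat <- vapply(dat, function(col) is.character(col) || is.factor(col),
                     logical(1))
    if (any(is_cat)) {
      ## fit with intercept then drop it, so every factor loses its first
      ## (reference) level
      mm <- stats::model.matrix(
        ~ ., data = as.data.frame(lapply(dat, function(col) {
          if (is.character(col)) factor(col) else col
        })))[, -1L, drop = FALSE]
      dat <- as.data.frame(mm)
    }
  }
  non_num <- !vapply(dat, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric data column(s) in ", path, ": ",
         paste(names(dat)[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(dat)
  keep <- complete.cases(m)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values dropped from ", path)
  m <- m[keep, , drop = FALSE]
  rownames(m) <- ids[keep]
  m
}

#' Write a matrix as tab-delimited text with an id column
#'
#' @param x Matrix with row names (ids).
#' @param path Output file.
#' @param id_name Name of the id column header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjust phenotypes for covariates and restandardize
#'
#' Each phenotype is replaced by its least-squares residual from a linear
#' regression on an intercept plus the covariate columns, then standardized
#' with [scale_phenotypes()].
#'
#' @param Y Phenotype matrix, N x M.
#' @param C Covariate matrix, N x C (continuous or dummy-coded), row-aligned
#'   with `Y`.
#' @return Scaled residual phenotype matrix.
#' @export
residualize <- function(Y, C) {
  Y <- as.matrix(Y); C <- as.matrix(C)
  if (nrow(Y) != nrow(C)) stop("`Y` and `C` must have matching rows",
                               call. = FALSE)
  X <- cbind(`(Intercept)` = 1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res <- qr.resid(qx, Y)
  dimnames(res) <- dimnames(Y)
  sds <- apply(res, 2, sd)
  ref <- pmax(apply(Y, 2, sd), 1)
  dead <- sds < 1e-10 * ref
  if (any(dead))
    stop("phenotype(s) constant after covariate adjustment: ",
         paste(colnames(Y)[dead], collapse = ", "), call. = FALSE)
  scale_phenotypes(res)
}

#' Run the full two-step association pipeline from files
#'
#' Reads the phenotype, genotype, and optional covariate files, aligns rows
#' on id (dropping individuals absent from any file), adjusts for covariates
#' if given, standardizes, clusters the phenotypes once if requested, and
#' then tests every genotype column with every requested method. Results and
#' a log (seed, chosen K, cluster memberships, dendrogram) are written next
#' to `out_prefix`.
#'
#' @param pheno,geno Paths of the phenotype and genotype files
#'   (see [read_matrix()]).
#' @param covar Optional covariate file path.
#' @param methods Character vector from `c("manova", "multiphen", "tates")`.
#' @param clustering `"none"`, `"hcm"`, or `"hcdc"`.
#' @param K Optional manual number of clusters.
#' @param abs_pearson Passed to the HCDC similarity rule.
#' @param threshold Significance threshold flagged in the output (default
#'   the genome-wide level 5e-8).
#' @param out_prefix Output path prefix; writes `<prefix>.results.tsv` and
#'   `<prefix>.log`.
#' @return Data frame of results (one row per variant x method),
#'   invisibly written to `<prefix>.results.tsv`.
#' @export
run_pipeline <- function(pheno, geno, covar = NULL,
                         methods = c("manova", "multiphen", "tates"),
                         clustering = c("none", "hcm", "hcdc"),
                         K = NULL, abs_pearson = FALSE, threshold = 5e-8,
                         out_prefix = "hcdc_run") {
  clustering <- match.arg(clustering)
  methods <- match.arg(methods, several.ok = TRUE)
  Y <- read_matrix(pheno, "pheno")
  G <- read_matrix(geno, "geno")
  C <- if (!is.null(covar)) read_matrix(covar, "covar") else NULL
  ids <- intersect(rownames(Y), rownames(G))
  if (!is.null(C)) ids <- intersect(ids, rownames(C))
  if (length(ids) == 0) stop("no individuals shared across input files",
                             call. = FALSE)
  Y <- Y[ids, , drop = FALSE]
  G <- G[ids, , drop = FALSE]
  log_lines <- c(sprintf("individuals analysed: %d", length(ids)),
                 sprintf("phenotypes: %s", paste(colnames(Y), collapse = ", ")),
                 sprintf("clustering: %s; methods: %s", clustering,
                         paste(methods, collapse = ", ")),
                 sprintf("significance threshold: %g", threshold))
  Ys <- if (!is.null(C)) {
    log_lines <- c(log_lines, sprintf("covariate adjustment: %s",
                                      paste(colnames(C), collapse = ", ")))
    residualize(Y, C[ids, , drop = FALSE])
  } else scale_phenotypes(Y)

  if (clustering != "none") {
    dend <- agglomerate(Ys, method = clustering, abs_pearson = abs_pearson)
    Kc <- if (is.null(K)) choose_k(dend) else as.integer(K)
    part <- cut_dendrogram(dend, Kc)
    Yt <- representative_phenotypes(Ys, part)
    log_lines <- c(log_lines,
                   sprintf("chosen K: %d", Kc),
                   sprintf("clusters: %s", paste(names(part), collapse = " | ")),
                   sprintf("dendrogram: %s", dendrogram_newick(dend)),
                   sprintf("heights: %s",
                           paste(signif(dend$heights, 5), collapse = " ")))
  } else {
    Yt <- Ys
    Kc <- ncol(Ys)
  }

  rows <- list()
  for (snp in colnames(G)) {
    x <- G[, snp]
    for (m in methods) {
      res <- switch(m, manova = manova_test(Yt, x),
                    multiphen = multiphen_test(Yt, x),
                    tates = tates_test(Yt, x))
      rows[[length(rows) + 1L]] <- data.frame(
        snp = snp, method = m, clustering = clustering, K = Kc,
        statistic = if (res$available) res$statistic else NA_real_,
        df = if (res$available) paste(signif(res$df, 6), collapse = ";")
             else NA_character_,
        p_value = if (res$available) res$p_value else NA_real_,
        available = res$available,
        significant = res$available && res$p_value < threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, paste0(out_prefix, ".results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(log_lines, paste0(out_prefix, ".log"))
  invisible(out)
}
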