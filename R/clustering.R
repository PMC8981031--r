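#' Agglomerative clustering of phenotypes by between-cluster correlation
#'
#' Bottom-up merging: every phenotype starts as its own cluster, and at each
#' of the M - 1 steps the pair of clusters with the largest between-cluster
#' similarity is merged. Under `method = "hcdc"` the similarity is the
#' size-dependent rule of [hcdc_similarity()] (Pearson / multiple / first
#' canonical correlation); under `method = "hcm"` it is average linkage on
#' the phenotype correlation matrix ([hcm_similarity()]). The similarity of
#' the pair merged at step b is recorded as the dendrogram height h_b.
#'
#' All three size-dependent rules depend on the data only through the sample
#' correlation matrix of the phenotypes, which is computed once; after each
#' merge only the similarities involving the new cluster are recomputed.
#' Ties (equal similarities) are broken toward the pair with the lowest
#' cluster indices, so the merge sequence is a deterministic function of the
#' input.
#'
#' @param Y Numeric phenotype matrix, N x M with M >= 2. (Both similarity
#'   schemes are invariant to per-column standardization.)
#' @param method `"hcdc"` (size-dependent correlations) or `"hcm"`
#'   (average linkage).
#' @param abs_pearson Passed to the singleton-singleton rule; see
#'   [hcdc_similarity()].
#' @return Object of class `"pheno_dendrogram"`: a list with `heights`
#'   (length M - 1), `merge_members` (list of the two member index sets
#'   merged at each step), `partitions` (cluster list after each step),
#'   `method`, `labels`, and `M`.
#' @examples
#' cfg <- build_model_config(2, M = 8, beta = 0, c2 = 0.6, rho_c2 = 0.1)
#' Y <- simulate_phenotypes(cfg, simulate_genotypes(400, 0.3, seed = 1), seed = 2)
#' d <- agglomerate(scale_phenotypes(Y), method = "hcdc")
#' round(d$heights, 2)
#' @export
agglomerate <- function(Y, method = c("hcdc", "hcm"), abs_pearson = FALSE) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  M <- ncol(Y)
  if (M < 2) stop("need at least 2 phenotypes to cluster", call. = FALSE)
  S <- cor(Y)
  labels <- colnames(Y)
  if (is.null(labels)) labels <- paste0("P", seq_len(M))

  sim_fun <- if (method == "hcdc") {
    function(g1, g2) hcdc_similarity_corr(S, g1, g2, abs_pearson = abs_pearson)
  } else {
    function(g1, g2) mean(S[g1, g2])
  }

  clusters <- lapply(seq_len(M), identity)
  K <- M
  ## pairwise similarity among active clusters (upper triangle used)
  P <- matrix(-Inf, M, M)
  for (i in seq_len(M - 1)) for (j in seq((i + 1), M))
    P[i, j] <- sim_fun(clusters[[i]], clusters[[j]])

  heights <- numeric(M - 1)
  merge_members <- vector("list", M - 1)
  partitions <- vector("list", M - 1)

  for (b in seq_len(M - 1)) {
    ## lowest-index pair attaining the maximum (column-major scan of the
    ## upper triangle gives (i, j) ordered by j then i; rescan for lowest i)
    mx <- max(P[seq_len(K), seq_len(K)])
    hit <- which(P[seq_len(K), seq_len(K)] == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    bi <- hit[1L, 1L]; bj <- hit[1L, 2L]
    heights[b] <- mx
    merge_members[[b]] <- list(clusters[[bi]], clusters[[bj]])
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    K <- K - 1L
    ## compact the similarity matrix: drop row/col bj
    keep <- setdiff(seq_len(K + 1L), bj)
    P[seq_len(K), seq_len(K)] <- P[keep, keep]
    bi2 <- if (bj < bi) bi - 1L else bi
    for (k in seq_len(K)) {
      if (k == bi2) next
      s <- sim_fun(clusters[[min(k, bi2)]], clusters[[max(k, bi2)]])
      P[min(k, bi2), max(k, bi2)] <- s
    }
    partitions[[b]] <- clusters
  }

  structure(list(heights = heights, merge_members = merge_members,
                 partitions = partitions, method = method,
                 labels = labels, M = M, abs_pearson = abs_pearson),
            class = "pheno_dendrogram")
}

#' @export
print.pheno_dendrogram <- function(x, ...) {
  cat(sprintf("Phenotype dendrogram (%s), %d phenotypes, %d merges\n",
              x$method, x$M, x$M - 1L))
  cat("heights:", paste(signif(x$heights, 4), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of clusters from the dendrogram heights
#'
#' The stopping rule selects the step before the largest drop in dendrogram
#' heights: \eqn{b^* = \arg\min_{1 \le b \le M-2} (h_{b+1} - h_b)}, and the
#' partition in force before merge \eqn{b^*+1} has \eqn{K = M - b^*}
#' clusters. Ties are broken toward the smallest b (more clusters). The
#' drop marks the first merge whose similarity falls well below its
#' predecessor's, i.e. the first unnatural merge.
#'
#' For M = 2 the rule's index range is empty and `m2_default` (2 clusters,
#' i.e. never merge) is returned.
#'
#' @param dend A `"pheno_dendrogram"` from [agglomerate()].
#' @param m2_default Number of clusters to report when M = 2 (1 or 2).
#' @return Integer K, with attribute `b_star` (the selected step).
#' @export
choose_k <- function(dend, m2_default = 2L) {
  stopifnot(inherits(dend, "pheno_dendrogram"))
  M <- dend$M
  if (M == 2L) {
    if (!m2_default %in% 1:2) stop("`m2_default` must be 1 or 2", call. = FALSE)
    return(structure(as.integer(m2_default), b_star = NA_integer_))
  }
  gaps <- diff(dend$heights)[seq_len(M - 2L)]
  b_star <- which.min(gaps)  # ties -> smallest b
  structure(M - b_star, b_star = b_star)
}

#' Materialize the partition with K clusters
#'
#' Replays the recorded merge sequence for M - K steps and returns the
#' resulting disjoint clusters.
#'
#' @param dend A `"pheno_dendrogram"`.
#' @param K Number of clusters, `1 <= K <= M`.
#' @return List of K integer vectors (phenotype column indices), each named
#'   by its member labels; the list covers `1:M` disjointly.
#' @export
cut_dendrogram <- function(dend, K) {
  stopifnot(inherits(dend, "pheno_dendrogram"))
  M <- dend$M
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > M || K != round(K))
    stop("`K` must be an integer in 1..M", call. = FALSE)
  K <- as.integer(K)
  part <- if (K == M) lapply(seq_len(M), identity) else dend$partitions[[M - K]]
  names(part) <- vapply(part, function(g)
    paste(dend$labels[g], collapse = "+"), character(1))
  part
}

#' Representative phenotypes: within-cluster means of scaled phenotypes
#'
#' The representative of cluster G_k is the row-wise mean of the
#' standardized phenotypes in G_k. The input must already be standardized
#' (see [scale_phenotypes()]) so that every trait contributes on the same
#' scale.
#'
#' @param Y Scaled phenotype matrix (columns mean 0, sd 1).
#' @param partition List of disjoint index sets covering the columns of `Y`,
#'   e.g. from [cut_dendrogram()].
#' @return N x K matrix whose k-th column is the mean of the columns in the
#'   k-th cluster.
#' @export
representative_phenotypes <- function(Y, partition) {
  Y <- as.matrix(Y)
  if (!is_scaled(Y))
    stop("`Y` must be standardized first; call scale_phenotypes()", call. = FALSE)
  idx <- sort(unlist(partition))
  if (!identical(as.integer(idx), seq_len(ncol(Y))))
    stop("`partition` must disjointly cover the phenotype columns", call. = FALSE)
  R <- vapply(partition, function(g) rowMeans(Y[, g, drop = FALSE]),
              numeric(nrow(Y)))
  R <- as.matrix(R)
  if (!is.null(names(partition))) colnames(R) <- names(partition)
  R
}

#' Newick string for a phenotype dendrogram
#'
#' Branch lengths are the recorded merge heights (similarities, as drawn on
#' the clustering tree), attached to the internal node created at each merge.
#'
#' @param dend A `"pheno_dendrogram"`.
#' @return A single Newick-format string terminated by `";"`.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "pheno_dendrogram"))
  rep_of <- as.list(dend$labels)          # current newick per leading member
  key <- seq_len(dend$M)                  # cluster identified by first member
  for (b in seq_len(dend$M - 1L)) {
    m <- dend$merge_members[[b]]
    a <- m[[1L]][1L]; z <- m[[2L]][1L]
    rep_of[[a]] <- sprintf("(%s,%s):%g", rep_of[[a]], rep_of[[z]],
                           dend$heights[b])
    rep_of[[z]] <- NA_character_
  }
  paste0(sub(":[^:]*$", "", rep_of[[dend$merge_members[[dend$M - 1L]][[1L]][1L]]]), ";")
}
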