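# Unbiased phenotyping: arcsinh transform, PCA + t-SNE embedding, k-means
# clustering with silhouette-based model selection, heat-map summaries and
# cluster-vs-gate agreement.

#' Clustering parameters
#'
#' @param arcsinhScale Cofactor of the arcsinh transform
#'   (`x -> asinh(x / scale)`); 0.2 by convention for 0-1 scaled MFIs.
#' @param nComponents Number of principal components fed into t-SNE (52 for
#'   tonsil panels, 48 for colon); capped at the number of markers.
#' @param perplexity t-SNE perplexity.
#' @param nIterations t-SNE iterations.
#' @param expressionCutoff When `applyCutoff`, cells whose maximum marker MFI
#'   is below this are dropped before embedding (0.1, colon mode).
#' @param applyCutoff Apply the expression cut-off row filter.
#' @param seed Integer seed for PCA/t-SNE/k-means.
#' @return A validated parameter list.
#' @export
clusterParams <- function(arcsinhScale = 0.2, nComponents = 52L,
                          perplexity = 30, nIterations = 1000L,
                          expressionCutoff = 0.1, applyCutoff = FALSE,
                          seed = 1L) {
  stopifnot(arcsinhScale > 0, nComponents >= 1L, perplexity > 0,
            nIterations >= 50L, expressionCutoff >= 0)
  structure(list(arcsinhScale = arcsinhScale,
                 nComponents = as.integer(nComponents),
                 perplexity = perplexity, nIterations = as.integer(nIterations),
                 expressionCutoff = expressionCutoff,
                 applyCutoff = applyCutoff, seed = as.integer(seed)),
            class = "clusterParams")
}

#' Arcsinh-transform the per-cell expression matrix
#'
#' `x -> asinh(x / arcsinhScale)`; strictly monotone, so per-marker cell
#' rankings are preserved. With `applyCutoff`, cells expressing no marker at
#' or above `expressionCutoff` are dropped.
#'
#' @param table Cell table with `mfi_` columns in [0,1].
#' @param params [clusterParams()].
#' @return Numeric matrix cells x markers; rownames are cell ids; attribute
#'   `kept` holds the retained row indices of `table`.
#' @export
transformExpression <- function(table, params = clusterParams()) {
  cols <- grep("^mfi_", names(table), value = TRUE)
  if (length(cols) == 0L) stop("no MFI columns in table", call. = FALSE)
  m <- as.matrix(table[, cols, drop = FALSE])
  colnames(m) <- sub("^mfi_", "", cols)
  keep <- seq_len(nrow(m))
  if (isTRUE(params$applyCutoff)) {
    keep <- which(apply(m, 1, max) >= params$expressionCutoff)
    m <- m[keep, , drop = FALSE]
  }
  out <- asinh(m / params$arcsinhScale)
  rownames(out) <- table$cell_id[keep]
  attr(out, "kept") <- keep
  out
}

#' PCA + t-SNE embedding of transformed expression
#'
#' PCA (centered, unscaled) reduces the matrix to
#' `min(nComponents, n_markers, n_cells - 1)` components, followed by t-SNE
#' at the configured perplexity and iteration count. Deterministic for a
#' fixed seed.
#'
#' @param matrix Cells x markers matrix from [transformExpression()].
#' @param params [clusterParams()].
#' @return Cells x 2 embedding matrix (rownames preserved).
#' @export
embedTSNE <- function(matrix, params = clusterParams()) {
  n <- nrow(matrix)
  if (3 * params$perplexity >= n - 1)
    stop("parameter error: perplexity too large for ", n, " cells",
         call. = FALSE)
  k <- min(params$nComponents, ncol(matrix), n - 1L)
  pca <- stats::prcomp(matrix, center = TRUE, scale. = FALSE, rank. = k)
  set.seed(stageSeed(params$seed, "tsne"))
  ts <- Rtsne::Rtsne(pca$x, dims = 2, perplexity = params$perplexity,
                     max_iter = params$nIterations, pca = FALSE,
                     check_duplicates = FALSE, verbose = FALSE)
  emb <- ts$Y
  rownames(emb) <- rownames(matrix)
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' Cluster cells on the embedding (or any feature matrix)
#'
#' With a numeric `k`, seeded k-means. With `k = "auto"` the default
#' "density" method cuts a single-linkage dendrogram at
#' `gapFactor x` the 90th percentile of nearest-neighbor distances —
#' on a t-SNE map this separates every density-connected blob, including
#' rare populations far smaller than any balanced-size criterion would
#' retain, and is fully deterministic. The alternative
#' `method = "kmeans"` picks the k in `kRange` maximizing the mean
#' silhouette width (classical, but biased against small clusters).
#'
#' @param x Cells x d matrix (typically the t-SNE embedding).
#' @param k Integer number of clusters, or "auto".
#' @param seed Integer seed (used by the k-means paths).
#' @param kRange Candidate k values for silhouette-based auto selection.
#' @param method Auto-selection method: "density" or "kmeans".
#' @param gapFactor Cut-height multiplier for the density method.
#' @return Integer cluster id per cell (named by rownames of `x`).
#' @export
clusterCells <- function(x, k = "auto", seed = 1L, kRange = 2:12,
                         method = c("density", "kmeans"), gapFactor = 5) {
  method <- match.arg(method)
  n <- nrow(x)
  if (is.numeric(k) && k > n) stop("k exceeds number of cells", call. = FALSE)
  if (is.numeric(k) && k == 1L)
    return(stats::setNames(rep(1L, n), rownames(x)))
  km <- function(kk) {
    set.seed(stageSeed(seed, paste0("kmeans", kk)))
    stats::kmeans(x, centers = kk, nstart = 10L, iter.max = 100L)$cluster
  }
  if (identical(k, "auto")) {
    d <- stats::dist(x)
    if (method == "density") {
      dm <- as.matrix(d); diag(dm) <- Inf
      nn <- apply(dm, 1, min)
      cl <- stats::cutree(stats::hclust(d, method = "single"),
                          h = gapFactor * stats::quantile(nn, 0.9))
      return(stats::setNames(as.integer(cl), rownames(x)))
    }
    kRange <- kRange[kRange < n]
    sil <- vapply(kRange, function(kk) {
      mean(cluster::silhouette(km(kk), d)[, "sil_width"])
    }, 0)
    k <- kRange[which.max(sil)]
  }
  stats::setNames(as.integer(km(k)), rownames(x))
}

#' Mean relative expression per cluster (heat-map matrix)
#'
#' Per cluster and marker, the mean MFI; each marker column is then
#' rescaled to [0,1] by its min/max across clusters (constant markers map
#' to 0).
#'
#' @param table Cell table with `mfi_` columns.
#' @param cluster_id Integer cluster per row of `table` (or for the subset
#'   named by its `names`, matching `cell_id`).
#' @return Matrix clusters x markers in [0,1].
#' @export
clusterHeatmap <- function(table, cluster_id) {
  cols <- grep("^mfi_", names(table), value = TRUE)
  if (!is.null(names(cluster_id))) {
    rows <- match(as.character(names(cluster_id)), as.character(table$cell_id))
    table <- table[rows, , drop = FALSE]
  }
  stopifnot(length(cluster_id) == nrow(table))
  m <- as.matrix(table[, cols, drop = FALSE])
  colnames(m) <- sub("^mfi_", "", cols)
  means <- rowsum(m, group = cluster_id) /
    as.vector(table(cluster_id)[as.character(sort(unique(cluster_id)))])
  apply(means, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
}

#' Agreement between a cluster and a gated type
#'
#' @param table Gated cell table with a `cluster_id` column (or supply
#'   `cluster_id` separately, named by cell id).
#' @param focus_cluster Cluster id of interest.
#' @param focus_type Gated type of interest.
#' @param cluster_id Optional cluster vector (named by cell id).
#' @return List with `fraction` (share of the focus cluster gated as the
#'   focus type) and `confusion` (clusters x gated types count table).
#' @export
gateClusterAgreement <- function(table, focus_cluster, focus_type,
                                 cluster_id = NULL) {
  if (is.null(cluster_id)) {
    if (is.null(table$cluster_id)) stop("no cluster ids", call. = FALSE)
    cluster_id <- stats::setNames(table$cluster_id, table$cell_id)
  }
  rows <- match(as.character(names(cluster_id)), as.character(table$cell_id))
  gtype <- table$gated_type[rows]
  confusion <- table(cluster = cluster_id, gated_type = gtype)
  inCluster <- cluster_id == focus_cluster
  if (!any(inCluster)) stop("empty cluster: ", focus_cluster, call. = FALSE)
  list(fraction = mean(gtype[inCluster] == focus_type), confusion = confusion)
}
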