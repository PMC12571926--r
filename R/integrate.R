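# Per-modality normalisation and embedding, weighted-nearest-neighbour
# fusion with per-pixel modality weights, graph clustering, and cluster
# comparison.

#' UMI-collapsed gene x pixel count matrix
#'
#' A molecule is a distinct `(pixel, gene, UMI)` triple; reads sharing all
#' three collapse to one count (exact-match UMI collapse). Unassigned reads
#' are ignored and tallied.
#'
#' @param records demultiplexed RNA reads (the `records` element of a
#'   [demux_reads()] result, or any data.frame with `read_id`, `pixel`,
#'   `umi`, `status`).
#' @param assignments data.frame with `read_id`, `gene` (NA for unaligned).
#' @return sparse `dgCMatrix` (genes x pixels); attribute `n_unassigned`
#'   counts reads without pixel or gene.
#' @export
count_rna <- function(records, assignments) {
  d <- merge(records[, c("read_id", "pixel", "umi", "status")], assignments,
             by = "read_id")
  ok <- d$status == "assigned" & !is.na(d$gene)
  n_unassigned <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  trip <- unique(d[, c("pixel", "gene", "umi")])
  genes <- sort(unique(trip$gene))
  pixels <- sort(unique(trip$pixel))
  counts <- Matrix::sparseMatrix(
    i = match(trip$gene, genes), j = match(trip$pixel, pixels),
    x = 1, dims = c(length(genes), length(pixels)),
    dimnames = list(genes, pixels))
  attr(counts, "n_unassigned") <- n_unassigned
  counts
}

#' Median-ratio log-normalisation of RNA counts
#'
#' Scales every pixel to the median total count, then applies `log(1 + x)` —
#' a variance-stabilising normalisation for downstream PCA. Pixels with zero
#' total are dropped and reported.
#'
#' @param counts genes x pixels matrix of non-negative counts.
#' @return normalised sparse matrix; attribute `dropped_pixels` lists removed
#'   zero-total pixels.
#' @export
normalize_rna <- function(counts) {
  counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  tot <- Matrix::colSums(counts)
  dropped <- colnames(counts)[tot == 0]
  if (length(dropped)) counts <- counts[, tot > 0, drop = FALSE]
  tot <- tot[tot > 0]
  sf <- tot / median(tot)
  norm <- counts %*% Matrix::Diagonal(length(sf), 1 / sf)
  dimnames(norm) <- dimnames(counts)
  out <- norm
  out@x <- log1p(out@x)
  attr(out, "dropped_pixels") <- dropped
  out
}

#' PCA embedding
#'
#' Centred (optionally unit-scaled) principal components via singular value
#' decomposition. Component signs are fixed by making the largest-magnitude
#' loading of each component positive, so results are deterministic across
#' runs.
#'
#' @param x observations x features matrix (no missing values; impute
#'   first — see [impute_iterative_pca()]).
#' @param n_components number of components.
#' @param center,scale. centre/scale columns before decomposition
#'   (zero-variance columns are left unscaled).
#' @param modality optional tag carried into the result (e.g. `"rna"`).
#' @return object of class `sdmt_embedding`: list with `scores`
#'   (observations x components), `loadings`, `var_share`, `modality`.
#' @export
embed_pca <- function(x, n_components = 10L, center = TRUE, scale. = FALSE,
                      modality = NA_character_) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x contains missing values; run impute_iterative_pca() first")
  if (n_components > min(dim(x))) stop("n_components must be <= min(dim(x))")
  sds <- if (scale.) apply(x, 2L, sd) else rep(1, ncol(x))
  sds[sds == 0] <- 1
  xc <- scale(x, center = center, scale = sds)
  s <- svd(xc)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  u <- s$u[, seq_len(n_components), drop = FALSE]
  v <- s$v[, seq_len(n_components), drop = FALSE]
  scores <- sweep(u, 2L, s$d[seq_len(n_components)] * flip, "*")
  loadings <- sweep(v, 2L, flip, "*")
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  dimnames(loadings) <- list(colnames(x), colnames(scores))
  structure(list(scores = scores, loadings = loadings,
                 var_share = s$d[seq_len(n_components)]^2 / sum(s$d^2),
                 modality = modality),
            class = "sdmt_embedding")
}

#' @export
print.sdmt_embedding <- function(x, ...) {
  cat(sprintf("sdmt_embedding (%s): %d observations x %d components (%.1f%% variance)\n",
              x$modality, nrow(x$scores), ncol(x$scores),
              100 * sum(x$var_share)))
  invisible(x)
}

# k nearest neighbours (excluding self) from a distance matrix; ties broken
# by index order
.knn_from_dist <- function(d, k) {
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) {
    o <- order(d[i, ], seq_len(n))
    o[o != i][seq_len(k)]
  }, integer(k)))
}

#' Weighted-nearest-neighbour fusion of two modalities
#'
#' A simplified WNN: for every pixel, each modality's k-nearest-neighbour
#' mean predicts the pixel's profile in that modality, once using its own
#' neighbours (within-modality error) and once using the other modality's
#' neighbours (cross-modality error). The gap between the two errors, scaled
#' by the pixel's local neighbour distance, is turned into a modality
#' affinity with an exponential kernel; the softmax-normalised affinities are
#' the per-pixel modality weights (they sum to 1, and are exactly 0.5/0.5
#' when the two embeddings are identical). Fused similarity is the
#' weight-blended exponential kernel of the two distances; the output is a
#' shared-nearest-neighbour (SNN) graph built from the fused k-NN sets.
#'
#' @param emb_rna,emb_meth [embed_pca()] embeddings over the same pixel set.
#' @param k neighbours per pixel (>= 2).
#' @param snn_prune drop SNN edges with Jaccard overlap below this value.
#' @return object of class `wnn_graph`: list with `weights` (data.frame
#'   pixel/w_rna/w_meth), `graph` (weighted undirected igraph), `knn`
#'   (fused neighbour indices), `params`.
#' @export
wnn_fuse <- function(emb_rna, emb_meth, k = 20L, snn_prune = 1 / 15) {
  xr <- emb_rna$scores
  xm <- emb_meth$scores
  if (nrow(xr) != nrow(xm)) stop("embeddings cover different pixel sets")
  if (!is.null(rownames(xr)) && !is.null(rownames(xm)) &&
      !identical(rownames(xr), rownames(xm))) {
    xm <- xm[rownames(xr), , drop = FALSE]
  }
  n <- nrow(xr)
  if (k < 2L) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of pixels")
  dr <- as.matrix(stats::dist(xr))
  dm <- as.matrix(stats::dist(xm))
  nn_r <- .knn_from_dist(dr, k)
  nn_m <- .knn_from_dist(dm, k)

  pred_err <- function(x, nn) {
    # distance from each pixel to the mean of its neighbours' profiles
    vapply(seq_len(n), function(i) {
      sqrt(sum((x[i, ] - colMeans(x[nn[i, ], , drop = FALSE]))^2))
    }, numeric(1))
  }
  e_rr <- pred_err(xr, nn_r)   # RNA profile from RNA neighbours
  e_rm <- pred_err(xr, nn_m)   # RNA profile from methylation neighbours
  e_mm <- pred_err(xm, nn_m)
  e_mr <- pred_err(xm, nn_r)
  sig_r <- pmax(rowMeans(matrix(dr[cbind(rep(seq_len(n), k), as.vector(nn_r))],
                                n, k)), 1e-12)
  sig_m <- pmax(rowMeans(matrix(dm[cbind(rep(seq_len(n), k), as.vector(nn_m))],
                                n, k)), 1e-12)
  beta_r <- (e_rm - e_rr) / sig_r
  beta_m <- (e_mr - e_mm) / sig_m
  w_rna <- 1 / (1 + exp(beta_m - beta_r))
  w_meth <- 1 - w_rna

  s_r <- exp(-dr / sig_r)      # row-local bandwidth
  s_m <- exp(-dm / sig_m)
  fused <- w_rna * s_r + w_meth * s_m
  diag(fused) <- -Inf
  nn_f <- t(vapply(seq_len(n), function(i) {
    o <- order(fused[i, ], decreasing = TRUE)
    o[seq_len(k)]
  }, integer(k)))

  # shared-nearest-neighbour Jaccard over fused kNN sets (self included)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                              j = as.vector(t(cbind(seq_len(n), nn_f))),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- methods::as(shared, "TsparseMatrix")
  keep <- jac@i < jac@j
  i <- jac@i[keep] + 1L
  j <- jac@j[keep] + 1L
  w <- jac@x[keep] / (2 * (k + 1L) - jac@x[keep])
  edge_keep <- w >= snn_prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[edge_keep], to = j[edge_keep],
               weight = w[edge_keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  pixels <- rownames(xr)
  if (is.null(pixels)) pixels <- as.character(seq_len(n))
  structure(list(weights = data.frame(pixel = pixels, w_rna = w_rna,
                                      w_meth = w_meth,
                                      stringsAsFactors = FALSE),
                 graph = g, knn = nn_f,
                 params = list(k = k, snn_prune = snn_prune)),
            class = "wnn_graph")
}

#' @export
print.wnn_graph <- function(x, ...) {
  cat(sprintf("wnn_graph: %d pixels, %d SNN edges, median w_rna %.3f (k = %d)\n",
              nrow(x$weights), igraph::ecount(x$graph),
              median(x$weights$w_rna), x$params$k))
  invisible(x)
}

#' Graph community clustering
#'
#' Modularity-based community detection (Leiden by default, Louvain as
#' alternative) on a weighted SNN graph. Deterministic given `seed`.
#'
#' @param graph an igraph object or a [wnn_fuse()] result.
#' @param resolution modularity resolution parameter.
#' @param method `"leiden"` or `"louvain"`.
#' @param seed RNG seed.
#' @return integer cluster labels (factor), named by vertex name.
#' @export
cluster_graph <- function(graph, resolution = 0.8,
                          method = c("leiden", "louvain"), seed = 1L) {
  method <- match.arg(method)
  if (inherits(graph, "wnn_graph")) graph <- graph$graph
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  set.seed(seed)
  comm <- if (method == "leiden") {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10L)
  } else {
    igraph::cluster_louvain(graph, resolution = resolution)
  }
  labels <- igraph::membership(comm)
  out <- factor(as.integer(labels))
  names(out) <- igraph::V(graph)$name
  out
}

#' Compare two clusterings
#'
#' @param labels_a,labels_b cluster labels over the same pixels.
#' @return list with `table` (contingency counts), `confusion` (row-normalised
#'   so each row of `labels_a` sums to 1), `flow` (long-format counts for
#'   alluvial plots) and `ari` (adjusted Rand index).
#' @export
compare_clusterings <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length")
  }
  tab <- table(a = labels_a, b = labels_b)
  confusion <- sweep(tab, 1L, pmax(rowSums(tab), 1L), "/")
  flow <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(flow) <- c("from", "to", "n")
  flow <- flow[flow$n > 0L, , drop = FALSE]
  list(table = tab, confusion = confusion, flow = flow,
       ari = adjusted_rand_index(labels_a, labels_b))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items.
#' @param a,b label vectors.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
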