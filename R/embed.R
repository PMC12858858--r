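# Built-in encoders and embedding-space clustering. The learning stage only
# requires *some* N x d matrix aligned to the cell table; self-supervised
# image encoders are a pluggable external input.

#' One-hot label encoding
#'
#' Encodes categorical labels as rows of the standard basis of R^K: an ideal
#' noise-free embedding that perfectly represents the cell classes.
#'
#' @param labels integer labels in `1..K` (or a factor, whose levels index the
#'   columns).
#' @param K number of classes (default: number of levels / max label).
#' @param cell_ids row identifiers (default `names(labels)`).
#' @return an [embedding_matrix] of dimension N x K.
#' @export
one_hot_encode <- function(labels, K = NULL, cell_ids = names(labels)) {
  if (is.factor(labels)) {
    K <- K %||% nlevels(labels)
    labels <- as.integer(labels)
  }
  labels <- as.integer(labels)
  K <- K %||% max(labels)
  if (any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K (K = ", K, ")")
  m <- matrix(0, length(labels), K)
  m[cbind(seq_along(labels), labels)] <- 1
  colnames(m) <- paste0("class_", seq_len(K))
  embedding_matrix(m, cell_ids = cell_ids %||% paste0("cell_", seq_along(labels)),
                   encoder_tag = "one_hot")
}

#' Synthetic cluster embeddings
#'
#' Stand-in for image embeddings in fully synthetic experiments: each cluster
#' receives a fixed random unit anchor in R^d and every cell's embedding is
#' its cluster anchor plus isotropic Gaussian noise. With small `noise_sd`
#' the clusters are cleanly separable, emulating embeddings that carry the
#' morphological cluster and nothing else.
#'
#' @param labels integer cluster labels in `1..K`.
#' @param d embedding dimension (must be >= number of clusters).
#' @param noise_sd isotropic noise scale.
#' @param seed RNG seed (anchors and noise are both derived from it).
#' @param cell_ids row identifiers.
#' @return an [embedding_matrix] N x d.
#' @export
synthetic_cluster_encode <- function(labels, d = 16, noise_sd = 0.1, seed = 0,
                                     cell_ids = names(labels)) {
  labels <- as.integer(labels)
  K <- max(labels)
  if (d < K) stop("embedding dimension d must be at least the number of clusters")
  set.seed(derive_seed(seed, "anchors"))
  anchors <- matrix(stats::rnorm(K * d), K, d)
  anchors <- anchors / sqrt(rowSums(anchors^2))
  set.seed(derive_seed(seed, "noise"))
  E <- anchors[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * d, sd = noise_sd), length(labels), d)
  embedding_matrix(E, cell_ids = cell_ids %||% paste0("cell_", seq_along(labels)),
                   encoder_tag = sprintf("synthetic_cluster(d=%d,sd=%g)", d, noise_sd))
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- d2 / sum(d2)
    pick <- if (all(d2 == 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = probs)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
  }
  centers
}

#' k-means clustering of embeddings
#'
#' Lloyd's algorithm with k-means++ initialization, best of `n_init` restarts
#' by total within-cluster sum of squares; deterministic given the seed.
#'
#' @param E numeric matrix (cells x dims).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with integer `labels` (1..k), `centroids` (k x d) and
#'   `tot_withinss`.
#' @export
kmeans_cluster <- function(E, k, seed = 0, n_init = 10, max_iter = 300) {
  E <- as.matrix(E)
  if (nrow(E) < k) stop("fewer observations than clusters (N < k)")
  set.seed(derive_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- kmeanspp_init(E, k)
    fit <- suppressWarnings(
      stats::kmeans(E, centers = init, iter.max = max_iter, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers),
       tot_withinss = best$tot.withinss)
}

#' Keep the cells closest to their cluster centroid
#'
#' Per cluster, retains the `keep` cells with the smallest Euclidean distance
#' to the cluster centroid (ties at the cutoff: lower index wins), so that the
#' retained cells show strong, unambiguous cluster membership. Clusters
#' smaller than `keep` are returned whole with a warning.
#'
#' @param E embedding matrix (cells x dims).
#' @param labels integer cluster labels (1..k).
#' @param centroids k x d centroid matrix.
#' @param keep cells to retain per cluster (default 2000).
#' @return integer vector of selected row indices (sorted increasing).
#' @export
nearest_to_centroid <- function(E, labels, centroids, keep = 2000) {
  E <- as.matrix(E)
  labels <- as.integer(labels)
  out <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    d <- sqrt(rowSums(sweep(E[idx, , drop = FALSE], 2, centroids[cl, ], "-")^2))
    if (keep >= length(idx)) {
      if (keep > length(idx))
        warning(sprintf("cluster %d has %d cells (< keep = %d); kept whole",
                        cl, length(idx), keep))
      out <- c(out, idx)
    } else {
      out <- c(out, idx[order(d, seq_along(idx))[seq_len(keep)]])
    }
  }
  sort(out)
}
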