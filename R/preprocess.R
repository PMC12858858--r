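# Quality filters, normalization, gene selection, and bag construction.

#' Gene and spot quality filters
#'
#' A gene is kept when its total count over (training) spots is at least
#' `min_gene_counts` and it is detected (count > 0) in at least
#' `min_detect_frac` of the (training) spots. A spot is kept when it has at
#' least one assigned cell (if a bag assignment is supplied) and a total count
#' of at least `min_spot_counts`. Low-count genes are unlikely to be
#' predictable and cell-free spots carry no instances to learn from.
#'
#' @param sc a [spot_counts].
#' @param bags optional [bag_assignment] on the same spots; spots with empty
#'   bags are dropped.
#' @param min_gene_counts minimum total gene count (default 200).
#' @param min_detect_frac minimum fraction of spots in which a gene is
#'   detected (default 0.10).
#' @param min_spot_counts minimum total count per spot (default 20).
#' @param train_spots optional logical/integer index of training spots; when a
#'   train/validation split exists, gene totals and detection fractions are
#'   computed on the training spots only.
#' @return list with logical `gene_mask` and `spot_mask`; the matrix itself is
#'   not mutated.
#' @export
qc_filter <- function(sc, bags = NULL, min_gene_counts = 200,
                      min_detect_frac = 0.10, min_spot_counts = 20,
                      train_spots = NULL) {
  stopifnot(inherits(sc, "spot_counts"))
  counts <- sc$counts
  ref <- if (is.null(train_spots)) counts else counts[train_spots, , drop = FALSE]
  gene_total <- colSums(ref)
  detect_frac <- colMeans(ref > 0)
  gene_mask <- gene_total >= min_gene_counts & detect_frac >= min_detect_frac
  if (!any(gene_mask))
    stop("all genes removed by qc_filter; review min_gene_counts/min_detect_frac")
  spot_mask <- rowSums(counts) >= min_spot_counts
  if (!is.null(bags)) {
    stopifnot(inherits(bags, "bag_assignment"))
    k <- bags$k_s[match(sc$spot_ids, names(bags$spot_to_cells))]
    k[is.na(k)] <- 0L
    spot_mask <- spot_mask & k >= 1L
  }
  names(gene_mask) <- sc$gene_ids
  names(spot_mask) <- sc$spot_ids
  list(gene_mask = gene_mask, spot_mask = spot_mask)
}

#' Library-size log-normalization
#'
#' Applies y_p = ln(1 + s * y / sum(y)) to a count vector, or row-wise to a
#' spots-by-genes (or cells-by-genes) matrix. The scale constant `s` defaults
#' to 10000. The transform is invariant to rescaling the counts.
#'
#' @param y non-negative count vector, or matrix with observations in rows.
#' @param s positive scale constant.
#' @return transformed vector or matrix (entries >= 0).
#' @export
lognormalize <- function(y, s = 10000) {
  if (is.matrix(y)) {
    tot <- rowSums(y)
    if (any(tot <= 0))
      stop("all-zero row(s) at index ", which(tot <= 0)[1],
           "; zero-count observations should have been filtered")
    return(log1p(s * y / tot))
  }
  tot <- sum(y)
  if (tot <= 0) stop("all-zero vector; zero-count spots should have been filtered")
  log1p(s * y / tot)
}

#' Per-gene robust scaling
#'
#' Centres each gene at its median and divides by its interquartile range
#' (75th minus 25th percentile, linear-interpolation quantiles), computed per
#' slide so that several slides stacked into one matrix are scaled
#' independently. Genes with zero IQR are centred only (divided by 1). Used so
#' that all genes contribute comparably to the squared-error training loss.
#'
#' @param values numeric matrix, observations in rows, genes in columns.
#' @param slide character vector assigning each row to a slide (default: one
#'   slide).
#' @param params optional scaler parameters from a previous fit; when given,
#'   they are applied instead of re-estimated (e.g. to scale validation spots
#'   with training-spot statistics).
#' @param center subtract the per-gene median before dividing (default TRUE).
#'   The training losses use `center = FALSE` so that scaled targets stay
#'   non-negative and remain reachable by the softplus-activated scorer.
#' @return list with `values` (scaled matrix) and `params` (named list per
#'   slide of `center` and `spread` vectors), class `robust_scaled`.
#' @export
robust_scale <- function(values, slide = NULL, params = NULL, center = TRUE) {
  values <- as.matrix(values)
  slide <- as.character(slide %||% rep("slide", nrow(values)))
  stopifnot(length(slide) == nrow(values))
  out <- values
  if (is.null(params)) {
    params <- list()
    for (sl in unique(slide)) {
      rows <- slide == sl
      if (sum(rows) < 2L) stop("robust_scale needs at least 2 observations per slide")
      block <- values[rows, , drop = FALSE]
      ctr <- if (center) apply(block, 2, stats::median) else rep(0, ncol(block))
      qs <- apply(block, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
      spread <- qs[2, ] - qs[1, ]
      spread[spread == 0] <- 1
      params[[sl]] <- list(center = ctr, spread = spread)
    }
  }
  for (sl in unique(slide)) {
    if (is.null(params[[sl]])) stop("no scaler parameters for slide ", sl)
    rows <- slide == sl
    out[rows, ] <- sweep(sweep(values[rows, , drop = FALSE], 2,
                               params[[sl]]$center, "-"),
                         2, params[[sl]]$spread, "/")
  }
  structure(list(values = out, params = params, slide = slide),
            class = "robust_scaled")
}

#' Invert a robust scaling
#'
#' @param values scaled matrix (observations x genes).
#' @param params scaler parameters as returned by [robust_scale()].
#' @param slide per-row slide assignment (default: the single slide in
#'   `params`).
#' @return matrix on the original scale.
#' @export
inverse_robust_scale <- function(values, params, slide = NULL) {
  values <- as.matrix(values)
  slide <- as.character(slide %||% rep(names(params)[1], nrow(values)))
  out <- values
  for (sl in unique(slide)) {
    if (is.null(params[[sl]])) stop("no scaler parameters for slide ", sl)
    rows <- slide == sl
    out[rows, ] <- sweep(sweep(values[rows, , drop = FALSE], 2,
                               params[[sl]]$spread, "*"),
                         2, params[[sl]]$center, "+")
  }
  out
}

# Seurat-v3-style standardized variance for one batch of raw counts.
# Fits a loess trend of log10 variance on log10 mean, then computes the
# variance of the clipped standardized counts (clip at sqrt(N)); genes with
# zero mean or variance score 0. Falls back to a flat trend when the loess
# fit is not feasible (few genes or degenerate mean spread).
std_variance <- function(counts, span = 0.3) {
  n <- nrow(counts)
  mu <- colMeans(counts)
  v <- col_vars(counts)
  stat <- rep(0, ncol(counts))
  ok <- which(mu > 0 & v > 0)
  if (!length(ok)) return(stat)
  lx <- log10(mu[ok]); ly <- log10(v[ok])
  fitted <- tryCatch({
    if (length(unique(lx)) < 10L) stop("too few distinct means")
    fit <- stats::loess(ly ~ lx, span = span, degree = 2)
    stats::fitted(fit)
  }, error = function(e) rep(mean(ly), length(ok)),
     warning = function(w) rep(mean(ly), length(ok)))
  sd_exp <- sqrt(10^fitted)
  clip <- sqrt(n)
  x <- counts[, ok, drop = FALSE]
  upper <- mu[ok] + clip * sd_exp
  xc <- pmin(x, rep(upper, each = n))
  ss <- colSums(xc^2) - 2 * mu[ok] * colSums(xc) + n * mu[ok]^2
  stat[ok] <- ss / ((n - 1) * sd_exp^2)
  stat
}

#' Highly variable gene selection
#'
#' Ranks genes by variance-stabilized standardized variance (loess trend of
#' log10 variance against log10 mean on raw counts, standardized values
#' clipped at sqrt(N)). With several batches (slides), the statistic is
#' computed per batch and genes are aggregated by, first, the number of
#' batches in which the gene ranks in the top `n`, then the median
#' within-batch rank — so slide-specific genes are avoided.
#'
#' @param counts spots-by-genes raw count matrix (slides stacked in rows), or
#'   a [spot_counts].
#' @param n number of genes to return.
#' @param batch optional per-row batch (slide) assignment.
#' @return tibble with `gene_id`, `statistic` (median standardized variance
#'   across batches), `median_rank`, `n_top_batches` and `method = "HVG"`,
#'   ordered by the selection rule, `n` rows.
#' @export
select_hvg <- function(counts, n, batch = NULL) {
  if (inherits(counts, "spot_counts")) {
    batch <- batch %||% counts$slide
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  G <- ncol(counts)
  if (n > G) stop("n exceeds the number of genes (", G, ")")
  gene_ids <- colnames(counts) %||% default_ids(G, "gene_")
  batch <- as.character(batch %||% rep("batch", nrow(counts)))
  batches <- unique(batch)
  stats_mat <- sapply(batches, function(b)
    std_variance(counts[batch == b, , drop = FALSE]))
  stats_mat <- matrix(stats_mat, nrow = G)
  # within-batch rank, 1 = most variable; ties broken by gene order
  ranks <- apply(stats_mat, 2, function(s) rank(-s, ties.method = "first"))
  ranks <- matrix(ranks, nrow = G)
  median_rank <- apply(ranks, 1, stats::median)
  n_top <- rowSums(ranks <= n)
  ord <- order(-n_top, median_rank, seq_len(G))
  sel <- ord[seq_len(n)]
  tibble::tibble(
    gene_id = gene_ids[sel],
    statistic = apply(stats_mat, 1, stats::median)[sel],
    median_rank = median_rank[sel],
    n_top_batches = n_top[sel],
    method = "HVG"
  )
}

# Symmetrized binary k-nearest-neighbour adjacency from coordinates.
knn_graph <- function(xy, k) {
  n <- nrow(xy)
  if (k >= n) k <- n - 1L
  d <- as.matrix(stats::dist(xy))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    w[i, nb] <- 1
  }
  pmax(w, t(w))
}

# Moran's I for every column of `values` given a fixed weight matrix.
moran_all <- function(values, w) {
  n <- nrow(values)
  W <- sum(w)
  xc <- sweep(values, 2, colMeans(values), "-")
  num <- colSums(xc * (w %*% xc))
  den <- colSums(xc^2)
  ifelse(den > 0, (n / W) * num / den, NA_real_)
}

#' Moran's I spatial autocorrelation
#'
#' I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with w the symmetrized binary k-nearest-neighbour adjacency of the spot
#' centres (k = 6 by default, matching the hexagonal Visium neighbourhood)
#' and W the sum of all weights. Positive for spatially smooth fields,
#' negative for alternating ones.
#'
#' @param values numeric vector, one value per spot.
#' @param spot_xy spot-centre coordinates (n x 2).
#' @param n_neighbors number of nearest neighbours.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, spot_xy, n_neighbors = 6) {
  spot_xy <- as.matrix(spot_xy)
  n <- length(values)
  if (n < 3L) stop("Moran's I needs at least 3 spots")
  stopifnot(nrow(spot_xy) == n)
  if (stats::var(values) == 0) stop("constant field: Moran's I undefined")
  w <- knn_graph(spot_xy, n_neighbors)
  as.numeric(moran_all(matrix(values, ncol = 1), w))
}

#' Spatially variable gene selection
#'
#' Computes Moran's I of the log-normalized expression of every gene on each
#' slide, then ranks genes by the geometric mean of the per-slide scores.
#' Because Moran's I lies in \[-1, 1\] and can be negative, scores are shifted
#' by +1 (an order-preserving positive transform) before the geometric mean.
#'
#' @param slides a [spot_counts] or list of them (one per slide).
#' @param n number of genes to return.
#' @param n_neighbors neighbours for the Moran weight graph.
#' @param s log-normalization scale constant.
#' @return tibble with `gene_id`, `statistic` (geometric mean of the shifted
#'   scores), one `moran_<slide>` column per slide, `method = "SVG"`, ordered
#'   by decreasing statistic. Genes absent from any slide are excluded with a
#'   warning.
#' @export
select_svg <- function(slides, n, n_neighbors = 6, s = 10000) {
  if (inherits(slides, "spot_counts")) slides <- list(slides)
  stopifnot(all(vapply(slides, inherits, TRUE, "spot_counts")))
  common <- Reduce(intersect, lapply(slides, function(x) x$gene_ids))
  all_genes <- unique(unlist(lapply(slides, function(x) x$gene_ids)))
  dropped <- setdiff(all_genes, common)
  if (length(dropped))
    warning(length(dropped), " gene(s) absent from at least one slide were excluded")
  if (n > length(common)) stop("n exceeds the number of shared genes")
  scores <- sapply(slides, function(sc) {
    vals <- lognormalize(sc$counts[, common, drop = FALSE], s = s)
    w <- knn_graph(sc$spot_xy, n_neighbors)
    moran_all(vals, w)
  })
  scores <- matrix(scores, nrow = length(common),
                   dimnames = list(common, paste0("moran_", seq_along(slides))))
  scores[is.na(scores)] <- 0   # constant genes: no spatial signal
  gm <- exp(rowMeans(log(scores + 1)))
  ord <- order(-gm, common)
  sel <- ord[seq_len(n)]
  out <- tibble::tibble(gene_id = common[sel], statistic = gm[sel], method = "SVG")
  dplyr::bind_cols(out, tibble::as_tibble(scores[sel, , drop = FALSE]))
}

#' Link detected cells to spots
#'
#' Assigns each cell to the nearest spot centre whose Euclidean distance is at
#' most the spot radius (boundary inclusive); cells within radius of several
#' spots go to the nearest one, equidistant ties to the lower spot index.
#' Cells outside every spot are recorded as unassigned.
#'
#' @param cells a cell table (see [cell_table()]).
#' @param sc a [spot_counts] in the same coordinate frame.
#' @return a [bag_assignment]; spots with no cells get empty bags.
#' @export
assign_cells_to_spots <- function(cells, sc) {
  cells <- cell_table(cells)
  stopifnot(inherits(sc, "spot_counts"))
  S <- nrow(sc$spot_xy)
  n <- nrow(cells)
  nearest <- integer(n); ndist <- numeric(n)
  cxy <- cbind(cells$x, cells$y)
  chunk <- 4096L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(rowSums(cxy[idx, , drop = FALSE]^2), rowSums(sc$spot_xy^2), "+") -
      2 * cxy[idx, , drop = FALSE] %*% t(sc$spot_xy)
    nearest[idx] <- max.col(-d2, ties.method = "first")
    ndist[idx] <- sqrt(pmax(d2[cbind(seq_along(idx), nearest[idx])], 0))
  }
  assigned <- ndist <= sc$spot_radius + 1e-9
  spot_to_cells <- lapply(seq_len(S), function(s)
    cells$cell_id[assigned & nearest == s])
  names(spot_to_cells) <- sc$spot_ids
  bag_assignment(spot_to_cells, cell_ids = cells$cell_id,
                 unassigned = cells$cell_id[!assigned])
}
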