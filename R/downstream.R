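# Evaluation metrics, bootstrap intervals, marker-gene signature scoring,
# group-wise gene ranking and gallery selection.

#' Per-gene prediction metrics
#'
#' For each gene (column) computes the Pearson correlation (PCC), Spearman
#' correlation (SCC = Pearson of average ranks), root mean squared error and
#' mean absolute error between prediction and truth across observations
#' (spots or cells). Genes whose truth or prediction is constant have
#' undefined correlations; they are recorded as missing and excluded from the
#' summary means rather than silently becoming 0. Summary means carry 95%
#' bootstrap percentile intervals (genes resampled with replacement).
#'
#' @param pred,truth matrices of matching shape (observations x genes); for
#'   correlation reporting the truth should be on the log-normalized scale.
#' @param level `"spot"` or `"cell"` (recorded in the report).
#' @param n_boot bootstrap replicates for the summary CIs (default 1000).
#' @param seed bootstrap seed.
#' @return a `metrics_report`: `per_gene` tibble (gene_id, pcc, scc, rmse,
#'   mae), `summary` tibble (metric, mean, ci_low, ci_high, n_genes_used) and
#'   `level`.
#' @export
compute_metrics <- function(pred, truth, level = c("spot", "cell"),
                            n_boot = 1000, seed = 0) {
  level <- match.arg(level)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (nrow(pred) < 3L) stop("need at least 3 observations")
  gene_ids <- colnames(truth) %||% default_ids(ncol(truth), "gene_")
  ok <- apply(truth, 2, stats::sd) > 0 & apply(pred, 2, stats::sd) > 0
  pcc <- scc <- rep(NA_real_, ncol(truth))
  if (any(ok)) {
    pcc[ok] <- sapply(which(ok), function(j) stats::cor(pred[, j], truth[, j]))
    scc[ok] <- sapply(which(ok), function(j)
      stats::cor(rank(pred[, j]), rank(truth[, j])))
  }
  rmse <- unname(sqrt(colMeans((pred - truth)^2)))
  mae <- unname(colMeans(abs(pred - truth)))
  per_gene <- tibble::tibble(gene_id = gene_ids, pcc = pcc, scc = scc,
                             rmse = rmse, mae = mae)
  summarise_metric <- function(v, name, i) {
    v_ok <- v[!is.na(v)]
    ci <- bootstrap_ci(v_ok, n_boot = n_boot, seed = derive_seed(seed, name))
    tibble::tibble(metric = name, mean = mean(v_ok),
                   ci_low = ci[1], ci_high = ci[2], n_genes_used = length(v_ok))
  }
  summary <- dplyr::bind_rows(
    summarise_metric(pcc, "pcc"), summarise_metric(scc, "scc"),
    summarise_metric(rmse, "rmse"), summarise_metric(mae, "mae"))
  structure(list(per_gene = per_gene, summary = summary, level = level),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> level = %s, %d genes\n", x$level, nrow(x$per_gene)))
  print(x$summary)
  invisible(x)
}

#' Percentile bootstrap interval for a mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' percentile interval of the resampled means.
#'
#' @param values numeric vector (length >= 2).
#' @param n_boot replicates (default 1000).
#' @param level interval level (default 0.95).
#' @param seed RNG seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  set.seed(derive_seed(seed, "boot"))
  means <- vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(length(values), replace = TRUE)]), numeric(1))
  unname(stats::quantile(means, probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Marker-gene signature score per cell
#'
#' s_m = mean predicted expression over the marker genes minus mean over a
#' control gene list, computed after (1) scaling each cell to the same total
#' expression (the median cell total) and (2) standardizing each gene. When no
#' control list is given, control genes are drawn matched on expression: all
#' genes are cut into `n_bins` bins by mean expression and `n_ctrl` controls
#' are sampled (seeded) from the bin of each marker gene.
#'
#' @param pred a [cell_prediction] or cells x genes matrix.
#' @param markers character vector of marker gene ids (all must be present).
#' @param controls optional explicit control gene ids.
#' @param n_bins expression bins for control matching (default 25).
#' @param n_ctrl controls sampled per marker bin (default 50).
#' @param seed RNG seed for control sampling.
#' @return tibble with `cell_id` and `score`, plus the control set in the
#'   `controls` attribute.
#' @export
score_cells <- function(pred, markers, controls = NULL, n_bins = 25,
                        n_ctrl = 50, seed = 0) {
  scores <- if (inherits(pred, "cell_prediction")) pred$scores else as.matrix(pred)
  gene_ids <- colnames(scores)
  absent <- setdiff(markers, gene_ids)
  if (length(absent))
    stop("marker gene(s) absent from the prediction: ",
         paste(absent, collapse = ", "))
  # (1) equal total expression per cell
  tot <- rowSums(scores)
  target <- stats::median(tot)
  if (any(tot <= 0)) stop("cell(s) with zero total predicted expression")
  x <- scores * (target / tot)
  # (2) per-gene standardization
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  # (3) expression-bin-matched controls
  if (is.null(controls)) {
    bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
    set.seed(derive_seed(seed, "controls"))
    ctrl <- character(0)
    for (g in markers) {
      pool <- gene_ids[bins == bins[match(g, gene_ids)]]
      ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
    }
    controls <- unique(ctrl)
  } else {
    absent <- setdiff(controls, gene_ids)
    if (length(absent))
      stop("control gene(s) absent from the prediction: ",
           paste(absent, collapse = ", "))
  }
  s <- rowMeans(z[, markers, drop = FALSE]) - rowMeans(z[, controls, drop = FALSE])
  out <- tibble::tibble(cell_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
                        score = as.numeric(s))
  attr(out, "controls") <- controls
  out
}

#' Rank genes per group by Welch t statistic
#'
#' For every group g and gene j computes the Welch statistic of group-g cells
#' against all remaining cells,
#' t = (mean_g - mean_rest) / sqrt(var_g/n_g + var_rest/n_rest),
#' with two-sided p-values on the Welch-Satterthwaite degrees of freedom; the
#' (vanishingly rare) zero pooled variance is guarded at 1e-9. Genes are
#' ranked by descending t within each group.
#'
#' @param pred a [cell_prediction] or cells x genes matrix.
#' @param labels per-cell group labels (>= 2 groups, >= 2 cells each).
#' @return tibble with `group`, `gene_id`, `t`, `p_value`, `rank`.
#' @export
rank_genes_by_group <- function(pred, labels) {
  x <- if (inherits(pred, "cell_prediction")) pred$scores else as.matrix(pred)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  gene_ids <- colnames(x) %||% default_ids(ncol(x), "gene_")
  res <- lapply(groups, function(g) {
    in_g <- labels == g
    n1 <- sum(in_g); n2 <- sum(!in_g)
    if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 cells")
    m1 <- colMeans(x[in_g, , drop = FALSE]); m2 <- colMeans(x[!in_g, , drop = FALSE])
    v1 <- col_vars(x[in_g, , drop = FALSE]); v2 <- col_vars(x[!in_g, , drop = FALSE])
    se2 <- pmax(v1 / n1 + v2 / n2, 1e-9)
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[!is.finite(df)] <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
    tibble::tibble(group = g, gene_id = gene_ids, t = unname(t),
                   p_value = unname(p)) |>
      dplyr::arrange(dplyr::desc(t)) |>
      dplyr::mutate(rank = dplyr::row_number())
  })
  dplyr::bind_rows(res)
}

#' Top-scoring cells
#'
#' The `n` cells with the highest score, descending; ties broken by ascending
#' cell id so galleries are deterministic.
#'
#' @param scores tibble with `cell_id` and `score` (e.g. from
#'   [score_cells()]), or a named numeric vector.
#' @param n number of cells (default 100; all cells if n exceeds N).
#' @return character vector of cell ids in rank order.
#' @export
top_cells <- function(scores, n = 100) {
  if (is.numeric(scores))
    scores <- tibble::tibble(cell_id = names(scores) %||%
                               as.character(seq_along(scores)),
                             score = as.numeric(scores))
  ord <- order(-scores$score, scores$cell_id)
  scores$cell_id[ord][seq_len(min(n, nrow(scores)))]
}

#' Per-gene min-max scaling
#'
#' (x - min) / (max - min) per gene (column); constant genes map to all
#' zeros. Output lies in \[0, 1\].
#'
#' @param values observations x genes matrix.
#' @return scaled matrix.
#' @export
minmax_per_gene <- function(values) {
  values <- as.matrix(values)
  lo <- apply(values, 2, min)
  hi <- apply(values, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  out <- sweep(sweep(values, 2, lo, "-"), 2, rng, "/")
  out[, hi == lo] <- 0
  out
}
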