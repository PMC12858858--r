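# Simulation framework: a clustered synthetic single-cell reference, three
# morphology-expression coupling scenarios (random / centroid / cell), and
# spot synthesis by summing member-cell expression.

#' Generate a clustered synthetic single-cell reference
#'
#' Draws an M x G negative-binomial count matrix with K clusters. Per-gene
#' baseline means are log-normal (so a realistic skewed mean distribution);
#' each cluster owns `markers_per_cluster` designated marker genes whose mean
#' is multiplied by `fold_change` in that cluster only. Highly variable genes
#' are ranked on the reference itself, so downstream gene lists always come
#' from the reference, never from simulated spots.
#'
#' @param K number of clusters (default 6).
#' @param G number of genes (default 300).
#' @param cells_per_cluster cells per cluster (default 500).
#' @param markers_per_cluster marker genes per cluster (default 10);
#'   `K * markers_per_cluster` must not exceed `G`.
#' @param base_mean median of the log-normal baseline gene means (default 1
#'   transcript per cell per gene).
#' @param fold_change marker up-regulation factor in the owning cluster
#'   (default 5).
#' @param dispersion negative-binomial size parameter (default 2; variance =
#'   mu + mu^2/size).
#' @param seed RNG seed.
#' @return an object of class `mil_reference`: `counts` (M x G), `cluster`
#'   (integer labels 1..K), `marker_sets` (per-cluster gene-id lists),
#'   `hvg` (full HVG ranking tibble) and `gene_ids`.
#' @export
generate_reference <- function(K = 6, G = 300, cells_per_cluster = 500,
                               markers_per_cluster = 10, base_mean = 1,
                               fold_change = 5, dispersion = 2, seed = 0) {
  if (markers_per_cluster * K > G)
    stop("markers_per_cluster * K exceeds the number of genes")
  set.seed(derive_seed(seed, "reference"))
  gene_ids <- sprintf("g%04d", seq_len(G))
  base <- stats::rlnorm(G, meanlog = log(base_mean), sdlog = 1)
  marker_sets <- lapply(seq_len(K), function(k)
    gene_ids[((k - 1) * markers_per_cluster + 1):(k * markers_per_cluster)])
  names(marker_sets) <- paste0("cluster_", seq_len(K))
  M <- K * cells_per_cluster
  cluster <- rep(seq_len(K), each = cells_per_cluster)
  counts <- matrix(0L, M, G, dimnames = list(sprintf("ref%05d", seq_len(M)), gene_ids))
  for (k in seq_len(K)) {
    mu <- base
    idx <- match(marker_sets[[k]], gene_ids)
    mu[idx] <- mu[idx] * fold_change
    rows <- which(cluster == k)
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * G, size = dispersion,
                     mu = rep(mu, each = length(rows))),
      length(rows), G)
  }
  hvg <- select_hvg(counts, n = G)
  structure(list(counts = counts, cluster = cluster,
                 marker_sets = marker_sets, hvg = hvg,
                 gene_ids = gene_ids, K = K, seed = seed),
            class = "mil_reference")
}

#' @export
print.mil_reference <- function(x, ...) {
  cat(sprintf("<mil_reference> %d cells x %d genes, %d clusters, %d markers/cluster\n",
              nrow(x$counts), ncol(x$counts), x$K, length(x$marker_sets[[1]])))
  invisible(x)
}

#' Match image clusters to reference clusters
#'
#' Draws a seeded random bijection from the K morphological (image) clusters
#' to the K reference expression clusters. The matching is arbitrary by
#' design: it does not reflect biology, it just installs a strong
#' morphology-expression correspondence for evaluation.
#'
#' @param image_labels integer image-cluster labels (1..K) or the number of
#'   image clusters.
#' @param reference a `mil_reference` with the same number of clusters.
#' @param seed RNG seed.
#' @return integer vector `map` with `map[i]` the reference cluster matched to
#'   image cluster i.
#' @export
match_clusters <- function(image_labels, reference, seed = 0) {
  k_img <- if (length(image_labels) == 1L) as.integer(image_labels)
           else max(as.integer(image_labels))
  if (k_img != reference$K)
    stop(sprintf("number of image clusters (%d) must equal reference clusters (%d)",
                 k_img, reference$K))
  set.seed(derive_seed(seed, "match"))
  map <- sample.int(k_img)
  stats::setNames(map, paste0("image_", seq_len(k_img)))
}

#' Assign expression vectors to cells under a scenario
#'
#' The three scenarios set the level of coupling between cell morphology
#' (the image cluster) and expression:
#' * `random` — no link: each cell gets a reference row drawn uniformly from
#'   the whole reference;
#' * `centroid` — perfect link: each cell gets the per-gene mean vector of its
#'   mapped reference cluster (identical for all cells of an image cluster);
#' * `cell` — partial link: each cell gets a reference row drawn uniformly
#'   from its mapped cluster.
#'
#' @param scenario one of `"random"`, `"centroid"`, `"cell"`.
#' @param image_labels integer image-cluster labels per cell.
#' @param map image-to-reference cluster bijection from [match_clusters()].
#' @param reference a `mil_reference`.
#' @param seed RNG seed.
#' @return N x G expression matrix with attributes `source_cluster` (the
#'   mapped reference cluster per cell) and `source_row` (reference row drawn,
#'   NA for centroid).
#' @export
assign_expression <- function(scenario, image_labels, map, reference, seed = 0) {
  if (!scenario %in% c("random", "centroid", "cell"))
    stop("unknown scenario: ", scenario)
  image_labels <- as.integer(image_labels)
  N <- length(image_labels)
  target_cluster <- unname(map[image_labels])
  set.seed(derive_seed(seed, paste0("assign_", scenario)))
  if (scenario == "random") {
    rows <- sample.int(nrow(reference$counts), N, replace = TRUE)
    expr <- reference$counts[rows, , drop = FALSE]
  } else if (scenario == "centroid") {
    centroids <- rowsum(reference$counts, reference$cluster) /
      as.vector(table(reference$cluster))
    expr <- centroids[target_cluster, , drop = FALSE]
    rows <- rep(NA_integer_, N)
  } else {
    rows <- vapply(target_cluster, function(cl) {
      members <- which(reference$cluster == cl)
      members[sample.int(length(members), 1L)]
    }, integer(1))
    expr <- reference$counts[rows, , drop = FALSE]
  }
  expr <- unname(expr)
  colnames(expr) <- reference$gene_ids
  attr(expr, "source_cluster") <- target_cluster
  attr(expr, "source_row") <- rows
  expr
}

#' Synthesize spots by summing member-cell expression
#'
#' Draws `cells_per_spot` member cells per spot (without replacement within a
#' spot, with replacement across spots — each draw becomes a distinct cell
#' instance) and sets the spot count vector to the exact element-wise sum of
#' its members' expression. Spot centres are laid on a square grid with
#' non-overlapping capture disks and each instance is placed uniformly inside
#' its spot's disk, so geometric cell-to-spot linkage reproduces the bags.
#'
#' @param cell_expression N x G source expression matrix (rows: candidate
#'   cells), e.g. from [assign_expression()].
#' @param n_spots number of spots.
#' @param cells_per_spot cells per spot.
#' @param seed RNG seed.
#' @param spot_radius spot radius in pixels (default 50).
#' @param slide_id slide identifier.
#' @return a `sim_dataset`: list with `spot_counts` ([spot_counts]), `cells`
#'   (instance table), `bags` ([bag_assignment]), `embeddings` slot left NULL,
#'   `cell_expression` (instances x G ground truth), `source_index`
#'   (instance -> source row) and `truth_labels` (copied from the
#'   `source_cluster` attribute when present).
#' @export
simulate_spots <- function(cell_expression, n_spots, cells_per_spot, seed = 0,
                           spot_radius = 50, slide_id = "sim") {
  cell_expression <- as.matrix(cell_expression)
  N <- nrow(cell_expression)
  if (N < cells_per_spot) stop("fewer source cells than cells_per_spot")
  set.seed(derive_seed(seed, "spots"))
  draws <- matrix(0L, n_spots, cells_per_spot)
  for (s in seq_len(n_spots))
    draws[s, ] <- sample.int(N, cells_per_spot, replace = FALSE)
  src <- as.vector(t(draws))                       # instance order: spot-major
  inst_expr <- cell_expression[src, , drop = FALSE]
  inst_ids <- sprintf("c%06d", seq_along(src))
  rownames(inst_expr) <- inst_ids
  spot_ids <- sprintf("s%05d", seq_len(n_spots))
  counts <- rowsum(inst_expr, rep(seq_len(n_spots), each = cells_per_spot),
                   reorder = FALSE)
  rownames(counts) <- spot_ids
  side <- ceiling(sqrt(n_spots))
  spacing <- 3.6 * spot_radius
  grid <- cbind(x = ((seq_len(n_spots) - 1L) %% side) * spacing + spacing,
                y = ((seq_len(n_spots) - 1L) %/% side) * spacing + spacing)
  # place instances uniformly inside their spot's disk
  r <- spot_radius * sqrt(stats::runif(length(src)))
  th <- stats::runif(length(src), 0, 2 * pi)
  cxy <- grid[rep(seq_len(n_spots), each = cells_per_spot), , drop = FALSE] +
    cbind(r * cos(th), r * sin(th))
  cells <- tibble::tibble(cell_id = inst_ids, x = cxy[, 1], y = cxy[, 2],
                          slide_id = slide_id)
  integer_counts <- is_wholenumber(cell_expression)
  sc <- spot_counts(counts, spot_xy = grid, spot_radius = spot_radius,
                    spot_ids = spot_ids, slide_id = slide_id,
                    check_integer = integer_counts)
  bags <- bag_assignment(split(inst_ids, rep(spot_ids, each = cells_per_spot)),
                         cell_ids = inst_ids)
  bags$spot_to_cells <- bags$spot_to_cells[spot_ids]  # keep spot order
  bags$k_s <- lengths(bags$spot_to_cells)
  labels <- attr(cell_expression, "source_cluster")
  structure(list(spot_counts = sc, cells = cells, bags = bags,
                 embeddings = NULL,
                 cell_expression = inst_expr,
                 source_index = src,
                 truth_labels = if (!is.null(labels)) labels[src] else NULL),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d spots x %d genes, %d cell instances\n",
              nrow(x$spot_counts$counts), ncol(x$spot_counts$counts),
              nrow(x$cells)))
  invisible(x)
}

#' Scenario configuration
#'
#' Defaults follow the typical Visium regime the simulations emulate: 5000
#' spots of 20 cells, 6 morphological clusters, the 2000 cells nearest each
#' cluster centroid retained.
#'
#' @param scenario `"random"`, `"centroid"` or `"cell"`.
#' @param k_image_clusters number of morphology clusters (default 6).
#' @param keep_per_cluster cells retained nearest each centroid (default
#'   2000).
#' @param n_spots spots per dataset (default 5000).
#' @param cells_per_spot cells per spot (default 20).
#' @param encoder `"synthetic_cluster"` (noisy cluster anchors) or `"one_hot"`
#'   (ideal noise-free encoding of the k-means image clusters).
#' @param embed_dim synthetic encoder dimension (default 16).
#' @param noise_sd synthetic encoder noise (default 0.1).
#' @param image_cells_per_cluster latent image cells generated per cluster
#'   before the nearest-to-centroid cut (default 2500).
#' @param spot_radius synthetic spot radius in pixels.
#' @param seed root seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("random", "centroid", "cell"),
                            k_image_clusters = 6, keep_per_cluster = 2000,
                            n_spots = 5000, cells_per_spot = 20,
                            encoder = c("synthetic_cluster", "one_hot"),
                            embed_dim = 16, noise_sd = 0.1,
                            image_cells_per_cluster = 2500,
                            spot_radius = 50, seed = 0) {
  scenario <- match.arg(scenario)
  encoder <- match.arg(encoder)
  stopifnot(k_image_clusters > 0, keep_per_cluster > 0, n_spots > 0,
            cells_per_spot > 0)
  structure(list(scenario = scenario, k_image_clusters = k_image_clusters,
                 keep_per_cluster = keep_per_cluster, n_spots = n_spots,
                 cells_per_spot = cells_per_spot, encoder = encoder,
                 embed_dim = embed_dim, noise_sd = noise_sd,
                 image_cells_per_cluster = image_cells_per_cluster,
                 spot_radius = spot_radius, seed = seed),
            class = "scenario_config")
}

#' Run a full simulation scenario
#'
#' Pipeline: generate (or accept) cell embeddings, cluster them with k-means
#' (k = `k_image_clusters`), keep the `keep_per_cluster` cells nearest each
#' centroid, draw the image-to-reference cluster matching, assign expression
#' per the scenario, and synthesize spots — independently (fresh sampling,
#' derived seeds) for a training and a test dataset that share the cluster
#' matching. Ground-truth per-cell expression is retained in both.
#'
#' @param cfg a [scenario_config()].
#' @param reference a `mil_reference` with `K = k_image_clusters` clusters.
#' @param embeddings optional external embedding matrix for the latent image
#'   cells; by default the synthetic cluster encoder generates them.
#' @return list with `train` and `test` (`sim_dataset`s, each with an
#'   `embeddings` matrix aligned to its cell instances), `map`, `kmeans_labels`
#'   (retained cells) and `kept` (indices into the latent image cells).
#' @export
run_scenario <- function(cfg, reference, embeddings = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(reference, "mil_reference"))
  K <- cfg$k_image_clusters
  if (is.null(embeddings)) {
    latent <- rep(seq_len(K), each = cfg$image_cells_per_cluster)
    embeddings <- synthetic_cluster_encode(latent, d = cfg$embed_dim,
                                           noise_sd = cfg$noise_sd,
                                           seed = derive_seed(cfg$seed, "encode"))
  }
  km <- kmeans_cluster(embeddings, k = K, seed = derive_seed(cfg$seed, "cluster"))
  kept <- nearest_to_centroid(embeddings, km$labels, km$centroids,
                              keep = cfg$keep_per_cluster)
  E_kept <- embeddings[kept, , drop = FALSE]
  labels_kept <- km$labels[kept]
  if (cfg$encoder == "one_hot")
    E_kept <- one_hot_encode(labels_kept, K = K, cell_ids = rownames(E_kept))
  map <- match_clusters(K, reference, seed = derive_seed(cfg$seed, "match"))

  build <- function(which) {
    seed <- derive_seed(cfg$seed, which)
    expr <- assign_expression(cfg$scenario, labels_kept, map, reference,
                              seed = seed)
    ds <- simulate_spots(expr, cfg$n_spots, cfg$cells_per_spot, seed = seed,
                         spot_radius = cfg$spot_radius,
                         slide_id = paste0("sim_", which))
    E_inst <- E_kept[ds$source_index, , drop = FALSE]
    rownames(E_inst) <- ds$cells$cell_id
    ds$embeddings <- embedding_matrix(E_inst,
                                      encoder_tag = attr(E_kept, "encoder_tag") %||% cfg$encoder)
    ds$image_labels <- labels_kept[ds$source_index]
    ds
  }
  list(train = build("train"), test = build("test"),
       map = map, kmeans_labels = labels_kept, kept = kept,
       reference = reference, cfg = cfg)
}
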