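# The multiple-instance regressor: each spot is a bag of cells, a shared
# feed-forward scorer predicts per-cell gene scores, and the bag mean is
# trained against the measured spot profile.

#' Training configuration
#'
#' @param learning_rate AdamW learning rate (default 1e-4).
#' @param batch_size bags (spots) per optimization step (default 128).
#' @param val_fraction fraction of spots held out for validation (default
#'   0.20). The split is by spot, so a spot's cells never straddle the split.
#' @param patience early-stopping patience in epochs (default 20).
#' @param max_epochs hard cap on epochs (default 400; in practice patience,
#'   not the cap, terminates training).
#' @param weight_decay decoupled AdamW weight decay on weight matrices
#'   (default 0.01).
#' @param hidden_dim,n_hidden scorer architecture: `n_hidden` hidden layers of
#'   width `hidden_dim` (default 3 x 256).
#' @param seed root seed; the split, weight init and epoch shuffles use
#'   independent streams derived from it.
#' @param verbose print per-epoch losses.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128,
                         val_fraction = 0.20, patience = 20, max_epochs = 400,
                         weight_decay = 0.01, hidden_dim = 256, n_hidden = 3,
                         seed = 0, verbose = FALSE) {
  stopifnot(val_fraction > 0, val_fraction < 1, patience >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 val_fraction = val_fraction, patience = patience,
                 max_epochs = max_epochs, weight_decay = weight_decay,
                 hidden_dim = hidden_dim, n_hidden = n_hidden,
                 seed = seed, verbose = verbose),
            class = "train_config")
}

#' Mean bag aggregation
#'
#' Aggregates instance-level predictions to a bag (spot) prediction by the
#' arithmetic mean over the k_s cells of the spot, emulating the measurement
#' process in which a spot's signal pools its cells. Permutation invariant.
#'
#' @param instance_preds k_s x G matrix of per-cell predictions.
#' @return numeric vector of length G.
#' @export
aggregate_bag <- function(instance_preds) {
  instance_preds <- as.matrix(instance_preds)
  if (nrow(instance_preds) == 0L)
    stop("empty bag: spots without cells should be filtered before aggregation")
  colMeans(instance_preds)
}

#' Mean squared error loss
#'
#' L = (1/(S*G)) * sum_ij (pred_ij - target_ij)^2 over all spots and genes,
#' computed on preprocessed (log-normalized, robust-scaled) expression.
#'
#' @param pred,target S x G matrices of matching shape.
#' @return scalar loss.
#' @export
mse_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target))) stop("shape mismatch in mse_loss")
  mean((pred - target)^2)
}

# Negative binomial log pmf with mean mu and inverse overdispersion alpha
# (variance mu + mu^2/alpha), in log-gamma form.
nb_log_pmf <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-12)
  lgamma(y + alpha) - lgamma(alpha) - lgamma(y + 1) +
    alpha * (log(alpha) - log(alpha + mu)) +
    y * (log(mu) - log(alpha + mu))
}

#' Negative binomial negative log-likelihood
#'
#' Counts are modelled as negative binomial with mean mu_ij = l_i * pred_ij
#' (the spot library factor times the predicted mean) and gene-wise inverse
#' overdispersion alpha_j, so variance = mu + mu^2/alpha. Returns
#' -(1/S) * sum over all spots and genes of the log pmf.
#'
#' @param pred_mean S x G matrix of positive predicted means.
#' @param counts S x G matrix of non-negative integer counts.
#' @param alpha positive vector of G gene-wise inverse overdispersions.
#' @param l positive vector of S library factors (library size / median
#'   training library size).
#' @return scalar loss.
#' @export
nb_nll_loss <- function(pred_mean, counts, alpha, l) {
  pred_mean <- as.matrix(pred_mean); counts <- as.matrix(counts)
  if (!identical(dim(pred_mean), dim(counts))) stop("shape mismatch in nb_nll_loss")
  if (!is_wholenumber(counts)) stop("counts must be integer-valued")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(pred_mean <= 0)) stop("pred_mean must be positive")
  S <- nrow(counts)
  mu <- pred_mean * l
  lp <- nb_log_pmf(counts, mu, rep(alpha, each = S))
  -sum(lp) / S
}

#' Spot library factors
#'
#' l_i = library size of spot i divided by the median library size over the
#' training spots, so that the median factor over training spots is 1. Used as
#' a multiplicative offset on the negative-binomial mean so the model does not
#' absorb sequencing depth into the per-cell scores.
#'
#' @param counts spots x genes count matrix.
#' @param train_idx index of training spots (default: all).
#' @return list with `l` (length-S factor vector) and `median_libsize`.
#' @export
library_factors <- function(counts, train_idx = NULL) {
  lib <- rowSums(as.matrix(counts))
  train_idx <- train_idx %||% seq_along(lib)
  med <- stats::median(lib[train_idx])
  if (med <= 0) stop("non-positive median library size")
  list(l = lib / med, median_libsize = med)
}

# Shared minibatch training loop. X: instance embeddings; inst_by_spot: list
# of instance row indices per spot (all spots); the target block depends on
# the loss. Returns the best-validation-epoch weights and the loss history.
train_core <- function(X, inst_by_spot, loss_kind, target, counts, l,
                       cfg, G) {
  S <- length(inst_by_spot)
  d <- ncol(X)
  set.seed(derive_seed(cfg$seed, "split"))
  n_val <- max(1L, round(cfg$val_fraction * S))
  val_idx <- sort(sample.int(S, n_val))
  train_idx <- setdiff(seq_len(S), val_idx)
  if (length(train_idx) < 1L) stop("no training spots after the validation split")

  out_mean <- if (loss_kind == "mse") {
    colMeans(target[train_idx, , drop = FALSE])
  } else {
    colMeans(counts[train_idx, , drop = FALSE] / l[train_idx])
  }
  net <- nn_init(d, G, hidden = cfg$hidden_dim, n_hidden = cfg$n_hidden,
                 seed = cfg$seed, out_mean = out_mean)
  log_alpha <- if (loss_kind == "nb_nll") rep(0, G) else NULL
  params <- nn_flatten(net, log_alpha)
  decay_mask <- lapply(names(params), function(k) grepl("^W", k))
  names(decay_mask) <- names(params)
  state <- adamw_init(params)

  val_inst <- unlist(inst_by_spot[val_idx], use.names = FALSE)
  val_bag <- rep(seq_along(val_idx), lengths(inst_by_spot[val_idx]))
  val_k <- lengths(inst_by_spot[val_idx])

  eval_loss <- function(net, log_alpha, idx, inst, bag, k) {
    P <- nn_forward(net, X[inst, , drop = FALSE])
    Yhat <- rowsum(P, bag, reorder = FALSE) / k
    if (loss_kind == "mse") {
      mse_loss(Yhat, target[idx, , drop = FALSE])
    } else {
      mu <- pmax(Yhat * l[idx], 1e-12)
      -sum(nb_log_pmf(counts[idx, , drop = FALSE], mu,
                      rep(exp(log_alpha), each = length(idx)))) / length(idx)
    }
  }

  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  since_improve <- 0L
  history <- vector("list", cfg$max_epochs)

  set.seed(derive_seed(cfg$seed, "shuffle"))
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(train_idx)
    batch_starts <- seq(1L, length(perm), by = cfg$batch_size)
    epoch_loss <- 0; epoch_n <- 0L
    for (st in batch_starts) {
      spots <- perm[st:min(st + cfg$batch_size - 1L, length(perm))]
      k <- lengths(inst_by_spot[spots])
      inst <- unlist(inst_by_spot[spots], use.names = FALSE)
      bag <- rep(seq_along(spots), k)
      net <- nn_unflatten(params, net)
      fwd <- nn_forward(net, X[inst, , drop = FALSE], cache = TRUE)
      Yhat <- rowsum(fwd$P, bag, reorder = FALSE) / k
      B <- length(spots)
      if (loss_kind == "mse") {
        diff <- Yhat - target[spots, , drop = FALSE]
        loss <- mean(diff^2)
        dYhat <- 2 * diff / (B * G)
        g_alpha <- NULL
      } else {
        alpha <- exp(params$log_alpha)
        mu <- pmax(Yhat * l[spots], 1e-12)
        y <- counts[spots, , drop = FALSE]
        a <- rep(alpha, each = B)
        loss <- -sum(nb_log_pmf(y, mu, a)) / B
        dmu <- -(y / mu - (y + a) / (a + mu)) / B
        dYhat <- dmu * l[spots]
        dlp_da <- digamma(y + a) - digamma(a) + log(a / (a + mu)) +
          1 - (y + a) / (a + mu)
        g_alpha <- -colSums(dlp_da) / B * alpha
      }
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate or check the inputs")
      dP <- (dYhat / k)[bag, , drop = FALSE]
      grads <- nn_backward(net, fwd, dP)
      gflat <- nn_flatten(list(W = grads$W, b = grads$b, dims = net$dims), g_alpha)
      upd <- adamw_step(params, gflat, state, lr = cfg$learning_rate,
                        weight_decay = cfg$weight_decay, decay_mask = decay_mask)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + loss * B
      epoch_n <- epoch_n + B
    }
    net <- nn_unflatten(params, net)
    val_loss <- eval_loss(net, params$log_alpha, val_idx, val_inst, val_bag, val_k)
    if (!is.finite(val_loss))
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    history[[epoch]] <- c(epoch = epoch, train_loss = epoch_loss / epoch_n,
                          val_loss = val_loss)
    if (cfg$verbose)
      message(sprintf("epoch %3d train %.6f val %.6f", epoch,
                      epoch_loss / epoch_n, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) break
    }
  }
  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, TRUE)]))
  net <- nn_unflatten(best_params, net)
  list(net = net,
       log_alpha = best_params$log_alpha,
       history = history, best_epoch = best_epoch, best_val = best_val,
       train_idx = train_idx, val_idx = val_idx)
}

#' Train the multiple-instance expression regressor
#'
#' Learns an instance-level scorer f(h) from spot-level supervision: per spot,
#' the mean of the per-cell predictions over the bag is compared to the
#' measured spot profile. With `loss = "mse"` the targets are log-normalized
#' and robust-scaled spot vectors (scaler fitted on the training split, per
#' slide); with `loss = "nb_nll"` the targets are the raw counts under a
#' negative binomial likelihood with library-size offsets (median computed on
#' the training split) and gene-wise learned inverse overdispersion. 20% of
#' spots are held out as a validation set and the weights from the epoch with
#' the lowest validation loss are returned (early stopping with patience).
#'
#' @param bags a [bag_assignment] mapping spots to member cells.
#' @param embeddings an [embedding_matrix] whose rownames cover all bag
#'   members.
#' @param sc a [spot_counts] on the same spots (apply [qc_filter()] first).
#' @param cfg a [train_config()].
#' @param loss `"mse"` or `"nb_nll"`.
#' @param genes optional gene subset: a character vector of gene ids or a
#'   selection tibble with a `gene_id` column (e.g. from [select_hvg()]).
#' @return a fitted `mil_model` with elements `history` (per-epoch train and
#'   validation loss), `alpha` (for the NB loss), `scaler_params` (for the MSE
#'   loss) and the best-epoch weights.
#' @export
train_mil <- function(bags, embeddings, sc, cfg = train_config(),
                      loss = c("mse", "nb_nll"), genes = NULL) {
  loss <- match.arg(loss)
  stopifnot(inherits(bags, "bag_assignment"), inherits(sc, "spot_counts"))
  if (is.data.frame(genes)) genes <- genes$gene_id
  gene_ids <- genes %||% sc$gene_ids
  if (!all(gene_ids %in% sc$gene_ids)) stop("unknown gene id(s) in `genes`")
  spot_ids <- intersect(sc$spot_ids, names(bags$spot_to_cells))
  if (length(spot_ids) < 2L) stop("need at least 2 spots shared by counts and bags")
  member_lists <- bags$spot_to_cells[spot_ids]
  empty <- lengths(member_lists) == 0L
  if (any(empty)) {
    warning(sum(empty), " spot(s) with empty bags were dropped")
    spot_ids <- spot_ids[!empty]
    member_lists <- member_lists[!empty]
  }
  all_members <- unlist(member_lists, use.names = FALSE)
  if (!all(all_members %in% rownames(embeddings)))
    stop("bag members missing from the embedding matrix")
  X <- unname(embeddings[all_members, , drop = FALSE])
  inst_by_spot <- split(seq_along(all_members),
                        rep(seq_along(member_lists), lengths(member_lists)))
  counts <- sc$counts[spot_ids, gene_ids, drop = FALSE]
  slide <- sc$slide[match(spot_ids, sc$spot_ids)]
  G <- length(gene_ids)

  # the split must be known before target preprocessing (fit-on-train rule),
  # so replicate the seeded split here
  set.seed(derive_seed(cfg$seed, "split"))
  S <- length(spot_ids)
  val_idx <- sort(sample.int(S, max(1L, round(cfg$val_fraction * S))))
  train_idx <- setdiff(seq_len(S), val_idx)

  target <- NULL; l <- NULL; scaler_params <- NULL
  if (loss == "mse") {
    Yp <- lognormalize(counts)
    # scale-only (no centring): the softplus head emits non-negative scores,
    # so centred targets would be unreachable for half the values
    fit <- robust_scale(Yp[train_idx, , drop = FALSE], slide = slide[train_idx],
                        center = FALSE)
    scaler_params <- fit$params
    target <- robust_scale(Yp, slide = slide, params = scaler_params)$values
  } else {
    lf <- library_factors(counts, train_idx)
    l <- lf$l
  }
  res <- train_core(X, inst_by_spot, loss, target, counts, l, cfg, G)
  structure(
    list(net = res$net, loss_kind = loss,
         alpha = if (loss == "nb_nll") exp(res$log_alpha) else NULL,
         gene_ids = gene_ids, scaler_params = scaler_params,
         cfg = cfg, history = res$history, best_epoch = res$best_epoch,
         best_val_loss = res$best_val,
         input_dim = ncol(X), level = "spot",
         encoder_tag = attr(embeddings, "encoder_tag") %||% "unknown",
         spot_ids = spot_ids, val_spots = spot_ids[res$val_idx]),
    class = "mil_model")
}

#' Train the fully supervised baseline
#'
#' Same architecture, loss and early-stopping protocol as the MIL regressor,
#' but trained directly on matched per-cell expression (available in
#' simulations only): MSE on per-cell log-normalized, robust-scaled targets,
#' each cell its own bag. Serves as an upper reference for what is learnable
#' from the embeddings.
#'
#' @param E_cells embedding matrix (cells x d).
#' @param Y_cells matched per-cell expression matrix (cells x genes, raw
#'   scale). Cells with zero totals are dropped with a warning.
#' @param cfg a [train_config()].
#' @return a fitted `mil_model` with `level = "cell"`.
#' @export
train_supervised <- function(E_cells, Y_cells, cfg = train_config()) {
  Y_cells <- as.matrix(Y_cells)
  stopifnot(nrow(E_cells) == nrow(Y_cells))
  tot <- rowSums(Y_cells)
  if (any(tot <= 0)) {
    warning(sum(tot <= 0), " zero-total cell(s) dropped")
    E_cells <- E_cells[tot > 0, , drop = FALSE]
    Y_cells <- Y_cells[tot > 0, , drop = FALSE]
  }
  N <- nrow(Y_cells)
  gene_ids <- colnames(Y_cells) %||% default_ids(ncol(Y_cells), "gene_")
  set.seed(derive_seed(cfg$seed, "split"))
  val_idx <- sort(sample.int(N, max(1L, round(cfg$val_fraction * N))))
  train_idx <- setdiff(seq_len(N), val_idx)
  Yp <- lognormalize(Y_cells)
  fit <- robust_scale(Yp[train_idx, , drop = FALSE], center = FALSE)
  target <- robust_scale(Yp, params = fit$params)$values
  inst_by_spot <- as.list(seq_len(N))
  res <- train_core(unname(as.matrix(E_cells)), inst_by_spot, "mse", target,
                    NULL, NULL, cfg, ncol(Y_cells))
  structure(
    list(net = res$net, loss_kind = "mse", alpha = NULL,
         gene_ids = gene_ids, scaler_params = fit$params,
         cfg = cfg, history = res$history, best_epoch = res$best_epoch,
         best_val_loss = res$best_val,
         input_dim = ncol(E_cells), level = "cell",
         encoder_tag = attr(E_cells, "encoder_tag") %||% "unknown"),
    class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %s loss, %d genes, input dim %d, best epoch %d (val %.5f)\n",
              x$loss_kind, length(x$gene_ids), x$input_dim, x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' Predict per-cell gene scores
#'
#' Applies the trained instance scorer to every embedding row. Outputs are
#' non-negative by the softplus contract. When the model was trained with the
#' MSE loss on robust-scaled targets and `unscale = TRUE`, the stored scaler
#' is inverted so the scores are on the log-normalized expression scale.
#'
#' @param model a fitted `mil_model`.
#' @param E embedding matrix (cells x d), d matching the model input.
#' @param unscale invert the training robust scaler (default TRUE).
#' @param slide per-cell slide assignment for multi-slide scalers (default:
#'   the first stored slide).
#' @return a [cell_prediction].
#' @export
predict_cells <- function(model, E, unscale = TRUE, slide = NULL) {
  stopifnot(inherits(model, "mil_model"))
  E <- as.matrix(E)
  if (ncol(E) != model$input_dim)
    stop(sprintf("embedding dimension %d does not match model input %d",
                 ncol(E), model$input_dim))
  P <- nn_forward(model$net, unname(E))
  if (unscale && !is.null(model$scaler_params))
    P <- inverse_robust_scale(P, model$scaler_params, slide = slide)
  cell_prediction(P, cell_ids = rownames(E) %||% default_ids(nrow(E), "cell_"),
                  gene_ids = model$gene_ids)
}

#' Predict spot-level expression
#'
#' Aggregates the per-cell predictions over each bag with the mean, the same
#' pooling used during training.
#'
#' @param model a fitted `mil_model`.
#' @param bags a [bag_assignment].
#' @param E embedding matrix covering all bag members.
#' @param unscale see [predict_cells()].
#' @return S x G matrix of spot predictions (spots with empty bags are skipped
#'   with a warning).
#' @export
predict_spots <- function(model, bags, E, unscale = TRUE) {
  stopifnot(inherits(bags, "bag_assignment"))
  keep <- bags$k_s >= 1L
  if (any(!keep)) warning(sum(!keep), " empty bag(s) skipped")
  lists <- bags$spot_to_cells[keep]
  members <- unlist(lists, use.names = FALSE)
  pred <- predict_cells(model, E[members, , drop = FALSE], unscale = unscale)
  grp <- rep(seq_along(lists), lengths(lists))
  out <- rowsum(pred$scores, grp, reorder = FALSE) / lengths(lists)
  rownames(out) <- names(lists)
  colnames(out) <- model$gene_ids
  out
}
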