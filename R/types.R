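#' Spot-level count container
#'
#' Bundles a spots-by-genes matrix of raw transcript counts with the spot
#' geometry needed to link detected cells to spots: full-resolution pixel
#' coordinates of each spot centre and the capture-spot radius. This is the
#' unit at which sequencing-based spatial transcriptomics (e.g. Visium)
#' measures expression; each spot typically covers 10-20 cells.
#'
#' @param counts numeric matrix, spots in rows, genes in columns, raw
#'   non-negative counts. Row and column names are used as spot and gene ids
#'   when `spot_ids`/`gene_ids` are not given.
#' @param spot_xy numeric matrix (S x 2) of spot-centre coordinates in pixels,
#'   full-resolution frame, origin top-left, x = column, y = row.
#' @param spot_radius positive scalar, spot radius in the same pixel units.
#' @param spot_ids,gene_ids character identifiers; must be unique.
#' @param slide_id single identifier for the slide.
#' @param slide optional per-spot slide assignment (defaults to `slide_id`);
#'   used by per-slide scaling when several slides are stacked.
#' @param check_integer should counts be required to be integer-valued?
#'   Measured data always is; the centroid simulation scenario assigns
#'   per-cluster mean expression and produces fractional sums, so the
#'   simulator disables the check there.
#' @return an object of class `spot_counts`.
#' @export
spot_counts <- function(counts, spot_xy, spot_radius,
                        spot_ids = rownames(counts),
                        gene_ids = colnames(counts),
                        slide_id = "slide",
                        slide = NULL,
                        check_integer = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(spot_ids)) spot_ids <- default_ids(nrow(counts), "spot_")
  if (is.null(gene_ids)) gene_ids <- default_ids(ncol(counts), "gene_")
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (length(spot_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("spot/gene id lengths do not match the count matrix dimensions")
  if (anyDuplicated(spot_ids)) stop("spot ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (check_integer && !is_wholenumber(counts))
    stop("counts must be integer-valued")
  spot_xy <- as.matrix(spot_xy)
  if (nrow(spot_xy) != nrow(counts) || ncol(spot_xy) != 2L)
    stop("spot_xy must be an S x 2 matrix matching the count matrix")
  if (!all(is.finite(spot_xy))) stop("spot coordinates must be finite")
  if (!is.numeric(spot_radius) || length(spot_radius) != 1L || spot_radius <= 0)
    stop("spot_radius must be a positive scalar")
  dimnames(counts) <- list(spot_ids, gene_ids)
  colnames(spot_xy) <- c("x", "y")
  rownames(spot_xy) <- spot_ids
  slide <- slide %||% rep(slide_id, nrow(counts))
  structure(
    list(counts = counts, spot_ids = spot_ids, gene_ids = gene_ids,
         spot_xy = spot_xy, spot_radius = spot_radius,
         slide_id = slide_id, slide = as.character(slide)),
    class = "spot_counts"
  )
}

#' @export
print.spot_counts <- function(x, ...) {
  cat(sprintf("<spot_counts> %d spots x %d genes, slide '%s', radius %.1f px\n",
              nrow(x$counts), ncol(x$counts), x$slide_id, x$spot_radius))
  invisible(x)
}

#' @export
dim.spot_counts <- function(x) dim(x$counts)

#' Detected-cell table
#'
#' Validates a table of detected cells (one row per cell) into the canonical
#' tibble used throughout the package: columns `cell_id`, `x`, `y`, optional
#' `slide_id`, `label` (broad type, e.g. neoplastic / connective /
#' inflammatory) and `crop_ref` (opaque reference to the cell image crop).
#' Coordinates are in the same full-resolution pixel frame as spot centres.
#'
#' @param df data frame with at least cell id and x/y coordinate columns.
#'   `id` is accepted as an alias for `cell_id`.
#' @return a tibble with validated columns.
#' @export
cell_table <- function(df) {
  df <- tibble::as_tibble(df)
  if ("id" %in% names(df) && !"cell_id" %in% names(df))
    df <- dplyr::rename(df, cell_id = "id")
  need <- c("cell_id", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) {
    dup <- unique(df$cell_id[duplicated(df$cell_id)])
    stop("duplicate cell id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite '%s' coordinate at row %d", col, bad[1]))
    df[[col]] <- v
  }
  df
}

#' Cell embedding matrix
#'
#' An N x d real matrix of per-cell image embeddings h = f(x), rows aligned to
#' a cell table by cell id (rownames). The encoder that produced it is
#' recorded in the `encoder_tag` attribute; the learning stage is agnostic to
#' how embeddings were obtained (self-supervised network, transfer learning,
#' one-hot type encodings, or the synthetic encoder used for simulations).
#'
#' @param values numeric N x d matrix.
#' @param cell_ids character vector of N unique ids (default: rownames).
#' @param encoder_tag provenance string.
#' @return the validated matrix with rownames set and an `encoder_tag`
#'   attribute.
#' @export
embedding_matrix <- function(values, cell_ids = rownames(values),
                             encoder_tag = "external") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- default_ids(nrow(values), "cell_")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match embedding rows")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (!all(is.finite(values))) stop("embedding entries must be finite")
  rownames(values) <- cell_ids
  attr(values, "encoder_tag") <- encoder_tag
  values
}

#' Spot-to-cell bag assignment
#'
#' Records which cells fall inside which spot: each spot is a bag of cell
#' instances, and bag size k_s is the number of cells in the spot. A cell
#' belongs to at most one bag; cells outside every spot are listed as
#' unassigned.
#'
#' @param spot_to_cells named list (one element per spot) of character vectors
#'   of cell ids.
#' @param cell_ids all known cell ids (members plus unassigned).
#' @param unassigned cell ids not claimed by any spot.
#' @return an object of class `bag_assignment`.
#' @export
bag_assignment <- function(spot_to_cells, cell_ids = NULL, unassigned = character()) {
  if (is.null(names(spot_to_cells)))
    names(spot_to_cells) <- paste0("spot_", seq_along(spot_to_cells))
  members <- unlist(spot_to_cells, use.names = FALSE)
  if (anyDuplicated(members))
    stop("a cell may belong to at most one spot's bag")
  cell_ids <- cell_ids %||% c(members, unassigned)
  if (!all(members %in% cell_ids)) stop("bag members missing from cell_ids")
  structure(
    list(spot_to_cells = spot_to_cells,
         k_s = lengths(spot_to_cells),
         cell_ids = cell_ids,
         unassigned = unassigned),
    class = "bag_assignment"
  )
}

#' @export
print.bag_assignment <- function(x, ...) {
  cat(sprintf("<bag_assignment> %d spots, %d assigned cells (%d unassigned), k_s in [%s]\n",
              length(x$spot_to_cells), sum(x$k_s), length(x$unassigned),
              paste(range(c(x$k_s, Inf * 0)), collapse = ", ")))
  invisible(x)
}

#' Per-cell predicted expression scores
#'
#' Wraps the N x G matrix of non-negative per-cell gene scores produced by a
#' trained instance regressor. Non-negativity is the softplus output contract.
#'
#' @param scores numeric N x G matrix, entries >= 0, dimnames = cell and gene
#'   ids.
#' @param cell_ids,gene_ids identifiers (default from dimnames).
#' @return an object of class `cell_prediction`.
#' @export
cell_prediction <- function(scores, cell_ids = rownames(scores),
                            gene_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(cell_ids)) cell_ids <- default_ids(nrow(scores), "cell_")
  if (is.null(gene_ids)) gene_ids <- default_ids(ncol(scores), "gene_")
  if (length(cell_ids) != nrow(scores) || length(gene_ids) != ncol(scores))
    stop("id lengths do not match score matrix dimensions")
  if (nrow(scores) > 0 && any(scores < 0))
    stop("predicted scores must be non-negative")
  dimnames(scores) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(list(scores = scores,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "cell_prediction")
}

#' @export
print.cell_prediction <- function(x, ...) {
  cat(sprintf("<cell_prediction> %d cells x %d genes\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
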