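# Readers/writers for the MatrixMarket + TSV bundles and cell tables.

read_table_auto <- function(path, header = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = header, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a Space-Ranger-style count bundle
#'
#' Reads a MatrixMarket count matrix with barcode and feature sidecars plus a
#' tissue-positions table, and returns a [spot_counts] restricted to
#' in-tissue barcodes. Matrices stored genes-in-rows (the Space Ranger
#' convention) are detected from the sidecar lengths and transposed so the
#' internal orientation is always spots-in-rows. Positions tables are accepted
#' with or without a header, with columns
#' (barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
#' pxl_col_in_fullres); pixel row/column are converted to the internal
#' top-left-origin frame with x = column and y = row.
#'
#' @param matrix_path path to the `.mtx` file (integer counts).
#' @param barcodes_path,features_path one-id-per-line TSV sidecars (features
#'   may have extra columns; the first is used).
#' @param positions_path CSV positions table.
#' @param spot_radius spot radius in full-resolution pixels. The pixel size of
#'   the slide scan varies, so the radius is a required input rather than a
#'   constant.
#' @param slide_id slide identifier.
#' @return a [spot_counts] containing only in-tissue barcodes. Barcodes absent
#'   from the positions table are dropped with a warning.
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path,
                        positions_path, spot_radius, slide_id = "slide",
                        check_integer = TRUE) {
  for (p in c(matrix_path, barcodes_path, features_path, positions_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_table_auto(barcodes_path, header = FALSE)[[1]]
  feats <- read_table_auto(features_path, header = FALSE)
  features <- as.character(feats[[1]])
  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nb && ncol(m) == nf) {
    # already spots x genes
  } else if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions (%d x %d) do not match barcode (%d) / feature (%d) sidecars",
      nrow(m), ncol(m), nb, nf))
  }
  pos <- read_positions(positions_path)
  missing <- setdiff(barcodes, pos$barcode)
  if (length(missing)) {
    warning(length(missing), " barcode(s) missing from the positions table were dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
  keep <- !is.na(pos$barcode) & pos$in_tissue == 1
  m <- as.matrix(m[keep, , drop = FALSE])
  pos <- pos[keep, , drop = FALSE]
  spot_counts(m, spot_xy = cbind(x = pos$x, y = pos$y),
              spot_radius = spot_radius,
              spot_ids = barcodes[keep], gene_ids = features,
              slide_id = slide_id, check_integer = check_integer)
}

#' Read a tissue-positions table
#'
#' Accepts both the headered and headerless dialects. Returns a tibble with
#' columns `barcode`, `in_tissue`, `array_row`, `array_col`, `x`, `y` where
#' x is the full-resolution pixel column and y the pixel row.
#'
#' @param path CSV file.
#' @return tibble of spot positions.
#' @export
read_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(pos) < 6L) stop("positions table must have 6 columns")
    names(pos)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                         "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  names(pos) <- tolower(names(pos))
  row_col <- grep("pxl_row", names(pos), value = TRUE)[1]
  col_col <- grep("pxl_col", names(pos), value = TRUE)[1]
  if (is.na(row_col) || is.na(col_col))
    stop("positions table lacks pxl_row/pxl_col columns")
  tibble::tibble(
    barcode = as.character(pos$barcode),
    in_tissue = as.integer(pos$in_tissue),
    array_row = pos$array_row, array_col = pos$array_col,
    x = as.numeric(pos[[col_col]]),
    y = as.numeric(pos[[row_col]])
  )
}

#' Read a detected-cell table
#'
#' Reads a delimited table (CSV or TSV by extension) with at least id, x and y
#' columns — typically the output of an external nucleus
#' segmentation/classification model — and validates it via [cell_table()].
#'
#' @param path file path.
#' @return tibble with `cell_id`, `x`, `y` and any extra columns (e.g.
#'   `label`) preserved.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  cell_table(read_table_auto(path, header = TRUE))
}

#' Write / read per-cell predictions
#'
#' Predictions are stored as a sparse MatrixMarket matrix `scores.mtx` with
#' `cells.tsv` and `genes.tsv` id sidecars inside `dir`. Reading back
#' reproduces the values to serialization precision.
#'
#' @param pred a [cell_prediction].
#' @param dir output directory (created if needed).
#' @return `write_prediction` returns `dir` invisibly; `read_prediction`
#'   returns a [cell_prediction].
#' @export
write_prediction <- function(pred, dir) {
  stopifnot(inherits(pred, "cell_prediction"))
  if (nrow(pred$scores) > 0 && any(pred$scores < 0))
    stop("predicted scores must be non-negative")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(pred$scores, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "scores.mtx"))
  writeLines(pred$cell_ids, file.path(dir, "cells.tsv"))
  writeLines(pred$gene_ids, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_prediction
#' @export
read_prediction <- function(dir) {
  scores <- as.matrix(Matrix::readMM(file.path(dir, "scores.mtx")))
  cells <- readLines(file.path(dir, "cells.tsv"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  if (length(cells) != nrow(scores) || length(genes) != ncol(scores))
    stop("prediction sidecars do not match the score matrix")
  cell_prediction(scores, cells, genes)
}

#' Write / read a spot-count bundle
#'
#' Writes `matrix.mtx` (spots x genes), `barcodes.tsv`, `features.tsv`, a
#' headered `positions.csv` and a small `meta.json` carrying the spot radius
#' and slide id, so a bundle round-trips without external information.
#'
#' @param sc a [spot_counts].
#' @param dir output directory.
#' @return `write_spot_counts` returns `dir` invisibly; `read_spot_counts`
#'   a [spot_counts].
#' @export
write_spot_counts <- function(sc, dir) {
  stopifnot(inherits(sc, "spot_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(sc$counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(sc$spot_ids, file.path(dir, "barcodes.tsv"))
  writeLines(sc$gene_ids, file.path(dir, "features.tsv"))
  utils::write.csv(
    data.frame(barcode = sc$spot_ids, in_tissue = 1L,
               array_row = 0L, array_col = 0L,
               pxl_row_in_fullres = sc$spot_xy[, "y"],
               pxl_col_in_fullres = sc$spot_xy[, "x"]),
    file.path(dir, "positions.csv"), row.names = FALSE)
  jsonlite::write_json(list(spot_radius = sc$spot_radius, slide_id = sc$slide_id,
                            integer_counts = is_wholenumber(sc$counts)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_spot_counts
#' @export
read_spot_counts <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  read_counts(file.path(dir, "matrix.mtx"), file.path(dir, "barcodes.tsv"),
              file.path(dir, "features.tsv"), file.path(dir, "positions.csv"),
              spot_radius = meta$spot_radius, slide_id = meta$slide_id,
              check_integer = isTRUE(meta$integer_counts))
}

#' Read / write an embedding matrix as TSV
#'
#' TSV with `cell_id` as the first column and one numeric column per
#' embedding dimension.
#'
#' @param path file path.
#' @param E an [embedding_matrix].
#' @return `read_embeddings` returns an [embedding_matrix].
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  embedding_matrix(as.matrix(df[, -1, drop = FALSE]), cell_ids = df[[1]],
                   encoder_tag = "external_file")
}

#' @rdname read_embeddings
#' @export
write_embeddings <- function(E, path) {
  df <- data.frame(cell_id = rownames(E), as.data.frame(unclass(E)[, , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
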