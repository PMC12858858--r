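# Domain types and file round trips.

test_that("spot_counts validates ids, geometry and integer counts", {
  m <- matrix(c(3, 0, 0, 5), 2, 2)
  sc <- spot_counts(m, cbind(c(0, 10), c(0, 0)), spot_radius = 3)
  expect_s3_class(sc, "spot_counts")
  expect_equal(dim(sc), c(2L, 2L))
  expect_error(spot_counts(m, cbind(c(0, 10), c(0, 0)), spot_radius = 0),
               "positive")
  expect_error(spot_counts(matrix(c(1.5, 0, 0, 2), 2, 2),
                           cbind(c(0, 10), c(0, 0)), 3), "integer")
  expect_error(spot_counts(m, cbind(c(0, 10), c(0, 0)), 3,
                           spot_ids = c("a", "a")), "unique")
})

test_that("mtx bundle round-trips and respects the in-tissue flag", {
  d <- withr::local_tempdir()
  m <- matrix(c(3L, 0L, 0L, 5L), 2, 2,
              dimnames = list(c("BC1", "BC2"), c("geneA", "geneB")))
  sc <- spot_counts(m, cbind(x = c(100, 200), y = c(50, 60)), spot_radius = 10)
  write_spot_counts(sc, d)
  back <- read_spot_counts(d)
  expect_equal(back$counts, sc$counts)
  expect_equal(back$spot_xy, sc$spot_xy)
  expect_equal(back$spot_radius, sc$spot_radius)

  # flag the second barcode out of tissue: it must be dropped
  pos <- read.csv(file.path(d, "positions.csv"))
  pos$in_tissue[2] <- 0L
  write.csv(pos, file.path(d, "positions.csv"), row.names = FALSE)
  back2 <- read_spot_counts(d)
  expect_equal(nrow(back2$counts), 1L)
  expect_equal(back2$spot_ids, "BC1")
})

test_that("read_counts rejects sidecar/matrix dimension mismatch and drops unknown barcodes", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(3, 0, 0, 5), 2, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(d, "m.mtx"))
  writeLines(c("BC1", "BC2"), file.path(d, "b.tsv"))
  writeLines(c("g1", "g2", "g3"), file.path(d, "f3.tsv"))
  writeLines(c("g1", "g2"), file.path(d, "f2.tsv"))
  write.csv(data.frame(barcode = c("BC1", "BC2"), in_tissue = 1,
                       array_row = 0, array_col = 0,
                       pxl_row_in_fullres = c(1, 2),
                       pxl_col_in_fullres = c(3, 4)),
            file.path(d, "pos.csv"), row.names = FALSE)
  expect_error(read_counts(file.path(d, "m.mtx"), file.path(d, "b.tsv"),
                           file.path(d, "f3.tsv"), file.path(d, "pos.csv"), 5),
               "do not match")
  ok <- read_counts(file.path(d, "m.mtx"), file.path(d, "b.tsv"),
                    file.path(d, "f2.tsv"), file.path(d, "pos.csv"), 5)
  expect_equal(unname(ok$counts), matrix(c(3, 0, 0, 5), 2, 2))
  # x = pixel column, y = pixel row
  expect_equal(unname(ok$spot_xy[, "x"]), c(3, 4))
  expect_equal(unname(ok$spot_xy[, "y"]), c(1, 2))

  # a barcode absent from the positions table is dropped with a warning
  write.csv(data.frame(barcode = "BC1", in_tissue = 1, array_row = 0,
                       array_col = 0, pxl_row_in_fullres = 1,
                       pxl_col_in_fullres = 3),
            file.path(d, "pos1.csv"), row.names = FALSE)
  expect_warning(
    one <- read_counts(file.path(d, "m.mtx"), file.path(d, "b.tsv"),
                       file.path(d, "f2.tsv"), file.path(d, "pos1.csv"), 5),
    "missing from the positions")
  expect_equal(one$spot_ids, "BC1")
})

test_that("genes-in-rows matrices are transposed to spots-in-rows", {
  d <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(1:6, 3, 2), sparse = TRUE)  # 3 genes x 2 spots
  Matrix::writeMM(m, file.path(d, "m.mtx"))
  writeLines(c("BC1", "BC2"), file.path(d, "b.tsv"))
  writeLines(c("g1", "g2", "g3"), file.path(d, "f.tsv"))
  write.csv(data.frame(barcode = c("BC1", "BC2"), in_tissue = 1,
                       array_row = 0, array_col = 0,
                       pxl_row_in_fullres = 0, pxl_col_in_fullres = 0),
            file.path(d, "pos.csv"), row.names = FALSE)
  sc <- read_counts(file.path(d, "m.mtx"), file.path(d, "b.tsv"),
                    file.path(d, "f.tsv"), file.path(d, "pos.csv"), 5)
  expect_equal(dim(sc$counts), c(2L, 3L))
  expect_equal(unname(sc$counts["BC1", ]), c(1, 2, 3))
})

test_that("cell tables validate ids, coordinates and keep labels", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cells.csv")
  write.csv(data.frame(id = c("a", "b", "c"), x = 1:3, y = 4:6,
                       label = c("neoplastic", "connective", "inflammatory")),
            f, row.names = FALSE)
  ct <- read_cell_table(f)
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$label, c("neoplastic", "connective", "inflammatory"))

  write.csv(data.frame(id = c("a", "a"), x = 1:2, y = 1:2), f, row.names = FALSE)
  expect_error(read_cell_table(f), "duplicate")

  write.csv(data.frame(id = c("a", "b"), x = c("1", "oops"), y = 1:2),
            f, row.names = FALSE)
  expect_error(read_cell_table(f), "row 2")
})

test_that("prediction write/read round-trips, rejects negatives, allows empty", {
  d <- withr::local_tempdir()
  p <- cell_prediction(matrix(c(0.5, 0, 1.25, 3), 2, 2),
                       cell_ids = c("c1", "c2"), gene_ids = c("g1", "g2"))
  write_prediction(p, file.path(d, "pred"))
  back <- read_prediction(file.path(d, "pred"))
  expect_equal(back$scores, p$scores)

  expect_error(cell_prediction(matrix(c(-1, 0, 0, 0), 2, 2)), "non-negative")

  empty <- cell_prediction(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("g1", "g2"))))
  write_prediction(empty, file.path(d, "empty"))
  back0 <- read_prediction(file.path(d, "empty"))
  expect_equal(dim(back0$scores), c(0L, 2L))
})

test_that("embedding matrices validate and round-trip as TSV", {
  E <- embedding_matrix(matrix(rnorm(12), 4, 3), encoder_tag = "test")
  expect_equal(attr(E, "encoder_tag"), "test")
  expect_error(embedding_matrix(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  d <- withr::local_tempdir()
  write_embeddings(E, file.path(d, "e.tsv"))
  back <- read_embeddings(file.path(d, "e.tsv"))
  expect_equal(unname(unclass(back)[, ]), unname(unclass(E)[, ]), tolerance = 1e-12)
  expect_equal(rownames(back), rownames(E))
})

test_that("bag assignment enforces single membership", {
  expect_error(bag_assignment(list(s1 = c("a", "b"), s2 = c("b"))),
               "at most one")
  b <- bag_assignment(list(s1 = c("a", "b"), s2 = "c"), unassigned = "d")
  expect_equal(unname(b$k_s), c(2L, 1L))
})
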