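# Filters, normalization, scaling, gene selection, bag construction.

test_that("qc_filter applies both gene rules and both spot rules", {
  # genes: totals 300 / 250 / 100, detection fractions 1.0 / 0.25 / 1.0
  S <- 20
  g1 <- rep(15L, S)                       # total 300, detected everywhere
  g2 <- c(rep(50L, 5), rep(0L, 15))       # total 250, detected in 25%
  g3 <- rep(5L, S)                        # total 100, detected everywhere
  sc <- toy_spot_counts(cbind(g1, g2, g3))
  qc <- qc_filter(sc, min_gene_counts = 200, min_detect_frac = 0.10,
                  min_spot_counts = 0)
  expect_equal(unname(qc$gene_mask), c(TRUE, TRUE, FALSE))

  # spots: totals 360 / 120 / 15 with cells; 15 < 20 drops
  sc2 <- toy_spot_counts(rbind(c(300L, 60L), c(100L, 20L), c(10L, 5L)))
  bags <- bag_assignment(setNames(list("a", "b", "c"), sc2$spot_ids),
                         cell_ids = c("a", "b", "c"))
  qc2 <- qc_filter(sc2, bags, min_gene_counts = 1, min_detect_frac = 0)
  expect_equal(unname(qc2$spot_mask), c(TRUE, TRUE, FALSE))

  # a spot with 40 counts but zero assigned cells is dropped
  bags3 <- bag_assignment(setNames(list(c("a", "b"), character(0), "c"),
                                   sc2$spot_ids), cell_ids = c("a", "b", "c"))
  sc3 <- toy_spot_counts(rbind(c(300L, 60L), c(30L, 10L), c(100L, 20L)))
  qc3 <- qc_filter(sc3, bags3, min_gene_counts = 1, min_detect_frac = 0)
  expect_equal(unname(qc3$spot_mask), c(TRUE, FALSE, TRUE))

  expect_error(qc_filter(sc, min_gene_counts = 1e6), "review")
})

test_that("qc_filter is idempotent", {
  set.seed(11)
  counts <- matrix(rnbinom(50 * 30, mu = 2, size = 1), 50, 30)
  sc <- toy_spot_counts(counts)
  bags <- bag_assignment(setNames(as.list(paste0("c", 1:50)), sc$spot_ids))
  qc <- qc_filter(sc, bags, min_gene_counts = 50, min_detect_frac = 0.3,
                  min_spot_counts = 40)
  sub <- spot_counts(sc$counts[qc$spot_mask, qc$gene_mask, drop = FALSE],
                     sc$spot_xy[qc$spot_mask, , drop = FALSE], sc$spot_radius)
  bags2 <- bag_assignment(bags$spot_to_cells[qc$spot_mask],
                          cell_ids = bags$cell_ids)
  bags2$spot_to_cells <- setNames(bags2$spot_to_cells, sub$spot_ids)
  qc2 <- qc_filter(sub, bags2, min_gene_counts = 50, min_detect_frac = 0.3,
                   min_spot_counts = 40)
  expect_true(all(qc2$gene_mask))
  expect_true(all(qc2$spot_mask))
})

test_that("lognormalize matches the formula and is scale invariant", {
  expect_equal(lognormalize(c(0, 4)), c(0, log(10001)), tolerance = 1e-12)
  expect_equal(lognormalize(c(1, 3)), c(log(2501), log(7501)), tolerance = 1e-12)
  expect_equal(lognormalize(7), log(1 + 10000))   # single gene: fraction is 1
  y <- c(3, 0, 9, 1)
  expect_equal(lognormalize(2 * y), lognormalize(y), tolerance = 1e-12)
  expect_error(lognormalize(c(0, 0)), "all-zero")
  # matrix form applies row-wise
  m <- rbind(c(1, 3), c(0, 4))
  expect_equal(unname(lognormalize(m)[1, ]), lognormalize(c(1, 3)))
})

test_that("robust_scale centres at the median, divides by IQR, and inverts", {
  x <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  sc <- robust_scale(x)
  expect_equal(as.numeric(sc$values), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(as.numeric(robust_scale(matrix(7, 3, 1))$values), c(0, 0, 0))

  set.seed(3)
  m <- matrix(rnorm(40), 10, 4)
  fit <- robust_scale(m)
  expect_equal(inverse_robust_scale(fit$values, fit$params), m,
               tolerance = 1e-12)

  # two slides are scaled independently: per-slide medians map to 0
  slide <- rep(c("A", "B"), each = 5)
  m2 <- rbind(matrix(rnorm(10), 5), matrix(rnorm(10, mean = 100), 5))
  fit2 <- robust_scale(m2, slide = slide)
  expect_equal(apply(fit2$values[1:5, , drop = FALSE], 2, median), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(apply(fit2$values[6:10, , drop = FALSE], 2, median), c(0, 0),
               ignore_attr = TRUE)
})

test_that("select_hvg ranks by standardized variance under a flat trend", {
  # equal means, raw variances 1 / 9 / 4 -> order g2, g3, g1
  set.seed(5)
  n <- 40
  base <- rep(c(0L, 20L), n / 2)                 # mean 10, var ~103
  g1 <- rep(c(9L, 11L), n / 2)                   # mean 10, small var
  g2 <- rep(c(1L, 19L), n / 2)                   # mean 10, large var
  g3 <- rep(c(5L, 15L), n / 2)                   # mean 10, middle var
  counts <- cbind(g1, g2, g3)
  colnames(counts) <- c("g1", "g2", "g3")
  sel <- select_hvg(counts, n = 3)
  expect_equal(sel$gene_id, c("g2", "g3", "g1"))

  # two identical batches give the same selection
  sel2 <- select_hvg(rbind(counts, counts), n = 3,
                     batch = rep(c("a", "b"), each = n))
  expect_equal(sel2$gene_id, sel$gene_id)

  expect_error(select_hvg(counts, n = 4), "exceeds")
})

test_that("batch-aware HVG selection demotes slide-specific genes", {
  set.seed(8)
  n <- 60
  # gene "shared" is variable in both batches; "specific" only in batch A
  make_batch <- function(spec_var) {
    cbind(shared = rnbinom(n, mu = 10, size = 1),
          specific = if (spec_var) rnbinom(n, mu = 10, size = 0.3)
                     else rpois(n, 10),
          flat1 = rpois(n, 10), flat2 = rpois(n, 10), flat3 = rpois(n, 10))
  }
  counts <- rbind(make_batch(TRUE), make_batch(FALSE))
  sel <- select_hvg(counts, n = 1, batch = rep(c("A", "B"), each = n))
  expect_equal(sel$gene_id, "shared")
})

test_that("morans_i matches hand computation and brute force", {
  # 4 spots on a ring, alternating values, 2 ring neighbours each -> I = -1
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(morans_i(c(1, -1, 1, -1), xy, n_neighbors = 2), -1,
               tolerance = 1e-12)

  # gradient on a 10-spot chain is positively autocorrelated, and stronger
  # than a shuffled version of the same values
  xy10 <- cbind(1:10, 0)
  grad <- as.numeric(1:10)
  i_grad <- morans_i(grad, xy10, n_neighbors = 2)
  expect_gt(i_grad, 0)
  set.seed(4)
  i_perm <- morans_i(sample(grad), xy10, n_neighbors = 2)
  expect_gt(i_grad, abs(i_perm))

  # brute-force double loop agreement on random fields
  set.seed(9)
  for (rep in 1:5) {
    xy <- matrix(runif(2 * 15), 15, 2)
    v <- rnorm(15)
    w <- cellmil:::knn_graph(xy, 4)
    expect_equal(morans_i(v, xy, n_neighbors = 4), moran_brute(v, w),
                 tolerance = 1e-12)
  }
  expect_error(morans_i(rep(1, 5), cbind(1:5, 0)), "constant")
})

test_that("select_svg reduces to Moran ordering on one slide and pools by shifted geometric mean", {
  set.seed(10)
  S <- 36
  xy <- as.matrix(expand.grid(x = 1:6, y = 1:6)) * 40
  smooth <- outer(xy[, 1], 1)[, 1]                     # spatial gradient
  counts <- cbind(
    spatial = rpois(S, 2 + 4 * smooth / max(smooth)),
    noise1 = rpois(S, 4), noise2 = rpois(S, 4))
  sc <- spot_counts(counts, xy, spot_radius = 10)
  sel <- select_svg(sc, n = 3)
  vals <- lognormalize(sc$counts)
  i_each <- sapply(1:3, function(j) morans_i(vals[, j], xy))
  expect_equal(sel$gene_id, colnames(counts)[order(-i_each)])
  expect_equal(sel$gene_id[1], "spatial")

  # two slides: ordering follows the geometric mean of shifted scores
  counts2 <- cbind(spatial = rpois(S, 4), noise1 = rpois(S, 2 + 4 * smooth / max(smooth)),
                   noise2 = rpois(S, 4))
  sc2 <- spot_counts(counts2, xy, spot_radius = 10)
  sel2 <- select_svg(list(sc, sc2), n = 3)
  i1 <- sapply(1:3, function(j) morans_i(lognormalize(sc$counts)[, j], xy))
  i2 <- sapply(1:3, function(j) morans_i(lognormalize(sc2$counts)[, j], xy))
  gm <- sqrt((i1 + 1) * (i2 + 1))
  expect_equal(sel2$gene_id, colnames(counts)[order(-gm)])
})

test_that("cells link to the nearest spot within the radius, boundary inclusive", {
  sc <- spot_counts(matrix(c(5L, 5L), 2, 1),
                    spot_xy = rbind(c(0, 0), c(8, 0)), spot_radius = 5)
  cells <- tibble::tibble(
    cell_id = c("boundary", "outside", "overlap"),
    x = c(3, 60, 4.2), y = c(4, 0, 0))
  bags <- assign_cells_to_spots(cells, sc)
  # distance exactly 5 -> assigned; (60,0) -> unassigned;
  # (4.2, 0) is within both disks but nearer spot 2 (3.8 < 4.2)
  expect_equal(bags$spot_to_cells[[1]], "boundary")
  expect_equal(bags$spot_to_cells[[2]], "overlap")
  expect_equal(bags$unassigned, "outside")

  # equidistant tie goes to the lower spot index
  tie <- assign_cells_to_spots(tibble::tibble(cell_id = "mid", x = 4, y = 0), sc)
  expect_equal(tie$spot_to_cells[[1]], "mid")
})
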