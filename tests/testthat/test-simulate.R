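# Reference generator, scenario assignment, spot synthesis.

test_that("reference markers are up-regulated in their own cluster", {
  ref <- generate_reference(K = 4, G = 80, cells_per_cluster = 500,
                            markers_per_cluster = 5, fold_change = 5, seed = 2)
  expect_true(all(ref$counts >= 0))
  expect_true(cellmil:::is_wholenumber(ref$counts))
  for (k in seq_len(4)) {
    mk <- ref$marker_sets[[k]]
    own <- colMeans(ref$counts[ref$cluster == k, mk, drop = FALSE])
    other <- colMeans(ref$counts[ref$cluster != k, mk, drop = FALSE])
    expect_true(all(own > other))
  }
  # fold_change = 1 removes cluster structure
  flat <- generate_reference(K = 2, G = 40, cells_per_cluster = 800,
                             markers_per_cluster = 5, fold_change = 1, seed = 3)
  m1 <- colMeans(flat$counts[flat$cluster == 1, ])
  m2 <- colMeans(flat$counts[flat$cluster == 2, ])
  expect_lt(max(abs(m1 - m2) / (1 + (m1 + m2) / 2)), 0.25)
})

test_that("cluster matching is a seeded bijection of the right size", {
  ref <- generate_reference(K = 5, G = 60, cells_per_cluster = 20, seed = 1)
  map <- match_clusters(5, ref, seed = 4)
  expect_equal(sort(unname(map)), 1:5)
  expect_identical(map, match_clusters(5, ref, seed = 4))
  ref1 <- generate_reference(K = 1, G = 20, cells_per_cluster = 10,
                             markers_per_cluster = 2, seed = 1)
  expect_equal(unname(match_clusters(1, ref1, seed = 0)), 1L)
  expect_error(match_clusters(4, ref, seed = 0), "must equal")
})

test_that("assign_expression implements the three coupling scenarios", {
  ref <- generate_reference(K = 3, G = 40, cells_per_cluster = 50,
                            markers_per_cluster = 3, seed = 6)
  lab <- rep(1:3, each = 10)
  map <- match_clusters(3, ref, seed = 1)

  cen <- assign_expression("centroid", lab, map, ref, seed = 0)
  expect_equal(cen[1, ], cen[10, ])        # same image cluster -> identical
  expect_equal(unname(cen[1, ]),
               unname(colMeans(ref$counts[ref$cluster == map[lab[1]], ])))

  cel <- assign_expression("cell", lab, map, ref, seed = 0)
  for (i in c(1, 15, 25)) {
    members <- which(ref$cluster == map[lab[i]])
    hit <- apply(ref$counts[members, , drop = FALSE], 1,
                 function(r) all(r == cel[i, ]))
    expect_true(any(hit))                  # row comes from the mapped cluster
  }

  expect_error(assign_expression("bogus", lab, map, ref), "unknown scenario")
})

test_that("random assignment is uncoupled from image clusters", {
  ref <- generate_reference(K = 6, G = 60, cells_per_cluster = 200,
                            markers_per_cluster = 4, seed = 9)
  lab <- rep(1:6, each = 2000)
  map <- match_clusters(6, ref, seed = 2)
  rnd <- assign_expression("random", lab, map, ref, seed = 3)
  src_cluster <- ref$cluster[attr(rnd, "source_row")]
  frac_match <- mean(src_cluster == unname(map[lab]))
  expect_lt(abs(frac_match - 1 / 6), 0.02)
})

test_that("spot counts are exact sums of member-cell expression", {
  ref <- generate_reference(K = 3, G = 30, cells_per_cluster = 40,
                            markers_per_cluster = 3, seed = 8)
  lab <- rep(1:3, each = 30)
  map <- match_clusters(3, ref, seed = 0)
  expr <- assign_expression("cell", lab, map, ref, seed = 1)
  ds <- simulate_spots(expr, n_spots = 25, cells_per_spot = 6, seed = 2)
  for (s in c(1, 13, 25)) {
    members <- ds$bags$spot_to_cells[[s]]
    expect_identical(ds$spot_counts$counts[s, ],
                     colSums(ds$cell_expression[members, , drop = FALSE]))
  }
  expect_true(cellmil:::is_wholenumber(ds$spot_counts$counts))
  # conservation over the whole slide
  expect_equal(colSums(ds$spot_counts$counts), colSums(ds$cell_expression),
               ignore_attr = TRUE)

  # 20 identical cells -> 20 * e; cells_per_spot = 1 -> spot = cell
  e <- matrix(rep(c(2, 0, 7), 25), 25, 3, byrow = TRUE)
  ds20 <- simulate_spots(e, n_spots = 3, cells_per_spot = 20, seed = 0)
  expect_equal(unname(ds20$spot_counts$counts[1, ]), 20 * c(2, 0, 7))
  ds1 <- simulate_spots(expr, n_spots = 5, cells_per_spot = 1, seed = 0)
  expect_equal(unname(ds1$spot_counts$counts[3, ]),
               unname(ds1$cell_expression[3, ]))
})

test_that("geometric cell linkage reproduces the synthetic bags", {
  sim <- toy_scenario("cell", seed = 11, n_spots = 30, cells_per_spot = 5)
  ds <- sim$train
  bags <- assign_cells_to_spots(ds$cells, ds$spot_counts)
  expect_equal(bags$unassigned, character(0))
  for (s in seq_along(bags$spot_to_cells))
    expect_setequal(bags$spot_to_cells[[s]], ds$bags$spot_to_cells[[s]])
})

test_that("run_scenario is reproducible and centroid spots live in the centroid hull", {
  sim1 <- toy_scenario("centroid", seed = 12)
  sim2 <- toy_scenario("centroid", seed = 12)
  expect_identical(serialize(sim1$train, NULL), serialize(sim2$train, NULL))
  expect_identical(serialize(sim1$test, NULL), serialize(sim2$test, NULL))

  # spot vector / cells_per_spot is a convex combination of the K centroids
  ref <- sim1$reference
  centroids <- rowsum(ref$counts, ref$cluster) / as.vector(table(ref$cluster))
  Y <- sim1$train$spot_counts$counts / sim1$cfg$cells_per_spot
  fit <- lm.fit(t(centroids), t(Y))
  resid <- Y - t(t(centroids) %*% fit$coefficients)
  expect_lt(max(abs(resid)), 1e-8)
  expect_true(all(fit$coefficients > -1e-9))
  expect_equal(colSums(fit$coefficients), rep(1, nrow(Y)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # train and test are fresh draws, not copies
  expect_false(identical(sim1$train$spot_counts$counts,
                         sim1$test$spot_counts$counts))
})

test_that("random-scenario expression is independent of the embeddings", {
  ref <- generate_reference(K = 4, G = 40, cells_per_cluster = 100,
                            markers_per_cluster = 4, seed = 13)
  lab <- rep(1:4, each = 2500)
  map <- match_clusters(4, ref, seed = 13)
  rnd <- assign_expression("random", lab, map, ref, seed = 13)
  keep <- rowSums(rnd) > 0
  onehot <- one_hot_encode(lab, 4)[keep, , drop = FALSE]
  expr <- lognormalize(rnd[keep, , drop = FALSE])
  cors <- abs(stats::cor(unclass(onehot), expr))
  expect_lt(mean(cors), 0.03)
})
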