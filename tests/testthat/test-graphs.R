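# naive O(cells^2) counting oracle for the conditional association
# statistic, written independently of the package implementation

test_that("similarity edge features match their printed formulas", {
  expect_equal(unname(similarity_edge_features(c(1, 2, 2), c(1, 2, 2))),
               c(1, 1, 1))
  f <- similarity_edge_features(c(1, 0), c(0, 1))
  expect_equal(unname(f), c(0, exp(-sqrt(2)), -1), tolerance = 1e-12)
  expect_equal(exp(-sqrt(2)), 0.2431, tolerance = 1e-4)
  # constant-vector rule for the correlation channel
  expect_equal(unname(similarity_edge_features(c(1, 1, 1), c(1, 5, 9))[3]), 0)
  expect_error(similarity_edge_features(c(0, 0), c(1, 2)), "zero vector")
  expect_error(similarity_edge_features(c(1), c(2)), "length")
})

test_that("location edge features honour the published thresholds", {
  # mu = 10, lambda = 200 operating point
  f <- location_edge_features(c(0, 0), c(3, 4), lambda = 200, mu = 10)
  expect_equal(unname(f), c(0, 1, 1))
  f2 <- location_edge_features(c(100, 100), c(400, 500), lambda = 200,
                               mu = 10)
  expect_equal(unname(f2), c(180, 0, 0))      # dot 90000 / dist 500
  # threshold direction flip
  f3 <- location_edge_features(c(0, 0), c(3, 4), mu = 10, e3_rule = "gt")
  expect_equal(unname(f3[3]), 0)
  # 3D: adjacent slice connected, two slices apart not
  za <- location_edge_features(c(0, 0, 0), c(3, 4, 100), xi = 150)
  zb <- location_edge_features(c(0, 0, 0), c(3, 4, 200), xi = 150)
  expect_equal(unname(za[4]), 1)
  expect_equal(unname(zb[4]), 0)
  expect_error(location_edge_features(c(1, 1), c(1, 1)), "coincident")
})

test_that("conditional rho equals naive counting and stays in [-1, 1]", {
  set.seed(11)
  for (rep in 1:50) {
    x <- rpois(20, 5); y <- rpois(20, 5); z <- rpois(20, 5)
    k <- sample(20, 1)
    expect_identical(conditional_rho(x, y, z, k, 1.5),
                     naive_rho(x, y, z, k, 1.5))
  }
  worst <- 0
  for (rep in 1:1000) {
    x <- rpois(15, sample(1:10, 1)); y <- rpois(15, sample(1:10, 1))
    z <- rpois(15, sample(1:10, 1))
    r <- conditional_rho(x, y, z, sample(15, 1), runif(1, 0.5, 3))
    if (!is.na(r)) worst <- max(worst, abs(r))
  }
  expect_lte(worst, 1)
})

test_that("coupled genes gain degree, conditioning genes and constant data do not", {
  set.seed(12)
  n <- 40
  base <- rpois(n, 20)
  counts <- cbind(g1 = base + rpois(n, 2),        # g1, g2 strongly coupled
                  g2 = base + rpois(n, 2),
                  g3 = rpois(n, 20))              # independent
  cdm <- conditional_degree_matrix(counts, alpha = 0.5, boxsize = 1.5,
                                   kk = 1L, conditioning_genes = 3L)
  expect_equal(dim(cdm$V), c(3L, n))
  expect_true(all(cdm$V[3, ] == 0))              # conditioning gene: degree 0
  expect_gt(mean(cdm$V[1, ] > 0), 0.5)           # coupling detected
  # all-identical cells: every neighbourhood holds every cell, rho = 0
  flat <- matrix(5, 20, 4)
  cdm0 <- conditional_degree_matrix(flat, conditioning_genes = 1L)
  expect_true(all(cdm0$V == 0))
  # no randomness anywhere
  cdm2 <- conditional_degree_matrix(counts, alpha = 0.5, boxsize = 1.5,
                                    kk = 1L, conditioning_genes = 3L)
  expect_identical(cdm$V, cdm2$V)
})

test_that("hub selection picks the most connected gene", {
  set.seed(13)
  n <- 40
  hub <- rpois(n, 20)
  counts <- cbind(a = hub + rpois(n, 2), b = hub + rpois(n, 2),
                  hub = hub, d = rpois(n, 20), e = rpois(n, 20))
  cdm <- conditional_degree_matrix(counts, kk = 1L)
  expect_true(cdm$conditioning_genes %in% 1:3)
})

test_that("view graphs are symmetric k-NN with strictly positive features", {
  cfg <- spotfuse_config(knn_edges = 1L)
  X <- matrix(rnorm(4 * 3), 4, 3)
  coords <- cbind(x = c(0, 1, 2, 3), y = c(0, 0, 0, 0) + 5)
  vg <- build_view_graph("SLG", X, coords, cfg)
  und <- unique(t(apply(vg$edges, 1, sort)))
  expect_equal(und[order(und[, 1]), ], cbind(c(1, 2, 3), c(2, 3, 4)),
               ignore_attr = TRUE)
  # both orientations stored with equal features
  key <- paste(vg$edges[, 1], vg$edges[, 2])
  rev_key <- paste(vg$edges[, 2], vg$edges[, 1])
  expect_setequal(key, rev_key)
  for (e in seq_len(nrow(vg$edges))) {
    mirror <- which(vg$edges[, 1] == vg$edges[e, 2] &
                      vg$edges[, 2] == vg$edges[e, 1])
    expect_equal(vg$edge_features[e, ], vg$edge_features[mirror, ])
  }
  expect_true(all(vg$edge_features > 0))
  # SLG binary channels are exactly 0/1 before the positivity shift
  expect_true(all(vg$edge_features_raw[, 2] %in% c(0, 1)))
  expect_true(all(vg$edge_features_raw[, 3] %in% c(0, 1)))
  expect_error(build_view_graph("SLG", X, coords,
                                spotfuse_config(knn_edges = 4L)),
               "smaller")
})

test_that("identical auxiliary features still build a graph (ties by index)", {
  cfg <- spotfuse_config(knn_edges = 2L)
  X <- matrix(rnorm(6 * 4), 6, 4)
  v <- matrix(1, 6, 5)
  vg <- build_view_graph("HSG", X, v, cfg)
  expect_gt(nrow(vg$edges), 0)
  expect_true(all(vg$edge_features > 0))
  expect_true(all(abs(vg$edge_features_raw[, 1] - 1) < 1e-12))
})

test_that("3D spatial graphs carry the fourth edge channel", {
  cfg <- spotfuse_config(knn_edges = 2L)
  co <- cbind(x = rep(1:4, 2), y = rep(c(0, 3), each = 4),
              z = rep(c(0, 100), 4))
  X <- matrix(rnorm(8 * 3), 8, 3)
  vg <- build_view_graph("SLG3D", X, co, cfg)
  expect_equal(ncol(vg$edge_features), 4L)
  expect_equal(vg$xi, 100)                       # smallest positive gap
  expect_true(all(vg$edge_features_raw[, 4] %in% c(0, 1)))
})

test_that("view graph serialization writes edge and node tables", {
  d <- withr::local_tempdir()
  cfg <- spotfuse_config(knn_edges = 2L)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  vg <- build_view_graph("SLG", X, cbind(runif(6), runif(6)), cfg)
  write_view_graph(vg, file.path(d, "slg"))
  ed <- read.delim(file.path(d, "slg_edges.tsv"))
  expect_equal(nrow(ed), nrow(vg$edges))
  expect_equal(ed$e1, unname(vg$edge_features[, 1]))
})
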