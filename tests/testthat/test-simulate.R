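test_that("simulation is a pure function of its seed", {
  a <- simulate_srt(n_spots = 60L, n_genes = 40L, seed = 9L)
  b <- simulate_srt(n_spots = 60L, n_genes = 40L, seed = 9L)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$dataset$coords, b$dataset$coords)
  expect_identical(a$truth$domain_of_spot, b$truth$domain_of_spot)
  c <- simulate_srt(n_spots = 60L, n_genes = 40L, seed = 10L)
  expect_false(identical(a$dataset$counts, c$dataset$counts))
})

test_that("generated counts are non-negative integers on contiguous domains", {
  sim <- simulate_srt(n_spots = 150L, n_genes = 60L, k_domains = 3L,
                      seed = 2L)
  expect_true(all(sim$dataset$counts >= 0))
  expect_true(all(sim$dataset$counts == round(sim$dataset$counts)))
  expect_gte(min(tabulate(sim$truth$domain_of_spot + 1L, 3L)), 10L)
  # contiguity: each spot's nearest neighbour shares its domain most often
  D <- as.matrix(dist(sim$dataset$coords))
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min)
  expect_gt(mean(sim$truth$domain_of_spot ==
                   sim$truth$domain_of_spot[nn]), 0.85)
})

test_that("zero mean shift removes all domain information", {
  aris <- vapply(1:10, function(s) {
    sim <- simulate_srt(n_spots = 120L, n_genes = 60L, nb_mean_shift = 0,
                        seed = s)
    km <- with(sim, kmeans(log1p(dataset$counts), 2, nstart = 5))
    cluster_ari(km$cluster, sim$truth$domain_of_spot)
  }, numeric(1))
  expect_lt(max(abs(aris)), 0.1)
})

test_that("a strong shift separates SVG means between domains", {
  sim <- simulate_srt(n_spots = 400L, n_genes = 100L, k_domains = 2L,
                      nb_mean_shift = 4, seed = 3L)
  g <- sim$truth$svg_genes[1]
  up <- sim$truth$svg_up_domain[1]
  p <- wilcox.test(sim$dataset$counts[sim$truth$domain_of_spot == up, g],
                   sim$dataset$counts[sim$truth$domain_of_spot != up, g])$p.value
  expect_lt(p, 1e-6)
})

test_that("planted dark genes are raw-masked but spatially recoverable", {
  sim <- simulate_srt(n_spots = 400L, n_genes = 200L, seed = 4L)
  pl <- plant_dark_genes(sim$dataset, sim$truth, n_sdg = 20L,
                         spatial_amplitude = 0.5, noise_sd = 5, seed = 4L)
  expect_length(pl$truth$sdg_genes, 20L)
  expect_length(intersect(pl$truth$sdg_genes, pl$truth$svg_genes), 0L)
  # calibration: raw rank-sum between domains stays non-significant
  pvals <- vapply(seq_len(20L), function(j) {
    g <- pl$truth$sdg_genes[j]; up <- pl$truth$sdg_up_domain[j]
    suppressWarnings(wilcox.test(
      pl$dataset$counts[pl$truth$domain_of_spot == up, g],
      pl$dataset$counts[pl$truth$domain_of_spot != up, g])$p.value)
  }, numeric(1))
  expect_gt(median(pvals), 0.2)
  # the k-NN spatial average of the true mean field separates the domains
  # for every planted gene (noise-free calibration guarantee)
  D <- as.matrix(dist(pl$dataset$coords))
  diag(D) <- Inf
  nb <- t(apply(D, 1L, function(r) order(r)[1:15]))
  gaps <- vapply(seq_len(20L), function(j) {
    up <- pl$truth$sdg_up_domain[j]
    mu_true <- 10 + 0.5 * (pl$truth$domain_of_spot == up)
    smoothed <- vapply(seq_len(nrow(D)),
                       function(i) mean(mu_true[nb[i, ]]), numeric(1))
    mean(smoothed[pl$truth$domain_of_spot == up]) -
      mean(smoothed[pl$truth$domain_of_spot != up])
  }, numeric(1))
  expect_true(all(gaps > 0.25))
  # replanting with the same seed is identical
  pl2 <- plant_dark_genes(sim$dataset, sim$truth, n_sdg = 20L,
                          spatial_amplitude = 0.5, noise_sd = 5, seed = 4L)
  expect_identical(pl$dataset$counts, pl2$dataset$counts)
  expect_error(plant_dark_genes(sim$dataset, sim$truth, n_sdg = 50L),
               "n_genes / 10")
})

test_that("zero amplitude planting leaves planted genes exchangeable with nulls", {
  sim <- simulate_srt(n_spots = 300L, n_genes = 150L, seed = 6L)
  pl <- plant_dark_genes(sim$dataset, sim$truth, n_sdg = 15L,
                         spatial_amplitude = 0, noise_sd = 5, seed = 6L)
  g <- pl$truth$sdg_genes[1]; up <- pl$truth$sdg_up_domain[1]
  p <- suppressWarnings(wilcox.test(
    pl$dataset$counts[pl$truth$domain_of_spot == up, g],
    pl$dataset$counts[pl$truth$domain_of_spot != up, g])$p.value)
  expect_gt(p, 0.001)
})

test_that("multislice batches shift library sizes and stack along z", {
  ms <- simulate_multislice(n_slices = 3L, batch_shift_sd = 1, z_gap = 100,
                            seed = 2L, n_spots = 80L, n_genes = 60L)
  expect_equal(ncol(ms$dataset$coords), 3L)
  expect_equal(sort(unique(ms$dataset$slice_id)), 0:2)
  expect_equal(sort(unique(ms$dataset$coords[, 3])), c(0, 100, 200))
  lib <- tapply(rowSums(ms$dataset$counts), ms$dataset$slice_id, mean)
  expect_gt(max(lib) / min(lib), 1.5)
  ms0 <- simulate_multislice(n_slices = 3L, batch_shift_sd = 0,
                             z_gap = 100, seed = 2L, n_spots = 80L,
                             n_genes = 60L)
  lib0 <- tapply(rowSums(ms0$dataset$counts), ms0$dataset$slice_id, mean)
  expect_lt(max(lib0) / min(lib0), 1.15)
  ms2 <- simulate_multislice(n_slices = 3L, batch_shift_sd = 1, z_gap = 100,
                             seed = 2L, n_spots = 80L, n_genes = 60L)
  expect_identical(ms$dataset$counts, ms2$dataset$counts)
})

test_that("truth sidecar serializes to JSON", {
  d <- withr::local_tempdir()
  sim <- simulate_srt(n_spots = 40L, n_genes = 20L, seed = 1L)
  write_truth(sim$truth, file.path(d, "truth.json"))
  tr <- jsonlite::read_json(file.path(d, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$domain_of_spot, sim$truth$domain_of_spot)
  expect_equal(tr$svg_genes, sim$truth$svg_genes)
})
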