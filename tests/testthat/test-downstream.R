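# textbook single-purpose implementations used as oracles
naive_dbi <- function(X, cl) {
  ks <- sort(unique(cl))
  cen <- lapply(ks, function(c) colMeans(X[cl == c, , drop = FALSE]))
  S <- vapply(seq_along(ks), function(i) {
    pts <- X[cl == ks[i], , drop = FALSE]
    mean(apply(pts, 1, function(r) sqrt(sum((r - cen[[i]])^2))))
  }, numeric(1))
  db <- 0
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      m <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      best <- max(best, (S[i] + S[j]) / m)
    }
    db <- db + best
  }
  db / length(ks)
}

naive_asw <- function(X, cl) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(c2) mean(D[i, cl == c2]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

test_that("DBI and ASW agree with textbook implementations", {
  set.seed(70)
  bl <- make_blobs(25, rbind(c(0, 0), c(4, 1)), sd = 1, seed = 70L)
  expect_equal(davies_bouldin(bl$X, bl$labels),
               naive_dbi(bl$X, bl$labels), tolerance = 1e-8)
  expect_equal(average_silhouette(bl$X, bl$labels),
               naive_asw(bl$X, bl$labels), tolerance = 1e-8)
  expect_equal(cluster_ari(bl$labels, bl$labels), 1)
  expect_lt(abs(cluster_ari(bl$labels, sample(bl$labels))), 0.2)
})

test_that("DBI model selection finds the planted number of blobs", {
  hits2 <- 0; hits3 <- 0
  for (s in 1:10) {
    two <- make_blobs(30, rbind(c(0, 0), c(6, 6)), sd = 1, seed = s)
    if (select_k_dbi(two$X, 2:6, seed = s)$k == 2L) hits2 <- hits2 + 1
    three <- make_blobs(30, rbind(c(0, 0), c(8, 0), c(4, 7)), sd = 1,
                        seed = 100 + s)
    if (select_k_dbi(three$X, 2:6, seed = s)$k == 3L) hits3 <- hits3 + 1
  }
  expect_gte(hits2, 9L)
  expect_gte(hits3, 9L)
  # singleton range is trivially selected
  bl <- make_blobs(20, rbind(c(0, 0), c(5, 5)), seed = 1L)
  expect_equal(select_k_dbi(bl$X, 4L, seed = 1L)$k, 4L)
  expect_error(select_k_dbi(matrix(1, 10, 3), 2:3), "degenerate")
})

test_that("k-means clustering is accurate, stable and size-ordered", {
  bl <- make_blobs(40, rbind(c(0, 0), c(6, 6)), sd = 0.8, seed = 7L)
  cl <- cluster_spots(bl$X, 2L, seed = 3L)
  expect_gte(cluster_ari(cl, bl$labels), 0.95)
  expect_identical(cl, cluster_spots(bl$X, 2L, seed = 3L))
  # duplicate rows always share a label
  X <- rbind(bl$X, bl$X[1, , drop = FALSE])
  cl2 <- cluster_spots(X, 2L, seed = 3L)
  expect_equal(cl2[nrow(X)], cl2[1], ignore_attr = TRUE)
  # ids are renumbered by descending size
  un <- make_blobs(10, rbind(c(0, 0), c(9, 9)), sd = 0.5, seed = 8L)
  Xu <- rbind(un$X, sweep(matrix(rnorm(120, 0, 0.5), 60), 2, c(0, 0), "+"))
  clu <- cluster_spots(Xu, 2L, seed = 2L)
  expect_gte(sum(clu == 1L), sum(clu == 2L))
})

test_that("SPE is the mean of nearest raw rows in embedding space", {
  # identical counts: averaging changes nothing
  counts <- matrix(7, 10, 4)
  R <- matrix(rnorm(20), 10, 2)
  spe <- compute_spe(R, counts, k_nn = 3L)
  expect_equal(spe$spe, counts, ignore_attr = TRUE)
  # collinear embeddings with k = 1: each spot adopts its nearest neighbour
  R3 <- matrix(c(0, 1, 2.1), 3, 1)
  c3 <- matrix(c(10, 20, 30), 3, 1)
  s3 <- compute_spe(R3, c3, k_nn = 1L)
  expect_equal(unname(s3$spe[, 1]), c(20, 10, 20))
  expect_error(compute_spe(R3, c3, k_nn = 3L), "smaller")
  # convex combination bound, per gene
  set.seed(71)
  counts <- matrix(rpois(200 * 5, 9), 200)
  R <- matrix(rnorm(400), 200, 2)
  sp <- compute_spe(R, counts, k_nn = 15L)
  for (g in 1:5) {
    expect_gte(min(sp$spe[, g]), min(counts[, g]))
    expect_lte(max(sp$spe[, g]), max(counts[, g]))
  }
})

test_that("SPE averaging reduces iid-noise variance by about k", {
  set.seed(72)
  n <- 400L
  counts <- matrix(rpois(n * 20, 10), n)
  R <- matrix(rnorm(n * 2), n, 2)               # unstructured embedding
  sp <- compute_spe(R, counts, k_nn = 15L)
  ratio <- apply(counts, 2, var) / apply(sp$spe, 2, var)
  # within a factor 1.5 of the nominal 15-fold reduction
  expect_true(all(ratio > 10 & ratio < 22.5))
})

test_that("gene classes partition with SDG excluded from raw markers", {
  set.seed(73)
  n <- 200L
  cl <- rep(1:2, each = n / 2)
  counts <- matrix(rpois(n * 30, 8), n)
  colnames(counts) <- sprintf("g%02d", 1:30)
  counts[, 1] <- rpois(n, ifelse(cl == 1, 30, 8))   # strong raw marker
  counts[, 2] <- 0                                  # dead gene
  R <- cbind(rnorm(n, cl * 3), rnorm(n))
  sp <- compute_spe(R, counts, k_nn = 15L)
  rep <- call_sdgs(counts, sp, cl)
  cls <- sdg_gene_classes(rep)
  expect_equal(unname(cls["g01"]), factor("SVG", levels = levels(cls)))
  expect_equal(unname(cls["g02"]), factor("none", levels = levels(cls)))
  # every gene has exactly one class; SDG implies SPVG and not SVG
  expect_equal(length(cls), 30L)
  expect_false(any(rep$is_sdg & rep$is_svg))
  expect_true(all(rep$is_sdg == (rep$is_spvg & !rep$is_svg)))
  expect_error(call_sdgs(counts, sp, rep(1, n)), ">= 2 clusters")
})
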