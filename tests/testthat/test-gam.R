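zero_params <- function(p) {
  for (nm in c("M1", "m1", "M2", "m2", "K1", "k1b", "K2", "k2b"))
    p[[nm]] <- p[[nm]] * 0
  p
}

test_that("zero attention weights give the constant 0.5 gate", {
  set.seed(30)
  p <- zero_params(gam_init_params(3L, c(8L, 8L, 8L), W = 8L))
  F1 <- lapply(1:3, function(i) matrix(rnorm(50 * 8), 50, 8))
  F2 <- channel_attention(F1, p)
  for (c in 1:3) expect_equal(F2[[c]], 0.5 * F1[[c]], tolerance = 1e-12)
  F3 <- spatial_attention(F2, p, kernel = 7L)
  for (c in 1:3) expect_equal(F3[[c]], 0.5 * F2[[c]], tolerance = 1e-12)
})

test_that("attention stages preserve shape and keep gates in (0, 1)", {
  set.seed(31)
  for (rep in 1:20) {
    p <- gam_init_params(3L, c(32L, 32L, 32L), W = 32L)
    for (nm in c("M1", "M2", "K1", "K2"))
      p[[nm]] <- matrix(rnorm(length(p[[nm]]), 0, 0.5), nrow(p[[nm]]))
    F1 <- lapply(1:3, function(i) matrix(rnorm(50 * 32), 50, 32))
    F2 <- channel_attention(F1, p)
    F3 <- spatial_attention(F2, p, kernel = 7L)
    for (c in 1:3) {
      expect_equal(dim(F2[[c]]), c(50L, 32L))
      expect_equal(dim(F3[[c]]), c(50L, 32L))
      gate2 <- F2[[c]] / F1[[c]]
      gate2 <- gate2[is.finite(gate2)]
      expect_true(all(gate2 > 0 & gate2 < 1))
    }
  }
})

test_that("a kernel longer than the map is clipped with a warning", {
  p <- gam_init_params(2L, c(4L, 4L), W = 4L, kernel = 7L)
  F2 <- lapply(1:2, function(i) matrix(rnorm(5 * 4), 5, 4))
  # both the spot-axis and latent-axis kernels are clipped here
  expect_warning(expect_warning(spatial_attention(F2, p, kernel = 7L),
                                "clipped"), "clipped")
})

test_that("with gates forced open the fused map is the sum of projections", {
  set.seed(32)
  views <- lapply(1:3, function(i)
    matrix(rnorm(20 * 6), 20, 6, dimnames = list(paste0("s", 1:20), NULL)))
  p <- gam_init_params(3L, rep(6L, 3), W = 8L)
  fw <- spotfuse:::gam_forward(p, views, kernel = 7L, force_gates = TRUE)
  manual <- Reduce(`+`, lapply(1:3, function(m)
    views[[m]] %*% t(p[[paste0("Proj", m)]])))
  expect_equal(spotfuse:::nval(fw$R), manual, tolerance = 1e-12)
})

test_that("the fusion training loss is plain cross-entropy on labeled spots", {
  set.seed(33)
  views <- lapply(1:2, function(i)
    matrix(rnorm(10 * 4), 10, 4, dimnames = list(paste0("s", 1:10), NULL)))
  labels <- c("a", "b", rep(NA, 8))
  R <- fuse_views(views, labels, width = 8L, epochs = 1L, seed = 5L)
  # recompute the epoch-1 loss by hand from the seeded initial parameters
  h <- spotfuse:::with_seed_local(5L, {
    p <- gam_init_params(2L, c(4L, 4L), W = 8L, gamma = 4, kernel = 7L,
                         K = 2L)
    fw <- spotfuse:::gam_forward(p, views, kernel = 7L)
    logits <- spotfuse:::nval(fw$R) %*% t(p$Wc) +
      matrix(p$bc, 10, 2, byrow = TRUE)
    pr <- exp(logits - apply(logits, 1, max))
    pr <- pr / rowSums(pr)
    -mean(log(pr[cbind(1:2, 1:2)]))
  })
  expect_equal(attr(R, "loss_history")[1], h, tolerance = 1e-8)
})

test_that("fusing three informative copies does not hurt clustering", {
  bl <- make_blobs(30, rbind(c(0, 0, 0), c(3, 3, 0)), sd = 1, seed = 40L)
  emb <- bl$X
  rownames(emb) <- paste0("s", seq_len(nrow(emb)))
  single <- cluster_ari(kmeans(emb, 2, nstart = 10)$cluster, bl$labels)
  fused <- fuse_views(list(emb, emb, emb), labels = bl$labels,
                      width = 8L, epochs = 60L, seed = 41L)
  ari_f <- cluster_ari(cluster_spots(fused, 2L, seed = 1L), bl$labels)
  expect_gte(ari_f, single - 0.05)
})

test_that("fusion tolerates one pure-noise view", {
  deltas <- vapply(1:5, function(s) {
    bl <- make_blobs(30, rbind(c(0, 0, 0), c(4, 4, 0)), sd = 1,
                     seed = 50L + s)
    emb <- bl$X
    rownames(emb) <- paste0("s", seq_len(nrow(emb)))
    set.seed(60L + s)
    noise <- matrix(rnorm(length(emb)), nrow(emb),
                    dimnames = dimnames(emb))
    two <- fuse_views(list(emb, emb), labels = bl$labels, width = 8L,
                      epochs = 60L, seed = s)
    three <- fuse_views(list(emb, emb, noise), labels = bl$labels,
                        width = 8L, epochs = 60L, seed = s)
    ari2 <- cluster_ari(cluster_spots(two, 2L, seed = 1L), bl$labels)
    ari3 <- cluster_ari(cluster_spots(three, 2L, seed = 1L), bl$labels)
    ari2 - ari3
  }, numeric(1))
  expect_lte(mean(deltas), 0.1)
})

test_that("mismatched spot sets are rejected with the offending ids", {
  a <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  b <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("x", 1:4), NULL))
  expect_error(fuse_views(list(a, b), labels = NULL), "x1")
})

test_that("the untrained forward pass returns a finite fused matrix", {
  views <- lapply(1:2, function(i)
    matrix(rnorm(10 * 3), 10, 3, dimnames = list(paste0("s", 1:10), NULL)))
  R <- fuse_views(views, labels = rep(c("a", "b"), 5), width = 8L,
                  epochs = 0L, seed = 1L)
  expect_equal(dim(R), c(10L, 8L))
  expect_true(all(is.finite(R)))
})
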