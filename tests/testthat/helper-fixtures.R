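# Shared fixtures and desk-scale settings for the test suite.
#
# Network sizes and epoch counts here are desk-scale (small fixtures, CPU
# minutes); the simulated study conditions themselves (domain counts, shift
# sizes, noise levels) follow the package defaults.

desk_config <- function(...) {
  spotfuse_config(hvg_count = 80L, ae_hidden = 64L, ae_latent = 16L,
                  ae_epochs = 80L, ae_lr = 1e-3,
                  egat_dims = c(32L, 16L), egat_epochs = 80L,
                  egat_lr = 1e-2, gam_epochs = 100L, gag_genes = 50L,
                  visual_epochs = 20L, ...)
}

# memoized medium fixture used by several files
fixture_env <- new.env()

fix_srt <- function() {
  if (is.null(fixture_env$srt))
    fixture_env$srt <- simulate_srt(n_spots = 200L, n_genes = 120L,
                                    k_domains = 2L, nb_mean_shift = 4,
                                    seed = 101L)
  fixture_env$srt
}

fix_ae_embedding <- function() {
  if (is.null(fixture_env$ae)) {
    sim <- fix_srt()
    hv <- select_hvg(sim$dataset$counts, 80L)
    fixture_env$ae <- train_expr_ae(hv$counts, hidden = 64L, latent = 16L,
                                    epochs = 80L, lr = 1e-3, seed = 101L)
  }
  fixture_env$ae
}

# two well-separated Gaussian blob embeddings with labels
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1L) {
  k <- nrow(centers)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(c)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2L,
          centers[c, ], "+")))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

weak_labels <- function(labels, frac = 0.7, seed = 7L) {
  out <- labels
  set.seed(seed)
  out[sample(length(labels), round((1 - frac) * length(labels)))] <- NA
  out
}
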