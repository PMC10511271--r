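# Fusion of per-view embeddings by sequential channel and spatial
# attention.
#
# The C view embeddings (projected to a common width W) are stacked as the
# channels of a C x H x W feature map (H = spots, W = latent width). A
# per-position two-layer MLP over channels produces the channel gate; two
# composed one-dimensional convolutions (along the spot axis, then along
# the latent axis) produce the spatial gate. The fused representation is
# the channel sum of the gated map, trained with cross-entropy on the
# weakly labeled spots.

shift_matrix <- function(n, t) {
  S <- matrix(0, n, n)
  idx <- seq_len(n)
  keep <- idx + t >= 1L & idx + t <= n
  S[cbind(idx[keep], idx[keep] + t)] <- 1
  S
}

gam_kernel_size <- function(requested, extent) {
  k <- min(requested, extent)
  if (k < requested)
    warning("spatial-attention kernel clipped from ", requested, " to ", k)
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 1L)
}

#' Initialize fusion-attention parameters
#'
#' @param C number of view channels.
#' @param dims per-view embedding widths (length `C`).
#' @param W common latent width after projection.
#' @param gamma channel-attention reduction ratio; hidden width is
#'   `max(1, round(C / gamma))`.
#' @param kernel spatial-attention kernel length.
#' @param K number of label classes (0 for no head).
#' @return named list of parameter matrices.
#' @export
gam_init_params <- function(C, dims, W = 32L, gamma = 4, kernel = 7L,
                            K = 0L) {
  hid <- max(1L, round(C / gamma))
  p <- list(M1 = init_weight(hid, C), m1 = matrix(0, 1, hid),
            M2 = init_weight(C, hid), m2 = matrix(0, 1, C),
            K1 = init_weight(C, kernel) * 0.1, k1b = matrix(0, 1, 1),
            K2 = init_weight(C, kernel) * 0.1, k2b = matrix(0, 1, C))
  for (m in seq_len(C)) {
    p[[paste0("Proj", m)]] <- init_weight(W, dims[m])
  }
  if (K > 0L) {
    p$Wc <- init_weight(K, W)
    p$bc <- matrix(0, 1, K)
  }
  p
}

#' Channel attention over a stacked view map
#'
#' The map is permuted so channels are last, every (spot, latent) position
#' is passed through a 2-layer MLP over the C channel values, and the
#' sigmoid gate multiplies the input elementwise. Zero MLP weights give the
#' constant gate 0.5.
#'
#' @param F1 list of C matrices `H x W` (plain or autodiff nodes).
#' @param params list with `M1`, `m1`, `M2`, `m2` (see
#'   [gam_init_params()]).
#' @return list of C gated matrices, same shapes.
#' @export
channel_attention <- function(F1, params) {
  C <- length(F1)
  H <- nrow(nval(F1[[1]])); W <- ncol(nval(F1[[1]]))
  X <- ad_cbind(lapply(F1, function(f) ad_reshape(f, H * W, 1L)))
  Z <- ad_relu(ad_add(ad_matmul(X, ad_t(params$M1)), params$m1))
  Gate <- ad_sigmoid(ad_add(ad_matmul(Z, ad_t(params$M2)), params$m2))
  lapply(seq_len(C), function(ch) {
    sel <- matrix(0, C, 1L); sel[ch, 1L] <- 1
    g <- ad_reshape(ad_matmul(Gate, sel), H, W)
    ad_mul(F1[[ch]], g)
  })
}

conv1d_rows <- function(Fmat, kvec, shifts) {
  # sum_t k[t] * shift_t(F) along the row (spot) axis; kvec is a 1 x T node
  acc <- NULL
  for (t in seq_along(shifts)) {
    sel <- matrix(0, ncol(nval(kvec)), 1L); sel[t, 1L] <- 1
    term <- ad_mul(ad_matmul(kvec, sel), ad_matmul(shifts[[t]], Fmat))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  acc
}

conv1d_cols <- function(Fmat, kvec, shifts) {
  acc <- NULL
  for (t in seq_along(shifts)) {
    sel <- matrix(0, ncol(nval(kvec)), 1L); sel[t, 1L] <- 1
    term <- ad_mul(ad_matmul(kvec, sel), ad_matmul(Fmat, shifts[[t]]))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  acc
}

#' Spatial attention over a stacked view map
#'
#' Two composed convolutions fuse positional information: a
#' channel-reducing kernel along the spot axis followed by a
#' channel-restoring kernel along the latent axis; the sigmoid of the
#' result gates each channel elementwise. Zero kernels give the constant
#' gate 0.5. Kernels longer than the map extent are clipped with a
#' warning.
#'
#' @param F2 list of C matrices `H x W`.
#' @param params list with `K1`, `k1b`, `K2`, `k2b`.
#' @param kernel requested kernel length.
#' @return list of C gated matrices.
#' @export
spatial_attention <- function(F2, params, kernel = 7L) {
  C <- length(F2)
  H <- nrow(nval(F2[[1]])); W <- ncol(nval(F2[[1]]))
  kH <- gam_kernel_size(min(kernel, ncol(nval(params$K1))), H)
  kW <- gam_kernel_size(min(kernel, ncol(nval(params$K2))), W)
  offs_h <- seq_len(kH) - (kH + 1L) %/% 2L
  offs_w <- seq_len(kW) - (kW + 1L) %/% 2L
  sh_h <- lapply(offs_h, function(t) shift_matrix(H, t))
  sh_w <- lapply(offs_w, function(t) shift_matrix(W, t))
  selc <- function(M, ch) {
    sel <- matrix(0, C, 1L); sel[ch, 1L] <- 1
    ad_t(ad_matmul(ad_t(M), sel))              # 1 x T row of channel ch
  }
  red <- NULL
  for (ch in seq_len(C)) {
    term <- conv1d_rows(F2[[ch]], selc(params$K1, ch), sh_h)
    red <- if (is.null(red)) term else ad_add(red, term)
  }
  red <- ad_relu(ad_add(red, params$k1b))
  lapply(seq_len(C), function(ch) {
    bsel <- matrix(0, C, 1L); bsel[ch, 1L] <- 1
    gate <- ad_sigmoid(ad_add(conv1d_cols(red, selc(params$K2, ch), sh_w),
                              ad_matmul(params$k2b, bsel)))
    ad_mul(F2[[ch]], gate)
  })
}

gam_forward <- function(params, views, kernel, force_gates = FALSE) {
  C <- length(views)
  F1 <- lapply(seq_len(C), function(m)
    ad_matmul(views[[m]], ad_t(params[[paste0("Proj", m)]])))
  if (force_gates) {
    R <- F1[[1]]
    for (m in seq_len(C)[-1]) R <- ad_add(R, F1[[m]])
    return(list(R = R, F1 = F1, F2 = F1, F3 = F1))
  }
  F2 <- channel_attention(F1, params)
  F3 <- spatial_attention(F2, params, kernel)
  R <- F3[[1]]
  for (m in seq_len(C)[-1]) R <- ad_add(R, F3[[m]])
  list(R = R, F1 = F1, F2 = F2, F3 = F3)
}

#' Fuse per-view embeddings into one representation
#'
#' Views are linearly projected to a common width, stacked as channels,
#' passed through channel then spatial attention, and summed over channels.
#' All parameters (projections, both attention submodules, the linear
#' softmax head) are trained jointly by cross-entropy over the labeled
#' spots. With `epochs = 0` the untrained forward pass is returned.
#'
#' @param views list of 2 or more spots x d_m embedding matrices with
#'   matching row names (spot order).
#' @param labels per-spot labels, `NA` = unlabeled; required for training.
#' @param width common latent width.
#' @param gamma channel-attention reduction ratio.
#' @param kernel spatial-attention kernel length.
#' @param epochs,lr optimisation settings.
#' @param seed RNG seed.
#' @return spots x width fused matrix with attribute `loss_history`.
#' @export
fuse_views <- function(views, labels = NULL, width = 32L, gamma = 4,
                       kernel = 7L, epochs = 150L, lr = 1e-3, seed = 0L) {
  stopifnot(length(views) >= 2L)
  ids <- rownames(views[[1]])
  for (m in seq_along(views)[-1]) {
    if (!identical(rownames(views[[m]]), ids)) {
      bad <- union(setdiff(rownames(views[[m]]), ids),
                   setdiff(ids, rownames(views[[m]])))
      stop("views cover different spot sets; mismatches: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  n <- nrow(views[[1]])
  C <- length(views)
  lev <- NULL; Yint <- NULL
  if (!is.null(labels)) {
    lev <- sort(unique(stats::na.omit(as.character(labels))))
    Yint <- match(as.character(labels), lev)
    if (!sum(!is.na(Yint))) { lev <- NULL; Yint <- NULL }
  }
  K <- length(lev)
  with_seed_local(seed, {
    params <- gam_init_params(C, vapply(views, ncol, 1L), width, gamma,
                              kernel, K)
    state <- adam_init(params)
    hist <- numeric(epochs)
    if (K > 0L) {
      labeled <- which(!is.na(Yint))
      Yhot <- matrix(0, n, K)
      Yhot[cbind(labeled, Yint[labeled])] <- 1
    }
    for (ep in seq_len(epochs)) {
      if (K == 0L) break                       # nothing to train against
      g <- ad_graph()
      nodes <- lapply(stats::setNames(names(params), names(params)),
                      function(nm) ad_param(g, params[[nm]]))
      fw <- gam_forward(nodes, views, kernel)
      ls <- ad_logsoftmax_rows(ad_add(ad_matmul(fw$R, ad_t(nodes$Wc)),
                                      nodes$bc))
      loss <- ad_neg(ad_div(ad_sum(ad_mul(Yhot, ls)), length(labeled)))
      if (!is.finite(loss$val))
        stop("fusion diverged (loss not finite) at epoch ", ep)
      hist[ep] <- loss$val
      ad_backward(loss)
      upd <- adam_step(params, lapply(nodes, function(nd) nd$grad), state,
                       lr = lr)
      params <- upd$params; state <- upd$state
    }
    R <- nval(gam_forward(params, views, kernel)$R)
    rownames(R) <- ids
    attr(R, "loss_history") <- hist
    R
  })
}
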