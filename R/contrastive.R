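# Contrastive visual features from histology patches.
#
# Per-spot image tiles are embedded by a small encoder trained with the
# normalized temperature-scaled cross-entropy (NT-Xent) objective on pairs
# of stochastic augmentations (crop-resize, colour jitter, Gaussian blur),
# optionally fine-tuned on weakly labeled spots from the first projection
# layer, and optionally distilled into a smaller student. At the patch
# scale this package targets (32 px tiles), the encoder is a multilayer
# perceptron over block-mean-downsampled pixels.

blur_matrix <- function(n, sigma) {
  # constant-preserving 1D Gaussian blur operator (rows renormalized)
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K[abs(outer(idx, idx, "-")) > 2] <- 0      # radius-2 kernel
  K / rowSums(K)
}

resize_nn <- function(img, out_px) {
  # nearest-neighbour resize of an h x w x 3 array to out_px x out_px
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(h, pmax(1L, round((seq_len(out_px) - 0.5) * h / out_px + 0.5)))
  ci <- pmin(w, pmax(1L, round((seq_len(out_px) - 0.5) * w / out_px + 0.5)))
  img[ri, ci, , drop = FALSE]
}

augment_once <- function(patch, crop_range, jitter, blur_sigma_range) {
  px <- dim(patch)[1]
  frac <- stats::runif(1, crop_range[1], crop_range[2])
  side <- max(2L, round(frac * px))
  r0 <- sample.int(px - side + 1L, 1L)
  c0 <- sample.int(px - side + 1L, 1L)
  crop <- patch[r0 + seq_len(side) - 1L, c0 + seq_len(side) - 1L, , drop = FALSE]
  out <- resize_nn(crop, px)
  for (ch in 1:3) {
    sc <- stats::runif(1, 1 - jitter, 1 + jitter)
    off <- stats::runif(1, -jitter, jitter)
    out[, , ch] <- out[, , ch] * sc + off
  }
  sg <- stats::runif(1, blur_sigma_range[1], blur_sigma_range[2])
  Br <- blur_matrix(px, sg)
  for (ch in 1:3) out[, , ch] <- Br %*% out[, , ch] %*% t(Br)
  pmin(pmax(out, 0), 1)
}

#' Two stochastic augmentations of one image patch
#'
#' Each view applies, in order: random crop (side fraction in `crop_range`)
#' with nearest-neighbour resize back to the input size, per-channel colour
#' jitter (scale in `1 +- jitter`, offset in `+- jitter`), and Gaussian
#' blur (sigma drawn from `blur_sigma_range`), clamped to `[0, 1]`.
#' Deterministic given `(patch, seed)`.
#'
#' @param patch `px x px x 3` array in `[0, 1]`, `px >= 4`.
#' @param seed RNG seed.
#' @param crop_range,jitter,blur_sigma_range augmentation strengths.
#' @return list `(view_a, view_b)` of arrays shaped like the input.
#' @export
augment_patch <- function(patch, seed = 0L, crop_range = c(0.5, 1),
                          jitter = 0.2, blur_sigma_range = c(0.1, 1)) {
  if (dim(patch)[1] < 4L || dim(patch)[2] < 4L)
    stop("patch smaller than the minimum crop size (4 px)")
  with_seed_local(seed, {
    list(view_a = augment_once(patch, crop_range, jitter, blur_sigma_range),
         view_b = augment_once(patch, crop_range, jitter, blur_sigma_range))
  })
}

#' Normalized temperature-scaled cross-entropy (NT-Xent) loss
#'
#' Rows of `Z` are projection outputs of `2N` augmented views, paired as
#' `(1,2), (3,4), ...`. Similarities are cosine divided by `tau`; the loss
#' is the mean over both orderings of every pair of the negative log
#' softmax of the positive similarity over the `2N - 1` non-self
#' similarities. With `N = 1` the softmax denominator contains only the
#' positive term, forcing the loss to zero.
#'
#' @param Z `2N x d` matrix (plain, or an autodiff node during training),
#'   no zero rows.
#' @param tau temperature, > 0.
#' @return scalar loss (or scalar node).
#' @export
nt_xent_loss <- function(Z, tau = 0.5) {
  if (tau <= 0) stop("tau must be positive")
  n2 <- nrow(nval(Z))
  if (n2 %% 2L) stop("Z must have an even number of rows (paired views)")
  if (any(rowSums(nval(Z)^2) == 0)) stop("zero-norm row in Z")
  Zn <- ad_div(Z, ad_sqrt(ad_rowsums(ad_mul(Z, Z))))
  S <- ad_div(ad_matmul(Zn, ad_t(Zn)), tau)
  S <- ad_add(S, diag(-1e9, n2))               # exclude self-similarity
  LS <- ad_logsoftmax_rows(S)
  pos <- matrix(0, n2, n2)
  pos[cbind(seq_len(n2), seq_len(n2) + rep(c(1, -1), n2 / 2))] <- 1
  out <- ad_neg(ad_div(ad_sum(ad_mul(pos, LS)), n2))
  if (is_adnode(out)) out else as.numeric(out)
}

#' Distillation loss between teacher and student logits
#'
#' Cross-entropy of the temperature-softened teacher distribution against
#' the student distribution, averaged over rows:
#' `-mean_i sum_y P_T(y|x_i; tau) log P_S(y|x_i; tau)`. It is bounded below
#' by the teacher entropy, with equality iff the distributions coincide
#' (their difference is a KL divergence).
#'
#' @param teacher_logits,student_logits matrices of matching shape (the
#'   student may be an autodiff node during training).
#' @param tau softening temperature, > 0.
#' @return scalar loss (or scalar node).
#' @export
distill_loss <- function(teacher_logits, student_logits, tau = 1) {
  if (tau <= 0) stop("tau must be positive")
  tv <- nval(teacher_logits)
  if (!identical(dim(tv), dim(nval(student_logits))))
    stop("teacher and student logits must have matching shapes")
  PT <- softmax_rows(tv / tau)
  LS <- ad_logsoftmax_rows(ad_div(student_logits, tau))
  out <- ad_neg(ad_div(ad_sum(ad_mul(PT, LS)), nrow(tv)))
  if (is_adnode(out)) out else as.numeric(out)
}

downsample_patches <- function(patches, block = 4L) {
  # block-mean pooling of (n, px, px, 3) to (n, px/block * px/block * 3)
  n <- dim(patches)[1]; px <- dim(patches)[2]
  out_px <- px %/% block
  P <- matrix(0, px, out_px)
  for (j in seq_len(out_px))
    P[(j - 1L) * block + seq_len(block), j] <- 1 / block
  X <- matrix(0, n, out_px * out_px * 3L)
  for (i in seq_len(n)) {
    v <- vapply(1:3, function(ch) as.vector(t(P) %*% patches[i, , , ch] %*% P),
                numeric(out_px * out_px))
    X[i, ] <- as.vector(v)
  }
  X
}

contrastive_init <- function(d_in, d_enc, d_proj, K = 0L) {
  p <- list(W1 = init_weight(128L, d_in), b1 = matrix(0, 1, 128L),
            W2 = init_weight(d_enc, 128L), b2 = matrix(0, 1, d_enc),
            P1 = init_weight(d_enc, d_enc), q1 = matrix(0, 1, d_enc),
            P2 = init_weight(d_enc, d_enc), q2 = matrix(0, 1, d_enc),
            P3 = init_weight(d_proj, d_enc), q3 = matrix(0, 1, d_proj))
  if (K > 0L) {
    p$Wh <- init_weight(K, d_enc)
    p$bh <- matrix(0, 1, K)
  }
  p
}

enc_mid <- function(p, X) {
  h <- ad_relu(ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(X, ad_t(p$W1)), p$b1)),
                                ad_t(p$W2)), p$b2))
  # keep the first of the three projection layers ("half the head")
  ad_relu(ad_add(ad_matmul(h, ad_t(p$P1)), p$q1))
}

enc_proj <- function(p, X) {
  mid <- enc_mid(p, X)
  z2 <- ad_relu(ad_add(ad_matmul(mid, ad_t(p$P2)), p$q2))
  ad_add(ad_matmul(z2, ad_t(p$P3)), p$q3)
}

#' Learn per-spot visual features contrastively
#'
#' Step 1 pretrains the encoder + 3-layer projection head with
#' [nt_xent_loss()] on augmented patch pairs. Step 2 (when `labels` are
#' given) fine-tunes from the first projection layer with cross-entropy on
#' the labeled spots. Step 3 (when `distill_epochs > 0`) trains a smaller
#' student on the fine-tuned teacher's softened class probabilities with
#' [distill_loss()]. The returned features are the first-projection-layer
#' outputs.
#'
#' @param patches array `spots x px x px x 3` in `[0, 1]` (at least 8
#'   patches; a larger requested batch is clipped with a warning).
#' @param labels optional per-spot labels (`NA` = unlabeled).
#' @param d_v feature width.
#' @param tau NT-Xent temperature.
#' @param epochs,finetune_epochs,distill_epochs,lr training lengths.
#' @param batch_size patches per contrastive step.
#' @param seed RNG seed.
#' @return spots x `d_v` matrix with attributes `loss_history` and (after
#'   distillation) `student_agreement` (fraction of spots where student and
#'   teacher predict the same class).
#' @export
train_contrastive <- function(patches, labels = NULL, d_v = 64L, tau = 0.5,
                              epochs = 40L, finetune_epochs = 20L,
                              distill_epochs = 0L, lr = 1e-3,
                              batch_size = 128L, seed = 0L) {
  n <- dim(patches)[1]
  if (n < 8L) stop("need at least 8 patches")
  if (batch_size > n) {
    warning("batch_size clipped to the number of patches (", n, ")")
    batch_size <- n
  }
  lev <- NULL; Yint <- NULL
  if (!is.null(labels)) {
    lev <- sort(unique(stats::na.omit(as.character(labels))))
    Yint <- match(as.character(labels), lev)
  }
  K <- length(lev)
  with_seed_local(seed, {
    d_in <- (dim(patches)[2] %/% 4L)^2 * 3L
    params <- contrastive_init(d_in, d_v, 32L, K)
    state <- adam_init(params)
    hist <- numeric(0)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n, batch_size)
      views <- array(0, c(2L * batch_size, dim(patches)[2], dim(patches)[2], 3L))
      for (b in seq_along(idx)) {
        pr <- augment_patch(patches[idx[b], , , ],
                            seed = stats::runif(1, 0, 2^30))
        views[2L * b - 1L, , , ] <- pr$view_a
        views[2L * b, , , ] <- pr$view_b
      }
      X <- downsample_patches(views)
      g <- ad_graph()
      nodes <- lapply(stats::setNames(names(params), names(params)),
                      function(nm) ad_param(g, params[[nm]]))
      loss <- nt_xent_loss(enc_proj(nodes, X), tau)
      hist <- c(hist, loss$val)
      ad_backward(loss)
      upd <- adam_step(params, lapply(nodes, function(nd) nd$grad), state,
                       lr = lr)
      params <- upd$params; state <- upd$state
    }
    Xall <- downsample_patches(patches)
    if (K > 0L && finetune_epochs > 0L) {
      labeled <- which(!is.na(Yint))
      Yhot <- matrix(0, length(labeled), K)
      Yhot[cbind(seq_along(labeled), Yint[labeled])] <- 1
      Xlab <- Xall[labeled, , drop = FALSE]
      for (ep in seq_len(finetune_epochs)) {
        g <- ad_graph()
        nodes <- lapply(stats::setNames(names(params), names(params)),
                        function(nm) ad_param(g, params[[nm]]))
        mid <- enc_mid(nodes, Xlab)
        ls <- ad_logsoftmax_rows(ad_add(ad_matmul(mid, ad_t(nodes$Wh)),
                                        nodes$bh))
        loss <- ad_neg(ad_div(ad_sum(ad_mul(Yhot, ls)), length(labeled)))
        hist <- c(hist, loss$val)
        ad_backward(loss)
        upd <- adam_step(params, lapply(nodes, function(nd) nd$grad), state,
                         lr = lr)
        params <- upd$params; state <- upd$state
      }
    }
    v <- nval(enc_mid(params, Xall))
    rownames(v) <- dimnames(patches)[[1]]
    if (K > 0L && distill_epochs > 0L) {
      teacher_logits <- nval(ad_add(ad_matmul(enc_mid(params, Xall),
                                              ad_t(params$Wh)), params$bh))
      sp <- list(S1 = init_weight(32L, d_in), c1 = matrix(0, 1, 32L),
                 S2 = init_weight(K, 32L), c2 = matrix(0, 1, K))
      sstate <- adam_init(sp)
      for (ep in seq_len(distill_epochs)) {
        g <- ad_graph()
        nodes <- lapply(stats::setNames(names(sp), names(sp)),
                        function(nm) ad_param(g, sp[[nm]]))
        sl <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(Xall, ad_t(nodes$S1)),
                                              nodes$c1)), ad_t(nodes$S2)),
                     nodes$c2)
        loss <- distill_loss(teacher_logits, sl, tau = 1)
        ad_backward(loss)
        upd <- adam_step(sp, lapply(nodes, function(nd) nd$grad), sstate,
                         lr = lr)
        sp <- upd$params; sstate <- upd$state
      }
      sfinal <- nval(ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(Xall,
        ad_t(sp$S1)), sp$c1)), ad_t(sp$S2)), sp$c2))
      attr(v, "student_agreement") <-
        mean(max.col(sfinal) == max.col(teacher_logits))
    }
    attr(v, "loss_history") <- hist
    v
  })
}
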