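# Edge-feature-enhanced graph attention encoder.
#
# Each layer computes attention scores f_ij = exp(LeakyReLU(a^T [W x_i || W
# x_j])), modulates them channel-wise by the incoming edge features,
# normalizes every channel to a symmetric doubly stochastic matrix, and
# aggregates transformed node features per channel; the concatenation over
# channels is the layer output and the attention tensor becomes the edge
# features of the next layer. Training minimizes an adjacency
# reconstruction term (inner-product decoder) plus a weighted
# classification term over the weakly labeled spots.

# one channel of doubly stochastic normalization; polymorphic over plain
# matrices and autodiff nodes
ds_channel <- function(M) {
  Et <- ad_div(M, ad_rowsums(M))
  ad_matmul(ad_div(Et, ad_colsums(Et)), ad_t(Et))
}

#' Doubly stochastic normalization of positive edge-feature channels
#'
#' Per channel `p`: rows of the raw channel are first normalized to sum one
#' (`Etilde`), then `E_ijp = sum_k Etilde_ikp Etilde_jkp / sum_v
#' Etilde_vkp`. The result is symmetric, non-negative, and its rows (hence
#' columns) sum to one.
#'
#' @param E_hat `n x n` matrix or `n x n x P` array; entries must be
#'   positive on the support and zero elsewhere, every row must have
#'   support.
#' @return object of the same shape with each channel normalized.
#' @export
ds_normalize <- function(E_hat) {
  arr <- if (is.matrix(E_hat)) array(E_hat, c(dim(E_hat), 1L)) else E_hat
  stopifnot(length(dim(arr)) == 3L)
  if (any(arr < 0)) stop("edge features must be non-negative")
  out <- arr
  for (p in seq_len(dim(arr)[3])) {
    M <- arr[, , p]
    if (any(rowSums(M) == 0))
      stop("isolated node: a row of channel ", p, " has no support")
    out[, , p] <- ds_channel(M)
  }
  if (is.matrix(E_hat)) out[, , 1L] else out
}

#' One edge-feature graph attention layer (forward pass)
#'
#' @param X_prev `n x F` node features.
#' @param E_prev `n x n x P` positive edge-feature tensor (raw features at
#'   the first layer, the previous attention tensor afterwards).
#' @param params list with `W` (`F_out x F`), `a` (length `2 * F_out`),
#'   optional `slope` (LeakyReLU, default 0.2) and `activation`
#'   (`"elu"`, `"none"`).
#' @return list with `X` (`n x P*F_out`) and `E` (`n x n x P` attention
#'   tensor, each channel symmetric doubly stochastic).
#' @export
egat_layer <- function(X_prev, E_prev, params) {
  P <- dim(E_prev)[3]
  Elist <- lapply(seq_len(P), function(p) E_prev[, , p])
  out <- egat_layer_core(as.matrix(X_prev), Elist, params$W,
                         matrix(params$a, ncol = 1L),
                         slope = params$slope %||% 0.2,
                         activation = params$activation %||% "elu")
  E <- array(0, c(nrow(X_prev), nrow(X_prev), P))
  for (p in seq_len(P)) E[, , p] <- out$E[[p]]
  list(X = out$X, E = E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

egat_layer_core <- function(X, Elist, W, a, slope = 0.2,
                            activation = "elu") {
  H <- ad_matmul(X, ad_t(W))
  Fo <- ncol(nval(H))
  u <- ad_matmul(H, a[seq_len(Fo), , drop = FALSE])
  w <- ad_matmul(H, a[Fo + seq_len(Fo), , drop = FALSE])
  S <- ad_clamp(ad_leakyrelu(ad_add(u, ad_t(w)), slope), -30, 30)
  f <- ad_exp(S)
  alist <- vector("list", length(Elist))
  olist <- vector("list", length(Elist))
  for (p in seq_along(Elist)) {
    ahat <- ad_mul(f, Elist[[p]])
    alist[[p]] <- ds_channel(ahat)
    olist[[p]] <- ad_matmul(alist[[p]], H)
  }
  Xn <- ad_cbind(olist)
  if (activation == "elu") Xn <- ad_elu(Xn)
  list(X = Xn, E = alist, H = H)
}

#' Inner-product adjacency decoder
#'
#' `A' = sigmoid(R R^T)`: symmetric, entries in (0, 1), diagonal
#' `sigmoid(||R_i||^2)`.
#'
#' @param R `n x d` embedding.
#' @return `n x n` matrix.
#' @export
decode_adjacency <- function(R) {
  sigm(R %*% t(R))
}

#' Composite EGAT training loss
#'
#' `L = L_recon + weight * L_cls` where `L_recon` is the mean binary
#' cross-entropy of the decoded adjacency against the graph adjacency over
#' all `n^2` pairs, and `L_cls` the mean cross-entropy of the class
#' predictions over the labeled spots (0, with a warning, when no spot is
#' labeled).
#'
#' @param A binary adjacency matrix.
#' @param A_prime decoded adjacency in (0, 1).
#' @param Y integer class per spot (`NA` = unlabeled).
#' @param Y_prime `n x K` rows on the simplex.
#' @param weight classification weight (published value 8).
#' @return list `total`, `recon`, `cls`.
#' @export
egat_loss <- function(A, A_prime, Y = NULL, Y_prime = NULL, weight = 8) {
  Ap <- pmin(pmax(A_prime, 1e-7), 1 - 1e-7)
  recon <- -mean(A * log(Ap) + (1 - A) * log(1 - Ap))
  labeled <- if (is.null(Y)) integer(0) else which(!is.na(Y))
  if (!length(labeled)) {
    if (!is.null(Y)) warning("no labeled spots; classification term is 0")
    cls <- 0
  } else {
    pr <- pmax(Y_prime[cbind(labeled, Y[labeled])], 1e-12)
    cls <- -mean(log(pr))
  }
  list(total = recon + weight * cls, recon = recon, cls = cls)
}

egat_init_params <- function(F0, dims, P, K) {
  p <- list()
  fin <- F0
  for (l in seq_along(dims)) {
    p[[paste0("W", l)]] <- init_weight(dims[l], fin)
    p[[paste0("a", l)]] <- init_weight(2L * dims[l], 1L) * 0.1
    fin <- P * dims[l]
  }
  if (K > 0) {
    p$Wc <- init_weight(K, fin)
    p$bc <- matrix(0, 1L, K)
  }
  p
}

egat_forward <- function(g, params, X0, Elist, dims, P, slope) {
  wrap <- function(nm) if (is.null(g)) params[[nm]] else ad_param(g, params[[nm]])
  nodes <- lapply(stats::setNames(names(params), names(params)), wrap)
  X <- X0; E <- Elist
  for (l in seq_along(dims)) {
    W <- nodes[[paste0("W", l)]]
    a <- nodes[[paste0("a", l)]]
    out <- if (is_adnode(a)) {
      egat_layer_core_trainable(X, E, W, a, dims[l], slope)
    } else {
      egat_layer_core(X, E, W, a, slope)
    }
    X <- out$X; E <- out$E
  }
  list(R = X, E = E, nodes = nodes)
}

# training-path layer: same math as egat_layer_core but with the attention
# vector split handled through constant selector matrices so it stays
# differentiable
egat_layer_core_trainable <- function(X, Elist, W, a, Fo, slope) {
  H <- ad_matmul(X, ad_t(W))
  sel1 <- rbind(diag(1, Fo), matrix(0, Fo, Fo))   # (2Fo x Fo)
  sel2 <- rbind(matrix(0, Fo, Fo), diag(1, Fo))
  u <- ad_matmul(H, ad_matmul(ad_t(a), sel1) |> ad_t())
  w <- ad_matmul(H, ad_matmul(ad_t(a), sel2) |> ad_t())
  S <- ad_clamp(ad_leakyrelu(ad_add(u, ad_t(w)), slope), -30, 30)
  f <- ad_exp(S)
  alist <- vector("list", length(Elist))
  olist <- vector("list", length(Elist))
  for (p in seq_along(Elist)) {
    ahat <- ad_mul(f, Elist[[p]])
    alist[[p]] <- ds_channel(ahat)
    olist[[p]] <- ad_matmul(alist[[p]], H)
  }
  list(X = ad_elu(ad_cbind(olist)), E = alist)
}

#' Train the per-view graph attention encoder
#'
#' Two EGAT layers (widths `dims`), inner-product adjacency decoder, and a
#' linear softmax head over the labeled spots; full-batch Adam on
#' [egat_loss()]. With `epochs = 0` the returned embedding is the untrained
#' forward pass.
#'
#' @param view_graph a [build_view_graph()] result.
#' @param labels character or factor per spot, `NA` for unlabeled spots;
#'   `NULL` runs fully unsupervised (reconstruction only).
#' @param dims layer output widths.
#' @param epochs,lr optimisation settings.
#' @param loss_weight weight of the classification term.
#' @param slope LeakyReLU slope in the attention.
#' @param seed RNG seed (initialisation).
#' @param verbose print loss every 25 epochs.
#' @return spots x (P * last width) embedding matrix, row names from the
#'   node features, with attribute `loss_history`.
#' @export
train_egat <- function(view_graph, labels = NULL, dims = c(128L, 32L),
                       epochs = 120L, lr = 1e-3, loss_weight = 8,
                       slope = 0.2, seed = 0L, verbose = FALSE) {
  stopifnot(inherits(view_graph, "view_graph"))
  X0 <- view_graph$node_features
  n <- nrow(X0)
  P <- ncol(view_graph$edge_features)
  Earr <- edge_feature_tensor(view_graph)
  if (any(apply(Earr, 3L, function(M) any(rowSums(M) == 0))))
    stop("isolated node in view graph; increase knn_edges")
  Elist <- lapply(seq_len(P), function(p) Earr[, , p])
  A <- adjacency_matrix(view_graph)
  Yint <- NULL; K <- 0L; Yhot <- NULL; u <- 0L
  if (!is.null(labels)) {
    lev <- sort(unique(stats::na.omit(as.character(labels))))
    K <- length(lev)
    Yint <- match(as.character(labels), lev)
    u <- sum(!is.na(Yint))
    if (u == 0L) { K <- 0L; Yint <- NULL }
    else {
      Yhot <- matrix(0, n, K)
      Yhot[cbind(which(!is.na(Yint)), Yint[!is.na(Yint)])] <- 1
    }
  }
  with_seed_local(seed, {
    params <- egat_init_params(ncol(X0), dims, P, K)
    state <- adam_init(params)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      g <- ad_graph()
      fw <- egat_forward(g, params, X0, Elist, dims, P, slope)
      R <- fw$R
      Ap <- ad_sigmoid(ad_matmul(R, ad_t(R)))
      Apc <- ad_clamp(Ap, 1e-7, 1 - 1e-7)
      recon <- ad_neg(ad_mean(ad_add(ad_mul(A, ad_log(Apc)),
                                     ad_mul(1 - A, ad_log(ad_sub(1, Apc))))))
      loss <- recon
      if (K > 0L) {
        logits <- ad_add(ad_matmul(R, ad_t(fw$nodes$Wc)), fw$nodes$bc)
        ls <- ad_logsoftmax_rows(logits)
        cls <- ad_neg(ad_div(ad_sum(ad_mul(Yhot, ls)), u))
        loss <- ad_add(recon, ad_mul(loss_weight, cls))
      }
      if (!is.finite(loss$val))
        stop("EGAT diverged (loss not finite) at epoch ", ep, " with lr ", lr)
      hist[ep] <- loss$val
      ad_backward(loss)
      grads <- lapply(fw$nodes, function(nd) nd$grad)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      if (verbose && ep %% 25L == 0L)
        message("epoch ", ep, " EGAT loss ", signif(hist[ep], 5))
    }
    fw <- egat_forward(NULL, params, X0, Elist, dims, P, slope)
    emb <- nval(fw$R)
    rownames(emb) <- rownames(X0)
    attr(emb, "loss_history") <- hist
    emb
  })
}
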