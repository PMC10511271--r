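# Negative-binomial autoencoder for expression features.
#
# Counts are reduced to a low-dimensional feature matrix by an MLP
# autoencoder whose reconstruction likelihood is negative binomial: the
# decoder emits per-entry proportions (softmax head) scaled by the spot's
# library size as the NB mean, and a softplus head as the NB dispersion.
# The latent layer is the expression feature matrix used as node features
# of every view graph.

#' Select highly variable genes
#'
#' Genes are ranked by their variability on log-normalised counts (variance
#' of `log1p` of size-factor-normalised counts); ties are broken by gene id
#' so the selection is deterministic. Constant genes score zero and rank
#' last.
#'
#' @param counts spots x genes count matrix with column names.
#' @param n_top number of genes to keep (at most `ncol(counts)`).
#' @return list with `counts` (reduced matrix), `index` (column indices into
#'   the input, in original column order) and `score` (per selected gene).
#' @export
select_hvg <- function(counts, n_top) {
  counts <- as.matrix(counts)
  if (n_top > ncol(counts))
    stop("n_top (", n_top, ") exceeds number of genes (", ncol(counts), ")")
  gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  tot <- rowSums(counts)
  sf <- tot / stats::median(tot[tot > 0])
  sf[sf == 0] <- 1
  ln <- log1p(counts / sf)
  score <- apply(ln, 2L, stats::var)
  ord <- order(-score, gene_ids)
  keep <- sort(ord[seq_len(n_top)])
  list(counts = counts[, keep, drop = FALSE], index = keep,
       score = score[keep])
}

#' Negative binomial negative log-likelihood
#'
#' Total `-sum(log NB(x; mu = u, size = theta))` computed with log-gamma
#' arithmetic; finite for all valid inputs. In the limit `theta -> Inf` it
#' approaches the Poisson negative log-likelihood.
#'
#' @param x non-negative integer counts (vector or matrix).
#' @param u,theta NB mean and dispersion, strictly positive, broadcastable
#'   against `x`.
#' @return scalar, the summed negative log-likelihood.
#' @export
nb_negative_loglik <- function(x, u, theta) {
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (any(u <= 0)) stop("u must be strictly positive")
  if (any(theta <= 0)) stop("theta must be strictly positive")
  sh <- bshape(am(x), am(u))
  sum(ad_nb_nll_terms(expand_to(am(x), sh[1], sh[2]),
                      expand_to(am(u), sh[1], sh[2]),
                      expand_to(am(theta), sh[1], sh[2])))
}

ae_init_params <- function(n_in, hidden, latent) {
  list(
    We1 = init_weight(hidden, n_in),  be1 = matrix(0, 1, hidden),
    ge1 = matrix(1, 1, hidden),       bb1 = matrix(0, 1, hidden),
    We2 = init_weight(latent, hidden), be2 = matrix(0, 1, latent),
    Wd1 = init_weight(hidden, latent), bd1 = matrix(0, 1, hidden),
    gd1 = matrix(1, 1, hidden),        bbd = matrix(0, 1, hidden),
    Wu = init_weight(n_in, hidden),    bu = matrix(0, 1, n_in),
    Wt = init_weight(n_in, hidden),    bt = matrix(0, 1, n_in)
  )
}

ad_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  n <- nrow(nval(x))
  mu <- ad_div(ad_colsums(x), n)
  xc <- ad_sub(x, mu)
  v <- ad_div(ad_colsums(ad_mul(xc, xc)), n)
  ad_add(ad_mul(ad_div(xc, ad_sqrt(ad_add(v, eps))), gamma), beta)
}

ae_forward <- function(g, params, xin, lib, drop_mask = NULL,
                       mean_head = "softmax") {
  wrap <- function(nm) if (is.null(g)) params[[nm]] else ad_param(g, params[[nm]])
  p <- lapply(stats::setNames(names(params), names(params)), wrap)
  h1 <- ad_relu(ad_batchnorm(ad_add(ad_matmul(xin, ad_t(p$We1)), p$be1),
                             p$ge1, p$bb1))
  if (!is.null(drop_mask)) h1 <- ad_mul(h1, drop_mask)
  z <- ad_add(ad_matmul(h1, ad_t(p$We2)), p$be2)
  h2 <- ad_relu(ad_batchnorm(ad_add(ad_matmul(z, ad_t(p$Wd1)), p$bd1),
                             p$gd1, p$bbd))
  mu_raw <- ad_add(ad_matmul(h2, ad_t(p$Wu)), p$bu)
  u <- if (mean_head == "softmax") {
    ad_mul(ad_softmax_rows(mu_raw), lib)          # proportions x library size
  } else {
    ad_add(ad_softplus(mu_raw), 1e-8)
  }
  theta <- ad_add(ad_softplus(ad_add(ad_matmul(h2, ad_t(p$Wt)), p$bt)), 1e-4)
  list(z = z, u = u, theta = theta, nodes = p)
}

#' Train the negative binomial autoencoder
#'
#' Full-batch Adam on the mean per-entry NB negative log-likelihood. The
#' mean head emits per-gene proportions (row softmax) scaled by the spot
#' library size; the dispersion head is softplus. The latent layer is the
#' returned feature matrix.
#'
#' @param counts_hvg spots x genes count matrix (typically [select_hvg()]
#'   output).
#' @param hidden,latent layer widths (published frame: 1000 and 50).
#' @param epochs,lr,weight_decay,dropout optimisation settings.
#' @param mean_head `"softmax"` (proportions times library) or `"softplus"`.
#' @param seed RNG seed; training is deterministic given the seed.
#' @param verbose print loss every 25 epochs.
#' @return spots x latent feature matrix with the spot ids as row names and
#'   attribute `loss_history` (mean per-entry NB NLL per epoch).
#' @export
train_expr_ae <- function(counts_hvg, hidden = 1000L, latent = 50L,
                          epochs = 200L, lr = 8e-5, weight_decay = 1e-6,
                          dropout = 0.1, mean_head = "softmax", seed = 0L,
                          verbose = FALSE) {
  counts_hvg <- as.matrix(counts_hvg)
  n <- nrow(counts_hvg); gg <- ncol(counts_hvg)
  tot <- rowSums(counts_hvg)
  tot[tot == 0] <- 1
  # size factor normalised to mean one; the mean head is rescaled by the
  # actual library so reconstructed means live on the count scale
  lx <- matrix(tot / mean(tot), ncol = 1L)
  lib <- matrix(tot, ncol = 1L)
  xin <- log1p(sweep(counts_hvg, 1L, lx[, 1L], "/"))
  with_seed_local(seed, {
    params <- ae_init_params(gg, hidden, latent)
    state <- adam_init(params)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      g <- ad_graph()
      mask <- if (dropout > 0) {
        (matrix(stats::runif(n * hidden), n, hidden) > dropout) / (1 - dropout)
      } else NULL
      fw <- ae_forward(g, params, xin, lib, drop_mask = mask,
                       mean_head = mean_head)
      loss <- ad_mean(ad_nb_nll_terms(counts_hvg, fw$u, fw$theta))
      if (!is.finite(loss$val))
        stop("NB autoencoder diverged (loss not finite) at epoch ", ep,
             " with lr ", lr)
      hist[ep] <- loss$val
      ad_backward(loss)
      grads <- lapply(fw$nodes, function(nd) nd$grad)
      upd <- adam_step(params, grads, state, lr = lr,
                       weight_decay = weight_decay)
      params <- upd$params; state <- upd$state
      if (verbose && ep %% 25L == 0L)
        message("epoch ", ep, " mean NB NLL ", signif(hist[ep], 5))
    }
    g <- ad_graph()
    fw <- ae_forward(g, params, xin, lib, drop_mask = NULL,
                     mean_head = mean_head)
    emb <- nval(fw$z)
    rownames(emb) <- rownames(counts_hvg)
    attr(emb, "loss_history") <- hist
    emb
  })
}
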