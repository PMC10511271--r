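# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every trainable component in the package (NB autoencoder, contrastive
# encoder, edge-feature graph attention, fusion attention) is expressed in
# the ops below. Ops are polymorphic: called on plain matrices they return
# plain matrices (used by the exported forward-pass functions and by test
# oracles); called on tape nodes they record the operation for backward().
#
# Broadcasting follows the usual outer-product rules restricted to the cases
# the models need: equal shape, 1x1 scalar, n x 1 column against n x m, and
# 1 x m row against n x m.

am <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

is_adnode <- function(x) inherits(x, "adnode")

nval <- function(x) if (is_adnode(x)) x$val else am(x)

#' @noRd
ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- vector("list", 256L)
  g$n <- 0L
  g
}

new_node <- function(g, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$graph <- g
  class(nd) <- "adnode"
  g$n <- g$n + 1L
  if (g$n > length(g$tape)) g$tape <- c(g$tape, vector("list", length(g$tape)))
  g$tape[[g$n]] <- nd
  nd
}

ad_param <- function(g, val) new_node(g, am(val))

graph_of <- function(...) {
  for (x in list(...)) if (is_adnode(x)) return(x$graph)
  NULL
}

accum_grad <- function(node, gr) {
  if (is.null(node$grad)) node$grad <- gr else node$grad <- node$grad + gr
}

#' Run backpropagation from a scalar output node
#' @noRd
ad_backward <- function(node) {
  stopifnot(is_adnode(node), length(node$val) == 1L)
  g <- node$graph
  node$grad <- matrix(1, 1, 1)
  for (i in seq.int(g$n, 1L)) {
    nd <- g$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is_adnode(p) && !is.null(gs[[j]])) accum_grad(p, gs[[j]])
    }
  }
  invisible(node)
}

# --- broadcasting helpers ----------------------------------------------------

expand_to <- function(x, nr, nc) {
  dx <- dim(x)
  if (dx[1] == nr && dx[2] == nc) return(x)
  if (dx[1] == 1L && dx[2] == 1L) return(matrix(x[1L], nr, nc))
  if (dx[1] == nr && dx[2] == 1L) return(matrix(x, nr, nc))
  if (dx[1] == 1L && dx[2] == nc) return(matrix(x, nr, nc, byrow = TRUE))
  stop("incompatible broadcast: ", dx[1], "x", dx[2], " vs ", nr, "x", nc)
}

reduce_to <- function(gr, dx) {
  dg <- dim(gr)
  if (identical(dg, dx)) return(gr)
  if (dx[1] == 1L && dx[2] == 1L) return(matrix(sum(gr), 1, 1))
  if (dx[1] == dg[1] && dx[2] == 1L) return(matrix(rowSums(gr), ncol = 1L))
  if (dx[1] == 1L && dx[2] == dg[2]) return(matrix(colSums(gr), nrow = 1L))
  stop("incompatible gradient reduction")
}

bshape <- function(a, b) {
  c(max(nrow(a), nrow(b)), max(ncol(a), ncol(b)))
}

binary_op <- function(a, b, fwd, bwd_a, bwd_b) {
  va <- nval(a); vb <- nval(b)
  sh <- bshape(va, vb)
  ea <- expand_to(va, sh[1], sh[2]); eb <- expand_to(vb, sh[1], sh[2])
  out <- fwd(ea, eb)
  g <- graph_of(a, b)
  if (is.null(g)) return(out)
  da <- dim(va); db <- dim(vb)
  new_node(g, out, list(a, b), function(gr) {
    list(
      if (is_adnode(a)) reduce_to(bwd_a(gr, ea, eb, out), da) else NULL,
      if (is_adnode(b)) reduce_to(bwd_b(gr, ea, eb, out), db) else NULL
    )
  })
}

unary_op <- function(a, fwd, bwd) {
  va <- nval(a)
  out <- fwd(va)
  if (!is_adnode(a)) return(out)
  new_node(a$graph, out, list(a), function(gr) list(bwd(gr, va, out)))
}

# --- arithmetic --------------------------------------------------------------

ad_add <- function(a, b) binary_op(a, b, `+`,
  function(gr, ea, eb, o) gr, function(gr, ea, eb, o) gr)

ad_sub <- function(a, b) binary_op(a, b, `-`,
  function(gr, ea, eb, o) gr, function(gr, ea, eb, o) -gr)

ad_mul <- function(a, b) binary_op(a, b, `*`,
  function(gr, ea, eb, o) gr * eb, function(gr, ea, eb, o) gr * ea)

ad_div <- function(a, b) binary_op(a, b, `/`,
  function(gr, ea, eb, o) gr / eb, function(gr, ea, eb, o) -gr * ea / (eb * eb))

ad_neg <- function(a) unary_op(a, function(x) -x, function(gr, x, o) -gr)

ad_matmul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  out <- va %*% vb
  g <- graph_of(a, b)
  if (is.null(g)) return(out)
  new_node(g, out, list(a, b), function(gr) {
    list(
      if (is_adnode(a)) gr %*% t(vb) else NULL,
      if (is_adnode(b)) t(va) %*% gr else NULL
    )
  })
}

ad_t <- function(a) unary_op(a, t, function(gr, x, o) t(gr))

# --- elementwise nonlinearities ---------------------------------------------

ad_exp <- function(a) unary_op(a, exp, function(gr, x, o) gr * o)

ad_log <- function(a) unary_op(a, log, function(gr, x, o) gr / x)

ad_sqrt <- function(a) unary_op(a, sqrt, function(gr, x, o) gr / (2 * o))

sigm <- function(x) 1 / (1 + exp(-x))

ad_sigmoid <- function(a) unary_op(a, sigm, function(gr, x, o) gr * o * (1 - o))

ad_softplus <- function(a) unary_op(a,
  function(x) pmax(x, 0) + log1p(exp(-abs(x))),
  function(gr, x, o) gr * sigm(x))

ad_relu <- function(a) unary_op(a,
  function(x) pmax(x, 0),
  function(gr, x, o) gr * (x > 0))

ad_leakyrelu <- function(a, slope = 0.2) unary_op(a,
  function(x) ifelse(x > 0, x, slope * x),
  function(gr, x, o) gr * ifelse(x > 0, 1, slope))

ad_elu <- function(a) unary_op(a,
  function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
  function(gr, x, o) gr * ifelse(x > 0, 1, o + 1))

ad_clamp <- function(a, lo, hi) unary_op(a,
  function(x) pmin(pmax(x, lo), hi),
  function(gr, x, o) gr * (x >= lo & x <= hi))

# --- reductions and shape ----------------------------------------------------

ad_sum <- function(a) {
  va <- nval(a)
  out <- matrix(sum(va), 1, 1)
  if (!is_adnode(a)) return(out)
  d <- dim(va)
  new_node(a$graph, out, list(a), function(gr) list(matrix(gr[1L], d[1], d[2])))
}

ad_mean <- function(a) {
  va <- nval(a)
  out <- matrix(mean(va), 1, 1)
  if (!is_adnode(a)) return(out)
  d <- dim(va)
  new_node(a$graph, out, list(a),
           function(gr) list(matrix(gr[1L] / (d[1] * d[2]), d[1], d[2])))
}

ad_rowsums <- function(a) {
  va <- nval(a)
  out <- matrix(rowSums(va), ncol = 1L)
  if (!is_adnode(a)) return(out)
  nc <- ncol(va)
  new_node(a$graph, out, list(a), function(gr) list(matrix(gr, nrow(va), nc)))
}

ad_colsums <- function(a) {
  va <- nval(a)
  out <- matrix(colSums(va), nrow = 1L)
  if (!is_adnode(a)) return(out)
  nr <- nrow(va)
  new_node(a$graph, out, list(a),
           function(gr) list(matrix(gr, nr, ncol(va), byrow = TRUE)))
}

ad_reshape <- function(a, nr, nc) {
  va <- nval(a)
  out <- va
  dim(out) <- c(nr, nc)
  if (!is_adnode(a)) return(out)
  d <- dim(va)
  new_node(a$graph, out, list(a), function(gr) {
    dim(gr) <- d
    list(gr)
  })
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, nval)
  out <- do.call(cbind, vals)
  g <- do.call(graph_of, xs)
  if (is.null(g)) return(out)
  ncols <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  new_node(g, out, xs, function(gr) {
    lapply(seq_along(xs), function(j) {
      if (is_adnode(xs[[j]])) gr[, starts[j]:ends[j], drop = FALSE] else NULL
    })
  })
}

# --- softmax family ----------------------------------------------------------

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

ad_softmax_rows <- function(a) unary_op(a, softmax_rows, function(gr, x, o) {
  o * (gr - rowSums(gr * o))
})

ad_logsoftmax_rows <- function(a) unary_op(a,
  function(x) {
    m <- apply(x, 1L, max)
    x - m - log(rowSums(exp(x - m)))
  },
  function(gr, x, o) gr - exp(o) * rowSums(gr))

# --- negative binomial reconstruction term -----------------------------------

# Per-entry negative log-likelihood of counts x under NB(mean = u, size =
# theta); custom op with analytic gradients in (u, theta). x is held constant.
ad_nb_nll_terms <- function(x, u, theta) {
  xv <- am(x); uv <- nval(u); tv <- nval(theta)
  fwd <- function(uv, tv) {
    -(lgamma(xv + tv) - lgamma(tv) - lgamma(xv + 1) +
        tv * (log(tv) - log(tv + uv)) + xv * (log(uv) - log(tv + uv)))
  }
  out <- fwd(uv, tv)
  g <- graph_of(u, theta)
  if (is.null(g)) return(out)
  new_node(g, out, list(u, theta), function(gr) {
    list(
      if (is_adnode(u)) gr * ((xv + tv) / (tv + uv) - xv / uv) else NULL,
      if (is_adnode(theta)) {
        gr * -(digamma(xv + tv) - digamma(tv) +
                 log(tv) - log(tv + uv) + 1 - (xv + tv) / (tv + uv))
      } else NULL
    )
  })
}

# --- optimizer ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    if (weight_decay > 0) gk <- gk + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-style initialisation used across all models.
init_weight <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}
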