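# Construction of the three view graphs over spots:
#   HSG  - histological similarity graph (visual features drive edges),
#   SLG  - spatial location graph (2D, or 3D with a 4th edge channel),
#   GAG  - gene association graph (conditional cell-specific networks).
# Each edge carries a multidimensional positive real-valued feature vector;
# the graph attention encoder consumes these channels directly.

#' Similarity edge features between two feature vectors
#'
#' The three channels used by the histology and gene-association graphs:
#' `e1` cosine similarity, `e2 = exp(-||a - b||_2)`, `e3` Pearson
#' correlation (defined as 0 when either vector is constant).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return numeric vector `c(e1, e2, e3)`.
#' @export
similarity_edge_features <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("vectors must have length >= 2")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  e1 <- sum(a * b) / (na * nb)
  e2 <- exp(-sqrt(sum((a - b)^2)))
  e3 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  c(e1 = e1, e2 = e2, e3 = e3)
}

#' Location edge features between two spots
#'
#' Planar channels: `e1` is the planar dot product divided by planar
#' distance, `e2` indicates planar distance within `lambda`, `e3` indicates
#' `|dy|` within `mu` (rule configurable; the threshold direction appears in
#' both orientations in the literature, the within-`mu` form is the default).
#' With `xi` given, a fourth channel indicates `|dz| <= xi`, connecting
#' adjacent tissue slices in 3D mode.
#'
#' @param s_i,s_j coordinate vectors (x, y) or (x, y, z).
#' @param lambda,mu,xi thresholds in coordinate units.
#' @param e3_rule `"le"` (`e3 = 1` iff `|dy| <= mu`) or `"gt"`.
#' @return numeric vector `c(e1, e2, e3)` or `c(e1, e2, e3, e4)`.
#' @export
location_edge_features <- function(s_i, s_j, lambda = 200, mu = 10,
                                   xi = NULL, e3_rule = c("le", "gt")) {
  e3_rule <- match.arg(e3_rule)
  d <- sqrt(sum((s_i[1:2] - s_j[1:2])^2))
  if (d == 0) stop("coincident spot coordinates: planar distance is zero")
  e1 <- sum(s_i[1:2] * s_j[1:2]) / d
  e2 <- as.numeric(d <= lambda)
  dy <- abs(s_i[2] - s_j[2])
  e3 <- if (e3_rule == "le") as.numeric(dy <= mu) else as.numeric(dy > mu)
  out <- c(e1 = e1, e2 = e2, e3 = e3)
  if (!is.null(xi)) {
    if (length(s_i) < 3L || length(s_j) < 3L)
      stop("xi given but coordinates have no z component")
    out <- c(out, e4 = as.numeric(abs(s_i[3] - s_j[3]) <= xi))
  }
  out
}

# box membership: cells whose expression of each gene falls inside a window
# of total width boxsize * sd(gene) centred at cell k's value, truncated at 0
box_members <- function(expr, k, boxsize) {
  half <- boxsize * apply(expr, 2L, stats::sd) / 2
  centre <- expr[k, ]
  lo <- pmax(0, centre - half)
  hi <- centre + half
  t(t(expr) >= lo & t(expr) <= hi)          # cells x genes logical
}

#' Conditional gene-association statistic for one cell
#'
#' Measures the conditional dependence of genes `x` and `y` given gene `z`
#' around cell `k`: with `n_z`, `n_xz`, `n_yz`, `n_xyz` the numbers of cells
#' in the expression neighbourhoods of `z`, `(x,z)`, `(y,z)`, `(x,y,z)`,
#' the statistic is `rho = n_xyz/n_z - (n_xz/n_z)(n_yz/n_z)`, bounded in
#' `[-1, 1]` and 0 under product independence.
#'
#' @param x_gene,y_gene,z_gene expression vectors across cells.
#' @param cell_k cell index the neighbourhoods are centred on.
#' @param boxsize neighbourhood width, in per-gene sd units.
#' @return `rho`, or `NA` if the `z` neighbourhood is empty.
#' @export
conditional_rho <- function(x_gene, y_gene, z_gene, cell_k, boxsize = 1.5) {
  expr <- cbind(x = x_gene, y = y_gene, z = z_gene)
  B <- box_members(expr, cell_k, boxsize)
  in_z <- B[, 3L]
  n_z <- sum(in_z)
  if (n_z == 0) return(NA_real_)
  n_xz <- sum(B[, 1L] & in_z)
  n_yz <- sum(B[, 2L] & in_z)
  n_xyz <- sum(B[, 1L] & B[, 2L] & in_z)
  n_xyz / n_z - (n_xz / n_z) * (n_yz / n_z)
}

# standardized rho threshold test for all gene pairs under one conditioning
# gene in one cell; returns the logical edge matrix (diagonal FALSE)
csn_edges_for_cell <- function(B, z_col, q) {
  in_z <- B[, z_col]
  n_z <- sum(in_z)
  Bz <- B[in_z, , drop = FALSE]
  n_xz <- colSums(Bz)
  n_xyz <- crossprod(Bz)                     # genes x genes
  rho <- n_xyz / n_z - outer(n_xz, n_xz) / n_z^2
  if (n_z < 2L) return(matrix(FALSE, ncol(B), ncol(B)))
  sig <- sqrt(outer(n_xz * (n_z - n_xz), n_xz * (n_z - n_xz))) /
    (n_z^2 * sqrt(n_z - 1))
  edge <- sig > 0 & (rho / pmax(sig, .Machine$double.eps)) > q
  diag(edge) <- FALSE
  edge
}

#' Conditional degree matrix from cell-specific gene networks
#'
#' For every cell, a cell-specific gene network is built: genes `x` and `y`
#' are connected when the standardized conditional statistic
#' [conditional_rho()] exceeds the upper normal quantile at level `alpha`
#' (standardization by the hypergeometric-style null sd
#' `sqrt(n_xz n_yz (n_z - n_xz)(n_z - n_yz)) / (n_z^2 sqrt(n_z - 1))`).
#' With several conditioning genes (`kk > 1`) an edge must be significant
#' under every conditioning gene. The output is the genes x cells matrix of
#' per-cell network degrees.
#'
#' @param counts spots (cells) x genes matrix.
#' @param alpha significance level of the edge test.
#' @param boxsize neighbourhood width in per-gene sd units.
#' @param kk number of conditioning genes.
#' @param conditioning_genes explicit gene indices; by default the top `kk`
#'   hub genes by total degree of an unconditional cell-specific network
#'   pass.
#' @return list with `V` (genes x cells integer degree matrix) and
#'   `conditioning_genes`.
#' @export
conditional_degree_matrix <- function(counts, alpha = 0.5, boxsize = 1.5,
                                      kk = 1L, conditioning_genes = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts); m <- ncol(counts)
  q <- stats::qnorm(1 - alpha)
  boxes <- lapply(seq_len(n), function(k) box_members(counts, k, boxsize))
  if (is.null(conditioning_genes)) {
    # unconditional pass: same statistic with the whole cell set as the
    # conditioning universe; hubs are the genes of largest total degree
    deg <- numeric(m)
    for (k in seq_len(n)) {
      B <- cbind(boxes[[k]], TRUE)
      e <- csn_edges_for_cell(B, m + 1L, q)[seq_len(m), seq_len(m)]
      deg <- deg + rowSums(e)
    }
    conditioning_genes <- order(-deg, seq_len(m))[seq_len(kk)]
  }
  V <- matrix(0L, m, n)
  for (k in seq_len(n)) {
    B <- boxes[[k]]
    combined <- NULL
    for (z in conditioning_genes) {
      e <- csn_edges_for_cell(B, z, q)
      combined <- if (is.null(combined)) e else (combined & e)
    }
    V[, k] <- as.integer(rowSums(combined))
  }
  rownames(V) <- colnames(counts)
  colnames(V) <- rownames(counts)
  list(V = V, conditioning_genes = conditioning_genes)
}

# deterministic symmetric kNN edge list; ties broken by node index
knn_edges <- function(D, k) {
  n <- nrow(D)
  if (k >= n) stop("knn_edges must be smaller than the number of nodes")
  pairs <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])[seq_len(k)]
    nb <- seq_len(n)[-i][ord]
    pairs <- rbind(pairs, cbind(i, nb))
  }
  und <- unique(t(apply(pairs, 1L, sort)))
  rbind(und, und[, 2:1, drop = FALSE])       # both orientations
}

cosine_distance_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  S <- (X / nrm) %*% t(X / nrm)
  1 - S
}

positive_shift <- function(x, type, eps = 1e-6) {
  switch(type,
    corr = (x + 1) / 2 + eps,
    pos = x + eps,
    bin = x + eps,
    scale = (x / max(abs(x), 1e-12) + 1) / 2 + eps,
    stop("unknown channel type"))
}

#' Build one view graph
#'
#' Edges are the symmetric k-nearest-neighbour pairs under the view's
#' auxiliary metric: cosine distance on visual features (HSG) or expression
#' features (GAG), Euclidean distance on coordinates (SLG; in 2D mode on
#' multi-slice data neighbours are restricted to the same slice, in 3D mode
#' the z coordinate enters the metric and a 4th edge channel connects
#' adjacent slices). Edge features are [similarity_edge_features()] for
#' HSG/GAG and [location_edge_features()] for SLG, then shifted per channel
#' to be strictly positive (affine map `(x+1)/2 + eps` for correlation-type
#' channels, `+eps` for binary/positive ones, max-abs rescale then affine
#' for the unbounded SLG `e1`).
#'
#' @param view_name one of `"HSG"`, `"SLG"`, `"SLG3D"`, `"GAG"`.
#' @param node_features spots x F feature matrix (expression features for
#'   HSG/SLG, degree-matrix features for GAG).
#' @param aux auxiliary per-spot data driving edges and edge features:
#'   visual features (HSG), coordinates (SLG), expression features (GAG).
#' @param config a [spotfuse_config()].
#' @param slice_id per-spot slice index; with `view_name = "SLG"` edges are
#'   restricted to the same slice when present.
#' @return A `view_graph`: list with `view_name`, `n_nodes`,
#'   `node_features`, `edges` (both orientations), `edge_features`
#'   (strictly positive), `edge_features_raw`.
#' @export
build_view_graph <- function(view_name = c("HSG", "SLG", "SLG3D", "GAG"),
                             node_features, aux, config = spotfuse_config(),
                             slice_id = NULL) {
  view_name <- match.arg(view_name)
  node_features <- as.matrix(node_features)
  aux <- as.matrix(aux)
  n <- nrow(node_features)
  stopifnot(nrow(aux) == n)
  k <- config$knn_edges
  if (view_name %in% c("SLG", "SLG3D")) {
    D <- as.matrix(stats::dist(aux))
    if (view_name == "SLG" && !is.null(slice_id)) {
      D[outer(slice_id, slice_id, "!=")] <- Inf   # 2D mode: same-slice only
    }
  } else {
    D <- cosine_distance_matrix(aux)
  }
  edges <- knn_edges(D, k)
  xi <- NULL
  if (view_name == "SLG3D") {
    xi <- config$xi
    if (is.null(xi)) {
      dz <- abs(outer(aux[, 3L], aux[, 3L], "-"))
      gaps <- dz[dz > 0]
      xi <- if (length(gaps)) min(gaps) else 1
    }
  }
  feat <- t(apply(edges, 1L, function(e) {
    i <- e[1]; j <- e[2]
    if (view_name %in% c("SLG", "SLG3D")) {
      location_edge_features(aux[i, ], aux[j, ], lambda = config$lambda,
                             mu = config$mu, xi = xi,
                             e3_rule = config$slg_e3_rule)
    } else {
      similarity_edge_features(aux[i, ], aux[j, ])
    }
  }))
  types <- if (view_name %in% c("SLG", "SLG3D")) {
    c("scale", "bin", "bin", if (!is.null(xi)) "bin")
  } else c("corr", "pos", "corr")
  pos <- feat
  for (p in seq_len(ncol(feat))) pos[, p] <- positive_shift(feat[, p], types[p])
  structure(list(view_name = view_name, n_nodes = n,
                 node_features = node_features, edges = edges,
                 edge_features = pos, edge_features_raw = feat,
                 xi = xi),
            class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat("view_graph", x$view_name, ":", x$n_nodes, "nodes,",
      nrow(x$edges) / 2, "undirected edges,",
      ncol(x$edge_features), "edge-feature channels\n")
  invisible(x)
}

#' Dense edge-feature tensor of a view graph
#' @param vg a `view_graph`.
#' @return array `n x n x P`, zero off the edge support.
#' @export
edge_feature_tensor <- function(vg) {
  n <- vg$n_nodes; P <- ncol(vg$edge_features)
  E <- array(0, c(n, n, P))
  for (p in seq_len(P))
    E[cbind(vg$edges, p)] <- vg$edge_features[, p]
  E
}

#' Binary adjacency matrix of a view graph
#' @param vg a `view_graph`.
#' @return n x n 0/1 matrix, symmetric, zero diagonal.
#' @export
adjacency_matrix <- function(vg) {
  A <- matrix(0, vg$n_nodes, vg$n_nodes)
  A[vg$edges] <- 1
  A
}

#' Serialize a view graph as edge-list and node-feature TSVs
#' @param vg a `view_graph`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_nodes.tsv`.
#' @export
write_view_graph <- function(vg, prefix) {
  ef <- as.data.frame(vg$edge_features)
  names(ef) <- paste0("e", seq_len(ncol(ef)))
  df <- cbind(data.frame(i = vg$edges[, 1], j = vg$edges[, 2]), ef)
  utils::write.table(df, paste0(prefix, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(vg$node_features, paste0(prefix, "_nodes.tsv"),
                     sep = "\t", row.names = TRUE, quote = FALSE,
                     col.names = NA)
  invisible(prefix)
}
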