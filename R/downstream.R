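# Spatial-domain clustering, spatial pseudo-expression (SPE) denoising,
# and spatially variable / dark gene calling on the fused embedding.

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the maximal ratio `(S_i + S_j) / M_ij`, with `S_i`
#' the mean Euclidean distance of cluster members to their centroid and
#' `M_ij` the centroid distance. Smaller is better.
#'
#' @param X points x features matrix.
#' @param labels cluster assignment (>= 2 clusters).
#' @return scalar index.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  stopifnot(k >= 2L)
  cen <- t(vapply(seq_len(k), function(c) colMeans(X[labels == c, , drop = FALSE]),
                  numeric(ncol(X))))
  S <- vapply(seq_len(k), function(c) {
    d <- sweep(X[labels == c, , drop = FALSE], 2L, cen[c, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cen))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (S[i] + S[j]) / M[i, j], numeric(1)))
  }, numeric(1)))
}

#' Average silhouette width
#' @param X points x features matrix.
#' @param labels cluster assignment.
#' @return mean silhouette over points.
#' @export
average_silhouette <- function(X, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(as.matrix(X)))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two partitions
#' @param a,b assignments of equal length.
#' @return scalar in [-1, 1], 1 for identical partitions.
#' @export
cluster_ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' Select the cluster count by the Davies-Bouldin index
#'
#' k-means (10 restarts, seeded) at every `k` in `k_range`; the `k` with
#' the smallest index wins, ties going to the smaller `k`.
#'
#' @param R spots x d embedding.
#' @param k_range candidate cluster counts, within `[2, spots - 1]`.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with `k` (selected), `dbi` (named vector over `k_range`).
#' @export
select_k_dbi <- function(R, k_range = 2:8, seed = 0L, nstart = 10L) {
  R <- as.matrix(R)
  if (all(apply(R, 2L, stats::sd) == 0))
    stop("degenerate embedding: all rows identical")
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L), all(k_range < nrow(R)))
  dbi <- vapply(k_range, function(k) {
    cl <- cluster_spots(R, k, seed = seed, nstart = nstart)
    davies_bouldin(R, cl)
  }, numeric(1))
  names(dbi) <- k_range
  list(k = k_range[which.min(dbi)], dbi = dbi)
}

#' k-means spot clustering
#'
#' Deterministic given the seed; cluster ids are renumbered by descending
#' size (ties by first occurrence). Runs with an empty cluster are retried
#' with a shifted seed, at most 20 times.
#'
#' @param R spots x d embedding.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return integer vector of cluster ids `1..k`, named by spot.
#' @export
cluster_spots <- function(R, k, seed = 0L, nstart = 10L) {
  R <- as.matrix(R)
  stopifnot(k >= 2L)
  for (try in 0:19) {
    km <- with_seed_local(seed + try, {
      tryCatch(stats::kmeans(R, centers = k, nstart = nstart,
                             iter.max = 100L),
               error = function(e) NULL)
    })
    if (!is.null(km) && length(unique(km$cluster)) == k) break
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " non-empty clusters")
  sizes <- tabulate(km$cluster, k)
  remap <- integer(k)
  remap[order(-sizes, seq_len(k))] <- seq_len(k)
  out <- remap[km$cluster]
  names(out) <- rownames(R)
  out
}

#' Spatial pseudo-expression by k-nearest-neighbour averaging
#'
#' Each spot's SPE row is the arithmetic mean of the raw count rows of its
#' `k_nn` nearest spots in embedding space (Euclidean distance, self
#' excluded by default, distance ties broken by spot index).
#'
#' @param R spots x d embedding the neighbourhoods are computed in.
#' @param counts spots x genes raw counts (all genes by default; any
#'   matrix with matching rows works).
#' @param k_nn neighbourhood size (published value 15), `< spots`.
#' @param include_self count the spot itself as one of its neighbours.
#' @return object of class `spe_matrix`: list with `spe` (spots x genes),
#'   `k_nn`, `neighbors` (spots x k_nn index matrix).
#' @export
compute_spe <- function(R, counts, k_nn = 15L, include_self = FALSE) {
  R <- as.matrix(R); counts <- as.matrix(counts)
  n <- nrow(R)
  stopifnot(nrow(counts) == n)
  if (k_nn >= n) stop("k_nn must be smaller than the number of spots")
  D <- as.matrix(stats::dist(R))
  if (!include_self) diag(D) <- Inf else diag(D) <- -Inf
  nb <- matrix(vapply(seq_len(n), function(i) {
    order(D[i, ], seq_len(n))[seq_len(k_nn)]
  }, integer(k_nn)), nrow = n, ncol = k_nn, byrow = TRUE)
  spe <- matrix(0, n, ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(n))
    spe[i, ] <- colMeans(counts[nb[i, ], , drop = FALSE])
  structure(list(spe = spe, k_nn = k_nn, neighbors = nb),
            class = "spe_matrix")
}

#' @export
print.spe_matrix <- function(x, ...) {
  cat("spe_matrix:", nrow(x$spe), "spots x", ncol(x$spe), "genes, k_nn =",
      x$k_nn, "\n")
  invisible(x)
}

# vectorized one-vs-rest Wilcoxon rank-sum tests (normal approximation
# with tie correction) for every gene and cluster; returns genes x
# clusters p-value and log2 fold-change matrices
ranksum_test <- function(M, cl, pseudo = 1) {
  M <- as.matrix(M)
  n <- nrow(M)
  ks <- sort(unique(cl))
  ranks <- apply(M, 2L, rank)                  # ties: midranks
  tie_term <- apply(M, 2L, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  pv <- matrix(NA_real_, ncol(M), length(ks))
  lfc <- matrix(NA_real_, ncol(M), length(ks))
  colnames(pv) <- colnames(lfc) <- ks
  rownames(pv) <- rownames(lfc) <- colnames(M)
  for (ci in seq_along(ks)) {
    ind <- as.numeric(cl == ks[ci])
    n1 <- sum(ind); n2 <- n - n1
    W <- drop(crossprod(ranks, ind))
    ew <- n1 * (n + 1) / 2
    vw <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (W - ew) / sqrt(pmax(vw, .Machine$double.eps))
    pv[, ci] <- 2 * stats::pnorm(-abs(z))
    m_in <- colMeans(M[ind == 1, , drop = FALSE])
    m_out <- colMeans(M[ind == 0, , drop = FALSE])
    lfc[, ci] <- log2((m_in + pseudo) / (m_out + pseudo))
  }
  list(p = pv, lfc = lfc)
}

#' Call spatially variable, pseudo-variable and dark genes
#'
#' Per gene and cluster, one-vs-rest Wilcoxon rank-sum tests are run on the
#' raw counts and on the SPE matrix; BH correction is applied within each
#' modality across all gene x cluster tests. Gene-level calls: SVG when
#' some cluster is significant on raw counts (q below `fdr` and `|log2FC|`
#' at least `lfc_min`), SPVG when significant on SPE, and SDG = SPVG and
#' not SVG. All-zero genes are not tested.
#'
#' Note that SPE values are k-NN averages, so the rank-sum test on the SPE
#' modality treats smoothed (positively dependent) observations as
#' independent; this is what gives the denoised signal its sensitivity,
#' and it means SPE-modality significance is a screening call, not a
#' calibrated error rate (see the methods vignette).
#'
#' @param counts spots x genes raw counts.
#' @param spe matching SPE matrix (or a [compute_spe()] result).
#' @param cluster_labels per-spot cluster ids (>= 2 clusters with >= 5
#'   spots each).
#' @param fdr BH threshold within each modality.
#' @param lfc_min optional `|log2FC|` gate (0 disables it).
#' @param pseudo pseudocount in the fold-change.
#' @return data.frame of class `sdg_report`, one row per gene x cluster,
#'   with per-test statistics and the gene-level `class`
#'   (`SVG`/`SDG`/`none`) plus logical columns `is_svg`, `is_spvg`,
#'   `is_sdg`.
#' @export
call_sdgs <- function(counts, spe, cluster_labels, fdr = 0.05, lfc_min = 0,
                      pseudo = 1) {
  if (inherits(spe, "spe_matrix")) spe <- spe$spe
  counts <- as.matrix(counts); spe <- as.matrix(spe)
  cl <- as.vector(cluster_labels)
  stopifnot(nrow(counts) == length(cl), all(dim(counts) == dim(spe)))
  tab <- table(cl)
  if (length(tab) < 2L || any(tab < 5L))
    stop("need >= 2 clusters with >= 5 spots each")
  testable <- colSums(counts) > 0
  genes <- colnames(counts)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(counts)))
  raw <- ranksum_test(counts[, testable, drop = FALSE], cl, pseudo)
  sp <- ranksum_test(spe[, testable, drop = FALSE], cl, pseudo)
  q_raw <- matrix(stats::p.adjust(raw$p, method = "BH"), nrow(raw$p))
  q_spe <- matrix(stats::p.adjust(sp$p, method = "BH"), nrow(sp$p))
  hit_raw <- q_raw < fdr & abs(raw$lfc) >= lfc_min
  hit_spe <- q_spe < fdr & abs(sp$lfc) >= lfc_min
  svg <- rowSums(hit_raw) > 0
  spvg <- rowSums(hit_spe) > 0
  sdg <- spvg & !svg
  cls_t <- ifelse(svg, "SVG", ifelse(sdg, "SDG", "none"))
  ks <- colnames(raw$p)
  out <- do.call(rbind, lapply(seq_along(ks), function(ci) {
    data.frame(gene = genes[testable], cluster = ks[ci],
               lfc_raw = raw$lfc[, ci], p_raw = raw$p[, ci],
               q_raw = q_raw[, ci],
               lfc_spe = sp$lfc[, ci], p_spe = sp$p[, ci],
               q_spe = q_spe[, ci],
               is_svg = svg, is_spvg = spvg, is_sdg = sdg,
               class = factor(cls_t, levels = c("SVG", "SPVG", "SDG", "none")),
               row.names = NULL)
  }))
  if (any(!testable)) {
    zero <- do.call(rbind, lapply(ks, function(k2) {
      data.frame(gene = genes[!testable], cluster = k2, lfc_raw = NA_real_,
                 p_raw = NA_real_, q_raw = NA_real_, lfc_spe = NA_real_,
                 p_spe = NA_real_, q_spe = NA_real_, is_svg = FALSE,
                 is_spvg = FALSE, is_sdg = FALSE,
                 class = factor("none", levels = c("SVG", "SPVG", "SDG", "none")),
                 row.names = NULL)
    }))
    out <- rbind(out, zero)
  }
  out <- out[order(match(out$gene, genes), out$cluster), ]
  rownames(out) <- NULL
  class(out) <- c("sdg_report", "data.frame")
  out
}

#' Gene-level classification from an SDG report
#' @param report a [call_sdgs()] result.
#' @return named factor, one entry per gene.
#' @export
sdg_gene_classes <- function(report) {
  first <- !duplicated(report$gene)
  stats::setNames(report$class[first], report$gene[first])
}
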