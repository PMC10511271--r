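# Independent brute-force oracles, written as naive loops straight from
# the printed definitions. They deliberately share no code with the
# package implementation.

naive_rho <- function(x, y, z, k, boxsize) {
  n <- length(x)
  inbox <- function(v) {
    h <- boxsize * sd(v) / 2
    lo <- max(0, v[k] - h); hi <- v[k] + h
    v >= lo & v <= hi
  }
  bx <- inbox(x); by <- inbox(y); bz <- inbox(z)
  nz <- 0; nxz <- 0; nyz <- 0; nxyz <- 0
  for (c in seq_len(n)) {
    if (bz[c]) {
      nz <- nz + 1
      if (bx[c]) nxz <- nxz + 1
      if (by[c]) nyz <- nyz + 1
      if (bx[c] && by[c]) nxyz <- nxyz + 1
    }
  }
  if (nz == 0) return(NA_real_)
  nxyz / nz - (nxz / nz) * (nyz / nz)
}

oracle_ds <- function(M) {
  n <- nrow(M)
  Et <- M / rowSums(M)
  cs <- colSums(Et)
  E <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    E[i, j] <- sum(Et[i, ] * Et[j, ] / cs)
  E
}

oracle_layer <- function(X, Earr, W, a, slope = 0.2) {
  n <- nrow(X); P <- dim(Earr)[3]
  H <- X %*% t(W)
  Fo <- ncol(H)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(a[1:Fo] * H[i, ]) + sum(a[Fo + 1:Fo] * H[j, ])
    s <- if (s > 0) s else slope * s
    f[i, j] <- exp(min(max(s, -30), 30))
  }
  outs <- vector("list", P)
  for (p in seq_len(P)) {
    alpha <- oracle_ds(f * Earr[, , p])
    outs[[p]] <- alpha %*% H
  }
  Xn <- do.call(cbind, outs)
  ifelse(Xn > 0, Xn, exp(pmin(Xn, 0)) - 1)     # ELU
}

random_graph_tensor <- function(n, P) {
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- sample(seq(i + 1, n), 1)
      A[i, j] <- A[j, i] <- 1
    }
    extra <- which(upper.tri(A) & A == 0)
    if (length(extra)) {
      on <- sample(extra, min(length(extra), sample(0:3, 1)))
      A[on] <- 1
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
    }
    if (all(rowSums(A) > 0)) break
  }
  E <- array(0, c(n, n, P))
  for (p in seq_len(P)) {
    M <- matrix(runif(n * n, 0.1, 2), n, n)
    M <- (M + t(M)) / 2
    E[, , p] <- M * A
  }
  E
}
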