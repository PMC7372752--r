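# Independent oracles used to cross-check the implementation.

# Alternating (row, then column) Sinkhorn scaling to a doubly stochastic
# matrix. For symmetric input with total support this converges to the
# unique symmetric balancing diag(x) C diag(x), so it is an independent
# check on the Knight-Ruiz route.
sinkhorn_balance <- function(C, iters = 5000, tol = 1e-12) {
  S <- C
  for (i in seq_len(iters)) {
    S <- S / rowSums(S)
    S <- t(t(S) / colSums(S))
    if (max(abs(rowSums(S) - 1)) < tol && max(abs(colSums(S) - 1)) < tol)
      break
  }
  S
}

# Mean cluster-level silhouette of a contiguous partition, computed from
# 2-D prefix sums (a different algorithm than the package's direct
# submatrix means).
prefix_silhouette <- function(d, cuts) {
  n <- nrow(d)
  P <- matrix(0, n + 1, n + 1)
  P[2:(n + 1), 2:(n + 1)] <- apply(apply(d, 2, cumsum), 1, cumsum)
  bs <- function(r1, r2, c1, c2)
    P[c2 + 1, r2 + 1] - P[c2 + 1, r1] - P[c1, r2 + 1] + P[c1, r1]
  dg <- cumsum(diag(d))
  edges <- c(1, cuts, n + 1)
  m <- length(edges) - 1
  s <- numeric(m)
  for (i in seq_len(m)) {
    r1 <- edges[i]; r2 <- edges[i + 1] - 1; len <- r2 - r1 + 1
    b <- Inf
    for (j in seq_len(m)[-i]) {
      c1 <- edges[j]; c2 <- edges[j + 1] - 1
      b <- min(b, bs(r1, r2, c1, c2) / (len * (c2 - c1 + 1)))
    }
    if (len < 2) { s[i] <- 0; next }
    dsum <- dg[r2] - if (r1 > 1) dg[r1 - 1] else 0
    a <- (bs(r1, r2, r1, r2) - dsum) / (len^2 - len)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force TAD caller: enumerate every subset of the candidate cut
# positions (not just the top-m prefixes the implementation scores) and
# keep the partition with maximal mean silhouette; then apply the
# minimum-width filter. Returns the TAD end bins.
oracle_tad_ends <- function(C, min_tad = 5, k = 2) {
  n <- nrow(C)
  m <- rowSums(C)
  L <- C / (sqrt(m) %o% sqrt(m))
  V <- eigen(L, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  Z <- V / sqrt(rowSums(V^2))
  D <- sqrt(rowSums((Z[-1, , drop = FALSE] - Z[-n, , drop = FALSE])^2))
  for (i in seq_len(n - 1))
    if (max(abs(L[i, ] - L[i + 1, ])) <= 1e-12 * max(abs(L)) * n) D[i] <- 0
  l <- floor(n / min_tad)
  cand <- sort(order(-D, seq_along(D))[seq_len(l)] + 1L)
  d <- 1 / (C + 1)
  best <- -Inf
  best_cuts <- NULL
  for (size in seq_len(l)) {
    combs <- utils::combn(cand, size)
    for (ci in seq_len(ncol(combs))) {
      cuts <- combs[, ci]
      sc <- prefix_silhouette(d, cuts)
      if (sc > best + 1e-12) {
        best <- sc
        best_cuts <- cuts
      }
    }
  }
  edges <- c(1, best_cuts, n + 1)
  starts <- edges[-length(edges)]
  ends <- edges[-1] - 1
  ends[(ends - starts + 1) >= min_tad]
}

# Fisher combination through the Gamma identity: -sum(log p) ~ Gamma(k, 1)
# under the null, an algebraically distinct route to the same tail.
gamma_fisher <- function(p)
  pgamma(sum(-log(p)), shape = length(p), lower.tail = FALSE)
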