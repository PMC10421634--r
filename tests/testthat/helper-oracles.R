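# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately use naive
# enumeration, not the package's code paths.

# k nearest neighbours of each row of `query` among rows of `ref`, by full
# pairwise distance enumeration.
brute_knn <- function(query, ref, k, skip_self = FALSE) {
  t(vapply(seq_len(nrow(query)), function(i) {
    d <- sqrt(colSums((t(ref) - query[i, ])^2))
    if (skip_self) d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}

# mutual nearest neighbour sets by enumeration.
brute_mnn <- function(x1, x2, K) {
  f <- brute_knn(x2, x1, K)          # x1-neighbours of each x2 sample
  b <- brute_knn(x1, x2, K)          # x2-neighbours of each x1 sample
  lapply(seq_len(nrow(x2)), function(i) {
    cand <- f[i, ]
    cand[vapply(cand, function(j) i %in% b[j, ], TRUE)]
  })
}

# transition counts by an explicit loop over run pairs.
brute_transition <- function(post, lag, levels) {
  k <- length(levels)
  M <- matrix(0, k, k, dimnames = list(levels, levels))
  for (t in seq_len(length(post) - lag)) {
    i <- match(post[t + lag], levels); j <- match(post[t], levels)
    M[i, j] <- M[i, j] + 1
  }
  cs <- colSums(M)
  for (j in which(cs > 0)) M[, j] <- M[, j] / cs[j]
  M
}

# directed Newman modularity by literal double loop over the formula.
brute_modularity <- function(A, memb) {
  m <- sum(A)
  kout <- rowSums(A); kin <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    if (memb[i] == memb[j]) q <- q + A[i, j] - kout[i] * kin[j] / m
  q / m
}

# leaves under each internal node and pairwise LCA sizes by tree traversal.
brute_dasgupta <- function(merge, W) {
  n <- nrow(W)
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  lca_size <- function(i, j) {
    for (m in seq_len(nrow(merge))) {
      lv <- leaves(m)
      if (i %in% lv && j %in% lv) return(length(lv))
    }
    n
  }
  Ws <- (W + t(W)) / 2; diag(Ws) <- 0
  cost <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (Ws[i, j] > 0)
      cost <- cost + Ws[i, j] * lca_size(i, j)
  1 - cost / (n * sum(Ws) / 2)
}

# plain mutual information and entropies of two labelings (natural log).
brute_mi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(n * nij / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}

# AMI with the expected MI obtained by exhaustive enumeration over all
# permutations of one labeling (feasible for n <= 7): the literal
# permutation-model expectation.
brute_ami <- function(a, b) {
  n <- length(a)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  emi <- mean(vapply(perms(seq_len(n)), function(p) brute_mi(a, b[p]), 0))
  h <- function(x) { p <- table(x) / n; -sum(p * log(p)) }
  mi <- brute_mi(a, b)
  denom <- (h(a) + h(b)) / 2 - emi
  if (abs(denom) < 1e-12) return(1)
  (mi - emi) / denom
}

# random similarity transform (proper rotation + translation + scale > 0)
random_similarity <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  R <- R * sign(diag(qr.R(qr_d)))[col(R)]  # unique Q with positive diag R
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 2), s = exp(rnorm(1, 0, 0.5)))
}

apply_similarity <- function(coords, g) {
  sweep(g$s * coords %*% t(g$R), 2, g$t, `+`)
}
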