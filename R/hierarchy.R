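# Hierarchical organization of the transition graph: Paris agglomerative
# clustering, directed Newman modularity, modularity-maximizing dendrogram
# cuts, Dasgupta scores and adjusted mutual information.

# Symmetrized weight matrix of a transition graph (Paris and Dasgupta are
# defined for undirected graphs); modularity evaluation stays directed.
sym_weights <- function(g) {
  A <- graph_weights(g)
  (A + t(A)) / 2
}

# Directed weight matrix A[from, to] from a transition_graph (or accept a
# plain matrix already in from->to orientation).
graph_weights <- function(g) {
  if (inherits(g, "transition_graph")) t(g$M) else as.matrix(g)
}

graph_node_names <- function(g) {
  if (inherits(g, "transition_graph")) as.character(g$postures)
  else rownames(graph_weights(g)) %||% as.character(seq_len(nrow(graph_weights(g))))
}

#' Paris hierarchical clustering of a transition graph
#'
#' Agglomerative clustering by the node-pair sampling distance
#' `d(a, b) = p(a) p(b) / p(a, b)`, where `p(a, b)` is the probability of
#' sampling the (symmetrized) edge a-b and `p(a)` the probability of
#' sampling node `a` proportionally to its strength. The closest pair is
#' merged repeatedly, summing weights and strengths; the merge distance is
#' the dendrogram height. The distance is reducible, so merge heights are
#' non-decreasing; the result is deterministic and parameter-free, and acts
#' as a multi-resolution counterpart of Louvain community detection.
#' Disconnected components are clustered separately and joined at the top
#' with a warning.
#'
#' @param g a `transition_graph` from [transition_matrix()], or a square
#'   weight matrix oriented from-to.
#' @return A list of class `behavioral_dendrogram`: `merge` (hclust-style),
#'   `height`, `labels`, plus the node count.
#' @export
paris_dendrogram <- function(g) {
  W <- sym_weights(g)
  labels <- graph_node_names(g)
  n <- nrow(W)
  if (n < 2) stopf("graph must have at least 2 nodes")
  if (sum(W) <= 0) stopf("graph has no weight")
  total <- sum(W)
  # active cluster bookkeeping; W aggregates as clusters merge
  strength <- rowSums(W)
  active <- rep(TRUE, n + (n - 1))
  id <- seq_len(n)                  # hclust ids: -leaf or +merge index
  Wx <- matrix(0, 2 * n - 1, 2 * n - 1)
  Wx[1:n, 1:n] <- W
  sx <- c(strength, rep(0, n - 1))
  hid <- c(seq_len(n) * -1L, rep(NA_integer_, n - 1))
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  disconnected <- FALSE
  for (m in seq_len(n - 1)) {
    cur <- which(alive)
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(cur)) for (jj in seq_len(ii - 1L)) {
      a <- cur[ii]; b <- cur[jj]
      w <- Wx[a, b]
      if (w <= 0) next
      d <- (sx[a] / total) * (sx[b] / total) / (w / total)
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    if (!is.finite(bestd)) {
      # disconnected: join the two components with the largest strengths
      disconnected <- TRUE
      best <- cur[order(-sx[cur])][1:2]
      bestd <- if (m > 1) max(height[seq_len(m - 1)]) * 1.1 else 1
    }
    a <- best[1]; b <- best[2]
    new <- n + m
    merge[m, ] <- sort(c(hid[a], hid[b]))
    height[m] <- bestd
    Wx[new, ] <- Wx[a, ] + Wx[b, ]
    Wx[, new] <- Wx[, a] + Wx[, b]
    Wx[new, new] <- Wx[a, a] + Wx[b, b] + 2 * Wx[a, b]
    sx[new] <- sx[a] + sx[b]
    alive[c(a, b)] <- FALSE; alive[new] <- TRUE
    hid[new] <- m
  }
  if (disconnected) warnf("graph is disconnected; components joined at top height")
  structure(list(merge = merge, height = height,
                 height_monotone = cummax(height),
                 labels = labels, n = n),
            class = "behavioral_dendrogram")
}

#' @export
print.behavioral_dendrogram <- function(x, ...) {
  cat(sprintf("<behavioral_dendrogram: %d leaves, heights %.3g..%.3g>\n",
              x$n, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a behavioral dendrogram to hclust / Newick
#'
#' @param x a `behavioral_dendrogram`.
#' @param ... unused.
#' @return An `hclust` object (monotone heights).
#' @export
as.hclust.behavioral_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height_monotone,
                 order = dendrogram_order(x$merge, x$n),
                 labels = x$labels, method = "paris"),
            class = "hclust")
}

dendrogram_order <- function(merge, n) {
  walk <- function(i) {
    if (i < 0) return(-i)
    c(walk(merge[i, 1]), walk(merge[i, 2]))
  }
  walk(nrow(merge))
}

#' Write a behavioral dendrogram as a Newick tree
#'
#' Branch lengths encode merge heights.
#'
#' @param dend a `behavioral_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ph <- ape::as.phylo(as.hclust.behavioral_dendrogram(dend))
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Directed weighted Newman modularity of a partition
#'
#' `Q = (1/m) * sum_ij (A_ij - kout_i * kin_j / m) * delta(c_i, c_j)` with
#' `A` the directed weight matrix and `m` its total weight. The trivial
#' one-module partition scores exactly 0. Symmetric evaluation is available
#' as a sensitivity switch.
#'
#' @param g a `transition_graph` or from-to weight matrix.
#' @param membership integer/character module per node (named or in node
#'   order).
#' @param directed evaluate on the directed matrix (default) or its
#'   symmetrization.
#' @return Modularity Q.
#' @export
modularity_score <- function(g, membership, directed = TRUE) {
  A <- if (directed) graph_weights(g) else sym_weights(g)
  n <- nrow(A)
  if (length(membership) != n) stopf("partition does not cover the graph nodes")
  m <- sum(A)
  if (m <= 0) stopf("empty graph")
  kout <- rowSums(A); kin <- colSums(A)
  q <- 0
  for (cl in unique(membership)) {
    idx <- which(membership == cl)
    q <- q + sum(A[idx, idx]) - sum(kout[idx]) * sum(kin[idx]) / m
  }
  q / m
}

#' Cut a behavioral dendrogram at the modularity-maximizing height
#'
#' Evaluates the directed modularity of the partition induced by cutting
#' the dendrogram at each height in `heights` (51 values equally spaced
#' over 0.4-1.4 by default) and returns the maximizing partition. Merge
#' heights inside the evaluated window are also evaluated so no attainable
#' partition between grid points is skipped. If the dendrogram's height
#' span lies outside the window, the window is extended with a warning.
#' Ties prefer the coarser (fewer-modules) partition.
#'
#' @param dend a `behavioral_dendrogram`.
#' @param g the `transition_graph` the dendrogram was built from.
#' @param heights numeric vector of candidate cut heights.
#' @param auto_extend extend the height window to the dendrogram's span
#'   when they do not overlap (default TRUE).
#' @return A list of class `module_assignment`: `membership` (named module
#'   id per posture), `cut_height`, `Q`, `n_modules`, and `curve` (tibble
#'   of height, Q, n_modules).
#' @export
best_cut <- function(dend, g, heights = seq(0.4, 1.4, length.out = 51),
                     auto_extend = TRUE) {
  hm <- dend$height_monotone
  if (auto_extend && (min(hm) > max(heights) || max(hm) < min(heights))) {
    warnf("dendrogram heights [%.3g, %.3g] outside cut window; extending",
          min(hm), max(hm))
    heights <- seq(min(hm) * 0.99, max(hm) * 1.01, length.out = length(heights))
  }
  hs <- sort(unique(c(heights, hm[hm >= min(heights) & hm <= max(heights)] + 1e-12)))
  # the partition only changes at merge heights: evaluate Q once per
  # distinct number of applied merges, then map back onto the height grid
  parts <- partitions_by_merge(dend)
  n_applied <- findInterval(hs, hm)
  uniq <- sort(unique(n_applied))
  qs <- vapply(uniq, function(m) modularity_score(g, parts[[m + 1]]), 0)
  ks <- vapply(uniq, function(m) length(unique(parts[[m + 1]])), 0L)
  pos <- match(n_applied, uniq)
  curve <- tibble::tibble(height = hs, Q = qs[pos], n_modules = ks[pos])
  if (all(curve$n_modules == 1))
    warnf("all cuts yield a single module; returning the trivial partition")
  best <- curve[order(-curve$Q, curve$n_modules, -curve$height), ][1, ]
  memb <- parts[[findInterval(best$height, hm) + 1]]
  structure(list(membership = setNames(memb, dend$labels),
                 cut_height = best$height, Q = best$Q,
                 n_modules = best$n_modules, curve = curve),
            class = "module_assignment")
}

# Leaf partitions after 0, 1, ..., n-1 merges (list of n membership vectors).
partitions_by_merge <- function(dend) {
  n <- dend$n
  parent <- seq_len(2 * n - 1)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  out <- vector("list", n)
  out[[1]] <- seq_len(n)
  for (m in seq_len(n - 1)) {
    for (child in dend$merge[m, ]) {
      ci <- if (child < 0) -child else n + child
      parent[find(ci)] <- find(n + m)
    }
    roots <- vapply(seq_len(n), find, 0L)
    out[[m + 1]] <- match(roots, unique(roots))
  }
  out
}

#' Cut a behavioral dendrogram at a height
#'
#' Returns the partition obtained by applying every merge whose (monotone)
#' height is at most `h`.
#'
#' @param dend a `behavioral_dendrogram`.
#' @param h cut height.
#' @return Named integer module ids per leaf.
#' @export
cut_dendrogram <- function(dend, h) {
  m <- findInterval(h, dend$height_monotone)
  setNames(partitions_by_merge(dend)[[m + 1]], dend$labels)
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment: %d modules, Q = %.4f at height %.3g>\n",
              x$n_modules, x$Q, x$cut_height))
  invisible(x)
}

#' Dasgupta score of a dendrogram on its graph
#'
#' The Dasgupta cost of a tree on a weighted graph is
#' `sum_edges w_ij * |leaves(lca(i, j))|`; lower is better. The score
#' reported here is `1 - cost / (n * total_weight)`, i.e. one minus the
#' cost relative to the worst case in which every edge is separated only at
#' the root. Computed on the symmetrized weights.
#'
#' @param dend a `behavioral_dendrogram`.
#' @param g the `transition_graph` (or weight matrix) it was built on.
#' @return Score in \[0, 1\]; higher means the tree separates weak edges
#'   high and strong edges low.
#' @export
dasgupta_score <- function(dend, g) {
  W <- sym_weights(g)
  diag(W) <- 0
  n <- dend$n
  if (n < 2) stopf("tree must have at least 2 leaves")
  members <- c(as.list(seq_len(n)), vector("list", n - 1))
  cost <- 0
  for (m in seq_len(n - 1)) {
    ch <- dend$merge[m, ]
    A <- if (ch[1] < 0) members[[-ch[1]]] else members[[n + ch[1]]]
    B <- if (ch[2] < 0) members[[-ch[2]]] else members[[n + ch[2]]]
    cross <- sum(W[A, B])
    cost <- cost + cross * (length(A) + length(B))
    members[[n + m]] <- c(A, B)
  }
  totw <- sum(W) / 2
  if (totw <= 0) stopf("graph has no off-diagonal weight")
  1 - cost / (n * totw)
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement between module assignments:
#' `AMI = (MI - E[MI]) / (mean(H1, H2) - E[MI])`, with the expected mutual
#' information under the permutation (hypergeometric) model. Identical
#' partitions (up to label names) score 1; independent partitions score ~0.
#' Named vectors are matched on their shared name universe; unnamed vectors
#' are matched by position.
#'
#' @param p1,p2 module assignments: named vectors, `module_assignment`
#'   objects, or plain vectors of equal length.
#' @return The AMI value (<= 1).
#' @export
ami <- function(p1, p2) {
  v1 <- if (inherits(p1, "module_assignment")) p1$membership else p1
  v2 <- if (inherits(p2, "module_assignment")) p2$membership else p2
  if (!is.null(names(v1)) && !is.null(names(v2))) {
    shared <- intersect(names(v1), names(v2))
    if (!length(shared)) stopf("partitions share no items")
    v1 <- v1[shared]; v2 <- v2[shared]
  }
  if (length(v1) != length(v2)) stopf("partitions must cover the same items")
  n <- length(v1)
  tab <- table(v1, v2)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  h1 <- -sum(a / n * log(a / n)); h2 <- -sum(b / n * log(b / n))
  if (h1 < 1e-12 && h2 < 1e-12) return(1)  # both single-cluster
  emi <- expected_mi(a, b, n)
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < 1e-12) return(1)
  unname((mi - emi) / denom)
}

# Expected mutual information under the permutation model (hypergeometric
# cell counts given fixed margins).
expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    lo <- max(1, a[i] + b[j] - n)
    hi <- min(a[i], b[j])
    if (hi < lo) next
    nij <- lo:hi
    logp <- lchoose(b[j], nij) + lchoose(n - b[j], a[i] - nij) - lchoose(n, a[i])
    term <- nij / n * log(n * nij / (a[i] * b[j]))
    emi <- emi + sum(exp(logp) * term)
  }
  emi
}
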