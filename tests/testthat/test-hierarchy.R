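two_cliques <- function(eps = 0.01) {
  A <- matrix(eps / 100, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  A[3, 4] <- A[4, 3] <- eps
  diag(A) <- 0
  A
}

test_that("Paris merges cliques before joining them", {
  d <- paris_dendrogram(two_cliques())
  # the first four merges involve only within-clique pairs
  members <- lapply(1:5, function(m) {
    walk <- function(i) if (i < 0) -i else
      c(walk(d$merge[i, 1]), walk(d$merge[i, 2]))
    walk(m)
  })
  for (m in 1:4)
    expect_true(all(members[[m]] <= 3) || all(members[[m]] >= 4))
  expect_setequal(members[[5]], 1:6)
  expect_true(all(diff(d$height_monotone) >= 0))
})

test_that("Paris handles 2-node graphs and is permutation invariant", {
  d2 <- paris_dendrogram(matrix(c(0, 1, 1, 0), 2))
  expect_equal(nrow(d2$merge), 1)
  A <- two_cliques()
  perm <- c(4, 1, 6, 2, 3, 5)
  Ap <- A[perm, perm]
  rownames(Ap) <- colnames(Ap) <- as.character(perm)
  d <- paris_dendrogram(A)
  dp <- paris_dendrogram(Ap)
  expect_equal(sort(d$height), sort(dp$height), tolerance = 1e-12)
  # same partition at the 2-cluster level after un-permuting labels
  c1 <- cut_dendrogram(d, sort(d$height_monotone, decreasing = TRUE)[2])
  names(c1) <- as.character(1:6)
  c2 <- cut_dendrogram(dp, sort(dp$height_monotone, decreasing = TRUE)[2])
  expect_equal(ami(c1, c2), 1)
})

test_that("directed modularity matches hand-expanded and brute-force values", {
  # two equal-weight, fully disconnected 2-node communities: Q = 0.5
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(modularity_score(A, c(1, 1, 2, 2)), 0.5, tolerance = 1e-15)
  expect_equal(modularity_score(A, rep(1, 4)), 0, tolerance = 1e-15)
  # random graphs and partitions against the literal double loop
  set.seed(1)
  for (rep_i in 1:20) {
    n <- sample(3:6, 1)
    B <- matrix(runif(n * n), n, n) * matrix(rbinom(n * n, 1, 0.6), n)
    diag(B) <- 0
    if (sum(B) == 0) B[1, 2] <- 1
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_score(B, memb), brute_modularity(B, memb),
                 tolerance = 1e-12)
  }
  # mean Q over uniformly random 2-color partitions: nodes keep their own
  # community with probability 1, so E[Q] = (1 - p_same) / m *
  # sum_i (A_ii - kout_i * kin_i / m), not zero
  B <- two_cliques()
  m <- sum(B); kout <- rowSums(B); kin <- colSums(B)
  expected <- (1 - 0.5) / m * sum(diag(B) - kout * kin / m)
  set.seed(2)
  qs <- replicate(1000, modularity_score(B, sample(2, 6, replace = TRUE)))
  expect_lt(abs(mean(qs) - expected), 3 * sd(qs) / sqrt(1000) + 1e-3)
})

test_that("best_cut finds planted modules and reports a sane curve", {
  rep <- behavior_repertoire(n_postures = 12, n_modules = 4, seed = 3)
  lab <- generate_markov_labels(rep, 80000, seed = 4)
  g <- transition_matrix(compress_runs(lab$labels), lag = 1)
  bc <- best_cut(paris_dendrogram(g), g)
  expect_equal(bc$n_modules, 4)
  expect_gte(ami(unname(bc$membership), rep$module_of), 0.9)
  expect_true(all(bc$curve$Q <= bc$Q + 1e-12))
  expect_gte(bc$Q, 0)
  # two disconnected cliques: best cut equals the best of all 2^6 partitions
  A <- two_cliques(eps = 0)
  expect_warning(d <- paris_dendrogram(A), "disconnected")
  bc2 <- suppressWarnings(best_cut(d, A))
  brute_best <- -Inf
  for (code in 0:(2^6 - 1)) {
    memb <- as.integer(intToBits(code))[1:6]
    brute_best <- max(brute_best, brute_modularity(A, memb))
  }
  expect_equal(bc2$Q, brute_best, tolerance = 1e-12)
  expect_equal(unname(bc2$membership), c(1, 1, 1, 2, 2, 2))
})

test_that("a structureless complete graph yields ~zero modularity at best cut", {
  A <- matrix(1, 5, 5); diag(A) <- 0
  bc <- suppressWarnings(best_cut(paris_dendrogram(A), A))
  expect_lt(abs(bc$Q), 0.05)
})

test_that("Dasgupta score matches the brute-force LCA oracle", {
  set.seed(5)
  for (rep_i in 1:10) {
    n <- sample(4:8, 1)
    A <- matrix(runif(n * n) * rbinom(n * n, 1, 0.7), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    A[1, 2] <- A[2, 1] <- 1  # guarantee weight
    d <- suppressWarnings(paris_dendrogram(A))
    expect_equal(dasgupta_score(d, A), brute_dasgupta(d$merge, A),
                 tolerance = 1e-12)
  }
  # star graph explicitly
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1
  ds <- paris_dendrogram(S)
  expect_equal(dasgupta_score(ds, S), brute_dasgupta(ds$merge, S),
               tolerance = 1e-12)
  # invariance under node relabeling
  A <- two_cliques()
  perm <- c(2, 5, 1, 6, 3, 4)
  Ap <- A[perm, perm]
  expect_equal(dasgupta_score(paris_dendrogram(A), A),
               dasgupta_score(paris_dendrogram(Ap), Ap), tolerance = 1e-12)
})

test_that("a generating tree scores higher than random trees on its graph", {
  rep <- behavior_repertoire(n_postures = 8, n_modules = 2, seed = 6)
  lab <- generate_markov_labels(rep, 50000, seed = 7)
  g <- transition_matrix(compress_runs(lab$labels), lag = 1)
  d <- paris_dendrogram(g)
  obs <- dasgupta_score(d, g)
  set.seed(8)
  rand_scores <- replicate(100, {
    merge <- matrix(0L, 7, 2); ids <- -(1:8)
    for (m in 1:7) {
      pick <- sample(length(ids), 2)
      merge[m, ] <- sort(ids[pick]); ids <- c(ids[-pick], m)
    }
    dd <- structure(list(merge = merge, height = 1:7, height_monotone = 1:7,
                         labels = as.character(g$postures), n = 8),
                    class = "behavioral_dendrogram")
    dasgupta_score(dd, g)
  })
  expect_gt(obs, mean(rand_scores))
})

test_that("AMI agrees with the exhaustive permutation-model oracle", {
  set.seed(9)
  for (rep_i in 1:8) {
    n <- sample(5:7, 1)
    a <- sample(2, n, replace = TRUE)
    b <- sample(3, n, replace = TRUE)
    expect_equal(ami(a, b), brute_ami(a, b), tolerance = 1e-10)
  }
})

test_that("AMI has the standard identities", {
  p <- c(a = 1, b = 1, c = 2, d = 2, e = 3)
  expect_equal(ami(p, p), 1)
  relab <- setNames(c(7, 7, 5, 5, 9), names(p))  # renamed modules
  expect_equal(ami(p, relab), 1)
  q <- setNames(c(2, 1, 2, 1, 3), names(p))
  expect_equal(ami(p, q), ami(q, p), tolerance = 1e-12)
  expect_lte(ami(p, q), 1)
  # independent partitions: mean AMI ~ 0
  set.seed(10)
  vals <- replicate(100, ami(sample(5, 200, replace = TRUE),
                             sample(5, 200, replace = TRUE)))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(100) + 0.01)
  # single-cluster vs single-cluster over identical universes
  expect_equal(ami(rep(1, 4), rep(2, 4)), 1)
})

test_that("two-level hierarchies are recovered at low and high cuts", {
  rep <- behavior_repertoire(n_postures = 12, n_modules = 4,
                             n_super_modules = 2, seed = 11)
  lab <- generate_markov_labels(rep, 80000, seed = 12)
  g <- transition_matrix(compress_runs(lab$labels), lag = 1)
  d <- paris_dendrogram(g)
  low <- best_cut(d, g)
  expect_gte(ami(unname(low$membership), rep$module_of), 0.8)
  high <- cut_dendrogram(d, sort(d$height_monotone, decreasing = TRUE)[2])
  expect_gte(ami(unname(high), rep$super_module_of[rep$module_of]), 0.8)
})

test_that("dendrograms export to hclust and Newick", {
  d <- paris_dendrogram(two_cliques())
  hc <- as.hclust(d)
  expect_s3_class(hc, "hclust")
  expect_equal(sort(hc$order), 1:6)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(d, path)
  tr <- ape::read.tree(path)
  expect_equal(sort(tr$tip.label), as.character(1:6))
})
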