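make_blobs <- function(n_per = 300, k = 3, d = 8, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  list(x = do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE))),
    y = rep(seq_len(k), each = n_per))
}

silhouette_mean <- function(emb, y) {
  D <- as.matrix(dist(emb))
  s <- vapply(seq_along(y), function(i) {
    a <- mean(D[i, y == y[i] & seq_along(y) != i])
    b <- min(vapply(setdiff(unique(y), y[i]), function(cl)
      mean(D[i, y == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

test_that("well-separated blobs stay separated in the embedding", {
  bl <- make_blobs()
  emb <- umap_embed(bl$x, seed = 1)
  expect_equal(dim(emb), c(900, 2))
  expect_gt(silhouette_mean(emb, bl$y), 0.5)
})

test_that("the embedding is deterministic given a seed and continuous for duplicates", {
  bl <- make_blobs(n_per = 150)
  e1 <- umap_embed(bl$x, seed = 5)
  e2 <- umap_embed(bl$x, seed = 5)
  expect_identical(e1, e2)
  # duplicated rows land at near-identical positions
  xdup <- rbind(bl$x, bl$x[1:5, ])
  e3 <- umap_embed(xdup, seed = 5)
  span <- max(apply(e3, 2, function(c) diff(range(c))))
  for (i in 1:5)
    expect_lt(sqrt(sum((e3[450 + i, ] - e3[i, ])^2)), 1e-3 * span * 10)
})

test_that("feature distances correlate positively with embedded distances", {
  bl <- make_blobs(n_per = 250)
  emb <- umap_embed(bl$x, seed = 2)
  set.seed(3)
  i <- sample(nrow(bl$x), 1000, replace = TRUE)
  j <- sample(nrow(bl$x), 1000, replace = TRUE)
  keep <- i != j
  df <- sqrt(rowSums((bl$x[i[keep], ] - bl$x[j[keep], ])^2))
  de <- sqrt(rowSums((emb[i[keep], ] - emb[j[keep], ])^2))
  expect_gt(cor(df, de), 0.3)
})

test_that("umap_embed rejects too-small inputs", {
  expect_error(umap_embed(matrix(rnorm(30), 10, 3), n_neighbors = 20),
               "at least")
})

test_that("the density grid is a proper, well-shaped density", {
  set.seed(4)
  pts <- cbind(rnorm(500, 3, 0.4), rnorm(500, -1, 0.4))
  d <- density_map(pts, grid_n = 200)
  expect_equal(dim(d$z), c(200, 200))
  expect_true(all(d$z >= 0))
  expect_equal(sum(d$z) * d$cell_area, 1, tolerance = 1e-6)
  # argmax within one cell of the centroid
  am <- which(d$z == max(d$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(d$x[am[1]] - 3), 3 * diff(d$x[1:2]))
  expect_lt(abs(d$y[am[2]] + 1), 3 * diff(d$y[1:2]))
  # two equal clusters: two near-equal local maxima
  pts2 <- rbind(cbind(rnorm(400, -4, 0.3), rnorm(400, 0, 0.3)),
                cbind(rnorm(400, 4, 0.3), rnorm(400, 0, 0.3)))
  d2 <- density_map(pts2)
  left <- max(d2$z[d2$x < 0, ]); right <- max(d2$z[d2$x > 0, ])
  expect_lt(abs(left - right) / max(left, right), 0.10)
  expect_error(density_map(matrix(1, 5, 2)), "degenerate")
})

test_that("watershed recovers cluster structure and labels every point", {
  set.seed(5)
  pts <- rbind(cbind(rnorm(600, -4, 0.3), rnorm(600, 0, 0.3)),
               cbind(rnorm(600, 4, 0.3), rnorm(600, 0, 0.3)))
  truth <- rep(1:2, each = 600)
  pm <- watershed_postures(density_map(pts), pts)
  expect_equal(pm$n_postures, 2)
  expect_gt(max(mean((pm$labels == truth)), mean((3 - pm$labels) == truth)), 0.99)
  expect_true(all(!is.na(pm$labels)))
  # one cluster: one posture
  pm1 <- watershed_postures(density_map(pts[1:600, ]), pts[1:600, ])
  expect_equal(pm1$n_postures, 1)
})

test_that("basin assignment is equivariant to rescaling the embedding", {
  set.seed(6)
  pts <- rbind(cbind(rnorm(300, -3, 0.4), rnorm(300, 1, 0.4)),
               cbind(rnorm(300, 3, 0.4), rnorm(300, -1, 0.4)))
  a <- watershed_postures(density_map(pts), pts)
  b <- watershed_postures(density_map(pts * 7), pts * 7)
  expect_equal(ami(a$labels, b$labels), 1)
})

test_that("posture recovery improves with template separability", {
  # shrink the template jitter towards the rendering noise floor so the
  # planted inter-template distances actually vary across levels; speeds
  # are held equal so separability comes from the angles alone
  amis <- counts <- numeric(0)
  for (f in c(0.08, 0.3, 1)) {
    rep <- behavior_repertoire(n_postures = 6, n_modules = 2,
                               template_sd = 0.05 * f, module_sd = 0.08 * f,
                               min_separation = 0.01,
                               speed_range = c(0.15, 0.15), seed = 31)
    lab <- generate_markov_labels(rep, 4000, seed = 32)
    pose <- render_poses(lab, rep, seed = 33)
    pp <- preprocess_session(pose)
    fm <- normalize_features(compute_features(pp$normalized, pp$raw))
    emb <- umap_embed(pca_reduce(fm), seed = 34)
    pm <- watershed_postures(density_map(emb), emb)
    amis <- c(amis, ami(pm$labels, lab$ground_truth$posture[fm$frame]))
    counts <- c(counts, pm$n_postures)
  }
  expect_true(all(diff(amis) > -0.05))   # non-decreasing trend up to noise
  expect_gt(amis[3] - amis[1], 0.1)
  expect_lt(abs(counts[3] - 6), 3)
})
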