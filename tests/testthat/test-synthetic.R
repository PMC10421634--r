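rep_small <- behavior_repertoire(n_postures = 6, n_modules = 2,
                                 dwell_mean_frames = 10, seed = 42)

test_that("generators are pure functions of parameters and seed", {
  a <- generate_markov_labels(rep_small, 2000, seed = 7)
  b <- generate_markov_labels(rep_small, 2000, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, generate_markov_labels(rep_small, 2000, seed = 8)$labels))
  p1 <- render_poses(a, rep_small, noise_sd = 0.01, seed = 3)
  p2 <- render_poses(a, rep_small, noise_sd = 0.01, seed = 3)
  expect_identical(p1$coords, p2$coords)
})

test_that("within_module_prob = 1 makes the module absorbing", {
  r <- behavior_repertoire(n_postures = 6, n_modules = 2,
                           within_module_prob = 1, seed = 1)
  lab <- generate_markov_labels(r, 5000, seed = 2)
  expect_length(unique(lab$ground_truth$module), 1)
})

test_that("between-run transition frequencies match the planted matrix", {
  # symmetric two-posture chain: every transition must alternate
  r2 <- behavior_repertoire(n_postures = 2, n_modules = 1,
                            dwell_mean_frames = 5, seed = 3)
  expect_equal(unname(r2$transition), matrix(c(0, 1, 1, 0), 2))
  lab <- generate_markov_labels(r2, 100000, seed = 4)
  post <- lab$runs$posture
  expect_true(all(post[-1] != post[-length(post)]))

  # six postures in two modules: empirical frequencies within 3 binomial SE
  lab6 <- generate_markov_labels(rep_small, 100000, seed = 5)
  post6 <- lab6$runs$posture
  P <- rep_small$transition
  for (j in 1:6) {
    from_j <- which(post6[-length(post6)] == j)
    n_j <- length(from_j)
    emp <- tabulate(post6[from_j + 1], 6) / n_j
    se <- sqrt(P[, j] * (1 - P[, j]) / n_j)
    # 4 SE bound: 36 cells are tested jointly, so 3 SE per cell would give
    # a non-trivial family-wise false alarm rate
    expect_true(all(abs(emp - P[, j]) <= 4 * se + 1e-12),
                info = sprintf("source posture %d", j))
  }
})

test_that("run-length mean tracks dwell_mean_frames within 5%", {
  lab <- generate_markov_labels(rep_small, 100000, seed = 6)
  expect_lt(abs(mean(lab$runs$length) - 10) / 10, 0.05)
})

test_that("planted matrix with strong modules has positive directed modularity", {
  for (w in c(0.9, 0.95)) {
    r <- behavior_repertoire(n_postures = 12, n_modules = 4,
                             within_module_prob = w, seed = 8)
    q <- modularity_score(t(r$transition), r$module_of)
    expect_gt(q, 0)
    expect_equal(modularity_score(t(r$transition), rep(1, 12)), 0)
  }
})

test_that("rendering realizes template angles and is stationary without noise", {
  r <- behavior_repertoire(n_postures = 3, n_modules = 1, speed_range = c(0, 0),
                           seed = 9)
  lab <- rep(2L, 50)
  pose <- render_poses(lab, r, noise_sd = 0, seed = 1)
  # constant label, zero speed: frames identical (no transient: single run)
  for (t in 2:50) expect_equal(pose$coords[t, , ], pose$coords[1, , ])
  # recomputed vertex angles match the template to 1e-6 rad
  ang <- ethokit:::vertex_angles(pose$coords[10, , ],
                                 r$skeleton$angle_triplets)
  expect_equal(ang, r$templates[[2]]$angles, tolerance = 1e-6)
})

test_that("subject_scale scales rendered spine length proportionally", {
  r <- behavior_repertoire(n_postures = 4, n_modules = 2, seed = 10)
  lab <- generate_markov_labels(r, 3000, seed = 11)
  p1 <- render_poses(lab, r, noise_sd = 0, seed = 1, subject_scale = 1.0)
  p2 <- render_poses(lab, r, noise_sd = 0, seed = 1, subject_scale = 1.2)
  sk <- r$skeleton
  spine <- function(p) mean(sqrt(rowSums(
    (p$coords[, sk$spine_pair[1], ] - p$coords[, sk$spine_pair[2], ])^2)))
  expect_equal(spine(p2) / spine(p1), 1.2, tolerance = 0.01)
})

test_that("corrupt_session is identity without corruption and plants defects", {
  r <- rep_small
  lab <- generate_markov_labels(r, 500, seed = 12)
  pose <- render_poses(lab, r, seed = 13)
  same <- corrupt_session(pose)
  expect_identical(same$coords, pose$coords)
  cc <- corrupt_session(pose, dropout_runs = list(c(100, 5)),
                        outlier_frames = list(collapse = 200))
  expect_equal(sum(!cc$valid), 5)
  expect_true(all(!cc$valid[100:104]))
  fr <- cc$coords[200, , ]
  expect_equal(mean(ethokit:::bone_lengths(fr, r$skeleton$edges)), 0)
  expect_error(corrupt_session(pose, dropout_runs = list(c(499, 5))),
               "out of bounds")
})
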