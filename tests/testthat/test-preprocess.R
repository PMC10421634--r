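sk <- macaque_skeleton()

base_seq <- function(n = 60) {
  coords <- array(NA_real_, c(n, 15, 3))
  for (t in seq_len(n))
    coords[t, , ] <- sweep(sk$reference_pose, 2, c(1 + 0.005 * t, 1.2, 0.5), `+`)
  pose_sequence(coords)
}

test_that("QC invalidates out-of-cage and collapsed frames and nothing else", {
  seq <- base_seq(30)
  seq$coords[5, 7, 3] <- 3.0                     # wrist above a 2.75 m cage
  ctr <- colMeans(seq$coords[9, , ])
  seq$coords[9, , ] <- matrix(ctr, 15, 3, byrow = TRUE)  # collapsed
  out <- qc_filter(seq)
  expect_false(out$valid[5])
  expect_false(out$valid[9])
  expect_equal(sum(!out$valid), 2)
  expect_equal(attr(out, "qc")$out_of_cage, 1)
  expect_equal(attr(out, "qc")$collapsed, 1)
  clean <- qc_filter(base_seq(30))
  expect_equal(attr(clean, "qc")$n_removed, 0)
})

test_that("QC is monotone in its thresholds", {
  rep <- behavior_repertoire(n_postures = 4, n_modules = 2, seed = 1)
  lab <- generate_markov_labels(rep, 400, seed = 2)
  pose <- render_poses(lab, rep, noise_sd = 0.03, seed = 3)
  n_bad <- function(bounds, lim) sum(!qc_filter(pose, bounds, lim)$valid)
  full <- default_cage_bounds()
  small <- list(x = c(0.5, 2.0), y = c(0.5, 2.0), z = c(0, 2.75))
  expect_gte(n_bad(small, 0.10), n_bad(full, 0.10))
  expect_gte(n_bad(full, 0.20), n_bad(full, 0.10))
})

test_that("gaps of at most 10 frames are filled, longer ones are not", {
  seq <- base_seq(60)
  seq$valid[20:29] <- FALSE   # 10 frames
  seq$valid[40:50] <- FALSE   # 11 frames
  out <- interpolate_gaps(seq)
  expect_true(all(out$valid[20:29]))
  expect_true(all(!out$valid[40:50]))
})

test_that("interpolation is exact on linear trajectories and local elsewhere", {
  seq <- base_seq(60)   # linear drift in x
  orig <- seq$coords
  seq$coords[25:28, , ] <- NA
  seq$valid[25:28] <- FALSE
  out <- interpolate_gaps(seq)
  expect_equal(out$coords[25:28, , ], orig[25:28, , ], tolerance = 1e-9)
  untouched <- setdiff(seq_len(60), 25:28)
  expect_identical(out$coords[untouched, , ], orig[untouched, , ])
  # no gaps: identity
  seq2 <- base_seq(20)
  expect_identical(interpolate_gaps(seq2)$coords, seq2$coords)
  # boundary gap never filled
  seq3 <- base_seq(20)
  seq3$valid[1:3] <- FALSE
  expect_true(all(!interpolate_gaps(seq3)$valid[1:3]))
})

test_that("normalization pins neck, spine length and facing direction", {
  seq <- base_seq(10)
  norm <- normalize_pose(seq, sk)
  for (t in 1:10) {
    expect_equal(norm$coords[t, sk$spine_pair[1], ], c(0, 0, 0))
    spine <- norm$coords[t, sk$spine_pair[2], ] - norm$coords[t, sk$spine_pair[1], ]
    expect_equal(sqrt(sum(spine^2)), 1, tolerance = 1e-9)
    expect_equal(spine, c(0, 0, -1), tolerance = 1e-9)
    sh <- norm$coords[t, sk$shoulder_pair[1], ] - norm$coords[t, sk$shoulder_pair[2], ]
    expect_gt(sh[1], 0)      # shoulder axis in the +X half plane
    expect_equal(sh[2], 0, tolerance = 1e-9)
  }
})

test_that("normalization is invariant under 100 random similarity transforms", {
  set.seed(99)
  coords <- array(0, c(1, 15, 3))
  coords[1, , ] <- sk$reference_pose
  ref <- normalize_pose(pose_sequence(coords), sk)$coords[1, , ]
  worst <- 0
  for (i in 1:100) {
    g <- random_similarity()
    moved <- array(0, c(1, 15, 3))
    moved[1, , ] <- apply_similarity(sk$reference_pose, g)
    got <- normalize_pose(pose_sequence(moved), sk)$coords[1, , ]
    worst <- max(worst, max(abs(got - ref)))
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate frames are invalidated, not propagated", {
  seq <- base_seq(5)
  seq$coords[3, sk$spine_pair[2], ] <- seq$coords[3, sk$spine_pair[1], ]  # zero spine
  # shoulders parallel to spine
  neck <- seq$coords[4, sk$spine_pair[1], ]
  hip <- seq$coords[4, sk$spine_pair[2], ]
  u <- (hip - neck)
  seq$coords[4, sk$shoulder_pair[1], ] <- neck + u
  seq$coords[4, sk$shoulder_pair[2], ] <- neck - u
  norm <- normalize_pose(seq, sk)
  expect_false(norm$valid[3])
  expect_false(norm$valid[4])
  expect_equal(attr(norm, "degenerate"), 2L)
  expect_true(all(norm$valid[c(1, 2, 5)]))
})
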