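#' Generate a posture label sequence from a repertoire's Markov model
#'
#' Draws maximal runs whose lengths are geometric with mean
#' `dwell_mean_frames` and whose between-run transitions follow the
#' repertoire's planted column-stochastic matrix. Deterministic given `seed`.
#'
#' @param repertoire a [behavior_repertoire()].
#' @param n_frames number of frames to generate (>= 1).
#' @param seed integer seed.
#' @return A list of class `planted_labels`:
#'   `labels` (integer posture per frame), `ground_truth` (tibble with
#'   `frame`, `posture`, `module` and, for two-level repertoires,
#'   `super_module`), and `runs` (tibble of run posture/start/length).
#' @export
generate_markov_labels <- function(repertoire, n_frames, seed = 1) {
  stopifnot(inherits(repertoire, "behavior_repertoire"), is_count(n_frames))
  P <- repertoire$transition
  csum <- colSums(P)
  bad <- which(abs(csum - 1) > 1e-8)
  if (length(bad))
    stopf("transition probabilities for posture %d sum to %.6f, not 1", bad[1], csum[bad[1]])
  n_post <- ncol(P)
  m <- repertoire$dwell_mean_frames
  local_seed(seed, {
    est_runs <- ceiling(n_frames / m * 2) + 50
    post <- integer(0); lens <- integer(0); total <- 0
    cur <- sample.int(n_post, 1)
    while (total < n_frames) {
      len <- if (m <= 1) 1L else 1L + rgeom(1, prob = 1 / m)
      post <- c(post, cur); lens <- c(lens, len); total <- total + len
      cur <- sample.int(n_post, 1, prob = P[, cur])
    }
  })
  lens[length(lens)] <- lens[length(lens)] - (total - n_frames)
  keep <- lens > 0
  post <- post[keep]; lens <- lens[keep]
  labels <- rep(post, lens)
  gt <- tibble::tibble(frame = seq_len(n_frames), posture = labels,
                       module = repertoire$module_of[labels])
  if (!is.null(repertoire$super_module_of))
    gt$super_module <- repertoire$super_module_of[gt$module]
  runs <- tibble::tibble(posture = post,
                         start = cumsum(c(1L, lens[-length(lens)])),
                         length = lens)
  structure(list(labels = labels, ground_truth = gt, runs = runs,
                 repertoire = repertoire),
            class = "planted_labels")
}

#' Render a posture label sequence into 3D landmark coordinates
#'
#' Realizes each frame's posture template on the skeleton, linearly blending
#' templates over a short ramp at run boundaries so motion is continuous,
#' moving the body's center of mass according to each posture's velocity
#' tendency (reflecting off the cage walls), and adding isotropic Gaussian
#' observation noise.
#'
#' @param labels integer posture label per frame (e.g. from
#'   [generate_markov_labels()]), or a `planted_labels` object.
#' @param repertoire the [behavior_repertoire()] providing templates.
#' @param noise_sd observation noise standard deviation (meters).
#' @param seed integer seed.
#' @param fps sampling rate.
#' @param subject_scale uniform limb-scale factor for the rendered subject.
#' @param ramp number of frames of linear template blending after each run
#'   boundary.
#' @param cage_bounds arena box, as [default_cage_bounds()].
#' @param subject_id,session_id,task metadata stored on the output.
#' @return A [pose_sequence()].
#' @export
render_poses <- function(labels, repertoire, noise_sd = 0.01, seed = 1,
                         fps = 30, subject_scale = 1, ramp = 3,
                         cage_bounds = default_cage_bounds(),
                         subject_id = "subj1", session_id = "sess1",
                         task = "OFF") {
  if (inherits(labels, "planted_labels")) labels <- labels$labels
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  tpl <- repertoire$templates
  if (any(labels < 1 | labels > length(tpl)))
    stopf("label without a posture template")
  n <- length(labels)
  n_lm <- nrow(tpl[[1]]$coords)
  centered <- lapply(tpl, function(t) {
    sweep(t$coords, 2, colMeans(t$coords)) * subject_scale
  })
  vel <- t(vapply(tpl, `[[`, numeric(3), "velocity"))
  lo <- c(cage_bounds$x[1], cage_bounds$y[1], cage_bounds$z[1])
  hi <- c(cage_bounds$x[2], cage_bounds$y[2], cage_bounds$z[2])
  margin <- 0.45
  coords <- array(NA_real_, c(n, n_lm, 3))
  local_seed(seed, {
    com <- (lo + hi) / 2
    flip <- c(1, 1, 1)
    run_pos <- 1L
    prev_lab <- NA_integer_
    for (t in seq_len(n)) {
      if (t > 1) {
        if (labels[t] != labels[t - 1]) { prev_lab <- labels[t - 1]; run_pos <- 1L }
        else run_pos <- run_pos + 1L
      }
      v <- vel[labels[t], ] * flip
      com <- com + v / fps
      for (a in 1:3) {
        if (com[a] < lo[a] + margin) { com[a] <- lo[a] + margin; flip[a] <- -flip[a] }
        if (com[a] > hi[a] - margin) { com[a] <- hi[a] - margin; flip[a] <- -flip[a] }
      }
      pose <- centered[[labels[t]]]
      if (!is.na(prev_lab) && run_pos <= ramp) {
        alpha <- run_pos / (ramp + 1)
        pose <- (1 - alpha) * centered[[prev_lab]] + alpha * pose
      }
      coords[t, , ] <- sweep(pose, 2, com, `+`)
    }
    if (noise_sd > 0)
      coords <- coords + array(rnorm(length(coords), sd = noise_sd), dim(coords))
  })
  pose_sequence(coords, fps = fps, subject_id = subject_id,
                session_id = session_id, task = task)
}

#' Corrupt a pose sequence with batch effects and tracking failures
#'
#' Adds a per-landmark additive offset (a session-level batch effect), marks
#' dropout runs as missing, and plants outlier frames of two kinds:
#' `escape` frames displace one landmark far outside the cage; `collapse`
#' frames move every landmark to the frame centroid so the mean limb length
#' falls to zero.
#'
#' @param seq a [pose_sequence()].
#' @param offset numeric length-3 vector (same offset for all landmarks) or
#'   landmarks x 3 matrix.
#' @param dropout_runs list of `c(start, length)` integer pairs.
#' @param outlier_frames list with optional integer elements `escape` and
#'   `collapse`; a bare integer vector is treated as `escape`.
#' @return The corrupted [pose_sequence()].
#' @export
corrupt_session <- function(seq, offset = NULL, dropout_runs = list(),
                            outlier_frames = list()) {
  n <- n_frames(seq)
  n_lm <- dim(seq$coords)[2]
  if (!is.null(offset)) {
    if (is.null(dim(offset))) offset <- matrix(offset, n_lm, 3, byrow = TRUE)
    stopifnot(all(dim(offset) == c(n_lm, 3)))
    for (a in 1:3) seq$coords[, , a] <- seq$coords[, , a] +
        matrix(offset[, a], n, n_lm, byrow = TRUE)
  }
  for (dr in dropout_runs) {
    idx <- dr[1]:(dr[1] + dr[2] - 1)
    if (any(idx < 1 | idx > n)) stopf("dropout run out of bounds")
    seq$coords[idx, , ] <- NA_real_
    seq$valid[idx] <- FALSE
  }
  if (is.numeric(outlier_frames)) outlier_frames <- list(escape = outlier_frames)
  for (f in outlier_frames$escape %||% integer(0)) {
    if (f < 1 || f > n) stopf("outlier frame out of bounds")
    seq$coords[f, 1, 3] <- seq$coords[f, 1, 3] + 10  # one landmark far above cage
  }
  for (f in outlier_frames$collapse %||% integer(0)) {
    if (f < 1 || f > n) stopf("outlier frame out of bounds")
    ctr <- colMeans(seq$coords[f, , ])
    seq$coords[f, , ] <- matrix(ctr, n_lm, 3, byrow = TRUE)
  }
  seq
}

#' Simulate one recording session with ground truth
#'
#' Convenience wrapper: Markov labels, rendering, and session-level
#' corruption (batch offset, dropouts, outliers) in one call.
#'
#' @inheritParams render_poses
#' @param repertoire a [behavior_repertoire()].
#' @param n_frames frames to simulate.
#' @param session_offset per-landmark batch offset sd (meters); the offset
#'   itself is drawn once per session. Use 0 to disable.
#' @param n_dropouts number of missing-data runs (lengths 3-15 frames).
#' @param n_outliers number of escape and of collapse frames.
#' @param seed integer seed.
#' @return List with `pose` (a [pose_sequence()]), `ground_truth` (tibble),
#'   `offset` (the drawn batch offset matrix).
#' @export
simulate_session <- function(repertoire, n_frames = 20000, seed = 1,
                             subject_id = "subj1", session_id = "sess1",
                             task = "OFF", subject_scale = 1,
                             noise_sd = 0.01, fps = 30,
                             session_offset = 0.02, n_dropouts = 4,
                             n_outliers = 3) {
  lab <- generate_markov_labels(repertoire, n_frames, seed = child_seed(seed, "labels"))
  pose <- render_poses(lab, repertoire, noise_sd = noise_sd,
                       seed = child_seed(seed, "render"), fps = fps,
                       subject_scale = subject_scale,
                       subject_id = subject_id, session_id = session_id,
                       task = task)
  local_seed(child_seed(seed, "corrupt"), {
    n_lm <- dim(pose$coords)[2]
    off <- matrix(rnorm(n_lm * 3, sd = session_offset), n_lm, 3)
    drops <- if (n_dropouts > 0) lapply(seq_len(n_dropouts), function(i)
      c(sample.int(n_frames - 20, 1) + 2, sample(3:15, 1))) else list()
    outl <- list(escape = sample.int(n_frames, n_outliers),
                 collapse = sample.int(n_frames, n_outliers))
  })
  pose <- corrupt_session(pose, offset = off, dropout_runs = drops,
                          outlier_frames = outl)
  list(pose = pose, ground_truth = lab$ground_truth, offset = off,
       labels = lab)
}

#' Write a small synthetic multi-session study to disk
#'
#' Simulates `n_subjects` x `tasks` sessions from one or more repertoires,
#' writing the same tabular pose format the pipeline reads plus per-session
#' ground-truth label tables and a JSON manifest of all generator parameters
#' and seeds. Subjects differ by limb scale (and optionally by repertoire).
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n_frames frames per session.
#' @param n_subjects number of subjects.
#' @param tasks character vector of task conditions.
#' @param repertoire a [behavior_repertoire()] shared by all subjects, or a
#'   list of per-subject repertoires.
#' @param subject_scales per-subject limb scale factors.
#' @param ... further arguments to [simulate_session()].
#' @return Invisibly, a tibble manifest of the written sessions.
#' @export
make_demo <- function(dir, seed = 1, n_frames = 20000, n_subjects = 2,
                      tasks = c("OFF", "ON_controlled", "ON_random"),
                      repertoire = behavior_repertoire(seed = child_seed(seed, "repertoire")),
                      subject_scales = seq(1, by = 0.2, length.out = n_subjects),
                      ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reps <- if (inherits(repertoire, "behavior_repertoire"))
    rep(list(repertoire), n_subjects) else repertoire
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (tk in tasks) {
      sid <- sprintf("subj%d", s)
      sess <- sprintf("%s_%s", sid, tk)
      sim <- simulate_session(reps[[s]], n_frames = n_frames,
                              seed = child_seed(seed, sess),
                              subject_id = sid, session_id = sess, task = tk,
                              subject_scale = subject_scales[s], ...)
      pose_path <- file.path(dir, paste0(sess, "_pose.csv"))
      write_pose_table(sim$pose, pose_path, reps[[s]]$skeleton)
      readr::write_csv(sim$ground_truth,
                       file.path(dir, paste0(sess, "_truth.csv")), progress = FALSE)
      rows[[sess]] <- tibble::tibble(session = sess, subject = sid, task = tk,
                                     pose_file = pose_path,
                                     truth_file = file.path(dir, paste0(sess, "_truth.csv")))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(list(
    seed = seed, n_frames = n_frames, n_subjects = n_subjects, tasks = tasks,
    subject_scales = subject_scales,
    repertoire = list(n_postures = length(reps[[1]]$templates),
                      n_modules = max(reps[[1]]$module_of),
                      within_module_prob = reps[[1]]$within_module_prob,
                      dwell_mean_frames = reps[[1]]$dwell_mean_frames),
    sessions = manifest$session
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  readr::write_csv(manifest, file.path(dir, "sessions.csv"), progress = FALSE)
  invisible(manifest)
}
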