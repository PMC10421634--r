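#' Quality-control filter for pose frames
#'
#' Invalidates frames where any landmark lies outside the cage bounds (a
#' reconstruction failure) or where the pose has collapsed, defined as a
#' mean bone length below `min_mean_limb` (default 10 cm).
#'
#' @param seq a [pose_sequence()].
#' @param cage_bounds arena box as [default_cage_bounds()].
#' @param min_mean_limb collapse threshold on the mean bone length (meters).
#' @param skeleton a [skeleton_model()] providing the bone list.
#' @return The filtered [pose_sequence()], with a `qc` attribute: a list
#'   with `n_removed`, `fraction_removed` and per-reason counts.
#' @export
qc_filter <- function(seq, cage_bounds = default_cage_bounds(),
                      min_mean_limb = 0.10, skeleton = macaque_skeleton()) {
  stopifnot(cage_bounds$x[1] < cage_bounds$x[2],
            cage_bounds$y[1] < cage_bounds$y[2],
            cage_bounds$z[1] < cage_bounds$z[2])
  n <- n_frames(seq)
  was_valid <- seq$valid
  out_of_cage <- logical(n); collapsed <- logical(n)
  lims <- rbind(c(cage_bounds$x[1], cage_bounds$y[1], cage_bounds$z[1]),
                c(cage_bounds$x[2], cage_bounds$y[2], cage_bounds$z[2]))
  for (t in which(was_valid)) {
    fr <- seq$coords[t, , ]
    if (any(sweep(fr, 2, lims[1, ]) < 0) || any(sweep(fr, 2, lims[2, ]) > 0)) {
      out_of_cage[t] <- TRUE
    } else if (mean(bone_lengths(fr, skeleton$edges)) < min_mean_limb) {
      collapsed[t] <- TRUE
    }
  }
  seq$valid <- was_valid & !out_of_cage & !collapsed
  removed <- sum(was_valid) - sum(seq$valid)
  attr(seq, "qc") <- list(
    n_removed = removed,
    fraction_removed = removed / max(1, sum(was_valid)),
    out_of_cage = sum(out_of_cage), collapsed = sum(collapsed),
    already_missing = sum(!was_valid))
  seq
}

#' Interpolate short gaps of missing pose data
#'
#' Fills invalid runs of at most `max_gap_frames` frames (0.33 s at 30 fps)
#' per landmark coordinate with shape-preserving piecewise cubic
#' interpolation, using up to four valid frames on each side. Longer gaps
#' and gaps touching the sequence boundary are left invalid. Frames outside
#' a filled gap are untouched.
#'
#' @param seq a [pose_sequence()].
#' @param max_gap_frames longest gap (in frames) that will be filled.
#' @return The [pose_sequence()] with short gaps filled and marked valid.
#' @export
interpolate_gaps <- function(seq, max_gap_frames = 10) {
  v <- seq$valid
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n_lm <- dim(seq$coords)[2]
  for (g in which(!r$values)) {
    s <- starts[g]; e <- ends[g]
    if (e - s + 1 > max_gap_frames) next
    if (s == 1 || e == n) next  # no bracketing data
    left <- which(v[1:(s - 1)]); left <- utils::tail(left, 4)
    right <- which(v[(e + 1):n]) + e; right <- utils::head(right, 4)
    if (!length(left) || !length(right)) next
    xs <- c(left, right)
    for (l in seq_len(n_lm)) for (a in 1:3) {
      f <- splinefun(xs, seq$coords[xs, l, a], method = "monoH.FC")
      seq$coords[s:e, l, a] <- f(s:e)
    }
    seq$valid[s:e] <- TRUE
  }
  seq
}

#' Normalize postural orientation frame by frame
#'
#' Maps each valid frame to a canonical body frame: the neck landmark is
#' translated to the origin, the pose is scaled so the neck-to-hip spine has
#' length 1, and a proper rotation sends the spine direction to -Z and the
#' spine-orthogonalized left-to-right shoulder axis to +X. The result is
#' invariant to any rigid motion plus positive uniform scaling of the input.
#'
#' Degenerate frames (zero spine length, or shoulders parallel to the
#' spine) are invalidated and counted in the `degenerate` attribute.
#'
#' @param seq a [pose_sequence()].
#' @param skeleton a [skeleton_model()] defining spine and shoulder pairs.
#' @return A `normalized_pose` object: like a [pose_sequence()] but with
#'   dimensionless coordinates, plus a `source` reference.
#' @export
normalize_pose <- function(seq, skeleton = macaque_skeleton()) {
  neck <- skeleton$spine_pair[1]; hip <- skeleton$spine_pair[2]
  lsh <- skeleton$shoulder_pair[1]; rsh <- skeleton$shoulder_pair[2]
  n <- n_frames(seq)
  out <- array(NA_real_, dim(seq$coords))
  valid <- seq$valid
  degenerate <- 0L
  for (t in which(seq$valid)) {
    fr <- sweep(seq$coords[t, , ], 2, seq$coords[t, neck, ])
    spine <- fr[hip, ]
    L <- sqrt(sum(spine^2))
    if (L < 1e-12) { valid[t] <- FALSE; degenerate <- degenerate + 1L; next }
    fr <- fr / L
    u <- fr[hip, ]                       # unit spine (neck -> hip)
    s <- fr[lsh, ] - fr[rsh, ]           # left-to-right shoulder axis
    sperp <- s - sum(s * u) * u
    ns <- sqrt(sum(sperp^2))
    if (ns < 1e-9) { valid[t] <- FALSE; degenerate <- degenerate + 1L; next }
    r1 <- sperp / ns
    r3 <- -u
    r2 <- c(r3[2] * r1[3] - r3[3] * r1[2],
            r3[3] * r1[1] - r3[1] * r1[3],
            r3[1] * r1[2] - r3[2] * r1[1])
    R <- rbind(r1, r2, r3)
    out[t, , ] <- fr %*% t(R)
  }
  res <- pose_sequence(out, fps = seq$fps, valid = valid,
                       subject_id = seq$subject_id, session_id = seq$session_id,
                       task = seq$task, frame = seq$frame)
  class(res) <- c("normalized_pose", class(res))
  attr(res, "degenerate") <- degenerate
  attr(res, "source") <- seq$session_id
  res
}

#' Preprocess one session: QC, gap interpolation, normalization
#'
#' Applies [qc_filter()], [interpolate_gaps()] and [normalize_pose()] in
#' that order and returns both the cleaned arena-frame sequence (needed for
#' speed features) and the normalized one.
#'
#' @inheritParams qc_filter
#' @inheritParams interpolate_gaps
#' @return List with `raw` (cleaned [pose_sequence()]), `normalized`
#'   (a `normalized_pose`), and `qc` (the QC report).
#' @export
preprocess_session <- function(seq, skeleton = macaque_skeleton(),
                               cage_bounds = default_cage_bounds(),
                               min_mean_limb = 0.10, max_gap_frames = 10) {
  seq <- qc_filter(seq, cage_bounds, min_mean_limb, skeleton)
  qc <- attr(seq, "qc")
  seq <- interpolate_gaps(seq, max_gap_frames)
  norm <- normalize_pose(seq, skeleton)
  list(raw = seq, normalized = norm, qc = qc)
}
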