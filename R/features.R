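#' Compute the 23 pose features
#'
#' Per frame: the 19 vertex angles of the skeleton's joint triplets
#' (radians, computed on the normalized coordinates) plus four speed
#' features computed from the raw arena-frame coordinates — the
#' center-of-mass speed and the per-axis X/Y/Z speeds — using a centered
#' running-mean smoothing of the centroid (default 5 frames) and central
#' differences scaled by the sampling rate.
#'
#' Frames that are invalid in either sequence, or whose angles are
#' undefined (zero-length bone), are excluded.
#'
#' @param normalized a `normalized_pose` from [normalize_pose()].
#' @param raw the matching arena-frame [pose_sequence()].
#' @param skeleton a [skeleton_model()].
#' @param smooth_window centroid smoothing window (frames, odd).
#' @return A tibble (class `etho_features`) with columns `frame`,
#'   `subject_id`, `session_id`, `task`, `angle_01`..`angle_19`,
#'   `com_speed`, `speed_x`, `speed_y`, `speed_z`; attribute `groups` maps
#'   features to normalization groups, attribute `normalized` is FALSE.
#' @export
compute_features <- function(normalized, raw, skeleton = macaque_skeleton(),
                             smooth_window = 5) {
  stopifnot(n_frames(normalized) == n_frames(raw))
  n <- n_frames(normalized)
  tri <- skeleton$angle_triplets
  ang <- matrix(NA_real_, n, nrow(tri))
  for (t in which(normalized$valid))
    ang[t, ] <- vertex_angles(normalized$coords[t, , ], tri)
  # centroid in the arena frame; speeds must be computed before
  # normalization removes translation
  ctr <- apply(raw$coords, c(1, 3), mean)
  ctr[!raw$valid, ] <- NA_real_
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    for (a in 1:3) {
      sm <- stats::filter(ctr[, a], k, sides = 2)
      ctr[, a] <- ifelse(is.na(sm), ctr[, a], as.numeric(sm))
    }
  }
  vel <- matrix(NA_real_, n, 3)
  if (n >= 3) {
    vel[2:(n - 1), ] <- (ctr[3:n, ] - ctr[1:(n - 2), ]) / 2 * raw$fps
    vel[1, ] <- (ctr[2, ] - ctr[1, ]) * raw$fps
    vel[n, ] <- (ctr[n, ] - ctr[n - 1, ]) * raw$fps
  } else vel[] <- 0
  com_speed <- sqrt(rowSums(vel^2))
  keep <- normalized$valid & raw$valid &
    stats::complete.cases(ang) & stats::complete.cases(vel)
  out <- tibble::as_tibble(ang[keep, , drop = FALSE],
                           .name_repair = ~ sprintf("angle_%02d", seq_len(nrow(tri))))
  out$com_speed <- com_speed[keep]
  out$speed_x <- abs(vel[keep, 1])
  out$speed_y <- abs(vel[keep, 2])
  out$speed_z <- abs(vel[keep, 3])
  out <- tibble::add_column(out,
                            frame = normalized$frame[keep],
                            subject_id = raw$subject_id,
                            session_id = raw$session_id,
                            task = raw$task, .before = 1)
  structure(out,
            groups = feature_groups(),
            normalized = FALSE,
            class = c("etho_features", class(out)))
}

#' Feature column names and normalization groups
#'
#' The 23 features fall into three normalization groups: the 19 joint
#' angles, the center-of-mass speed, and the three per-axis speeds.
#'
#' @return `feature_groups()`: named character vector mapping feature
#'   column to group; `feature_cols()`: the 23 column names.
#' @export
feature_groups <- function() {
  c(setNames(rep("angles", 19), sprintf("angle_%02d", 1:19)),
    com_speed = "com_speed",
    speed_x = "axis_speeds", speed_y = "axis_speeds", speed_z = "axis_speeds")
}

#' @rdname feature_groups
#' @export
feature_cols <- function() names(feature_groups())

#' Normalize features to [0, 1] per subject and feature group
#'
#' Min-max scales each of the three feature groups (joint angles, COM
#' speed, per-axis speeds) to the range \[0, 1\], independently for each
#' subject, so no group dominates the embedding through its scale. The
#' operation is idempotent. Constant groups map to 0 with a warning.
#'
#' @param fm a feature tibble from [compute_features()] (sessions may be
#'   row-bound first).
#' @return The tibble with scaled feature columns and attribute
#'   `normalized = TRUE`.
#' @export
normalize_features <- function(fm) {
  groups <- attr(fm, "groups") %||% feature_groups()
  for (subj in unique(fm$subject_id)) {
    rows <- fm$subject_id == subj
    for (grp in unique(groups)) {
      cols <- names(groups)[groups == grp]
      vals <- as.matrix(fm[rows, cols])
      rng <- range(vals)
      if (diff(rng) < 1e-300) {
        warnf("feature group '%s' is constant for subject %s; mapped to 0", grp, subj)
        fm[rows, cols] <- 0
      } else {
        fm[rows, cols] <- (vals - rng[1]) / diff(rng)
      }
    }
  }
  attr(fm, "groups") <- groups
  attr(fm, "normalized") <- TRUE
  fm
}

#' PCA reduction of the feature matrix
#'
#' Principal component analysis of the (concatenated, normalized) feature
#' matrix, retaining the smallest leading set of components whose
#' cumulative explained variance reaches `var_fraction` (default 95%).
#'
#' @param fm normalized feature tibble (all sessions concatenated).
#' @param var_fraction target cumulative explained-variance fraction in
#'   (0, 1].
#' @return A list of class `etho_pca`: `scores` (tibble: frame/session
#'   metadata plus `PC1..PCk`), `rotation`, `explained` (per-component
#'   variance fractions), `n_components`.
#' @export
pca_reduce <- function(fm, var_fraction = 0.95) {
  if (var_fraction <= 0 || var_fraction > 1) stopf("var_fraction must be in (0, 1]")
  X <- as.matrix(fm[, intersect(feature_cols(), names(fm))])
  if (nrow(X) < 2) stopf("need at least 2 frames for PCA")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (var_fraction == 1) sum(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)
  else which(cumsum(ev) >= var_fraction)[1]
  k <- max(2L, k)
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  meta <- fm[, intersect(c("frame", "subject_id", "session_id", "task"), names(fm))]
  structure(list(scores = dplyr::bind_cols(meta, scores),
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center,
                 explained = ev, n_components = k),
            class = "etho_pca")
}

#' @export
print.etho_pca <- function(x, ...) {
  cat(sprintf("<etho_pca: %d components, %.1f%% variance>\n", x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}
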