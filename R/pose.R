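#' Construct a pose sequence
#'
#' A pose sequence stores per-frame 3D landmark coordinates (meters, arena
#' frame), a per-frame validity mask, the sampling rate and session metadata.
#'
#' @param coords numeric array, frames x landmarks x 3.
#' @param fps sampling rate in frames per second.
#' @param valid optional logical vector; defaults to frames with all
#'   coordinates finite.
#' @param subject_id,session_id,task session metadata labels.
#' @param frame optional integer frame indices (default `1:n`).
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, fps = 30, valid = NULL,
                          subject_id = "subj1", session_id = "sess1",
                          task = "OFF", frame = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (fps <= 0) stopf("fps must be positive")
  n <- dim(coords)[1]
  if (is.null(valid)) valid <- apply(is.finite(coords), 1, all)
  stopifnot(length(valid) == n)
  structure(list(
    coords = coords, valid = as.logical(valid), fps = fps,
    subject_id = subject_id, session_id = session_id, task = task,
    frame = frame %||% seq_len(n)
  ), class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence: %d frames (%d valid) @ %g fps, subject=%s session=%s task=%s>\n",
              n_frames(x), sum(x$valid), x$fps, x$subject_id, x$session_id, x$task))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Convert a pose sequence to a tibble
#'
#' One row per frame with columns `frame`, `time_s` and `<landmark>_{x,y,z}`.
#'
#' @param seq a [pose_sequence()].
#' @param skeleton a [skeleton_model()] naming the landmark columns.
#' @return A tibble.
#' @export
as_pose_tibble <- function(seq, skeleton = macaque_skeleton()) {
  n <- n_frames(seq)
  flat <- matrix(aperm(seq$coords, c(1, 3, 2)), nrow = n)  # lm-major blocks
  cols <- as.vector(t(outer(skeleton$landmark_names,
                            c("x", "y", "z"), paste, sep = "_")))
  colnames(flat) <- cols
  out <- tibble::as_tibble(flat)
  out <- tibble::add_column(out,
                            frame = seq$frame,
                            time_s = (seq$frame - 1) / seq$fps, .before = 1)
  out[!seq$valid, cols] <- NA_real_
  out
}

#' Write a pose table and its metadata sidecar
#'
#' Writes the tabular pose format the pipeline reads (CSV, one row per
#' frame: `frame`, `time_s`, `<landmark>_{x,y,z}` in meters) plus a JSON
#' sidecar `<path>.meta.json` with subject, session and task labels.
#'
#' @inheritParams as_pose_tibble
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(seq, path, skeleton = macaque_skeleton()) {
  readr::write_csv(as_pose_tibble(seq, skeleton), path, progress = FALSE)
  meta <- list(subject = seq$subject_id, session = seq$session_id,
               task = seq$task, fps = seq$fps)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a pose table
#'
#' Reads a tab- or comma-separated pose table (columns `frame`, `time_s`,
#' `<landmark>_{x,y,z}`). Rows with any missing coordinate are kept but
#' marked invalid. Session metadata is taken from the JSON sidecar
#' `<path>.meta.json` when present, else from the `meta` argument.
#'
#' @param path input file.
#' @param skeleton a [skeleton_model()]; landmark columns must match.
#' @param meta optional list with `subject`, `session`, `task`, `fps`.
#' @return A [pose_sequence()].
#' @export
read_pose_table <- function(path, skeleton = macaque_skeleton(), meta = NULL) {
  if (!file.exists(path)) stopf("pose file not found: %s", path)
  # base parser: correctly-rounded doubles, so write -> read is bitwise exact
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                           check.names = FALSE)
  cols <- as.vector(t(outer(skeleton$landmark_names,
                            c("x", "y", "z"), paste, sep = "_")))
  missing_cols <- setdiff(c("frame", cols), names(tab))
  if (length(missing_cols))
    stopf("pose table %s lacks columns: %s", path,
          paste(utils::head(missing_cols, 4), collapse = ", "))
  bad <- !vapply(tab[cols], is.numeric, logical(1))
  if (any(bad)) stopf("non-numeric landmark column: %s", names(which(bad))[1])
  fr <- tab$frame
  if (any(diff(fr) <= 0))
    stopf("non-monotone frame index at row %d of %s", which(diff(fr) <= 0)[1] + 1, path)
  n <- nrow(tab)
  coords <- array(NA_real_, c(n, length(skeleton$landmark_names), 3))
  for (l in seq_along(skeleton$landmark_names))
    for (a in 1:3)
      coords[, l, a] <- tab[[cols[(l - 1) * 3 + a]]]
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) meta <- modifyList(meta %||% list(), jsonlite::read_json(side))
  pose_sequence(coords,
                fps = meta$fps %||% 30,
                subject_id = meta$subject %||% "subj1",
                session_id = meta$session %||% basename(path),
                task = meta$task %||% "OFF",
                frame = as.integer(fr))
}
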