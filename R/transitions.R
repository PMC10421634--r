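#' Compress per-frame posture labels into maximal runs
#'
#' @param labels integer or factor posture label per frame; NA frames
#'   (dropped by preprocessing) are removed before compression so that
#'   transition lags stay in run units.
#' @param fps sampling rate, used to report dwell times in seconds.
#' @return A tibble of class `posture_runs` with columns `run`, `posture`,
#'   `start_frame`, `length`, `dwell_s`; attribute `fps`.
#' @export
compress_runs <- function(labels, fps = 30) {
  if (!length(labels)) stopf("labels must be non-empty")
  idx <- which(!is.na(labels))
  lab <- labels[idx]
  r <- rle(as.vector(lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- tibble::tibble(
    run = seq_along(r$values),
    posture = r$values,
    start_frame = idx[starts],
    length = r$lengths,
    dwell_s = r$lengths / fps)
  attr(out, "fps") <- fps
  class(out) <- c("posture_runs", class(out))
  out
}

#' Lag-T posture transition probability matrix
#'
#' Counts transitions from the posture of run `k` to the posture of run
#' `k + T` and normalizes per source column, giving
#' `M[i, j] = P(S(t + T) = i | S(t) = j)` over run-indexed time. Because
#' runs are maximal, the lag-1 diagonal is identically zero; self-returns
#' are possible (and kept) at higher lags. Postures never observed as a
#' source have all-zero columns, flagged rather than filled.
#'
#' @param runs a `posture_runs` tibble, or a list of them (one per
#'   session); sessions are counted separately so no transition spans a
#'   session boundary.
#' @param lag transition lag T in run units (>= 1).
#' @param postures optional vector of posture ids fixing the node set
#'   (default: all postures observed in `runs`).
#' @return A list of class `transition_graph`: `M` (column-stochastic
#'   matrix), `counts`, `lag`, `postures`, `n_transitions`,
#'   `unobserved_sources`.
#' @export
transition_matrix <- function(runs, lag = 1, postures = NULL) {
  rl <- if (inherits(runs, "posture_runs")) list(runs) else runs
  stopifnot(is_count(lag))
  postures <- postures %||% sort(unique(unlist(lapply(rl, function(r) r$posture))))
  k <- length(postures)
  counts <- matrix(0, k, k, dimnames = list(to = postures, from = postures))
  total <- 0L
  for (r in rl) {
    nr <- nrow(r)
    if (lag >= nr) next
    src <- factor(r$posture[seq_len(nr - lag)], levels = postures)
    dst <- factor(r$posture[seq_len(nr - lag) + lag], levels = postures)
    counts <- counts + t(table(src, dst))
    total <- total + (nr - lag)
  }
  if (total == 0) stopf("lag %d is not smaller than the number of runs", lag)
  csum <- colSums(counts)
  M <- counts
  M[, csum > 0] <- sweep(counts[, csum > 0, drop = FALSE], 2, csum[csum > 0], `/`)
  structure(list(M = M, counts = counts, lag = lag, postures = postures,
                 n_transitions = total,
                 unobserved_sources = postures[csum == 0]),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("<transition_graph: %d postures, lag %d, %d transitions>\n",
              length(x$postures), x$lag, x$n_transitions))
  invisible(x)
}

#' Transition matrices over a sweep of lags
#'
#' One [transition_matrix()] per requested lag, sharing a common posture
#' node set. Lags not smaller than the run count are dropped with a
#' warning.
#'
#' @inheritParams transition_matrix
#' @param lags integer vector of lags (run units).
#' @return Named list of `transition_graph` objects.
#' @export
lag_sweep <- function(runs, lags, postures = NULL) {
  rl <- if (inherits(runs, "posture_runs")) list(runs) else runs
  max_runs <- max(vapply(rl, nrow, 0L))
  ok <- lags < max_runs
  if (any(!ok)) warnf("dropping %d lag(s) >= run count (%d)", sum(!ok), max_runs)
  lags <- lags[ok]
  postures <- postures %||% sort(unique(unlist(lapply(rl, function(r) r$posture))))
  setNames(lapply(lags, function(T)
    transition_matrix(runs, lag = T, postures = postures)),
    paste0("lag", lags))
}

#' Summary statistics of posture dwell times
#'
#' @param runs a `posture_runs` tibble.
#' @return A tibble with mean, sem, and range of dwell times in seconds.
#' @export
dwell_summary <- function(runs) {
  tibble::tibble(
    n_runs = nrow(runs),
    mean_s = mean(runs$dwell_s),
    sem_s = sd(runs$dwell_s) / sqrt(nrow(runs)),
    min_s = min(runs$dwell_s),
    max_s = max(runs$dwell_s))
}
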