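#' Mutual nearest neighbors between two sample sets
#'
#' Runs two K-nearest-neighbor searches (each sample of `x2` among `x1`,
#' and each sample of `x1` among `x2`, euclidean distance) and returns, for
#' every sample of `x2`, the `x1` samples that appear in its K-neighborhood
#' while reciprocally containing it in their own.
#'
#' @param x1 reference sample matrix (rows = samples).
#' @param x2 sample matrix to be corrected.
#' @param K neighborhood size (truncated with a warning if it exceeds
#'   either set's size).
#' @return A list of class `mnn_pairs`: `pairs` (per-`x2`-sample integer
#'   vectors of mutual `x1` indices), `dist` (matching distances), `K`.
#' @export
mutual_nearest_neighbors <- function(x1, x2, K = 100) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (!nrow(x1) || !nrow(x2)) stopf("both sample sets must be non-empty")
  if (K > nrow(x1) || K > nrow(x2)) {
    K <- min(nrow(x1), nrow(x2))
    warnf("K larger than a set size; truncated to %d", K)
  }
  fwd <- knn_exact_cpp(x2, x1, K, FALSE)  # neighbors of x2 samples in x1
  bwd <- knn_exact_cpp(x1, x2, K, FALSE)  # neighbors of x1 samples in x2
  # reciprocal membership: j in fwd(i) and i in bwd(j)
  n2 <- nrow(x2)
  pairs <- vector("list", n2)
  dists <- vector("list", n2)
  bw_sets <- split(rep(seq_len(nrow(x1)), ncol(bwd$idx)), as.vector(bwd$idx))
  for (i in seq_len(n2)) {
    cand <- fwd$idx[i, ]
    back <- bw_sets[[as.character(i)]]
    keep <- cand %in% back
    pairs[[i]] <- cand[keep]
    dists[[i]] <- fwd$dist[i, keep]
  }
  structure(list(pairs = pairs, dist = dists, K = K,
                 n1 = nrow(x1), n2 = nrow(x2)),
            class = "mnn_pairs")
}

#' Distance-weighted correction vectors, smoothed in time
#'
#' For each `x2` sample with mutual nearest neighbors, the raw correction
#' is the weighted mean of the differences between the sample and its
#' mutual neighbors in `x1` (so that subtracting the smoothed correction
#' moves `x2` onto `x1`).
#' Weighting is a documented switch: `"kernel"` (default) uses Gaussian
#' weights `exp(-d^2 / sigma^2)` with `sigma` the median mutual-pair
#' distance; `"inverse"` uses `1/d`; `"proportional"` uses `d`. Exact
#' matches (zero distance) absorb all weight — the continuity limit of
#' inverse weighting — so aligning a set against itself is a no-op. Samples
#' without mutual neighbors get no raw vector; because poses vary
#' continuously in time, the raw vectors are then smoothed componentwise by
#' a running median of window `filter_order`, with empty entries filled by
#' temporal interpolation.
#'
#' @param x2 the sample matrix to correct (rows time-ordered).
#' @param x1 the reference sample matrix.
#' @param pairs an `mnn_pairs` from [mutual_nearest_neighbors()].
#' @param filter_order running-median window (odd; default 15).
#' @param weighting `"kernel"`, `"inverse"` or `"proportional"`.
#' @return A list of class `alignment_correction`: `C` (smoothed correction
#'   matrix, one row per `x2` sample), `raw` (unsmoothed, NA where no
#'   mutual pairs), `n_paired`.
#' @export
correction_vectors <- function(x2, x1, pairs, filter_order = 15,
                               weighting = c("kernel", "inverse", "proportional")) {
  weighting <- match.arg(weighting)
  x2 <- as.matrix(x2); x1 <- as.matrix(x1)
  stopifnot(inherits(pairs, "mnn_pairs"), nrow(x2) == length(pairs$pairs))
  if (filter_order %% 2 == 0) filter_order <- filter_order + 1L
  alld <- unlist(pairs$dist)
  if (!length(alld)) stopf("alignment aborted: no sample has mutual nearest neighbors")
  sigma <- stats::median(alld[alld > 0])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  n <- nrow(x2); d <- ncol(x2)
  raw <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    nb <- pairs$pairs[[i]]
    if (!length(nb)) next
    dd <- pairs$dist[[i]]
    if (any(dd < 1e-12)) {
      nb <- nb[dd < 1e-12]; w <- rep(1, length(nb))
    } else {
      w <- switch(weighting,
                  kernel = exp(-(dd / sigma)^2),
                  inverse = 1 / dd,
                  proportional = dd)
    }
    diffs <- matrix(x2[i, ], length(nb), d, byrow = TRUE) - x1[nb, , drop = FALSE]
    raw[i, ] <- colSums(diffs * w) / sum(w)
  }
  n_paired <- sum(stats::complete.cases(raw))
  if (n_paired == 0) stopf("alignment aborted: no sample has mutual nearest neighbors")
  C <- raw
  for (j in seq_len(d)) {
    col <- raw[, j]
    have <- which(!is.na(col))
    if (length(have) < n)  # fill gaps by temporal interpolation first
      col <- approx(have, col[have], xout = seq_len(n), rule = 2)$y
    C[, j] <- if (n >= filter_order)
      runmed(col, filter_order, endrule = "median") else col
  }
  structure(list(C = C, raw = raw, n_paired = n_paired, sigma = sigma,
                 weighting = weighting),
            class = "alignment_correction")
}

#' Apply a correction matrix to a sample set
#'
#' Subtracts the smoothed correction matrix elementwise (`x2' = x2 - C`).
#' Rows with no correction (NA) pass through unchanged.
#'
#' @param x2 sample matrix.
#' @param correction an `alignment_correction` or a plain matrix `C`.
#' @return The aligned matrix.
#' @export
apply_alignment <- function(x2, correction) {
  C <- if (inherits(correction, "alignment_correction")) correction$C else correction
  x2 <- as.matrix(x2)
  if (!all(dim(C) == dim(x2))) stopf("correction matrix shape mismatch")
  C[is.na(C)] <- 0
  x2 - C
}

#' Align several sessions' feature matrices to a reference session
#'
#' Sequentially aligns every session to the designated reference (by
#' default the largest session) with the mutual-nearest-neighbor
#' correction. Alignment operates on whatever per-frame sample matrices are
#' supplied; in the standard pipeline these are the normalized 23-feature
#' vectors, just before embedding.
#'
#' @param mats named list of sample matrices (rows time-ordered).
#' @param reference name or index of the reference session; default the
#'   largest.
#' @param K,filter_order,weighting see [mutual_nearest_neighbors()] and
#'   [correction_vectors()].
#' @return List with `aligned` (list of matrices; reference unchanged) and
#'   `report` (tibble: session, pairs found, mean correction norm).
#' @export
align_sessions <- function(mats, reference = NULL, K = 100,
                           filter_order = 15, weighting = "kernel") {
  stopifnot(is.list(mats), length(mats) >= 1)
  if (is.null(names(mats))) names(mats) <- paste0("session", seq_along(mats))
  ref <- reference %||% names(mats)[which.max(vapply(mats, nrow, 0L))]
  if (is.numeric(ref)) ref <- names(mats)[ref]
  x1 <- as.matrix(mats[[ref]])
  out <- mats
  rows <- list()
  for (nm in names(mats)) {
    if (nm == ref) {
      rows[[nm]] <- tibble::tibble(session = nm, reference = TRUE,
                                   n_paired = NA_integer_, mean_correction = 0)
      next
    }
    pr <- mutual_nearest_neighbors(x1, as.matrix(mats[[nm]]), K = K)
    cv <- correction_vectors(as.matrix(mats[[nm]]), x1, pr,
                             filter_order = filter_order, weighting = weighting)
    out[[nm]] <- apply_alignment(mats[[nm]], cv)
    rows[[nm]] <- tibble::tibble(session = nm, reference = FALSE,
                                 n_paired = cv$n_paired,
                                 mean_correction = mean(sqrt(rowSums(cv$C^2))))
  }
  list(aligned = out, reference = ref, report = dplyr::bind_rows(rows))
}
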