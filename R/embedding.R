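#' Embed feature scores in two dimensions
#'
#' Nonlinear 2-D embedding of the PCA scores built from the fuzzy
#' k-nearest-neighbor graph: exact euclidean kNN, locally calibrated
#' membership weights, fuzzy union symmetrization, and a stochastic
#' gradient layout whose attraction curve is set by `min_dist` and
#' `spread`. Defaults follow the posture-mapping configuration
#' (`min_dist = 0.001`, `n_neighbors = 20`, euclidean metric). The layout
#' is deterministic given `seed`.
#'
#' @param scores numeric matrix of per-frame scores (or an `etho_pca`).
#' @param n_neighbors neighborhood size of the kNN graph.
#' @param min_dist minimum separation of points in the embedding.
#' @param spread scale of the attraction curve.
#' @param n_epochs optimization epochs.
#' @param seed integer seed for the layout stream.
#' @return A matrix (frames x 2) of embedded coordinates, with the fitted
#'   attraction parameters in attributes `a`, `b`.
#' @export
umap_embed <- function(scores, n_neighbors = 20, min_dist = 0.001,
                       spread = 1, n_epochs = 200, seed = 1) {
  X <- embed_input_matrix(scores)
  n <- nrow(X)
  if (n < n_neighbors + 1)
    stopf("need at least n_neighbors + 1 = %d samples, got %d", n_neighbors + 1, n)
  kn <- knn_exact_cpp(X, X, n_neighbors, TRUE)
  W <- smooth_knn_cpp(kn$dist, log2(n_neighbors))
  i <- rep(seq_len(n), n_neighbors)
  j <- as.vector(kn$idx)
  w <- as.vector(W)
  P <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  S <- P + Matrix::t(P) - P * Matrix::t(P)   # fuzzy set union
  tr <- Matrix::summary(S)
  keep <- tr$x > max(tr$x) / n_epochs
  head_i <- tr$i[keep]; tail_j <- tr$j[keep]; w <- tr$x[keep]
  ab <- fit_ab(min_dist, spread)
  init <- prcomp(X, rank. = 2)$x
  init <- init / max(abs(init)) * 10
  emb <- layout_sgd_cpp(init, head_i - 1L, tail_j - 1L,
                        epochs_per_sample = max(w) / w,
                        n_epochs = n_epochs, a = ab[1], b = ab[2],
                        gamma = 1, alpha0 = 1, negative_rate = 5,
                        seed = as.numeric(seed %||% 1))
  colnames(emb) <- c("dim1", "dim2")
  attr(emb, "a") <- ab[1]; attr(emb, "b") <- ab[2]
  emb
}

embed_input_matrix <- function(scores) {
  if (inherits(scores, "etho_pca"))
    return(as.matrix(scores$scores[, grep("^PC", names(scores$scores))]))
  as.matrix(scores)
}

# Least-squares fit of the smooth attraction curve 1/(1 + a d^(2b)) to the
# target curve implied by min_dist and spread.
fit_ab <- function(min_dist, spread) {
  x <- seq(0, spread * 3, length.out = 300)
  y <- ifelse(x < min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- tryCatch(
    stats::nls(y ~ 1 / (1 + a * x^(2 * b)), start = list(a = 1.9, b = 0.8),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(1.93, 0.79))
  unname(stats::coef(fit))
}

#' Kernel density of embedded points on a square grid
#'
#' Gaussian kernel density estimate on a `grid_n` x `grid_n` lattice
#' spanning the data range plus a margin, renormalized so that the grid sums
#' (times cell area) to one. Bandwidths default to a Silverman-type
#' normal-reference rule per dimension.
#'
#' @param points embedded coordinates (n x 2).
#' @param grid_n grid points per dimension (default 200).
#' @param bandwidth optional length-2 bandwidth override.
#' @param margin_frac margin added to each side, as a fraction of the data
#'   span.
#' @return A list of class `density_grid`: `x`, `y` (grid coordinates),
#'   `z` (density matrix), `cell_area`.
#' @export
density_map <- function(points, grid_n = 200, bandwidth = NULL,
                        margin_frac = 0.05) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("need at least 2 points")
  rx <- range(points[, 1]); ry <- range(points[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) stopf("degenerate embedding: zero span")
  h <- bandwidth %||% c(MASS::bandwidth.nrd(points[, 1]),
                        MASS::bandwidth.nrd(points[, 2]))
  if (any(h <= 0)) stopf("degenerate embedding: zero bandwidth")
  mx <- diff(rx) * margin_frac + h[1]; my <- diff(ry) * margin_frac + h[2]
  kd <- MASS::kde2d(points[, 1], points[, 2], h = h, n = grid_n,
                    lims = c(rx[1] - mx, rx[2] + mx, ry[1] - my, ry[2] + my))
  area <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  kd$z <- kd$z / (sum(kd$z) * area)
  structure(list(x = kd$x, y = kd$y, z = kd$z, cell_area = area,
                 bandwidth = h), class = "density_grid")
}

#' Segment the density map into postures by watershed
#'
#' Applies the watershed transform to the density relief (equivalently, to
#' basins of its inverse), so each density peak seeds one basin. Two kinds
#' of spurious basin are merged away: low-persistence basins whose peak
#' rises less than `tolerance_frac` of the map maximum above the saddle to
#' a deeper neighbor (density filaments traced by the continuous
#' trajectories between postures), and negligible basins (peak below
#' `min_peak_frac` of the maximum, or holding fewer than `min_points_frac`
#' of the points — isolated tail speckle), which join their deepest
#' neighbor. Every embedded point is labeled by the basin of
#' its containing grid cell; points on unlabeled background cells take the
#' nearest basin so that every frame receives exactly one posture label.
#'
#' @param grid a `density_grid` from [density_map()].
#' @param points the embedded coordinates that produced the grid.
#' @param tolerance_frac watershed persistence threshold, as a fraction of
#'   the maximum density.
#' @param min_peak_frac basins whose peak density is below this fraction of
#'   the global maximum are merged away.
#' @param min_points_frac basins holding fewer than this fraction of the
#'   embedded points (at least one point) are merged away; isolated tail
#'   points then inherit the nearest real basin.
#' @return A list of class `posture_map`: `labels` (integer posture per
#'   point), `basins` (labeled grid matrix), `n_postures`, plus the grid.
#' @export
watershed_postures <- function(grid, points, tolerance_frac = 0.01,
                               min_peak_frac = 1e-6, min_points_frac = 0.002) {
  stopifnot(inherits(grid, "density_grid"))
  points <- as.matrix(points)
  basins <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(grid$z),
                       tolerance = tolerance_frac * max(grid$z), ext = 1))
  ci <- pmin(pmax(findInterval(points[, 1], grid$x), 1), length(grid$x))
  cj <- pmin(pmax(findInterval(points[, 2], grid$y), 1), length(grid$y))
  lab <- basins[cbind(ci, cj)]
  # merge numerical speckle: shallow or empty basins join deepest neighbor
  repeat {
    ids <- setdiff(sort(unique(as.vector(basins))), 0)
    peak <- vapply(ids, function(b) max(grid$z[basins == b]), 0)
    count <- vapply(ids, function(b) sum(lab == b), 0)
    min_pts <- max(1, min_points_frac * nrow(points))
    weak <- ids[peak < min_peak_frac * max(grid$z) | count < min_pts]
    if (!length(weak) || length(ids) <= 1) break
    b <- weak[which.min(peak[match(weak, ids)])]
    nb <- basin_neighbors(basins, b)
    if (!length(nb)) { basins[basins == b] <- 0 }
    else {
      target <- nb[which.max(vapply(nb, function(x) max(grid$z[basins == x]), 0))]
      basins[basins == b] <- target
    }
    lab <- basins[cbind(ci, cj)]
  }
  # background cells: nearest labeled cell
  if (any(lab == 0)) {
    labeled <- which(basins != 0, arr.ind = TRUE)
    for (p in which(lab == 0)) {
      d2 <- (labeled[, 1] - ci[p])^2 + (labeled[, 2] - cj[p])^2
      lab[p] <- basins[labeled[which.min(d2), , drop = FALSE]]
    }
  }
  ids <- sort(unique(as.vector(basins[basins != 0])))
  relab <- match(lab, ids)
  basins_rel <- matrix(match(basins, ids), nrow(basins), ncol(basins))
  basins_rel[is.na(basins_rel)] <- 0L
  structure(list(labels = as.integer(relab), basins = basins_rel,
                 n_postures = length(unique(relab)),
                 grid = grid, points = points),
            class = "posture_map")
}

basin_neighbors <- function(basins, b) {
  m <- basins == b
  nb <- integer(0)
  sh <- function(mat, di, dj) {
    out <- matrix(FALSE, nrow(mat), ncol(mat))
    ri <- seq_len(nrow(mat)); rj <- seq_len(ncol(mat))
    out[pmax(pmin(ri + di, nrow(mat)), 1), pmax(pmin(rj + dj, ncol(mat)), 1)] <-
      mat[ri, rj]
    out
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    adj <- sh(m, d[1], d[2]) & !m
    nb <- c(nb, unique(basins[adj]))
  }
  setdiff(unique(nb), c(0, b))
}

#' @export
print.posture_map <- function(x, ...) {
  cat(sprintf("<posture_map: %d postures over %d points (%dx%d grid)>\n",
              x$n_postures, length(x$labels), nrow(x$basins), ncol(x$basins)))
  invisible(x)
}
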