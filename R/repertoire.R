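#' Build a behavioral repertoire with planted structure
#'
#' A repertoire defines the generative ground truth for synthetic pose data:
#' a set of posture templates (canonical landmark configurations with a
#' velocity tendency), a partition of postures into modules (optionally
#' nested in super-modules), a between-posture Markov transition matrix that
#' keeps `within_module_prob` of its mass inside each module, and a
#' geometric dwell-time distribution with mean `dwell_mean_frames`.
#'
#' Templates are sampled once and frozen, hierarchically: each module draws
#' a center pose by perturbing the skeleton's reference pose (`module_sd`),
#' and each posture perturbs its module's center (`template_sd`), so that
#' modules are kinematically coherent the way actions are — postures of one
#' module resemble each other more than postures of different modules.
#' Sampling is repeated until every pair of templates is at least
#' `min_separation` apart in joint-angle space (euclidean distance over the
#' 19 vertex angles), which makes posture separability controllable.
#'
#' @param n_postures number of posture templates.
#' @param n_modules number of behavioral modules (postures are assigned
#'   round-robin, so module sizes differ by at most one).
#' @param within_module_prob probability mass of between-posture transitions
#'   staying inside the source posture's module.
#' @param dwell_mean_frames mean posture run length in frames (18 frames at
#'   30 fps gives the ~0.6 s dwell typical of primate postures).
#' @param n_super_modules optional number of super-modules over modules; when
#'   given, a fraction `within_super_prob` of cross-module mass stays within
#'   the source module's super-module, planting a two-level hierarchy.
#' @param within_super_prob see `n_super_modules`.
#' @param template_sd landmark perturbation (meters) of each posture around
#'   its module center.
#' @param module_sd landmark perturbation (meters) of each module center
#'   around the reference pose.
#' @param min_separation minimum pairwise distance between template
#'   joint-angle vectors (radians, euclidean over 19 angles).
#' @param speed_range range (m/s) of per-posture center-of-mass speeds.
#' @param skeleton a [skeleton_model()].
#' @param seed integer seed; the repertoire is a pure function of its
#'   arguments and the seed.
#' @return An object of class `behavior_repertoire` with elements
#'   `templates` (list of `coords`, `angles`, `velocity`), `module_of`,
#'   `super_module_of` (module-level, or NULL), `transition` (column-
#'   stochastic matrix, `[i, j]` = P(next = i | current = j), zero diagonal),
#'   `within_module_prob`, `dwell_mean_frames`, `skeleton`.
#' @export
#' @examples
#' rep <- behavior_repertoire(n_postures = 6, n_modules = 2, seed = 1)
#' colSums(rep$transition)
behavior_repertoire <- function(n_postures = 12, n_modules = 4,
                                within_module_prob = 0.9,
                                dwell_mean_frames = 18,
                                n_super_modules = NULL,
                                within_super_prob = 0.8,
                                template_sd = 0.05,
                                module_sd = 0.08,
                                min_separation = 0.8,
                                speed_range = c(0, 0.4),
                                skeleton = macaque_skeleton(),
                                seed = 1) {
  stopifnot(is_count(n_postures), is_count(n_modules), n_modules <= n_postures)
  if (within_module_prob < 0 || within_module_prob > 1)
    stopf("within_module_prob must be in [0, 1]")
  if (dwell_mean_frames < 1) stopf("dwell_mean_frames must be >= 1")
  module_of <- sort(rep_len(seq_len(n_modules), n_postures))
  super_of <- if (!is.null(n_super_modules))
    sort(rep_len(seq_len(n_super_modules), n_modules)) else NULL

  local_seed(seed, {
    templates <- sample_templates(n_postures, module_of, skeleton, template_sd,
                                  module_sd, min_separation, speed_range)
    P <- planted_transition_matrix(module_of, super_of,
                                   within_module_prob, within_super_prob)
  })

  structure(list(
    templates = templates, module_of = module_of, super_module_of = super_of,
    transition = P, within_module_prob = within_module_prob,
    dwell_mean_frames = dwell_mean_frames, skeleton = skeleton,
    seed = seed
  ), class = "behavior_repertoire")
}

#' @export
print.behavior_repertoire <- function(x, ...) {
  cat(sprintf("<behavior_repertoire: %d postures in %d modules%s, within-module mass %.2f, mean dwell %g frames>\n",
              length(x$templates), max(x$module_of),
              if (is.null(x$super_module_of)) "" else
                sprintf(" (%d super-modules)", max(x$super_module_of)),
              x$within_module_prob, x$dwell_mean_frames))
  invisible(x)
}

# Templates are sampled hierarchically so that behavioral modules are
# kinematically coherent, as actions are: each module gets a center pose
# (a perturbation of the reference pose), and each posture perturbs its
# module's center. Between-posture blends during transitions therefore stay
# near the module's region of pose space for within-module transitions.
sample_templates <- function(n, module_of, skeleton, template_sd, module_sd,
                             min_separation, speed_range) {
  base <- skeleton$reference_pose
  n_mod <- max(module_of)
  centers <- lapply(seq_len(n_mod), function(m)
    base + matrix(rnorm(length(base), sd = module_sd), nrow(base), ncol(base)))
  templates <- vector("list", n)
  angmat <- matrix(NA_real_, n, nrow(skeleton$angle_triplets))
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      coords <- centers[[module_of[k]]] +
        matrix(rnorm(length(base), sd = template_sd), nrow(base), ncol(base))
      ang <- vertex_angles(coords, skeleton$angle_triplets)
      if (k == 1 || all(sqrt(rowSums(sweep(angmat[seq_len(k - 1), , drop = FALSE],
                                           2, ang)^2)) >= min_separation)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stopf("could not place template %d at min_separation = %g; lower it or raise template_sd",
            k, min_separation)
    dir <- rnorm(3); dir[3] <- dir[3] * 0.3
    dir <- dir / sqrt(sum(dir^2))
    speed <- runif(1, speed_range[1], speed_range[2])
    angmat[k, ] <- ang
    templates[[k]] <- list(coords = coords, angles = ang, velocity = dir * speed)
  }
  templates
}

# Column-stochastic between-posture matrix with planted (two-level) module
# structure; diagonal is zero because only between-posture transitions exist.
planted_transition_matrix <- function(module_of, super_of,
                                      within_module_prob, within_super_prob) {
  n <- length(module_of)
  P <- matrix(0, n, n)
  for (j in seq_len(n)) {
    w <- numeric(n)
    same_mod <- which(module_of == module_of[j]); same_mod <- setdiff(same_mod, j)
    cross <- setdiff(which(module_of != module_of[j]), j)
    if (is.null(super_of)) {
      if (length(same_mod)) w[same_mod] <- within_module_prob / length(same_mod)
      if (length(cross)) w[cross] <- (1 - within_module_prob) / length(cross)
    } else {
      same_super <- cross[super_of[module_of[cross]] == super_of[module_of[j]]]
      diff_super <- setdiff(cross, same_super)
      if (length(same_mod)) w[same_mod] <- within_module_prob / length(same_mod)
      cm <- 1 - within_module_prob
      if (length(same_super) && length(diff_super)) {
        w[same_super] <- cm * within_super_prob / length(same_super)
        w[diff_super] <- cm * (1 - within_super_prob) / length(diff_super)
      } else if (length(same_super)) w[same_super] <- cm / length(same_super)
      else if (length(diff_super)) w[diff_super] <- cm / length(diff_super)
    }
    if (sum(w) == 0) stopf("posture %d has no available transition targets", j)
    P[, j] <- w / sum(w)
  }
  dimnames(P) <- list(seq_len(n), seq_len(n))
  P
}

vertex_angles <- function(coords, triplets) {
  u1 <- coords[triplets[, 1], , drop = FALSE] - coords[triplets[, 2], , drop = FALSE]
  u2 <- coords[triplets[, 3], , drop = FALSE] - coords[triplets[, 2], , drop = FALSE]
  n1 <- sqrt(rowSums(u1^2)); n2 <- sqrt(rowSums(u2^2))
  cosang <- rowSums(u1 * u2) / (n1 * n2)
  out <- acos(pmin(1, pmax(-1, cosang)))
  out[n1 == 0 | n2 == 0] <- NA_real_
  out
}
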