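#' Skeleton model for a 15-landmark pose
#'
#' A skeleton model fixes the landmark set, the bone graph, the 19 joint
#' triplets whose vertex angles become pose features, and the two body axes
#' (neck-hip spine, left-right shoulders) used to normalize orientation.
#'
#' @param landmark_names character vector of landmark identifiers, in column
#'   order of the pose tables.
#' @param edges two-column integer matrix of bone endpoints (landmark indices).
#' @param angle_triplets three-column integer matrix; each row is an ordered
#'   landmark triple whose middle element is the joint vertex.
#' @param spine_pair length-2 integer vector: neck and hip landmark indices.
#' @param shoulder_pair length-2 integer vector: left and right shoulder
#'   landmark indices.
#' @param reference_pose optional landmarks x 3 matrix of canonical
#'   coordinates (meters) used by the synthetic generator; bone reference
#'   lengths are derived from it.
#' @return An object of class `skeleton_model`.
#' @seealso [macaque_skeleton()] for the default 15-landmark skeleton.
#' @export
skeleton_model <- function(landmark_names, edges, angle_triplets,
                           spine_pair, shoulder_pair, reference_pose = NULL) {
  n <- length(landmark_names)
  edges <- matrix(as.integer(edges), ncol = 2)
  angle_triplets <- matrix(as.integer(angle_triplets), ncol = 3)
  sk <- structure(list(
    landmark_names = as.character(landmark_names),
    edges = edges,
    angle_triplets = angle_triplets,
    spine_pair = as.integer(spine_pair),
    shoulder_pair = as.integer(shoulder_pair),
    reference_pose = reference_pose,
    reference_bone_lengths = if (is.null(reference_pose)) NULL else
      bone_lengths(reference_pose, edges)
  ), class = "skeleton_model")
  validate_skeleton(sk)
  sk
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model: %d landmarks, %d bones, %d joint angles>\n",
              length(x$landmark_names), nrow(x$edges), nrow(x$angle_triplets)))
  invisible(x)
}

validate_skeleton <- function(sk) {
  n <- length(sk$landmark_names)
  if (n != 15L) stopf("skeleton must have exactly 15 landmarks, got %d", n)
  if (nrow(sk$angle_triplets) != 19L)
    stopf("skeleton must define exactly 19 angle triplets, got %d", nrow(sk$angle_triplets))
  if (any(sk$edges < 1 | sk$edges > n)) stopf("edge index out of range")
  if (any(sk$angle_triplets < 1 | sk$angle_triplets > n)) stopf("triplet index out of range")
  ekey <- paste(pmin(sk$edges[, 1], sk$edges[, 2]), pmax(sk$edges[, 1], sk$edges[, 2]))
  for (r in seq_len(nrow(sk$angle_triplets))) {
    tr <- sk$angle_triplets[r, ]
    for (outer in tr[c(1, 3)]) {
      k <- paste(min(outer, tr[2]), max(outer, tr[2]))
      if (!k %in% ekey)
        stopf("triplet %d: vertex %s not adjacent to landmark %s",
              r, sk$landmark_names[tr[2]], sk$landmark_names[outer])
    }
  }
  pp <- c(sk$spine_pair, sk$shoulder_pair)
  if (any(pp < 1 | pp > n) || anyDuplicated(pp))
    stopf("spine_pair and shoulder_pair must be four distinct valid landmarks")
  invisible(sk)
}

bone_lengths <- function(coords, edges) {
  sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                  coords[edges[, 2], , drop = FALSE])^2))
}

#' Default 15-landmark macaque skeleton
#'
#' Landmarks: head, neck, shoulders, elbows, wrists, mid-spine, hip, knees,
#' ankles and tail base. The bone graph is the usual kinematic tree; the 19
#' joint angles are every pair of bones meeting at the neck (6), mid-spine
#' (1), hip (6), shoulders (2), elbows (2) and knees (2). The reference pose
#' is a quadrupedal stance with plausible adult macaque segment lengths.
#'
#' @return A [skeleton_model()].
#' @export
#' @examples
#' sk <- macaque_skeleton()
#' sk$landmark_names
macaque_skeleton <- function() {
  lm <- c("head", "neck", "left_shoulder", "right_shoulder",
          "left_elbow", "right_elbow", "left_wrist", "right_wrist",
          "spine_mid", "hip", "left_knee", "right_knee",
          "left_ankle", "right_ankle", "tail_base")
  i <- function(x) match(x, lm)
  edges <- rbind(
    c(i("head"), i("neck")),
    c(i("neck"), i("left_shoulder")), c(i("neck"), i("right_shoulder")),
    c(i("left_shoulder"), i("left_elbow")), c(i("left_elbow"), i("left_wrist")),
    c(i("right_shoulder"), i("right_elbow")), c(i("right_elbow"), i("right_wrist")),
    c(i("neck"), i("spine_mid")), c(i("spine_mid"), i("hip")),
    c(i("hip"), i("left_knee")), c(i("left_knee"), i("left_ankle")),
    c(i("hip"), i("right_knee")), c(i("right_knee"), i("right_ankle")),
    c(i("hip"), i("tail_base")))
  tri <- rbind(
    # neck vertex: head, shoulders and spine meet here
    c(i("head"), i("neck"), i("left_shoulder")),
    c(i("head"), i("neck"), i("right_shoulder")),
    c(i("head"), i("neck"), i("spine_mid")),
    c(i("left_shoulder"), i("neck"), i("right_shoulder")),
    c(i("left_shoulder"), i("neck"), i("spine_mid")),
    c(i("right_shoulder"), i("neck"), i("spine_mid")),
    # spine
    c(i("neck"), i("spine_mid"), i("hip")),
    # hip vertex: spine, legs and tail
    c(i("spine_mid"), i("hip"), i("left_knee")),
    c(i("spine_mid"), i("hip"), i("right_knee")),
    c(i("spine_mid"), i("hip"), i("tail_base")),
    c(i("left_knee"), i("hip"), i("right_knee")),
    c(i("left_knee"), i("hip"), i("tail_base")),
    c(i("right_knee"), i("hip"), i("tail_base")),
    # limb joints
    c(i("neck"), i("left_shoulder"), i("left_elbow")),
    c(i("neck"), i("right_shoulder"), i("right_elbow")),
    c(i("left_shoulder"), i("left_elbow"), i("left_wrist")),
    c(i("right_shoulder"), i("right_elbow"), i("right_wrist")),
    c(i("hip"), i("left_knee"), i("left_ankle")),
    c(i("hip"), i("right_knee"), i("right_ankle")))
  ref <- rbind(
    head          = c( 0.10,  0.00, 0.47),
    neck          = c( 0.00,  0.00, 0.40),
    left_shoulder = c( 0.00,  0.10, 0.40),
    right_shoulder= c( 0.00, -0.10, 0.40),
    left_elbow    = c( 0.02,  0.12, 0.25),
    right_elbow   = c( 0.02, -0.12, 0.25),
    left_wrist    = c( 0.03,  0.13, 0.10),
    right_wrist   = c( 0.03, -0.13, 0.10),
    spine_mid     = c(-0.15,  0.00, 0.42),
    hip           = c(-0.30,  0.00, 0.40),
    left_knee     = c(-0.32,  0.10, 0.25),
    right_knee    = c(-0.32, -0.10, 0.25),
    left_ankle    = c(-0.33,  0.11, 0.08),
    right_ankle   = c(-0.33, -0.11, 0.08),
    tail_base     = c(-0.38,  0.00, 0.42))
  colnames(ref) <- c("x", "y", "z")
  skeleton_model(lm, edges, tri, spine_pair = c(i("neck"), i("hip")),
                 shoulder_pair = c(i("left_shoulder"), i("right_shoulder")),
                 reference_pose = ref)
}

#' Default arena bounds
#'
#' The open-field cage is a 2.45 x 2.45 x 2.75 m box; frames with any
#' landmark outside it are treated as reconstruction failures.
#'
#' @return A list with `x`, `y`, `z` range vectors (meters).
#' @export
default_cage_bounds <- function() {
  list(x = c(0, 2.45), y = c(0, 2.45), z = c(0, 2.75))
}
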