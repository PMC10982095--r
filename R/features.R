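snake_name <- function(x) {
  tolower(gsub("(?<=[a-z0-9])(?=[A-Z])", "_", x, perl = TRUE))
}

joint_pos <- function(rel_frames, joint, skeleton) {
  # Pelvis is the origin of the root-relative frame
  if (joint == skeleton$root) {
    return(matrix(0, dim(rel_frames)[1], 3L))
  }
  rel_frames[, joint, ]
}

angle_triples <- function(skel) {
  list(
    angle_neck = c("T8", "Neck", "Head"),
    angle_left_shoulder = c("T8", "LeftShoulder", "LeftElbow"),
    angle_right_shoulder = c("T8", "RightShoulder", "RightElbow"),
    angle_left_elbow = c("LeftShoulder", "LeftElbow", "LeftWrist"),
    angle_right_elbow = c("RightShoulder", "RightElbow", "RightWrist"),
    angle_left_hip = c("Pelvis", "LeftHip", "LeftKnee"),
    angle_right_hip = c("Pelvis", "RightHip", "RightKnee"),
    angle_left_knee = c("LeftHip", "LeftKnee", "LeftAnkle"),
    angle_right_knee = c("RightHip", "RightKnee", "RightAnkle")
  )
}

distance_pairs <- function(skel) {
  list(
    dist_head_left_elbow = c("Head", "LeftElbow"),
    dist_head_right_elbow = c("Head", "RightElbow"),
    dist_left_hand_right_hand = c("LeftHand", "RightHand"),
    dist_left_hand_right_elbow = c("LeftHand", "RightElbow"),
    dist_right_hand_left_elbow = c("RightHand", "LeftElbow"),
    dist_left_hand_left_knee = c("LeftHand", "LeftKnee"),
    dist_right_hand_right_knee = c("RightHand", "RightKnee"),
    dist_left_knee_right_knee = c("LeftKnee", "RightKnee"),
    dist_left_ankle_right_ankle = c("LeftAnkle", "RightAnkle"),
    dist_pelvis_right_ankle = c("Pelvis", "RightAnkle"),
    dist_pelvis_left_ankle = c("Pelvis", "LeftAnkle")
  )
}

body_part_members <- function(skel, parts) {
  names(skel$body_part)[skel$body_part %in% parts]
}

#' The 67-feature catalogue
#'
#' Enumerates the package's geometric features and their metadata. Four
#' feature types are computed on normalized (root-relative, size-standardized)
#' postures:
#' \itemize{
#'   \item movement (30): per-frame-pair Euclidean displacement of each of the
#'     22 non-root joints, plus totals for the six body parts, the upper body
#'     (arms + torso + head), and the full body;
#'   \item joint angle (10): angles at neck, shoulders, elbows, hips and knees
#'     between the two adjacent segments (0 degrees = extended), plus their
#'     mean;
#'   \item joint distance (12): eleven inter-joint distances capturing posture
#'     compactness and hand/face/knee configurations, plus their mean;
#'   \item symmetry (15): for the eight left/right joint pairs, the distance
#'     between the mirrored left joint and its right counterpart; for the six
#'     midline joints, the distance to their own mirror image; plus the mean.
#' }
#'
#' @param skeleton A `bc_skeleton`.
#' @return A data frame with 67 rows and columns `feature_id`, `feature_type`,
#'   `joints` (list column), `body_parts` (list column),
#'   `n_body_parts_class` (`"single"`, `"two"`, `"all"`).
#' @export
#' @examples
#' table(feature_catalogue()$feature_type)
feature_catalogue <- function(skeleton = canonical_skeleton()) {
  skel <- skeleton
  all_parts <- c("left_arm", "right_arm", "left_leg", "right_leg",
                 "torso", "head")
  rows <- list()
  add <- function(id, type, joints, parts) {
    rows[[length(rows) + 1L]] <<- list(feature_id = id, feature_type = type,
                                       joints = joints, parts = parts)
  }

  # movement: 22 joints, 6 body-part totals, upper body, full body
  for (j in skel$non_root) {
    add(paste0("movement_", snake_name(j)), "movement", j,
        unname(skel$body_part[[j]]))
  }
  for (p in all_parts) {
    add(paste0("movement_total_", p), "movement", body_part_members(skel, p), p)
  }
  upper <- c("left_arm", "right_arm", "torso", "head")
  add("movement_upper_body", "movement", body_part_members(skel, upper), upper)
  add("movement_full_body", "movement", skel$non_root, all_parts)

  # joint angles: 9 joints + mean
  for (nm in names(angle_triples(skel))) {
    tr <- angle_triples(skel)[[nm]]
    parts <- unique(unname(skel$body_part[intersect(tr, skel$non_root)]))
    add(nm, "joint_angle", tr, parts)
  }
  add("angle_mean", "joint_angle", skel$non_root, all_parts)

  # joint distances: 11 pairs + mean
  for (nm in names(distance_pairs(skel))) {
    pr <- distance_pairs(skel)[[nm]]
    parts <- unique(unname(skel$body_part[intersect(pr, skel$non_root)]))
    add(nm, "joint_distance", pr, parts)
  }
  add("dist_mean", "joint_distance", skel$non_root, all_parts)

  # symmetry: 8 left/right pairs + 6 midline + mean
  for (lft in names(skel$mirror_pair)) {
    rgt <- skel$mirror_pair[[lft]]
    parts <- unique(unname(skel$body_part[c(lft, rgt)]))
    add(paste0("sym_", snake_name(lft)), "symmetry", c(lft, rgt), parts)
  }
  for (m in skel$midline) {
    add(paste0("sym_", snake_name(m)), "symmetry", m,
        unname(skel$body_part[[m]]))
  }
  add("sym_mean", "symmetry", skel$non_root, all_parts)

  cat_df <- data.frame(
    feature_id = vapply(rows, `[[`, character(1), "feature_id"),
    feature_type = vapply(rows, `[[`, character(1), "feature_type"),
    stringsAsFactors = FALSE
  )
  cat_df$joints <- lapply(rows, `[[`, "joints")
  cat_df$body_parts <- lapply(rows, `[[`, "parts")
  np <- lengths(cat_df$body_parts)
  cat_df$n_body_parts_class <- ifelse(np == 1L, "single",
                               ifelse(np == 2L, "two", "all"))

  counts <- table(factor(cat_df$feature_type,
                         c("movement", "joint_angle", "joint_distance",
                           "symmetry")))
  stopifnot(identical(as.integer(counts), c(30L, 10L, 12L, 15L)),
            nrow(cat_df) == 67L, all(np >= 1L),
            !anyDuplicated(cat_df$feature_id))
  cat_df
}

#' Per-joint and aggregate movement streams
#'
#' Euclidean displacement of each joint between consecutive frames of the
#' normalized recording, plus body-part, upper-body and full-body totals.
#'
#' @param rel_frames Normalized `T x 22 x 3` frames.
#' @param skeleton A `bc_skeleton`.
#' @return A `(T-1) x 30` matrix; column i at row t is the displacement
#'   between frames t and t+1 (streams are aligned to the later frame).
#' @export
movement_features <- function(rel_frames, skeleton = canonical_skeleton()) {
  T <- dim(rel_frames)[1]
  if (T < 2L) bc_stop("bc_too_short", "movement needs at least 2 frames")
  d <- rel_frames[-1L, , , drop = FALSE] - rel_frames[-T, , , drop = FALSE]
  per_joint <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
  if (T == 2L) per_joint <- matrix(per_joint, nrow = 1)
  colnames(per_joint) <- skeleton$non_root
  all_parts <- c("left_arm", "right_arm", "left_leg", "right_leg",
                 "torso", "head")
  totals <- vapply(all_parts, function(p) {
    rowSums(per_joint[, body_part_members(skeleton, p), drop = FALSE])
  }, numeric(T - 1L))
  if (T == 2L) totals <- matrix(totals, nrow = 1, dimnames = list(NULL, all_parts))
  upper <- rowSums(totals[, c("left_arm", "right_arm", "torso", "head"),
                          drop = FALSE])
  full <- rowSums(per_joint)
  out <- cbind(per_joint, totals, upper, full)
  colnames(out) <- feature_ids_of_type("movement")
  out
}

#' Joint-angle streams
#'
#' For the neck, shoulders, elbows, hips and knees: the angle between the
#' incoming segment (parent to joint) and the outgoing segment (joint to
#' child), in degrees within [0, 180]; 0 means a fully extended chain. The
#' tenth stream is the mean of the nine angles.
#'
#' @inheritParams movement_features
#' @return A `T x 10` matrix.
#' @export
joint_angle_features <- function(rel_frames, skeleton = canonical_skeleton()) {
  T <- dim(rel_frames)[1]
  triples <- angle_triples(skeleton)
  out <- matrix(NA_real_, T, 10L,
                dimnames = list(NULL, feature_ids_of_type("joint_angle")))
  for (nm in names(triples)) {
    tr <- triples[[nm]]
    a <- joint_pos(rel_frames, tr[1], skeleton)
    b <- joint_pos(rel_frames, tr[2], skeleton)
    c_ <- joint_pos(rel_frames, tr[3], skeleton)
    v1 <- b - a
    v2 <- c_ - b
    n1 <- sqrt(rowSums(v1 * v1))
    n2 <- sqrt(rowSums(v2 * v2))
    if (any(n1 < 1e-12) || any(n2 < 1e-12)) {
      bc_stop("bc_zero_segment", "zero-length segment at angle ", nm)
    }
    cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2)))
    out[, nm] <- acos(cosang) * 180 / pi
  }
  out[, "angle_mean"] <- rowMeans(out[, seq_len(9L), drop = FALSE])
  out
}

#' Joint-distance streams
#'
#' Euclidean distances between eleven fixed joint pairs (head-elbows,
#' hand-hand, hand-elbow crossings, hand-knee, knee-knee, ankle-ankle,
#' pelvis-ankles) plus their mean. After centering the pelvis is the origin.
#'
#' @inheritParams movement_features
#' @return A `T x 12` matrix.
#' @export
joint_distance_features <- function(rel_frames,
                                    skeleton = canonical_skeleton()) {
  T <- dim(rel_frames)[1]
  pairs <- distance_pairs(skeleton)
  out <- matrix(NA_real_, T, 12L,
                dimnames = list(NULL, feature_ids_of_type("joint_distance")))
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    d <- joint_pos(rel_frames, pr[1], skeleton) -
      joint_pos(rel_frames, pr[2], skeleton)
    out[, nm] <- sqrt(rowSums(d * d))
  }
  out[, "dist_mean"] <- rowMeans(out[, seq_len(11L), drop = FALSE])
  out
}

#' Posture-symmetry streams
#'
#' Joint positions are mirrored in the plane through the root perpendicular
#' to the hip axis (the line joining the hips). Eight streams compare the
#' mirrored left joint with its right counterpart; six streams compare each
#' midline joint with its own mirror image; the fifteenth is the mean of the
#' fourteen. All streams are zero for a perfectly left/right symmetric pose.
#'
#' @inheritParams movement_features
#' @return A `T x 15` matrix.
#' @export
symmetry_features <- function(rel_frames, skeleton = canonical_skeleton()) {
  T <- dim(rel_frames)[1]
  lh <- rel_frames[, "LeftHip", , drop = TRUE]
  rh <- rel_frames[, "RightHip", , drop = TRUE]
  if (T == 1L) { lh <- matrix(lh, 1); rh <- matrix(rh, 1) }
  axis <- rh - lh
  an <- sqrt(rowSums(axis * axis))
  if (any(an < 1e-12)) {
    bc_stop("bc_degenerate_hips", "left and right hip coincide: ",
            "mirror plane undefined")
  }
  n <- axis / an  # T x 3 unit normals, plane passes through the origin (root)
  mirror <- function(p) p - 2 * rowSums(p * n) * n
  ids <- feature_ids_of_type("symmetry")
  out <- matrix(NA_real_, T, 15L, dimnames = list(NULL, ids))
  k <- 0L
  for (lft in names(skeleton$mirror_pair)) {
    k <- k + 1L
    rgt <- skeleton$mirror_pair[[lft]]
    d <- mirror(joint_pos(rel_frames, lft, skeleton)) -
      joint_pos(rel_frames, rgt, skeleton)
    out[, k] <- sqrt(rowSums(d * d))
  }
  for (m in skeleton$midline) {
    k <- k + 1L
    p <- joint_pos(rel_frames, m, skeleton)
    out[, k] <- 2 * abs(rowSums(p * n))
  }
  out[, "sym_mean"] <- rowMeans(out[, seq_len(14L), drop = FALSE])
  out
}

feature_ids_of_type <- function(type, catalogue = NULL) {
  if (is.null(catalogue)) {
    if (is.null(.bodycues$catalogue)) {
      .bodycues$catalogue <- feature_catalogue()
    }
    catalogue <- .bodycues$catalogue
  }
  catalogue$feature_id[catalogue$feature_type == type]
}

#' Extract all 67 feature streams from a normalized session
#'
#' @param norm A `mocap_norm` (from [normalize_session()]).
#' @return An object of class `feature_streams`: list with `movement`
#'   (`(T-1) x 30` matrix), `pose` (`T x 37` matrix: angles, distances,
#'   symmetry), `sample_rate_hz`, and the session labels. Column names follow
#'   the catalogue.
#' @export
extract_features <- function(norm) {
  stopifnot(inherits(norm, "mocap_norm"))
  skel <- canonical_skeleton()
  rel <- norm$frames
  structure(
    list(
      movement = movement_features(rel, skel),
      pose = cbind(joint_angle_features(rel, skel),
                   joint_distance_features(rel, skel),
                   symmetry_features(rel, skel)),
      sample_rate_hz = norm$sample_rate_hz,
      interviewee_id = norm$interviewee_id,
      session_kind = norm$session_kind,
      condition = norm$condition
    ),
    class = "feature_streams"
  )
}

#' Export feature streams as a tidy data frame
#'
#' One row per (feature, frame): columns `interviewee_id`, `session_kind`,
#' `condition`, `feature_id`, `frame_index`, `value`. Movement streams are
#' indexed by the later frame of each pair.
#'
#' @param streams A `feature_streams` object.
#' @return A data frame in long format.
#' @export
streams_to_long <- function(streams) {
  stopifnot(inherits(streams, "feature_streams"))
  mv <- streams$movement
  po <- streams$pose
  long <- rbind(
    data.frame(feature_id = rep(colnames(mv), each = nrow(mv)),
               frame_index = rep(seq_len(nrow(mv)) + 1L, ncol(mv)),
               value = as.vector(mv), stringsAsFactors = FALSE),
    data.frame(feature_id = rep(colnames(po), each = nrow(po)),
               frame_index = rep(seq_len(nrow(po)), ncol(po)),
               value = as.vector(po), stringsAsFactors = FALSE)
  )
  cbind(data.frame(interviewee_id = streams$interviewee_id,
                   session_kind = streams$session_kind,
                   condition = streams$condition,
                   stringsAsFactors = FALSE),
        long)
}
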