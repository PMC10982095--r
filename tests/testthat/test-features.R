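test_that("catalogue counts features by type as 30 + 10 + 12 + 15 = 67", {
  cat_df <- feature_catalogue()
  counts <- table(cat_df$feature_type)
  expect_equal(counts[["movement"]], 30)
  expect_equal(counts[["joint_angle"]], 10)
  expect_equal(counts[["joint_distance"]], 12)
  expect_equal(counts[["symmetry"]], 15)
  expect_equal(nrow(cat_df), 67)
  expect_true(all(lengths(cat_df$body_parts) >= 1))
  # body-part count classes partition the catalogue
  expect_equal(sum(table(cat_df$n_body_parts_class)), 67)
  # mean-type features span all six parts
  for (f in c("movement_full_body", "angle_mean", "dist_mean", "sym_mean")) {
    expect_length(cat_df$body_parts[[which(cat_df$feature_id == f)]], 6)
  }
})

test_that("movement streams measure per-joint displacement and conserve totals", {
  rel <- array(0, c(2, 22, 3),
               dimnames = list(NULL, canonical_skeleton()$non_root, NULL))
  rel[2, "LeftHand", ] <- c(0.3, 0.4, 0)  # a 3-4-5 displacement
  mv <- movement_features(rel)
  expect_equal(nrow(mv), 1)
  expect_equal(mv[1, "movement_left_hand"], 0.5, ignore_attr = TRUE)
  expect_equal(mv[1, "movement_total_left_arm"], 0.5, ignore_attr = TRUE)
  expect_equal(mv[1, "movement_upper_body"], 0.5, ignore_attr = TRUE)
  expect_equal(mv[1, "movement_full_body"], 0.5, ignore_attr = TRUE)
  expect_equal(sum(mv[1, ] != 0), 4)

  # static pose: all 30 streams identically zero
  rel0 <- center_on_root(static_session(T = 6)$frames)
  expect_true(all(movement_features(rel0) == 0))
  expect_error(movement_features(rel0[1, , , drop = FALSE]),
               class = "bc_too_short")

  # conservation: body-part totals equal the sum of member joint streams
  s <- generate_session(synthetic_config(2, session_length_s = 3, seed = 2),
                        "lie", "game", "P1", seed = 6)
  rel2 <- center_on_root(s$frames)
  mv2 <- movement_features(rel2)
  skel <- canonical_skeleton()
  arm <- paste0("movement_",
                snake_name(names(skel$body_part)[skel$body_part == "left_arm"]))
  expect_equal(unname(mv2[, "movement_total_left_arm"]),
               unname(rowSums(mv2[, arm])))
  joints22 <- paste0("movement_", snake_name(skel$non_root))
  expect_equal(unname(mv2[, "movement_full_body"]),
               unname(rowSums(mv2[, joints22])))
})

test_that("joint angles follow the adjacent-segment convention in degrees", {
  pose <- template_pose()
  t8 <- pose["T8", ]
  # collinear left arm: elbow angle 0
  pose["LeftShoulder", ] <- t8 + c(-0.2, 0, 0)
  pose["LeftElbow", ] <- t8 + c(-0.45, 0, 0)
  pose["LeftWrist", ] <- t8 + c(-0.7, 0, 0)
  # perpendicular right forearm: elbow angle 90
  pose["RightShoulder", ] <- t8 + c(0.2, 0, 0)
  pose["RightElbow", ] <- t8 + c(0.45, 0, 0)
  pose["RightWrist", ] <- t8 + c(0.45, -0.25, 0)
  rel <- center_on_root(static_session(T = 2, pose = pose)$frames)
  ang <- joint_angle_features(rel)
  expect_equal(ncol(ang), 10)
  expect_equal(ang[1, "angle_left_elbow"], 0, ignore_attr = TRUE)
  expect_equal(ang[1, "angle_right_elbow"], 90, ignore_attr = TRUE)
  expect_true(all(ang >= 0 & ang <= 180))
  expect_equal(unname(ang[, "angle_mean"]),
               unname(rowMeans(ang[, 1:9])))
})

test_that("joint distances cover the fixed pair list plus the mean", {
  pose <- template_pose()
  pose["LeftHand", ] <- c(0.1, 0.8, 0.1)
  pose["RightHand", ] <- c(-0.1, 0.8, 0.1)
  rel <- center_on_root(static_session(T = 2, pose = pose)$frames)
  dst <- joint_distance_features(rel)
  expect_equal(ncol(dst), 12)
  expect_equal(dst[1, "dist_left_hand_right_hand"], 0.2, ignore_attr = TRUE)
  # pelvis is the origin after centering
  expect_equal(dst[1, "dist_pelvis_left_ankle"],
               sqrt(sum(rel[1, "LeftAnkle", ]^2)), ignore_attr = TRUE)
  expect_equal(unname(dst[, "dist_mean"]), unname(rowMeans(dst[, 1:11])))
  # coincident hands
  pose["RightHand", ] <- pose["LeftHand", ]
  rel2 <- center_on_root(static_session(T = 2, pose = pose)$frames)
  expect_equal(joint_distance_features(rel2)[1, "dist_left_hand_right_hand"],
               0, ignore_attr = TRUE)
})

test_that("symmetry streams vanish for mirror-symmetric poses and match a reflection oracle", {
  rel0 <- center_on_root(static_session(T = 3)$frames)
  sym0 <- symmetry_features(rel0)
  expect_equal(ncol(sym0), 15)
  expect_true(all(abs(sym0) < 1e-12))

  # displacing the left hand 0.1 m along the hip axis gives stream 0.1
  pose <- template_pose()
  skel <- canonical_skeleton()
  axis <- pose["RightHip", ] - pose["LeftHip", ]
  axis <- axis / sqrt(sum(axis^2))
  pose["LeftHand", ] <- pose["LeftHand", ] + 0.1 * axis
  rel <- center_on_root(static_session(T = 2, pose = pose)$frames)
  sym <- symmetry_features(rel)
  expect_equal(sym[1, "sym_left_hand"], 0.1, ignore_attr = TRUE)

  # explicit reflection-matrix oracle on a random pose
  set.seed(31)
  jitter <- array(stats::rnorm(2 * 23 * 3, sd = 0.05), c(2, 23, 3))
  noisy <- static_session(T = 2)$frames + jitter
  reln <- center_on_root(noisy)
  symn <- symmetry_features(reln)
  n <- reln[1, "RightHip", ] - reln[1, "LeftHip", ]
  n <- n / sqrt(sum(n^2))
  H <- diag(3) - 2 * outer(n, n)
  for (lft in names(skel$mirror_pair)) {
    rgt <- skel$mirror_pair[[lft]]
    want <- sqrt(sum((H %*% reln[1, lft, ] - reln[1, rgt, ])^2))
    expect_equal(symn[1, paste0("sym_", snake_name(lft))], want,
                 ignore_attr = TRUE)
  }
  for (m in skel$midline) {
    want <- sqrt(sum((H %*% reln[1, m, ] - reln[1, m, ])^2))
    expect_equal(symn[1, paste0("sym_", snake_name(m))], want,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(symn[, "sym_mean"]), unname(rowMeans(symn[, 1:14])))

  # coincident hips leave the mirror plane undefined
  bad <- template_pose()
  bad["RightHip", ] <- bad["LeftHip", ]
  relb <- center_on_root(static_session(T = 2, pose = bad)$frames)
  expect_error(symmetry_features(relb), class = "bc_degenerate_hips")
})

test_that("full extraction yields 67 streams invariant to rigid transforms", {
  s <- generate_session(synthetic_config(2, session_length_s = 5, seed = 4),
                        "truth", "game", "P1", seed = 12)
  corp <- mocap_corpus(list(s))
  ref <- compute_reference_lengths(corp)
  fs <- extract_features(normalize_session(s, ref))
  expect_equal(ncol(fs$movement) + ncol(fs$pose), 67)
  expect_true(all(fs$movement >= 0))
  expect_true(all(fs$pose[, grep("^dist_|^sym_", colnames(fs$pose))] >= 0))

  set.seed(8)
  R <- rotation_matrix(stats::runif(3, 0, 2 * pi))
  v <- stats::rnorm(3, sd = 2)
  s2 <- rigid_transform_session(s, R, v)
  ref2 <- compute_reference_lengths(mocap_corpus(list(s2)))
  fs2 <- extract_features(normalize_session(s2, ref2))
  expect_lt(max(abs(fs$movement - fs2$movement)), 1e-9)
  expect_lt(max(abs(fs$pose - fs2$pose)), 1e-9)
})

test_that("tidy stream export is long-format and complete", {
  s <- generate_session(synthetic_config(2, session_length_s = 2, seed = 5),
                        "truth", "game", "P1", seed = 3)
  ref <- compute_reference_lengths(mocap_corpus(list(s)))
  fs <- extract_features(normalize_session(s, ref))
  long <- streams_to_long(fs)
  T <- nrow(fs$pose)
  expect_equal(nrow(long), 30 * (T - 1) + 37 * T)
  expect_setequal(unique(long$feature_id), feature_catalogue()$feature_id)
})
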