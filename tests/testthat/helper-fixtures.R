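# Shared fixtures: built in code at test time, no stored data.

# short synthetic corpus for unit tests (full-length corpora are used only
# where the property under test concerns the study-scale conditions)
tiny_corpus <- function(n = 4, len = 10, mult = 1, seed = 11) {
  generate_corpus(synthetic_config(n, session_length_s = len,
                                   lie_movement_multiplier = mult,
                                   seed = seed))
}

# constant-pose session from the seated template
static_session <- function(T = 24, rate = 60, id = "S1", kind = "game",
                           condition = "truth", pose = template_pose()) {
  frames <- array(rep(pose, each = T), c(T, 23, 3))
  mocap_session(frames, rate, id, kind, condition)
}

rotation_matrix <- function(theta) {
  Rx <- matrix(c(1, 0, 0, 0, cos(theta[1]), sin(theta[1]),
                 0, -sin(theta[1]), cos(theta[1])), 3)
  Ry <- matrix(c(cos(theta[2]), 0, -sin(theta[2]), 0, 1, 0,
                 sin(theta[2]), 0, cos(theta[2])), 3)
  Rz <- matrix(c(cos(theta[3]), sin(theta[3]), 0,
                 -sin(theta[3]), cos(theta[3]), 0, 0, 0, 1), 3)
  Rx %*% Ry %*% Rz
}

rigid_transform_session <- function(session, R, v) {
  fr <- session$frames
  T <- dim(fr)[1]
  out <- array(NA_real_, dim(fr))
  for (j in seq_len(23)) out[, j, ] <- fr[, j, ] %*% t(R) + rep(v, each = T)
  mocap_session(out, session$sample_rate_hz, session$interviewee_id,
                session$session_kind, session$condition)
}

# window_set built directly from a feature matrix (one window per session)
make_window_set <- function(x, ids, kinds, conditions) {
  p <- ncol(x)
  cols <- window_vector_names()
  stopifnot(p <= length(cols))
  full <- matrix(0, nrow(x), length(cols), dimnames = list(NULL, cols))
  full[, seq_len(p)] <- x
  structure(
    list(x = full,
         meta = data.frame(interviewee_id = ids, session_kind = kinds,
                           condition = conditions,
                           window_index = 1L, window_length = "session",
                           stringsAsFactors = FALSE),
         window_length = "session", reference = NULL),
    class = "window_set"
  )
}
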