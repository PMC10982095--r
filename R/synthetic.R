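#' Configuration for the synthetic interview-corpus generator
#'
#' Defines the statistical structure of a simulated seated motion-capture
#' interview study: low-amplitude postural sway on every joint, sparse
#' arm-gesture bursts, paired Game/Wallet sessions per interviewee, and a
#' condition-dependent overall movement multiplier (liars move more). The
#' defaults reproduce the recording conditions the analysis is designed for:
#' roughly 2.5-minute sessions captured at 60 Hz.
#'
#' @param n_interviewees Number of interviewees (even, at least 2); each
#'   contributes one Game and one Wallet session sharing one condition.
#' @param session_length_s Session duration in seconds (default 150).
#' @param sample_rate_hz Recording rate (default 60).
#' @param sway_sd Scale (meters) of the per-frame Gaussian innovations of the
#'   autoregressive postural sway (default 0.002).
#' @param gesture_rate_hz Poisson arrival rate of gesture bursts per second
#'   (default 0.05, i.e. one gesture per 20 s on average).
#' @param gesture_amplitude_m Peak displacement of the hand during a gesture
#'   (default 0.08 m).
#' @param gesture_duration_s Gesture burst duration (default 1 s).
#' @param lie_movement_multiplier Multiplier (>= 0) applied to `sway_sd` and
#'   `gesture_rate_hz` in the lie condition; 1 means no effect (the null).
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_interviewees, session_length_s = 150,
                             sample_rate_hz = 60, sway_sd = 0.002,
                             gesture_rate_hz = 0.05,
                             gesture_amplitude_m = 0.08,
                             gesture_duration_s = 1.0,
                             lie_movement_multiplier = 1.0, seed = 1L) {
  if (n_interviewees < 2L) {
    bc_stop("bc_bad_config", "n_interviewees must be at least 2")
  }
  pos <- c(session_length_s = session_length_s,
           sample_rate_hz = sample_rate_hz, sway_sd = sway_sd,
           gesture_rate_hz = gesture_rate_hz,
           gesture_amplitude_m = gesture_amplitude_m,
           gesture_duration_s = gesture_duration_s)
  if (any(pos <= 0)) {
    bc_stop("bc_bad_config", "all rates, durations and amplitudes must be ",
            "strictly positive")
  }
  if (lie_movement_multiplier < 0) {
    bc_stop("bc_bad_config", "lie_movement_multiplier must be >= 0")
  }
  structure(
    list(n_interviewees = as.integer(n_interviewees),
         session_length_s = session_length_s,
         sample_rate_hz = sample_rate_hz, sway_sd = sway_sd,
         gesture_rate_hz = gesture_rate_hz,
         gesture_amplitude_m = gesture_amplitude_m,
         gesture_duration_s = gesture_duration_s,
         lie_movement_multiplier = lie_movement_multiplier,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Template seated pose
#'
#' A fixed, anatomically plausible seated posture on the canonical skeleton,
#' exactly mirror-symmetric about the sagittal plane through the pelvis
#' (x = 0; y up, z forward, units meters). All synthetic motion is generated
#' as displacements around this pose.
#'
#' @return A 23 x 3 matrix (canonical joint order x x/y/z).
#' @export
template_pose <- function() {
  skel <- canonical_skeleton()
  pose <- rbind(
    Pelvis        = c(0.00, 0.55, 0.00),
    L5            = c(0.00, 0.62, 0.00),
    L3            = c(0.00, 0.72, 0.00),
    T12           = c(0.00, 0.82, 0.00),
    T8            = c(0.00, 0.92, 0.00),
    Neck          = c(0.00, 1.06, 0.00),
    Head          = c(0.00, 1.20, 0.02),
    LeftShoulder  = c(-0.20, 1.00, 0.00),
    LeftElbow     = c(-0.26, 0.76, 0.06),
    LeftWrist     = c(-0.24, 0.58, 0.22),
    LeftHand      = c(-0.22, 0.54, 0.32),
    RightShoulder = c(0.20, 1.00, 0.00),
    RightElbow    = c(0.26, 0.76, 0.06),
    RightWrist    = c(0.24, 0.58, 0.22),
    RightHand     = c(0.22, 0.54, 0.32),
    LeftHip       = c(-0.10, 0.52, 0.02),
    LeftKnee      = c(-0.13, 0.50, 0.46),
    LeftAnkle     = c(-0.13, 0.08, 0.42),
    LeftToe       = c(-0.13, 0.02, 0.58),
    RightHip      = c(0.10, 0.52, 0.02),
    RightKnee     = c(0.13, 0.50, 0.46),
    RightAnkle    = c(0.13, 0.08, 0.42),
    RightToe      = c(0.13, 0.02, 0.58)
  )
  pose <- pose[skel$joints, , drop = FALSE]
  colnames(pose) <- c("x", "y", "z")
  pose
}

# chain weights: gestures displace the whole arm, hand most
GESTURE_WEIGHTS <- c(0.25, 0.5, 0.85, 1.0)

#' Generate one synthetic interview session
#'
#' Motion model: template pose, plus independent AR(1) sway (coefficient 0.99
#' at the recording rate, stationary start) on every joint coordinate, plus
#' Poisson-arriving gesture bursts that displace one arm chain
#' (shoulder-elbow-wrist-hand) along a random direction with a raised-cosine
#' envelope. In the lie condition, the sway innovation scale and the gesture
#' rate are both multiplied by `lie_movement_multiplier`; the template pose
#' is unchanged. The output is fully determined by `seed`.
#'
#' @param config A `synthetic_config`.
#' @param condition `"truth"` or `"lie"`.
#' @param session_kind `"game"` or `"wallet"`.
#' @param interviewee_id Identifier for the session.
#' @param seed Integer seed for this session.
#' @return A `mocap_session`.
#' @export
generate_session <- function(config, condition, session_kind, interviewee_id,
                             seed) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition, c("truth", "lie"))
  session_kind <- match.arg(session_kind, SESSION_KINDS)
  set.seed(as.integer(seed))
  mult <- if (condition == "lie") config$lie_movement_multiplier else 1
  T <- as.integer(round(config$session_length_s * config$sample_rate_hz))
  phi <- 0.99
  s_innov <- config$sway_sd * mult

  # stationary AR(1) per joint coordinate: X_t = phi^t X_0 + sum phi^(t-k) e_k
  innov <- matrix(stats::rnorm(T * 69L, sd = s_innov), T, 69L)
  sway <- stats::filter(innov, phi, method = "recursive")
  x0 <- stats::rnorm(69L, sd = s_innov / sqrt(1 - phi^2))
  sway <- sway + outer(phi^seq_len(T), x0)

  pose <- template_pose()
  frames <- array(rep(pose, each = T), c(T, 23L, 3L)) +
    array(as.numeric(sway), c(T, 23L, 3L))

  # gesture bursts on one arm chain
  n_events <- stats::rpois(1L, config$gesture_rate_hz * mult *
                             config$session_length_s)
  if (n_events > 0L) {
    skel <- canonical_skeleton()
    arm_chains <- list(
      left = match(c("LeftShoulder", "LeftElbow", "LeftWrist", "LeftHand"),
                   skel$joints),
      right = match(c("RightShoulder", "RightElbow", "RightWrist",
                      "RightHand"), skel$joints)
    )
    times <- stats::runif(n_events, 0, config$session_length_s)
    sides <- sample(c("left", "right"), n_events, replace = TRUE)
    for (e in seq_len(n_events)) {
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir * dir))
      t0 <- times[e]
      idx <- which(
        (seq_len(T) - 1) / config$sample_rate_hz >= t0 &
        (seq_len(T) - 1) / config$sample_rate_hz < t0 + config$gesture_duration_s
      )
      if (!length(idx)) next
      phase <- ((idx - 1) / config$sample_rate_hz - t0) / config$gesture_duration_s
      env <- 0.5 * (1 - cos(2 * pi * phase))  # raised cosine, 0 -> 1 -> 0
      chain <- arm_chains[[sides[e]]]
      disp <- config$gesture_amplitude_m * outer(env, dir)  # |idx| x 3
      for (ci in seq_along(chain)) {
        frames[idx, chain[ci], ] <- frames[idx, chain[ci], ] +
          GESTURE_WEIGHTS[ci] * disp
      }
    }
  }
  mocap_session(frames, config$sample_rate_hz, interviewee_id, session_kind,
                condition)
}

#' Generate a balanced synthetic corpus
#'
#' Each interviewee is assigned one condition by a seeded random permutation
#' (half truth, half lie) and recorded in one Game and one Wallet session.
#'
#' @param config A `synthetic_config` with even `n_interviewees`.
#' @return A `mocap_corpus` of `2 * n_interviewees` sessions.
#' @export
#' @examples
#' corp <- generate_corpus(synthetic_config(4, session_length_s = 10, seed = 3))
#' length(corp)
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_interviewees
  if (n %% 2L != 0L) {
    bc_stop("bc_bad_config", "n_interviewees must be even so that truth and ",
            "lie conditions can be balanced; got ", n)
  }
  set.seed(config$seed)
  conditions <- sample(rep(c("truth", "lie"), n / 2L))
  session_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n), n, 2L)
  ids <- sprintf("P%03d", seq_len(n))
  sessions <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    sessions[[2L * i - 1L]] <- generate_session(
      config, conditions[i], "game", ids[i], session_seeds[i, 1])
    sessions[[2L * i]] <- generate_session(
      config, conditions[i], "wallet", ids[i], session_seeds[i, 2])
  }
  mocap_corpus(sessions)
}
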