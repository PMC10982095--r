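#' Temporal resampling by decimation
#'
#' Reduces the recording rate by keeping every (rate/target)-th frame starting
#' at frame 1. Posture analysis does not need the native 60 Hz of inertial
#' capture; the pipeline default downsamples to 5 Hz so that results remain
#' comparable with video-based pose estimation rates.
#'
#' @param session A `mocap_session`.
#' @param target_hz Target rate; must divide `sample_rate_hz` exactly.
#' @return The decimated `mocap_session`.
#' @export
resample_session <- function(session, target_hz = 5) {
  stopifnot(inherits(session, "mocap_session"))
  rate <- session$sample_rate_hz
  if (target_hz <= 0 || abs(rate / target_hz - round(rate / target_hz)) > 1e-9) {
    bc_stop("bc_bad_resample", "sample rate ", rate,
            " is not divisible by target rate ", target_hz)
  }
  step <- as.integer(round(rate / target_hz))
  if (step == 1L) return(session)
  idx <- seq(1L, n_frames(session), by = step)
  session$frames <- session$frames[idx, , , drop = FALSE]
  session$sample_rate_hz <- target_hz
  session
}

#' Express joint positions relative to the root
#'
#' Subtracts the same-frame pelvis position from every joint and drops the
#' pelvis, yielding a body-centred, translation-invariant representation
#' (22 non-root joints x 3 coordinates per frame).
#'
#' @param frames A `T x 23 x 3` array in canonical joint order.
#' @return A `T x 22 x 3` array (non-root joints in canonical order).
#' @export
center_on_root <- function(frames) {
  skel <- canonical_skeleton()
  stopifnot(length(dim(frames)) == 3L, dim(frames)[2] == 23L)
  root_idx <- match(skel$root, skel$joints)
  rel <- frames[, -root_idx, , drop = FALSE] -
    frames[, rep.int(root_idx, 22L), , drop = FALSE]
  dimnames(rel) <- list(NULL, skel$non_root, c("x", "y", "z"))
  rel
}

#' Average segment lengths over a corpus
#'
#' For each of the 22 parent-child segments, the mean Euclidean length over
#' all frames of all sessions. Used to rescale every subject to the same body
#' dimensions; computed once per corpus (no subject-specific knowledge is
#' required).
#'
#' @param corpus A `mocap_corpus` (or list of sessions).
#' @return Named numeric vector of 22 segment lengths (names = child joints).
#' @export
compute_reference_lengths <- function(corpus) {
  if (length(corpus) == 0L) bc_stop("bc_empty_corpus", "empty corpus")
  skel <- canonical_skeleton()
  sums <- numeric(22L)
  n <- 0L
  for (s in corpus) {
    fr <- s$frames
    for (k in seq_along(skel$non_root)) {
      child <- skel$non_root[k]
      par <- skel$parent[[child]]
      d <- fr[, child, ] - fr[, par, ]
      sums[k] <- sums[k] + sum(sqrt(rowSums(d * d)))
    }
    n <- n + dim(fr)[1]
  }
  stats::setNames(sums / n, skel$non_root)
}

#' Rescale segments to reference lengths
#'
#' Rebuilds each posture from the root outward: every joint is placed at its
#' parent's (rebuilt) position plus the original parent-to-joint unit vector
#' times the reference segment length. Joint directions are preserved; all
#' output segment lengths equal the reference lengths exactly (up to floating
#' point).
#'
#' @param rel_frames Root-relative frames (`T x 22 x 3`, from
#'   [center_on_root()]).
#' @param skeleton A `bc_skeleton` (default canonical).
#' @param reference Named segment lengths from [compute_reference_lengths()];
#'   all strictly positive.
#' @return A `T x 22 x 3` array with standardized segment lengths.
#' @export
scale_segments <- function(rel_frames, skeleton = canonical_skeleton(),
                           reference) {
  stopifnot(length(dim(rel_frames)) == 3L, dim(rel_frames)[2] == 22L)
  if (any(reference[skeleton$non_root] <= 0) || anyNA(reference[skeleton$non_root])) {
    bc_stop("bc_bad_reference", "reference lengths must be strictly positive")
  }
  out <- array(0, dim(rel_frames), dimnames = dimnames(rel_frames))
  for (child in topological_joints(skeleton)) {
    par <- skeleton$parent[[child]]
    if (par == skeleton$root) {
      par_in <- 0
      par_out <- 0
    } else {
      par_in <- rel_frames[, par, ]
      par_out <- out[, par, ]
    }
    dir <- rel_frames[, child, ] - par_in
    len <- sqrt(rowSums(dir * dir))
    if (any(len < 1e-12)) {
      bc_stop("bc_zero_segment", "zero-length segment ", par, "->", child,
              ": direction undefined")
    }
    out[, child, ] <- par_out + dir * (reference[[child]] / len)
  }
  out
}

#' Full spatial and temporal normalization of a session
#'
#' Applies, in order: decimation to `target_hz`, root-relative centering, and
#' segment-length standardization. The result is the body-centred, size- and
#' rate-standardized representation that all features are computed on.
#'
#' @param session A `mocap_session`.
#' @param reference Reference segment lengths (typically corpus-wide).
#' @param target_hz Analysis rate (default 5).
#' @param skeleton A `bc_skeleton`.
#' @return An object of class `mocap_norm`: list with `frames`
#'   (`T x 22 x 3`), `sample_rate_hz`, `interviewee_id`, `session_kind`,
#'   `condition`.
#' @export
normalize_session <- function(session, reference, target_hz = 5,
                              skeleton = canonical_skeleton()) {
  s <- resample_session(session, target_hz)
  rel <- center_on_root(s$frames)
  scaled <- scale_segments(rel, skeleton, reference)
  structure(
    list(frames = scaled, sample_rate_hz = s$sample_rate_hz,
         interviewee_id = s$interviewee_id, session_kind = s$session_kind,
         condition = s$condition),
    class = "mocap_norm"
  )
}

#' Normalize a whole corpus
#'
#' Computes corpus-wide reference segment lengths (unless supplied) and
#' normalizes every session.
#'
#' @param corpus A `mocap_corpus`.
#' @param target_hz Analysis rate (default 5).
#' @param reference Optional precomputed reference lengths.
#' @return List with `sessions` (list of `mocap_norm`) and `reference`.
#' @export
normalize_corpus <- function(corpus, target_hz = 5, reference = NULL) {
  if (is.null(reference)) reference <- compute_reference_lengths(corpus)
  skel <- canonical_skeleton()
  list(
    sessions = lapply(corpus, normalize_session, reference = reference,
                      target_hz = target_hz, skeleton = skel),
    reference = reference
  )
}
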