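SESSION_KINDS <- c("game", "wallet")
CONDITIONS <- c("truth", "lie", "unknown")

bc_stop <- function(class, ...) {
  stop(structure(
    class = c(class, "bodycues_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Construct a labeled motion-capture session
#'
#' A session is one recorded interview: a time series of 3D positions for the
#' 23 canonical joints, together with the recording rate and the labels used
#' by the classification pipeline (interviewee identity, session kind,
#' truth/lie condition).
#'
#' @param frames Numeric array of dimension `T x 23 x 3` (frames x joints x
#'   x/y/z coordinate, meters), joints in canonical skeleton order. `T >= 2`,
#'   no missing values.
#' @param sample_rate_hz Sampling rate in frames per second (positive).
#' @param interviewee_id Identifier of the interviewee (coerced to character).
#' @param session_kind `"game"` or `"wallet"`.
#' @param condition `"truth"`, `"lie"`, or `"unknown"` (prediction-only use).
#' @return An object of class `mocap_session`.
#' @export
#' @examples
#' pose <- template_pose()
#' frames <- array(rep(pose, each = 10), c(10, 23, 3))
#' s <- mocap_session(frames, 60, "P001", "game", "truth")
#' n_frames(s)
mocap_session <- function(frames, sample_rate_hz, interviewee_id,
                          session_kind, condition = "unknown") {
  skel <- canonical_skeleton()
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    bc_stop("bc_bad_frames", "frames must be a T x 23 x 3 array")
  }
  d <- dim(frames)
  if (d[2] != 23L || d[3] != 3L) {
    bc_stop("bc_bad_frames", "frames must be T x 23 x 3, got ",
            paste(d, collapse = " x "))
  }
  if (d[1] < 2L) bc_stop("bc_bad_frames", "a session needs at least 2 frames")
  if (anyNA(frames) || !is.numeric(frames)) {
    bc_stop("bc_bad_frames", "frames contain missing or non-numeric values")
  }
  jn <- dimnames(frames)[[2]]
  if (!is.null(jn) && !identical(jn, skel$joints)) {
    bc_stop("bc_bad_frames", "joint axis must follow canonical skeleton order")
  }
  dimnames(frames) <- list(NULL, skel$joints, c("x", "y", "z"))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    bc_stop("bc_bad_rate", "sample_rate_hz must be a positive scalar")
  }
  session_kind <- match.arg(session_kind, SESSION_KINDS)
  condition <- match.arg(condition, CONDITIONS)
  structure(
    list(frames = frames, sample_rate_hz = sample_rate_hz,
         interviewee_id = as.character(interviewee_id),
         session_kind = session_kind, condition = condition),
    class = "mocap_session"
  )
}

#' Number of frames in a session
#' @param session A `mocap_session`.
#' @return Integer frame count.
#' @export
n_frames <- function(session) dim(session$frames)[1]

#' @export
print.mocap_session <- function(x, ...) {
  cat(sprintf("<mocap_session> %s/%s/%s: %d frames @ %g Hz (%.1f s)\n",
              x$interviewee_id, x$session_kind, x$condition,
              n_frames(x), x$sample_rate_hz,
              n_frames(x) / x$sample_rate_hz))
  invisible(x)
}

#' Construct a corpus of sessions
#'
#' Bundles sessions and checks the pairing constraint of the study design:
#' each interviewee has at most one session per kind (Game/Wallet).
#'
#' @param sessions A list of `mocap_session` objects.
#' @return An object of class `mocap_corpus` (a validated list of sessions).
#' @export
mocap_corpus <- function(sessions) {
  stopifnot(is.list(sessions))
  ok <- vapply(sessions, inherits, logical(1), "mocap_session")
  if (!all(ok)) bc_stop("bc_bad_corpus", "all elements must be mocap_session")
  key <- vapply(sessions, function(s) {
    paste(s$interviewee_id, s$session_kind, sep = "\r")
  }, character(1))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    bc_stop("bc_duplicate_session",
            "duplicate (interviewee, kind): ", gsub("\r", "/", dup))
  }
  structure(sessions, class = "mocap_corpus")
}

#' @export
print.mocap_corpus <- function(x, ...) {
  ids <- unique(vapply(x, `[[`, character(1), "interviewee_id"))
  conds <- vapply(x, `[[`, character(1), "condition")
  cat(sprintf("<mocap_corpus> %d sessions, %d interviewees (%d truth / %d lie sessions)\n",
              length(x), length(ids), sum(conds == "truth"),
              sum(conds == "lie")))
  invisible(x)
}

corpus_meta <- function(corpus) {
  data.frame(
    interviewee_id = vapply(corpus, `[[`, character(1), "interviewee_id"),
    session_kind = vapply(corpus, `[[`, character(1), "session_kind"),
    condition = vapply(corpus, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE
  )
}
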