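WINDOW_TYPES <- c("mean", "minimum", "maximum", "range", "standard_deviation")

#' Column names of the 335-dimensional window vector
#'
#' Feature-major order: for each of the 67 features (catalogue order), the
#' five window statistics mean, minimum, maximum, range, standard deviation.
#'
#' @param catalogue A feature catalogue (default: canonical).
#' @return Character vector of 335 names `<feature_id>__<window_type>`.
#' @export
window_vector_names <- function(catalogue = feature_catalogue()) {
  as.vector(vapply(catalogue$feature_id,
                   function(f) paste0(f, "__", WINDOW_TYPES),
                   character(5L)))
}

#' Catalogue expanded to the 335 window-vector columns
#'
#' @param catalogue A feature catalogue.
#' @return Data frame with 335 rows: `column`, `feature_id`, `window_type`,
#'   `feature_type`, `body_parts` (list column), `n_body_parts_class`.
#' @export
window_catalogue <- function(catalogue = feature_catalogue()) {
  idx <- rep(seq_len(nrow(catalogue)), each = 5L)
  out <- data.frame(
    column = window_vector_names(catalogue),
    feature_id = catalogue$feature_id[idx],
    window_type = rep(WINDOW_TYPES, nrow(catalogue)),
    feature_type = catalogue$feature_type[idx],
    n_body_parts_class = catalogue$n_body_parts_class[idx],
    stringsAsFactors = FALSE
  )
  out$body_parts <- catalogue$body_parts[idx]
  out
}

window_bounds <- function(T, rate, window_length) {
  if (identical(window_length, "session")) {
    return(data.frame(lo = 1L, hi = as.integer(T)))
  }
  if (!is.numeric(window_length) || window_length <= 0) {
    bc_stop("bc_bad_window", "window_length must be 'session' or positive seconds")
  }
  n <- as.integer(round(window_length * rate))
  if (n < 2L) {
    bc_stop("bc_bad_window", "window of ", window_length,
            " s holds fewer than 2 samples at ", rate, " Hz")
  }
  k <- T %/% n  # trailing remainder shorter than the window is dropped
  if (k < 1L) {
    bc_stop("bc_bad_window", "session shorter than one window")
  }
  data.frame(lo = (seq_len(k) - 1L) * n + 1L, hi = seq_len(k) * n)
}

window_stats <- function(S) {
  n <- nrow(S)
  m <- colMeans(S)
  mn <- do.call(pmin, c(lapply(seq_len(n), function(i) S[i, ]),
                        list(na.rm = FALSE)))
  mx <- do.call(pmax, lapply(seq_len(n), function(i) S[i, ]))
  dev <- S - rep(m, each = n)
  sd_ <- sqrt(colSums(dev * dev) / (n - 1L))
  rbind(mean = m, minimum = mn, maximum = mx, range = mx - mn,
        standard_deviation = sd_)
}

#' Aggregate feature streams into window vectors
#'
#' Segments the session's feature streams into consecutive non-overlapping
#' windows (a trailing remainder shorter than the window is dropped;
#' `"session"` means one window spanning the recording) and summarizes every
#' feature with the five window statistics, producing one 335-dimensional
#' vector per window. Movement streams, which live on frame pairs, are
#' assigned to windows by the later frame of each pair.
#'
#' @param streams A `feature_streams` object.
#' @param window_length `"session"` or a window length in seconds (the study
#'   grid is 60, 30, 10, 5, 1).
#' @return List with `x` (W x 335 numeric matrix, columns named per
#'   [window_vector_names()]) and `meta` (data frame: `interviewee_id`,
#'   `session_kind`, `condition`, `window_index`, `window_length`).
#' @export
#' @examples
#' cfg <- synthetic_config(n_interviewees = 2, session_length_s = 10, seed = 1)
#' s <- generate_session(cfg, "truth", "game", "P1", seed = 1)
#' norm <- normalize_corpus(mocap_corpus(list(s)))
#' wv <- window_features(extract_features(norm$sessions[[1]]), "session")
#' dim(wv$x)
window_features <- function(streams, window_length = "session") {
  stopifnot(inherits(streams, "feature_streams"))
  T <- nrow(streams$pose)
  rate <- streams$sample_rate_hz
  bounds <- window_bounds(T, rate, window_length)
  Tm <- nrow(streams$movement)
  cols <- window_vector_names()
  fid <- sub("__.*$", "", cols[seq(1L, length(cols), by = 5L)])
  x <- matrix(NA_real_, nrow(bounds), length(cols),
              dimnames = list(NULL, cols))
  for (w in seq_len(nrow(bounds))) {
    lo <- bounds$lo[w]; hi <- bounds$hi[w]
    # movement sample t covers frames (t, t+1): later frame t+1 in [lo, hi]
    mlo <- max(1L, lo - 1L); mhi <- min(Tm, hi - 1L)
    if (mhi - mlo < 1L || hi - lo < 1L) {
      bc_stop("bc_bad_window", "window ", w, " has fewer than 2 samples")
    }
    stats5 <- cbind(window_stats(streams$movement[mlo:mhi, , drop = FALSE]),
                    window_stats(streams$pose[lo:hi, , drop = FALSE]))
    # 5 x 67 in catalogue order -> feature-major 335 vector
    x[w, ] <- as.vector(stats5[, fid])
  }
  list(
    x = x,
    meta = data.frame(
      interviewee_id = streams$interviewee_id,
      session_kind = streams$session_kind,
      condition = streams$condition,
      window_index = seq_len(nrow(bounds)),
      window_length = if (identical(window_length, "session")) "session"
                      else as.character(window_length),
      stringsAsFactors = FALSE
    )
  )
}

#' Window vectors for a whole corpus
#'
#' Runs normalization (resample to `target_hz`, root-centering, segment
#' scaling with corpus-wide reference lengths), feature extraction, and window
#' aggregation for every session, and stacks the results.
#'
#' @param corpus A `mocap_corpus`, or the result of [normalize_corpus()]
#'   (to reuse normalization across window lengths).
#' @param window_length `"session"` or seconds.
#' @param target_hz Analysis rate (default 5).
#' @return An object of class `window_set`: list with `x` (N x 335 matrix),
#'   `meta` (N-row data frame), `window_length`, `reference`.
#' @export
corpus_windows <- function(corpus, window_length = "session", target_hz = 5) {
  if (inherits(corpus, "mocap_corpus")) {
    normed <- normalize_corpus(corpus, target_hz = target_hz)
  } else {
    stopifnot(is.list(corpus), !is.null(corpus$sessions))
    normed <- corpus
  }
  pieces <- lapply(normed$sessions, function(ns) {
    window_features(extract_features(ns), window_length)
  })
  structure(
    list(
      x = do.call(rbind, lapply(pieces, `[[`, "x")),
      meta = do.call(rbind, lapply(pieces, `[[`, "meta")),
      window_length = window_length,
      reference = normed$reference
    ),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d columns (window length: %s)\n",
              nrow(x$x), ncol(x$x), as.character(x$window_length)))
  invisible(x)
}

#' Export a window set as a flat feature matrix CSV
#'
#' @param ws A `window_set`.
#' @param path Output CSV path; metadata columns first, then the 335 window
#'   feature columns named `<feature_id>__<window_type>`.
#' @return `path`, invisibly.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  utils::write.csv(cbind(ws$meta, as.data.frame(ws$x)), path,
                   row.names = FALSE)
  invisible(path)
}
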