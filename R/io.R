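#' Native session CSV dialect
#'
#' Sessions are stored as plain CSV, one row per frame, with columns
#' `<JointName>_x`, `<JointName>_y`, `<JointName>_z` for the 23 canonical
#' joints in canonical order, units meters. A corpus is a directory of such
#' files plus a manifest CSV with header
#' `path,interviewee_id,session_kind,condition`. External recordings whose
#' column names differ are mapped onto the canonical joints through a dialect:
#' a named list `joint name -> character(3)` of x/y/z column names, loadable
#' from a YAML adapter file via [read_dialect()].
#'
#' @return `native_dialect()` returns the identity column mapping.
#' @export
native_dialect <- function() {
  skel <- canonical_skeleton()
  d <- lapply(skel$joints, function(j) paste0(j, c("_x", "_y", "_z")))
  names(d) <- skel$joints
  d
}

#' Read a column-mapping dialect from a YAML adapter file
#'
#' @param path YAML file mapping each canonical joint name to a list/vector of
#'   three external column names (x, y, z).
#' @return A dialect usable with [read_session()].
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) bc_stop("bc_missing_file", "no such file: ", path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cols) {
    cols <- unlist(cols)
    if (length(cols) != 3L) {
      bc_stop("bc_bad_dialect", "each joint needs exactly 3 column names")
    }
    as.character(cols)
  })
}

#' Write a session to CSV
#'
#' @param session A `mocap_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "mocap_session"))
  skel <- canonical_skeleton()
  T <- n_frames(session)
  mat <- matrix(aperm(session$frames, c(1, 3, 2)), nrow = T)
  # columns grouped per joint (x,y,z), full round-trip precision
  colnames(mat) <- as.vector(vapply(
    skel$joints, function(j) paste0(j, c("_x", "_y", "_z")), character(3)
  ))
  txt <- apply(mat, 2, function(col) sprintf("%.17g", col))
  if (T == 1L) txt <- matrix(txt, nrow = 1)
  utils::write.table(txt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = colnames(mat))
  invisible(path)
}

#' Read a session from CSV
#'
#' @param path CSV file path.
#' @param metadata A list with `interviewee_id`, `session_kind`, and
#'   optionally `condition` (defaults `"unknown"`) and `sample_rate_hz`
#'   (defaults 60).
#' @param dialect Column mapping, joint name -> three column names
#'   (default: the native dialect).
#' @return A validated `mocap_session`.
#' @export
read_session <- function(path, metadata, dialect = native_dialect()) {
  if (!file.exists(path)) bc_stop("bc_missing_file", "no such file: ", path)
  skel <- canonical_skeleton()
  df <- utils::read.csv(path, check.names = FALSE)
  missing_joints <- setdiff(skel$joints, names(dialect))
  if (length(missing_joints)) {
    bc_stop("bc_unmapped_joint", "dialect does not map joint(s): ",
            paste(missing_joints, collapse = ", "))
  }
  frames <- array(NA_real_, c(nrow(df), 23L, 3L))
  for (k in seq_along(skel$joints)) {
    j <- skel$joints[k]
    cols <- dialect[[j]]
    absent <- setdiff(cols, names(df))
    if (length(absent)) {
      bc_stop("bc_unmapped_joint", "missing column(s) for joint ", j, ": ",
              paste(absent, collapse = ", "))
    }
    block <- as.matrix(df[cols])
    if (!is.numeric(block)) {
      bc_stop("bc_non_numeric", "non-numeric cells in columns of joint ", j)
    }
    frames[, k, ] <- block
  }
  if (anyNA(frames)) bc_stop("bc_non_numeric", "missing cells in ", path)
  mocap_session(
    frames,
    sample_rate_hz = if (is.null(metadata$sample_rate_hz)) 60 else metadata$sample_rate_hz,
    interviewee_id = metadata$interviewee_id,
    session_kind = metadata$session_kind,
    condition = if (is.null(metadata$condition)) "unknown" else metadata$condition
  )
}

#' Write a corpus and its manifest
#'
#' Each session is written as `<interviewee_id>_<kind>.csv` under `dir`, and a
#' `manifest.csv` with header `path,interviewee_id,session_kind,condition` is
#' written alongside.
#'
#' @param corpus A `mocap_corpus`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "mocap_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(corpus, function(s) {
    fname <- sprintf("%s_%s.csv", s$interviewee_id, s$session_kind)
    write_session(s, file.path(dir, fname))
    data.frame(path = fname, interviewee_id = s$interviewee_id,
               session_kind = s$session_kind, condition = s$condition,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a corpus from a manifest
#'
#' @param path Manifest CSV with header
#'   `path,interviewee_id,session_kind,condition`; session paths are resolved
#'   relative to the manifest's directory.
#' @param sample_rate_hz Recording rate of the stored sessions (default 60).
#' @param dialect Column mapping passed to [read_session()].
#' @return A `mocap_corpus`.
#' @export
read_manifest <- function(path, sample_rate_hz = 60,
                          dialect = native_dialect()) {
  if (!file.exists(path)) bc_stop("bc_missing_file", "no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("path", "interviewee_id", "session_kind", "condition")
  if (!all(needed %in% names(df))) {
    bc_stop("bc_bad_manifest", "manifest must have columns ",
            paste(needed, collapse = ","))
  }
  if (nrow(df) == 0L) {
    warning("empty manifest: returning an empty corpus")
    return(mocap_corpus(list()))
  }
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad)) {
    bc_stop("bc_bad_condition", "unknown condition token(s): ",
            paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df[c("interviewee_id", "session_kind")])) {
    bc_stop("bc_duplicate_session",
            "manifest has duplicate (interviewee_id, session_kind) rows")
  }
  base <- dirname(path)
  sessions <- lapply(seq_len(nrow(df)), function(i) {
    read_session(
      file.path(base, df$path[i]),
      metadata = list(interviewee_id = df$interviewee_id[i],
                      session_kind = df$session_kind[i],
                      condition = df$condition[i],
                      sample_rate_hz = sample_rate_hz),
      dialect = dialect
    )
  })
  mocap_corpus(sessions)
}
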