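.bodycues <- new.env(parent = emptyenv())

#' Canonical 23-joint skeleton
#'
#' The package codes body posture on a fixed 23-joint skeleton with the pelvis
#' as root: an axial chain Pelvis-L5-L3-T12-T8-Neck-Head, arm chains
#' T8-Shoulder-Elbow-Wrist-Hand and leg chains Pelvis-Hip-Knee-Ankle-Toe on
#' each side. Each of the 22 non-root joints belongs to one of six body parts
#' (left/right arm, left/right leg, torso, head); eight left joints have a
#' right mirror counterpart and six axial joints lie on the midline. The
#' definition is shipped as a YAML file so alternative skeletons can be
#' declared without code changes.
#'
#' @param path Path to a skeleton YAML file. Defaults to the definition
#'   shipped with the package.
#' @return An object of class `bc_skeleton`: a list with elements `joints`
#'   (ordered character vector of 23 names), `root`, `parent` (named character
#'   vector over the 22 non-root joints), `body_part` (named character vector),
#'   `mirror_pair` (named character vector, left to right), `midline`
#'   (character vector of 6), and `non_root` (the 22 non-root joints in
#'   canonical order).
#' @export
#' @examples
#' skel <- canonical_skeleton()
#' length(skel$joints)
canonical_skeleton <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bodycues$skeleton)) {
      return(.bodycues$skeleton)
    }
    path <- system.file("extdata", "skeleton.yaml", package = "bodycues",
                        mustWork = TRUE)
  }
  def <- yaml::read_yaml(path)
  skel <- structure(
    list(
      joints = as.character(def$joints),
      root = as.character(def$root),
      parent = unlist(def$parent),
      body_part = unlist(def$body_part),
      mirror_pair = unlist(def$mirror_pair),
      midline = as.character(def$midline)
    ),
    class = "bc_skeleton"
  )
  skel$non_root <- setdiff(skel$joints, skel$root)
  validate_skeleton(skel)
  if (is.null(def$.no_cache)) .bodycues$skeleton <- skel
  skel
}

validate_skeleton <- function(skel) {
  if (length(skel$joints) != 23L) {
    stop("skeleton must have exactly 23 joints, got ", length(skel$joints))
  }
  if (anyDuplicated(skel$joints)) stop("duplicate joint names in skeleton")
  if (!skel$root %in% skel$joints) stop("root joint not among joints")
  if (skel$root %in% names(skel$parent)) stop("root joint must have no parent")
  if (!setequal(names(skel$parent), skel$non_root)) {
    stop("parent map must cover exactly the 22 non-root joints")
  }
  if (!all(skel$parent %in% skel$joints)) stop("unknown parent joint")
  # the parent map must be a tree rooted at the root joint
  for (j in skel$non_root) {
    seen <- character()
    cur <- j
    while (cur != skel$root) {
      if (cur %in% seen) stop("cycle in skeleton parent map at joint ", j)
      seen <- c(seen, cur)
      cur <- skel$parent[[cur]]
    }
  }
  parts <- table(factor(skel$body_part,
                        levels = c("left_arm", "right_arm", "left_leg",
                                   "right_leg", "torso", "head")))
  expected <- c(left_arm = 4L, right_arm = 4L, left_leg = 4L,
                right_leg = 4L, torso = 4L, head = 2L)
  if (!identical(as.integer(parts[names(expected)]), unname(expected))) {
    stop("body-part cardinalities must be arms 4+4, legs 4+4, torso 4, head 2")
  }
  if (length(skel$mirror_pair) != 8L) stop("expected 8 left/right mirror pairs")
  if (length(skel$midline) != 6L) stop("expected 6 midline non-root joints")
  accounted <- c(names(skel$mirror_pair), unname(skel$mirror_pair),
                 skel$midline, skel$root)
  if (!setequal(accounted, skel$joints)) {
    stop("mirror pairs + midline + root must account for all 23 joints")
  }
  invisible(skel)
}

# non-root joints ordered so every parent precedes its children
topological_joints <- function(skel) {
  ordered <- skel$root
  remaining <- skel$non_root
  while (length(remaining)) {
    ready <- remaining[skel$parent[remaining] %in% ordered]
    if (!length(ready)) stop("skeleton parent map is not a tree")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  setdiff(ordered, skel$root)
}

#' @export
print.bc_skeleton <- function(x, ...) {
  cat("Canonical skeleton:", length(x$joints), "joints, root =", x$root, "\n")
  cat("  ", length(x$mirror_pair), "left/right pairs,",
      length(x$midline), "midline joints\n")
  invisible(x)
}
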