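CLASSES <- c("truth", "lie")

#' Fit per-feature Gaussian class models
#'
#' For each class (truth, lie) and each window feature, the sample mean and
#' sample standard deviation (n-1 denominator) over the training windows.
#' A zero class standard deviation is floored at `1e-9` times the feature's
#' pooled training standard deviation (absolute `1e-9` if that is zero too)
#' so that the Gaussian density stays defined.
#'
#' @param x Numeric training matrix, windows x features.
#' @param labels Character/factor vector in `{truth, lie}`, one per row;
#'   both classes need at least 2 samples.
#' @return An object of class `gnb_model`: list with `mu`, `sigma` (raw),
#'   `sigma_eff` (floored) — each a 2 x p matrix with rows `truth`, `lie` —
#'   plus `pooled_sd` and per-class counts `n`.
#' @export
#' @examples
#' m <- fit_gnb(matrix(c(0, 2, 10, 12)), c("truth", "truth", "lie", "lie"))
#' m$mu
fit_gnb <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (!all(labels %in% CLASSES)) {
    bc_stop("bc_bad_labels", "labels must be 'truth' or 'lie'")
  }
  n_c <- c(truth = sum(labels == "truth"), lie = sum(labels == "lie"))
  if (any(n_c < 2L)) {
    bc_stop("bc_class_absent",
            "need at least 2 training samples per class; got truth=",
            n_c[["truth"]], ", lie=", n_c[["lie"]])
  }
  mu <- rbind(truth = colMeans(x[labels == "truth", , drop = FALSE]),
              lie = colMeans(x[labels == "lie", , drop = FALSE]))
  sdev <- function(cls) {
    xs <- x[labels == cls, , drop = FALSE]
    dev <- xs - rep(mu[cls, ], each = nrow(xs))
    sqrt(colSums(dev * dev) / (nrow(xs) - 1L))
  }
  sigma <- rbind(truth = sdev("truth"), lie = sdev("lie"))
  dev_all <- x - rep(colMeans(x), each = nrow(x))
  pooled_sd <- sqrt(colSums(dev_all * dev_all) / (nrow(x) - 1L))
  floor_ <- 1e-9 * ifelse(pooled_sd > 0, pooled_sd, 1)
  sigma_eff <- pmax(sigma, rep(floor_, each = 2L))
  structure(
    list(mu = mu, sigma = sigma, sigma_eff = sigma_eff,
         pooled_sd = pooled_sd, n = n_c,
         features = colnames(x)),
    class = "gnb_model"
  )
}

gnb_log_scores <- function(model, newx, class) {
  mu <- model$mu[class, ]
  s <- model$sigma_eff[class, ]
  n <- nrow(newx)
  dev <- newx - rep(mu, each = n)
  -rep(log(s), each = n) - dev * dev / rep(2 * s * s, each = n)
}

#' Per-feature class votes
#'
#' Evaluates, for every test window and feature, which class has the larger
#' Gaussian density at the observed value (equal class priors). Exact density
#' ties vote truth — the deterministic, conservative direction.
#'
#' @param model A fitted `gnb_model`.
#' @param newx Test matrix, windows x features (same columns as training).
#' @return Logical matrix, same shape as `newx`: `TRUE` = truth vote.
#' @export
gnb_votes <- function(model, newx) {
  newx <- as.matrix(newx)
  gnb_log_scores(model, newx, "truth") >= gnb_log_scores(model, newx, "lie")
}

#' Classify a single feature value
#'
#' @param model A fitted `gnb_model`.
#' @param i Feature index (or column name).
#' @param x_i Observed feature value(s).
#' @return `"truth"` or `"lie"` per value.
#' @export
#' @examples
#' m <- fit_gnb(matrix(c(0, 2, 10, 12)), c("truth", "truth", "lie", "lie"))
#' classify_feature(m, 1, 3)
classify_feature <- function(model, i, x_i) {
  st <- -log(model$sigma_eff["truth", i]) -
    (x_i - model$mu["truth", i])^2 / (2 * model$sigma_eff["truth", i]^2)
  sl <- -log(model$sigma_eff["lie", i]) -
    (x_i - model$mu["lie", i])^2 / (2 * model$sigma_eff["lie", i]^2)
  unname(ifelse(st >= sl, "truth", "lie"))
}

#' Two-sample p-values per feature
#'
#' Column-wise two-sample test of the truth vs. lie training distributions,
#' used for the significance-filtered feature sets (stat-95, stat-99) and for
#' significance ranking. Default is Welch's t-test (unequal variances);
#' Student's t and the Wilcoxon rank-sum test are available. Features that
#' are constant within both classes get p = 1.
#'
#' @param x Training matrix, windows x features.
#' @param labels `{truth, lie}` per row.
#' @param method `"welch"`, `"student"`, or `"wilcoxon"`.
#' @return Numeric vector of p-values, one per column.
#' @export
feature_pvalues <- function(x, labels, method = c("welch", "student",
                                                  "wilcoxon")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.character(labels)
  x1 <- x[labels == "truth", , drop = FALSE]
  x2 <- x[labels == "lie", , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2L || n2 < 2L) bc_stop("bc_class_absent", "need 2 samples per class")
  if (method == "wilcoxon") {
    p <- vapply(seq_len(ncol(x)), function(j) {
      if (stats::var(x1[, j]) == 0 && stats::var(x2[, j]) == 0 &&
          x1[1, j] == x2[1, j]) return(1)
      suppressWarnings(stats::wilcox.test(x1[, j], x2[, j])$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    return(p)
  }
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1L)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1L)
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  } else {
    vp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(se2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 | !is.finite(tstat)] <- 1  # degenerate: no evidence of difference
  p
}

#' Significance-based feature selection
#'
#' Selects the window features whose truth/lie training distributions differ
#' at level `alpha` (p < alpha). `alpha = 0.05` and `0.01` give the stat-95
#' and stat-99 sets; `alpha >= 1` keeps all features.
#'
#' @inheritParams feature_pvalues
#' @param alpha Significance level; `1` (or more) selects everything.
#' @return List with `selected` (integer indices), `alpha`, `p` (all
#'   p-values).
#' @export
select_features <- function(x, labels, alpha = 0.05,
                            method = c("welch", "student", "wilcoxon")) {
  p <- feature_pvalues(x, labels, method)
  selected <- if (alpha >= 1) seq_along(p) else which(p < alpha)
  list(selected = selected, alpha = alpha, p = p)
}

#' Order features by significance
#'
#' Ascending p-value; ties broken by canonical (catalogue) order, so top-k
#' lists are prefixes of each other.
#'
#' @param p Numeric p-values in canonical feature order.
#' @return Integer permutation of `seq_along(p)`.
#' @export
sort_features_by_significance <- function(p) {
  order(p, seq_along(p))
}

#' Majority vote over per-feature class estimates
#'
#' @param votes Logical vector (`TRUE` = truth) of per-feature votes.
#' @param selected Indices of the features allowed to vote (non-empty).
#' @return `"truth"` if at least half the votes are truth (exact ties are
#'   resolved as truth), else `"lie"`.
#' @export
majority_vote <- function(votes, selected = seq_along(votes)) {
  if (length(selected) == 0L) bc_stop("bc_empty_selection", "no features to vote")
  v <- votes[selected]
  if (2L * sum(v) >= length(v)) "truth" else "lie"
}

fold_ids <- function(meta) unique(meta$interviewee_id)

#' Leave-one-interviewee-out cross-validated detection rate
#'
#' For each interviewee in turn: fit the per-feature Gaussian models and the
#' feature selection on all windows of the remaining interviewees (restricted
#' to `train_kinds`), then classify every window of the held-out interviewee
#' (restricted to `test_kinds`) by significance-filtered majority voting.
#' The detection rate is the mean of the per-fold accuracies.
#'
#' @param ws A `window_set` with known conditions.
#' @param train_kinds,test_kinds Subsets of `c("game", "wallet")`.
#' @param alpha Significance level for feature selection (`1` = all features).
#' @param top_k If non-`NULL`, use the `top_k` most significant training
#'   features instead of the alpha threshold.
#' @param method Two-sample test for selection/ranking.
#' @return List with `rate` (mean per-fold accuracy in [0, 1]), `folds`
#'   (per-fold data frame: id, n_test, n_selected, accuracy), and
#'   `predictions` (per-window data frame with `true` and `predicted`).
#' @export
loocv <- function(ws, train_kinds = c("game", "wallet"),
                  test_kinds = c("game", "wallet"), alpha = 0.05,
                  top_k = NULL, method = "welch") {
  folds <- gnb_loocv_folds(ws, train_kinds = train_kinds, method = method)
  score_folds(folds, test_kinds = test_kinds, alpha = alpha, top_k = top_k)
}

# One pass over the LOOCV folds: per held-out interviewee, the training
# p-values and the per-feature votes for all of that interviewee's windows
# (every kind; restrictions are applied when scoring). Also keeps what the
# noise experiment needs to re-vote on perturbed test windows.
gnb_loocv_folds <- function(ws, train_kinds = c("game", "wallet"),
                            method = "welch", keep_models = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  meta <- ws$meta
  if (any(meta$condition == "unknown")) {
    bc_stop("bc_bad_labels", "cross-validation needs known conditions")
  }
  ids <- fold_ids(meta)
  if (length(ids) < 2L) bc_stop("bc_too_few", "need at least 2 interviewees")
  lapply(ids, function(id) {
    tr <- meta$interviewee_id != id & meta$session_kind %in% train_kinds
    te <- meta$interviewee_id == id
    # leakage guard: training and test interviewees must be disjoint
    stopifnot(!any(meta$interviewee_id[tr] == id))
    if (!any(te)) return(NULL)
    model <- fit_gnb(ws$x[tr, , drop = FALSE], meta$condition[tr])
    p <- feature_pvalues(ws$x[tr, , drop = FALSE], meta$condition[tr],
                         method = method)
    list(
      id = id,
      p = p,
      votes = gnb_votes(model, ws$x[te, , drop = FALSE]),
      test_meta = meta[te, , drop = FALSE],
      test_x = if (keep_models) ws$x[te, , drop = FALSE] else NULL,
      model = if (keep_models) model else NULL
    )
  })
}

# Scores precomputed folds for one (test restriction, selection rule),
# optionally with per-fold vote matrices overridden (noise experiment) or
# the vote columns restricted (breakdowns).
score_folds <- function(folds, test_kinds = c("game", "wallet"),
                        alpha = 0.05, top_k = NULL, columns = NULL,
                        votes_override = NULL) {
  rows <- list()
  preds <- list()
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    if (is.null(f)) next
    keep <- f$test_meta$session_kind %in% test_kinds
    if (!any(keep)) next  # interviewee has no session of the requested kind
    votes <- if (is.null(votes_override)) f$votes else votes_override[[k]]
    votes <- votes[keep, , drop = FALSE]
    tm <- f$test_meta[keep, , drop = FALSE]
    if (is.null(top_k)) {
      sel <- if (alpha >= 1) seq_along(f$p) else which(f$p < alpha)
    } else {
      sel <- sort_features_by_significance(f$p)[seq_len(top_k)]
    }
    if (!is.null(columns)) sel <- intersect(sel, columns)
    if (length(sel) == 0L) {
      bc_stop("bc_empty_selection", "fold ", f$id,
              ": empty feature selection")
    }
    pred <- apply(votes[, sel, drop = FALSE], 1,
                  function(v) if (2L * sum(v) >= length(v)) "truth" else "lie")
    acc <- mean(pred == tm$condition)
    rows[[length(rows) + 1L]] <- data.frame(
      interviewee_id = f$id, n_test = nrow(tm), n_selected = length(sel),
      accuracy = acc, stringsAsFactors = FALSE
    )
    preds[[length(preds) + 1L]] <- cbind(
      tm[c("interviewee_id", "session_kind", "window_index")],
      data.frame(true = tm$condition, predicted = pred,
                 stringsAsFactors = FALSE)
    )
  }
  if (!length(rows)) bc_stop("bc_too_few", "no folds could be scored")
  folds_df <- do.call(rbind, rows)
  list(rate = mean(folds_df$accuracy), folds = folds_df,
       predictions = do.call(rbind, preds))
}

#' Confusion matrix of cross-validated predictions
#'
#' @param result A [loocv()] result.
#' @return A 2 x 2 matrix of percentages (actual truth/lie x guessed
#'   truth/lie) summing to 100.
#' @export
confusion_matrix <- function(result) {
  pr <- result$predictions
  tab <- table(factor(pr$true, CLASSES), factor(pr$predicted, CLASSES))
  100 * tab / sum(tab)
}
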