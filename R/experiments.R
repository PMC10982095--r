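#' Train/test set crossings
#'
#' Cross-validated detection rates for every combination of training set,
#' test set (both sessions / Game only / Wallet only) and feature set (all /
#' stat-95 / stat-99), using one feature vector per session (whole-session
#' windows reproduce the headline protocol).
#'
#' @param ws A `window_set` (typically whole-session windows).
#' @param alphas Feature-selection levels; `1` = all features.
#' @param method Two-sample test for selection.
#' @return Data frame with columns `train`, `test`, `alpha`, `rate` (the
#'   detection rate in [0, 1]) and `mean_n_selected`.
#' @export
run_crossings <- function(ws, alphas = c(1, 0.05, 0.01), method = "welch") {
  kinds <- list(both = c("game", "wallet"), game = "game", wallet = "wallet")
  out <- list()
  for (tr in names(kinds)) {
    folds <- gnb_loocv_folds(ws, train_kinds = kinds[[tr]], method = method)
    for (te in names(kinds)) {
      for (a in alphas) {
        res <- score_folds(folds, test_kinds = kinds[[te]], alpha = a)
        out[[length(out) + 1L]] <- data.frame(
          train = tr, test = te, alpha = a, rate = res$rate,
          mean_n_selected = mean(res$folds$n_selected),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Window-length sweep
#'
#' Detection rate as a function of the aggregation window length, for each
#' feature-selection level. Every window is classified and scored
#' independently (window-level accuracy).
#'
#' @param corpus A `mocap_corpus` or the result of [normalize_corpus()].
#' @param lengths Window lengths: `"session"` and/or seconds (study grid:
#'   session, 60, 30, 10, 5, 1).
#' @param alphas Selection levels.
#' @param target_hz Analysis rate.
#' @param method Two-sample test.
#' @return Data frame `window_length`, `alpha`, `rate`, `n_windows`.
#' @export
run_window_sweep <- function(corpus, lengths = list("session", 60, 30, 10, 5, 1),
                             alphas = c(1, 0.05, 0.01), target_hz = 5,
                             method = "welch") {
  normed <- if (inherits(corpus, "mocap_corpus")) {
    normalize_corpus(corpus, target_hz = target_hz)
  } else corpus
  out <- list()
  for (len in lengths) {
    ws <- corpus_windows(normed, window_length = len, target_hz = target_hz)
    folds <- gnb_loocv_folds(ws, method = method)
    for (a in alphas) {
      res <- score_folds(folds, alpha = a)
      out[[length(out) + 1L]] <- data.frame(
        window_length = as.character(len), alpha = a, rate = res$rate,
        n_windows = nrow(ws$x), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

category_columns <- function(wcat) {
  cats <- list()
  for (ft in unique(wcat$feature_type)) {
    cats[[paste0("feature_type:", ft)]] <- which(wcat$feature_type == ft)
  }
  for (wt in WINDOW_TYPES) {
    cats[[paste0("window_type:", wt)]] <- which(wcat$window_type == wt)
  }
  parts <- c("left_arm", "right_arm", "left_leg", "right_leg", "torso", "head")
  for (p in parts) {
    cats[[paste0("body_part:", p)]] <-
      which(vapply(wcat$body_parts, function(b) p %in% b, logical(1)))
  }
  for (cl in c("single", "two", "all")) {
    cats[[paste0("n_body_parts:", cl)]] <- which(wcat$n_body_parts_class == cl)
  }
  cats
}

#' Category breakdowns of selection and classification
#'
#' For each feature category (feature type, window type, linked body part,
#' number of involved body parts): the percentage of the category's window
#' features present in the stat-95 selection (averaged over cross-validation
#' folds), and the detection rate obtained by majority voting over the
#' selected features of that category only, tested on both/Game/Wallet
#' sessions (training on both).
#'
#' @param ws A `window_set`.
#' @param alpha Selection level (default stat-95).
#' @param method Two-sample test.
#' @return Data frame `category`, `value`, `n_columns`, `selected_pct`,
#'   `rate_both`, `rate_game`, `rate_wallet`.
#' @export
run_breakdowns <- function(ws, alpha = 0.05, method = "welch") {
  wcat <- window_catalogue()
  cats <- category_columns(wcat)
  folds <- gnb_loocv_folds(ws, method = method)
  live <- Filter(Negate(is.null), folds)
  sel_sets <- lapply(live, function(f) which(f$p < alpha))
  out <- list()
  for (nm in names(cats)) {
    cols <- cats[[nm]]
    sel_pct <- mean(vapply(sel_sets, function(s) {
      100 * length(intersect(s, cols)) / length(cols)
    }, numeric(1)))
    rates <- vapply(list(c("game", "wallet"), "game", "wallet"), function(tk) {
      score_folds(folds, test_kinds = tk, alpha = alpha, columns = cols)$rate
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      category = sub(":.*$", "", nm), value = sub("^.*:", "", nm),
      n_columns = length(cols), selected_pct = sel_pct,
      rate_both = rates[1], rate_game = rates[2], rate_wallet = rates[3],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Top-k feature-count sweep
#'
#' Detection rate when majority voting is restricted, per fold, to the k
#' training features with the smallest two-sample p-values, for k = 1..k_max.
#'
#' @param ws A `window_set`.
#' @param k_max Largest feature count (<= 335; study grid: 200).
#' @param test_kinds Test restriction.
#' @param method Two-sample test.
#' @return Data frame `k`, `rate`.
#' @export
run_topk_sweep <- function(ws, k_max = 200, test_kinds = c("game", "wallet"),
                           method = "welch") {
  stopifnot(k_max >= 1, k_max <= 335)
  folds <- gnb_loocv_folds(ws, method = method)
  acc <- matrix(NA_real_, 0, k_max)
  for (f in folds) {
    if (is.null(f)) next
    keep <- f$test_meta$session_kind %in% test_kinds
    if (!any(keep)) next
    ord <- sort_features_by_significance(f$p)[seq_len(k_max)]
    v <- f$votes[keep, ord, drop = FALSE]
    cum <- t(apply(v, 1, cumsum))  # truth votes among top-k, per window
    if (sum(keep) == 1L) cum <- matrix(cum, nrow = 1)
    ks <- rep(seq_len(k_max), each = sum(keep))
    pred_truth <- 2 * cum >= ks
    truth_actual <- f$test_meta$condition[keep] == "truth"
    correct <- pred_truth == truth_actual
    acc <- rbind(acc, colMeans(correct))
  }
  data.frame(k = seq_len(k_max), rate = colMeans(acc))
}

#' Cross-validated rate of every individual feature
#'
#' Removes the majority voting: each of the 335 window features classifies
#' alone, and its per-fold accuracy is averaged over the folds. Also reports
#' how often each feature enters the stat-95 selection.
#'
#' @param ws A `window_set`.
#' @param test_kinds Test restriction.
#' @param alpha Level used for the selection-frequency column.
#' @param method Two-sample test.
#' @return Data frame sorted by decreasing rate (ties in canonical order):
#'   `column`, `feature_id`, `window_type`, `feature_type`, `body_parts`,
#'   `rate`, `selected_freq`.
#' @export
run_per_feature_ranking <- function(ws, test_kinds = c("game", "wallet"),
                                    alpha = 0.05, method = "welch") {
  wcat <- window_catalogue()
  folds <- gnb_loocv_folds(ws, method = method)
  accs <- list()
  sel <- list()
  for (f in folds) {
    if (is.null(f)) next
    keep <- f$test_meta$session_kind %in% test_kinds
    if (!any(keep)) next
    truth_actual <- f$test_meta$condition[keep] == "truth"
    correct <- f$votes[keep, , drop = FALSE] == truth_actual
    accs[[length(accs) + 1L]] <- colMeans(correct)
    sel[[length(sel) + 1L]] <- f$p < alpha
  }
  rate <- colMeans(do.call(rbind, accs))
  freq <- colMeans(do.call(rbind, sel))
  out <- data.frame(
    column = wcat$column, feature_id = wcat$feature_id,
    window_type = wcat$window_type, feature_type = wcat$feature_type,
    body_parts = vapply(wcat$body_parts, paste, character(1), collapse = ";"),
    rate = rate, selected_freq = freq, stringsAsFactors = FALSE
  )
  out[order(-out$rate, seq_len(nrow(out))), ]
}

#' Measurement-noise robustness experiment
#'
#' Adds seeded zero-mean Gaussian noise to every test-window feature value,
#' with standard deviation `r` times that feature's pooled training standard
#' deviation (computed per fold), re-classifies, and averages the detection
#' rate over repetitions. `r = 0` reproduces the noiseless rates exactly.
#'
#' @param ws A `window_set`.
#' @param r_list Noise factors (>= 0).
#' @param repetitions Number of noise draws per factor (study value: 100).
#' @param seed Integer seed for the noise stream.
#' @param alphas Selection levels.
#' @param sd_basis `"pooled"` (class-agnostic training sd, default) or
#'   `"class"` (sd of the test window's true class).
#' @param method Two-sample test.
#' @return Data frame `r`, `alpha`, `rate` (mean over repetitions).
#' @export
run_noise_experiment <- function(ws, r_list = c(0, 0.5, 1, 2),
                                 repetitions = 100, seed = 1,
                                 alphas = c(1, 0.05, 0.01),
                                 sd_basis = c("pooled", "class"),
                                 method = "welch") {
  sd_basis <- match.arg(sd_basis)
  stopifnot(all(r_list >= 0), repetitions >= 1)
  folds <- gnb_loocv_folds(ws, method = method, keep_models = TRUE)
  out <- list()
  for (r in r_list) {
    rates <- matrix(NA_real_, repetitions, length(alphas))
    set.seed(as.integer(seed))
    for (rep_i in seq_len(repetitions)) {
      votes_override <- lapply(folds, function(f) {
        if (is.null(f)) return(NULL)
        m <- nrow(f$test_x)
        noise_sd <- if (sd_basis == "pooled") {
          matrix(rep(f$model$pooled_sd, each = m), m)
        } else {
          f$model$sigma[f$test_meta$condition, , drop = FALSE]
        }
        noisy <- f$test_x + r * noise_sd *
          matrix(stats::rnorm(length(f$test_x)), m)
        gnb_votes(f$model, noisy)
      })
      for (ai in seq_along(alphas)) {
        rates[rep_i, ai] <- score_folds(folds, alpha = alphas[ai],
                                        votes_override = votes_override)$rate
      }
    }
    for (ai in seq_along(alphas)) {
      out[[length(out) + 1L]] <- data.frame(r = r, alpha = alphas[ai],
                                            rate = mean(rates[, ai]))
    }
  }
  do.call(rbind, out)
}

#' Plot a detection-rate curve
#'
#' Convenience ggplot2 wrapper for the sweep results (rate vs. window length,
#' noise factor, or feature count).
#'
#' @param df A sweep result data frame.
#' @param xvar Name of the x column (e.g. `"k"`, `"r"`, `"window_length"`).
#' @param group Optional grouping column (e.g. `"alpha"`).
#' @return A ggplot object.
#' @export
plot_rate_curve <- function(df, xvar, group = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rate_curve needs the ggplot2 package")
  }
  df$rate_pct <- 100 * df$rate
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data[[xvar]], y = .data$rate_pct)
  } else {
    ggplot2::aes(x = .data[[xvar]], y = .data$rate_pct,
                 colour = factor(.data[[group]]), group = .data[[group]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "Detection rate (%)", colour = group) +
    ggplot2::theme_minimal()
}
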