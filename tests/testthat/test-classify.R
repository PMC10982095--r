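test_that("per-class Gaussian fits match hand arithmetic and a reference", {
  x <- matrix(c(0, 2, 10, 12), ncol = 1)
  m <- fit_gnb(x, c("truth", "truth", "lie", "lie"))
  expect_equal(m$mu["truth", 1], 1, ignore_attr = TRUE)
  expect_equal(m$mu["lie", 1], 11, ignore_attr = TRUE)
  expect_equal(m$sigma["truth", 1], sqrt(2), ignore_attr = TRUE)
  expect_equal(m$sigma["lie", 1], sqrt(2), ignore_attr = TRUE)

  # refitting is deterministic
  expect_identical(fit_gnb(x, c("truth", "truth", "lie", "lie")), m)

  # agrees with stats::sd / mean on random data
  set.seed(2)
  xr <- matrix(stats::rnorm(100 * 4), 100)
  lab <- rep(c("truth", "lie"), 50)
  mr <- fit_gnb(xr, lab)
  for (j in 1:4) {
    expect_equal(mr$mu["truth", j], mean(xr[lab == "truth", j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(mr$sigma["lie", j], stats::sd(xr[lab == "lie", j]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(fit_gnb(xr, rep("truth", 100)), class = "bc_class_absent")
})

test_that("per-feature decisions maximize the Gaussian density with truth ties", {
  m <- list(mu = rbind(truth = 0, lie = 2),
            sigma_eff = rbind(truth = 1, lie = 1))
  class(m) <- "gnb_model"
  # at the truth mean
  expect_equal(classify_feature(m, 1, 0), "truth")
  # exact midpoint tie resolves truth
  expect_equal(classify_feature(m, 1, 1), "truth")
  expect_equal(classify_feature(m, 1, 1.0001), "lie")

  # unequal variances: N(3; 0, 1) ~ 0.00443 < N(3; 0, 2) ~ 0.0648
  m2 <- list(mu = rbind(truth = 0, lie = 0),
             sigma_eff = rbind(truth = 1, lie = 2))
  class(m2) <- "gnb_model"
  expect_equal(classify_feature(m2, 1, 3), "lie")
  expect_equal(classify_feature(m2, 1, 0), "truth")
})

test_that("vote matrix agrees with a dnorm log-density oracle", {
  set.seed(7)
  n <- 2000
  mu_t <- stats::rnorm(n); mu_l <- stats::rnorm(n)
  s_t <- stats::rexp(n) + 0.01; s_l <- stats::rexp(n) + 0.01
  x <- stats::rnorm(n, sd = 2)
  m <- list(mu = rbind(truth = mu_t, lie = mu_l),
            sigma_eff = rbind(truth = s_t, lie = s_l))
  class(m) <- "gnb_model"
  votes <- gnb_votes(m, matrix(x, nrow = 1))
  oracle <- stats::dnorm(x, mu_t, s_t, log = TRUE) >=
    stats::dnorm(x, mu_l, s_l, log = TRUE)
  expect_identical(as.vector(votes), oracle)
})

test_that("equal-sigma decisions split at the midpoint of the class means", {
  set.seed(13)
  for (i in 1:20) {
    mu_t <- stats::rnorm(1); mu_l <- stats::rnorm(1); s <- stats::rexp(1) + 0.1
    if (abs(mu_t - mu_l) < 1e-6) next
    m <- list(mu = rbind(truth = mu_t, lie = mu_l),
              sigma_eff = rbind(truth = s, lie = s))
    class(m) <- "gnb_model"
    mid <- (mu_t + mu_l) / 2
    eps <- 1e-6 * sign(mu_t - mu_l)
    expect_equal(classify_feature(m, 1, mid + eps), "truth")
    expect_equal(classify_feature(m, 1, mid - eps), "lie")
  }
})

test_that("zero-variance features stay classifiable via the sigma floor", {
  x <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1)
  m <- fit_gnb(x, c("truth", "truth", "truth", "lie", "lie", "lie"))
  expect_true(all(m$sigma_eff > 0))
  expect_equal(classify_feature(m, 1, 1), "truth")
  expect_equal(classify_feature(m, 1, 2), "lie")
})

test_that("two-sample p-values match stats::t.test and handle degeneracy", {
  set.seed(17)
  x <- matrix(stats::rnorm(60 * 6), 60)
  x[, 3] <- x[, 3] + rep(c(0, 1.5), each = 30)[seq_len(60)]
  lab <- rep(c("truth", "lie"), each = 30)
  p_w <- feature_pvalues(x, lab, method = "welch")
  p_s <- feature_pvalues(x, lab, method = "student")
  for (j in 1:6) {
    expect_equal(p_w[j],
                 stats::t.test(x[lab == "truth", j], x[lab == "lie", j])$p.value,
                 tolerance = 1e-12)
    expect_equal(p_s[j],
                 stats::t.test(x[lab == "truth", j], x[lab == "lie", j],
                               var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # identical multisets in the two classes: p = 1 under Welch (t = 0)
  same <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1)
  p_same <- feature_pvalues(same, rep(c("truth", "lie"), each = 4))
  expect_equal(p_same, 1)
  # constant in both classes: degenerate, p = 1
  const <- matrix(5, 8, 1)
  expect_equal(feature_pvalues(const, rep(c("truth", "lie"), each = 4)), 1)
})

test_that("significance selection separates shifted features and nests by alpha", {
  set.seed(19)
  x <- cbind(
    shifted = c(stats::rnorm(50, 0), stats::rnorm(50, 10)),
    null1 = stats::rnorm(100),
    null2 = stats::rnorm(100)
  )
  lab <- rep(c("truth", "lie"), each = 50)
  sel01 <- select_features(x, lab, alpha = 0.01)
  expect_true(1 %in% sel01$selected)
  sel05 <- select_features(x, lab, alpha = 0.05)
  expect_true(all(sel01$selected %in% sel05$selected))
  expect_equal(select_features(x, lab, alpha = 1)$selected, 1:3)

  # nesting holds for arbitrary random data too
  for (seed in 1:5) {
    set.seed(seed)
    xr <- matrix(stats::rnorm(40 * 20), 40)
    labr <- rep(c("truth", "lie"), 20)
    s99 <- select_features(xr, labr, 0.01)$selected
    s95 <- select_features(xr, labr, 0.05)$selected
    expect_true(all(s99 %in% s95))
  }
})

test_that("significance ordering is ascending with canonical tie-breaks", {
  expect_equal(sort_features_by_significance(c(0.5, 0.001, 0.2)), c(2, 3, 1))
  expect_equal(sort_features_by_significance(c(0.2, 0.1, 0.2, 0.1)),
               c(2, 4, 1, 3))
  p <- stats::runif(50)
  ord <- sort_features_by_significance(p)
  expect_equal(ord[1:10], sort_features_by_significance(p)[1:10])
})

test_that("majority voting counts selected features with a truth tie rule", {
  expect_equal(majority_vote(c(TRUE, TRUE, FALSE)), "truth")
  expect_equal(majority_vote(c(TRUE, FALSE)), "truth")
  expect_equal(majority_vote(c(FALSE, FALSE, TRUE)), "lie")
  expect_equal(majority_vote(rep(c(TRUE, FALSE), c(2, 5)), selected = 1:3),
               "truth")
  expect_error(majority_vote(logical(0)), class = "bc_empty_selection")
})

test_that("leave-one-interviewee-out classification separates a clean signal", {
  set.seed(23)
  n <- 10
  ids <- rep(sprintf("P%02d", 1:n), each = 2)
  kinds <- rep(c("game", "wallet"), n)
  cond <- rep(rep(c("truth", "lie"), n / 2), each = 2)
  x <- matrix(stats::rnorm(2 * n * 3), ncol = 3)
  x <- x + ifelse(cond == "lie", 8, 0)  # three cleanly separated features
  ws <- make_window_set(x, ids, kinds, cond)
  res <- loocv(ws, alpha = 0.05)
  expect_equal(res$rate, 1)
  expect_equal(nrow(res$folds), n)
  # kind restrictions score only matching windows
  res_g <- loocv(ws, test_kinds = "game", alpha = 0.05)
  expect_true(all(res_g$predictions$session_kind == "game"))
  # detection rate is invariant to session order in the corpus
  perm <- sample(nrow(x))
  ws2 <- make_window_set(x[perm, ], ids[perm], kinds[perm], cond[perm])
  expect_equal(loocv(ws2, alpha = 0.05)$rate, res$rate)
  # confusion matrix percentages sum to 100
  cm <- confusion_matrix(res)
  expect_equal(sum(cm), 100)
  expect_error(loocv(make_window_set(x[1:2, ], ids[1:2], kinds[1:2],
                                     cond[1:2])),
               class = "bc_too_few")
})
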