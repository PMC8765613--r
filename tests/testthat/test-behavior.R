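# Accuracy-linked analyses: balanced outcome differences, bootstrap
# accuracy-amplitude correlations, linear-SVM separability.

# tensor with bands 5/20/85 Hz where correct trials carry `gain` on the
# chosen bands
outcome_tensor <- function(n_tr = 60, gain = 1.5, gain_bands = c(2, 3),
                           seed = 1, noise = 0.3) {
  set.seed(seed)
  correct <- rep(c(TRUE, FALSE), length.out = n_tr)
  ta <- seq(-1, 3, length.out = 120)
  amp <- array(abs(rnorm(n_tr * 3 * 120, mean = 1, sd = noise)), c(n_tr, 3, 120))
  for (b in gain_bands) amp[correct, b, ] <- amp[correct, b, ] * gain
  make_tensor(amp, ta, c(5, 20, 85),
              meta = data.frame(trial = 1:n_tr, correct = correct))
}

test_that("balanced outcome differences isolate the gained bands", {
  tz <- outcome_tensor(gain = 1.5, gain_bands = c(2, 3), seed = 2)
  res <- balanced_outcome_difference(tz, n_each = 30, reps = 200, seed = 3)
  # calibrated bootstrap-z reading: effect only in the gained bands
  expect_gt(res$bootstrap_z$theta$p, 0.05)
  expect_lt(res$bootstrap_z$beta$p, 1e-6)
  expect_lt(res$bootstrap_z$gamma$p, 1e-6)
  expect_gt(res$t_vs_zero$beta$mean, 0)
  expect_lt(res$t_vs_zero$beta$p, 1e-10)   # conventional t agrees on effects
  # null: the mean difference stays within 3 bootstrap SEs of 0
  tz0 <- outcome_tensor(gain = 1, seed = 4)
  r0 <- balanced_outcome_difference(tz0, n_each = 30, reps = 200, seed = 5)
  for (b in c("theta", "beta", "gamma")) {
    d <- r0$differences[, b]
    expect_lt(abs(mean(d)), 3 * stats::sd(d))
  }
  # label swap with equal pools negates the difference distribution exactly
  tz_sw <- tz; tz_sw$meta$correct <- !tz$meta$correct
  res_sw <- balanced_outcome_difference(tz_sw, n_each = 30, reps = 200, seed = 3)
  expect_equal(res_sw$differences, -res$differences)
  # degenerate outcomes are rejected
  tz1 <- tz; tz1$meta$correct <- TRUE
  expect_error(balanced_outcome_difference(tz1, n_each = 5), "incorrect")
})

test_that("accuracy correlations emerge only for amplitude-linked bands", {
  tz <- outcome_tensor(n_tr = 80, gain = 1.6, gain_bands = 3, seed = 6)
  ta <- tz$time_axis
  resp <- matrix(rep(cos(2 * pi * (ta - 1) / 4), 80), 80, byrow = TRUE)
  series <- list(theta = band_average(tz, c(4, 8)),
                 gamma = band_average(tz, c(30, 150)))
  res <- bootstrap_accuracy_correlation(series, tz$meta$correct, ta, resp,
                                        inner = 300, outer = 20, seed = 7)
  expect_gt(res$transition_s, 0)
  expect_lt(abs(res$t_vs_zero["mean_r", "theta.inhale"]),
            res$t_vs_zero["mean_r", "gamma.inhale"])
  expect_lt(res$t_vs_zero["p", "gamma.inhale"], 1e-4)
  expect_gt(res$t_vs_zero["mean_r", "gamma.inhale"], 0.5)
  # gamma r beats theta r (paired over the outer repetitions)
  pt <- stats::t.test(res$r[, "gamma.inhale"], res$r[, "theta.inhale"],
                      paired = TRUE)
  expect_lt(pt$p.value, 1e-4)
  # null: amplitudes independent of outcome give mean r within 3 SE of 0
  tz0 <- outcome_tensor(n_tr = 80, gain = 1, seed = 8)
  series0 <- list(gamma = band_average(tz0, c(30, 150)))
  res0 <- bootstrap_accuracy_correlation(series0, tz0$meta$correct, ta, resp,
                                         inner = 300, outer = 20, seed = 9)
  rv <- res0$r[, "gamma.inhale"]
  expect_lt(abs(mean(rv)), 3 * stats::sd(rv) / sqrt(length(rv)))
})

test_that("ROC bookkeeping: monotone curve, trapezoidal AUC, invariances", {
  set.seed(14)
  scores <- c(rnorm(50, 1), rnorm(50, -1))
  labels <- rep(c(TRUE, FALSE), each = 50)
  rc <- roc_curve(scores, labels)
  expect_true(all(diff(rc$roc$tpr) >= 0))
  expect_true(all(diff(rc$roc$fpr) >= 0))
  expect_gt(rc$auc, 0.85)
  # AUC invariant under strictly increasing transforms of the scores
  rc2 <- roc_curve(exp(scores), labels)
  expect_equal(rc2$auc, rc$auc)
  # class swap maps AUC to 1 - AUC
  rc3 <- roc_curve(scores, !labels)
  expect_equal(rc3$auc, 1 - rc$auc, tolerance = 1e-12)
  # perfect separation: AUC 1 and Youden accuracy 1
  rc4 <- roc_curve(c(1, 2, 3, -1, -2, -3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rc4$auc, 1)
  expect_equal(rc4$youden$accuracy, 1)
})

test_that("linear SVM separates separable data and stays at chance on noise", {
  set.seed(15)
  x <- rbind(matrix(rnorm(200, 2), ncol = 2), matrix(rnorm(200, -2), ncol = 2))
  y <- factor(rep(c("b", "a"), each = 100), levels = c("a", "b"))
  fit <- linear_svm(x, y)
  acc <- mean((svm_decision(fit, x) > 0) == (y == "b"))
  expect_gt(acc, 0.95)
})

test_that("SVM separability: chance on exchangeable classes, shuffled labels
           at chance, gained band beats ungained", {
  ta <- seq(-1, 3, length.out = 120)
  # classes drawn from one distribution (label-agnostic resampling): chance
  aucs <- vapply(1:5, function(s) {
    tz0 <- outcome_tensor(n_tr = 60, gain = 1, seed = 20 + s)
    series <- band_average(tz0, c(30, 150))
    bl <- rep(1, 60)
    svm_separability(series, tz0$meta$correct, ta, baseline = bl,
                     inhale = c(0, 1.5), exhale = c(1.5, 3),
                     reps = 400, shuffle_labels = TRUE, seed = s)$auc
  }, numeric(1))
  expect_true(all(aucs > 0.4 & aucs < 0.6))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # separable data with per-repetition label shuffling: accuracy ~ chance
  accs <- vapply(1:5, function(s) {
    tz <- outcome_tensor(n_tr = 60, gain = 1.6, gain_bands = 3, seed = 30 + s)
    series <- band_average(tz, c(30, 150))
    svm_separability(series, tz$meta$correct, ta, baseline = rep(1, 60),
                     reps = 400, shuffle_labels = TRUE, seed = s)$cv_accuracy
  }, numeric(1))
  expect_true(mean(accs) > 0.45 && mean(accs) < 0.55)
  # amplitude gain on gamma only: AUC(gamma) > AUC(theta)
  wins <- 0
  for (s in 1:5) {
    tz <- outcome_tensor(n_tr = 60, gain = 1.6, gain_bands = 3, seed = 40 + s)
    bl <- rep(1, 60)
    auc_g <- svm_separability(band_average(tz, c(30, 150)), tz$meta$correct,
                              ta, baseline = bl, reps = 120, seed = s)$auc
    auc_t <- svm_separability(band_average(tz, c(4, 8)), tz$meta$correct,
                              ta, baseline = bl, reps = 120, seed = s)$auc
    wins <- wins + (auc_g > auc_t)
  }
  expect_gte(wins, 5 - 1)
  # both classes must be present
  tz <- outcome_tensor(seed = 50)
  expect_error(svm_separability(band_average(tz, c(30, 150)),
                                rep(TRUE, 60), ta, baseline = rep(1, 60)),
               "both outcome classes")
})
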