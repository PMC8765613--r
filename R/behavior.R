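# Linking band amplitudes to identification accuracy: balanced resampling of
# correct/incorrect trials, bootstrap accuracy-amplitude correlations, and
# linear-SVM separability with ROC/AUC.

#' Attach pre-cue baseline means to a trial tensor without subtracting them
#'
#' Percent-change analyses need raw amplitudes together with their baselines;
#' this computes the per-trial, per-band baseline means (as in
#' [baseline_correct()]) and stores them in `$baseline`, leaving the
#' amplitudes untouched.
#'
#' @inheritParams baseline_correct
#' @return the tensor with `$baseline` attached (trials without a usable
#'   baseline are excluded with a warning).
#' @export
attach_baseline <- function(trials, stack, window = c(-0.55, -0.05)) {
  if (is.null(trials$meta$cue_time_s)) stop("trial metadata lacks cue_time_s")
  bl <- baseline_means_from_stack(stack, trials$meta$cue_time_s, window)
  ok <- stats::complete.cases(bl)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) without a usable baseline window were excluded")
    trials$amplitudes <- trials$amplitudes[ok, , , drop = FALSE]
    trials$meta <- trials$meta[ok, , drop = FALSE]
    bl <- bl[ok, , drop = FALSE]
  }
  trials$baseline <- bl
  trials
}

#' Balanced correct/incorrect amplitude difference by resampling
#'
#' On each repetition, `n_each` correct and `n_each` incorrect trials are
#' resampled with replacement; the per-band mean amplitude over the full
#' window is computed for each outcome and the difference
#' (correct - incorrect) recorded. The `reps` differences are tested against
#' 0 (one-sample t) per band, and between bands (paired t).
#'
#' Two significance readings are reported. `t_vs_zero` is the one-sample t
#' test on the `reps` differences (the conventional report for this
#' analysis); note that its standard error reflects resampling noise only, so
#' it is anticonservative about the underlying trial population.
#' `bootstrap_z` treats the bootstrap spread as the standard error of the
#' difference estimate (`z = mean / sd` of the differences), which is
#' calibrated against the trial-sampling variability and is the reading used
#' for null-vs-effect decisions in this package.
#'
#' @param trials a `trial_tensor` (typically z-normalized) whose `meta` has a
#'   logical `correct` column.
#' @param bands named list of `c(lo, hi)` band ranges (default
#'   [band_definitions()]).
#' @param n_each trials resampled per outcome per repetition (default 71).
#' @param reps repetitions (default 200).
#' @param seed optional RNG seed.
#' @return list with `differences` (reps x band matrix), `t_vs_zero`
#'   (per band: t, df, p), `bootstrap_z` (per band: z, p), and `paired`
#'   (between-band comparisons).
#' @export
balanced_outcome_difference <- function(trials, bands = band_definitions(),
                                        n_each = 71, reps = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  correct <- as.logical(trials$meta$correct)
  if (anyNA(correct)) stop("every trial needs a correct/incorrect flag")
  i_cor <- which(correct); i_inc <- which(!correct)
  if (length(i_inc) == 0) {
    stop("no incorrect trials: lower n_each or provide both outcomes")
  }
  if (length(i_cor) == 0) stop("no correct trials")
  # per trial x band mean amplitude over the full window
  feat <- vapply(bands, function(b) {
    rowMeans(band_average(trials, b))
  }, numeric(dim(trials$amplitudes)[1]))
  diffs <- matrix(0, reps, length(bands),
                  dimnames = list(NULL, names(bands)))
  for (r in seq_len(reps)) {
    # one shared uniform draw indexes both pools, so that swapping the
    # outcome labels negates the difference distribution exactly
    u <- stats::runif(n_each)
    mc <- colMeans(feat[i_cor[ceiling(u * length(i_cor))], , drop = FALSE])
    mi <- colMeans(feat[i_inc[ceiling(u * length(i_inc))], , drop = FALSE])
    diffs[r, ] <- mc - mi
  }
  t_vs_zero <- lapply(seq_along(bands), function(j) {
    ht <- stats::t.test(diffs[, j])
    list(band = names(bands)[j], t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value,
         mean = mean(diffs[, j]))
  })
  names(t_vs_zero) <- names(bands)
  bootstrap_z <- lapply(seq_along(bands), function(j) {
    z <- mean(diffs[, j]) / stats::sd(diffs[, j])
    list(band = names(bands)[j], z = z,
         p = 2 * stats::pnorm(-abs(z)))
  })
  names(bootstrap_z) <- names(bands)
  pairs <- utils::combn(names(bands), 2, simplify = FALSE)
  paired <- lapply(pairs, function(pr) {
    ht <- stats::t.test(diffs[, pr[1]], diffs[, pr[2]], paired = TRUE)
    list(bands = pr, t = unname(ht$statistic), p = ht$p.value)
  })
  list(differences = diffs, t_vs_zero = t_vs_zero, bootstrap_z = bootstrap_z,
       paired = paired, n_each = n_each, reps = reps)
}

# time of the inhale-to-exhale transition (first post-sniff crossing of +pi/2)
# of the trial-averaged breathing signal
phase_transition_time <- function(resp_epochs, time_axis, threshold = pi / 2) {
  phase <- respiratory_phase(colMeans(resp_epochs))
  post <- which(time_axis >= 0)
  cross <- post[phase[post] >= threshold][1]
  if (is.na(cross)) stop("averaged breathing signal never crosses the phase threshold")
  time_axis[cross]
}

#' Bootstrap correlation between task accuracy and band amplitude
#'
#' Inner loop (`inner` times): resample the full trial set with replacement,
#' record the resample's accuracy (fraction correct, duplicates counted) and
#' its mean band amplitude during inhale and exhale (split at the first
#' post-sniff crossing of respiratory phase +pi/2 of the trial-averaged
#' breathing signal); Pearson r between accuracy and amplitude over the inner
#' points, per band x window. Outer loop repeats the whole process `outer`
#' times, giving a distribution of r values; Fisher z transforms are included
#' for between-condition tests.
#'
#' @param series_list named list of trial x time band-amplitude matrices.
#' @param correct logical outcome flag per trial.
#' @param time_axis epoch time axis (s).
#' @param resp_epochs trial x time respiration epochs on the same axis.
#' @param inner resamples per correlation (default 1000).
#' @param outer number of correlation repetitions (default 50).
#' @param seed optional RNG seed.
#' @return list with `r` (outer x (band.window) matrix), `fisher_z`, the
#'   split time `transition_s`, and per-column one-sample t tests `t_vs_zero`.
#' @export
bootstrap_accuracy_correlation <- function(series_list, correct, time_axis,
                                           resp_epochs, inner = 1000,
                                           outer = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  correct <- as.logical(correct)
  n <- length(correct)
  t_split <- phase_transition_time(resp_epochs, time_axis)
  in_idx <- which(time_axis >= 0 & time_axis <= t_split)
  ex_idx <- which(time_axis > t_split)
  feat <- do.call(cbind, lapply(names(series_list), function(b) {
    cbind(rowMeans(series_list[[b]][, in_idx, drop = FALSE]),
          rowMeans(series_list[[b]][, ex_idx, drop = FALSE]))
  }))
  colnames(feat) <- as.vector(t(outer(names(series_list),
                                      c("inhale", "exhale"), paste, sep = ".")))
  r_out <- matrix(NA_real_, outer, ncol(feat),
                  dimnames = list(NULL, colnames(feat)))
  for (o in seq_len(outer)) {
    acc <- numeric(inner)
    fm <- matrix(0, inner, ncol(feat))
    for (i in seq_len(inner)) {
      rows <- sample.int(n, n, replace = TRUE)
      acc[i] <- mean(correct[rows])
      fm[i, ] <- colMeans(feat[rows, , drop = FALSE])
    }
    if (stats::sd(acc) == 0) next  # degenerate accuracy: r undefined, skip
    r_out[o, ] <- suppressWarnings(stats::cor(acc, fm))
  }
  skipped <- !stats::complete.cases(r_out)
  if (any(skipped)) {
    warning(sum(skipped), " outer repetition(s) skipped (degenerate accuracy)")
    r_out <- r_out[!skipped, , drop = FALSE]
  }
  t_vs_zero <- apply(r_out, 2, function(rv) {
    ht <- stats::t.test(rv)
    c(t = unname(ht$statistic), p = ht$p.value, mean_r = mean(rv))
  })
  list(r = r_out, fisher_z = atanh(pmin(pmax(r_out, -1 + 1e-12), 1 - 1e-12)),
       transition_s = t_split, t_vs_zero = t_vs_zero)
}

# ---- linear SVM and ROC -----------------------------------------------------

#' Fit a linear maximum-margin classifier (hinge loss + L2)
#'
#' Deterministic full-batch subgradient descent on
#' `0.5 * ||w||^2 + C * sum(hinge)`, on standardized features. Adequate for
#' the low-dimensional separability analyses here; not a general SVM solver.
#'
#' @param x feature matrix (n x d).
#' @param y labels coercible to two classes; the second level is +1.
#' @param C margin penalty (default 1).
#' @param iters gradient iterations.
#' @return a `linear_svm` model with `decision(newx)` scores.
#' @export
linear_svm <- function(x, y, C = 1, iters = 400) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2)
  yy <- ifelse(as.integer(y) == 2L, 1, -1)
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  n <- nrow(xs)
  lambda <- 1 / (C * n)
  w <- numeric(ncol(xs)); b <- 0
  w_acc <- w; b_acc <- 0
  for (t in seq_len(iters)) {
    margins <- yy * (xs %*% w + b)
    viol <- margins < 1
    gw <- lambda * w - colSums(xs[viol, , drop = FALSE] * yy[viol]) / n
    gb <- -sum(yy[viol]) / n
    eta <- 1 / (lambda * (t + 10))
    w <- w - eta * gw
    b <- b - eta * gb
    w_acc <- w_acc + w; b_acc <- b_acc + b
  }
  w <- w_acc / iters; b <- b_acc / iters
  structure(list(w = w, b = b, mu = mu, sd = sdv, levels = levels(y), C = C),
            class = "linear_svm")
}

#' @param object a `linear_svm` model.
#' @param newx feature matrix to score.
#' @rdname linear_svm
#' @export
svm_decision <- function(object, newx) {
  xs <- sweep(sweep(as.matrix(newx), 2, object$mu), 2, object$sd, "/")
  as.numeric(xs %*% object$w + object$b)
}

#' ROC curve and AUC from decision scores
#'
#' @param scores decision scores (higher = more positive class).
#' @param labels logical or two-level labels (TRUE / second level = positive).
#' @return list with `roc` (data.frame fpr, tpr, threshold), `auc`
#'   (trapezoidal area), and `youden` (threshold, accuracy at the point
#'   maximizing sensitivity + specificity - 1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.integer(as.factor(labels)) == 2L
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  jbest <- which.max(j)
  thr <- c(Inf, scores[ord])[jbest]
  acc <- (tp[max(jbest - 1, 1)] + sum(!pos) - fp[max(jbest - 1, 1)]) / length(pos)
  if (jbest == 1) acc <- sum(!pos) / length(pos)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, scores[ord])),
       auc = auc, youden = list(threshold = thr, accuracy = acc))
}

#' Linear-SVM separability of correct vs incorrect resampled amplitudes
#'
#' For each repetition and outcome class, `n_per_class` trials are resampled
#' with replacement, their amplitude time series averaged, converted to
#' percent change using the resample's average baseline, and reduced to
#' (inhale mean, exhale mean) features. The `2 * reps` points are classified
#' with a linear SVM under k-fold cross-validation; ROC/AUC and the
#' Youden-optimized accuracy are computed from the cross-validated decision
#' scores.
#'
#' @param series trial x time raw band-amplitude matrix.
#' @param baseline per-trial baseline means (defaults to the matrix's
#'   `baseline` attribute, as attached by [band_average()] after
#'   [attach_baseline()]).
#' @param correct logical outcome per trial.
#' @param time_axis epoch time axis (s).
#' @param inhale,exhale feature windows in seconds post-sniff.
#' @param n_per_class resampled trials per class per repetition (default 30).
#' @param reps repetitions per class (default 500).
#' @param folds cross-validation folds (default 5).
#' @param C SVM margin penalty (default 1).
#' @param shuffle_labels if TRUE the outcome flags are freshly permuted on
#'   every repetition before the class pools are drawn -- the chance-level
#'   control. (Shuffling once, outside the repetition loop, would still
#'   separate: bootstrap points concentrate around their fixed pool means,
#'   so any finite-pool difference is learnable.)
#' @param seed optional RNG seed.
#' @return a `classifier_eval`: `roc`, `auc`, `optimized_accuracy`,
#'   `cv_accuracy`, `points` (features + labels), `folds`.
#' @export
svm_separability <- function(series, correct, time_axis,
                             baseline = attr(series, "baseline"),
                             inhale = c(0, 1.5), exhale = c(1.5, 3),
                             n_per_class = 30, reps = 500, folds = 5, C = 1,
                             shuffle_labels = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline)) stop("per-trial baseline means are required")
  correct <- as.logical(correct)
  if (!any(correct) || !any(!correct)) stop("both outcome classes must be present")
  in_idx <- which(time_axis >= inhale[1] & time_axis < inhale[2])
  ex_idx <- which(time_axis >= exhale[1] & time_axis < exhale[2])
  pts <- matrix(NA_real_, 2 * reps, 2,
                dimnames = list(NULL, c("inhale", "exhale")))
  lab <- logical(2 * reps)
  row <- 0L
  for (r in seq_len(reps)) {
    flags <- if (shuffle_labels) sample(correct) else correct
    for (cl in c(FALSE, TRUE)) {
      rows <- sample(which(flags == cl), n_per_class, replace = TRUE)
      avg <- colMeans(series[rows, , drop = FALSE])
      bl <- mean(baseline[rows])
      pc <- (avg - bl) / bl
      row <- row + 1L
      pts[row, ] <- c(mean(pc[in_idx]), mean(pc[ex_idx]))
      lab[row] <- cl
    }
  }
  keep <- stats::complete.cases(pts) & is.finite(rowSums(pts))
  n_dropped <- sum(!keep)
  if (n_dropped) warning(n_dropped, " repetition(s) with non-finite features dropped")
  pts <- pts[keep, , drop = FALSE]; lab <- lab[keep]

  fold_id <- sample(rep_len(seq_len(folds), nrow(pts)))
  scores <- numeric(nrow(pts))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- linear_svm(pts[!test, , drop = FALSE], factor(lab[!test], c(FALSE, TRUE)), C = C)
    scores[test] <- svm_decision(fit, pts[test, , drop = FALSE])
  }
  rc <- roc_curve(scores, lab)
  structure(list(roc = rc$roc, auc = rc$auc,
                 optimized_accuracy = rc$youden$accuracy,
                 cv_accuracy = mean((scores > 0) == lab),
                 points = data.frame(pts, correct = lab),
                 folds = folds, n_dropped = n_dropped),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> AUC = %.3f, optimized accuracy = %.3f, CV accuracy = %.3f (%d-fold)\n",
              x$auc, x$optimized_accuracy, x$cv_accuracy, x$folds))
  invisible(x)
}
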