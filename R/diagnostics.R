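## Cutoff-based diagnostic accuracy and ROC/AUC machinery. Both biomarkers
## fall with chiasmal compression, so the clinical orientation is
## lower-is-positive: a value at or below the cutoff calls disease. The fixed
## cutoffs of interest are 15.5 uV for the pVEP amplitude AOz12 and 65 um for
## the bi-nasal GCC+IPL sectors.

#' Dichotomize a biomarker at a cutoff
#'
#' Values at or below the cutoff are called `"positive"` (diseased): lower
#' amplitudes and thinner layers indicate compression. The boundary value
#' counts as positive; the cutoffs sit far from both group centres, so the
#' convention is immaterial but fixed.
#'
#' @param values Numeric vector.
#' @param cutoff Cutoff in the same units.
#' @return Character vector `"positive"`/`"negative"` (`NA` propagated).
#' @export
#' @examples
#' dichotomize(c(3.9, 17.8), 15.5)
dichotomize <- function(values, cutoff) {
  ifelse(is.na(values), NA_character_,
         ifelse(values <= cutoff, "positive", "negative"))
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Se = true positives / all diseased; Sp = true negatives / all
#' non-diseased, with the lower-is-positive call of [dichotomize()]. Missing
#' values are excluded.
#'
#' @param values Numeric biomarker values.
#' @param diseased Logical vector: `TRUE` for diseased subjects.
#' @param cutoff Cutoff value.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
confusion_accuracy <- function(values, diseased, cutoff) {
  ok <- !is.na(values) & !is.na(diseased)
  values <- values[ok]; diseased <- as.logical(diseased[ok])
  if (!any(diseased) || all(diseased)) {
    stop("both diseased and non-diseased subjects are required")
  }
  pos <- values <= cutoff
  c(sensitivity = mean(pos[diseased]), specificity = mean(!pos[!diseased]))
}

## Rank-based AUC: probability that a diseased score is below a non-diseased
## one (orientation "lower"), ties counted half. Identical to the trapezoidal
## area of the empirical ROC and to U/(n_pos * n_neg).
auc_rank <- function(scores, diseased, orientation = "lower") {
  r <- rank(scores)
  n1 <- sum(diseased); n0 <- sum(!diseased)
  u_neg <- sum(r[!diseased]) - n0 * (n0 + 1) / 2
  auc <- u_neg / (n0 * n1)  # P(score_neg > score_pos) + 0.5 P(tie)
  if (orientation == "lower") auc else 1 - auc
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the observed values and plots
#' sensitivity against 1 - specificity. With `orientation = "lower"`
#' (default) a value at or below the threshold is called positive, so
#' informative markers that *fall* with disease give AUC >= 0.5.
#'
#' @param scores Numeric biomarker values (`NA` rows dropped); at least two
#'   distinct values.
#' @param diseased Logical disease labels; both classes must be present.
#' @param orientation `"lower"` (value <= threshold is positive) or
#'   `"higher"`.
#' @return List of class `"roc_result"`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `n_pos`,
#'   `n_neg`, `orientation`.
#' @export
roc_curve <- function(scores, diseased, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores) & !is.na(diseased)
  scores <- scores[ok]; diseased <- as.logical(diseased[ok])
  if (!any(diseased) || all(diseased)) stop("both classes are required")
  if (length(unique(scores)) < 2) stop("need at least 2 distinct score values")
  s <- if (orientation == "lower") scores else -scores
  thr <- sort(unique(s))
  tpr <- vapply(thr, function(t) mean(s[diseased] <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!diseased] <= t), numeric(1))
  pts <- data.frame(threshold = c(-Inf, if (orientation == "lower") thr else -thr),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = sum(diseased),
                 n_neg = sum(!diseased), orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s-is-positive): AUC = %.3f, %d diseased vs %d non-diseased, %d points\n",
              x$orientation, x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Plot an ROC curve
#'
#' Base-graphics Se vs 1-Sp plot of a [roc_curve()] result.
#'
#' @param x A `roc_result`.
#' @param ... Passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Stratified bootstrap confidence interval for an AUC
#'
#' Case-resampling bootstrap stratified by disease status (class balance is
#' preserved, so degenerate single-class resamples cannot occur); percentile
#' interval.
#'
#' @param scores,diseased As in [roc_curve()].
#' @param iterations Bootstrap iterations, default 10000.
#' @param seed Integer seed.
#' @param orientation As in [roc_curve()].
#' @param conf_level Confidence level, default 0.95.
#' @return List: `ci` (length-2 interval), `auc` (point estimate),
#'   `iterations`, `n_redrawn` (always 0 under stratification).
#' @export
bootstrap_auc_ci <- function(scores, diseased, iterations = 10000, seed = 1L,
                             orientation = "lower", conf_level = 0.95) {
  ok <- !is.na(scores) & !is.na(diseased)
  scores <- scores[ok]; diseased <- as.logical(diseased[ok])
  if (!any(diseased) || all(diseased)) stop("both classes are required")
  set.seed(as.integer(seed))
  ip <- which(diseased); ineg <- which(!diseased)
  boot <- vapply(seq_len(iterations), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    auc_rank(scores[idx], diseased[idx], orientation)
  }, numeric(1))
  alpha <- 1 - conf_level
  list(ci = unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2))),
       auc = auc_rank(scores, diseased, orientation),
       iterations = iterations, n_redrawn = 0L)
}

#' Permutation comparison of two AUCs
#'
#' Compares the AUCs of a biomarker evaluated on two datasets: the observed
#' difference is standardized by a bootstrap SE (independent stratified
#' bootstraps of each dataset) and referred to the permutation null obtained
#' by shuffling dataset membership of the pooled (score, label) rows. The
#' datasets may share subjects (the ESC datasets do); membership is permuted
#' regardless, mirroring the independent-columns treatment of the original
#' analysis.
#'
#' @param scores_a,diseased_a First dataset's biomarker values and labels.
#' @param scores_b,diseased_b Second dataset's.
#' @param iterations Permutation (and bootstrap) iterations, >= 100.
#' @param seed Integer seed.
#' @param orientation As in [roc_curve()].
#' @return List of class `"auc_comparison"`: `auc_a`, `auc_b`, `delta_auc`,
#'   `se`, `z_stat`, `p_perm`, `iterations`.
#' @export
compare_auc <- function(scores_a, diseased_a, scores_b, diseased_b,
                        iterations = 10000, seed = 1L, orientation = "lower") {
  if (iterations < 100) stop("iterations < 100 give an unstable p-value")
  seed <- as.integer(seed)
  ka <- !is.na(scores_a); kb <- !is.na(scores_b)
  scores_a <- scores_a[ka]; diseased_a <- as.logical(diseased_a[ka])
  scores_b <- scores_b[kb]; diseased_b <- as.logical(diseased_b[kb])
  auc_a <- auc_rank(scores_a, diseased_a, orientation)
  auc_b <- auc_rank(scores_b, diseased_b, orientation)
  delta <- auc_a - auc_b

  set.seed(seed)
  boot_one <- function(s, d) {
    ip <- which(d); ineg <- which(!d)
    vapply(seq_len(iterations), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
      auc_rank(s[idx], d[idx], orientation)
    }, numeric(1))
  }
  se <- sqrt(stats::var(boot_one(scores_a, diseased_a)) +
               stats::var(boot_one(scores_b, diseased_b)))
  z <- if (se > 0) delta / se else 0

  pool_s <- c(scores_a, scores_b)
  pool_d <- c(diseased_a, diseased_b)
  na <- length(scores_a); n <- length(pool_s)
  perm <- vapply(seq_len(iterations), function(b) {
    ia <- sample.int(n, na)
    da <- pool_d[ia]; db <- pool_d[-ia]
    if (!any(da) || all(da) || !any(db) || all(db)) return(NA_real_)
    auc_rank(pool_s[ia], da, orientation) - auc_rank(pool_s[-ia], db, orientation)
  }, numeric(1))
  perm <- perm[!is.na(perm)]
  p <- (1 + sum(abs(perm) >= abs(delta) - 1e-12)) / (length(perm) + 1)
  structure(list(auc_a = auc_a, auc_b = auc_b, delta_auc = delta, se = se,
                 z_stat = z, p_perm = p, iterations = iterations),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC comparison: %.3f vs %.3f (delta %.3f, z = %.2f), permutation p = %.4g\n",
              x$auc_a, x$auc_b, x$delta_auc, x$z_stat, x$p_perm))
  invisible(x)
}

#' Evaluate a biomarker on an ESC dataset against controls
#'
#' Convenience wrapper assembling the full univariate diagnostic result for
#' one biomarker under one eye-selection criterion: Se/Sp at the fixed
#' cutoff, the ROC curve and trapezoidal AUC, and (optionally) a stratified
#' bootstrap CI.
#'
#' @param dataset An `esc_dataset` of patient rows.
#' @param controls A data.frame of control rows (e.g. the controls' RSE
#'   dataset).
#' @param biomarker `"AOz12"` or `"BiNS"` (any measurement variable works).
#' @param cutoff Cutoff value (defaults: 15.5 for `AOz12`, 65 for `BiNS`).
#' @param ci_iterations Bootstrap iterations for the AUC CI; 0 skips the CI.
#' @param seed Seed for the bootstrap.
#' @return List of class `"diagnostic_result"`: `biomarker`, `criterion`,
#'   `cutoff`, `sensitivity`, `specificity`, `roc`, `auc`, `auc_ci`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_biomarker <- function(dataset, controls, biomarker,
                               cutoff = c(AOz12 = 15.5, BiNS = 65)[[biomarker]],
                               ci_iterations = 0, seed = 1L) {
  pv <- dataset[[biomarker]]; cv <- controls[[biomarker]]
  values <- c(pv, cv)
  diseased <- rep(c(TRUE, FALSE), c(length(pv), length(cv)))
  ok <- !is.na(values)
  acc <- confusion_accuracy(values, diseased, cutoff)
  roc <- roc_curve(values, diseased, orientation = "lower")
  ci <- if (ci_iterations > 0) {
    bootstrap_auc_ci(values, diseased, iterations = ci_iterations,
                     seed = seed)$ci
  } else NULL
  structure(list(biomarker = biomarker,
                 criterion = attr(dataset, "criterion"),
                 cutoff = cutoff,
                 sensitivity = unname(acc["sensitivity"]),
                 specificity = unname(acc["specificity"]),
                 roc = roc, auc = roc$auc, auc_ci = ci,
                 n_pos = sum(diseased & ok), n_neg = sum(!diseased & ok)),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("%s under %s @ cutoff %g: Se = %.3f, Sp = %.3f, AUC = %.3f",
              x$biomarker, x$criterion %||% "?", x$cutoff,
              x$sensitivity, x$specificity, x$auc))
  if (!is.null(x$auc_ci)) cat(sprintf(" [%.3f, %.3f]", x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf(" (n = %d/%d)\n", x$n_pos, x$n_neg))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
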