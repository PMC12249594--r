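## Inter-eye reliability: intraclass correlation on right/left pairs, the
## Koo-Li qualitative scale, and the pooling decision rule (random single eye
## when inter-eye agreement is high, pooled eyes otherwise).

#' Intraclass correlation on right/left eye pairs
#'
#' Two-way, single-measure ICC on an n x 2 matrix of (right, left) values,
#' treating eyes as fixed "raters". The default `"consistency"` flavour
#' (commonly labelled ICC(3,1)) is invariant to a constant inter-eye offset
#' and matches a Pearson-style definition of inter-eye agreement; the
#' absolute-agreement flavour ICC(2,1) is also available. Confidence bounds
#' use the standard F-based formulas (exact for consistency; McGraw-Wong
#' Satterthwaite approximation for agreement).
#'
#' @param pairs Data.frame with columns `right` and `left` (as returned by
#'   [interocular_pairs()]) or a 2-column numeric matrix. At least 3 complete
#'   pairs are required.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `n_pairs`, `type`, `koo_li_class`.
#' @export
#' @examples
#' x <- rnorm(30, 100, 10)
#' icc_pairs(cbind(right = x, left = x + rnorm(30, 0, 3)))
icc_pairs <- function(pairs, type = c("consistency", "agreement"),
                      conf_level = 0.95) {
  type <- match.arg(type)
  if (is.data.frame(pairs)) {
    stopifnot(all(c("right", "left") %in% names(pairs)))
    x <- as.matrix(pairs[, c("right", "left")])
  } else {
    x <- as.matrix(pairs)
    stopifnot(ncol(x) == 2)
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- 2
  if (n < 3) stop("at least 3 complete pairs are required")

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps * grand^2 && mse < .Machine$double.eps * grand^2) {
    stop("zero variance across subjects: ICC undefined")
  }

  alpha <- 1 - conf_level
  if (mse == 0) {
    ## degenerate perfect agreement/consistency: CI collapses
    icc <- if (type == "consistency") 1 else
      (msr) / (msr + (k / n) * msc)
    return(structure(list(icc = icc, ci_low = icc, ci_high = icc, n_pairs = n,
                          type = type, conf_level = conf_level,
                          koo_li_class = koo_li_classify(max(-1, min(1, icc)))),
                     class = "icc_result"))
  }
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fstat <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fstat / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fstat * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msr - f1 * mse) /
              (f1 * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (f2 * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * f2 * msr))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], n_pairs = n,
                 type = type, conf_level = conf_level,
                 koo_li_class = koo_li_classify(max(-1, min(1, icc)))),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f  [%.3f, %.3f] (%d%% CI), n = %d pairs, %s\n",
              x$type, x$icc, x$ci_low, x$ci_high,
              round(100 * x$conf_level), x$n_pairs, x$koo_li_class))
  invisible(x)
}

#' Qualify an ICC magnitude on the Koo-Li scale
#'
#' `< 0.5` poor; `[0.5, 0.75)` moderate; `[0.75, 0.9)` good; `>= 0.9`
#' excellent.
#'
#' @param icc Numeric vector of ICC values in `[-1, 1]`.
#' @return Character vector of classes.
#' @export
#' @examples
#' koo_li_classify(c(0.4, 0.6, 0.8, 0.95))
koo_li_classify <- function(icc) {
  if (any(is.na(icc)) || any(icc < -1 | icc > 1)) {
    stop("icc values must lie in [-1, 1]")
  }
  cut_points <- cut(icc, breaks = c(-1, 0.5, 0.75, 0.9, 1),
                    labels = c("poor", "moderate", "good", "excellent"),
                    right = FALSE, include.lowest = TRUE)
  ## cut(right = FALSE) puts 1 in the top class via include.lowest
  as.character(cut_points)
}

#' Decide between a random single eye and pooling both eyes
#'
#' Encodes the unit-of-analysis rule: when inter-eye agreement is high for all
#' supplied variables (every ICC above 0.7, the threshold the field applies in
#' practice) a randomly selected single eye carries the same information as
#' both and avoids double-counting; otherwise pooling both eyes as independent
#' rows is permitted. With mixed evidence the conservative pooling branch is
#' taken and flagged so the caller sees the per-variable classes.
#'
#' @param icc_results A non-empty list of [icc_pairs()] results (optionally
#'   named by variable).
#' @param threshold Agreement threshold, default 0.7.
#' @return List of class `"pooling_decision"`: `decision`
#'   (`"use_random_single_eye"` or `"pool_both_eyes"`), `mixed_evidence`
#'   flag, and a per-variable data.frame `evidence`.
#' @export
pooling_decision <- function(icc_results, threshold = 0.7) {
  if (inherits(icc_results, "icc_result")) icc_results <- list(icc_results)
  if (!length(icc_results)) stop("at least one ICC result is required")
  iccs <- vapply(icc_results, function(r) r$icc, numeric(1))
  classes <- vapply(icc_results, function(r) r$koo_li_class, character(1))
  nm <- names(icc_results)
  if (is.null(nm)) nm <- paste0("variable", seq_along(iccs))
  above <- iccs > threshold
  structure(list(
    decision = if (all(above)) "use_random_single_eye" else "pool_both_eyes",
    mixed_evidence = any(above) && !all(above),
    threshold = threshold,
    evidence = data.frame(variable = nm, icc = iccs, koo_li_class = classes,
                          above_threshold = above, stringsAsFactors = FALSE)
  ), class = "pooling_decision")
}

#' @export
print.pooling_decision <- function(x, ...) {
  cat("pooling decision:", x$decision,
      if (x$mixed_evidence) "(mixed evidence)" else "", "\n")
  print(x$evidence, row.names = FALSE)
  invisible(x)
}
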