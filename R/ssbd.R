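## Stable Sparse Biomarkers Detection (SSBD): repeated subject-level
## subsampling, an elastic-net generalized linear model fitted on each
## subsample with cross-validated penalty selection, and a per-variable
## stability index defined as the exact ratio of subsamples in which the
## variable is selected (nonzero coefficient) to the total number of
## subsamples. The penalized fits themselves are delegated to glmnet; the
## resampling protocol, fold-based penalty selection, stability bookkeeping
## and aggregation are implemented here.

#' SSBD configuration
#'
#' @param n_subsamples Number of resampled fits, at least 100 (default 1000).
#' @param subsample_fraction Fraction of subjects per subsample in
#'   `(0.5, 1]`, drawn without replacement (default 0.8). The value 1 is
#'   admitted so that the no-penalty degeneracy of the procedure (every
#'   subsample identical, stability indices all 0 or 1) can be exercised.
#' @param alpha Elastic-net mixing value(s) in `[0, 1]`. A single value
#'   (default 0.5) is used directly; a vector is searched by the same
#'   cross-validation as the penalty.
#' @param lambda_selection `"cv_min"` (default) or `"cv_1se"`.
#' @param cv_folds Cross-validation folds for penalty selection, default 5.
#' @param nlambda Length of the penalty path, default 30.
#' @param lambda_fixed Optional fixed penalty (skips cross-validation);
#'   `lambda_fixed = 0` gives unpenalized fits.
#' @param replace Draw subsamples with replacement (bootstrap) instead of
#'   without; default `FALSE`.
#' @param seed Integer seed.
#' @return List of class `"ssbd_config"`.
#' @export
ssbd_config <- function(n_subsamples = 1000L, subsample_fraction = 0.8,
                        alpha = 0.5, lambda_selection = c("cv_min", "cv_1se"),
                        cv_folds = 5L, nlambda = 30L, lambda_fixed = NULL,
                        replace = FALSE, seed = 1L) {
  lambda_selection <- match.arg(lambda_selection)
  if (n_subsamples < 100) stop("n_subsamples must be >= 100")
  if (subsample_fraction <= 0.5 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0.5, 1]")
  }
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  structure(list(n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 alpha = alpha, lambda_selection = lambda_selection,
                 cv_folds = as.integer(cv_folds), nlambda = as.integer(nlambda),
                 lambda_fixed = lambda_fixed, replace = replace,
                 seed = as.integer(seed)),
            class = "ssbd_config")
}

## Elastic-net fit with fold-based penalty (and optionally mixing) selection.
## Returns the coefficient vector (no intercept) at the chosen (alpha,
## lambda). Deviance is the CV loss for binomial models, MSE for gaussian.
## glmnet advises when a binomial class has < 8 observations; routine for the
## small clinical subsamples used here, so that advisory alone is muffled.
quiet_glmnet <- function(...) {
  withCallingHandlers(glmnet::glmnet(...), warning = function(w) {
    if (grepl("fewer than 8 observations", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

cv_enet_coef <- function(x, y, family, config, foldid = NULL) {
  n <- nrow(x)
  if (!is.null(config$lambda_fixed)) {
    lam <- sort(unique(c(config$lambda_fixed, config$lambda_fixed + 1)),
                decreasing = TRUE)
    fit <- quiet_glmnet(x, y, family = family, alpha = config$alpha[1],
                        lambda = lam, standardize = FALSE, thresh = 1e-7)
    b <- as.numeric(stats::coef(fit, s = config$lambda_fixed))[-1]
    return(b)
  }
  if (is.null(foldid)) {
    foldid <- sample(rep(seq_len(config$cv_folds), length.out = n))
  }
  best <- NULL
  for (a in config$alpha) {
    path <- quiet_glmnet(x, y, family = family, alpha = max(a, 1e-3),
                         nlambda = config$nlambda, standardize = FALSE,
                         thresh = 1e-5)
    lam <- path$lambda
    loss <- matrix(NA_real_, config$cv_folds, length(lam))
    for (f in seq_len(config$cv_folds)) {
      tr <- foldid != f
      fit_f <- quiet_glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                            alpha = max(a, 1e-3), lambda = lam,
                            standardize = FALSE, thresh = 1e-5)
      pred <- stats::predict(fit_f, x[!tr, , drop = FALSE],
                             type = if (family == "binomial") "response" else "link")
      if (ncol(pred) < length(lam)) {  # path may end early on a fold
        pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                   length(lam) - ncol(pred)))
      }
      yt <- y[!tr]
      loss[f, ] <- if (family == "binomial") {
        p <- pmin(pmax(pred, 1e-10), 1 - 1e-10)
        -2 * colMeans(yt * log(p) + (1 - yt) * log(1 - p))
      } else {
        colMeans((yt - pred)^2)
      }
    }
    cvm <- colMeans(loss)
    cvse <- apply(loss, 2, stats::sd) / sqrt(config$cv_folds)
    j_min <- which.min(cvm)
    j <- if (config$lambda_selection == "cv_1se") {
      min(which(cvm <= cvm[j_min] + cvse[j_min]))
    } else j_min
    if (is.null(best) || cvm[j_min] < best$cvm_min) {
      best <- list(path = path, lambda = lam[j], cvm_min = cvm[j_min])
    }
  }
  as.numeric(stats::coef(best$path, s = best$lambda))[-1]
}

#' Fit a Stable Sparse Biomarkers Detection model
#'
#' Runs the SSBD procedure on an analysis table: predictors are z-scored on
#' the full data (so coefficients are in standardized units and selection is
#' invariant to predictor rescaling), then `n_subsamples` subject-level
#' subsamples are drawn and an elastic-net GLM (binomial for diagnosis,
#' identity/gaussian for prediction of the 12-month amplitude) is fitted on
#' each with its penalty chosen by cross-validation on that subsample. A
#' variable counts as *selected* in a subsample when its coefficient is
#' nonzero; its stability index is the exact selection ratio. The aggregated
#' beta is the mean coefficient over all subsamples, zeros included. A final
#' model is refit on the full data with the same penalty-selection rule;
#' diagnosis mode scores it by the trapezoidal AUC of its linear scores, and
#' prediction mode by the consistency ICC, squared Pearson correlation and
#' the AUC after dichotomizing predicted and observed outcomes at the
#' 15.5 uV amplitude cutoff.
#'
#' Subject-level sampling keeps all rows of a subject together (relevant for
#' the pooled both-eyes dataset). Diagnosis subsamples that lose one outcome
#' class entirely are redrawn and counted.
#'
#' @param data A data.frame (typically an `esc_dataset`, possibly after
#'   [join_outcome()]) with complete predictor columns.
#' @param predictors Character vector of predictor columns; constant columns
#'   are dropped with a warning.
#' @param outcome Outcome column: a binary patient/control label (diagnosis
#'   mode; `"group"`, logical, or 0/1) or a continuous follow-up value
#'   (prediction mode).
#' @param mode `"diagnosis"` or `"prediction"`.
#' @param config An [ssbd_config()].
#' @param recovery_cutoff Amplitude cutoff (uV) used to dichotomize
#'   predicted and observed outcomes for the prediction-mode AUC.
#' @return List of class `"ssbd_result"`: `mode`, `variables` (data.frame
#'   with `stability_index`, `beta_aggregate`, `beta_q2.5` ... `beta_q97.5`),
#'   `model_auc`, and in prediction mode `icc_pred_obs`, `r2`; plus
#'   `full_coefficients`, `fitted_scores`, `selections` (logical
#'   subsample x variable matrix), `n_redrawn`, `config`.
#' @export
fit_ssbd <- function(data, predictors, outcome,
                     mode = c("diagnosis", "prediction"),
                     config = ssbd_config(), recovery_cutoff = 15.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "ssbd_config"))
  df <- as.data.frame(data)
  stopifnot(all(predictors %in% names(df)), outcome %in% names(df))

  ok <- stats::complete.cases(df[, c(predictors, outcome, "subject_id")])
  if (!all(ok)) {
    stop(sprintf("predictor/outcome matrix has %d incomplete rows; impute upstream",
                 sum(!ok)))
  }
  n <- nrow(df)
  if (n < 20) stop(sprintf("n = %d is below the minimum of 20", n))

  y_raw <- df[[outcome]]
  if (mode == "diagnosis") {
    y <- if (is.character(y_raw) || is.factor(y_raw)) {
      as.integer(as.character(y_raw) == "patient")
    } else as.integer(y_raw > if (is.logical(y_raw)) 0.5 else 0.5)
    if (length(unique(y)) != 2) stop("diagnosis outcome must be binary")
    family <- "binomial"
  } else {
    y <- as.numeric(y_raw)
    family <- "gaussian"
  }

  x_raw <- as.matrix(df[, predictors, drop = FALSE])
  sds <- apply(x_raw, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant predictor(s): ",
            paste(predictors[sds == 0], collapse = ", "))
    predictors <- predictors[sds > 0]
    x_raw <- x_raw[, predictors, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x_raw)
  p <- length(predictors)

  set.seed(config$seed)
  subjects <- unique(df$subject_id)
  ns <- length(subjects)
  m <- max(2L, round(config$subsample_fraction * ns))
  B <- config$n_subsamples
  coefs <- matrix(0, B, p, dimnames = list(NULL, predictors))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    for (try in 1:100) {
      sub <- sample(subjects, m, replace = config$replace)
      idx <- which(df$subject_id %in% sub)
      if (family != "binomial" || length(unique(y[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    coefs[b, ] <- cv_enet_coef(x[idx, , drop = FALSE], y[idx], family, config)
  }
  selected <- coefs != 0
  stability <- colMeans(selected)
  beta_agg <- colMeans(coefs)
  qs <- t(apply(coefs, 2, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975)))

  ## full-data refit with the same selection rule
  full_coef <- cv_enet_coef(x, y, family, config)
  eta <- drop(x %*% full_coef)
  variables <- data.frame(variable = predictors, stability_index = stability,
                          beta_aggregate = beta_agg,
                          beta_q2.5 = qs[, 1], beta_q25 = qs[, 2],
                          beta_q50 = qs[, 3], beta_q75 = qs[, 4],
                          beta_q97.5 = qs[, 5], row.names = NULL,
                          stringsAsFactors = FALSE)
  res <- list(mode = mode, variables = variables,
              full_coefficients = full_coef, selections = selected,
              n_redrawn = n_redrawn, config = config)
  if (mode == "diagnosis") {
    res$fitted_scores <- eta
    res$model_auc <- auc_rank(eta, y == 1, orientation = "higher")
  } else {
    ## identity link: add intercept implied by centring
    pred <- mean(y) + eta - mean(eta)
    res$fitted_scores <- pred
    ev <- evaluate_prediction(pred, y, cutoff = recovery_cutoff)
    res$model_auc <- ev$auc
    res$icc_pred_obs <- ev$icc
    res$r2 <- ev$r2
  }
  class(res) <- "ssbd_result"
  res
}

#' @export
print.ssbd_result <- function(x, ...) {
  cat(sprintf("<ssbd_result> mode = %s, %d subsamples (%d redrawn)\n",
              x$mode, x$config$n_subsamples, x$n_redrawn))
  v <- x$variables[order(-x$variables$stability_index), c("variable", "stability_index", "beta_aggregate")]
  print(v, row.names = FALSE, digits = 3)
  cat(sprintf("model AUC = %.3f", x$model_auc))
  if (x$mode == "prediction") {
    cat(sprintf(", ICC(pred, obs) = %.3f, r2 = %.3f", x$icc_pred_obs, x$r2))
  }
  cat("\n")
  invisible(x)
}

#' Agreement between predicted and observed recovery outcomes
#'
#' Scores a continuous prediction of the 12-month pVEP amplitude against the
#' observed values: consistency-type ICC (invariant to a constant offset),
#' squared Pearson correlation, and the AUC for discriminating recovered from
#' non-recovered eyes after dichotomizing both series at the amplitude
#' cutoff (an eye at or below 15.5 uV counts as non-recovered; the predicted
#' value is used as the continuous score with the lower-is-positive
#' orientation).
#'
#' @param predicted,observed Aligned numeric vectors, at least 3 pairs.
#' @param cutoff Recovery cutoff in uV, default 15.5.
#' @return List: `icc`, `r2`, `auc` (`NA` with a message attribute when all
#'   observed values fall on one side of the cutoff).
#' @export
evaluate_prediction <- function(predicted, observed, cutoff = 15.5) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 3) stop("need at least 3 prediction/observation pairs")
  icc <- icc_pairs(cbind(right = predicted, left = observed),
                   type = "consistency")$icc
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) 0 else
    stats::cor(predicted, observed)^2
  event <- observed <= cutoff
  auc <- if (any(event) && !all(event) && length(unique(predicted)) >= 2) {
    auc_rank(predicted, event, orientation = "lower")
  } else NA_real_
  list(icc = icc, r2 = r2, auc = auc)
}
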