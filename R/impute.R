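## Single-imputation procedures: ordinary-least-squares prediction with a
## residual-SD Gaussian perturbation (electrophysiology), and unweighted
## 5-nearest-neighbour means over standardized features (OCT). Observed cells
## are never altered.

#' Perturbed-regression single imputation
#'
#' Fits OLS of `target` on `predictors` over complete cases and fills each
#' missing target with the linear prediction plus Gaussian noise whose SD
#' equals the residual SD of the fit, so that single imputation does not
#' artificially shrink the target's variance. Only missing cells change.
#'
#' @param cohort An [eye_cohort()].
#' @param target Measurement variable to impute.
#' @param predictors Character vector of predictor variables.
#' @param seed Integer seed for the perturbation.
#' @return List with elements `cohort` (imputed copy) and `report`
#'   (`method`, `variable`, `n_imputed`, `n_left_missing` for rows whose
#'   predictors were themselves missing, `residual_sd`, `seed`).
#' @export
impute_regression_perturbed <- function(cohort, target, predictors, seed = 1L) {
  stopifnot(inherits(cohort, "eye_cohort"))
  stopifnot(target %in% measurement_vars(),
            all(predictors %in% c(measurement_vars(), "age")))
  df <- as.data.frame(cohort)
  complete <- stats::complete.cases(df[, c(target, predictors)])
  if (sum(complete) < 10) {
    stop(sprintf("need >= 10 complete cases on (%s; %s), have %d",
                 target, paste(predictors, collapse = ", "), sum(complete)))
  }
  fml <- stats::reformulate(predictors, response = target)
  fit <- stats::lm(fml, data = df[complete, , drop = FALSE])
  ## a zero-residual fit is a legitimate degenerate case (imputed = predicted)
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (!is.finite(sigma)) sigma <- 0

  needs <- which(is.na(df[[target]]))
  pred_ok <- needs[stats::complete.cases(df[needs, predictors, drop = FALSE])]
  set.seed(as.integer(seed))
  if (length(pred_ok)) {
    mu <- stats::predict(fit, newdata = df[pred_ok, , drop = FALSE])
    val <- mu + stats::rnorm(length(pred_ok), 0, sigma)
    ## measurements are strictly positive; redraw offending perturbations
    for (iter in 1:100) {
      bad <- which(val <= 0)
      if (!length(bad)) break
      val[bad] <- mu[bad] + stats::rnorm(length(bad), 0, sigma)
    }
    val[val <= 0] <- pmax(mu[val <= 0], min(df[[target]], na.rm = TRUE))
    df[[target]][pred_ok] <- val
  }
  out <- eye_cohort(df, provenance = paste0(attr(cohort, "provenance"),
                                            " + regression imputation of ", target))
  list(cohort = out,
       report = list(method = "regression_perturbed", variable = target,
                     predictors = predictors,
                     n_imputed = length(pred_ok),
                     n_left_missing = length(needs) - length(pred_ok),
                     residual_sd = sigma, seed = as.integer(seed)))
}

#' k-nearest-neighbour single imputation
#'
#' For each row missing `target`, finds the `k` complete-case rows nearest in
#' standardized Euclidean distance over `features` (z-scores from complete
#' cases; a row's distance uses only its observed features) and imputes the
#' unweighted mean of their targets. Deterministic; distance ties are broken
#' by row order.
#'
#' @param cohort An [eye_cohort()].
#' @param target Measurement variable to impute.
#' @param features Character vector of distance features.
#' @param k Number of neighbours, default 5.
#' @return List with elements `cohort` and `report` (`method = "knn5"` style
#'   fields as in [impute_regression_perturbed()]).
#' @export
impute_knn <- function(cohort, target, features, k = 5L) {
  stopifnot(inherits(cohort, "eye_cohort"))
  stopifnot(target %in% measurement_vars(),
            all(features %in% c(measurement_vars(), "age")))
  k <- as.integer(k)
  df <- as.data.frame(cohort)
  complete <- which(stats::complete.cases(df[, c(target, features)]))
  if (length(complete) < k) {
    stop(sprintf("need >= k = %d complete cases, have %d", k, length(complete)))
  }
  feat <- as.matrix(df[, features, drop = FALSE])
  mu <- colMeans(feat[complete, , drop = FALSE])
  sdv <- apply(feat[complete, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(feat, 2, mu), 2, sdv, "/")

  needs <- which(is.na(df[[target]]))
  n_imputed <- 0L; n_left <- 0L
  for (i in needs) {
    obs <- which(!is.na(z[i, ]))
    if (!length(obs)) { n_left <- n_left + 1L; next }
    d <- sqrt(colSums((t(z[complete, obs, drop = FALSE]) - z[i, obs])^2))
    nb <- complete[order(d, seq_along(d))[seq_len(k)]]
    df[[target]][i] <- mean(df[[target]][nb])
    n_imputed <- n_imputed + 1L
  }
  out <- eye_cohort(df, provenance = paste0(attr(cohort, "provenance"),
                                            " + ", k, "-NN imputation of ", target))
  list(cohort = out,
       report = list(method = paste0("knn", k), variable = target,
                     features = features, n_imputed = n_imputed,
                     n_left_missing = n_left, k = k))
}
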