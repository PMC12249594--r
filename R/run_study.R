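## End-to-end study replica: generate (or read) a cohort, age-match controls,
## inject and impute missingness, build the six ESC datasets, estimate
## inter-eye ICCs and the pooling decision, run the univariate comparison
## battery, the cutoff/ROC diagnostics, and the SSBD diagnosis and 12-month
## prediction models. One top-level seed derives per-stage seeds by a fixed
## offset scheme so a single integer reproduces everything.

stage_seed <- function(seed, stage) {
  offsets <- c(generate = 1L, missing = 2L, impute = 3L, esc = 4L,
               diagnostics = 5L, ssbd = 6L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Default study configuration
#'
#' Returns the configuration list shipped with the package
#' (`inst/extdata/default_config.yaml`): generator settings reproducing the
#' published group summaries, the fixed diagnostic cutoffs (15.5 uV for
#' `AOz12`, 65 um for `BiNS`), bootstrap iterations and SSBD settings.
#'
#' @return Nested named list.
#' @export
default_study_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "escbio"))
}

#' Run the full eye-selection-criteria study replica
#'
#' Executes every stage in order on a synthetic cohort and returns the
#' results plus a run manifest (per-stage seeds, row counts, config hash,
#' package version). Any stage failure aborts with a stage-named error.
#'
#' @param config A nested list like [default_study_config()], or a path to a
#'   YAML file with the same structure. Fields not supplied fall back to the
#'   defaults.
#' @return List of class `"study_report"` with elements `manifest`, `cohort`
#'   sizes, `pooling` (per-group ICC table and decision), `univariate` (one
#'   `esc_comparison` per variable), `patients_vs_controls` p-value table,
#'   `diagnostics` (12 `diagnostic_result`s: 6 criteria x 2 biomarkers),
#'   `ssbd_diagnosis` (per criterion) and `ssbd_prediction` (per criterion).
#' @export
run_study <- function(config = default_study_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_study_config(), config)
  seed <- as.integer(cfg$seed)
  stage <- "setup"
  fail <- function(e) stop(sprintf("%s stage: %s", stage, conditionMessage(e)),
                           call. = FALSE)

  tryCatch({
    stage <- "generate"
    gen <- generator_config(n_patients = cfg$generator$n_patients,
                            n_controls = cfg$generator$n_control_pool,
                            missing_rate = cfg$generator$missing_rate,
                            seed = stage_seed(seed, "generate"))
    cohort <- generate_cohort(gen)
    patients <- eye_cohort(as.data.frame(cohort[cohort$group == "patient", ]),
                           provenance = attr(cohort, "provenance"))
    pool <- eye_cohort(as.data.frame(cohort[cohort$group == "control", ]),
                       provenance = attr(cohort, "provenance"))
    controls <- match_controls(patients, pool)
    cohort <- eye_cohort(rbind(as.data.frame(patients), as.data.frame(controls)),
                         provenance = attr(cohort, "provenance"))

    stage <- "missing"
    rate <- cfg$generator$missing_rate
    if (rate > 0) {
      cohort <- inject_missingness(cohort, rate, seed = stage_seed(seed, "missing"))
      stage <- "impute"
      iseed <- stage_seed(seed, "impute")
      for (v in measurement_vars("pvep")) {
        preds <- setdiff(measurement_vars("pvep"), v)
        cohort <- impute_regression_perturbed(cohort, v, preds,
                                              seed = iseed)$cohort
      }
      for (v in measurement_vars("oct")) {
        feats <- setdiff(measurement_vars("oct"), v)
        cohort <- impute_knn(cohort, v, feats, k = 5)$cohort
      }
    }

    stage <- "esc"
    eseed <- stage_seed(seed, "esc")
    patients <- eye_cohort(as.data.frame(cohort[cohort$group == "patient", ]),
                           provenance = "patients")
    controls <- eye_cohort(as.data.frame(cohort[cohort$group == "control", ]),
                           provenance = "controls")
    esc_pvep <- build_all_esc_datasets(patients, family = "pvep", seed = eseed)
    esc_oct <- build_all_esc_datasets(patients, family = "oct", seed = eseed)
    esc_all <- build_all_esc_datasets(patients, family = "all", seed = eseed)
    control_rse <- build_esc_dataset(controls, "RSE", family = "all",
                                     seed = eseed)

    stage <- "reliability"
    icc_tab <- list()
    for (g in c("control", "patient")) {
      sub <- if (g == "control") controls else patients
      res <- lapply(measurement_vars(), function(v) {
        pr <- interocular_pairs(sub, v)
        if (nrow(pr) >= 3) icc_pairs(pr) else NULL
      })
      names(res) <- measurement_vars()
      icc_tab[[g]] <- res[!vapply(res, is.null, logical(1))]
    }
    pooling <- pooling_decision(icc_tab$control)

    stage <- "univariate"
    univariate <- lapply(measurement_vars(), function(v) {
      ds <- if (v %in% measurement_vars("pvep")) esc_pvep else esc_oct
      compare_esc_groups(ds, v)
    })
    names(univariate) <- measurement_vars()
    pvc <- sapply(measurement_vars(), function(v) {
      sapply(esc_all, function(d) {
        compare_patients_vs_controls(d[[v]], control_rse[[v]])
      })
    })

    stage <- "diagnostics"
    dseed <- stage_seed(seed, "diagnostics")
    cutoffs <- c(AOz12 = cfg$cutoffs$AOz12, BiNS = cfg$cutoffs$BiNS)
    diag_results <- list()
    for (bm in names(cutoffs)) {
      fam <- if (bm == "AOz12") esc_pvep else esc_oct
      for (cr in ESC_CRITERIA) {
        diag_results[[paste(bm, cr, sep = ".")]] <-
          evaluate_biomarker(fam[[cr]], control_rse, bm,
                             cutoff = cutoffs[[bm]],
                             ci_iterations = cfg$bootstrap_iterations,
                             seed = dseed)
      }
    }

    stage <- "ssbd"
    sseed <- stage_seed(seed, "ssbd")
    sc <- ssbd_config(n_subsamples = cfg$ssbd$n_subsamples,
                      subsample_fraction = cfg$ssbd$subsample_fraction,
                      alpha = cfg$ssbd$alpha,
                      cv_folds = cfg$ssbd$cv_folds, seed = sseed)
    predictors <- c(amplitude_vars(), measurement_vars("oct"))
    ssbd_diag <- lapply(esc_all, function(d) {
      tab <- rbind(as.data.frame(d)[, c("subject_id", "group", predictors)],
                   as.data.frame(control_rse)[, c("subject_id", "group", predictors)])
      tab <- tab[stats::complete.cases(tab), ]
      fit_ssbd(tab, predictors, "group", mode = "diagnosis", config = sc)
    })
    pred_vars <- c("AOz12", measurement_vars("oct"))
    ssbd_pred <- lapply(esc_all, function(d) {
      tab <- join_outcome(d, cohort, "AOz12", "m12")
      tab <- as.data.frame(tab)[, c("subject_id", pred_vars, "AOz12_m12")]
      tab <- tab[stats::complete.cases(tab), ]
      fit_ssbd(tab, pred_vars, "AOz12_m12", mode = "prediction", config = sc,
               recovery_cutoff = cfg$cutoffs$AOz12)
    })

    manifest <- list(
      config_hash = unname(tools::md5sum(local({
        f <- tempfile(); writeLines(deparse(cfg), f); f
      }))),
      package_version = as.character(utils::packageVersion("escbio")),
      seed = seed,
      stage_seeds = vapply(c("generate", "missing", "impute", "esc",
                             "diagnostics", "ssbd"),
                           function(s) stage_seed(seed, s), integer(1)),
      rows = c(cohort = nrow(cohort),
               patients = nrow(patients), controls = nrow(controls),
               vapply(esc_all, nrow, integer(1))))

    structure(list(manifest = manifest,
                   pooling = pooling, icc = icc_tab,
                   univariate = univariate,
                   patients_vs_controls = pvc,
                   diagnostics = diag_results,
                   ssbd_diagnosis = ssbd_diag,
                   ssbd_prediction = ssbd_pred),
              class = "study_report")
  }, error = fail)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  seed:", x$manifest$seed, " package:", x$manifest$package_version, "\n")
  cat("  rows:", paste(names(x$manifest$rows), x$manifest$rows,
                       sep = "=", collapse = " "), "\n")
  cat("  pooling decision (controls):", x$pooling$decision, "\n")
  cat("  diagnostics:\n")
  for (d in x$diagnostics) {
    cat("   "); print(d)
  }
  cat("  SSBD diagnosis AUC by criterion:",
      paste(names(x$ssbd_diagnosis),
            sprintf("%.3f", vapply(x$ssbd_diagnosis, function(s) s$model_auc,
                                   numeric(1))), sep = "=", collapse = " "), "\n")
  invisible(x)
}
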