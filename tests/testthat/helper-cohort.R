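## Small in-code fixtures shared across tests.

tiny_record <- function(subject_id, side, timepoint = "pre", group = "patient",
                        age = 50, ...) {
  row <- data.frame(subject_id = subject_id, group = group, side = side,
                    timepoint = timepoint, age = age,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (v in names(extra)) row[[v]] <- extra[[v]]
  row
}

## A deterministic two-subject cohort with both eyes and a few measurements.
tiny_cohort <- function() {
  eye_cohort(rbind(
    tiny_record("S1", "right", AOz12 = 4.1, BiNS = 58, gRNFL = 77, TS = 50, gGCCIPL = 63),
    tiny_record("S1", "left",  AOz12 = 5.2, BiNS = 61, gRNFL = 84, TS = 52, gGCCIPL = 66),
    tiny_record("S2", "right", AOz12 = 17.5, BiNS = 88, gRNFL = 102, TS = 65, gGCCIPL = 86,
                group = "control"),
    tiny_record("S2", "left",  AOz12 = 18.0, BiNS = 86, gRNFL = 99, TS = 63, gGCCIPL = 84,
                group = "control")
  ))
}

## Cohort with per-side pVEP availability: `n_right` subjects have a right-eye
## AOz12, the last `n_left` of them also have a left-eye AOz12. gRNFL always
## present so worst/best-eye classification works.
availability_cohort <- function(n_right = 19, n_left = 16) {
  rows <- list()
  for (i in seq_len(n_right)) {
    sid <- sprintf("S%02d", i)
    rows[[length(rows) + 1]] <- tiny_record(sid, "right", AOz12 = 4 + i / 10,
                                            gRNFL = 80 + i)
    has_left <- i > n_right - n_left
    rows[[length(rows) + 1]] <- tiny_record(
      sid, "left", AOz12 = if (has_left) 5 + i / 10 else NA_real_,
      gRNFL = 78 + i)
  }
  eye_cohort(do.call(rbind, rows))
}

patients_of <- function(cohort) {
  eye_cohort(as.data.frame(cohort[cohort$group == "patient", ]))
}
controls_of <- function(cohort) {
  eye_cohort(as.data.frame(cohort[cohort$group == "control", ]))
}

## Synthetic design matrix for exercising the stability-selection machinery.
ssbd_toy <- function(n = 100, p = 5, beta = rep(0, p), family = "binomial",
                     seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- drop(x %*% beta)
  y <- if (family == "binomial") rbinom(n, 1, plogis(eta)) else
    eta + rnorm(n)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), x, y = y,
             stringsAsFactors = FALSE)
}
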