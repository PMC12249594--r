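#' @keywords internal
"_PACKAGE"

## Column roster shared across the package. One row of a cohort is one eye at
## one timepoint; any measurement may be NA.

#' Measurement variable names
#'
#' Variable rosters used throughout the package: pattern visual evoked
#' potential (pVEP) P100 latencies (`LOz*`, ms) and amplitudes (`AOz*`, uV) at
#' 60/20/12 arcmin, and OCT thicknesses (um): global peripapillary RNFL
#' (`gRNFL`), temporal RNFL sectors (`TS`), global ganglion cell complex plus
#' inner plexiform layer (`gGCCIPL`) and its bi-nasal sectors (`BiNS`).
#'
#' @param family `"pvep"`, `"oct"` or `"all"`.
#' @return Character vector of measurement column names.
#' @export
#' @examples
#' measurement_vars("oct")
measurement_vars <- function(family = c("all", "pvep", "oct")) {
  family <- match.arg(family)
  pvep <- c("LOz60", "LOz20", "LOz12", "AOz60", "AOz20", "AOz12")
  oct <- c("gRNFL", "TS", "gGCCIPL", "BiNS")
  switch(family, pvep = pvep, oct = oct, all = c(pvep, oct))
}

latency_vars <- function() c("LOz60", "LOz20", "LOz12")
amplitude_vars <- function() c("AOz60", "AOz20", "AOz12")

cohort_columns <- function() {
  c("subject_id", "group", "side", "timepoint", "age", measurement_vars())
}

#' Construct a paired-eye cohort table
#'
#' Builds and validates the tabular container the whole pipeline consumes: one
#' row per eye x timepoint, with identifying columns `subject_id`, `group`
#' (`"patient"`/`"control"`), `side` (`"right"`/`"left"`), `timepoint`
#' (`"pre"`, `"m3"`, `"m12"`), `age` in years, and the measurement columns of
#' [measurement_vars()].
#'
#' Validation enforces: no duplicated (subject, side, timepoint); all present
#' measurements strictly positive; controls observed at `"pre"` only (healthy
#' volunteers are evaluated a single time); every subject has at least one
#' pre-surgical record.
#'
#' @param records A data.frame with the columns above (missing measurement
#'   columns are added as `NA`).
#' @param provenance Free-text origin note (generator seed or input file).
#' @return A data.frame of class `"eye_cohort"` with attribute `provenance`.
#' @export
eye_cohort <- function(records, provenance = "constructed in R") {
  stopifnot(is.data.frame(records))
  required <- c("subject_id", "group", "side", "timepoint")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"age" %in% names(records)) records$age <- NA_real_
  for (v in measurement_vars()) {
    if (!v %in% names(records)) records[[v]] <- NA_real_
    records[[v]] <- as.numeric(records[[v]])
  }
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  records$side <- as.character(records$side)
  records$timepoint <- as.character(records$timepoint)
  records <- records[, cohort_columns()]
  rownames(records) <- NULL
  validate_cohort(records)
  structure(records, provenance = provenance,
            class = c("eye_cohort", "data.frame"))
}

validate_cohort <- function(records) {
  if (!all(records$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  if (!all(records$side %in% c("right", "left"))) {
    stop("side must be 'right' or 'left'")
  }
  if (!all(records$timepoint %in% c("pre", "m3", "m12"))) {
    stop("timepoint must be one of 'pre', 'm3', 'm12'")
  }
  key <- paste(records$subject_id, records$side, records$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicated (subject, side, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (v in measurement_vars()) {
    bad <- which(!is.na(records[[v]]) & records[[v]] <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive %s in row(s) %s", v,
                   paste(bad, collapse = ", ")))
    }
  }
  ctrl_late <- records$group == "control" & records$timepoint != "pre"
  if (any(ctrl_late)) {
    stop("controls may only have timepoint 'pre' (rows ",
         paste(which(ctrl_late), collapse = ", "), ")")
  }
  no_pre <- setdiff(records$subject_id,
                    records$subject_id[records$timepoint == "pre"])
  if (nrow(records) && length(no_pre)) {
    stop("subjects without any pre-surgical record: ",
         paste(no_pre, collapse = ", "))
  }
  invisible(records)
}

#' @export
print.eye_cohort <- function(x, ...) {
  cat(sprintf("<eye_cohort> %d records, %d subjects (%d patients, %d controls)\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(x$subject_id[x$group == "patient"])),
              length(unique(x$subject_id[x$group == "control"]))))
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Reads a UTF-8 delimited file with one row per eye x timepoint and the column
#' names of [cohort_columns()]; empty measurement cells become `NA`. The result
#' is validated (duplicate eye records or non-positive measurements are
#' errors).
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return An [eye_cohort()].
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", check.names = FALSE)
  for (v in c("age", measurement_vars())) {
    if (v %in% names(df)) df[[v]] <- as.numeric(df[[v]])
  }
  eye_cohort(df, provenance = paste("read from", path))
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: stable column order, missing values as empty
#' cells. Round-trips values written with up to 6 significant digits exactly.
#'
#' @param cohort An [eye_cohort()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  stopifnot(inherits(cohort, "eye_cohort"))
  utils::write.table(as.data.frame(cohort), path, sep = delim, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Age-match controls to patients
#'
#' Greedy nearest-age 1:1 matching without replacement, the single-covariate
#' reduction of propensity-score matching: with age as the only covariate the
#' propensity score is monotone in age, so nearest-propensity and nearest-age
#' orderings coincide. Patients are processed in descending age order; ties in
#' candidate age are broken by pool order, which makes the result deterministic
#' for a given input order.
#'
#' @param patients An [eye_cohort()] of patients (age present at `"pre"`).
#' @param pool An [eye_cohort()] of candidate controls, at least as many
#'   subjects as `patients`.
#' @return An [eye_cohort()] containing all records of the selected controls,
#'   with attribute `matching` (data.frame: patient, control, patient and
#'   control age).
#' @export
match_controls <- function(patients, pool) {
  p_tab <- subject_ages(patients)
  c_tab <- subject_ages(pool)
  if (nrow(c_tab) < nrow(p_tab)) {
    stop(sprintf("control pool (%d) smaller than patient set (%d)",
                 nrow(c_tab), nrow(p_tab)))
  }
  if (anyNA(p_tab$age) || anyNA(c_tab$age)) {
    stop("age must be present for all subjects to match")
  }
  p_tab <- p_tab[order(-p_tab$age), , drop = FALSE]
  taken <- rep(FALSE, nrow(c_tab))
  pairs <- data.frame(patient = p_tab$subject_id, control = NA_character_,
                      patient_age = p_tab$age, control_age = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(p_tab))) {
    d <- abs(c_tab$age - p_tab$age[i])
    d[taken] <- Inf
    j <- which.min(d)  # ties -> first in pool order
    taken[j] <- TRUE
    pairs$control[i] <- c_tab$subject_id[j]
    pairs$control_age[i] <- c_tab$age[j]
  }
  keep <- pool[pool$subject_id %in% pairs$control, , drop = FALSE]
  out <- eye_cohort(as.data.frame(keep),
                    provenance = paste0("age-matched controls (",
                                        attr(pool, "provenance"), ")"))
  attr(out, "matching") <- pairs
  out
}

subject_ages <- function(cohort) {
  pre <- cohort[cohort$timepoint == "pre", c("subject_id", "age")]
  agg <- pre[!duplicated(pre$subject_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
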