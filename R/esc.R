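## Construction of the six eye-selection-criteria (ESC) datasets: right eye
## (RE), left eye (LE), randomly selected eye (RSE), both eyes (BoE), best eye
## (BeE) and worst eye (WE). Best/worst status is decided by pre-surgical
## global RNFL thickness: the worst eye is the one with strictly lower gRNFL.

ESC_CRITERIA <- c("RE", "LE", "RSE", "BoE", "BeE", "WE")

#' Build an eye-selection-criteria dataset
#'
#' Selects, per subject, which eye(s) enter analysis under one of the six
#' criteria. Eligibility is per variable family: an eye is eligible at the
#' requested timepoint if it has a record there with at least one non-missing
#' measurement of that family (pVEP and OCT availability differ in practice,
#' so datasets are built per family).
#'
#' Rules: `RE`/`LE` keep the named side where eligible (pure per-side
#' availability); `RSE` draws `u ~ U[0,1)` per subject with both eyes
#' eligible, `u < 0.5` selecting the right eye, and falls back to the only
#' eligible eye otherwise; `BoE` keeps all eligible eyes as independent rows;
#' `WE`/`BeE` keep the eye with strictly lower/higher pre-surgical `gRNFL`,
#' breaking exact ties by lower/higher `BiNS` and then by the RSE random rule.
#' Subjects with a single classifiable eye contribute that eye; subjects with
#' `gRNFL` missing in all eyes are excluded from `WE`/`BeE` with an audit row.
#'
#' @param cohort An [eye_cohort()].
#' @param criterion One of `"RE"`, `"LE"`, `"RSE"`, `"BoE"`, `"BeE"`, `"WE"`.
#' @param timepoint Timepoint of the returned rows (selection for `WE`/`BeE`
#'   is always decided on pre-surgical `gRNFL`).
#' @param family `"pvep"`, `"oct"` or `"all"` eligibility family.
#' @param seed Integer seed, required for `RSE` (and for random tie-breaks in
#'   `WE`/`BeE`).
#' @return A data.frame of class `"esc_dataset"` (rows of the cohort) with
#'   attributes `criterion`, `family`, `timepoint`, `seed_used` and `audit`
#'   (one row per subject: `chosen_side`, `reason` in
#'   `fixed-side`/`random-draw`/`lower-gRNFL`/`higher-gRNFL`/
#'   `only-eligible-eye`/`excluded-no-gRNFL`, and `random_u` when drawn).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 6, n_controls = 0))
#' we <- build_esc_dataset(cohort, "WE", family = "oct")
#' attr(we, "audit")
build_esc_dataset <- function(cohort, criterion, timepoint = "pre",
                              family = c("all", "pvep", "oct"), seed = NULL) {
  stopifnot(inherits(cohort, "eye_cohort"))
  criterion <- ESC_CRITERIA[match(toupper(criterion), toupper(ESC_CRITERIA))]
  if (is.na(criterion)) {
    stop("criterion must be one of ", paste(ESC_CRITERIA, collapse = ", "))
  }
  family <- match.arg(family)
  if (criterion == "RSE" && is.null(seed)) stop("RSE requires a seed")
  if (!is.null(seed)) set.seed(as.integer(seed))

  fam_vars <- measurement_vars(family)
  tp_rows <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  has_fam <- rowSums(!is.na(tp_rows[, fam_vars, drop = FALSE])) > 0
  elig <- tp_rows[has_fam, , drop = FALSE]
  pre_rows <- cohort[cohort$timepoint == "pre", , drop = FALSE]

  subjects <- unique(elig$subject_id)
  audit <- data.frame(subject_id = character(0), criterion = character(0),
                      chosen_side = character(0), reason = character(0),
                      random_u = numeric(0), stringsAsFactors = FALSE)
  keep_idx <- integer(0)

  grnfl_at_pre <- function(sid, side) {
    v <- pre_rows$gRNFL[pre_rows$subject_id == sid & pre_rows$side == side]
    if (length(v)) v[1] else NA_real_
  }
  bins_at_pre <- function(sid, side) {
    v <- pre_rows$BiNS[pre_rows$subject_id == sid & pre_rows$side == side]
    if (length(v)) v[1] else NA_real_
  }

  for (sid in subjects) {
    rows_s <- which(elig$subject_id == sid)
    sides <- elig$side[rows_s]
    add <- function(side, reason, u = NA_real_) {
      keep_idx <<- c(keep_idx, rows_s[match(side, sides)])
      audit[nrow(audit) + 1L, ] <<- list(sid, criterion, side, reason, u)
    }
    if (criterion == "BoE") {
      keep_idx <- c(keep_idx, rows_s)
      audit[nrow(audit) + 1L, ] <- list(sid, criterion,
                                        paste(sort(sides), collapse = "+"),
                                        "fixed-side", NA_real_)
    } else if (criterion %in% c("RE", "LE")) {
      want <- if (criterion == "RE") "right" else "left"
      if (want %in% sides) add(want, "fixed-side")
      ## per-side availability: no fallback for RE/LE
    } else if (criterion == "RSE") {
      if (length(sides) == 1) {
        add(sides, "only-eligible-eye")
      } else {
        u <- stats::runif(1)
        add(if (u < 0.5) "right" else "left", "random-draw", u)
      }
    } else {  # WE / BeE
      g <- vapply(sides, function(s) grnfl_at_pre(sid, s), numeric(1))
      classifiable <- sides[!is.na(g)]
      if (length(classifiable) == 0) {
        audit[nrow(audit) + 1L, ] <- list(sid, criterion, NA_character_,
                                          "excluded-no-gRNFL", NA_real_)
      } else if (length(classifiable) == 1) {
        add(classifiable, "only-eligible-eye")
      } else {
        gc_ <- g[!is.na(g)]
        pick_low <- criterion == "WE"
        if (gc_[1] != gc_[2]) {
          side <- classifiable[if (pick_low) which.min(gc_) else which.max(gc_)]
          add(side, if (pick_low) "lower-gRNFL" else "higher-gRNFL")
        } else {
          b <- vapply(classifiable, function(s) bins_at_pre(sid, s), numeric(1))
          if (!anyNA(b) && b[1] != b[2]) {
            side <- classifiable[if (pick_low) which.min(b) else which.max(b)]
            add(side, if (pick_low) "lower-gRNFL" else "higher-gRNFL")
          } else {
            u <- stats::runif(1)
            add(if (u < 0.5) "right" else "left", "random-draw", u)
          }
        }
      }
    }
  }

  out <- elig[keep_idx, , drop = FALSE]
  if (nrow(out) == 0) stop("ESC dataset '", criterion, "' is empty")
  rownames(out) <- NULL
  structure(as.data.frame(out), criterion = criterion, family = family,
            timepoint = timepoint,
            seed_used = if (is.null(seed)) NA_integer_ else as.integer(seed),
            audit = audit, class = c("esc_dataset", "data.frame"))
}

#' @export
print.esc_dataset <- function(x, ...) {
  cat(sprintf("<esc_dataset> criterion=%s family=%s timepoint=%s: %d rows, %d subjects\n",
              attr(x, "criterion"), attr(x, "family"), attr(x, "timepoint"),
              nrow(x), length(unique(x$subject_id))))
  invisible(x)
}

#' Build all six eye-selection-criteria datasets
#'
#' @inheritParams build_esc_dataset
#' @return Named list of six `esc_dataset` objects (`RE`, `LE`, `RSE`, `BoE`,
#'   `BeE`, `WE`).
#' @export
build_all_esc_datasets <- function(cohort, timepoint = "pre",
                                   family = "all", seed = 1L) {
  out <- lapply(ESC_CRITERIA, function(cr) {
    build_esc_dataset(cohort, cr, timepoint = timepoint, family = family,
                      seed = seed)
  })
  names(out) <- ESC_CRITERIA
  out
}

#' Right/left value pairs for a variable
#'
#' Returns one `(right, left)` pair per subject with both eyes measured for
#' `variable` at `timepoint`; subjects missing either eye are dropped.
#'
#' @param cohort An [eye_cohort()].
#' @param variable A measurement variable name.
#' @param timepoint Timepoint, default `"pre"`.
#' @return Data.frame with columns `subject_id`, `right`, `left`.
#' @export
interocular_pairs <- function(cohort, variable, timepoint = "pre") {
  stopifnot(inherits(cohort, "eye_cohort"))
  if (!variable %in% measurement_vars()) {
    stop("unknown variable: ", variable)
  }
  tp <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  r <- tp[tp$side == "right", c("subject_id", variable)]
  l <- tp[tp$side == "left", c("subject_id", variable)]
  names(r)[2] <- "right"; names(l)[2] <- "left"
  m <- merge(r, l, by = "subject_id", sort = FALSE)
  m <- m[!is.na(m$right) & !is.na(m$left), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Attach a follow-up outcome to an ESC dataset
#'
#' Joins a follow-up measurement of the *same eye* onto a (typically
#' pre-surgical) ESC dataset, for prediction modelling: e.g. the 12-month
#' `AOz12` outcome next to pre-surgical predictors.
#'
#' @param dataset An `esc_dataset` (rows at the predictor timepoint).
#' @param cohort The cohort the dataset came from.
#' @param variable Outcome variable, default `"AOz12"`.
#' @param timepoint Outcome timepoint, default `"m12"`.
#' @return The dataset with an extra column `<variable>_<timepoint>`; rows
#'   without an outcome record keep `NA`.
#' @export
join_outcome <- function(dataset, cohort, variable = "AOz12",
                         timepoint = "m12") {
  stopifnot(inherits(cohort, "eye_cohort"))
  fu <- cohort[cohort$timepoint == timepoint, c("subject_id", "side", variable)]
  newcol <- paste0(variable, "_", timepoint)
  names(fu)[3] <- newcol
  out <- merge(as.data.frame(dataset), fu, by = c("subject_id", "side"),
               all.x = TRUE, sort = FALSE)
  for (a in c("criterion", "family", "timepoint", "seed_used", "audit")) {
    attr(out, a) <- attr(dataset, a)
  }
  class(out) <- c("esc_dataset", "data.frame")
  out
}
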