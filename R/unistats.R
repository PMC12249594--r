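## Univariate comparison battery: normality screening, rank-based omnibus and
## pairwise comparisons across the six ESC datasets (Kruskal-Wallis plus
## Holm-adjusted Wilcoxon rank-sum), and the patients-vs-controls
## Mann-Whitney test.

#' Normality screen with a size-dependent test
#'
#' Shapiro-Wilk for samples up to 50 observations, Kolmogorov-Smirnov against
#' a normal with estimated mean and SD for larger ones (the estimated-
#' parameter caveat is recorded: the KS p-value is conservative when
#' parameters are fitted from the same sample).
#'
#' @param values Numeric vector (`NA`s dropped); at least 3 distinct values.
#' @return List: `p_value`, `test` (`"shapiro_wilk"` or
#'   `"kolmogorov_smirnov"`), `n`, `caveat` (KS branch only).
#' @export
normality_check <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant input: normality test undefined")
  if (n <= 50) {
    list(p_value = stats::shapiro.test(x)$p.value, test = "shapiro_wilk",
         n = n, caveat = NULL)
  } else {
    p <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    list(p_value = p, test = "kolmogorov_smirnov", n = n,
         caveat = "KS computed with parameters estimated from the sample")
  }
}

#' Homoscedasticity screen (Levene)
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return Levene test p-value (centre = median).
#' @export
levene_check <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  tab <- car::leveneTest(values[ok] ~ factor(groups[ok]))
  tab[["Pr(>F)"]][1]
}

## Two-sided rank-sum p-value with the package's exactness rule: exact when
## both groups have n <= 25 and there are no ties, tie-corrected normal
## approximation otherwise.
ranksum_p <- function(x, y) {
  exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Compare a variable across ESC datasets
#'
#' Omnibus Kruskal-Wallis across the supplied datasets followed by all
#' pairwise two-sided rank-sum tests with Holm adjustment, reported as a
#' lower-triangular matrix (the layout of the published comparison tables).
#' The datasets share subjects by construction; they are nevertheless treated
#' as independent columns, which is the displayed procedure of the original
#' analysis, and the caveat is attached to the result.
#'
#' For very small problems (total n of at most `exact_max_n` with no ties)
#' the omnibus p-value is the exhaustive permutation tail probability of the
#' Kruskal-Wallis statistic rather than its chi-square approximation.
#'
#' @param datasets Named list of `esc_dataset` objects (or data.frames with
#'   the variable column). Datasets with fewer than 2 observations are
#'   excluded with a warning.
#' @param variable Measurement variable to compare.
#' @param exact_max_n Total-size ceiling for the exact omnibus, default 12.
#' @return List of class `"esc_comparison"`: `variable`, `omnibus_p`,
#'   `omnibus_method`, `pairwise` (lower-triangular Holm-adjusted matrix),
#'   `pairwise_raw`, `normality_p` per dataset, `levene_p`, `n`, `test_used`,
#'   `caveat`.
#' @export
compare_esc_groups <- function(datasets, variable, exact_max_n = 12) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  nm <- names(datasets)
  if (is.null(nm)) nm <- paste0("D", seq_along(datasets))
  values <- lapply(datasets, function(d) {
    v <- d[[variable]]
    v[!is.na(v)]
  })
  names(values) <- nm
  sizes <- lengths(values)
  if (any(sizes < 2)) {
    warning("excluding dataset(s) with < 2 observations: ",
            paste(nm[sizes < 2], collapse = ", "))
    values <- values[sizes >= 2]
  }
  if (length(values) < 2) stop("need at least 2 nonempty datasets")

  all_v <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)))
  no_ties <- !anyDuplicated(all_v)
  if (length(all_v) <= exact_max_n && no_ties) {
    omnibus <- kw_exact_p(values)
    method <- "kruskal_wallis_exact_permutation"
  } else {
    omnibus <- stats::kruskal.test(all_v, g)$p.value
    method <- "kruskal_wallis_chisq"
  }

  pairs <- utils::combn(names(values), 2)
  raw <- apply(pairs, 2, function(pr) ranksum_p(values[[pr[1]]], values[[pr[2]]]))
  adj <- stats::p.adjust(raw, method = "holm")
  k <- length(values)
  pm <- matrix(NA_real_, k, k, dimnames = list(names(values), names(values)))
  pm_raw <- pm
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    pm[b, a] <- adj[j]       # lower triangle: row index follows column index
    pm_raw[b, a] <- raw[j]
  }
  norm_p <- lapply(values, function(v) {
    if (length(v) >= 3 && stats::sd(v) > 0) normality_check(v)$p_value else NA_real_
  })
  structure(list(variable = variable, omnibus_p = omnibus,
                 omnibus_method = method, pairwise = pm, pairwise_raw = pm_raw,
                 normality_p = unlist(norm_p),
                 levene_p = levene_check(all_v, g),
                 n = lengths(values),
                 test_used = "kruskal_wallis+wilcoxon_holm",
                 caveat = "datasets overlap in subjects; treated as independent columns"),
            class = "esc_comparison")
}

## Exhaustive permutation null of the Kruskal-Wallis statistic for tiny
## untied samples: enumerate all assignments of the pooled ranks to groups of
## the observed sizes and count those with H >= observed.
kw_exact_p <- function(values) {
  sizes <- lengths(values)
  N <- sum(sizes)
  ranks <- rank(unlist(values, use.names = FALSE))
  kw_stat <- function(split_ranks) {
    12 / (N * (N + 1)) *
      sum(vapply(split_ranks, function(r) sum(r)^2 / length(r), numeric(1))) -
      3 * (N + 1)
  }
  obs <- kw_stat(split(ranks, rep(seq_along(sizes), sizes)))
  ge <- 0L; total <- 0L
  ## exhaustive enumeration of rank assignments via nested combinations
  count <- function(pool, idx, acc) {
    if (idx == length(sizes)) {
      h <- kw_stat(c(acc, list(pool)))
      total <<- total + 1L
      if (h >= obs - 1e-12) ge <<- ge + 1L
      return(invisible(NULL))
    }
    cmb <- utils::combn(length(pool), sizes[idx])
    for (j in seq_len(ncol(cmb))) {
      sel <- cmb[, j]
      count(pool[-sel], idx + 1L, c(acc, list(pool[sel])))
    }
    invisible(NULL)
  }
  count(seq_len(N), 1L, list())
  ge / total
}

#' Patients-versus-controls rank test
#'
#' Two-sided Mann-Whitney comparison of a biomarker between patients and
#' healthy controls.
#'
#' @param patient_values,control_values Numeric vectors (`NA`s dropped),
#'   both nonempty.
#' @return Two-sided p-value. Completely tied inputs give `p = 1` with a
#'   warning.
#' @export
compare_patients_vs_controls <- function(patient_values, control_values) {
  x <- patient_values[!is.na(patient_values)]
  y <- control_values[!is.na(control_values)]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied across both groups")
    return(1)
  }
  ranksum_p(x, y)
}
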