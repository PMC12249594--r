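test_that("normality screen switches test by sample size", {
  r <- normality_check(rnorm(20))
  expect_equal(r$test, "shapiro_wilk")
  r2 <- normality_check(rnorm(200))
  expect_equal(r2$test, "kolmogorov_smirnov")
  expect_match(r2$caveat, "estimated")
  expect_error(normality_check(rep(3, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "at least 3")
})

test_that("normality p-values are well-calibrated and powered against skew", {
  set.seed(42)
  ## Shapiro branch: exactly null-uniform p-values
  null_p <- vapply(1:400, function(i) normality_check(rnorm(40))$p_value,
                   numeric(1))
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)

  ## KS branch: with parameters estimated from the sample the p-values are
  ## conservative (the recorded caveat), never anti-conservative
  null_ks <- vapply(1:300, function(i) normality_check(rnorm(200))$p_value,
                    numeric(1))
  expect_lte(mean(null_ks < 0.05), 0.05)

  skew_reject <- vapply(1:200, function(i) {
    normality_check(rexp(200))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(skew_reject), 0.95)
})

test_that("identical datasets give a null omnibus and no pairwise rejections", {
  set.seed(3)
  base <- data.frame(AOz12 = rnorm(30, 10, 2))
  ds <- setNames(lapply(1:6, function(i) base), c("RE", "LE", "RSE", "BoE", "BeE", "WE"))
  cmp <- compare_esc_groups(ds, "AOz12")
  expect_gt(cmp$omnibus_p, 0.99)
  expect_true(all(cmp$pairwise[lower.tri(cmp$pairwise)] > 0.99, na.rm = TRUE))
  ## lower-triangular layout
  expect_true(all(is.na(cmp$pairwise[upper.tri(cmp$pairwise, diag = TRUE)])))
})

test_that("a strongly shifted dataset is flagged against every other", {
  set.seed(4)
  ds <- setNames(lapply(1:6, function(i) data.frame(AOz12 = rnorm(30, 10, 1))),
                 c("RE", "LE", "RSE", "BoE", "BeE", "WE"))
  ds$WE$AOz12 <- ds$WE$AOz12 - 10  # 10 SD shift
  cmp <- compare_esc_groups(ds, "AOz12")
  expect_lt(cmp$omnibus_p, 1e-6)
  we_ps <- c(cmp$pairwise["WE", ], cmp$pairwise[, "WE"])
  expect_true(all(we_ps[!is.na(we_ps)] < 0.05))
})

test_that("tiny untied omnibus equals the exhaustive permutation value", {
  ds <- list(A = data.frame(x = c(1, 2, 3)), B = data.frame(x = c(4, 5, 6)),
             C = data.frame(x = c(7, 8, 9)))
  cmp <- compare_esc_groups(ds, "x")
  expect_equal(cmp$omnibus_method, "kruskal_wallis_exact_permutation")

  ## oracle: enumerate all 1680 assignments of ranks 1..9 to groups of 3
  H <- function(g) {
    r <- unlist(g); N <- length(r)
    12 / (N * (N + 1)) * sum(vapply(g, function(v) sum(v)^2 / length(v),
                                    numeric(1))) - 3 * (N + 1)
  }
  obs <- H(list(1:3, 4:6, 7:9))
  ge <- 0; tot <- 0
  c1 <- combn(9, 3)
  for (i in seq_len(ncol(c1))) {
    rem <- setdiff(1:9, c1[, i])
    c2 <- combn(rem, 3)
    for (j in seq_len(ncol(c2))) {
      tot <- tot + 1
      if (H(list(c1[, i], c2[, j], setdiff(rem, c2[, j]))) >= obs - 1e-12) {
        ge <- ge + 1
      }
    }
  }
  expect_equal(cmp$omnibus_p, ge / tot)
  expect_equal(cmp$omnibus_p, 6 / 1680)
})

test_that("undersized datasets are excluded with a warning", {
  ds <- list(A = data.frame(x = rnorm(10)), B = data.frame(x = rnorm(10)),
             C = data.frame(x = 1))
  expect_warning(cmp <- compare_esc_groups(ds, "x"), "excluding")
  expect_equal(dim(cmp$pairwise), c(2, 2))
})

test_that("Holm adjustment is monotone and order-preserving", {
  set.seed(9)
  ds <- setNames(lapply(1:6, function(i) {
    data.frame(x = rnorm(20, mean = i / 3))
  }), c("RE", "LE", "RSE", "BoE", "BeE", "WE"))
  cmp <- compare_esc_groups(ds, "x")
  raw <- cmp$pairwise_raw[lower.tri(cmp$pairwise_raw)]
  adj <- cmp$pairwise[lower.tri(cmp$pairwise)]
  expect_true(all(adj >= raw - 1e-12))
  expect_true(all(diff(adj[order(raw)]) >= -1e-12))
})

test_that("rank tests are invariant to strictly monotone transformations", {
  set.seed(10)
  x <- rnorm(25, 5, 1); y <- rnorm(25, 6, 1)
  p1 <- compare_patients_vs_controls(x, y)
  p2 <- compare_patients_vs_controls(exp(x), exp(y))
  expect_equal(p1, p2)
  ds <- list(A = data.frame(v = x), B = data.frame(v = y))
  expect_equal(compare_esc_groups(ds, "v")$omnibus_p,
               compare_esc_groups(list(A = data.frame(v = x^3),
                                       B = data.frame(v = y^3)), "v")$omnibus_p,
               tolerance = 1e-10)
})

test_that("patients-vs-controls test matches exact enumeration and handles ties", {
  ## oracle: all C(4,2) = 6 rank assignments; {1,2} vs {3,4} is one of the two
  ## most extreme, so the two-sided exact p is 2/6
  expect_equal(compare_patients_vs_controls(c(1, 2), c(3, 4)), 2 / 6)
  expect_gt(compare_patients_vs_controls(c(1, 2, 3), c(1, 2, 3)), 0.99)
  expect_warning(p <- compare_patients_vs_controls(rep(4, 5), rep(4, 5)), "tied")
  expect_equal(p, 1)
  expect_error(compare_patients_vs_controls(numeric(0), 1), "nonempty")
})

test_that("patient-control amplitude separation reaches the reported order of magnitude", {
  ## at the configured group marginals the worst-eye AOz12 comparison is
  ## overwhelmingly significant in nearly every replicate
  hits <- vapply(1:60, function(s) {
    ch <- generate_cohort(generator_config(n_patients = 19, n_controls = 42,
                                           seed = 5000 + s))
    we <- build_esc_dataset(patients_of(ch), "WE", family = "all", seed = s)
    rse <- build_esc_dataset(controls_of(ch), "RSE", family = "all", seed = s)
    compare_patients_vs_controls(we$AOz12, rse$AOz12) < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("homoscedasticity screen returns a Levene p-value", {
  set.seed(12)
  v <- c(rnorm(40, 0, 1), rnorm(40, 0, 5))
  g <- rep(c("a", "b"), each = 40)
  expect_lt(levene_check(v, g), 0.01)
  v2 <- rnorm(80)
  expect_gt(levene_check(v2, g), 0.01)
})
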