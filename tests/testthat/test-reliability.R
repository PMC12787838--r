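test_that("one-way ANOVA decomposition matches hand and lm() oracles", {
  m <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  d <- variance_decomposition(m)
  expect_equal(d$ms_within, 0)
  expect_equal(d$ms_between, 3)
  expect_equal(d$df_between, 2L)
  expect_equal(d$df_within, 6L)

  # identical rows: no between-subject variance
  d2 <- variance_decomposition(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(d2$ms_between, 0)

  set.seed(101)
  for (i in 1:5) {
    n <- sample(4:15, 1L); k <- sample(2:5, 1L)
    mm <- matrix(stats::rnorm(n * k, 10, 3), n, k)
    d3 <- variance_decomposition(mm)
    o <- oracle_anova_oneway(mm)
    expect_equal(d3$ms_between, o$ms_between, tolerance = 1e-10)
    expect_equal(d3$ms_within, o$ms_within, tolerance = 1e-10)
    # independent route: one-way ANOVA via lm on the long layout
    long <- data.frame(y = as.vector(mm),
                       subj = factor(rep(seq_len(n), k)))
    av <- stats::anova(stats::lm(y ~ subj, data = long))
    expect_equal(d3$ms_between, av["subj", "Mean Sq"], tolerance = 1e-10)
    expect_equal(d3$ms_within, av["Residuals", "Mean Sq"], tolerance = 1e-10)
  }
})

test_that("Cronbach's alpha follows the item/total variance formula", {
  # perfectly duplicated items
  dup <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(cronbach_alpha(dup), 1)
  # two uncorrelated items with equal variance: alpha exactly 0
  z <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(cronbach_alpha(z), 0)
  expect_error(cronbach_alpha(matrix(5, 3, 3)), "undefined-alpha")
  set.seed(102)
  for (i in 1:5) {
    mm <- matrix(stats::rnorm(60, 0, 2), 20, 3)
    expect_equal(cronbach_alpha(mm), oracle_alpha(mm), tolerance = 1e-12)
  }
})

test_that("one-way ICC matches its printed formula at the closed-form corners", {
  expect_equal(icc_oneway(rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))), 1)
  # no between-subject variance: ICC = -1/(k-1)
  expect_equal(icc_oneway(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))), -0.5)
  expect_equal(icc_oneway(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), -1 / 3)
  expect_error(icc_oneway(matrix(2, 4, 3)), "undefined-ICC")
  set.seed(103)
  for (i in 1:10) {
    mm <- matrix(stats::rnorm(30), 10, 3)
    expect_equal(icc_oneway(mm), oracle_icc(mm), tolerance = 1e-10)
    expect_gte(icc_oneway(mm), -0.5 - 1e-12)
    expect_lte(icc_oneway(mm), 1)
  }
})

test_that("alpha and ICC are invariant to shifting and positive scaling", {
  set.seed(104)
  m <- matrix(stats::rnorm(45, 5, 2), 15, 3)
  for (tf in list(function(x) x + 100, function(x) 3.7 * x,
                  function(x) 0.2 * x - 8)) {
    expect_equal(cronbach_alpha(tf(m)), cronbach_alpha(m), tolerance = 1e-10)
    expect_equal(icc_oneway(tf(m)), icc_oneway(m), tolerance = 1e-10)
  }
})

test_that("ICC estimation recovers the generating intraclass correlation", {
  set.seed(105)
  est <- replicate(200, icc_oneway(simulate_repeated_measures(200, 3, 0.8)))
  expect_lt(abs(mean(est) - 0.8), 0.05)
})

test_that("qualitative bands use the standard reliability thresholds", {
  expect_equal(band_icc(c(0.71, 0.87, 0.90, 0.49, 0.75, 0.57, 0.995)),
               c("moderate", "good", "excellent", "poor", "good", "moderate",
                 "excellent"))
  expect_equal(band_alpha(c(0.88, 0.80, 0.99, 0.90, 0.75, 0.65, 0.4)),
               c("good", "good", "excellent", "excellent", "acceptable",
                 "questionable", "poor"))
  expect_error(band_icc(1.2))
})

test_that("Cohen's d uses the pooled SD and guards degenerate groups", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "undefined-d")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  set.seed(106)
  for (i in 1:5) {
    a <- stats::rnorm(12, 1); b <- stats::rnorm(9)
    expect_equal(cohens_d(a, b), oracle_cohens_d(a, b), tolerance = 1e-12)
  }
})

test_that("the reliability fit bundles mean, SD, alpha, ICC and bands", {
  set.seed(107)
  fit <- reliability(simulate_repeated_measures(40, 3, 0.9, mean = 20, sd = 5))
  expect_s3_class(fit, "reliability_fit")
  expect_equal(unname(coef(fit)), c(fit$alpha, fit$icc))
  expect_equal(fit$icc_band, band_icc(fit$icc))
  expect_lt(abs(fit$mean - 20), 2)
  expect_output(print(fit), "Cronbach")
  expect_output(summary(fit), "MS between")
  expect_error(repeated_measures(matrix(1, 1, 3)), "2 subjects")
  expect_error(repeated_measures(cbind(c(1, NA), c(2, 3))), "incomplete")
})

test_that("the 9-row reliability table bands each plane and body part", {
  for (rho in c(0.60, 0.82, 0.95)) {
    coh <- simulate_cohort(200, "CG", within_subject_rho = rho, seed = 108)
    tab <- reliability_table(coh$minute_values)
    expect_equal(nrow(tab), 9L)
    expect_equal(tab$plane, rep(c("frontal", "sagittal", "transverse"),
                                each = 3L))
    expected <- band_icc(rho)
    expect_true(all(tab$icc_band == expected),
                label = sprintf("all rows %s at rho=%.2f", expected, rho))
    expect_true(all(abs(tab$icc - rho) < 0.12))
  }

  # identical subjects: no between-subject variance anywhere -> flagged
  snap <- expand.grid(subject = c("a", "b", "c"), minute = c(1, 3, 6),
                      plane = c("frontal", "sagittal", "transverse"),
                      part = c("left_leg", "right_leg", "pelvis"),
                      stringsAsFactors = FALSE)
  snap$value <- 5
  tab2 <- reliability_table(snap)
  expect_true(all(!is.na(tab2$flag)))
  expect_true(all(is.na(tab2$icc)))

  # subjects missing a minute are dropped listwise with a count
  part <- coh$minute_values
  drop_idx <- part$subject == "cg01" & part$minute == 6
  tab3 <- reliability_table(part[!drop_idx, ])
  expect_true(all(tab3$n == 199L))
  expect_true(all(tab3$n_dropped == 1L))
})

test_that("pipeline snapshots map onto reliability-table input", {
  res <- shared_analysis()
  per_subject <- list(s1 = res$snapshots, s2 = res$snapshots)
  long <- snapshots_from_minutes(per_subject)
  expect_setequal(unique(long$part), c("left_leg", "right_leg", "pelvis"))
  expect_equal(nrow(long), 2L * nrow(res$snapshots))
})
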