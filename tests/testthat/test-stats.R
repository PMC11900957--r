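# Agreement and outcome statistics against closed-form oracles.

test_that("paired t matches the closed form and guards degenerate variance", {
  pre <- c(50, 55, 60, 65); post <- c(70, 72, 80, 85)
  d <- pre - post
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  res <- paired_t(pre, post)
  expect_equal(res$t_stat, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_oracle), df = 3), tolerance = 1e-12)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)),
               class = "degenerate_variance_error")
  expect_error(paired_t(1:3, 1:4), class = "series_validation_error")
  expect_error(paired_t(1, 2), class = "series_validation_error")
})

test_that("ICC matches an explicit variance-components oracle", {
  a <- c(71.2, 65.4, 80.1, 55.0, 62.3, 77.7)
  b <- c(70.0, 66.1, 79.2, 57.5, 61.0, 78.3)
  ms <- ms_oracle(a, b)
  icc_a_oracle <- (ms$MSR - ms$MSE) /
    (ms$MSR + ms$MSE + 2 / ms$n * (ms$MSC - ms$MSE))
  icc_c_oracle <- (ms$MSR - ms$MSE) / (ms$MSR + ms$MSE)

  res_a <- icc_agreement(a, b)
  res_c <- icc_agreement(a, b, form = "consistency")
  expect_equal(res_a$icc, icc_a_oracle, tolerance = 1e-10)
  expect_equal(res_c$icc, icc_c_oracle, tolerance = 1e-10)
  expect_equal(res_a$band, "excellent")

  # cross-check against an independent reference implementation (pingouin
  # 0.6.1, ICC(A,1) / ICC(C,1) on this exact table)
  expect_equal(res_a$icc, 0.9891826216465155, tolerance = 1e-12)
  expect_equal(res_c$icc, 0.9870780518520555, tolerance = 1e-12)
  expect_equal(round(c(res_a$ci_lower, res_a$ci_upper), 2), c(0.93, 1.00))
  expect_equal(round(c(res_c$ci_lower, res_c$ci_upper), 2), c(0.91, 1.00))
})

test_that("ICC separates agreement from consistency and handles identity", {
  a <- c(50, 60, 70, 80, 90)
  res <- icc_agreement(a, a)
  expect_identical(res$icc, 1)
  expect_true(res$identical_series)
  expect_true(is.na(res$ci_lower))

  shifted <- icc_agreement(a, a + 5)
  expect_equal(icc_agreement(a, a + 5, form = "consistency")$icc, 1,
               tolerance = 1e-12)
  expect_lt(shifted$icc, 1)

  expect_error(icc_agreement(rep(3, 5), rep(7, 5)),
               class = "degenerate_variance_error")
  expect_error(icc_agreement(1:2, 1:2), class = "series_validation_error")
})

test_that("ICC bands follow the stated interpretation cut-points", {
  expect_equal(cermetrics:::icc_band(0.5), "moderate")
  expect_equal(cermetrics:::icc_band(0.7), "substantial")
  expect_equal(cermetrics:::icc_band(0.85), "excellent")
  expect_equal(cermetrics:::icc_band(0.2), "poor")
})

test_that("Bland-Altman matches hand computation and is antisymmetric", {
  a0 <- c(10, 20, 30, 40)
  ba0 <- bland_altman(a0, a0)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  b <- a0 - c(1, -1, 1, -1)   # differences +1, -1, +1, -1
  ba <- bland_altman(a0, b)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-12)

  sw <- bland_altman(b, a0)
  expect_equal(sw$bias, -ba$bias)
  expect_equal(sw$loa_low, -ba$loa_high)
  expect_equal(sw$loa_high, -ba$loa_low)
  expect_error(bland_altman(1, 2), class = "series_validation_error")
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  grand <- mean(c(g1, g2))
  ss_between <- 3 * (mean(g1) - grand)^2 + 3 * (mean(g2) - grand)^2
  ss_within <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  F_oracle <- (ss_between / 1) / (ss_within / 4)
  res <- one_way_anova(list(a = g1, b = g2))
  expect_equal(res$F_stat, F_oracle, tolerance = 1e-10)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)

  ident <- one_way_anova(list(x = g1, y = g1, z = g1))
  expect_equal(ident$F_stat, 0)

  shift <- one_way_anova(list(a = g1 + 100, b = g2 + 100))
  expect_equal(shift$F_stat, res$F_stat, tolerance = 1e-10)

  expect_error(one_way_anova(list(1:3)), class = "series_validation_error")
  expect_error(one_way_anova(list(a = 1, b = 1:3)),
               class = "series_validation_error")
})

test_that("statistics are invariant under relabeling of eyes", {
  set.seed(8)
  a <- runif(10, 40, 90); b <- a + rnorm(10, 0, 3)
  perm <- sample(10)
  expect_equal(icc_agreement(a, b)$icc, icc_agreement(a[perm], b[perm])$icc,
               tolerance = 1e-12)
  expect_equal(bland_altman(a, b)$bias, bland_altman(a[perm], b[perm])$bias,
               tolerance = 1e-12)
  expect_equal(paired_t(a, b)$t_stat, paired_t(a[perm], b[perm])$t_stat,
               tolerance = 1e-12)
})

test_that("improvement rate and severity classification follow their rules", {
  expect_identical(improvement_rate(63.59, 75.93), 19.41)
  expect_identical(improvement_rate(47.67, 75.74), 58.88)
  expect_identical(improvement_rate(80, 80), 0)
  expect_error(improvement_rate(0, 50), class = "series_validation_error")

  expect_equal(as.character(classify_severity(c(0, 2, 2.1, 5))),
               c("mild", "mild", "moderate_to_severe", "moderate_to_severe"))
  expect_error(classify_severity(-1), class = "series_validation_error")
})

test_that("cohort_report: identical methods agree perfectly", {
  set.seed(3)
  n <- 12
  cer_pre <- runif(n, 40, 70); cer_post <- pmin(cer_pre + 20, 100)
  data <- rbind(
    data.frame(eye_id = paste0("e", 1:n), timepoint = "pre", method = "ai",
               cer = cer_pre, droop_mm = runif(n, 0, 5)),
    data.frame(eye_id = paste0("e", 1:n), timepoint = "post", method = "ai",
               cer = cer_post, droop_mm = runif(n, 0, 5)))
  data2 <- transform(data, method = "manual")
  rep <- cohort_report(rbind(data, data2))
  expect_true(all(rep$agreement$icc == 1))
  expect_true(all(rep$agreement$bias == 0))
  expect_true(all(rep$agreement$loa_low == 0 & rep$agreement$loa_high == 0))
  expect_equal(nrow(rep$exclusions), 0)
  expect_equal(sort(unique(rep$summary$method)), c("ai", "manual"))
})

test_that("cohort_report recovers an injected pre/post shift", {
  set.seed(41)
  n <- 60; shift <- 20; noise_sd <- 2
  base <- runif(n, 40, 70)
  droop <- runif(n, 0, 6)
  data <- rbind(
    data.frame(eye_id = paste0("e", 1:n), timepoint = "pre", method = "ai",
               cer = base + rnorm(n, 0, noise_sd), droop_mm = droop),
    data.frame(eye_id = paste0("e", 1:n), timepoint = "post", method = "ai",
               cer = base + shift + rnorm(n, 0, noise_sd), droop_mm = droop))
  rep <- cohort_report(data)
  pre_m <- rep$summary$mean_cer[rep$summary$timepoint == "pre"]
  post_m <- rep$summary$mean_cer[rep$summary$timepoint == "post"]
  # mean recovered shift within 3 Monte-Carlo standard errors
  se <- sqrt(2) * noise_sd / sqrt(n)
  expect_lt(abs((post_m - pre_m) - shift), 3 * se)
  expect_true(all(c("mild", "moderate_to_severe") %in%
                  rep$severity$means$severity))
  expect_equal(rep$anova_severity$term,
               c("severity", "timepoint", "severity:timepoint"))
  # timepoint effect dominates
  expect_gt(rep$anova_severity$F_stat[2], 50)
})

test_that("Bland-Altman SD recovers the generating noise level", {
  set.seed(12)
  n <- 80; noise_sd <- 2
  truth <- runif(n, 40, 90)
  a <- truth + rnorm(n, 0, noise_sd)
  b <- truth + rnorm(n, 0, noise_sd)
  ba <- bland_altman(a, b)
  target <- sqrt(2) * noise_sd
  se_sd <- target / sqrt(2 * (n - 1))
  expect_lt(abs(ba$sd_diff - target), 3 * se_sd)
})

test_that("cohort_report enforces its input schema", {
  expect_error(cohort_report(data.frame(eye_id = "e1", cer = 50)),
               "missing column", class = "schema_error")
  bad <- data.frame(eye_id = "e1", timepoint = "mid", method = "ai", cer = 50)
  expect_error(cohort_report(bad), "timepoint", class = "schema_error")
  bad <- data.frame(eye_id = "e1", timepoint = "pre", method = "ai", cer = 150)
  expect_error(cohort_report(bad), "offending row", class = "schema_error")
  # missing timepoint for one eye: excluded from pairing, reported
  ok <- rbind(
    data.frame(eye_id = c("e1", "e2", "e3"), timepoint = "pre",
               method = "ai", cer = c(50, 60, 70)),
    data.frame(eye_id = c("e1", "e2"), timepoint = "post",
               method = "ai", cer = c(75, 85)))
  rep <- cohort_report(ok)
  expect_equal(rep$exclusions$eye_id, "e3")
  expect_equal(rep$paired_tests$n, 2)
})
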