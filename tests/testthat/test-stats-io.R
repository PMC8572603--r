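test_that("pearson correlation honours its identities", {
  x <- sin(seq(0, 3, length.out = 40))
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 * x + 3), 1)       # affine invariance
  expect_error(pearson_r(x, x[-1]), "equal length")
  expect_error(pearson_r(x, rep(1, 40)), "constant")
})

test_that("correlation labels follow the conventional bands", {
  expect_equal(correlation_label(0.993), "ESC")
  expect_equal(correlation_label(0.970), "ESC")
  expect_equal(correlation_label(-0.85), "ESC")
  expect_equal(correlation_label(c(0, 0.3, 0.5, 0.7, 0.8)),
               c("very weak", "weak", "moderate", "strong", "ESC"))
})

test_that("one-way ANOVA matches its closed-form identities", {
  # identical groups: zero F, no significant difference
  g <- sin(seq(0, 2, length.out = 30))
  res0 <- one_way_anova(list(g, g))
  expect_equal(res0$F, 0)
  expect_equal(res0$verdict, "NSD")
  # two-group F equals the squared equal-variance t statistic
  withr::with_seed(21, {
    a <- rnorm(25); b <- rnorm(30, mean = 0.4)
  })
  res <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # critical value consistency with the t distribution at the same df
  expect_equal(res$F_crit, qt(0.975, res$df2)^2, tolerance = 1e-9)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 53)
  expect_error(one_way_anova(list(a)), ">= 2")
  expect_error(one_way_anova(list(a, 1)), ">= 2 observations")
})

test_that("two 201-sample groups give the textbook critical value 3.865", {
  x <- seq_len(201) / 201
  res <- one_way_anova(list(x, x + 0.01), alpha = 0.05)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 400)
  expect_equal(round(res$F_crit, 3), 3.865)
})

test_that("ANOVA p value agrees with a permutation null", {
  withr::with_seed(31, {
    a <- rnorm(8)
    b <- rnorm(8, mean = 0.8)
    res <- one_way_anova(list(a, b))
    pooled <- c(a, b)
    n <- length(a)
    fstat <- function(idx) {
      g1 <- pooled[idx]; g2 <- pooled[-idx]
      # between/within mean squares, written out
      gm <- mean(pooled)
      ssb <- n * (mean(g1) - gm)^2 + n * (mean(g2) - gm)^2
      ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
      (ssb / 1) / (ssw / (2 * n - 2))
    }
    perm <- replicate(10000, fstat(sample(2 * n, n)))
    p_perm <- mean(perm >= res$F - 1e-12)
    expect_equal(p_perm, res$p, tolerance = 0.03)
  })
})

test_that("agreement report combines correlation and ANOVA", {
  withr::with_seed(41, {
    x <- sin(seq(0, pi, length.out = 201)) * 10
    y <- x + rnorm(201, sd = 0.3)
  })
  rep <- agreement_report(x, y)
  expect_gt(rep$pearson_r, 0.99)
  expect_equal(rep$correlation_label, "ESC")
  expect_equal(rep$anova$verdict, "NSD")
  expect_lt(rep$anova$F, rep$anova$F_crit)
})

test_that("CSV round trip preserves values and metadata layout", {
  tr <- planned_trajectory()
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(tr, path)
  back <- read_timeseries(path)
  expect_equal(back$time, tr$time, tolerance = 1e-12)
  expect_equal(back$theta, tr$theta, tolerance = 1e-12)
})

test_that("sto round trip preserves values and keeps the header", {
  res <- simulate_elbow_torque(planned_trajectory(),
                               synthetic_activations(planned_trajectory()))
  path <- withr::local_tempfile(fileext = ".sto")
  write_timeseries(res$resultant, path,
                   header = c("resultant torque", "version=1"))
  back <- read_timeseries(path)
  expect_equal(back$tau_sum, res$resultant$tau_sum, tolerance = 1e-12)
  expect_equal(attr(back, "header")[1:2], c("resultant torque", "version=1"))
  # dialect detection by extension
  expect_equal(read_timeseries(path, dialect = "auto")$time,
               res$resultant$time)
})

test_that("malformed time-series files are rejected with hints", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x", "0,1", "0,2", "1,3"), bad)   # non-monotone time
  expect_error(read_timeseries(bad), "strictly increasing")
  noheader <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("time\tx", "0\t1"), noheader)
  expect_error(read_timeseries(noheader), "endheader")
  notime <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x", "0,1", "1,2"), notime)
  expect_error(read_timeseries(notime), "must be `time`")
})

test_that("torque results and configs round-trip through disk", {
  tr <- planned_trajectory()
  res <- simulate_elbow_torque(tr, synthetic_activations(tr, seed = 12))
  dir <- withr::local_tempdir()
  write_torque_result(res, dir)
  states <- utils::read.csv(file.path(dir, "muscle_states.csv"))
  expect_equal(nrow(states), 201L * 6L)
  expect_true(all(c("time", "muscle", "F_M", "r", "tau") %in%
                    names(states)))
  resultant <- read_timeseries(file.path(dir, "resultant.csv"))
  expect_equal(resultant$tau_sum, res$resultant$tau_sum, tolerance = 1e-9)

  cfg <- read_muscle_config(system.file("extdata", "arm_default.yaml",
                                        package = "elbownms"))
  expect_equal(cfg$formula, formula_params())
  expect_equal(cfg$muscles, arm_muscles())
  base <- read_muscle_config(system.file("extdata",
                                         "baseline_double_synthetic.yaml",
                                         package = "elbownms"))
  expect_equal(base$muscles, baseline_muscles())
})
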