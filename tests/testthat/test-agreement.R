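test_that("consistency ICC matches brute-force ANOVA and aov() mean squares", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    y <- cbind(rnorm(n, 0, 2) + rnorm(n), rnorm(n, 0, 2) + rnorm(n))
    s <- rnorm(n, 0, 2)
    y <- cbind(s + rnorm(n), s + 0.3 + rnorm(n))
    fit <- icc_consistency(tibble::tibble(video = y[, 1], imu = y[, 2]))
    expect_equal(fit$rho, icc_bruteforce(y), tolerance = 1e-9)

    # cross-check mean squares against a two-way aov fit
    long <- data.frame(val = c(y), subj = factor(rep(1:n, 2)),
                       rater = factor(rep(1:2, each = n)))
    ms <- anova(stats::aov(val ~ subj + rater, data = long))
    expect_equal(fit$msr, ms["subj", "Mean Sq"], tolerance = 1e-9)
    expect_equal(fit$mse, ms["Residuals", "Mean Sq"], tolerance = 1e-9)
  }
})

test_that("identical and constant-offset columns give rho = 1", {
  v <- c(1, 3, 2, 5, 4, 6)
  d1 <- tibble::tibble(video = v, imu = v)
  expect_equal(icc_consistency(d1)$rho, 1)
  d2 <- tibble::tibble(video = v + 2.5, imu = v)
  fit2 <- icc_consistency(d2)
  expect_equal(fit2$rho, 1)
  expect_equal(c(fit2$ci_lower, fit2$ci_upper), c(1, 1))
  expect_error(icc_consistency(tibble::tibble(video = rep(1, 5), imu = rnorm(5))),
               class = "tremorcam_error_degenerate")
  expect_error(icc_consistency(tibble::tibble(video = rnorm(2), imu = rnorm(2))),
               class = "tremorcam_error_alignment")
})

test_that("a known variance-component design is recovered on average", {
  # sigma_s^2 = 4, sigma_e^2 = 1 -> true rho = 0.8; the mean-squares
  # estimator is biased low at small n, so the 6-subject check is loose
  # while the large-n check verifies consistency
  sim_mean_rho <- function(n, reps) {
    mean(replicate(reps, {
      s <- rnorm(n, 0, 2)
      icc_bruteforce(cbind(s + rnorm(n), s + rnorm(n)))
    }))
  }
  set.seed(23)
  expect_equal(sim_mean_rho(6, 400), 0.8, tolerance = 0.12)
  expect_equal(sim_mean_rho(100, 200), 0.8, tolerance = 0.02)
})

test_that("ICC reliability classes use upward-mapping boundaries", {
  expect_equal(classify_icc(c(0.08, 0.49, 0.50, 0.70, 0.75, 0.80, 0.90, 0.95)),
               c("poor", "poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent"))
})

test_that("MAE and relative MAE follow their definitions", {
  d <- tibble::tibble(video = c(2, 4), imu = c(1, 2))
  m <- mae_agreement(d)
  expect_equal(m$mae, 1.5)
  expect_equal(m$relative_mae_pct, 100)
  ident <- tibble::tibble(video = c(1, 2, 3), imu = c(1, 2, 3))
  expect_equal(unlist(mae_agreement(ident)[c("mae", "relative_mae_pct")]),
               c(mae = 0, relative_mae_pct = 0))
  # mae symmetric in the columns, relative mae not
  sw <- mae_agreement(tibble::tibble(video = c(1, 2), imu = c(2, 4)))
  expect_equal(sw$mae, m$mae)
  expect_false(isTRUE(all.equal(sw$relative_mae_pct, m$relative_mae_pct)))
  # zero-imu subjects excluded with warning; all-zero errors
  expect_warning(mz <- mae_agreement(tibble::tibble(video = c(1, 2), imu = c(0, 2))),
                 "zero IMU")
  expect_equal(mz$n_excluded, 1L)
  expect_error(suppressWarnings(
    mae_agreement(tibble::tibble(video = c(1, 2), imu = c(0, 0)))),
    class = "tremorcam_error_degenerate")
  # cohort-mean normalisation
  mc <- mae_agreement(d, relative = "cohort_mean")
  expect_equal(mc$relative_mae_pct, 100 * 1.5 / 1.5)
})

test_that("Bland-Altman limits follow mean(d) +/- 1.96 sd(d)", {
  ident <- tibble::tibble(video = c(1, 2, 3), imu = c(1, 2, 3))
  ba0 <- bland_altman(ident)
  expect_equal(c(ba0$mean_diff, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  shifted <- tibble::tibble(video = c(2, 3, 4), imu = c(1, 2, 3))
  ba1 <- bland_altman(shifted)
  expect_equal(c(ba1$mean_diff, ba1$loa_lower, ba1$loa_upper), c(1, 1, 1))
  d <- tibble::tibble(video = c(1, -1, 0), imu = c(0, 0, 0))
  ba2 <- bland_altman(d)
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$loa_upper, 1.96 * 1, tolerance = 1e-12)   # sd({1,-1,0}) = 1
  # mae >= |mean difference| (Jensen)
  set.seed(4)
  dd <- tibble::tibble(video = rnorm(20), imu = rnorm(20))
  expect_gte(mae_agreement(dd)$mae, abs(bland_altman(dd)$mean_diff))
})

test_that("agreement_report assembles per-group rows with all columns", {
  set.seed(31)
  s <- rnorm(30, 5, 1.5)
  data <- dplyr::bind_rows(
    tibble::tibble(region = "right_hand", metric = "PPF",
                   video = s + rnorm(30, 0, 0.3), imu = s + rnorm(30, 0, 0.3)),
    tibble::tibble(region = "right_hand", metric = "PP",
                   video = rnorm(30, -10, 15), imu = rnorm(30, -20, 9)))
  rep <- agreement_report(data, video, imu, groups = c("region", "metric"))
  expect_equal(nrow(rep), 2L)
  expect_true(all(c("icc", "icc_lo", "icc_hi", "icc_class", "mae",
                    "relative_mae_pct", "ba_mean_diff", "ba_loa_lower",
                    "ba_loa_upper", "mean_video", "sd_video", "mean_imu",
                    "sd_imu") %in% names(rep)))
  expect_true(all(rep$ba_loa_lower <= rep$ba_mean_diff &
                    rep$ba_mean_diff <= rep$ba_loa_upper))
  # perfect agreement collapses the report row
  perfect <- tibble::tibble(video = s, imu = s)
  r1 <- agreement_report(perfect, video, imu)
  expect_equal(r1$icc, 1)
  expect_equal(r1$mae, 0)
  expect_equal(r1$ba_loa_lower, r1$ba_loa_upper)
  # incomplete pairs are an alignment error
  expect_error(agreement_report(tibble::tibble(video = c(1, NA, 3), imu = c(1, 2, 3)),
                                video, imu),
               class = "tremorcam_error_alignment")
})

test_that("cohorts with known noise recover near-zero bias and matching limits", {
  set.seed(47)
  sd_noise <- 0.5
  md <- replicate(200, {
    s <- rnorm(30, 5, 2)
    ba <- bland_altman(tibble::tibble(video = s + rnorm(30, 0, sd_noise),
                                      imu = s + rnorm(30, 0, sd_noise)))
    c(ba$mean_diff, ba$loa_upper - ba$loa_lower)
  })
  expect_equal(mean(md[1, ]), 0, tolerance = 0.05)
  # LoA width ~= 2 * 1.96 * sd_noise * sqrt(2)
  expect_equal(mean(md[2, ]), 2 * 1.96 * sd_noise * sqrt(2), tolerance = 0.1)
})

test_that("tidy and glance methods return the documented one-row summaries", {
  set.seed(8)
  s <- rnorm(12, 0, 2)
  fit <- icc_consistency(tibble::tibble(video = s + rnorm(12), imu = s + rnorm(12)))
  td <- tidy(fit)
  expect_equal(names(td), c("term", "estimate", "conf.low", "conf.high", "reliability"))
  expect_equal(td$estimate, fit$rho)
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 12L)
  expect_equal(gl$statistic, fit$msr / fit$mse)
  ba <- bland_altman(tibble::tibble(video = s, imu = s + rnorm(12)))
  expect_equal(tidy(ba)$mean_diff, ba$mean_diff)
})
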