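#' Intraclass correlation: two-way random effects, single measures, consistency
#'
#' Treats the two measurement modalities (video and IMU) as two raters of
#' each subject and computes the consistency, single-measure ICC from the
#' two-way ANOVA mean squares: with `k = 2` raters,
#' `rho = (MSR - MSE) / (MSR + (k - 1) * MSE)`, where `MSR` is the
#' between-subject and `MSE` the residual mean square. The 95% confidence
#' interval follows Fleiss and Shrout's F-based construction: with
#' `F = MSR / MSE`, the bounds are `(FL - 1) / (FL + k - 1)` and
#' `(FU - 1) / (FU + k - 1)`, where
#' `FL = F / qf(1 - alpha/2, n - 1, (n - 1)(k - 1))` and
#' `FU = F * qf(1 - alpha/2, (n - 1)(k - 1), n - 1)`.
#' Consistency ICC is invariant to a constant offset between the two
#' modalities (the rater effect is absorbed by the column term).
#'
#' @param data A data frame of paired per-subject metrics.
#' @param video,imu Columns of `data` holding the video- and IMU-derived
#'   values (unquoted; defaults `video`, `imu`).
#' @param alpha Significance level for the confidence interval (default 0.05).
#' @return An object of class `icc_result`: a list with `rho`, `ci_lower`,
#'   `ci_upper`, `n_subjects`, `k`, `alpha`, `model_tag`,
#'   `reliability_class`, the mean squares `msr`, `msc`, `mse` and the F
#'   statistic. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
icc_consistency <- function(data, video = video, imu = imu, alpha = 0.05) {
  v <- dplyr::pull(data, {{ video }})
  w <- dplyr::pull(data, {{ imu }})
  pairs_check(v, w, min_n = 3L)
  ms <- anova_mean_squares(cbind(v, w))
  if (ms$msr <= 0 || (ms$msr == 0 && ms$mse == 0)) {
    abort_tc("No between-subject variance; the ICC is degenerate.", "degenerate")
  }
  if (stats::var(v) == 0 || stats::var(w) == 0) {
    abort_tc("One modality has zero variance; the ICC is degenerate.", "degenerate")
  }
  n <- length(v); k <- 2L
  if (ms$mse == 0) {
    rho <- 1; ci <- c(1, 1); Fstat <- Inf
  } else {
    rho <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    Fstat <- ms$msr / ms$mse
    df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
    FL <- Fstat / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fstat * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  }
  structure(list(rho = rho, ci_lower = ci[1], ci_upper = ci[2],
                 n_subjects = n, k = k, alpha = alpha,
                 model_tag = "two-way random, single measures, consistency",
                 reliability_class = classify_icc(rho),
                 msr = ms$msr, msc = ms$msc, mse = ms$mse, f_statistic = Fstat),
            class = "icc_result")
}

# Two-way crossed ANOVA mean squares for an n x k matrix (subjects x raters).
anova_mean_squares <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  ssr <- k * sum((rowMeans(y) - gm)^2)             # between subjects (rows)
  ssc <- n * sum((colMeans(y) - gm)^2)             # between raters (columns)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = max(sse, 0) / ((n - 1) * (k - 1)))
}

pairs_check <- function(v, w, min_n = 1L) {
  if (length(v) != length(w)) {
    abort_tc("Video and IMU columns must have equal length.", "alignment")
  }
  if (anyNA(v) || anyNA(w)) {
    abort_tc("Paired metrics must be complete (no missing entries).", "alignment")
  }
  if (length(v) < min_n) {
    abort_tc(sprintf("At least %d paired subjects are required (got %d).",
                     min_n, length(v)), "alignment")
  }
  invisible(TRUE)
}

#' Classify an ICC estimate into reliability bands
#'
#' Thresholds 0.50 / 0.75 / 0.90 separate poor, moderate, good and excellent
#' reliability; boundary values map to the higher class (0.50 is moderate,
#' 0.75 good, 0.90 excellent).
#'
#' @param rho ICC estimate(s).
#' @return Character vector: `"poor"`, `"moderate"`, `"good"` or
#'   `"excellent"`.
#' @export
classify_icc <- function(rho) {
  stopifnot(is.numeric(rho))
  dplyr::case_when(rho < 0.50 ~ "poor",
                   rho < 0.75 ~ "moderate",
                   rho < 0.90 ~ "good",
                   TRUE ~ "excellent")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s)\n  rho = %.3f  [%.3f, %.3f] (%d%% CI), n = %d, %s reliability\n",
              x$model_tag, x$rho, x$ci_lower, x$ci_upper,
              round(100 * (1 - x$alpha)), x$n_subjects, x$reliability_class))
  invisible(x)
}

#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.icc_result <- function(x, ...) {
  tibble::tibble(term = "icc_consistency", estimate = x$rho,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 reliability = x$reliability_class)
}

#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.icc_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, k = x$k, statistic = x$f_statistic,
                 msr = x$msr, msc = x$msc, mse = x$mse, alpha = x$alpha,
                 model = x$model_tag)
}

#' Mean absolute error between paired metrics
#'
#' `mae = mean(|video_i - imu_i|)`. The relative MAE (in percent) defaults to
#' the per-subject normalisation `100 * mean(|video_i - imu_i| / |imu_i|)`
#' (subjects with `imu_i = 0` are excluded with a warning); the alternative
#' `"cohort_mean"` form is `100 * mae / |mean(imu)|`.
#'
#' @inheritParams icc_consistency
#' @param relative Relative-MAE normalisation: `"per_subject"` (default) or
#'   `"cohort_mean"`.
#' @return A one-row tibble: `mae`, `relative_mae_pct`, `n`, `n_excluded`.
#' @export
mae_agreement <- function(data, video = video, imu = imu,
                          relative = c("per_subject", "cohort_mean")) {
  relative <- match.arg(relative)
  v <- dplyr::pull(data, {{ video }})
  w <- dplyr::pull(data, {{ imu }})
  pairs_check(v, w, min_n = 1L)
  d <- abs(v - w)
  mae <- mean(d)
  n_excl <- 0L
  if (relative == "per_subject") {
    nz <- w != 0
    n_excl <- sum(!nz)
    if (!any(nz)) {
      abort_tc("All IMU values are zero; relative MAE is undefined.", "degenerate")
    }
    if (n_excl > 0L) {
      rlang::warn(sprintf("Excluded %d subject(s) with zero IMU value from relative MAE.",
                          n_excl))
    }
    rel <- 100 * mean(d[nz] / abs(w[nz]))
  } else {
    if (mean(w) == 0) {
      abort_tc("Mean IMU value is zero; cohort-mean relative MAE is undefined.", "degenerate")
    }
    rel <- 100 * mae / abs(mean(w))
  }
  tibble::tibble(mae = mae, relative_mae_pct = rel, n = length(v), n_excluded = n_excl)
}

#' Bland-Altman agreement analysis
#'
#' Per-subject differences `d_i = video_i - imu_i` are summarised by their
#' mean (bias) and the 95% limits of agreement `mean(d) +/- 1.96 * SD(d)`
#' (sample SD, `n - 1` denominator). [autoplot()][ggplot2::autoplot] draws
#' the standard plot: points at `((video + imu) / 2, d)`, a solid mean line
#' and dashed limit lines.
#'
#' @inheritParams icc_consistency
#' @param conf_mult Multiplier on the SD for the limits (default 1.96).
#' @return An object of class `bland_altman`: list with `mean_diff`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `n` and the per-subject tibble
#'   `data` (`avg`, `diff`). Has `tidy()` and `autoplot()` methods.
#' @export
bland_altman <- function(data, video = video, imu = imu, conf_mult = 1.96) {
  v <- dplyr::pull(data, {{ video }})
  w <- dplyr::pull(data, {{ imu }})
  pairs_check(v, w, min_n = 3L)
  d <- v - w
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_diff = md,
                 loa_lower = md - conf_mult * sdd,
                 loa_upper = md + conf_mult * sdd,
                 sd_diff = sdd, conf_mult = conf_mult, n = length(d),
                 data = tibble::tibble(avg = (v + w) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.3f, limits of agreement [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, loa_lower = x$loa_lower,
                 loa_upper = x$loa_upper, sd_diff = x$sd_diff, n = x$n)
}

#' Assemble a per-region, per-metric agreement report
#'
#' Runs [icc_consistency()], [mae_agreement()] and [bland_altman()] plus
#' descriptive statistics for each group of paired metrics, mirroring the
#' report structure of a video-vs-IMU validation table (one row per region
#' and metric).
#'
#' @inheritParams icc_consistency
#' @param groups Character vector of grouping columns in `data` (e.g.
#'   `c("region", "metric")`); `NULL` treats `data` as one group.
#' @param relative Passed to [mae_agreement()].
#' @return A tibble with one row per group: the grouping columns plus `n`,
#'   `icc`, `icc_lo`, `icc_hi`, `icc_class`, `mae`, `relative_mae_pct`,
#'   `ba_mean_diff`, `ba_loa_lower`, `ba_loa_upper`, `mean_video`,
#'   `sd_video`, `mean_imu`, `sd_imu`.
#' @export
agreement_report <- function(data, video = video, imu = imu, groups = NULL,
                             alpha = 0.05, relative = c("per_subject", "cohort_mean")) {
  relative <- match.arg(relative)
  one <- function(df) {
    v <- dplyr::pull(df, {{ video }})
    w <- dplyr::pull(df, {{ imu }})
    fit <- icc_consistency(df, {{ video }}, {{ imu }}, alpha = alpha)
    m <- mae_agreement(df, {{ video }}, {{ imu }}, relative = relative)
    ba <- bland_altman(df, {{ video }}, {{ imu }})
    tibble::tibble(n = length(v),
                   icc = fit$rho, icc_lo = fit$ci_lower, icc_hi = fit$ci_upper,
                   icc_class = fit$reliability_class,
                   mae = m$mae, relative_mae_pct = m$relative_mae_pct,
                   ba_mean_diff = ba$mean_diff, ba_loa_lower = ba$loa_lower,
                   ba_loa_upper = ba$loa_upper,
                   mean_video = mean(v), sd_video = stats::sd(v),
                   mean_imu = mean(w), sd_imu = stats::sd(w))
  }
  if (is.null(groups)) return(one(data))
  missing <- setdiff(groups, names(data))
  if (length(missing)) {
    abort_tc(paste0("Grouping column(s) not in data: ", paste(missing, collapse = ", ")),
             "format")
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}
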