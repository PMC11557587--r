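# Statistical layer: summary-statistic and raw-sample t tests, two-sample
# Kolmogorov-Smirnov, per-region linear mixed models for delta-SUV, and
# region-vs-behavior correlations.

#' Group summary (n, mean, SEM)
#' @param n number of subjects (>= 2)
#' @param mean group mean
#' @param sem standard error of the mean, same units as the mean
#' @return object of class `group_summary`
#' @export
group_summary <- function(n, mean, sem) {
  assert_that(n >= 2, "group summary needs n >= 2")
  assert_that(sem >= 0, "sem must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sem = sem),
            class = "group_summary")
}

#' Summarize a raw sample
#' @param x numeric sample
#' @return a [group_summary()]
#' @export
summarize_sample <- function(x) {
  assert_that(length(x) >= 2, "need at least 2 observations")
  group_summary(length(x), mean(x), stats::sd(x) / sqrt(length(x)))
}

test_result <- function(statistic, value, p_value, df = NA_real_, extra = list()) {
  structure(c(list(statistic = statistic, value = value, df = df,
                   p_value = p_value), extra),
            class = "betapet_test")
}

#' @export
print.betapet_test <- function(x, ...) {
  cat(sprintf("%s = %.4g%s, p = %.3g\n", x$statistic, x$value,
              if (all(is.na(x$df))) "" else
                sprintf(" (df = %s)", paste(signif(x$df, 4), collapse = ", ")),
              x$p_value))
  invisible(x)
}

#' Pooled-variance Student's t test from group summaries
#'
#' Reconstructs SDs from the SEMs (`sd = sem * sqrt(n)`), pools the
#' variance, and returns the two-sided Student's t with
#' `df = n_a + n_b - 2`. The pooled variant is the default throughout
#' because it reproduces published t statistics computed from mean +/- SEM
#' summaries (Welch generally does not).
#'
#' @param a,b [group_summary()] objects.
#' @return a test result (statistic `"t"`, value, df, two-sided p).
#' @export
pooled_t_from_summary <- function(a, b) {
  assert_that(inherits(a, "group_summary") && inherits(b, "group_summary"),
              "a and b must be group_summary objects")
  sd_a <- a$sem * sqrt(a$n)
  sd_b <- b$sem * sqrt(b$n)
  df <- a$n + b$n - 2
  s2p <- ((a$n - 1) * sd_a^2 + (b$n - 1) * sd_b^2) / df
  t <- (a$mean - b$mean) / sqrt(s2p * (1 / a$n + 1 / b$n))
  test_result("t", t, 2 * stats::pt(-abs(t), df), df = df)
}

#' Two-sample t test on raw samples
#'
#' @param x,y numeric samples (>= 2 observations each).
#' @param variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @return a test result (statistic `"t"`).
#' @export
t_from_raw <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  assert_that(length(x) >= 2 && length(y) >= 2,
              "need at least 2 observations per group")
  ht <- stats::t.test(x, y, var.equal = variant == "pooled")
  test_result("t", unname(ht$statistic), ht$p.value,
              df = unname(ht$parameter))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' is the asymptotic two-sided one (bout-duration samples are large enough
#' that the asymptotic distribution is appropriate, and it tolerates ties).
#'
#' @param x,y numeric samples.
#' @return a test result (statistic `"D"`).
#' @export
ks_two_sample <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1, "empty sample")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  test_result("D", unname(ht$statistic), ht$p.value)
}

#' Mixed-model group test for one region's delta-SUVs
#'
#' Fits `delta_suv ~ group + (1 | subject_id)` on the region's rows: the
#' random intercept absorbs the repeated slice/hemisphere measurements per
#' mouse. Reports the group-effect F statistic (squared Wald t from the
#' mixed fit) with a residual-based denominator df, and its p-value. When
#' the design degenerates to one row per subject (or the fit is singular
#' with no within-subject replication), falls back to ordinary one-way
#' ANOVA with a warning.
#'
#' @param table a `delta_suv_table`.
#' @param region region name.
#' @return a test result (statistic `"F"`, `df = c(1, den_df)`) with extra
#'   fields `group_means` and `method`.
#' @export
lmm_region_group_test <- function(table, region) {
  sel <- table$region == region
  assert_that(any(sel), sprintf("no rows for region %s", region))
  d <- table[sel, c("subject_id", "group", "delta_suv")]
  d$group <- factor(d$group)
  assert_that(nlevels(d$group) == 2, "need exactly two groups")
  per_group <- tapply(d$subject_id, d$group, function(s) length(unique(s)))
  assert_that(all(per_group >= 2), "need >= 2 subjects per group")
  gm <- tapply(d$delta_suv, d$group, mean)
  if (stats::var(d$delta_suv) == 0) {
    # degenerate: no variation anywhere, hence no group effect
    return(test_result("F", 0, 1, df = c(1, nrow(d) - 2),
                       extra = list(group_means = as.list(gm),
                                    method = "degenerate", region = region)))
  }
  rows_per_subject <- table(d$subject_id)
  use_lmm <- max(rows_per_subject) > 1
  if (use_lmm) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(delta_suv ~ group + (1 | subject_id), data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    ct <- stats::coef(summary(fit))
    tval <- ct[2, "t value"]  # second row = group fixed effect
    den_df <- nrow(d) - 2
    Fval <- tval^2
    method <- "lmm"
  } else {
    warning(sprintf(
      "region %s: one row per subject; falling back to one-way ANOVA", region))
    fit <- stats::lm(delta_suv ~ group, data = d)
    a <- stats::anova(fit)
    Fval <- a$`F value`[1]
    den_df <- a$Df[2]
    method <- "anova"
  }
  p <- stats::pf(Fval, 1, den_df, lower.tail = FALSE)
  test_result("F", unname(Fval), p, df = c(1, den_df),
              extra = list(group_means = as.list(gm), method = method,
                           region = region))
}

#' Region-vs-behavior correlation and linear fit
#'
#' Pearson correlation and least-squares line of a behavioral readout (e.g.
#' mean percent freezing over the last 5 min of the memory test) on the
#' per-subject region-mean delta-SUV.
#'
#' @param delta_means numeric per-subject region-mean delta-SUV
#'   (independent variable).
#' @param behavior numeric per-subject behavioral readout, same order
#'   (dependent variable).
#' @return list of class `correlation_fit` with `r`, `slope`, `intercept`,
#'   `n`, and the two-sided `p_value` of the correlation; `r` is `NA` with a
#'   warning when `delta_means` has zero variance.
#' @export
correlate_region_behavior <- function(delta_means, behavior) {
  assert_that(length(delta_means) == length(behavior),
              "x and y must have equal length")
  assert_that(length(delta_means) >= 3, "need at least 3 subjects")
  if (stats::sd(delta_means) == 0) {
    warning("zero variance in delta-SUV; correlation undefined")
    return(structure(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                          n = length(behavior), p_value = NA_real_),
                     class = "correlation_fit"))
  }
  fit <- stats::lm(behavior ~ delta_means)
  ct <- stats::cor.test(delta_means, behavior)
  structure(list(r = unname(ct$estimate),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(behavior), p_value = ct$p.value),
            class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat(sprintf("r = %.3f  (y = %.3g x + %.3g, n = %d, p = %.3g)\n",
              x$r, x$slope, x$intercept, x$n, x$p_value))
  invisible(x)
}
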