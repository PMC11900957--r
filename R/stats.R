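# Method-agreement and outcome statistics for CER measurement series:
# paired t-test, one-way ANOVA, two-way single-measure ICC with
# F-distribution confidence bounds, Bland-Altman bias and 95% limits of
# agreement, ptosis severity classification, and pre/post improvement rate.

as_series <- function(x, what) {
  v <- as.numeric(x)
  if (anyNA(v))
    cm_stop(paste(what, "contains missing values"), "series_validation_error")
  v
}

check_paired <- function(a, b, n_min, what) {
  a <- as_series(a, what); b <- as_series(b, what)
  if (length(a) != length(b))
    cm_stop(paste(what, ": series lengths differ"), "series_validation_error")
  if (length(a) < n_min)
    cm_stop(sprintf("%s: need at least %d pairs", what, n_min),
            "series_validation_error")
  list(a = a, b = b)
}

#' Paired t-test between two matched measurement series
#'
#' Standard paired t statistic on the elementwise differences `pre - post`,
#' with a two-sided p-value. Two degenerate cases are handled explicitly:
#' identical series give `t = 0, p = 1`, and a non-zero difference vector
#' with zero variance (every eye shifted by exactly the same amount) raises
#' a degenerate-variance error rather than returning an infinite statistic.
#'
#' @param pre,post numeric vectors of equal length `>= 2`, matched by eye.
#' @return list with `t_stat`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  s <- check_paired(pre, post, 2, "paired_t")
  d <- s$a - s$b
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(list(t_stat = 0, p_value = 1, df = length(d) - 1, mean_diff = 0))
    cm_stop("paired_t: differences have (numerically) zero variance but non-zero mean; t is unbounded",
            "degenerate_variance_error")
  }
  tt <- t.test(s$a, s$b, paired = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

icc_band <- function(icc) {
  if (icc >= 0.8) "excellent"
  else if (icc >= 0.6) "substantial"
  else if (icc >= 0.41) "moderate"
  else "poor"
}

#' Intraclass correlation coefficient between two measurement series
#'
#' Two-way single-measure ICC from the variance components of the
#' subjects-by-raters ANOVA decomposition. `absolute_agreement` (the
#' default, appropriate for method comparison) penalizes systematic offsets
#' between the series; `consistency` does not. The 95% confidence interval
#' uses the standard F-distribution bounds (Satterthwaite degrees of freedom
#' for the absolute-agreement form). Identical series return exactly 1 with
#' an undefined (NA) interval, flagged via `identical_series`.
#'
#' @param a,b numeric vectors of matched measurements, `n >= 3`.
#' @param form `"absolute_agreement"` or `"consistency"`.
#' @param conf_level confidence level for the interval.
#' @return object of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `band` (agreement label: poor / moderate / substantial / excellent),
#'   `form`, `n`, `identical_series`.
#' @export
icc_agreement <- function(a, b, form = c("absolute_agreement", "consistency"),
                          conf_level = 0.95) {
  form <- match.arg(form)
  s <- check_paired(a, b, 3, "icc_agreement")
  a <- s$a; b <- s$b
  n <- length(a); k <- 2

  if (identical(a, b)) {
    # degenerate variance components; 1.0 by convention, interval undefined
    return(structure(list(icc = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                          band = "excellent", form = form, n = n,
                          identical_series = TRUE),
                     class = "icc_result"))
  }
  x <- cbind(a, b)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  if (MSR == 0 && MSE == 0)
    cm_stop("icc_agreement: no between-subject or residual variance; ICC undefined",
            "degenerate_variance_error")

  alpha <- 1 - conf_level
  if (form == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) { lo <- hi <- NA_real_ } else {
      Fo <- MSR / MSE
      FL <- Fo / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fo * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (FL - 1) / (FL + k - 1)
      hi <- (FU - 1) / (FU + k - 1)
    }
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
    if (MSE == 0) { lo <- hi <- NA_real_ } else {
      # Satterthwaite df for the denominator mean square (McGraw & Wong)
      Fj <- MSC / MSE
      vn <- (k - 1) * (n - 1) *
        (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
      vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
        (n * (1 + (k - 1) * icc) - k * icc)^2
      v <- vn / vd
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    }
  }
  structure(list(icc = icc, ci_lower = lo, ci_upper = hi,
                 band = icc_band(icc), form = form, n = n,
                 identical_series = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  ci <- if (is.na(x$ci_lower)) "-"
        else sprintf("(%.3f-%.3f)", x$ci_lower, x$ci_upper)
  cat(sprintf("ICC (%s, n=%d): %.3f %s  [%s agreement]%s\n",
              x$form, x$n, x$icc, ci, x$band,
              if (x$identical_series) "  (identical series)" else ""))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`: bias is `mean(d)` and the 95% limits of
#' agreement are `bias +/- 1.96 * SD(d)` with the sample (n-1) standard
#' deviation. Per-pair points `(mean, difference)` are returned for
#' plotting.
#'
#' @param a,b numeric vectors of matched measurements, `n >= 2`.
#' @return object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `points` (data frame with columns `mean` and `diff`).
#' @export
bland_altman <- function(a, b) {
  s <- check_paired(a, b, 2, "bland_altman")
  d <- s$a - s$b
  bias <- mean(d)
  sdd <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * sdd,
                 loa_high = bias + 1.96 * sdd, sd_diff = sdd,
                 points = data.frame(mean = (s$a + s$b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, 95%% LoA [%.3f, %.3f] (n=%d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' One-way ANOVA across measurement series
#'
#' Standard between/within mean-square F ratio across two or more groups of
#' CER measurements, via [stats::aov()].
#'
#' @param series named list of numeric vectors, each of length `>= 2`.
#' @return list with `F_stat`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(series) {
  if (!is.list(series) || length(series) < 2)
    cm_stop("one_way_anova: need at least 2 groups", "series_validation_error")
  lens <- lengths(series)
  if (any(lens < 2))
    cm_stop("one_way_anova: every group needs at least 2 values",
            "series_validation_error")
  if (is.null(names(series)))
    names(series) <- paste0("group", seq_along(series))
  df <- data.frame(
    value = unlist(series, use.names = FALSE),
    group = factor(rep(names(series), lens))
  )
  tab <- anova(aov(value ~ group, data = df))
  list(F_stat = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Pre/post improvement rate
#'
#' Relative change of the group-mean CER:
#' `100 * (post_mean - pre_mean) / pre_mean`, reported to 2 decimals.
#'
#' @param pre_mean,post_mean group means in percent; `pre_mean` must be
#'   positive.
#' @return numeric percentage rounded to 2 decimals.
#' @examples
#' improvement_rate(63.59, 75.93)  # 19.41
#' @export
improvement_rate <- function(pre_mean, post_mean) {
  if (any(pre_mean <= 0))
    cm_stop("improvement_rate: pre_mean must be positive",
            "series_validation_error")
  round(100 * (post_mean - pre_mean) / pre_mean, 2)
}

#' Classify ptosis severity from lid droop
#'
#' Mild when the droop is at most the threshold (default 2 mm), otherwise
#' moderate-to-severe.
#'
#' @param droop_mm non-negative droop in millimetres (vectorized).
#' @param threshold_mm mild/moderate boundary in millimetres.
#' @return factor with levels `mild`, `moderate_to_severe`.
#' @export
classify_severity <- function(droop_mm, threshold_mm = 2) {
  if (any(is.na(droop_mm)) || any(droop_mm < 0))
    cm_stop("classify_severity: droop must be non-negative",
            "series_validation_error")
  factor(ifelse(droop_mm <= threshold_mm, "mild", "moderate_to_severe"),
         levels = c("mild", "moderate_to_severe"))
}

#' Cohort-level agreement and outcome report
#'
#' Assembles the full evaluation of a measured cohort from long-format data:
#' per-method pre/post means and SDs, paired pre-vs-post t-tests per method,
#' pairwise cross-method agreement (two-way single-measure ICC with
#' interpretation band, Bland-Altman bias and limits of agreement) at each
#' timepoint, and - when lid droop is available - severity-stratified means,
#' improvement rates, and a two-way ANOVA of CER on severity x timepoint.
#' Eyes missing a timepoint for a method are excluded from that method's
#' paired analyses and listed in the exclusions table.
#'
#' @param data data frame with columns `eye_id`, `timepoint` (`"pre"` /
#'   `"post"`), `method`, `cer`, and optionally `droop_mm`.
#' @param severity_threshold_mm mild/moderate boundary, millimetres.
#' @param severity_method method whose CER feeds the severity analysis;
#'   default the first method present.
#' @return object of class `cer_cohort_report`: list of data frames
#'   `summary`, `paired_tests`, `agreement`, `severity`, `anova_severity`,
#'   `exclusions`.
#' @export
cohort_report <- function(data, severity_threshold_mm = 2,
                          severity_method = NULL) {
  need <- c("eye_id", "timepoint", "method", "cer")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    cm_stop(paste("cohort_report: missing column(s):",
                  paste(missing_cols, collapse = ", ")),
            "schema_error")
  bad <- which(!data$timepoint %in% c("pre", "post"))
  if (length(bad))
    cm_stop(paste("cohort_report: timepoint must be 'pre' or 'post'; offending row(s):",
                  paste(utils::head(bad, 10), collapse = ", ")),
            "schema_error")
  bad <- which(is.na(data$cer) | data$cer < 0 | data$cer > 100)
  if (length(bad))
    cm_stop(paste("cohort_report: cer must lie in [0, 100]; offending row(s):",
                  paste(utils::head(bad, 10), collapse = ", ")),
            "schema_error")

  methods <- unique(data$method)
  summary_tab <- aggregate(cer ~ method + timepoint, data = data,
                           function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  summary_tab <- data.frame(method = summary_tab$method,
                            timepoint = summary_tab$timepoint,
                            mean_cer = summary_tab$cer[, "mean"],
                            sd_cer = summary_tab$cer[, "sd"],
                            n = summary_tab$cer[, "n"])

  wide <- function(method, timepoint) {
    d <- data[data$method == method & data$timepoint == timepoint, ]
    stats::setNames(d$cer, d$eye_id)
  }

  paired_rows <- list(); excl <- list()
  for (m in methods) {
    pre <- wide(m, "pre"); post <- wide(m, "post")
    ids <- intersect(names(pre), names(post))
    dropped <- setdiff(union(names(pre), names(post)), ids)
    if (length(dropped))
      excl[[length(excl) + 1]] <- data.frame(
        method = m, eye_id = dropped, reason = "missing timepoint")
    if (length(ids) >= 2) {
      # a uniform shift across all eyes (zero-variance differences) leaves
      # the paired t undefined; report NA rather than aborting the report
      tt <- tryCatch(paired_t(pre[ids], post[ids]),
                     degenerate_variance_error = function(e)
                       list(t_stat = NA_real_, p_value = NA_real_))
      paired_rows[[m]] <- data.frame(method = m, n = length(ids),
                                     t_stat = tt$t_stat, p_value = tt$p_value)
    }
  }

  agree_rows <- list()
  if (length(methods) >= 2) {
    combs <- utils::combn(methods, 2, simplify = FALSE)
    for (tp in c("pre", "post")) {
      for (cp in combs) {
        va <- wide(cp[1], tp); vb <- wide(cp[2], tp)
        ids <- intersect(names(va), names(vb))
        if (length(ids) < 3) next
        icc <- icc_agreement(va[ids], vb[ids])
        ba <- bland_altman(va[ids], vb[ids])
        agree_rows[[length(agree_rows) + 1]] <- data.frame(
          timepoint = tp, method_a = cp[1], method_b = cp[2], n = length(ids),
          icc = icc$icc, icc_lower = icc$ci_lower, icc_upper = icc$ci_upper,
          icc_band = icc$band, bias = ba$bias, loa_low = ba$loa_low,
          loa_high = ba$loa_high)
      }
    }
  }

  severity_tab <- NULL; anova_tab <- NULL
  if ("droop_mm" %in% names(data)) {
    if (is.null(severity_method)) severity_method <- methods[1]
    sd_dat <- data[data$method == severity_method, ]
    sd_dat$severity <- classify_severity(sd_dat$droop_mm, severity_threshold_mm)
    sev <- aggregate(cer ~ severity + timepoint, data = sd_dat,
                     function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
    sev <- data.frame(severity = sev$severity, timepoint = sev$timepoint,
                      mean_cer = sev$cer[, "mean"], sd_cer = sev$cer[, "sd"],
                      n = sev$cer[, "n"])
    rates <- lapply(levels(sd_dat$severity), function(s) {
      pre <- sev$mean_cer[sev$severity == s & sev$timepoint == "pre"]
      post <- sev$mean_cer[sev$severity == s & sev$timepoint == "post"]
      if (length(pre) && length(post) && pre > 0)
        data.frame(severity = s, improvement_rate = improvement_rate(pre, post))
    })
    severity_tab <- list(means = sev, improvement = do.call(rbind, rates))
    if (nrow(sd_dat) >= 4 && length(unique(sd_dat$severity)) == 2) {
      fit <- aov(cer ~ severity * timepoint,
                 data = transform(sd_dat, timepoint = factor(timepoint)))
      at <- anova(fit)
      anova_tab <- data.frame(term = rownames(at)[1:3], df = at$Df[1:3],
                              F_stat = at$`F value`[1:3],
                              p_value = at$`Pr(>F)`[1:3])
    }
  }

  structure(list(
    summary = summary_tab,
    paired_tests = if (length(paired_rows)) do.call(rbind, paired_rows) else NULL,
    agreement = if (length(agree_rows)) do.call(rbind, agree_rows) else NULL,
    severity = severity_tab,
    anova_severity = anova_tab,
    exclusions = if (length(excl)) do.call(rbind, excl)
                 else data.frame(method = character(0), eye_id = character(0),
                                 reason = character(0))
  ), class = "cer_cohort_report")
}

#' @export
print.cer_cohort_report <- function(x, ...) {
  cat("== CER cohort report ==\n\nPer-method summary:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$paired_tests)) {
    cat("\nPaired pre/post t-tests:\n")
    print(x$paired_tests, row.names = FALSE)
  }
  if (!is.null(x$agreement)) {
    cat("\nCross-method agreement:\n")
    print(x$agreement, row.names = FALSE)
  }
  if (!is.null(x$severity)) {
    cat("\nSeverity-stratified CER:\n")
    print(x$severity$means, row.names = FALSE)
    cat("\nImprovement rates:\n")
    print(x$severity$improvement, row.names = FALSE)
  }
  if (!is.null(x$anova_severity)) {
    cat("\nTwo-way ANOVA (severity x timepoint):\n")
    print(x$anova_severity, row.names = FALSE)
  }
  if (nrow(x$exclusions)) {
    cat("\nExclusions:\n"); print(x$exclusions, row.names = FALSE)
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the bias and
#' 95% limits of agreement drawn as horizontal lines.
#'
#' @param ba a [bland_altman()] result.
#' @param ... passed to [plot()].
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, ...) {
  stopifnot(inherits(ba, "bland_altman"))
  plot(ba$points$mean, ba$points$diff,
       xlab = "Mean of paired measurements (%)",
       ylab = "Difference (%)", pch = 19, ...)
  graphics::abline(h = c(ba$loa_low, ba$bias, ba$loa_high),
                   lty = c(2, 1, 2), col = c("grey40", "black", "grey40"))
  invisible(ba)
}
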