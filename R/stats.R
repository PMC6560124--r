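# Measurement-analysis layer: ICC(1,1) test-retest reliability with the
# one-way random-effects F-based confidence interval, Pearson and partial
# correlations, and cohort summarisation / QC against the >10% failure rule.

#' Intraclass correlation ICC(1,1) with 95% confidence interval
#'
#' One-way random-effects model for the consistency of single measurements:
#' \deqn{ICC(1,1) = (MS_B - MS_W) / (MS_B + (k - 1) MS_W)}
#' where the mean squares come from a one-way ANOVA with subject as the
#' grouping factor.  The confidence interval is the standard F-based
#' interval for the one-way single-measurement design:
#' \eqn{F = MS_B / MS_W} with \eqn{(n-1, n(k-1))} degrees of freedom,
#' \eqn{F_L = F / F_{1-\alpha/2}}, \eqn{F_U = F \cdot F'_{1-\alpha/2}}, and
#' each bound mapped through \eqn{(F^* - 1)/(F^* + k - 1)}.
#'
#' Values of .75 and above are conventionally read as excellent
#' reliability, .60-.74 good, .40-.59 fair, below .40 poor (see
#' [icc_classify()]).
#'
#' @param data A data frame in long format with columns `subject`,
#'   `session`, `value`, or a numeric subjects x sessions matrix.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_fit` with elements `icc`, `ci_low`,
#'   `ci_high`, `ms_between`, `ms_within`, `n_subjects`, `k_sessions`,
#'   `n_dropped` (subjects removed for incomplete sessions), `conf_level`,
#'   and `degenerate` (`TRUE` when total variance is zero, in which case
#'   `icc` is `NA`, not 1).  Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
#' @examples
#' m <- cbind(s1 = c(1, 4, 9), s2 = c(2, 5, 8))
#' icc_1_1(m)
icc_1_1 <- function(data, conf_level = 0.95) {
  if (is.matrix(data)) {
    data <- tibble::tibble(
      subject = rep(seq_len(nrow(data)), ncol(data)),
      session = rep(seq_len(ncol(data)), each = nrow(data)),
      value = as.numeric(data))
  }
  stopifnot(all(c("subject", "session", "value") %in% names(data)))
  data <- dplyr::filter(data, !is.na(.data$value))
  k <- length(unique(data$session))
  counts <- dplyr::count(data, .data$subject)
  complete <- counts$subject[counts$n == k]
  n_dropped <- nrow(counts) - length(complete)
  data <- dplyr::filter(data, .data$subject %in% complete)
  n <- length(complete)
  if (n < 2L || k < 2L) {
    stop("ICC(1,1) needs >= 2 subjects with complete values in >= 2 sessions",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ factor(subject), data = data)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  msb <- ms[1L]; msw <- ms[2L]
  tot_var <- stats::var(data$value)
  degenerate <- !is.finite(msb) || !is.finite(msw) ||
    tot_var <= .Machine$double.eps * max(1, mean(data$value)^2)
  if (degenerate || (msw == 0 && msb == 0)) {
    icc <- NA_real_; lo <- NA_real_; hi <- NA_real_
    degenerate <- TRUE
  } else if (msw == 0) {
    # sessions are exact copies of a varying subject vector
    icc <- 1; lo <- 1; hi <- 1
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    alpha <- 1 - conf_level
    df1 <- n - 1L; df2 <- n * (k - 1L)
    f_obs <- msb / msw
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 ms_between = msb, ms_within = msw,
                 n_subjects = n, k_sessions = k, n_dropped = n_dropped,
                 conf_level = conf_level, degenerate = degenerate),
            class = "icc_fit")
}

#' Qualitative reliability band for an ICC value
#'
#' `>= .75` excellent, `.60-.74` good, `.40-.59` fair, `< .40` poor.
#'
#' @param icc Numeric ICC value(s) or an `icc_fit`.
#' @return Character vector of band labels.
#' @export
icc_classify <- function(icc) {
  if (inherits(icc, "icc_fit")) icc <- icc$icc
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc >= 0.75 ~ "excellent",
    icc >= 0.60 ~ "good",
    icc >= 0.40 ~ "fair",
    TRUE ~ "poor")
}

#' @export
print.icc_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_fit: undefined (zero total variance)>\n")
  } else {
    cat(sprintf(
      "<icc_fit: ICC(1,1) = %.3f [%.3f, %.3f] (%s), n = %d, k = %d>\n",
      x$icc, x$ci_low, x$ci_high, icc_classify(x), x$n_subjects,
      x$k_sessions))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "ICC(1,1)", estimate = x$icc,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 classification = icc_classify(x))
}

#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 ms_between = x$ms_between, ms_within = x$ms_within,
                 n_subjects = x$n_subjects, k_sessions = x$k_sessions,
                 n_dropped = x$n_dropped, conf_level = x$conf_level,
                 degenerate = x$degenerate)
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete Pearson correlation with the two-sided p value from
#' the t transform.  Zero variance in either vector yields an `NA` result
#' with `degenerate = TRUE` rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `r`, `p`, `n`, `degenerate`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                          degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                 degenerate = FALSE)
}

#' Partial correlation controlling for covariates
#'
#' Correlation between the residuals of `x` and `y` after linear regression
#' on the control covariates; the p value uses degrees of freedom reduced
#' by the number of controls (`df = n - 2 - q`).  With no controls this is
#' exactly the Pearson correlation.  A variable fully explained by the
#' controls (numerically zero residual variance) yields `r = 0, p = 1`:
#' nothing is left to correlate.
#'
#' @param x,y Numeric vectors.
#' @param controls Data frame / matrix of control covariates (columns), or
#'   `NULL` for none.
#' @return One-row tibble: `r`, `p`, `n`, `df`, `n_controls`,
#'   `rank_deficient` (`TRUE` when the controls are collinear, in which
#'   case the redundant columns were dropped by the regression).
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0L) {
    pr <- pearson_r(x, y)
    return(tibble::tibble(r = pr$r, p = pr$p, n = pr$n,
                          df = pr$n - 2L, n_controls = 0L,
                          rank_deficient = FALSE))
  }
  z <- as.data.frame(controls)
  q <- ncol(z)
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  if (n < q + 3L) {
    stop(sprintf("need >= %d complete cases for %d controls", q + 3L, q),
         call. = FALSE)
  }
  mm <- stats::model.matrix(~ ., data = z)
  rank_deficient <- qr(mm)$rank < ncol(mm)
  if (rank_deficient) {
    warning("control covariates are collinear; redundant columns dropped",
            call. = FALSE)
  }
  rx <- stats::lm.fit(mm, x)$residuals
  ry <- stats::lm.fit(mm, y)$residuals
  # a variable fully explained by the controls leaves only floating-point
  # noise in its residuals: nothing left to correlate, so r_p = 0
  if (stats::sd(rx) <= 1e-8 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-8 * max(stats::sd(y), 1e-300)) {
    return(tibble::tibble(r = 0, p = 1, n = n,
                          df = n - 2L - q, n_controls = q,
                          rank_deficient = rank_deficient))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(r = r, p = p, n = n, df = df, n_controls = q,
                 rank_deficient = rank_deficient)
}

#' Summarise a cohort of per-sulcus measures
#'
#' Assembles the wide per-subject measurement table and the per-sulcus QC
#' report from long-format pipeline output.  Any sulcus whose failure rate
#' exceeds 10% of attempted measurements is flagged
#' unsupported-for-this-cohort — the same rule under which the temporal and
#' intraparietal sulci were dropped from the validated set.
#'
#' @param measures Long tibble from [run_cohort()] / [run_subject()]:
#'   columns `subject`, `hemi`, `sulcus`, `metric`, `value`, `status`.
#' @param mean_requires_complete If `TRUE` (default), the per-subject mean
#'   width/depth is only computed when every requested sulcus measure is
#'   present (the mean across the 16 individual sulci in a bilateral
#'   8-sulcus run); otherwise the mean over available measures is returned
#'   with `n_width`/`n_depth` recording how many contributed.
#' @param failure_threshold Failure-rate threshold above which a sulcus is
#'   flagged (default 0.10, strictly greater).
#' @return List of class `cohort_summary`: `wide` (one row per subject:
#'   `<hemi>_<sulcus>_<metric>` columns plus `mean_width`, `mean_depth`,
#'   `n_width`, `n_depth`), `qc` (per sulcus x metric: `n`, `n_failed`,
#'   `failure_rate`, `flagged`), `flagged_sulci`.
#' @export
summarize_cohort <- function(measures, mean_requires_complete = TRUE,
                             failure_threshold = 0.10) {
  stopifnot(all(c("subject", "hemi", "sulcus", "metric", "value", "status")
                %in% names(measures)))
  qc <- measures |>
    dplyr::group_by(.data$hemi, .data$sulcus, .data$metric) |>
    dplyr::summarise(n = dplyr::n(),
                     n_failed = sum(.data$status != "ok"),
                     failure_rate = .data$n_failed / .data$n,
                     .groups = "drop") |>
    dplyr::mutate(flagged = .data$failure_rate > failure_threshold)
  flagged <- qc |>
    dplyr::filter(.data$flagged) |>
    dplyr::distinct(.data$sulcus) |>
    dplyr::pull(.data$sulcus)

  wide <- measures |>
    dplyr::mutate(col = paste(.data$hemi, .data$sulcus, .data$metric,
                              sep = "_")) |>
    dplyr::select("subject", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")

  n_expected <- dplyr::n_distinct(measures$hemi) *
    dplyr::n_distinct(measures$sulcus)
  means <- measures |>
    dplyr::group_by(.data$subject, .data$metric) |>
    dplyr::summarise(m = mean(.data$value, na.rm = TRUE),
                     n_ok = sum(!is.na(.data$value)),
                     .groups = "drop") |>
    dplyr::mutate(m = dplyr::if_else(
      mean_requires_complete & .data$n_ok < n_expected, NA_real_, .data$m)) |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("m", "n_ok"))
  names(means) <- sub("^m_", "mean_", names(means))
  names(means) <- sub("^n_ok_", "n_", names(means))
  wide <- dplyr::left_join(wide, means, by = "subject")

  structure(list(wide = wide, qc = qc, flagged_sulci = flagged,
                 failure_threshold = failure_threshold),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d subjects, %d sulcus x metric cells>\n",
              nrow(x$wide), nrow(x$qc)))
  if (length(x$flagged_sulci) > 0L) {
    cat(sprintf("  flagged (> %.0f%% failures): %s\n",
                100 * x$failure_threshold,
                paste(x$flagged_sulci, collapse = ", ")))
  } else {
    cat("  no sulci flagged\n")
  }
  invisible(x)
}
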