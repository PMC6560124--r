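# ICC(1,1), correlations, partial correlations, cohort QC.

test_that("ICC(1,1) matches the hand-computed one-way ANOVA identity", {
  m <- cbind(c(1, 4, 9), c(2, 5, 8))
  oracle <- icc_oracle(m)
  fit <- icc_1_1(m)
  expect_equal(fit$ms_between, oracle$msb, tolerance = 1e-12)
  expect_equal(fit$ms_within, oracle$msw, tolerance = 1e-12)
  expect_equal(fit$icc, oracle$icc, tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$icc && fit$icc <= fit$ci_high)
  expect_identical(fit$n_subjects, 3L)
  expect_identical(fit$k_sessions, 2L)
})

test_that("duplicated sessions give ICC exactly 1", {
  v <- c(3.1, 5.7, 2.2, 9.9, 4.4)
  fit <- icc_1_1(cbind(v, v))
  expect_identical(fit$icc, 1)
  expect_true(fit$ci_low <= 1 && fit$ci_high >= 1)
})

test_that("ICC is invariant to subject permutation and constant shifts", {
  set.seed(9)
  m <- matrix(rnorm(20), 10, 2) + rnorm(10)
  base <- icc_1_1(m)$icc
  expect_equal(icc_1_1(m[sample(10), ])$icc, base, tolerance = 1e-12)
  expect_equal(icc_1_1(m + 100)$icc, base, tolerance = 1e-10)
})

test_that("zero total variance is flagged undefined, not 1", {
  fit <- icc_1_1(matrix(5, 4, 2))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$icc))
})

test_that("long-format input with incomplete subjects drops and logs them", {
  df <- tibble::tibble(
    subject = c("a", "a", "b", "b", "c"),
    session = c(1, 2, 1, 2, 1),
    value = c(1, 2, 4, 5, 9))
  fit <- icc_1_1(df)
  expect_identical(fit$n_subjects, 2L)
  expect_identical(fit$n_dropped, 1L)
})

test_that("classification bands follow the conventional cutpoints", {
  expect_identical(icc_classify(c(0.9, 0.75, 0.74, 0.60, 0.59, 0.40, 0.39)),
                   c("excellent", "excellent", "good", "good", "fair",
                     "fair", "poor"))
})

test_that("tidy and glance return one-row tibbles", {
  fit <- icc_1_1(cbind(c(1, 4, 9), c(2, 5, 8)))
  td <- generics::tidy(fit)
  expect_identical(nrow(td), 1L)
  expect_identical(td$classification, icc_classify(fit))
  gl <- generics::glance(fit)
  expect_identical(gl$icc, fit$icc)
})

test_that("pearson_r handles exact linear and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  expect_true(pearson_r(x, rep(3, 5))$degenerate)
  expect_error(pearson_r(c(1, 2), c(3, 4)), ">= 3")
})

test_that("sampled correlation falls in the Fisher-z 99% band of truth", {
  set.seed(500)
  n <- 500; rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_r(x, y)$r
  z_half <- qnorm(0.995) / sqrt(n - 3)
  expect_lt(abs(atanh(r) - atanh(rho)), z_half)
})

test_that("partial correlation reduces to pearson with no/orthogonal controls", {
  set.seed(13)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60, 0, 0.8)
  p0 <- partial_correlation(x, y)
  expect_equal(p0$r, pearson_r(x, y)$r)
  # controls orthogonalised against x and y: partial equals raw to 1e-10
  z_raw <- cbind(rnorm(60), rnorm(60))
  z <- apply(z_raw, 2, function(col) stats::lm.fit(cbind(1, x, y), col)$residuals)
  pp <- partial_correlation(x, y, z)
  expect_equal(pp$r, pearson_r(x, y)$r, tolerance = 1e-10)
  expect_identical(pp$df, 60L - 2L - 2L)
})

test_that("controlling for a variable that fully explains y zeroes the partial r", {
  set.seed(14)
  x <- rnorm(40); z1 <- rnorm(40); z2 <- rnorm(40)
  y <- z1
  pp <- partial_correlation(x, y, cbind(z1, z2))
  expect_identical(pp$r, 0)
  expect_identical(pp$p, 1)
})

test_that("partial correlation matches the two-stage regression oracle", {
  # small fixed fixture, oracle computed with lm() residuals directly
  x <- c(2.1, 3.5, 1.2, 4.8, 5.1, 2.9, 3.3, 4.0)
  y <- c(1.0, 2.2, 0.5, 3.9, 4.4, 1.8, 2.6, 3.1)
  z1 <- c(0.2, 0.8, 0.1, 1.5, 1.9, 0.5, 0.9, 1.1)
  z2 <- c(5.0, 4.1, 6.2, 3.3, 2.9, 4.8, 4.2, 3.6)
  rx <- residuals(lm(x ~ z1 + z2))
  ry <- residuals(lm(y ~ z1 + z2))
  r_oracle <- cor(rx, ry)
  t_oracle <- r_oracle * sqrt((8 - 4) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), 8 - 4)
  pp <- partial_correlation(x, y, data.frame(z1, z2))
  expect_equal(pp$r, r_oracle, tolerance = 1e-12)
  expect_equal(pp$p, p_oracle, tolerance = 1e-12)
})

test_that("collinear controls are flagged", {
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30); z1 <- rnorm(30)
  expect_warning(pp <- partial_correlation(x, y, cbind(z1, 2 * z1)),
                 "collinear")
  expect_true(pp$rank_deficient)
})

# small long-format measurement table builder
fake_measures <- function(n_subj, fail_subjects = integer(0),
                          sulci = c("S_central", "S_postcentral"),
                          fail_sulcus = "S_central") {
  rows <- list()
  for (s in seq_len(n_subj)) {
    for (su in sulci) {
      for (met in c("width", "depth")) {
        failed <- s %in% fail_subjects && su == fail_sulcus && met == "width"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = sprintf("s%02d", s), hemi = "lh", sulcus = su,
          metric = met,
          value = if (failed) NA_real_ else s + nchar(su) / 10,
          status = if (failed) "discontinuous-region" else "ok",
          n = 10L, flags = "")
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("QC flags a sulcus strictly above the 10% failure rate", {
  m15 <- fake_measures(20, fail_subjects = 1:3)   # 15% width failures
  s15 <- summarize_cohort(m15)
  expect_identical(s15$flagged_sulci, "S_central")

  m05 <- fake_measures(20, fail_subjects = 1L)    # 5%
  expect_length(summarize_cohort(m05)$flagged_sulci, 0L)

  m10 <- fake_measures(20, fail_subjects = 1:2)   # exactly 10%: not flagged
  expect_length(summarize_cohort(m10)$flagged_sulci, 0L)
})

test_that("subject means require completeness by default", {
  m <- fake_measures(4, fail_subjects = 2L)
  s <- summarize_cohort(m)
  wide <- s$wide[order(s$wide$subject), ]
  # subject 2 lost one width measure -> mean_width NA under the default rule
  expect_true(is.na(wide$mean_width[2]))
  expect_false(any(is.na(wide$mean_width[-2])))
  # mean equals the arithmetic mean of the per-sulcus values on a full row
  row1 <- m[m$subject == "s01" & m$metric == "width", ]
  expect_equal(wide$mean_width[1], mean(row1$value))

  s2 <- summarize_cohort(m, mean_requires_complete = FALSE)
  wide2 <- s2$wide[order(s2$wide$subject), ]
  expect_false(is.na(wide2$mean_width[2]))
  expect_identical(wide2$n_width[2], 1L)
})

test_that("failed measures are missing values, never zeros", {
  m <- fake_measures(10, fail_subjects = 1:2)
  expect_true(all(is.na(m$value[m$status != "ok"])))
  expect_false(any(m$value[m$status == "ok"] == 0, na.rm = TRUE))
})
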