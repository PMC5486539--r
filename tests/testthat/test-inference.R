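test_that("analysis table applies the >35 C daily-maximum filter", {
  dates <- as.Date("2013-01-01") + (25L - 1L) * 7L + 0:6
  days <- toy_days(dates, mean_tb = 37,
                   max_tb = c(rep(39, 6), 30.5))
  tab <- build_analysis_table(list(a = days),
                              data.frame(animal_id = "a", sex = "female",
                                         age_class = "adult", site = "field",
                                         year = 2013, mast = "mast"),
                              c(a = as.Date("2013-10-01")))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$max_tb, 39)       # the 30.5 torpor-tainted max is gone
  expect_equal(tab$n_days, 7L)
})

test_that("animals without onset are excluded with a warning; short weeks
           are dropped", {
  dates <- as.Date("2013-06-17") + 0:9      # 7 days wk25 + 3 days wk26
  days <- toy_days(dates, mean_tb = 37)
  meta <- data.frame(animal_id = c("a", "b"), sex = "female",
                     age_class = "adult", site = "field", year = 2013,
                     mast = "mast")
  expect_warning(
    tab <- build_analysis_table(list(a = days, b = days),
                                meta, c(a = as.Date("2013-10-01"),
                                        b = as.Date(NA))),
    "no hibernation onset")
  expect_identical(unique(tab$animal_id), "a")
  expect_identical(tab$week, 25L)    # the 3-day week 26 was dropped
})

test_that("the weeks-prior scheme yields non-positive indices only", {
  fx <- default_cohort_analysis()
  tabp <- build_analysis_table(fx$daily, fx$coh$meta, fx$onsets,
                               scheme = "prior_to_hibernation")
  expect_true(all(tabp$week <= 0))
})

test_that("weekly mean and SEM are computed across animals", {
  r <- weekly_mean_sem(c(1, 2, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sem, 1 / sqrt(3), tolerance = 1e-12)
  r1 <- weekly_mean_sem(5)
  expect_equal(r1$mean, 5)
  expect_true(is.na(r1$sem))
  ## duplicating the mean leaves the mean, shrinks the SEM
  r2 <- weekly_mean_sem(c(1, 2, 3, 2))
  expect_equal(r2$mean, 2)
  expect_lt(r2$sem, r$sem)
})

test_that("Box-Cox closed forms, estimation and round-trip hold", {
  y <- c(0.5, 1, 2, 5)
  expect_equal(boxcox_transform(y, lambda = 1)$y, y - 1)
  expect_equal(boxcox_transform(y, lambda = 0)$y, log(y))
  expect_error(boxcox_transform(c(1, -1)), "positive")
  set.seed(42)
  z <- rlnorm(500)
  expect_equal(boxcox_transform(z)$lambda, 0, tolerance = 0.15)
  bc <- boxcox_transform(y, lambda = 1)
  expect_equal(boxcox_inverse(bc$y, 1), y, tolerance = 1e-10)
})

test_that("Pearson test matches the closed-form t statistic", {
  expect_equal(corr_test(1:10, -(1:10))$r, -1)
  set.seed(7)
  ct0 <- corr_test(rnorm(1000), rnorm(1000))
  expect_lt(abs(ct0$r), 0.1)
  ## t = r sqrt(df / (1 - r^2)); at r = -0.39, n = 432 this gives -8.78
  r <- -0.39; df <- 430
  expect_equal(r * sqrt(df / (1 - r^2)), -8.78, tolerance = 0.01)
  set.seed(8)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  ct <- corr_test(x, y)
  expect_equal(ct$t, ct$r * sqrt(ct$df / (1 - ct$r^2)), tolerance = 1e-9)
  expect_true(is.na(corr_test(rep(1, 10), rnorm(10))$r))
})

test_that("two-group comparison reduces to the two-sample t test", {
  g <- two_group_lm(c(37.4, 37.5, 36.0, 36.1),
                    c("repro", "repro", "non", "non"))
  expect_equal(abs(g$difference), 1.4, tolerance = 1e-9)
  set.seed(9)
  v <- rnorm(12); grp <- rep(c("a", "b"), each = 6)
  g2 <- two_group_lm(v, grp)
  tt <- t.test(v ~ grp, var.equal = TRUE)
  expect_equal(g2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  ## identical groups: F ~ 0
  g3 <- two_group_lm(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(g3$F, 1e-9)
})

test_that("degenerate data reduce the mixed model to OLS", {
  set.seed(10)
  d <- make_model_table(n_anim = 60, weeks = 11:30, re_sd = 0, rho = 0,
                       sd = 0.5)
  f <- fit_lme_ar1(d, hours_above ~ week + sex + mast)
  expect_equal(f$status, "converged")
  ols <- lm(hours_above ~ factor(week) + sex + mast, d,
            contrasts = list(`factor(week)` = "contr.sum",
                             sex = "contr.sum", mast = "contr.sum"))
  expect_lt(max(abs(f$coefficients - coef(ols))), 1e-3)
})

test_that("type-3 table is invariant to term order and constants drop", {
  set.seed(11)
  d <- make_model_table(n_anim = 12, weeks = 20:29)
  f1 <- fit_lme_ar1(d, hours_above ~ week + sex + mast + mean_ta)
  f2 <- fit_lme_ar1(d, hours_above ~ mean_ta + mast + sex + week)
  expect_equal(f1$status, "converged")
  a1 <- f1$anova[order(f1$anova$term), ]
  a2 <- f2$anova[order(f2$anova$term), ]
  expect_equal(a1$chisq, a2$chisq, tolerance = 1e-6)
  ## a constant predictor is dropped with a warning, not an error
  d$mast <- "mast"
  expect_warning(f3 <- fit_lme_ar1(d, hours_above ~ week + sex + mast),
                 "constant")
  expect_false("mast" %in% f3$anova$term)
})

test_that("the mixed model recovers its own fixed effects", {
  set.seed(12)
  d <- make_model_table(n_anim = 80, weeks = 16:35, re_sd = 0.3, rho = 0.4,
                       sd = 0.6, beta_fm = 2)
  f <- fit_lme_ar1(d, hours_above ~ week + sex + mast + sex:mast)
  expect_equal(f$status, "converged")
  ## with sum contrasts the interaction coefficient is beta_fm / 4
  ic <- f$coefficients[grep(":", names(f$coefficients))]
  expect_equal(abs(unname(ic)), 2 / 4, tolerance = 0.25)
  expect_gt(f$ar1, 0.15)
  expect_lt(f$ar1, 0.65)
})

test_that("the calendar-week scheme wins when the signal is seasonal", {
  fx <- default_cohort_analysis()
  tab_y <- fx$table
  tab_p <- build_analysis_table(fx$daily, fx$coh$meta, fx$onsets,
                                scheme = "prior_to_hibernation")
  cmp <- compare_week_predictors(tab_y, tab_p)
  expect_equal(cmp$chosen, "of_year")
  expect_gt(cmp$r2_of_year, cmp$r2_prior)
  ## identical tables tie, and the tie goes to week of year
  cmp2 <- compare_week_predictors(tab_y, tab_y)
  expect_equal(cmp2$chosen, "of_year")
  expect_equal(cmp2$r2_of_year, cmp2$r2_prior)
})
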