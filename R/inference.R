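#' Build the animal-week analysis table
#'
#' Aggregates daily summaries to one row per animal-week: weekly mean of
#' daily maximum Tb (after excluding daily maxima of 35 degrees C or less,
#' so torpor-contaminated maxima do not enter), weekly mean hours above
#' the hyperthermia threshold, torpor-day count, weekly mean/minimum Tb and
#' ambient covariates.  Only complete days strictly before hibernation
#' onset contribute; weeks with fewer than \code{min_days} complete days
#' are dropped, as are weeks at/after the onset week.  Animals without a
#' known onset are excluded with a warning.
#'
#' @param daily Named list of daily-summary tables (one per animal-year),
#'   keyed by animal id.
#' @param meta Data frame with columns animal_id, sex, age_class, site,
#'   year, mast.
#' @param onsets Named \code{Date} vector of hibernation onsets, keyed like
#'   \code{daily}.
#' @param scheme \code{"of_year"} (calendar blocks from Jan 1) or
#'   \code{"prior_to_hibernation"} (0 = onset week, negative backwards).
#' @param min_days Minimum complete days for a week to be retained.
#' @param maxtb_filter Daily maxima must exceed this (degrees C) to enter
#'   the weekly max-Tb mean.
#' @return Data frame, one row per animal-week.
#' @export
build_analysis_table <- function(daily, meta, onsets,
                                 scheme = c("of_year",
                                            "prior_to_hibernation"),
                                 min_days = 4L, maxtb_filter = 35) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (id in names(daily)) {
    onset <- onsets[[id]]
    if (is.null(onset) || is.na(onset)) {
      warning("animal ", id, " has no hibernation onset; excluded")
      next
    }
    d <- daily[[id]]
    d <- d[d$complete & d$date < as.Date(onset), , drop = FALSE]
    if (nrow(d) == 0) next
    wk <- if (scheme == "of_year") week_of_year(d$date) else
      weeks_prior_to_hibernation(d$date, onset)
    keep_wk <- if (scheme == "of_year") wk < week_of_year(as.Date(onset))
      else rep(TRUE, length(wk))
    d <- d[keep_wk, , drop = FALSE]; wk <- wk[keep_wk]
    if (nrow(d) == 0) next
    mrow <- meta[meta$animal_id == id, , drop = FALSE][1, ]
    for (w in sort(unique(wk))) {
      i <- wk == w
      if (sum(i) < min_days) next
      mx <- d$max_tb[i]
      mx <- mx[mx > maxtb_filter]
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, year = mrow$year, sex = mrow$sex,
        age_class = mrow$age_class, site = mrow$site, mast = mrow$mast,
        week = as.integer(w),
        max_tb = if (length(mx)) mean(mx) else NA_real_,
        hours_above = mean(d$hours_above[i]),
        torpor_days = as.integer(sum(d$torpor_day[i])),
        mean_tb = mean(d$mean_tb[i]),
        min_tb = mean(d$min_tb[i]),
        mean_ta = mean(d$mean_ta[i]),
        min_ta = mean(d$min_ta[i]),
        n_days = as.integer(sum(i)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Weekly mean and SEM across animals
#'
#' The SEM is computed across animals (sample SD over the square root of
#' the number of animals contributing), never across days.
#'
#' @param values Per-animal values for one week/group.
#' @return List with \code{mean}, \code{sem} (NA when n = 1) and \code{n}.
#' @export
weekly_mean_sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  list(mean = mean(values),
       sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Box-Cox transform with profile-likelihood lambda
#'
#' Lambda is chosen by profile maximum likelihood on a fixed grid
#' (-2..2, step 0.01) for an intercept-only model, then the standard
#' power transform \code{(y^lambda - 1)/lambda} (natural log at
#' lambda = 0) is applied.
#'
#' @param y Positive numeric values.
#' @param lambda Fix lambda instead of estimating it.
#' @return List with \code{y} (transformed) and \code{lambda}.
#' @export
boxcox_transform <- function(y, lambda = NULL) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Box-Cox requires strictly positive finite values")
  if (is.null(lambda)) {
    grid <- seq(-2, 2, by = 0.01)
    bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y), lambda = grid,
                       plotit = FALSE)
    lambda <- bc$x[which.max(bc$y)]
  }
  z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(y = z, lambda = lambda)
}

#' Inverse Box-Cox transform
#'
#' @param z Transformed values.
#' @param lambda The lambda used in \code{\link{boxcox_transform}}.
#' @return Values on the original scale.
#' @export
boxcox_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
}

#' Random-intercept model with AR(1) residual correlation
#'
#' Fits \code{nlme::lme} with a per-animal random intercept and an AR(1)
#' within-animal residual correlation indexed by week, and reports a
#' type-3 Wald chi-square table (sum-to-zero contrasts, via
#' \code{car::Anova}).  \code{week} enters as a categorical factor.
#' Terms that are constant in the data (e.g. mast within a single year)
#' are dropped with a warning.  Non-convergence is returned as an explicit
#' failed status, never a silent fallback.  The pseudo-R-squared is the
#' squared correlation between marginal (fixed-effect) fitted values and
#' the observed response.
#'
#' @param data An analysis table from \code{\link{build_analysis_table}}
#'   (or any data frame with an \code{animal_id} column and an integer
#'   \code{week} column).
#' @param formula Fixed-effects formula, e.g.
#'   \code{hours_above ~ week + sex + age_class + mast + mean_ta}.
#'   \code{week} is coerced to a factor internally; the AR(1) correlation
#'   uses its integer value as the time position.
#' @param boxcox Apply \code{\link{boxcox_transform}} to the response
#'   first (requires a positive response).
#' @return An object of class \code{"lme_ar1_result"}: list with
#'   \code{status}, \code{response}, \code{lambda}, \code{coefficients},
#'   \code{anova} (term, chisq, df, p), \code{ar1}, \code{pseudo_r2},
#'   \code{n_rows}, \code{n_animals} and the underlying \code{fit}.
#' @export
fit_lme_ar1 <- function(data, formula, boxcox = FALSE) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            "animal_id" %in% names(data))
  if (length(unique(data$animal_id)) < 5)
    stop("need at least 5 animals")
  response <- all.vars(formula)[1]
  terms_rhs <- attr(stats::terms(formula), "term.labels")

  d <- data
  d$.week_num <- as.integer(d$week)
  if ("week" %in% all.vars(formula)) d$week <- factor(d$week)
  keep <- complete.cases(d[, unique(c(all.vars(formula), "animal_id")),
                           drop = FALSE])
  d <- d[keep, , drop = FALSE]

  ## drop terms with no variation (singular design protection)
  varying <- vapply(terms_rhs, function(tt) {
    vs <- all.vars(stats::as.formula(paste("~", tt)))
    all(vapply(vs, function(v) length(unique(d[[v]])) > 1, logical(1)))
  }, logical(1))
  if (any(!varying)) {
    warning("dropping constant term(s): ",
            paste(terms_rhs[!varying], collapse = ", "))
    terms_rhs <- terms_rhs[varying]
  }
  if (!length(terms_rhs)) stop("no varying fixed-effect terms left")
  fml <- stats::reformulate(terms_rhs, response = response)

  lambda <- NA_real_
  if (boxcox) {
    bc <- boxcox_transform(d[[response]])
    d[[response]] <- bc$y
    lambda <- bc$lambda
  }

  oc <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(oc))
  fit <- tryCatch(
    nlme::lme(fixed = fml, random = ~ 1 | animal_id,
              correlation = nlme::corAR1(form = ~ .week_num | animal_id),
              data = d, method = "REML",
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         opt = "optim")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(status = "failed",
                          message = conditionMessage(fit),
                          response = response, lambda = lambda,
                          formula = fml),
                     class = "lme_ar1_result"))
  }
  a3 <- car::Anova(fit, type = 3)
  atab <- data.frame(term = rownames(a3),
                     chisq = a3[["Chisq"]],
                     df = a3[["Df"]],
                     p = a3[["Pr(>Chisq)"]],
                     row.names = NULL)
  atab <- atab[atab$term != "(Intercept)", , drop = FALSE]
  phi <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  fitted0 <- as.numeric(fitted(fit, level = 0))
  obs <- d[[response]]
  structure(list(status = "converged", response = response,
                 formula = fml, lambda = lambda,
                 coefficients = nlme::fixef(fit),
                 anova = atab, ar1 = phi,
                 pseudo_r2 = cor(fitted0, obs)^2,
                 n_rows = nrow(d),
                 n_animals = length(unique(d$animal_id)),
                 fit = fit),
            class = "lme_ar1_result")
}

#' @export
print.lme_ar1_result <- function(x, ...) {
  cat("Random-intercept + AR(1) model:", deparse(x$formula), "\n")
  cat("status:", x$status, "\n")
  if (x$status == "converged") {
    if (!is.na(x$lambda)) cat("Box-Cox lambda:", x$lambda, "\n")
    cat(sprintf("AR(1) phi = %.3f, pseudo-R2 = %.3f, n = %d rows / %d animals\n",
                x$ar1, x$pseudo_r2, x$n_rows, x$n_animals))
    cat("Type-3 Wald chi-square:\n")
    print(x$anova, row.names = FALSE)
  } else cat("message:", x$message, "\n")
  invisible(x)
}

#' Compare calendar-week vs weeks-prior-to-hibernation predictors
#'
#' Fits the full mean-Tb model (mean Tb ~ age + sex + mean Ta + week) under
#' both week schemes and returns both pseudo-R-squared values and the
#' scheme explaining more variance (ties go to week of year).
#'
#' @param table_of_year,table_prior Analysis tables built under the two
#'   schemes (see \code{\link{build_analysis_table}}).
#' @return List: \code{chosen}, \code{r2_of_year}, \code{r2_prior}.
#' @export
compare_week_predictors <- function(table_of_year, table_prior) {
  fml <- mean_tb ~ age_class + sex + mean_ta + week
  f1 <- fit_lme_ar1(table_of_year, fml)
  f2 <- fit_lme_ar1(table_prior, fml)
  if (f1$status != "converged" || f2$status != "converged")
    stop("week-scheme comparison failed to converge")
  list(chosen = if (f1$pseudo_r2 >= f2$pseudo_r2) "of_year" else
         "prior_to_hibernation",
       r2_of_year = f1$pseudo_r2, r2_prior = f2$pseudo_r2)
}

#' Pearson correlation test
#'
#' Product-moment correlation with the t statistic on n - 2 degrees of
#' freedom.  Zero variance in either vector yields an explicit NA result
#' rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @return List: r, t, df, p.
#' @export
corr_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, t = NA_real_, df = n - 2L, p = NA_real_))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Two-group linear-model comparison
#'
#' One-way linear model of a per-animal value on a two-level group factor
#' (equivalent to a two-sample t test; F = t squared).  Used for the
#' lactation-window highest minimum Tb of reproductive vs non-reproductive
#' females.
#'
#' @param values Per-animal values.
#' @param group Two-level factor/character of the same length.
#' @return List: means (named), difference (first level minus second),
#'   F, df (numerator, denominator), p.
#' @export
two_group_lm <- function(values, group) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("need at least 2 animals per group")
  fit <- lm(values ~ group)
  an <- anova(fit)
  m <- tapply(values, group, mean)
  list(means = m, difference = unname(m[1] - m[2]),
       F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p = an$`Pr(>F)`[1])
}
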