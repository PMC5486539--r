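## shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

## the default field cohort, classified end-to-end; reused by several files
default_cohort_analysis <- function() {
  if (!is.null(.fixture_env$coh)) return(.fixture_env$coh)
  cfg <- generator_config(seed = 42)
  coh <- generate_cohort(cfg)
  th <- thresholds()
  ids <- names(coh$series)
  daily <- list(); bouts <- list()
  onsets <- as.Date(rep(NA, length(ids))); names(onsets) <- ids
  for (id in ids) {
    s <- coh$series[[id]]
    bouts[[id]] <- assemble_bouts(s, th)
    onsets[id] <- detect_hibernation_onset(bouts[[id]])
    daily[[id]] <- daily_summaries(s, coh$ta[[as.character(s$meta$year)]], th)
  }
  tab <- build_analysis_table(daily, coh$meta, onsets, scheme = "of_year")
  out <- list(cfg = cfg, coh = coh, daily = daily, bouts = bouts,
              onsets = onsets, table = tab[tab$week >= 20, ])
  .fixture_env$coh <- out
  out
}

## animal-week table drawn from the AR(1) + random-intercept model itself,
## used for the parameter-recovery, type-I and power checks
make_model_table <- function(n_anim = 36, weeks = 20:31, re_sd = 0.3,
                             rho = 0.4, sd = 0.5, beta_fm = 0) {
  rows <- vector("list", n_anim)
  for (a in seq_len(n_anim)) {
    mast <- if (a %% 2) "mast" else "failure"
    sex <- if (a %% 4 < 2) "female" else "male"
    e <- if (rho == 0) stats::rnorm(length(weeks), 0, sd) else
      as.numeric(stats::arima.sim(list(ar = rho), length(weeks), sd = sd))
    y <- 3 + stats::rnorm(1, 0, re_sd) + e +
      ifelse(mast == "mast" & sex == "female", beta_fm, 0)
    rows[[a]] <- data.frame(animal_id = paste0("a", a), sex = sex,
                            mast = mast, week = weeks, hours_above = y,
                            mean_ta = stats::rnorm(length(weeks), 15, 2),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## one mast-year female with daily summaries and truth, cached by seed
mast_female <- function(seed) {
  key <- paste0("mf", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  if (is.null(.fixture_env$ta2013)) .fixture_env$ta2013 <- generate_ta(2013, 1)
  m <- animal_meta(sprintf("F%03d", seed), "female", "adult", "field",
                   "intraperitoneal", 2013, "mast")
  r <- generate_animal_year(m, .fixture_env$ta2013,
                            generator_config(seed = 1), seed = seed)
  r$daily <- daily_summaries(r$series, .fixture_env$ta2013)
  .fixture_env[[key]] <- r
  r
}

## tiny hand-built daily-summary table
toy_days <- function(dates, mean_tb, min_tb = mean_tb - 1,
                     max_tb = mean_tb + 2, hours_above = 0,
                     torpor_day = FALSE, complete = TRUE) {
  data.frame(date = as.Date(dates), n_samples = 22L, max_tb = max_tb,
             min_tb = min_tb, mean_tb = mean_tb, hours_above = hours_above,
             torpor_day = torpor_day, complete = complete,
             mean_ta = 15, min_ta = 10)
}
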