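## ---- internal helpers for the trace generator ----------------------------

## weekly activity shape for non-reproductive animals (weeks 18..44),
## peaking in week 35 (late August); rescaled per animal to the group mean
.act_shape_weeks <- 18:44
.act_shape <- c(0.60, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 1.00, 1.05,
                1.00, 0.95, 0.90, 0.95, 1.05, 1.15, 1.30, 1.45, 1.60,
                1.55, 1.40, 1.30, 1.20, 1.10, 1.00, 0.90, 0.85, 0.80)

## raw day-level activity target (h/day above 40 C) before rescaling;
## reproductive females get the gestation dip and lactation recovery
.raw_activity <- function(doy, meta, partum_doy, onset_doy, cfg) {
  g <- numeric(length(doy))
  reproductive <- !is.na(partum_doy)
  if (!reproductive) {
    wk <- pmin(pmax(week_of_year(as.Date(doy - 1,
             origin = as.Date("2013-01-01"))), 18L), 44L)
    shp <- .act_shape[match(wk, .act_shape_weeks)]
    if (meta$sex == "male" && meta$mast == "mast")
      shp <- shp * ifelse(wk %in% 25:27, 1.25, 1)   # mating-season bump
    g <- shp
  } else {
    ms <- cfg$mastF_shape
    dip_from <- cfg$dip_start_doy
    dip_to <- partum_doy + cfg$dip_end_rel
    rise_to <- partum_doy + 4L + cfg$lactation_rise_days
    for (i in seq_along(doy)) {
      d <- doy[i]
      g[i] <-
        if (d < 158) ms$early
        else if (d < 178) ms$early +          # mating activity builds up
          (d - 158) / 20 * (ms$mating - ms$early)
        else if (d < 190) ms$mating
        else if (d < dip_from) ms$pre_dip
        else if (d <= dip_to) cfg$dip_level
        else if (d <= rise_to)
          cfg$dip_level + (d - dip_to) / (rise_to - dip_to) *
            (ms$peak - cfg$dip_level)
        else if (d <= cfg$lactation_end_doy + 4) ms$peak
        else ms$peak + (d - cfg$lactation_end_doy - 4) /
               (280 - cfg$lactation_end_doy - 4) * (ms$tail_end - ms$peak)
    }
  }
  ## activity collapses during the onset week (test drops, entry)
  g[doy > onset_doy - 7L] <- g[doy > onset_doy - 7L] * cfg$week0_activity_factor
  g
}

## day-level activity targets scaled so the mean over the analysed weeks
## (20 .. week(onset)-1) equals the configured group mean; for reproductive
## females the dip days are held fixed at dip_level and only the rest is
## scaled (the dip is a printed calibration constant, <2 h/day)
.activity_targets_by_day <- function(doy_grid, meta, partum_doy, onset_doy,
                                     cfg) {
  target <- cfg$activity_targets[[paste(meta$sex, meta$mast, sep = "_")]]
  if (meta$site == "enclosure") target <- target * cfg$enclosure_activity_scale
  g <- .raw_activity(doy_grid, meta, partum_doy, onset_doy, cfg)
  wk_on <- ((onset_doy - 1L) %/% 7L) + 1L
  covered <- doy_grid >= 134L & doy_grid <= (wk_on - 1L) * 7L
  reproductive <- !is.na(partum_doy)
  if (reproductive) {
    dip <- doy_grid >= cfg$dip_start_doy &
      doy_grid <= partum_doy + cfg$dip_end_rel
    n_cov <- sum(covered)
    s <- (target * n_cov - sum(g[covered & dip])) / sum(g[covered & !dip])
    h <- ifelse(dip, g, s * g)
  } else {
    s <- target / mean(g[covered])
    h <- s * g
  }
  pmin(pmax(h, 0), 7.2)
}

## per-day short-torpor probability: seasonal weekly shape, damped on warm
## days and on high-activity days, normalised so the expected frequency
## over the analysed weeks equals the configured group rate
.torpor_prob_by_day <- function(doy_grid, h_day, ta_day, meta, partum_doy,
                                onset_doy, cfg) {
  rate <- cfg$torpor_rate[[meta$mast]]
  wk <- pmin(pmax(((doy_grid - 1L) %/% 7L) + 1L, 18L), 44L)
  shp <- if (meta$mast == "mast") cfg$torpor_shape_mast else
    cfg$torpor_shape_failure
  w <- shp[match(wk, cfg$torpor_shape_weeks)]
  mta <- ta_day$min_ta[match(doy_grid, ta_day$doy)]
  mta[is.na(mta)] <- mean(ta_day$min_ta)
  w <- w * exp(-cfg$torpor_ta_coef * (mta - mean(mta)))
  w <- w * exp(cfg$torpor_activity_coupling * (h_day - mean(h_day)))

  wk_on <- ((onset_doy - 1L) %/% 7L) + 1L
  covered <- doy_grid >= 134L & doy_grid <= (wk_on - 1L) * 7L
  testwin <- doy_grid >= onset_doy - cfg$testdrop_window_days &
    doy_grid < onset_doy
  allowed <- !testwin
  if (meta$mast == "mast" && meta$sex == "female")
    allowed <- allowed & !(doy_grid >= cfg$no_torpor_repro_doy[1] &
                           doy_grid <= cfg$no_torpor_repro_doy[2])
  p <- numeric(length(doy_grid))
  ac <- allowed & covered
  if (any(ac)) {
    td_expect <- cfg$testdrop_p_animal * cfg$testdrop_p_day *
      sum(testwin & covered)
    m <- max((rate / 7 * sum(covered) - td_expect) / sum(ac), 0)
    p[allowed] <- m * w[allowed] / mean(w[ac])
  }
  pmin(pmax(p, 0), 0.9)
}

## nightly peak-temperature mean: fluctuating plateau through mid-season,
## a ramp over the last 7 weeks prior to onset, and a drop in week 0
.peak_mu <- function(doy, onset_doy, cfg) {
  wp <- -((onset_doy - doy) %/% 7L)
  key <- as.character(wp)
  mu <- rep(cfg$peak_mu_default, length(doy))
  hit <- key %in% names(cfg$peak_ramp_wp)
  mu[hit] <- cfg$peak_ramp_wp[key[hit]]
  mu
}

#' Generate one synthetic animal-year Tb trace with ground truth
#'
#' Simulates an annual body-temperature record for one animal from
#' emergence (week 18) to 14 days past hibernation onset, at the configured
#' cadence and 0.5 degree C quantisation, together with a ground-truth
#' sidecar recording every injected event.  The trace contains: a circadian
#' baseline (daytime rest, nocturnal activity); one contiguous hyperthermic
#' block per night whose duration tracks the sex-by-mast-by-week activity
#' target; daytime short torpor days drawn from the seasonal torpor model
#' (torpor Tb tracks daily ambient temperature with a 5 degree C floor);
#' for mast-year females a gestation rest-phase plateau, the activity dip
#' of late pregnancy, a parturition step in the daily baseline and the
#' lactation minimum-Tb elevation; Bernoulli test drops in the final week
#' (some animals show none); and entry into a multiday torpor bout on the
#' onset date.
#'
#' @param meta An \code{\link{animal_meta}}.
#' @param ta A \code{\link{ta_series}} covering \code{meta$year}.
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed for this animal (derived from the master seed
#'   by \code{\link{generate_cohort}}).
#' @return A list with elements \code{series} (a \code{\link{tb_series}})
#'   and \code{truth} (list: per-sample \code{state}, \code{onset} date,
#'   \code{partum} date or \code{NA}, \code{partum_step},
#'   \code{testdrop_days}, \code{torpor_days}, and per-day
#'   \code{daily_hours_above}).
#' @export
generate_animal_year <- function(meta, ta, config = generator_config(),
                                 seed = 1L) {
  stopifnot(inherits(meta, "animal_meta"), inherits(ta, "ta_series"),
            inherits(config, "generator_config"))
  cfg <- config
  .with_seed(seed, {
    year <- meta$year
    origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
    start_doy <- sample(cfg$season_start_doy[1]:cfg$season_start_doy[2], 1)
    onset_doy <- sample(cfg$onset_doy_window[1]:cfg$onset_doy_window[2], 1)
    reproductive <- meta$sex == "female" && meta$mast == "mast"
    partum_doy <- if (reproductive)
      sample(cfg$partum_doy_window[1]:cfg$partum_doy_window[2], 1) else NA

    doy_grid <- start_doy:(onset_doy + cfg$hibernation_tail_days)
    ta_d <- .ta_daily(ta)
    ta_d$doy <- as.integer(format(ta_d$date, "%j"))

    h_day <- .activity_targets_by_day(doy_grid, meta, partum_doy, onset_doy,
                                      cfg)
    p_tor <- .torpor_prob_by_day(doy_grid, h_day, ta_d, meta, partum_doy,
                                 onset_doy, cfg)

    ## --- day-level draws ---------------------------------------------
    nd <- length(doy_grid)
    torpor_day <- runif(nd) < p_tor
    shows_testdrops <- runif(1) < cfg$testdrop_p_animal
    testwin <- doy_grid >= onset_doy - cfg$testdrop_window_days &
      doy_grid < onset_doy
    testdrop_day <- testwin & shows_testdrops & (runif(nd) < cfg$testdrop_p_day)
    torpor_day <- (torpor_day | testdrop_day) & doy_grid < onset_doy
    tor_start <- runif(nd, cfg$torpor_start_h[1], cfg$torpor_start_h[2])
    tor_dur <- ifelse(testwin,
                      runif(nd, cfg$testdrop_bout_h[1], cfg$testdrop_bout_h[2]),
                      runif(nd, cfg$torpor_bout_h[1], cfg$torpor_bout_h[2]))
    day_jitter <- rnorm(nd, 0, cfg$day_jitter_sd)

    ## nightly hyperthermic block (night indexed by its evening doy)
    k <- cfg$block_gamma_shape
    blk_dur <- ifelse(h_day > 0.05,
                      pmin(rgamma(nd, shape = k, rate = k / pmax(h_day, 0.05)),
                           cfg$block_max_h), 0)
    blk_dur[doy_grid >= onset_doy] <- 0
    ## blocks are anchored around the middle of the night (activity peaks
    ## mid-night), with a modest jitter
    blk_start <- pmin(pmax((cfg$block_max_h - blk_dur) / 2 +
                             runif(nd, -1.5, 1.5), 0),
                      pmax(cfg$block_max_h - blk_dur, 0))
    peak <- rnorm(nd, .peak_mu(doy_grid, onset_doy, cfg), cfg$peak_sd)

    ## --- circadian baseline levels -----------------------------------
    ## individuals differ in baseline Tb; the offset shifts both phases
    a_off <- rnorm(1, 0, cfg$animal_sd)
    rest_lv <- rep(cfg$rest_mean, nd)
    act_lv <- rep(cfg$active_mean, nd)
    if (reproductive) {
      lact_rest <- cfg$rest_mean + cfg$lactation_elevation
      rest_step <- lact_rest - cfg$gestation_rest
      n_tot <- 86400 / cfg$sampling_interval_s
      n_rest <- (24 - cfg$block_max_h) * 3600 / cfg$sampling_interval_s
      n_act_nb <- cfg$block_max_h * 3600 / cfg$sampling_interval_s -
        cfg$dip_level * 3600 / cfg$sampling_interval_s
      act_step <- (cfg$partum_step * n_tot - rest_step * n_rest) / n_act_nb
      g0 <- partum_doy - cfg$gestation_lead_days
      g1 <- g0 + cfg$gestation_ramp_days
      l1 <- cfg$lactation_end_doy
      dk <- cfg$lactation_decay_days
      for (i in seq_len(nd)) {
        d <- doy_grid[i]
        rest_lv[i] <-
          if (d < g0) cfg$rest_mean
          else if (d < g1) cfg$rest_mean +
            (d - g0) / (g1 - g0) * (cfg$gestation_rest - cfg$rest_mean)
          else if (d < partum_doy) cfg$gestation_rest
          else if (d <= l1) lact_rest
          else if (d <= l1 + dk) lact_rest +
            (d - l1) / dk * (cfg$rest_mean - lact_rest)
          else cfg$rest_mean
        act_lv[i] <-
          if (d >= partum_doy && d <= l1) cfg$active_mean + act_step
          else if (d > l1 && d <= l1 + dk) cfg$active_mean +
            act_step * (1 - (d - l1) / dk)
          else cfg$active_mean
      }
    }
    rest_lv <- rest_lv + a_off
    act_lv <- act_lv + a_off

    ## --- sample grid --------------------------------------------------
    t0 <- as.numeric(origin) + (start_doy - 1) * 86400 +
      runif(1, 0, cfg$sampling_interval_s)
    t1 <- as.numeric(origin) +
      (onset_doy - 1 + cfg$hibernation_tail_days) * 86400 + 86000
    tnum <- seq(t0, t1, by = cfg$sampling_interval_s)
    n <- length(tnum)
    doy <- as.integer((tnum - as.numeric(origin)) %/% 86400) + 1L
    hour <- ((tnum - as.numeric(origin)) %% 86400) / 3600
    di <- match(doy, doy_grid)

    ## night membership: evening doy indexes the night
    is_evening <- hour >= cfg$active_start_h
    is_morning <- hour < cfg$active_end_h
    night_doy <- ifelse(is_evening, doy, ifelse(is_morning, doy - 1L, NA))
    ni <- match(night_doy, doy_grid)
    night_pos <- ifelse(is_evening, hour - cfg$active_start_h,
                        ifelse(is_morning, hour + (24 - cfg$active_start_h),
                               NA))
    active <- !is.na(ni)

    in_block <- active & !is.na(ni) & blk_dur[ni] > 0 &
      night_pos >= blk_start[ni] & night_pos < blk_start[ni] + blk_dur[ni]
    in_block[is.na(in_block)] <- FALSE

    onset_time <- as.numeric(origin) + (onset_doy - 1) * 86400 +
      cfg$hibernation_start_h * 3600
    hibernating <- tnum >= onset_time

    tor_b <- !active & !hibernating & !is.na(di) & torpor_day[di] &
      hour >= tor_start[di] & hour < tor_start[di] + tor_dur[di]
    tor_b[is.na(tor_b)] <- FALSE

    ## --- temperatures -------------------------------------------------
    ta_mean_day <- ta_d$mean_ta[match(doy, ta_d$doy)]
    ta_mean_day[is.na(ta_mean_day)] <- mean(ta_d$mean_ta)
    tb <- numeric(n)
    state <- character(n)

    rest_i <- !active & !hibernating & !tor_b
    tb[rest_i] <- rnorm(sum(rest_i), rest_lv[di[rest_i]] +
                          day_jitter[di[rest_i]], cfg$rest_sd)
    tb[rest_i] <- pmin(pmax(tb[rest_i], 32.3), 39.8)
    state[rest_i] <- "euthermia"

    act_nb <- active & !hibernating & !in_block
    tb[act_nb] <- rnorm(sum(act_nb), act_lv[ni[act_nb]] +
                          day_jitter[ni[act_nb]], cfg$active_sd)
    tb[act_nb] <- pmin(pmax(tb[act_nb], 32.3), cfg$nonblock_cap)
    state[act_nb] <- "euthermia"

    hyp <- active & !hibernating & in_block
    tb[hyp] <- pmax(peak[ni[hyp]], cfg$hyper_floor) -
      abs(rnorm(sum(hyp), 0, 0.08))
    tb[hyp] <- pmax(tb[hyp], cfg$hyper_floor)
    state[hyp] <- "hyperthermia"

    ## on block-free nights one active sample carries the nightly peak so
    ## the daily-maximum profile survives activity suppression (week 0)
    for (j in which(blk_dur == 0 & doy_grid < onset_doy)) {
      cand <- which(act_nb & !is.na(ni) & ni == j)
      if (length(cand))
        tb[cand[sample.int(length(cand), 1)]] <- min(peak[j],
                                                     cfg$nonblock_cap)
    }

    tor_all <- tor_b | hibernating
    ttb <- pmin(pmax(ta_mean_day[tor_all] + cfg$torpor_tb_offset,
                     cfg$torpor_tb_floor), cfg$torpor_tb_cap) +
      rnorm(sum(tor_all), 0, 0.3)
    tb[tor_all] <- pmin(pmax(ttb, 2), 30.9)
    state[tor_all] <- "torpor"

    ## subcutaneous mode: active-phase readings run 2 C below core
    if (meta$implant_route == "subcutaneous" ||
        cfg$implant_route == "subcutaneous") {
      sc <- active & !tor_all
      tb[sc] <- tb[sc] - 2
    }

    tb_q <- round(tb / cfg$quantization) * cfg$quantization
    stamp <- as.POSIXct(tnum, origin = "1970-01-01", tz = "UTC")
    series <- tb_series(meta, data.frame(timestamp = stamp, tb = tb_q),
                        nominal_interval_s = cfg$sampling_interval_s)

    date <- as.Date(stamp, tz = "UTC")
    hrs <- tapply(state == "hyperthermia", date, sum) *
      cfg$sampling_interval_s / 3600
    truth <- list(
      animal_id = meta$animal_id, year = year,
      state = state,
      onset = as.Date(onset_doy - 1, origin = as.Date(sprintf("%d-01-01",
                                                              year))),
      partum = if (reproductive)
        as.Date(partum_doy - 1, origin = as.Date(sprintf("%d-01-01", year)))
        else as.Date(NA),
      partum_step = if (reproductive) cfg$partum_step else NA_real_,
      lactation_elevation = if (reproductive) cfg$lactation_elevation
        else NA_real_,
      testdrop_days = as.Date(doy_grid[testdrop_day] - 1,
                              origin = as.Date(sprintf("%d-01-01", year))),
      torpor_days = as.Date(doy_grid[torpor_day] - 1,
                            origin = as.Date(sprintf("%d-01-01", year))),
      daily_hours_above = data.frame(
        date = as.Date(names(hrs)), hours = as.numeric(hrs),
        row.names = NULL))
    list(series = series, truth = truth)
  })
}
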