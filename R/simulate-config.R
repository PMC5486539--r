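#' Synthetic-cohort generator configuration
#'
#' Bundles every tunable of the synthetic Tb/Ta generator.  The defaults
#' define the reference study conditions: 7 females and 7 males per year,
#' one mast year (2013) flanked by two mast-failure years (2012, 2014),
#' hourly sampling at 3850 s with 0.5 degree C logger quantisation, and
#' group-level activity and torpor calibration constants taken from the
#' printed cohort summaries this generator is designed to emulate
#' (mast-year females ~4.2 h/day above 40 degrees C, males ~2.5 h/day,
#' mast-failure females ~2.1 h/day; ~2.29 torpor days/week in failure years
#' vs ~0.26 in mast years; parturition step +0.49 degrees C; lactation
#' minimum-Tb elevation +1.37 degrees C; pre-hibernation maximum-Tb ramp
#' peaking at 40.45 degrees C in week -1 and dropping to 39.53 in week 0).
#'
#' Nightly activity is injected as one contiguous hyperthermic block per
#' night whose duration is Gamma-distributed around a per-day target; the
#' per-day targets are scaled per animal so the mean over the animal's
#' analysed weeks (week 20 up to the week before hibernation onset) equals
#' the configured group mean.  Torpor is a per-day Bernoulli whose
#' probability follows a weekly seasonal shape, is damped on warm days
#' (minimum-Ta coefficient) and on high-activity days (activity coupling),
#' and is normalised per animal so the expected torpor-day frequency equals
#' the configured group mean.
#'
#' @param seed Master seed; per-animal streams are derived by stable hashing.
#' @param n_females,n_males Animals per sex per year.
#' @param years Data frame with columns \code{year}, \code{mast}.
#' @param site \code{"field"} or \code{"enclosure"}; enclosure scales the
#'   activity targets by \code{enclosure_activity_scale} and leaves torpor
#'   untouched (site does not affect torpor frequency).
#' @param implant_route \code{"intraperitoneal"} or \code{"subcutaneous"};
#'   subcutaneous mode subtracts 2 degrees C from every active-phase sample,
#'   so hours-above computed at the corrected 38 degree C threshold match
#'   the intraperitoneal values.
#' @param sampling_interval_s,quantization Logger cadence and resolution.
#' @param ... Named overrides for any default listed in the function body
#'   (circadian levels, activity targets, torpor shape and coupling,
#'   reproduction and hibernation parameters).
#' @return An object of class \code{"generator_config"}.
#' @export
generator_config <- function(seed = 42L, n_females = 7L, n_males = 7L,
                             years = data.frame(
                               year = c(2012L, 2013L, 2014L),
                               mast = c("failure", "mast", "failure")),
                             site = c("field", "enclosure"),
                             implant_route = c("intraperitoneal",
                                               "subcutaneous"),
                             sampling_interval_s = 3850,
                             quantization = 0.5, ...) {
  site <- match.arg(site)
  implant_route <- match.arg(implant_route)
  cfg <- list(
    seed = as.integer(seed), n_females = as.integer(n_females),
    n_males = as.integer(n_males), years = years,
    site = site, implant_route = implant_route,
    sampling_interval_s = sampling_interval_s, quantization = quantization,

    ## season span
    season_start_doy = c(120L, 126L),   # emergence drawn within week 18
    onset_doy_window = c(258L, 285L),   # hibernation onset mid-Sept..mid-Oct
    hibernation_tail_days = 14L,        # trace continues past onset

    ## circadian baseline (degrees C); rest = daytime, active = night
    rest_mean = 36.2, active_mean = 38.3,
    rest_sd = 0.25, active_sd = 0.4, day_jitter_sd = 0.07,
    animal_sd = 0.18,        # individual variation in baseline Tb

    active_start_h = 21, active_end_h = 6,

    ## nightly hyperthermia blocks
    activity_targets = c(female_mast = 4.20, female_failure = 2.06,
                         male_mast = 2.53, male_failure = 2.55),
    enclosure_activity_scale = 2.32 / 2.90,
    block_gamma_shape = 12,             # duration ~ Gamma(k, mean = target)
    block_max_h = 9,                    # length of the night window
    week0_activity_factor = 0.05,       # activity collapses in onset week
    hyper_floor = 40.3,                 # raw block samples stay above this
    nonblock_cap = 40.2,                # euthermic samples stay below this
    peak_sd = 0.2,
    peak_mu_default = 40.55,            # nightly peak draw, mid-season
    peak_ramp_wp = c(`-7` = 39.9, `-6` = 40.0, `-5` = 40.1, `-4` = 40.2,
                     `-3` = 40.3, `-2` = 40.38, `-1` = 40.45, `0` = 39.53),

    ## short torpor (active season)
    torpor_rate = c(mast = 0.26, failure = 2.29),   # days/week group means
    torpor_shape_weeks = 18:44,
    torpor_shape_failure = c(0.5, 0.55, 0.6, 0.7, 0.8, 0.9, 1.0, 1.2,
                             1.5, 1.6, 1.6, 1.6, 1.5, 1.5, 1.4, 1.1,
                             0.8, 0.5, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4,
                             0.4, 0.4, 0.4),
    torpor_shape_mast = c(2.0, 2.0, 2.0, 1.8, 1.5, 1.2, 1.0, 0.8,
                          0.5, 0.3, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15,
                          0.15, 0.15, 0.3, 0.4, 0.4, 0.4, 0.4, 0.4,
                          0.4, 0.4, 0.4),
    torpor_ta_coef = 0.08,              # per degree C of daily minimum Ta
    torpor_activity_coupling = -0.6,    # per hour of daily activity target
    torpor_bout_h = c(2, 8), torpor_start_h = c(8, 11),
    torpor_tb_offset = 2, torpor_tb_floor = 5, torpor_tb_cap = 30.5,
    no_torpor_repro_doy = c(190L, 245L), # gestation+lactation exclusion

    ## reproduction (mast-year females only)
    partum_doy_window = c(205L, 218L),  # births late July .. early August
    partum_step = 0.49,                 # daily-mean Tb step at parturition
    lactation_elevation = 1.37,         # minimum-Tb elevation vs non-repro
    gestation_rest = 37.3,              # rest-phase level in late gestation
    gestation_ramp_days = 40L,          # slow rise into gestation level
    gestation_lead_days = 60L,          # ramp starts partum - lead
    dip_start_doy = 196L,               # activity dip: late gestation
    dip_end_rel = 3L,                   # ... until partum + 3
    dip_level = 1.5,                    # h/day above 40 during the dip
    lactation_rise_days = 18L,          # activity recovery after partum + 4
    lactation_end_doy = 248L, lactation_decay_days = 10L,
    mastF_shape = NULL,                 # filled below

    ## hibernation entry
    testdrop_window_days = 7L,          # test drops in the final week
    testdrop_p_animal = 0.8,            # some animals show none at all
    testdrop_p_day = 0.35,
    testdrop_bout_h = c(3, 10),
    hibernation_start_h = 10
  )
  ## raw day-level activity shape for reproductive females outside the
  ## dip (absolute h/day before per-animal rescaling): early season,
  ## mating bump (weeks 25-27), post-partum recovery to a lactation peak
  ## around week 34-35, then a slow decline
  cfg$mastF_shape <- list(early = 3.2, mating = 4.3, pre_dip = 2.5,
                          peak = 6.8, tail_end = 4.5)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown generator_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(nrow(cfg$years) >= 1, all(cfg$years$mast %in% c("mast", "failure")))
  structure(cfg, class = "generator_config")
}

## deterministic 31-bit string hash (polynomial, double arithmetic is exact
## here because intermediates stay below 2^52)
.hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

## derive a per-animal seed from the master seed and the animal id
.animal_seed <- function(seed, animal_id) {
  as.integer((as.numeric(seed) * 7919 + .hash_string(animal_id)) %% 2147483647)
}

## run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
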