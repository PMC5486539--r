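#' Pipeline run configuration
#'
#' Validated settings for a full simulate-classify-phenology-analyze run.
#' Either a generator configuration (synthetic mode) or input paths to
#' logger CSVs plus a metadata table must be supplied.
#'
#' @param out_dir Output directory (created if missing).
#' @param generator A \code{\link{generator_config}} for synthetic input,
#'   or \code{NULL} to read files.
#' @param traces_dir,meta_csv,ta_csv Input paths (file mode).
#' @param th A \code{\link{thresholds}} object.
#' @param scheme Week scheme for the analysis table.
#' @param detector_k,detector_min_step Parturition-detector settings.
#' @param seed Seed recorded in the manifest; in synthetic mode it
#'   overrides the generator seed.
#' @param write_samples Also write the per-sample state table (large).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(out_dir, generator = generator_config(),
                       traces_dir = NULL, meta_csv = NULL, ta_csv = NULL,
                       th = thresholds(), scheme = "of_year",
                       detector_k = 5L, detector_min_step = 0.3,
                       seed = NULL, write_samples = FALSE) {
  if (is.null(generator)) {
    for (p in c(traces_dir, meta_csv, ta_csv))
      if (is.null(p) || !file.exists(p))
        stop("file-mode pipeline requires existing traces_dir, meta_csv ",
             "and ta_csv")
  } else if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, generator = generator,
                 traces_dir = traces_dir, meta_csv = meta_csv,
                 ta_csv = ta_csv, th = th, scheme = scheme,
                 detector_k = as.integer(detector_k),
                 detector_min_step = detector_min_step,
                 seed = if (is.null(seed) && !is.null(generator))
                   generator$seed else as.integer(seed),
                 write_samples = isTRUE(write_samples)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' \code{\link{run_config}}; keys under \code{generator:} are passed to
#' \code{\link{generator_config}} and keys under \code{thresholds:} to
#' \code{\link{thresholds}}.
#'
#' @param path YAML file.
#' @param out_dir Override for the output directory.
#' @return A \code{\link{run_config}}.
#' @export
run_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) do.call(generator_config, y$generator)
    else generator_config()
  th <- if (!is.null(y$thresholds)) do.call(thresholds, y$thresholds)
    else thresholds()
  run_config(out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
             generator = gen, th = th,
             scheme = if (!is.null(y$scheme)) y$scheme else "of_year",
             detector_k = if (!is.null(y$detector_k)) y$detector_k else 5L,
             detector_min_step = if (!is.null(y$detector_min_step))
               y$detector_min_step else 0.3,
             seed = y$seed,
             write_samples = isTRUE(y$write_samples))
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (or read), classify, phenology and analyze in order,
#' writes each stage's tables under \code{out_dir}, and returns (and
#' writes) a manifest recording the package version, seed, a configuration
#' hash, and per-stage outputs with row counts.  A given configuration
#' always produces an identical manifest.
#'
#' @param config A \code{\link{run_config}}.
#' @return The manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "dormouseTb",
    version = as.character(packageVersion("dormouseTb")),
    seed = config$seed,
    config_hash = .hash_string(paste(deparse(unclass(config)),
                                     collapse = "")),
    stages = list())
  od <- config$out_dir

  ## -- stage 1: obtain input -----------------------------------------
  if (!is.null(config$generator)) {
    coh <- generate_cohort(config$generator)
  } else {
    metas <- read_meta_csv(config$meta_csv)
    ta <- read_ta_csv(config$ta_csv)
    series <- lapply(metas, function(m)
      read_logger_csv(file.path(config$traces_dir,
                                paste0(m$animal_id, ".csv")), m))
    names(series) <- vapply(metas, `[[`, "", "animal_id")
    md <- do.call(rbind, lapply(metas, function(m)
      as.data.frame(unclass(m), stringsAsFactors = FALSE)))
    coh <- list(series = series, truths = NULL,
                ta = setNames(rep(list(ta), length(unique(md$year))),
                              unique(md$year)),
                meta = md)
  }
  .write_tsv(coh$meta, file.path(od, "meta.tsv"))
  manifest$stages$simulate <- list(outputs = "meta.tsv",
                                   n_animals = length(coh$series))

  ## -- stage 2: classification ---------------------------------------
  ids <- names(coh$series)
  bouts <- list(); daily <- list(); onsets <- as.Date(rep(NA, length(ids)))
  names(onsets) <- ids
  for (id in ids) {
    s <- coh$series[[id]]
    b <- assemble_bouts(s, config$th)
    ta_y <- coh$ta[[as.character(s$meta$year)]]
    d <- daily_summaries(s, ta_y, config$th)
    onsets[id] <- detect_hibernation_onset(b)
    bouts[[id]] <- cbind(animal_id = id, b)
    daily[[id]] <- cbind(animal_id = id, d)
    if (config$write_samples) {
      cl <- classify_series(s, config$th)
      .write_tsv(cbind(animal_id = id, cl),
                 file.path(od, paste0("samples-", id, ".tsv")))
    }
  }
  bouts_all <- do.call(rbind, c(bouts, list(make.row.names = FALSE)))
  daily_all <- do.call(rbind, c(daily, list(make.row.names = FALSE)))
  .write_tsv(bouts_all, file.path(od, "bouts.tsv"))
  .write_tsv(daily_all, file.path(od, "daily.tsv"))
  manifest$stages$classify <- list(
    outputs = c("bouts.tsv", "daily.tsv"),
    n_bouts = nrow(bouts_all), n_days = nrow(daily_all),
    n_onsets = sum(!is.na(onsets)))

  ## -- stage 3: phenology ---------------------------------------------
  daily_by_id <- lapply(ids, function(id) {
    d <- daily[[id]]; d$animal_id <- NULL; d
  })
  names(daily_by_id) <- ids
  phen <- do.call(rbind, lapply(ids, function(id) {
    d <- daily_by_id[[id]]
    cand <- detect_parturition(d, k = config$detector_k,
                               min_step = config$detector_min_step)
    top <- if (nrow(cand)) cand[cand$rank == 1, ] else NULL
    data.frame(animal_id = id,
               onset = as.character(onsets[id]),
               parturition = if (!is.null(top)) as.character(top$date)
                 else NA_character_,
               parturition_step = if (!is.null(top)) top$step else NA_real_,
               n_candidates = nrow(cand),
               lactation_peak_min_tb = lactation_peak_min_tb(d),
               stringsAsFactors = FALSE)
  }))
  .write_tsv(phen, file.path(od, "phenology.tsv"))
  manifest$stages$phenology <- list(outputs = "phenology.tsv",
                                    n_rows = nrow(phen))

  ## -- stage 4: weekly table + models ---------------------------------
  tab <- build_analysis_table(daily_by_id, coh$meta, onsets,
                              scheme = config$scheme)
  .write_tsv(tab, file.path(od, "weekly.tsv"))
  models <- list()
  if (nrow(tab) && length(unique(tab$animal_id)) >= 5) {
    fml_h <- if (length(unique(tab$mast)) > 1)
      hours_above ~ week + sex + age_class + mast + mean_ta + sex:mast
      else hours_above ~ week + sex + age_class + mean_ta
    fit_h <- fit_lme_ar1(tab, fml_h)
    models$hours_above <- if (fit_h$status == "converged")
      fit_h[c("status", "anova", "ar1", "pseudo_r2", "lambda")] else
      fit_h[c("status", "message")]
    fml_t <- if (length(unique(tab$mast)) > 1)
      torpor_days ~ week + sex + age_class + mast + min_ta
      else torpor_days ~ week + sex + age_class + min_ta
    fit_t <- fit_lme_ar1(tab, fml_t)
    models$torpor_days <- if (fit_t$status == "converged")
      fit_t[c("status", "anova", "ar1", "pseudo_r2", "lambda")] else
      fit_t[c("status", "message")]
  } else {
    models$note <- "too few animals for mixed models; weekly table only"
  }
  jsonlite::write_json(models, file.path(od, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$stages$analyze <- list(outputs = c("weekly.tsv", "models.json"),
                                  n_weekly_rows = nrow(tab))

  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
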