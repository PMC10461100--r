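#' Run configuration for the end-to-end pipeline
#'
#' Either a `scenario` (simulate inputs) or `traces`/`meta` paths (load
#' recordings) must be given; everything else has canonical defaults.
#'
#' @param scenario A `tci_scenario` to simulate from, or `NULL`.
#' @param traces,meta Trace/metadata CSV paths (alternative to
#'   `scenario`).
#' @param reference Optional reference-profile CSV (`stimulus_id,
#'   amplitude`) or `reference_profile` for cross-correlation; a
#'   simulated scenario supplies its own paired reference.
#' @param quantify Settings from [quantify_config()].
#' @param n_flies Panel size when simulating.
#' @param dose Optional dose analysis: `list(odorant=, solvent=, doses=)`;
#'   when simulating, `doses` drives [simulate_dose_panel()].
#' @param longevity Optional `list(n_stims=)` to run the repeated
#'   stimulation analysis (simulation only).
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing files.
#' @param seed Overrides the scenario seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, traces = NULL, meta = NULL,
                       reference = NULL, quantify = quantify_config(),
                       n_flies = 16, dose = NULL, longevity = NULL,
                       out_dir = NULL, seed = NULL) {
  if (is.null(scenario) && is.null(traces))
    stop("config needs either a scenario or a traces path")
  if (!is.null(traces) && !file.exists(traces))
    stop("traces file not found: ", traces)
  if (!is.null(seed) && !is.null(scenario)) scenario$seed <- as.integer(seed)
  structure(list(scenario = scenario, traces = traces, meta = meta,
                 reference = reference, quantify = quantify,
                 n_flies = n_flies, dose = dose, longevity = longevity,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(unclass(config), digits = 15), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, quantification, tuning and (optionally)
#' dose-response and longevity analyses into one deterministic, logged
#' run: the response matrix, the tuning profile with its sparseness, the
#' frame-wise cross-correlation against the reference channel, per-fly
#' Hill fits, the stimulations-to-half-max count, and a human-readable
#' summary. All numeric outputs are deterministic given the configuration
#' and seed; outputs are stamped with a configuration hash and the
#' package version.
#'
#' @param config A `run_config`.
#' @return A `tci_report` (list of all result objects), invisibly when
#'   writing files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config_hash = config_hash(config),
                 version = as.character(utils::packageVersion("tcikit")))

  # --- acquire recordings -------------------------------------------------
  reference <- config$reference
  if (!is.null(config$scenario)) {
    panel <- simulate_panel(config$scenario, n_flies = config$n_flies)
    recordings <- panel$recordings
    blanks <- panel$blanks
    if (is.null(reference)) reference <- panel$reference
  } else {
    recordings <- tryCatch(read_traces(config$traces, config$meta),
                           error = function(e)
                             stop("stage imaging_io: ", conditionMessage(e)))
    blanks <- list()
  }
  if (is.character(reference)) reference <- reference_profile(
    utils::read.csv(reference))

  # --- quantify -----------------------------------------------------------
  rm <- tryCatch(build_response_matrix(recordings, blanks, config$quantify),
                 error = function(e) stop("stage quantify: ",
                                          conditionMessage(e)))
  report$response_matrix <- rm

  # --- tuning -------------------------------------------------------------
  profile <- tuning_profile(rm)
  report$tuning <- list(profile = profile, sparseness = sparseness(profile))
  if (!is.null(reference)) {
    dmat <- build_dff_matrix(recordings, blanks, config$quantify)
    report$crosscorr <- tryCatch(
      framewise_crosscorrelation(dmat, reference),
      error = function(e) stop("stage tuning: ", conditionMessage(e)))
  }

  # --- dose-response ------------------------------------------------------
  if (!is.null(config$dose)) {
    d <- config$dose
    if (!is.null(config$scenario) && !is.null(d$doses)) {
      dp <- simulate_dose_panel(config$scenario, d$doses,
                                n_flies = config$n_flies)
      drm <- build_response_matrix(dp$recordings, dp$blanks, config$quantify)
      series <- dose_series_from_matrix(drm, "dosed_odorant",
                                        config$scenario$solvent_id)
    } else {
      series <- dose_series_from_matrix(rm, d$odorant, d$solvent)
    }
    report$dose_fits <- tryCatch(fit_hill_set(series),
                                 error = function(e)
                                   stop("stage dose_response: ",
                                        conditionMessage(e)))
  }

  # --- longevity ----------------------------------------------------------
  if (!is.null(config$longevity) && !is.null(config$scenario)) {
    series <- simulate_adaptation_series(config$scenario,
                                         config$longevity$n_stims)
    report$longevity <- c(list(series = series),
                          stimulations_to_half_max(series))
  }

  class(report) <- "tci_report"
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

#' Write a pipeline report bundle to a directory
#'
#' Emits `response_matrix.csv` (+ `_long.csv`), `tuning.json`,
#' `dose_fits.csv`, `longevity.csv` and `summary.txt` as applicable.
#'
#' @param report A `tci_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_response_matrix(report$response_matrix,
                        file.path(dir, "response_matrix.csv"))
  tun <- list(stimuli = report$tuning$profile$stimuli,
              mean_amplitude_pct = report$tuning$profile$r,
              n = report$tuning$profile$n,
              sparseness = report$tuning$sparseness)
  if (!is.null(report$crosscorr))
    tun$crosscorr <- list(r2 = report$crosscorr$r2,
                          peak_frame = report$crosscorr$peak_frame,
                          peak_r2 = report$crosscorr$peak_r2,
                          n_stimuli = report$crosscorr$n_stimuli)
  jsonlite::write_json(tun, file.path(dir, "tuning.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$dose_fits))
    utils::write.csv(report$dose_fits$fits, file.path(dir, "dose_fits.csv"),
                     row.names = FALSE)
  if (!is.null(report$longevity))
    utils::write.csv(
      data.frame(stimulation = seq_along(report$longevity$series$amplitudes),
                 amplitude_pct = report$longevity$series$amplitudes),
      file.path(dir, "longevity.csv"), row.names = FALSE)
  writeLines(format_summary(report), file.path(dir, "summary.txt"))
  invisible(dir)
}

format_summary <- function(report) {
  rm <- report$response_matrix
  sem <- function(v) stats::sd(v) / sqrt(sum(!is.na(v)))
  lines <- c(
    sprintf("tcikit %s  (config %s)", report$version, report$config_hash),
    sprintf("%d flies x %d stimuli; response window frames %d-%d",
            nrow(rm$amplitudes), ncol(rm$amplitudes),
            rm$response_window[1], rm$response_window[2]),
    "",
    "Mean response amplitudes (% dF/F0, mean +/- SEM across flies):")
  for (s in colnames(rm$amplitudes)) {
    v <- rm$amplitudes[, s]
    lines <- c(lines, sprintf("  %-22s %6.2f +/- %.2f%s", s, mean(v, na.rm = TRUE),
                              sem(v), if (rm$solvent[[s]]) "  [solvent]" else ""))
  }
  lines <- c(lines, "",
             sprintf("Lifetime sparseness S = %.3f (n = %d odorants)",
                     report$tuning$sparseness, report$tuning$profile$n))
  if (!is.null(report$crosscorr))
    lines <- c(lines, sprintf(
      "Peak calcium-reference correlation r2 = %.3f at frame %d (%d stimuli)",
      report$crosscorr$peak_r2, report$crosscorr$peak_frame,
      report$crosscorr$n_stimuli))
  if (!is.null(report$dose_fits)) {
    s <- report$dose_fits$summary
    g <- function(p, col) s[[col]][s$parameter == p]
    lines <- c(lines, sprintf(
      "Dose-response (n = %d flies): EC50 = %.3g +/- %.2g ug, Hill slope = %.3g +/- %.2g",
      g("ec50_ug", "n"), g("ec50_ug", "mean"), g("ec50_ug", "sem"),
      g("hill_slope", "mean"), g("hill_slope", "sem")))
  }
  if (!is.null(report$longevity))
    lines <- c(lines, sprintf(
      "Longevity: %d stimulations to half-max%s (of %d applied)",
      report$longevity$count,
      if (report$longevity$censored) " (censored)" else "",
      length(report$longevity$series$amplitudes)))
  lines
}

#' @export
print.tci_report <- function(x, ...) {
  cat(format_summary(x), sep = "\n")
  invisible(x)
}
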