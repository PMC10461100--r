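#' Default quantification settings
#'
#' Canonical frame windows for the 100-frame, 5 Hz protocol: F0 baseline
#' over the 5 frames immediately preceding stimulus onset (frames 11--15),
#' 1 s stimulus over frames 16--20, and the response amplitude as the mean
#' of the 15 frames (3 s) after stimulus start (frames 17--31).
#'
#' @param baseline_frames Inclusive window for the F0 baseline.
#' @param stim_frames Inclusive stimulation window.
#' @param response_frames Inclusive response-amplitude window.
#' @param blank_scope `"per_fly"` to average each fly's own blank
#'   recordings as its bleach reference, `"global"` to use the grand
#'   average across flies.
#' @return A list of settings.
#' @export
quantify_config <- function(baseline_frames = c(11, 15),
                            stim_frames = c(16, 20),
                            response_frames = c(17, 31),
                            blank_scope = c("per_fly", "global")) {
  blank_scope <- match.arg(blank_scope)
  if (baseline_frames[2] >= stim_frames[1])
    stop("baseline window must end before stimulus onset")
  if (response_frames[1] <= stim_frames[1] - 1)
    stop("response window must start at or after stimulus onset")
  list(baseline_frames = as.integer(baseline_frames),
       stim_frames = as.integer(stim_frames),
       response_frames = as.integer(response_frames),
       blank_scope = blank_scope)
}

#' Relative fluorescence change, dF/F0
#'
#' Computes `(F - F0)/F0` per frame, with F0 the mean fluorescence over the
#' pre-stimulus baseline window. Values are stored as dimensionless
#' fractions; [response_amplitude()] reports percent. By construction the
#' uncorrected trace has exactly zero mean over its baseline window.
#'
#' @param rec A `tci_recording`.
#' @param baseline_frames Inclusive 1-based F0 window (default frames
#'   11--15, the 5 frames before the canonical onset at frame 16).
#' @return A `dff_trace`: fields `values`, `baseline_frames`, `corrected`
#'   (`FALSE` here), plus the recording's metadata.
#' @export
compute_dff <- function(rec, baseline_frames = c(11, 15)) {
  stopifnot(inherits(rec, "tci_recording"))
  w <- frame_window(baseline_frames, rec$frame_count, "baseline window")
  if (w[2] >= rec$stimulus_onset_frame)
    stop("baseline window [", w[1], ", ", w[2],
         "] must lie strictly before stimulus onset (frame ",
         rec$stimulus_onset_frame, ")")
  f0 <- mean(rec$trace[window_frames(w)])
  if (!is.finite(f0) || f0 <= 0)
    stop("F0 <= 0 in recording ", rec$recording_id,
         ": dead or empty ROI (F0 = ", signif(f0, 4), ")")
  structure(
    list(values = (rec$trace - f0) / f0,
         baseline_frames = w,
         corrected = FALSE,
         f0 = f0,
         frame_rate_hz = rec$frame_rate_hz,
         stimulus_onset_frame = rec$stimulus_onset_frame,
         stimulus_offset_frame = rec$stimulus_offset_frame,
         stimulus_id = rec$stimulus_id,
         dose_ug = rec$dose_ug,
         is_solvent = rec$is_solvent,
         from_blank = rec$is_blank,
         fly_id = rec$fly_id,
         recording_id = rec$recording_id,
         repeat_index = rec$repeat_index),
    class = "dff_trace")
}

#' Photobleaching correction by blank-trace subtraction
#'
#' Subtracts the dF/F0 time course of a no-stimulus (blank) recording --
#' the GCaMP fluorescence decay curve -- from a stimulated dF/F0 trace,
#' frame by frame. Both curves must already be in dF/F0 units with the
#' same baseline window.
#'
#' @param dff A `dff_trace` from a stimulated recording.
#' @param blank A `dff_trace` derived from blank recording(s); see
#'   [average_blank_dff()].
#' @return The corrected `dff_trace` (`corrected = TRUE`).
#' @export
bleach_correct <- function(dff, blank) {
  stopifnot(inherits(dff, "dff_trace"), inherits(blank, "dff_trace"))
  if (length(dff$values) != length(blank$values))
    stop("trace length mismatch: ", length(dff$values), " vs ",
         length(blank$values), " frames")
  if (!identical(dff$baseline_frames, blank$baseline_frames))
    stop("baseline windows differ between trace and blank")
  if (!isTRUE(blank$from_blank))
    stop("bleach reference must derive from no-stimulus (blank) recordings")
  out <- dff
  out$values <- dff$values - blank$values
  out$corrected <- TRUE
  out
}

#' Average the dF/F0 traces of several blank recordings
#'
#' @param blanks List of blank `tci_recording`s.
#' @param baseline_frames F0 window passed to [compute_dff()].
#' @return A `dff_trace` flagged as a blank-derived bleach reference.
#' @export
average_blank_dff <- function(blanks, baseline_frames = c(11, 15)) {
  if (!length(blanks)) stop("no blank recording available")
  if (!all(vapply(blanks, function(b) isTRUE(b$is_blank), logical(1))))
    stop("bleach reference must derive from no-stimulus (blank) recordings")
  dffs <- lapply(blanks, compute_dff, baseline_frames = baseline_frames)
  out <- dffs[[1]]
  out$values <- rowMeans(vapply(dffs, `[[`, numeric(length(out$values)),
                                "values"))
  out$from_blank <- TRUE
  out
}

#' Scalar response amplitude over a frame window, in percent
#'
#' Arithmetic mean of the dF/F0 values over the inclusive window,
#' multiplied by 100. With canonical settings this is the mean of the 15
#' frames (3 s) following stimulus start, frames 17--31.
#'
#' @param dff A `dff_trace`.
#' @param window Inclusive 1-based frame window (default `c(17, 31)`).
#' @return Response amplitude in percent dF/F0.
#' @export
response_amplitude <- function(dff, window = c(17, 31)) {
  stopifnot(inherits(dff, "dff_trace"))
  w <- frame_window(window, length(dff$values), "response window")
  100 * mean(dff$values[window_frames(w)])
}

#' Assemble the fly-by-stimulus response matrix
#'
#' For every stimulated recording: dF/F0, subtraction of the fly's (or the
#' global) averaged blank curve, then the windowed amplitude. Solvent
#' controls are retained as columns -- they are the negative controls, not
#' subtracted. Recordings carrying a dose keep it in the long table so a
#' dose-response analysis can be built from the same object.
#'
#' @param recordings List of stimulated `tci_recording`s (solvents
#'   included, blanks excluded or ignored).
#' @param blanks List of blank `tci_recording`s (bleach references).
#' @param config Settings from [quantify_config()].
#' @return A `response_matrix`: `amplitudes` (fly x stimulus matrix, %),
#'   `response_window`, `solvent` (named logical per stimulus), and `long`
#'   (one row per recording with fly, stimulus, dose, repeat, amplitude).
#' @export
build_response_matrix <- function(recordings, blanks,
                                  config = quantify_config()) {
  stim <- Filter(function(r) !r$is_blank, recordings)
  blanks <- c(Filter(function(r) r$is_blank, recordings), blanks)
  if (!length(blanks)) stop("no blank recording available for bleach correction")
  if (!length(stim)) stop("no stimulated recordings")

  key <- vapply(stim, function(r)
    paste(r$fly_id, r$stimulus_id, r$dose_ug, r$repeat_index), character(1))
  if (anyDuplicated(key)) {
    d <- stim[[which(duplicated(key))[1]]]
    stop("duplicate unindexed (fly, stimulus) pair: ", d$fly_id, " / ",
         d$stimulus_id, "; add repeat_index to disambiguate")
  }

  refs <- blank_references(blanks, stim, config)
  long <- do.call(rbind, lapply(stim, function(r) {
    ref <- refs[[blank_key(r$fly_id, config$blank_scope)]]
    if (is.null(ref))
      stop("no blank recording for fly ", r$fly_id,
           " (blank_scope = \"per_fly\")")
    dff <- bleach_correct(compute_dff(r, config$baseline_frames), ref)
    data.frame(fly_id = r$fly_id, stimulus_id = r$stimulus_id,
               dose_ug = r$dose_ug, is_solvent = r$is_solvent,
               repeat_index = r$repeat_index,
               recording_id = r$recording_id,
               amplitude_pct = response_amplitude(dff,
                                                  config$response_frames))
  }))

  flies <- unique(long$fly_id)
  stimuli <- unique(long$stimulus_id)
  amp <- matrix(NA_real_, length(flies), length(stimuli),
                dimnames = list(flies, stimuli))
  # a (fly, stimulus) cell averages over repeats/doses if several exist
  for (i in seq_len(nrow(long)))
    amp[long$fly_id[i], long$stimulus_id[i]] <-
      mean(long$amplitude_pct[long$fly_id == long$fly_id[i] &
                              long$stimulus_id == long$stimulus_id[i]])
  solvent <- vapply(stimuli, function(s)
    any(long$is_solvent[long$stimulus_id == s]), logical(1))
  structure(list(amplitudes = amp,
                 response_window = frame_window(config$response_frames,
                                                .Machine$integer.max),
                 solvent = solvent, long = long,
                 config = config),
            class = "response_matrix")
}

blank_key <- function(fly_id, scope) if (scope == "global") ".global" else fly_id

blank_references <- function(blanks, stim, config) {
  if (config$blank_scope == "global") {
    list(.global = average_blank_dff(blanks, config$baseline_frames))
  } else {
    by_fly <- split(blanks, vapply(blanks, `[[`, character(1), "fly_id"))
    refs <- lapply(by_fly, average_blank_dff,
                   baseline_frames = config$baseline_frames)
    refs
  }
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d flies x %d stimuli (%d solvent), window %d-%d\n",
              nrow(x$amplitudes), ncol(x$amplitudes), sum(x$solvent),
              x$response_window[1], x$response_window[2]))
  print(round(x$amplitudes, 2))
  invisible(x)
}

#' Write a response matrix as wide + long CSV
#'
#' @param rm A `response_matrix`.
#' @param path Wide CSV path (rows = fly, columns = stimulus); the long
#'   companion goes to `<path minus .csv>_long.csv`.
#' @return Invisible list of paths.
#' @export
write_response_matrix <- function(rm, path) {
  stopifnot(inherits(rm, "response_matrix"))
  wide <- data.frame(fly_id = rownames(rm$amplitudes), rm$amplitudes,
                     check.names = FALSE)
  utils::write.csv(wide, path, row.names = FALSE)
  long_path <- paste0(sub("\\.csv$", "", path), "_long.csv")
  utils::write.csv(rm$long, long_path, row.names = FALSE)
  invisible(list(wide = path, long = long_path))
}

#' Ordered amplitudes of one fly under repeated stimulation
#'
#' @param amplitudes Response amplitudes (%) in stimulation order.
#' @param inter_trial_interval_s Seconds between stimulations (canonical
#'   120: one stimulation every 2 min).
#' @return A `longevity_series`.
#' @export
longevity_series <- function(amplitudes, inter_trial_interval_s = 120) {
  amplitudes <- as.numeric(amplitudes)
  if (!length(amplitudes)) stop("longevity series must be non-empty")
  structure(list(amplitudes = amplitudes,
                 inter_trial_interval_s = inter_trial_interval_s),
            class = "longevity_series")
}

#' Number of stimulations sustained above half-maximal response
#'
#' Counts the stimulations whose amplitude stays at or above 50% of the
#' series maximum, up to (and not including) the first stimulation that
#' drops below half-max. If the series never drops below half-max the
#' count equals the series length and the result is right-censored.
#'
#' @param series A `longevity_series` or a numeric amplitude vector.
#' @return List with `count` and `censored`.
#' @export
stimulations_to_half_max <- function(series) {
  a <- if (inherits(series, "longevity_series")) series$amplitudes
       else as.numeric(series)
  if (!length(a)) stop("longevity series must be non-empty")
  mx <- max(a)
  if (mx <= 0) stop("all-zero (or non-positive) series: half-max undefined")
  below <- which(a < mx / 2)
  if (!length(below)) list(count = length(a), censored = TRUE)
  else list(count = below[1] - 1L, censored = FALSE)
}
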