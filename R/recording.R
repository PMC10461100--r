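#' Construct a single-ROI fluorescence recording
#'
#' A `tci_recording` is the atomic unit of analysis: the mean-fluorescence
#' time series of one region of interest (one antenna) during one
#' stimulation, together with the acquisition and stimulus metadata needed
#' to quantify it. All frame indices are 1-based and windows are inclusive,
#' so "frames 17--31" means 15 frames.
#'
#' @param trace Numeric vector of per-frame mean fluorescence (arbitrary
#'   camera units); length defines the frame count (canonically 100).
#' @param frame_rate_hz Sampling rate in Hz (canonically 5).
#' @param stimulus_onset_frame 1-based index of the first stimulated frame
#'   (canonically 16, i.e. 3 s into the recording at 5 Hz).
#' @param stimulus_offset_frame 1-based index of the last stimulated frame
#'   (canonically 20, a 1 s stimulus).
#' @param stimulus_id Stimulus label, or `NA` for a blank (no-stimulus)
#'   recording.
#' @param dose_ug Dose in micrograms on filter paper, or `NA` when the
#'   stimulus is undosed (single screening concentration or solvent).
#' @param is_solvent Logical; `TRUE` for a solvent negative control.
#' @param is_blank Logical; `TRUE` for a no-stimulus recording used as the
#'   photobleaching reference.
#' @param fly_id Fly/ROI identifier (one label per antenna ROI).
#' @param recording_id Unique recording identifier; defaults to a
#'   combination of fly and stimulus.
#' @param repeat_index Optional 1-based index ordering repeated
#'   presentations of the same stimulus to the same fly.
#'
#' @return An object of class `tci_recording`.
#' @export
recording <- function(trace, frame_rate_hz = 5, stimulus_onset_frame = 16,
                      stimulus_offset_frame = 20, stimulus_id = NA_character_,
                      dose_ug = NA_real_, is_solvent = FALSE, is_blank = FALSE,
                      fly_id = "fly1", recording_id = NULL,
                      repeat_index = NA_integer_) {
  trace <- as.numeric(trace)
  if (length(trace) < 1L || !all(is.finite(trace)))
    stop("trace must be a non-empty vector of finite fluorescence values")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive")
  if (is_blank) {
    stimulus_id <- NA_character_
  } else {
    if (is.na(stimulus_id) || !nzchar(stimulus_id))
      stop("a non-blank recording needs a stimulus_id")
  }
  onset <- as.integer(stimulus_onset_frame)
  offset <- as.integer(stimulus_offset_frame)
  if (onset < 1L || offset < onset || offset > length(trace))
    stop("stimulus window must satisfy 1 <= onset <= offset <= frame_count")
  if (!is.na(dose_ug) && dose_ug < 0) stop("dose_ug must be non-negative")
  if (is.null(recording_id))
    recording_id <- paste(fly_id,
                          if (is_blank) "blank" else stimulus_id,
                          sep = "_")
  structure(
    list(trace = trace,
         frame_count = length(trace),
         frame_rate_hz = as.numeric(frame_rate_hz),
         stimulus_onset_frame = onset,
         stimulus_offset_frame = offset,
         stimulus_id = stimulus_id,
         dose_ug = as.numeric(dose_ug),
         is_solvent = isTRUE(is_solvent),
         is_blank = isTRUE(is_blank),
         fly_id = as.character(fly_id),
         recording_id = as.character(recording_id),
         repeat_index = as.integer(repeat_index)),
    class = "tci_recording")
}

#' @export
print.tci_recording <- function(x, ...) {
  what <- if (x$is_blank) "blank" else
    if (x$is_solvent) paste0("solvent (", x$stimulus_id, ")") else x$stimulus_id
  cat(sprintf("<tci_recording %s> %s, %d frames @ %g Hz, stimulus frames %d-%d%s\n",
              x$recording_id, what, x$frame_count, x$frame_rate_hz,
              x$stimulus_onset_frame, x$stimulus_offset_frame,
              if (!is.na(x$dose_ug)) sprintf(", %g ug", x$dose_ug) else ""))
  invisible(x)
}

#' Inclusive 1-based frame window
#'
#' Normalizes a window given as `c(first, last)` into a validated integer
#' pair. Used for baseline, stimulus and response windows throughout.
#'
#' @param window Integer vector `c(first, last)`, inclusive.
#' @param frame_count Total frame count the window must fit in.
#' @param what Label used in error messages.
#' @return Integer vector `c(first, last)`.
#' @keywords internal
frame_window <- function(window, frame_count, what = "window") {
  w <- as.integer(window)
  if (length(w) != 2L || anyNA(w))
    stop(what, " must be c(first, last)")
  if (w[1] < 1L || w[2] < w[1] || w[2] > frame_count)
    stop(what, sprintf(" [%d, %d] out of range for %d frames", w[1], w[2],
                       frame_count))
  w
}

window_frames <- function(window) seq.int(window[1], window[2])
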