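#' Tuning profile of one receptor
#'
#' Per-stimulus mean response amplitudes across flies, the input to
#' lifetime-sparseness and cross-correlation analyses. Solvent controls
#' are excluded by default: the panel is the odorants.
#'
#' @param rm A `response_matrix`, or a named numeric vector of
#'   per-stimulus amplitudes.
#' @param include_solvents Keep solvent columns in the panel.
#' @return A `tuning_profile`: `stimuli`, `r` (mean amplitudes, %), `n`.
#' @export
tuning_profile <- function(rm, include_solvents = FALSE) {
  if (inherits(rm, "response_matrix")) {
    keep <- if (include_solvents) rep(TRUE, ncol(rm$amplitudes))
            else !rm$solvent
    r <- colMeans(rm$amplitudes[, keep, drop = FALSE], na.rm = TRUE)
  } else {
    r <- rm
    if (is.null(names(r))) names(r) <- paste0("stim", seq_along(r))
  }
  if (length(r) < 2L) stop("a tuning profile needs at least 2 stimuli")
  structure(list(stimuli = names(r), r = unname(r), n = length(r)),
            class = "tuning_profile")
}

#' Lifetime sparseness of a response spectrum
#'
#' Tuning-breadth statistic in \[0, 1\]:
#' \deqn{S = \frac{1}{1 - 1/n}\left(1 -
#'   \frac{(\sum_i r_i / n)^2}{\sum_i r_i^2 / n}\right)}
#' where \eqn{r_i} is the response amplitude to stimulus \eqn{i} in a
#' panel of \eqn{n} stimuli. S = 1 for a receptor responding to a single
#' stimulus, S = 0 for a uniform response across the panel. The formula is
#' undefined for negative responses, so negative amplitudes are clamped to
#' zero before evaluation.
#'
#' @param profile A `tuning_profile` or numeric vector of amplitudes
#'   (n >= 2).
#' @return Sparseness S in \[0, 1\].
#' @export
sparseness <- function(profile) {
  r <- if (inherits(profile, "tuning_profile")) profile$r
       else as.numeric(profile)
  n <- length(r)
  if (n < 2L) stop("sparseness needs at least 2 stimuli")
  r <- pmax(r, 0)
  if (all(r == 0))
    stop("all responses <= 0 after clamping: sparseness undefined (0/0)")
  (1 / (1 - 1 / n)) * (1 - (sum(r) / n)^2 / (sum(r^2) / n))
}

#' Across-fly mean dF/F0 trace per stimulus
#'
#' Quantifies every stimulated recording to a bleach-corrected dF/F0 trace
#' and averages across flies per stimulus, producing the frames x stimuli
#' matrix on which [framewise_crosscorrelation()] operates.
#'
#' @inheritParams build_response_matrix
#' @param include_solvents Keep solvent stimuli as columns.
#' @return Numeric matrix, frames x stimuli (fractional dF/F0).
#' @export
build_dff_matrix <- function(recordings, blanks, config = quantify_config(),
                             include_solvents = FALSE) {
  stim <- Filter(function(r) !r$is_blank, recordings)
  if (!include_solvents) stim <- Filter(function(r) !r$is_solvent, stim)
  blanks <- c(Filter(function(r) r$is_blank, recordings), blanks)
  if (!length(blanks)) stop("no blank recording available")
  refs <- blank_references(blanks, stim, config)
  dffs <- lapply(stim, function(r) {
    ref <- refs[[blank_key(r$fly_id, config$blank_scope)]]
    if (is.null(ref)) stop("no blank recording for fly ", r$fly_id)
    bleach_correct(compute_dff(r, config$baseline_frames), ref)
  })
  stimuli <- unique(vapply(stim, `[[`, character(1), "stimulus_id"))
  mat <- vapply(stimuli, function(s) {
    sel <- vapply(stim, function(r) identical(r$stimulus_id, s), logical(1))
    rowMeans(vapply(dffs[sel], `[[`,
                    numeric(length(dffs[[1]]$values)), "values"))
  }, numeric(length(dffs[[1]]$values)))
  mat
}

#' Frame-resolved correlation between calcium tuning and a reference
#' profile
#'
#' At every frame, correlates the across-fly mean calcium signal of each
#' stimulus with an external per-stimulus reference amplitude (typically
#' single-sensillum-recording spike rates), reporting the squared Pearson
#' correlation r2 per frame. This asks at which point in time the calcium
#' signal best reproduces the electrophysiological tuning. This is a
#' per-frame correlation across stimuli, not a signal-processing lag
#' correlation.
#'
#' Frames where the calcium values have zero variance across stimuli
#' (e.g. before stimulus onset in noise-free data) have undefined
#' correlation and are recorded as `NA`.
#'
#' @param dff_by_stimulus Frames x stimuli matrix of mean dF/F0 traces
#'   (see [build_dff_matrix()]); column names are stimulus labels.
#' @param reference A `reference_profile`, or data frame with columns
#'   `stimulus_id` and `amplitude`.
#' @param aliases Optional named character vector mapping calcium stimulus
#'   labels to reference labels (`c(calcium_label = reference_label)`).
#' @return A `crosscorr_series`: `r2` per frame, `peak_frame` (earliest
#'   frame attaining the maximal defined r2), `peak_r2`, `n_stimuli`,
#'   `stimuli` used.
#' @export
framewise_crosscorrelation <- function(dff_by_stimulus, reference,
                                       aliases = NULL) {
  if (is.data.frame(reference)) reference <- reference_profile(reference)
  stopifnot(inherits(reference, "reference_profile"))
  labels <- colnames(dff_by_stimulus)
  if (is.null(labels)) stop("dff_by_stimulus needs stimulus column names")
  mapped <- labels
  if (!is.null(aliases)) {
    hit <- labels %in% names(aliases)
    mapped[hit] <- aliases[labels[hit]]
  }
  shared <- mapped %in% reference$stimuli
  if (any(!shared))
    warning("dropping stimuli absent from reference: ",
            paste(labels[!shared], collapse = ", "))
  if (sum(shared) < 3L)
    stop("need at least 3 stimuli shared with the reference profile (got ",
         sum(shared), ")")
  ca <- dff_by_stimulus[, shared, drop = FALSE]
  ref <- reference$amplitudes[match(mapped[shared], reference$stimuli)]
  if (stats::sd(ref) == 0)
    stop("reference profile has zero variance across stimuli")
  r2 <- apply(ca, 1, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, ref)^2
  })
  if (all(is.na(r2))) stop("correlation undefined at every frame")
  peak <- which(r2 == max(r2, na.rm = TRUE))[1]  # ties -> earliest frame
  structure(list(r2 = unname(r2), peak_frame = peak,
                 peak_r2 = unname(r2[peak]), n_stimuli = sum(shared),
                 stimuli = labels[shared]),
            class = "crosscorr_series")
}

#' Electrophysiological reference tuning profile
#'
#' Per-stimulus response amplitudes from an external modality (e.g. spike
#' rate increases from single-sensillum recordings) used as the reference
#' in cross-correlation analyses.
#'
#' @param x Data frame with columns `stimulus_id` and `amplitude`, or a
#'   named numeric vector.
#' @return A `reference_profile`.
#' @export
reference_profile <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("stimulus_id", "amplitude") %in% names(x)))
    structure(list(stimuli = as.character(x$stimulus_id),
                   amplitudes = as.numeric(x$amplitude)),
              class = "reference_profile")
  } else {
    structure(list(stimuli = names(x), amplitudes = unname(as.numeric(x))),
              class = "reference_profile")
  }
}

#' @export
print.crosscorr_series <- function(x, ...) {
  cat(sprintf("<crosscorr_series> %d stimuli, peak r2 = %.3f at frame %d\n",
              x$n_stimuli, x$peak_r2, x$peak_frame))
  invisible(x)
}
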