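#' Generative scenario for simulated GCaMP recordings
#'
#' Parameterizes everything the simulator needs to emulate a
#' transcuticular calcium-imaging experiment: the acquisition protocol
#' (100 frames at 5 Hz, 1 s stimulus at frames 16--20), a multiplicative
#' exponential photobleach, a phenomenological GCaMP transient kernel,
#' additive Gaussian sensor noise, a latent per-odorant tuning map shared
#' with a simulated electrophysiology (SSR) channel, a Hill dose
#' dependence, and amplitude adaptation across repeated stimulations.
#'
#' The model of one recording is
#' \deqn{F(t) = B\,e^{-t/\tau_{bleach}}\,(1 + a\,k(t)) + \epsilon_t,\quad
#'   \epsilon_t \sim N(0, \sigma^2)}
#' with `a` the stimulus activation (peak dF/F fraction) and `k(t)` the
#' unit-peak transient kernel. Bleach is multiplicative -- it attenuates
#' baseline and signal alike -- so blank-curve subtraction in dF/F0 space
#' is a close approximation rather than an exact inverse, exactly the
#' situation the correction addresses in real data.
#'
#' @param frame_rate_hz,frame_count Acquisition protocol (5 Hz, 100
#'   frames).
#' @param stim_frames Inclusive stimulation window, frames 16--20.
#' @param baseline_level Mean pre-bleach fluorescence B in camera units.
#' @param bleach_tau_s Photobleaching time constant in seconds (`Inf`
#'   disables bleaching).
#' @param kernel Probe kinetics: preset name `"GCaMP6s"` (rise 0.4 s,
#'   decay 2.5 s) or `"GCaMP6m"` (rise 0.2 s, decay 1.2 s), or a list
#'   `list(rise_tau_s=, decay_tau_s=)`. The presets are order-of-magnitude
#'   kinetic placeholders (6s slower than 6m), fully configurable.
#' @param noise_sd Additive Gaussian sensor noise, camera units per frame.
#' @param tuning Named vector of latent activations a_s >= 0 (peak dF/F
#'   fraction per odorant). The default is a graded 14-odorant spectrum
#'   typical of a generalist receptor.
#' @param hill Dose scenarios: `list(ec50_ug=, h=, a_max=)`; the
#'   activation at dose d is `a_max * d^h / (d^h + ec50^h)`.
#' @param ssr_gain,ssr_noise_sd Map latent activation to the simulated
#'   reference channel: amplitude = `ssr_gain * a_s + N(0, ssr_noise_sd^2)`
#'   (spikes/s).
#' @param gain_cv Coefficient of variation of a per-recording
#'   multiplicative response gain (biological across-fly variability of
#'   response amplitude).
#' @param repeat_gain_cv Trial-to-trial gain variability within one fly's
#'   repeated stimulations of the same odorant; much smaller than the
#'   across-fly `gain_cv` since the same neurons are imaged every 2 min.
#' @param adaptation Across-repeat amplitude decay:
#'   `list(floor_fraction=, decay_constant=)`; stimulation j has
#'   activation `a1 * (f + (1 - f) * exp(-(j - 1)/kappa))`. With the
#'   defaults (f = 0.2, kappa = 128) the expected decay crosses half of
#'   the initial response near stimulation 126; the first-drop counting
#'   rule of [stimulations_to_half_max()] reads below that crossing on
#'   noisy series.
#' @param solvent_id,blank_noise Solvent label; whether blanks carry
#'   sensor noise.
#' @param seed Integer seed; identical seed + scenario give bit-identical
#'   output.
#' @return A `tci_scenario` list.
#' @export
tci_scenario <- function(frame_rate_hz = 5, frame_count = 100,
                         stim_frames = c(16, 20),
                         baseline_level = 1000, bleach_tau_s = 30,
                         kernel = "GCaMP6s", noise_sd = 10,
                         tuning = NULL,
                         hill = list(ec50_ug = 1, h = 2, a_max = 0.08),
                         ssr_gain = 1000, ssr_noise_sd = 5,
                         gain_cv = 0.1, repeat_gain_cv = 0.03,
                         adaptation = list(floor_fraction = 0.2,
                                           decay_constant = 128),
                         solvent_id = "solvent", blank_noise = TRUE,
                         seed = 1L) {
  if (is.character(kernel)) {
    kernel <- switch(kernel,
      GCaMP6s = list(rise_tau_s = 0.4, decay_tau_s = 2.5),
      GCaMP6m = list(rise_tau_s = 0.2, decay_tau_s = 1.2),
      stop("unknown kernel preset: ", kernel))
  }
  if (kernel$rise_tau_s <= 0 || kernel$decay_tau_s <= 0)
    stop("kernel time constants must be positive")
  if (bleach_tau_s <= 0) stop("bleach_tau_s must be positive (use Inf for none)")
  if (is.null(tuning))
    tuning <- stats::setNames(
      c(0.100, 0.080, 0.062, 0.048, 0.038, 0.030, 0.024, 0.019,
        0.015, 0.012, 0.009, 0.007, 0.005, 0.003),
      paste0("odorant_", sprintf("%02d", 1:14)))
  if (any(tuning < 0)) stop("latent activations must be >= 0")
  f <- adaptation$floor_fraction
  if (f < 0 || f > 1) stop("floor_fraction must lie in [0, 1]")
  structure(list(frame_rate_hz = frame_rate_hz, frame_count = frame_count,
                 stim_frames = as.integer(stim_frames),
                 baseline_level = baseline_level, bleach_tau_s = bleach_tau_s,
                 kernel = kernel, noise_sd = noise_sd, tuning = tuning,
                 hill = hill, ssr_gain = ssr_gain,
                 ssr_noise_sd = ssr_noise_sd, gain_cv = gain_cv,
                 repeat_gain_cv = repeat_gain_cv,
                 adaptation = adaptation, solvent_id = solvent_id,
                 blank_noise = blank_noise, seed = as.integer(seed)),
            class = "tci_scenario")
}

# Evaluate an expression with a private, restorable RNG stream so the
# generator is deterministic without clobbering the caller's RNG state.
with_scenario_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# Deterministic sub-seed for the i-th draw of a scenario.
sub_seed <- function(seed, i) (seed + 7919L * i) %% .Machine$integer.max

#' Unit-peak GCaMP transient kernel
#'
#' Discrete response kernel at frame resolution: a boxcar over the
#' stimulation window convolved with the phenomenological impulse
#' response `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`, normalized to a
#' peak of 1. The kernel is exactly zero at and before stimulus onset
#' (calcium lags the stimulus), rises during the stimulus, and decays
#' after it; with an infinite decay constant it saturates to a plateau.
#'
#' @param scenario A `tci_scenario`.
#' @return Numeric vector of length `frame_count`, peak 1.
#' @export
response_kernel <- function(scenario) {
  stopifnot(inherits(scenario, "tci_scenario"))
  n <- scenario$frame_count
  dt <- 1 / scenario$frame_rate_hz
  box <- numeric(n)
  box[scenario$stim_frames[1]:scenario$stim_frames[2]] <- 1
  lag_t <- (seq_len(n) - 1) * dt
  h <- (1 - exp(-lag_t / scenario$kernel$rise_tau_s)) *
    exp(-lag_t / scenario$kernel$decay_tau_s)
  k <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    k[i] <- sum(box[j] * h[i - j + 1])
  }
  if (max(k) > 0) k <- k / max(k)
  k
}

# Latent activation for a stimulus (or a dose of the dosed odorant).
scenario_activation <- function(scenario, stimulus, dose = NULL) {
  if (!is.null(dose)) {
    h <- scenario$hill
    return(h$a_max * dose^h$h / (dose^h$h + h$ec50_ug^h$h))
  }
  if (identical(stimulus, scenario$solvent_id)) return(0)
  if (!stimulus %in% names(scenario$tuning))
    stop("unknown stimulus: ", stimulus)
  scenario$tuning[[stimulus]]
}

#' Simulate one recording (trace form)
#'
#' Draws `F(t) = B exp(-t/tau_bleach) (1 + a k(t)) + noise`, with `a`
#' taken from the tuning map, from the Hill curve when a dose is given,
#' or 0 for the solvent and for blanks. A per-recording multiplicative
#' gain with CV `gain_cv` models biological amplitude variability.
#'
#' @param scenario A `tci_scenario`.
#' @param stimulus Stimulus label; the scenario's `solvent_id` gives an
#'   activation-0 solvent control.
#' @param dose Optional dose in micrograms (activates the Hill model).
#' @param fly_id,repeat_index Metadata for the produced recording.
#' @param seed Seed override (defaults to the scenario seed).
#' @return A `tci_recording`.
#' @export
simulate_recording <- function(scenario, stimulus, dose = NULL,
                               fly_id = "fly1", repeat_index = NA,
                               seed = scenario$seed) {
  a <- scenario_activation(scenario, stimulus, dose)
  with_scenario_rng(seed, {
    if (scenario$gain_cv > 0 && a > 0)
      a <- a * max(0, 1 + scenario$gain_cv * stats::rnorm(1))
    trace <- simulate_trace_values(scenario, a, noise = TRUE)
    recording(trace, frame_rate_hz = scenario$frame_rate_hz,
              stimulus_onset_frame = scenario$stim_frames[1],
              stimulus_offset_frame = scenario$stim_frames[2],
              stimulus_id = stimulus,
              dose_ug = if (is.null(dose)) NA_real_ else dose,
              is_solvent = identical(stimulus, scenario$solvent_id),
              fly_id = fly_id, repeat_index = repeat_index,
              recording_id = paste0(fly_id, "_", stimulus,
                                    if (!is.null(dose)) paste0("_", dose),
                                    if (!is.na(repeat_index))
                                      paste0("_r", repeat_index)))
  })
}

simulate_trace_values <- function(scenario, a, noise = TRUE) {
  t <- (seq_len(scenario$frame_count) - 1) / scenario$frame_rate_hz
  k <- response_kernel(scenario)
  f <- scenario$baseline_level * exp(-t / scenario$bleach_tau_s) *
    (1 + a * k)
  if (noise && scenario$noise_sd > 0)
    f <- f + stats::rnorm(scenario$frame_count, 0, scenario$noise_sd)
  f
}

#' Simulate a blank (no-stimulus) recording
#'
#' Pure photobleaching decay plus sensor noise (unless the scenario sets
#' `blank_noise = FALSE`); the bleach reference of a simulated fly.
#'
#' @inheritParams simulate_recording
#' @return A blank `tci_recording`.
#' @export
simulate_blank <- function(scenario, fly_id = "fly1",
                           seed = scenario$seed) {
  with_scenario_rng(seed, {
    trace <- simulate_trace_values(scenario, 0,
                                   noise = isTRUE(scenario$blank_noise))
    recording(trace, frame_rate_hz = scenario$frame_rate_hz,
              stimulus_onset_frame = scenario$stim_frames[1],
              stimulus_offset_frame = scenario$stim_frames[2],
              is_blank = TRUE, fly_id = fly_id,
              recording_id = paste0(fly_id, "_blank"))
  })
}

#' Spread a simulated trace over ROI pixels (movie form)
#'
#' Renders a recording as a `movie_stack`: every pixel inside the ROI
#' carries the trace plus independent per-pixel noise; pixels outside
#' carry a dim background. Useful for exercising the image-I/O path.
#'
#' @param scenario A `tci_scenario`.
#' @param stimulus,dose As in [simulate_recording()].
#' @param shape Spatial shape `c(rows, cols)`.
#' @param roi A `roi_mask` of that shape; default is a centered square.
#' @param seed Seed override.
#' @return List with `stack` (a `movie_stack`) and `roi`.
#' @export
simulate_movie <- function(scenario, stimulus, dose = NULL,
                           shape = c(16, 16), roi = NULL,
                           seed = scenario$seed) {
  if (is.null(roi)) {
    m <- matrix(FALSE, shape[1], shape[2])
    r <- seq.int(max(1, shape[1] %/% 4), shape[1] - shape[1] %/% 4)
    c <- seq.int(max(1, shape[2] %/% 4), shape[2] - shape[2] %/% 4)
    m[r, c] <- TRUE
    roi <- roi_mask(m, "roi1")
  }
  a <- scenario_activation(scenario, stimulus, dose)
  with_scenario_rng(seed, {
    clean <- simulate_trace_values(scenario, a, noise = FALSE)
    frames <- array(0.05 * scenario$baseline_level,
                    dim = c(scenario$frame_count, shape[1], shape[2]))
    idx <- which(roi$mask)
    for (i in seq_len(scenario$frame_count)) {
      pl <- frames[i, , ]
      pl[idx] <- clean[i] +
        stats::rnorm(length(idx), 0, scenario$noise_sd)
      frames[i, , ] <- pl
    }
    frames[frames < 0] <- 0
    list(stack = movie_stack(frames, scenario$frame_rate_hz), roi = roi)
  })
}

#' Simulate a screening panel with its paired reference profile
#'
#' Per fly: one blank, one solvent control, and one recording per odorant
#' in the tuning map. The paired reference channel reports, per odorant,
#' `ssr_gain * a_s` plus Gaussian noise -- a simulated
#' single-sensillum-recording tuning profile sharing the latent tuning
#' with the calcium panel.
#'
#' @param scenario A `tci_scenario`.
#' @param stimuli Odorant labels (default: the scenario's tuning map).
#' @param n_flies Number of flies.
#' @return List with `recordings` (stimulated + solvent), `blanks`, and
#'   `reference` (a `reference_profile`).
#' @export
simulate_panel <- function(scenario, stimuli = names(scenario$tuning),
                           n_flies = 16) {
  if (n_flies < 1) stop("n_flies must be >= 1")
  recs <- list(); blanks <- list(); i <- 0L
  for (fly in paste0("fly", seq_len(n_flies))) {
    blanks[[fly]] <- simulate_blank(scenario, fly_id = fly,
                                    seed = sub_seed(scenario$seed, i <- i + 1L))
    for (s in c(scenario$solvent_id, stimuli)) {
      recs[[paste0(fly, "_", s)]] <-
        simulate_recording(scenario, s, fly_id = fly,
                           seed = sub_seed(scenario$seed, i <- i + 1L))
    }
  }
  reference <- with_scenario_rng(sub_seed(scenario$seed, i + 1L), {
    amps <- scenario$ssr_gain * scenario$tuning[stimuli] +
      stats::rnorm(length(stimuli), 0, scenario$ssr_noise_sd)
    reference_profile(stats::setNames(amps, stimuli))
  })
  list(recordings = unname(recs), blanks = unname(blanks),
       reference = reference)
}

#' Simulate a dose-response panel
#'
#' Per fly: one blank, one solvent control, and one recording per dose of
#' the dosed odorant, activations following the scenario's Hill curve.
#'
#' @param scenario A `tci_scenario`.
#' @param doses Doses in micrograms on filter paper.
#' @param n_flies Number of flies.
#' @param odorant Label for the dosed odorant.
#' @return List with `recordings` and `blanks`.
#' @export
simulate_dose_panel <- function(scenario, doses, n_flies = 11,
                                odorant = "dosed_odorant") {
  if (any(doses <= 0)) stop("doses must be positive")
  recs <- list(); blanks <- list(); i <- 100000L
  for (fly in paste0("fly", seq_len(n_flies))) {
    blanks[[fly]] <- simulate_blank(scenario, fly_id = fly,
                                    seed = sub_seed(scenario$seed, i <- i + 1L))
    recs[[paste0(fly, "_solv")]] <-
      simulate_recording(scenario, scenario$solvent_id, fly_id = fly,
                         seed = sub_seed(scenario$seed, i <- i + 1L))
    for (d in doses) {
      recs[[paste0(fly, "_", d)]] <-
        simulate_recording(scenario, odorant, dose = d, fly_id = fly,
                           seed = sub_seed(scenario$seed, i <- i + 1L))
    }
  }
  list(recordings = unname(recs), blanks = unname(blanks))
}

#' Simulate amplitudes across repeated stimulations of one fly
#'
#' Stimulation j carries activation
#' `a1 * (f + (1 - f) * exp(-(j - 1)/kappa))` -- adaptation toward a
#' floor fraction `f` of the initial response. Each stimulation is
#' simulated as a full recording and quantified through the standard
#' pipeline (dF/F0, blank subtraction, windowed amplitude), so the series
#' carries realistic measurement noise.
#'
#' @param scenario A `tci_scenario`; the stimulated odorant is the
#'   strongest one in the tuning map.
#' @param n_stims Number of repeated stimulations (>= 1).
#' @param fly_id Fly identifier.
#' @return A `longevity_series` of amplitudes in percent.
#' @export
simulate_adaptation_series <- function(scenario, n_stims, fly_id = "fly1") {
  if (n_stims < 1) stop("n_stims must be >= 1")
  best <- names(scenario$tuning)[which.max(scenario$tuning)]
  a1 <- max(scenario$tuning)
  f <- scenario$adaptation$floor_fraction
  kappa <- scenario$adaptation$decay_constant
  cfg <- quantify_config(stim_frames = scenario$stim_frames)
  blank <- simulate_blank(scenario, fly_id = fly_id,
                          seed = sub_seed(scenario$seed, 200000L))
  ref <- average_blank_dff(list(blank), cfg$baseline_frames)
  amps <- vapply(seq_len(n_stims), function(j) {
    aj <- a1 * (f + (1 - f) * exp(-(j - 1) / kappa))
    sc <- scenario
    sc$tuning[[best]] <- aj
    sc$gain_cv <- scenario$repeat_gain_cv
    rec <- simulate_recording(sc, best, fly_id = fly_id, repeat_index = j,
                              seed = sub_seed(scenario$seed, 200000L + j))
    response_amplitude(bleach_correct(compute_dff(rec, cfg$baseline_frames),
                                      ref),
                       cfg$response_frames)
  }, numeric(1))
  longevity_series(amps, inter_trial_interval_s = 120)
}
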