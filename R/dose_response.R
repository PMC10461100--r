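#' Per-fly dose-response series
#'
#' @param doses Strictly increasing positive doses (micrograms of odorant
#'   on filter paper).
#' @param amplitudes Response amplitude (%) at each dose for one fly.
#' @param solvent_amplitude This fly's response to the solvent control.
#' @param fly_id Fly identifier.
#' @param normalized Whether the series is already on the 0--100 scale of
#'   [normalize_curve()].
#' @return A `dose_series`.
#' @export
dose_series <- function(doses, amplitudes, solvent_amplitude = 0,
                        fly_id = "fly1", normalized = FALSE) {
  doses <- as.numeric(doses); amplitudes <- as.numeric(amplitudes)
  if (length(doses) != length(amplitudes))
    stop("doses and amplitudes must have equal length")
  if (any(doses <= 0)) stop("doses must be positive (solvent is not a dose)")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  structure(list(doses = doses, amplitudes = amplitudes,
                 solvent_amplitude = as.numeric(solvent_amplitude),
                 fly_id = as.character(fly_id),
                 normalized = isTRUE(normalized)),
            class = "dose_series")
}

#' Normalize a dose-response series to a 0--100% scale
#'
#' Maps the fly's highest response (over all doses, not necessarily the top
#' dose) to 100% and the solvent response to 0%:
#' `100 * (value - solvent) / (max - solvent)`. Idempotent: a normalized
#' series normalizes to itself.
#'
#' @param series A `dose_series`.
#' @return The normalized `dose_series` (`solvent_amplitude` becomes 0).
#' @export
normalize_curve <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  mx <- max(series$amplitudes)
  s <- series$solvent_amplitude
  if (mx <= s)
    stop("non-responding fly ", series$fly_id,
         ": maximum response (", signif(mx, 4),
         ") does not exceed solvent (", signif(s, 4), ")")
  out <- series
  out$amplitudes <- 100 * (series$amplitudes - s) / (mx - s)
  out$solvent_amplitude <- 0
  out$normalized <- TRUE
  out
}

#' Fit a variable-slope Hill (four-parameter logistic) dose-response curve
#'
#' Least-squares fit of
#' \deqn{R(d) = bottom + \frac{top - bottom}{1 + (EC_{50}/d)^h}}
#' with the dose on its native microgram scale and the optimization
#' carried out over log10(EC50). This is the standard variable-slope
#' sigmoid of dose-response graphing software. The solvent point is not
#' part of the fit (log of zero dose is undefined); it enters only through
#' [normalize_curve()]. With normalized input the asymptotes may be fixed
#' at 0/100 via `fix_asymptotes`.
#'
#' Starting values: EC50 at the geometric mean of the doses, h = 1,
#' bottom/top at the observed extremes; bounded Levenberg-Marquardt within
#' EC50 in \[min dose/100, max dose x 100\] and h in \[0.05, 20\]. An EC50
#' outside \[min dose/10, max dose x 10\] is flagged `extrapolated`.
#'
#' @param series A `dose_series` (>= 4 distinct doses).
#' @param fix_asymptotes Fix bottom = 0 and top = 100 (normalized input).
#' @return A `hill_fit`: `ec50`, `log10_ec50`, `hill_slope`, `top`,
#'   `bottom`, `converged`, `extrapolated`, `rss`, `n`, `fly_id`.
#' @export
fit_hill <- function(series, fix_asymptotes = FALSE) {
  stopifnot(inherits(series, "dose_series"))
  d <- series$doses; y <- series$amplitudes
  if (length(unique(d)) < 4L) stop("need at least 4 distinct doses for a fit")
  if (!all(is.finite(y))) stop("non-finite response amplitudes")
  if (diff(range(y)) < 1e-9)
    stop("zero dynamic range: all responses equal (", signif(y[1], 4),
         "); nothing to fit")
  ld <- log10(d)
  lo_ec <- log10(min(d)) - 2; hi_ec <- log10(max(d)) + 2
  # start EC50 where the curve crosses midway between its extremes
  mid <- (min(y) + max(y)) / 2
  ord <- order(ld)
  cross <- which(diff(y[ord] >= mid) != 0)
  lec0 <- if (length(cross)) {
    i <- cross[1]
    stats::approx(y[ord][i:(i + 1)], ld[ord][i:(i + 1)], xout = mid,
                  ties = "ordered")$y
  } else mean(ld)
  if (!is.finite(lec0)) lec0 <- mean(ld)
  lower <- c(lec50 = lo_ec, h = 0.05)
  upper <- c(lec50 = hi_ec, h = 20)
  starts <- expand.grid(lec50 = unique(c(lec0, mean(ld))),
                        h = c(1, 0.5, 2, 4))
  if (fix_asymptotes) {
    model <- function(p) 100 / (1 + 10^(p[["h"]] * (p[["lec50"]] - ld)))
  } else {
    model <- function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["h"]] * (p[["lec50"]] - ld)))
    span <- diff(range(y))
    starts$bottom <- min(y); starts$top <- max(y)
    lower <- c(lower, bottom = min(y) - span, top = min(y))
    upper <- c(upper, bottom = max(y), top = max(y) + span)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = as.list(starts[s, ]),
      lower = lower, upper = upper,
      fn = function(p) y - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      silent = TRUE)
    if (inherits(fit, "try-error") || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("Hill fit did not converge for fly ", series$fly_id)
  p <- stats::coef(best)
  ec50 <- 10^p[["lec50"]]
  structure(list(
    ec50 = ec50, log10_ec50 = p[["lec50"]], hill_slope = p[["h"]],
    bottom = if (fix_asymptotes) 0 else p[["bottom"]],
    top = if (fix_asymptotes) 100 else p[["top"]],
    converged = TRUE,
    extrapolated = ec50 < min(d) / 10 || ec50 > max(d) * 10,
    rss = best$deviance, n = length(d),
    fly_id = series$fly_id),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit %s> EC50 = %.4g ug, h = %.3g, bottom = %.3g, top = %.3g%s\n",
    x$fly_id, x$ec50, x$hill_slope, x$bottom, x$top,
    if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Fit Hill curves fly by fly and summarize EC50 and slope
#'
#' Normalizes each fly's series (unless already normalized), fits each
#' fly separately and reports per-fly parameters plus mean +/- SEM
#' summaries, the form in which dose-response sensitivity is usually
#' reported. Non-responding flies (maximum not above solvent) and
#' non-converged fits are dropped with a warning.
#'
#' @param series_list List of `dose_series`, one per fly.
#' @param fix_asymptotes Passed to [fit_hill()]; default `TRUE` since
#'   fitting follows normalization.
#' @return A `hill_fit_set`: `fits` (data frame, one row per fly) and
#'   `summary` (mean, SEM, n for EC50, log10 EC50 and Hill slope).
#' @export
fit_hill_set <- function(series_list, fix_asymptotes = TRUE) {
  fits <- list()
  for (s in series_list) {
    f <- try({
      sn <- if (s$normalized) s else normalize_curve(s)
      fit_hill(sn, fix_asymptotes = fix_asymptotes)
    }, silent = TRUE)
    if (inherits(f, "try-error")) {
      warning("dropping fly ", s$fly_id, ": ",
              attr(f, "condition")$message, call. = FALSE)
    } else if (f$converged) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("no converged fit in the set")
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(fly_id = f$fly_id, ec50_ug = f$ec50,
               log10_ec50 = f$log10_ec50, hill_slope = f$hill_slope,
               top = f$top, bottom = f$bottom, converged = f$converged,
               extrapolated = f$extrapolated, rss = f$rss)))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(
    fits = df,
    summary = data.frame(
      parameter = c("ec50_ug", "log10_ec50", "hill_slope"),
      mean = c(mean(df$ec50_ug), mean(df$log10_ec50), mean(df$hill_slope)),
      sem = c(sem(df$ec50_ug), sem(df$log10_ec50), sem(df$hill_slope)),
      n = nrow(df))),
    class = "hill_fit_set")
}

#' @export
print.hill_fit_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<hill_fit_set> %d flies: EC50 = %.3g +/- %.2g ug, h = %.3g +/- %.2g\n",
              s$n[1], s$mean[s$parameter == "ec50_ug"],
              s$sem[s$parameter == "ec50_ug"],
              s$mean[s$parameter == "hill_slope"],
              s$sem[s$parameter == "hill_slope"]))
  invisible(x)
}

#' Fit one Hill curve to the pooled normalized points of all flies
#'
#' Alternative to per-fly fitting: every fly's normalized (dose,
#' response) points enter a single least-squares fit. More stable when
#' individual flies contribute few informative doses; gives no per-fly
#' dispersion.
#'
#' @param series_list List of `dose_series`.
#' @param fix_asymptotes Fix bottom = 0 / top = 100.
#' @return A single `hill_fit` (with `fly_id = "pooled"`).
#' @export
fit_hill_pooled <- function(series_list, fix_asymptotes = TRUE) {
  norm <- lapply(series_list, function(s)
    if (s$normalized) s else normalize_curve(s))
  d <- unlist(lapply(norm, `[[`, "doses"))
  y <- unlist(lapply(norm, `[[`, "amplitudes"))
  ord <- order(d)
  # collapse to a pseudo-series carrying replicate points per dose
  pooled <- structure(list(doses = d[ord], amplitudes = y[ord],
                           solvent_amplitude = 0, fly_id = "pooled",
                           normalized = TRUE),
                      class = "dose_series")
  fit_hill(pooled, fix_asymptotes = fix_asymptotes)
}

#' Descriptive comparison of two sets of dose-response fits
#'
#' Differences of mean log10 EC50 and mean Hill slope between two
#' modalities (e.g. calcium imaging vs single-sensillum recording), plus
#' optional per-dose normalized means +/- SEM for curve overlays. Purely
#' descriptive; no hypothesis test is performed.
#'
#' @param fits_a,fits_b `hill_fit_set` objects.
#' @param series_a,series_b Optional lists of normalized `dose_series`
#'   backing each set, for the per-dose summary.
#' @return List with `diff_log10_ec50` (a minus b), `diff_hill_slope`,
#'   and a `per_dose` data frame (or `NULL`).
#' @export
compare_curves <- function(fits_a, fits_b, series_a = NULL, series_b = NULL) {
  stopifnot(inherits(fits_a, "hill_fit_set"), inherits(fits_b, "hill_fit_set"))
  ms <- function(x, p) x$summary$mean[x$summary$parameter == p]
  per_dose <- NULL
  dose_tab <- function(sl, set) {
    if (is.null(sl)) return(NULL)
    long <- do.call(rbind, lapply(sl, function(s)
      data.frame(set = set, dose_ug = s$doses, value = s$amplitudes)))
    agg <- do.call(rbind, lapply(split(long, long$dose_ug), function(g)
      data.frame(set = set, dose_ug = g$dose_ug[1], mean = mean(g$value),
                 sem = stats::sd(g$value) / sqrt(nrow(g)), n = nrow(g))))
    agg
  }
  per_dose <- rbind(dose_tab(series_a, "a"), dose_tab(series_b, "b"))
  if (!is.null(per_dose)) rownames(per_dose) <- NULL
  list(diff_log10_ec50 = ms(fits_a, "log10_ec50") - ms(fits_b, "log10_ec50"),
       diff_hill_slope = ms(fits_a, "hill_slope") - ms(fits_b, "hill_slope"),
       per_dose = per_dose)
}

#' Extract per-fly dose series from a response matrix
#'
#' Pulls one odorant's dosed recordings out of the long table of a
#' [build_response_matrix()] result, pairing each fly's amplitudes with
#' its solvent-control amplitude.
#'
#' @param rm A `response_matrix` whose long table carries `dose_ug`.
#' @param odorant Stimulus label of the dosed odorant.
#' @param solvent Stimulus label of its solvent control.
#' @return List of `dose_series`, one per fly.
#' @export
dose_series_from_matrix <- function(rm, odorant, solvent) {
  stopifnot(inherits(rm, "response_matrix"))
  long <- rm$long
  if (!odorant %in% long$stimulus_id)
    stop("unknown stimulus referenced by dose table: ", odorant)
  if (!solvent %in% long$stimulus_id)
    stop("unknown solvent stimulus: ", solvent)
  od <- long[long$stimulus_id == odorant & !is.na(long$dose_ug), ]
  if (!nrow(od)) stop("no dosed recordings for ", odorant)
  lapply(split(od, od$fly_id), function(g) {
    g <- g[order(g$dose_ug), ]
    sv <- long$amplitude_pct[long$stimulus_id == solvent &
                             long$fly_id == g$fly_id[1]]
    if (!length(sv)) stop("no solvent recording for fly ", g$fly_id[1])
    dose_series(g$dose_ug, g$amplitude_pct, solvent_amplitude = mean(sv),
                fly_id = g$fly_id[1])
  })
}
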