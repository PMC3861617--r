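#' Compute the Fluo4/FuraRed ratio
#'
#' @param fluo4,furared Equal-length intensity vectors; `furared` must be
#'   strictly positive.
#' @return The element-wise ratio.
#' @export
compute_ratio <- function(fluo4, furared) {
  if (length(fluo4) != length(furared)) {
    abort("channel lengths differ", class = "wntwave_input_error")
  }
  if (any(!is.finite(furared)) || any(furared <= 0)) {
    abort("FuraRed channel must be strictly positive",
          class = "wntwave_degenerate_channel_error")
  }
  fluo4 / furared
}

# Accept a ratio_trace tibble or any data frame with time_s + ratio
# (or fluo4/furared from which the ratio is computed).
as_trace <- function(trace) {
  trace <- as_tibble(trace)
  if (!"time_s" %in% names(trace)) {
    abort("trace needs a time_s column", class = "wntwave_input_error")
  }
  if (!"ratio" %in% names(trace)) {
    if (!all(c("fluo4", "furared") %in% names(trace))) {
      abort("trace needs ratio or fluo4 + furared columns",
            class = "wntwave_input_error")
    }
    trace$ratio <- compute_ratio(trace$fluo4, trace$furared)
  }
  trace
}

#' Fit a single Gaussian to a ratio trace
#'
#' Least-squares fit of `y0 + A * exp(-(t - t0)^2 / (2 sigma^2))` to the
#' measured ratio. Initialisation: `y0` = median of the first 10% of samples,
#' `A` = max - y0, `t0` = argmax, `sigma` = FWHM/2.355 with the FWHM measured
#' at half of `A`. The optimizer never raises on failure; `converged = FALSE`
#' is returned instead.
#'
#' @param trace Data frame with `time_s` and `ratio` (or `fluo4`/`furared`).
#' @return An object of class `gaussian_fit` with elements `y0`, `A`, `t0`,
#'   `sigma`, `rss`, `converged`, `note`, `n`. Use [tidy()] / [glance()].
#' @examples
#' tr <- simulate_trace(transient_params(amplitude = 1.5, sigma = 20), seed = 1)
#' glance(fit_gaussian(tr))
#' @export
fit_gaussian <- function(trace) {
  trace <- as_trace(trace)
  t <- trace$time_s
  y <- trace$ratio
  n <- length(y)
  if (n < 10) {
    abort("trace too short for a Gaussian fit (need >= 10 samples)",
          class = "wntwave_input_error")
  }
  y0_init <- median(y[seq_len(max(1, floor(0.1 * n)))])
  a_init <- max(y) - y0_init
  span <- diff(range(t))
  if (a_init <= 1e-6 || diff(range(y)) <= 1e-6) {
    # flat trace: the Gaussian amplitude is zero and sigma is unidentifiable
    return(new_gaussian_fit(y0 = mean(y), A = 0, t0 = t[which.max(y)],
                            sigma = span / 4, rss = sum((y - mean(y))^2),
                            converged = TRUE, note = "degenerate_flat", n = n))
  }
  t0_init <- t[which.max(y)]
  above_half <- which(y >= y0_init + a_init / 2)
  fwhm <- max(diff(range(t[above_half])), 2 * (t[2] - t[1]))
  sigma_init <- fwhm / 2.355
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + A * exp(-(t - t0)^2 / (2 * sigma^2)),
      data = dat,
      start = list(y0 = y0_init, A = a_init, t0 = t0_init, sigma = sigma_init),
      lower = c(y0 = -Inf, A = 0, t0 = min(t) - span, sigma = 1e-9),
      upper = c(y0 = Inf, A = Inf, t0 = max(t) + span, sigma = span),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-14, ptol = 1e-14
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_gaussian_fit(y0 = y0_init, A = a_init, t0 = t0_init,
                            sigma = sigma_init, rss = NA_real_,
                            converged = FALSE, note = conditionMessage(fit),
                            n = n))
  }
  cf <- coef(fit)
  new_gaussian_fit(y0 = unname(cf["y0"]), A = unname(cf["A"]),
                   t0 = unname(cf["t0"]), sigma = unname(cf["sigma"]),
                   rss = deviance(fit), converged = TRUE, note = "", n = n)
}

new_gaussian_fit <- function(y0, A, t0, sigma, rss, converged, note, n) {
  structure(
    list(y0 = y0, A = A, t0 = t0, sigma = sigma, rss = rss,
         converged = converged, note = note, n = n),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Single-Gaussian fit: y0 = %.4g, A = %.4g, t0 = %.4g s, sigma = %.4g s (%s)\n",
    x$y0, x$A, x$t0, x$sigma,
    if (x$converged) "converged" else paste0("NOT converged: ", x$note)
  ))
  invisible(x)
}

# Locate a crossing of `level` on sampled data. Brackets on the measured
# samples; refines inside the bracket with a local cubic spline (default) or
# linear interpolation. Returns NA when no such crossing exists.
crossing_time <- function(time, y, level, direction = c("up", "down"),
                          which = c("first", "last"),
                          interp = c("cubic", "linear")) {
  direction <- match.arg(direction)
  which <- match.arg(which)
  interp <- match.arg(interp)
  d <- y - level
  n <- length(y)
  i1 <- d[-n]
  i2 <- d[-1]
  idx <- if (direction == "up") {
    which(i1 < 0 & i2 >= 0)
  } else {
    which(i1 >= 0 & i2 < 0)
  }
  if (length(idx) == 0) return(NA_real_)
  i <- if (which == "first") idx[1] else idx[length(idx)]
  if (d[i] == 0) return(time[i])
  if (interp == "linear") {
    return(time[i] + (level - y[i]) * (time[i + 1] - time[i]) / (y[i + 1] - y[i]))
  }
  win <- max(1, i - 3):min(n, i + 4)
  f <- splinefun(time[win], y[win], method = "fmm")
  root <- tryCatch(
    uniroot(function(tt) f(tt) - level,
            lower = time[i], upper = time[i + 1], tol = 1e-10)$root,
    error = function(e) NA_real_
  )
  if (is.na(root)) {
    time[i] + (level - y[i]) * (time[i + 1] - time[i]) / (y[i + 1] - y[i])
  } else {
    root
  }
}

# Robust noise SD of the pre-stimulus (first `fraction`) segment plus an
# absolute floor, used as the "no response" detection threshold (x5).
detection_threshold <- function(y, fraction = 0.1, floor = 0.05) {
  m <- max(2, ceiling(fraction * length(y)))
  max(5 * mad(y[seq_len(m)]), floor)
}

no_transient_row <- function(flag) {
  tibble(
    amplitude = NA_real_, rise_s = NA_real_, dwell_s = NA_real_,
    fall_s = NA_real_, t_lower_up = NA_real_, t_upper_up = NA_real_,
    t_upper_down = NA_real_, t_lower_down = NA_real_, flag = flag
  )
}

#' Extract rise, dwell and fall time constants by 10%/90% thresholding
#'
#' Threshold levels are `y0 + f * A` for the lower (default 10%) and upper
#' (default 90%) fractions of the fitted amplitude; crossing times are
#' located on the measured ratio. Rise = first upper up-crossing minus first
#' lower up-crossing; dwell = time sustained at peak amplitude (last upper
#' down-crossing minus first upper up-crossing); fall = last lower
#' down-crossing minus last upper down-crossing. The reported amplitude is
#' the peak of the waveform, `max(ratio) - y0`.
#'
#' Traces whose fitted amplitude falls below the detection threshold
#' (5 x the robust noise SD of the pre-stimulus segment, with an absolute
#' floor of 0.05 ratio units) are flagged `no_transient` rather than timed.
#'
#' @param trace Data frame with `time_s` and `ratio` (or the two channels).
#' @param fit A [fit_gaussian()] result for the same trace (fitted if omitted).
#' @param lower,upper Threshold fractions of the fitted amplitude.
#' @param interp Crossing refinement: `"cubic"` (local spline, default) or
#'   `"linear"`.
#' @param min_amplitude Detection threshold override (ratio units).
#' @return A one-row tibble: `amplitude`, `rise_s`, `dwell_s`, `fall_s`, the
#'   four crossing times, and `flag` (`"ok"`, `"no_transient"`,
#'   `"multi_peak"`, `"incomplete_crossings"`, `"fit_failed"`).
#' @examples
#' tr <- simulate_trace(transient_params(amplitude = 1.5, sigma = 20), seed = 1)
#' extract_time_constants(tr)
#' @export
extract_time_constants <- function(trace, fit = NULL, lower = 0.10,
                                   upper = 0.90, interp = c("cubic", "linear"),
                                   min_amplitude = NULL) {
  interp <- match.arg(interp)
  trace <- as_trace(trace)
  if (is.null(fit)) fit <- fit_gaussian(trace)
  if (!fit$converged) return(no_transient_row("fit_failed"))
  thr <- min_amplitude %||% detection_threshold(trace$ratio)
  if (fit$A < thr) return(no_transient_row("no_transient"))

  t <- trace$time_s
  y <- trace$ratio
  lo <- fit$y0 + lower * fit$A
  hi <- fit$y0 + upper * fit$A
  flag <- "ok"
  runs <- rle(y > hi)
  if (sum(runs$values) > 1) flag <- "multi_peak"

  t_lo_up <- crossing_time(t, y, lo, "up", "first", interp)
  t_hi_up <- crossing_time(t, y, hi, "up", "first", interp)
  t_hi_dn <- crossing_time(t, y, hi, "down", "last", interp)
  t_lo_dn <- crossing_time(t, y, lo, "down", "last", interp)
  xs <- c(t_lo_up, t_hi_up, t_hi_dn, t_lo_dn)
  if (anyNA(xs)) {
    out <- no_transient_row("incomplete_crossings")
    out$amplitude <- max(y) - fit$y0
    out[, c("t_lower_up", "t_upper_up", "t_upper_down", "t_lower_down")] <-
      as.list(xs)
    return(out)
  }
  tibble(
    amplitude = max(y) - fit$y0,
    rise_s = t_hi_up - t_lo_up,
    dwell_s = t_hi_dn - t_hi_up,
    fall_s = t_lo_dn - t_hi_dn,
    t_lower_up = t_lo_up, t_upper_up = t_hi_up,
    t_upper_down = t_hi_dn, t_lower_down = t_lo_dn,
    flag = flag
  )
}

#' Detect transient onset
#'
#' Onset is the first up-crossing of `y0 + fraction * A` (default 10% of the
#' fitted amplitude) on the measured ratio.
#'
#' @inheritParams extract_time_constants
#' @param fraction Threshold fraction of the fitted amplitude.
#' @return A one-row tibble: `onset_s`, `detected`.
#' @export
detect_onset <- function(trace, fit = NULL, fraction = 0.10,
                         interp = c("cubic", "linear"), min_amplitude = NULL) {
  interp <- match.arg(interp)
  trace <- as_trace(trace)
  if (is.null(fit)) fit <- fit_gaussian(trace)
  thr <- min_amplitude %||% detection_threshold(trace$ratio)
  if (!fit$converged || fit$A < thr) {
    return(tibble(onset_s = NA_real_, detected = FALSE))
  }
  level <- fit$y0 + fraction * fit$A
  x <- crossing_time(trace$time_s, trace$ratio, level, "up", "first", interp)
  tibble(onset_s = x, detected = !is.na(x))
}

#' Lag between cytosolic and intranuclear calcium onsets
#'
#' @param cytosolic,nuclear Ratio traces (data frames with `time_s`, `ratio`
#'   or the two channels).
#' @inheritParams detect_onset
#' @return A one-row tibble: `lag_s` (nuclear onset minus cytosolic onset;
#'   negative when the nuclear signal leads), `cytosolic_onset_s`,
#'   `nuclear_onset_s`, `detected`.
#' @export
onset_lag <- function(cytosolic, nuclear, fraction = 0.10,
                      interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  oc <- detect_onset(cytosolic, fraction = fraction, interp = interp)
  on <- detect_onset(nuclear, fraction = fraction, interp = interp)
  tibble(
    lag_s = if (oc$detected && on$detected) on$onset_s - oc$onset_s else NA_real_,
    cytosolic_onset_s = oc$onset_s,
    nuclear_onset_s = on$onset_s,
    detected = oc$detected && on$detected
  )
}

#' Estimate calcium wave-front speed from onset times
#'
#' Ordinary least squares of onset time on distance from the ligand entry
#' point; the front speed is the reciprocal slope, with its standard error
#' propagated by the delta method (`se(speed) = se(slope) / slope^2`).
#'
#' @param onsets Data frame with columns `distance_um` and `onset_s`
#'   (e.g. from [dish_onsets()]).
#' @return A one-row tibble: `speed_um_s`, `speed_se`, `slope_s_per_um`,
#'   `slope_se`, `r_squared`, `n`.
#' @export
estimate_front_speed <- function(onsets) {
  onsets <- as_tibble(onsets)
  d <- onsets$distance_um
  o <- onsets$onset_s
  if (length(unique(d)) < 2) {
    abort("need >= 2 distinct distances", class = "wntwave_input_error")
  }
  fit <- ols_fit(d, o)
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    abort("onset does not increase with distance: no propagating front",
          class = "wntwave_front_error")
  }
  tibble(
    speed_um_s = 1 / fit$slope,
    speed_se = fit$slope_se / fit$slope^2,
    slope_s_per_um = fit$slope,
    slope_se = fit$slope_se,
    r_squared = fit$r_squared,
    n = fit$n
  )
}

#' Per-ROI onsets from a multi-ROI dish table
#'
#' @param traces Wide trace table from [simulate_dish()] (or read with
#'   [read_trace_tsv()]): `time_s` plus `<roi>_fluo4` / `<roi>_furared`.
#' @param roi_info Tibble with `roi` and `distance_um`; defaults to the
#'   table's `"roi_info"` attribute.
#' @inheritParams detect_onset
#' @return Tibble: `roi`, `distance_um`, `onset_s`, `detected`.
#' @export
dish_onsets <- function(traces, roi_info = attr(traces, "roi_info"),
                        fraction = 0.10, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  if (is.null(roi_info)) {
    abort("roi_info with ROI distances is required", class = "wntwave_input_error")
  }
  purrr::map_dfr(seq_len(nrow(roi_info)), function(i) {
    tr <- extract_roi_trace(traces, roi_info$roi[i])
    on <- detect_onset(tr, fraction = fraction, interp = interp)
    tibble(roi = roi_info$roi[i], distance_um = roi_info$distance_um[i],
           onset_s = on$onset_s, detected = on$detected)
  })
}

#' Time for a trace to return to baseline after a stimulus
#'
#' Baseline is the mean pre-stimulus ratio; return is the first time after
#' the post-stimulus peak at which the ratio stays within `tol` (relative)
#' of baseline for at least `min_samples` consecutive samples.
#'
#' @param trace A ratio trace.
#' @param stimulus_time Stimulus addition time, s (defaults to the trace's
#'   `"stimulus_time"` attribute).
#' @param tol Relative tolerance around baseline (default 0.05).
#' @param min_samples Consecutive in-tolerance samples required (default 3).
#' @return One-row tibble: `return_s` (elapsed from stimulus onset),
#'   `baseline`, `detected`.
#' @export
baseline_return_time <- function(trace, stimulus_time = attr(trace, "stimulus_time"),
                                 tol = 0.05, min_samples = 3) {
  trace <- as_trace(trace)
  if (is.null(stimulus_time)) {
    abort("stimulus_time is required", class = "wntwave_input_error")
  }
  pre <- trace$ratio[trace$time_s < stimulus_time]
  if (length(pre) < 2) {
    abort("no pre-stimulus segment", class = "wntwave_input_error")
  }
  y0 <- mean(pre)
  post <- which(trace$time_s >= stimulus_time)
  peak <- post[which.max(trace$ratio[post])]
  within <- abs(trace$ratio - y0) <= tol * y0
  n <- nrow(trace)
  for (i in seq(peak, n - min_samples + 1)) {
    if (all(within[i:(i + min_samples - 1)])) {
      return(tibble(return_s = trace$time_s[i] - stimulus_time,
                    baseline = y0, detected = TRUE))
    }
  }
  tibble(return_s = NA_real_, baseline = y0, detected = FALSE)
}

#' Per-ROI waveform kinetics for a multi-ROI trace table
#'
#' Runs the full kinetics pipeline (ratio, Gaussian fit, 10%/90%
#' thresholding) on every ROI of a wide trace table.
#'
#' @inheritParams dish_onsets
#' @inheritParams extract_time_constants
#' @return Tibble with one row per ROI: `roi`, fit parameters (`y0`, `A`,
#'   `t0`, `sigma`, `rss`, `converged`), `amplitude`, `rise_s`, `dwell_s`,
#'   `fall_s`, `flag`.
#' @export
trace_kinetics <- function(traces, lower = 0.10, upper = 0.90,
                           interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  traces <- as_tibble(traces)
  rois <- unique(sub("_(fluo4|furared)$", "",
                     grep("_(fluo4|furared)$", names(traces), value = TRUE)))
  if (length(rois) == 0) {
    abort("no <roi>_fluo4 / <roi>_furared columns found",
          class = "wntwave_input_error")
  }
  purrr::map_dfr(rois, function(roi) {
    tr <- extract_roi_trace(traces, roi)
    fit <- fit_gaussian(tr)
    tc <- extract_time_constants(tr, fit, lower = lower, upper = upper,
                                 interp = interp)
    dplyr::bind_cols(
      tibble(roi = roi, y0 = fit$y0, A = fit$A, t0 = fit$t0,
             sigma = fit$sigma, rss = fit$rss, converged = fit$converged),
      tc[, c("amplitude", "rise_s", "dwell_s", "fall_s", "flag")]
    )
  })
}
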