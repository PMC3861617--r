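# Asymmetric Gaussian bump: unit peak, rising width sigma, falling width sigma*(1+a)
transient_shape <- function(t, center, sigma, asymmetry = 0) {
  w <- ifelse(t <= center, sigma, sigma * (1 + asymmetry))
  exp(-((t - center)^2) / (2 * w^2))
}

# Split a designed ratio curve into two channels whose quotient is the curve:
# fluo4 rises as sqrt(r/baseline), furared falls reciprocally.
ratio_to_channels <- function(ratio_true, baseline, fluo4_baseline = 1000) {
  q <- sqrt(ratio_true / baseline)
  list(fluo4 = fluo4_baseline * q, furared = (fluo4_baseline / baseline) / q)
}

#' Simulate a single-ROI ratiometric calcium transient
#'
#' Generates a Fluo4-like channel that rises with the transient, a
#' FuraRed-like channel that decreases reciprocally, and their per-sample
#' ratio. The noiseless ratio is exactly
#' `baseline + amplitude * exp(-(t - center)^2 / (2 w^2))` with rising-limb
#' width `sigma` and falling-limb width `sigma * (1 + asymmetry)`. Channel
#' noise is additive Gaussian, scaled per sample so the first-order noise SD
#' of the ratio equals `noise_sd`.
#'
#' @param params A [transient_params()] object.
#' @param seed Integer seed; the trace is reproducible given `(params, seed)`.
#' @return A `ratio_trace` tibble with columns `time_s`, `fluo4`, `furared`,
#'   `ratio`.
#' @examples
#' tr <- simulate_trace(transient_params(amplitude = 1.5, noise_sd = 0), seed = 1)
#' tr[which.max(tr$ratio), ]
#' @export
simulate_trace <- function(params, seed = 1) {
  if (!inherits(params, "transient_params")) {
    params <- do.call(transient_params, params)
  }
  time_s <- seq(0, params$duration, by = params$sample_interval)
  r_true <- params$baseline +
    params$amplitude * transient_shape(time_s, params$center_time,
                                       params$sigma, params$asymmetry)
  channels_from_design(time_s, r_true, params$baseline, params$noise_sd, seed)
}

channels_from_design <- function(time_s, r_true, baseline, noise_sd, seed) {
  ch <- ratio_to_channels(r_true, baseline)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      n <- length(time_s)
      list(f = rnorm(n), r = rnorm(n))
    })
    sd_f <- noise_sd * ch$furared / sqrt(2)
    sd_r <- noise_sd * ch$furared / (sqrt(2) * r_true)
    ch$fluo4 <- ch$fluo4 + sd_f * noise$f
    ch$furared <- pmax(ch$furared + sd_r * noise$r, 1e-6)
  }
  new_ratio_trace(time_s, ch$fluo4, ch$furared)
}

new_ratio_trace <- function(time_s, fluo4, furared) {
  out <- tibble(
    time_s = time_s, fluo4 = fluo4, furared = furared,
    ratio = compute_ratio(fluo4, furared)
  )
  class(out) <- c("ratio_trace", class(out))
  out
}

#' Dish geometry for wave-front simulations
#'
#' Describes ROI positions on the dish, the point where the ligand is added,
#' and the speed of the propagating calcium wave front. Each ROI's transient
#' onset is delayed by `distance / front_speed`.
#'
#' @param roi_positions Data frame with columns `x`, `y` (micrometres), one
#'   row per ROI; an optional `roi` column names the ROIs.
#' @param entry_point Numeric length-2, the ligand entry point (micrometres).
#' @param front_speed Wave-front speed, micrometres per second (default 23.3,
#'   the measured dish diffusion constant used throughout the package).
#' @return A list of class `dish_layout` with an `roi_info` tibble
#'   (`roi`, `distance_um`, `delay_s`).
#' @export
dish_layout <- function(roi_positions, entry_point = c(0, 0), front_speed = 23.3) {
  roi_positions <- as_tibble(roi_positions)
  if (!all(c("x", "y") %in% names(roi_positions)) || nrow(roi_positions) < 1) {
    abort("roi_positions needs columns x, y and at least one row",
          class = "wntwave_parameter_error")
  }
  if (!is.finite(front_speed) || front_speed <= 0) {
    abort("front_speed must be positive", class = "wntwave_parameter_error")
  }
  roi <- if ("roi" %in% names(roi_positions)) {
    roi_positions$roi
  } else {
    sprintf("roi%02d", seq_len(nrow(roi_positions)))
  }
  d <- sqrt((roi_positions$x - entry_point[1])^2 +
            (roi_positions$y - entry_point[2])^2)
  structure(
    list(
      roi_info = tibble(roi = roi, distance_um = d, delay_s = d / front_speed),
      entry_point = entry_point,
      front_speed = front_speed
    ),
    class = "dish_layout"
  )
}

#' Simulate a multi-ROI dish recording with a propagating wave front
#'
#' Each ROI receives the same transient, time-shifted by its distance from
#' the ligand entry point divided by the front speed.
#'
#' @param layout A [dish_layout()].
#' @param per_roi A [transient_params()] object shared by all ROIs; its
#'   `center_time` is the transient centre at the entry point.
#' @param seed Integer seed (per-ROI noise streams are derived from it).
#' @return A wide tibble, tab-delimited-export ready: `time_s`, then
#'   `<roi>_fluo4` and `<roi>_furared` per ROI. The layout's `roi_info` is
#'   attached as attribute `"roi_info"`.
#' @export
simulate_dish <- function(layout, per_roi, seed = 1) {
  stopifnot(inherits(layout, "dish_layout"))
  info <- layout$roi_info
  cols <- purrr::imap(
    setNames(info$delay_s, info$roi),
    function(delay, roi) {
      p <- per_roi
      p$center_time <- p$center_time + delay
      if (p$duration <= p$center_time) {
        p$duration <- p$center_time + 4 * p$sigma
      }
      tr <- simulate_trace(p, seed = seed + match(roi, info$roi))
      setNames(list(tr$fluo4, tr$furared),
               paste0(roi, c("_fluo4", "_furared")))
    }
  )
  time_s <- seq(0, per_roi$duration, by = per_roi$sample_interval)
  n <- length(time_s)
  flat <- unlist(unname(cols), recursive = FALSE)
  flat <- purrr::map(flat, function(x) x[seq_len(n)])
  out <- dplyr::bind_cols(tibble(time_s = time_s), as_tibble(flat))
  attr(out, "roi_info") <- info
  out
}

#' Simulate the thapsigargin control recording
#'
#' Emulates SERCA-pump inhibition: thapsigargin itself evokes one store-release
#' transient whose ratio declines back to baseline within 120 s of stimulus
#' onset, after which the stores are depleted and a subsequent Wnt addition
#' evokes no transient.
#'
#' @param seed Integer seed.
#' @param noise_sd Channel noise in ratio units (default 0).
#' @return A `ratio_trace` tibble with attributes `stimulus_time` (s, when
#'   thapsigargin is added) and `wnt_time` (s, when Wnt is subsequently added).
#' @export
simulate_thapsigargin_trace <- function(seed = 1, noise_sd = 0) {
  p <- transient_params(
    baseline = 1.0, amplitude = 0.8, center_time = 100, sigma = 15,
    noise_sd = noise_sd, sample_interval = 1.1, duration = 400,
    asymmetry = 0.3
  )
  stimulus_time <- 60
  time_s <- seq(0, p$duration, by = p$sample_interval)
  shape <- transient_shape(time_s, p$center_time, p$sigma, p$asymmetry)
  shape[time_s < stimulus_time] <- 0 # no release before the addition
  r_true <- p$baseline + p$amplitude * shape
  tr <- channels_from_design(time_s, r_true, p$baseline, p$noise_sd, seed)
  attr(tr, "stimulus_time") <- stimulus_time
  attr(tr, "wnt_time") <- 250
  attr(tr, "params") <- p
  tr
}
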