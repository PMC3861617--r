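#' Ligand presets for the synthetic study
#'
#' The package ships a versioned preset file describing, for each Wnt ligand,
#' the kinetic class of its calcium transient (short / long / very long / none),
#' the transient amplitude and falling-limb asymmetry, and its dwell-time
#' dose-response model: negative cooperativity (first-order decay
#' \eqn{y_0 + A_1 e^{-C/t_1}}), Michaelis-Menten
#' (\eqn{DT_{max} C / (K_{1/2} + C)} with \eqn{K_{1/2}} = 67 ng/ml for Wnt5A),
#' or flat. Wnt11 and vehicle evoke no transient.
#'
#' The Gaussian width of each responding preset is derived from its
#' dose-response curve evaluated at the reference concentration (100 ng/ml),
#' so that the noiseless dwell time extracted by the 10%/90% thresholding
#' pipeline equals the curve value there and lands inside the ligand's class
#' interval by construction.
#'
#' @return A tibble with one row per ligand: `ligand`, `kinetic_class`,
#'   `amplitude`, `asymmetry`, `sigma` (Gaussian width, s), `dwell_ref_s`
#'   (noiseless dwell at the reference concentration), `dose_mode`, and a
#'   list-column `dose_params`.
#' @examples
#' ligand_presets()
#' @export
ligand_presets <- function() {
  raw <- preset_data()
  cref <- raw$reference_concentration_ng_ml
  purrr::map_dfr(raw$ligands, function(lg) {
    dp <- lg$dose_response
    dwell_ref <- dose_response_value(dp, cref)
    sigma <- if (lg$amplitude > 0) {
      # dwell of an asymmetric Gaussian at the 90% level:
      # sigma * sqrt(2 log(10/9)) * (1 + (1 + asymmetry))
      dwell_ref / (gauss_u(0.9) * (2 + lg$asymmetry))
    } else {
      NA_real_
    }
    tibble(
      ligand = lg$name,
      kinetic_class = lg$kinetic_class,
      amplitude = lg$amplitude,
      asymmetry = lg$asymmetry,
      sigma = sigma,
      dwell_ref_s = if (lg$amplitude > 0) dwell_ref else NA_real_,
      dose_mode = dp$mode,
      dose_params = list(dp[setdiff(names(dp), "mode")])
    )
  })
}

preset_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ligand_presets.json", package = "wntwave")
      cache <<- jsonlite::fromJSON(path, simplifyVector = FALSE)
    }
    cache
  }
})

#' Evaluate a dose-response model
#'
#' @param dose_params List with a `mode` element (`"negative_cooperative"`,
#'   `"michaelis_menten"` or `"flat"`) and the matching parameters
#'   (`y0`, `A1`, `t1`; `dt_max`, `k_half`; or `dt`).
#' @param concentration Ligand concentration(s), ng/ml.
#' @return Dwell time(s), s.
#' @export
dose_response_value <- function(dose_params, concentration) {
  mode <- dose_params$mode
  switch(mode,
    negative_cooperative =
      dose_params$y0 + dose_params$A1 * exp(-concentration / dose_params$t1),
    michaelis_menten =
      dose_params$dt_max * concentration / (dose_params$k_half + concentration),
    flat = rep(dose_params$dt, length(concentration)),
    abort(paste0("unknown dose-response mode: ", mode), class = "wntwave_parameter_error")
  )
}

#' Transient generation parameters
#'
#' Bundle of parameters describing one ratiometric calcium transient: a
#' baseline ratio, a Gaussian bump of given amplitude, centre and width, an
#' asymmetry factor stretching the falling limb, channel noise, and the
#' sampling grid (images are acquired every 1.1 or 2.2 s for up to 600-800 s).
#'
#' @param baseline Baseline Fluo4/FuraRed ratio (dimensionless).
#' @param amplitude Peak ratio above baseline; 0 means no transient.
#' @param center_time Centre of the Gaussian, s.
#' @param sigma Gaussian width of the rising limb, s.
#' @param noise_sd Noise SD in ratio units (additive Gaussian on channels).
#' @param sample_interval Sampling interval, s (default 1.1).
#' @param duration Trace duration, s (default 600).
#' @param asymmetry Non-negative factor; the falling-limb width is
#'   `sigma * (1 + asymmetry)`. 0 gives a pure Gaussian.
#' @return A list of class `transient_params`.
#' @export
transient_params <- function(baseline = 1.0, amplitude = 1.0, center_time = 200,
                             sigma = 20, noise_sd = 0, sample_interval = 1.1,
                             duration = 600, asymmetry = 0) {
  p <- list(
    baseline = baseline, amplitude = amplitude, center_time = center_time,
    sigma = sigma, noise_sd = noise_sd, sample_interval = sample_interval,
    duration = duration, asymmetry = asymmetry
  )
  ok <- is.finite(baseline) && baseline > 0 &&
    is.finite(amplitude) && amplitude >= 0 &&
    is.finite(sigma) && sigma > 0 &&
    is.finite(sample_interval) && sample_interval > 0 &&
    is.finite(duration) && duration > center_time &&
    is.finite(noise_sd) && noise_sd >= 0 &&
    is.finite(asymmetry) && asymmetry >= 0
  if (!ok) {
    abort("invalid transient parameters", class = "wntwave_parameter_error")
  }
  structure(p, class = "transient_params")
}

#' Transient parameters for a named ligand preset
#'
#' @param ligand Preset name (e.g. `"Wnt5A"`, `"Wnt11"`, `"vehicle"`).
#' @param concentration Concentration, ng/ml; the preset's dose-response
#'   curve at this concentration sets the Gaussian width (default 100, the
#'   reference concentration).
#' @param noise_sd Channel noise in ratio units (default: preset file value).
#' @inheritParams transient_params
#' @return A `transient_params` object (amplitude 0 for non-responders).
#' @export
preset_transient_params <- function(ligand, concentration = 100, noise_sd = NULL,
                                    sample_interval = NULL, duration = NULL) {
  raw <- preset_data()
  defs <- raw$trace_defaults
  presets <- ligand_presets()
  row <- presets[presets$ligand == ligand, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown ligand preset: ", ligand), class = "wntwave_parameter_error")
  }
  if (row$amplitude > 0) {
    dp <- c(list(mode = row$dose_mode), row$dose_params[[1]])
    dwell <- dose_response_value(dp, concentration)
    sigma <- dwell / (gauss_u(0.9) * (2 + row$asymmetry))
  } else {
    sigma <- 20 # unused: amplitude 0 generates a flat trace
  }
  transient_params(
    baseline = defs$baseline,
    amplitude = row$amplitude,
    center_time = defs$center_time,
    sigma = sigma,
    noise_sd = noise_sd %||% defs$noise_sd,
    sample_interval = sample_interval %||% defs$sample_interval,
    duration = duration %||% defs$duration,
    asymmetry = row$asymmetry
  )
}
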