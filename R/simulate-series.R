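#' Simulate replicate dwell times across a concentration series
#'
#' Draws dwell times around the ligand preset's dose-response curve
#' (negative-cooperative first-order decay, Michaelis-Menten, or flat) with
#' multiplicative log-normal noise, emulating repeated kinetic measurements
#' at increasing ligand concentration.
#'
#' @param ligand Ligand preset name (see [ligand_presets()]).
#' @param concentrations Positive concentrations, ng/ml, ascending.
#' @param replicates Replicates per concentration.
#' @param noise_fraction Multiplicative noise fraction (SD of log dwell).
#' @param seed Integer seed.
#' @return Tibble: `ligand`, `concentration_ng_ml`, `replicate`, `dwell_s`.
#' @examples
#' simulate_concentration_series("Wnt5A", c(30, 100, 300), replicates = 3,
#'                               noise_fraction = 0, seed = 1)
#' @export
simulate_concentration_series <- function(ligand, concentrations = c(30, 100, 300),
                                          replicates = 10, noise_fraction = 0.05,
                                          seed = 1) {
  if (any(concentrations <= 0) || is.unsorted(concentrations)) {
    abort("concentrations must be positive and ascending",
          class = "wntwave_parameter_error")
  }
  presets <- ligand_presets()
  row <- presets[presets$ligand == ligand, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown ligand preset: ", ligand),
          class = "wntwave_parameter_error")
  }
  dp <- c(list(mode = row$dose_mode), row$dose_params[[1]])
  mu <- dose_response_value(dp, concentrations)
  grid <- tidyr::expand_grid(
    concentration_ng_ml = concentrations,
    replicate = seq_len(replicates)
  )
  mu_rep <- rep(mu, each = replicates)
  eps <- if (noise_fraction > 0) {
    withr::with_seed(seed, rnorm(nrow(grid), sd = noise_fraction))
  } else {
    rep(0, nrow(grid))
  }
  tibble(
    ligand = ligand,
    concentration_ng_ml = grid$concentration_ng_ml,
    replicate = grid$replicate,
    dwell_s = mu_rep * exp(eps)
  )
}

#' Wound-closure simulation parameters
#'
#' @param initial_width Initial wound width, micrometres.
#' @param closure_rate True closure rate (slope magnitude), micrometres/hour.
#' @param sample_interval Imaging interval, hours (default 2).
#' @param duration Total follow-up, hours.
#' @param noise_sd Measurement noise SD, micrometres.
#' @return A list of class `wound_params`.
#' @export
wound_params <- function(initial_width = 500, closure_rate = 10,
                         sample_interval = 2, duration = 24, noise_sd = 5) {
  ok <- initial_width > 0 && closure_rate >= 0 && sample_interval > 0 &&
    duration > 0 && noise_sd >= 0
  if (!ok) abort("invalid wound parameters", class = "wntwave_parameter_error")
  structure(
    list(initial_width = initial_width, closure_rate = closure_rate,
         sample_interval = sample_interval, duration = duration,
         noise_sd = noise_sd),
    class = "wound_params"
  )
}

#' Simulate scratch-wound width time courses
#'
#' Width follows `max(0, initial_width - rate * t)` plus Gaussian noise,
#' sampled every `sample_interval` hours, one series per condition.
#'
#' @param params A [wound_params()] object; its `closure_rate` is used when
#'   `condition_rates` is `NULL`.
#' @param condition_rates Named numeric vector of closure rates
#'   (micrometres/hour), one series per element.
#' @param seed Integer seed.
#' @return Tibble: `condition`, `time_h`, `width_um`.
#' @export
simulate_wound_series <- function(params = wound_params(),
                                  condition_rates = NULL, seed = 1) {
  stopifnot(inherits(params, "wound_params"))
  if (is.null(condition_rates)) {
    condition_rates <- c(default = params$closure_rate)
  }
  if (is.null(names(condition_rates))) {
    names(condition_rates) <- paste0("condition", seq_along(condition_rates))
  }
  time_h <- seq(0, params$duration, by = params$sample_interval)
  purrr::imap_dfr(condition_rates, function(rate, cond) {
    noise <- if (params$noise_sd > 0) {
      withr::with_seed(seed + match(cond, names(condition_rates)),
                       rnorm(length(time_h), sd = params$noise_sd))
    } else {
      rep(0, length(time_h))
    }
    tibble(
      condition = cond,
      time_h = time_h,
      width_um = pmax(0, params$initial_width - rate * time_h) + noise
    )
  })
}
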