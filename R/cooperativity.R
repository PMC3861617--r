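series_means <- function(series, response = "dwell_s") {
  series <- as_tibble(series)
  if (!all(c("concentration_ng_ml", response) %in% names(series))) {
    abort(paste0("series needs concentration_ng_ml and ", response, " columns"),
          class = "wntwave_input_error")
  }
  dplyr::summarise(
    dplyr::group_by(series, .data$concentration_ng_ml),
    mean_response = mean(.data[[response]]), n = dplyr::n(), .groups = "drop"
  )
}

#' Fit the first-order decay dose-response model
#'
#' Least squares of `y0 + A1 * exp(-x / t1)` on per-concentration mean dwell
#' times (the negative-cooperativity model: dwell time decreases as ligand
#' concentration increases). The rate constant `k = 1/t1` is reported.
#' Non-convergence never raises; it yields a flagged fit.
#'
#' @param series Data frame with `concentration_ng_ml` and a response column.
#' @param response Response column name (default `dwell_s`; use the amplitude
#'   column to analyse amplitude-concentration dependence instead).
#' @return Object of class `decay_fit`: `y0`, `A1`, `t1`, `k`, `rss`,
#'   `converged`, `note`, `n_conc`. Use [tidy()] / [glance()].
#' @export
fit_first_order_decay <- function(series, response = "dwell_s") {
  m <- series_means(series, response)
  if (nrow(m) < 3) {
    abort("need >= 3 distinct concentrations for the 3-parameter decay fit",
          class = "wntwave_input_error")
  }
  x <- m$concentration_ng_ml
  y <- m$mean_response
  if (diff(range(y)) <= 1e-10) {
    return(new_decay_fit(y0 = mean(y), A1 = 0, t1 = NA_real_, k = NA_real_,
                         rss = 0, converged = FALSE,
                         note = "constant response; t1 unidentifiable",
                         n_conc = nrow(m)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + A1 * exp(-x / t1),
      data = data.frame(x = x, y = y),
      start = list(y0 = min(y), A1 = max(y) - min(y), t1 = diff(range(x)) / 3),
      lower = c(y0 = -Inf, A1 = -Inf, t1 = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_decay_fit(y0 = NA_real_, A1 = NA_real_, t1 = NA_real_,
                         k = NA_real_, rss = NA_real_, converged = FALSE,
                         note = conditionMessage(fit), n_conc = nrow(m)))
  }
  cf <- coef(fit)
  new_decay_fit(y0 = unname(cf["y0"]), A1 = unname(cf["A1"]),
                t1 = unname(cf["t1"]), k = 1 / unname(cf["t1"]),
                rss = deviance(fit), converged = TRUE, note = "",
                n_conc = nrow(m))
}

new_decay_fit <- function(y0, A1, t1, k, rss, converged, note, n_conc) {
  structure(list(y0 = y0, A1 = A1, t1 = t1, k = k, rss = rss,
                 converged = converged, note = note, n_conc = n_conc),
            class = "decay_fit")
}

#' Fit the Michaelis-Menten dose-response model
#'
#' Least squares of `dt_max * C / (k_half + C)` on per-concentration mean
#' dwell times; `k_half` is the half-maximal concentration (ng/ml).
#'
#' @inheritParams fit_first_order_decay
#' @return Object of class `mm_fit`: `dt_max`, `k_half`, `rss`, `converged`,
#'   `note`, `n_conc`. Use [tidy()] / [glance()].
#' @examples
#' s <- simulate_concentration_series("Wnt5A", c(30, 100, 300),
#'                                    noise_fraction = 0, seed = 1)
#' glance(fit_michaelis_menten(s))
#' @export
fit_michaelis_menten <- function(series, response = "dwell_s") {
  m <- series_means(series, response)
  if (nrow(m) < 2) {
    abort("need >= 2 distinct concentrations", class = "wntwave_input_error")
  }
  x <- m$concentration_ng_ml
  y <- m$mean_response
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dt_max * x / (k_half + x),
      data = data.frame(x = x, y = y),
      start = list(dt_max = max(y) * 1.2, k_half = median(x)),
      lower = c(dt_max = 1e-9, k_half = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(dt_max = NA_real_, k_half = NA_real_, rss = NA_real_,
                          converged = FALSE, note = conditionMessage(fit),
                          n_conc = nrow(m)),
                     class = "mm_fit"))
  }
  cf <- coef(fit)
  structure(list(dt_max = unname(cf["dt_max"]), k_half = unname(cf["k_half"]),
                 rss = deviance(fit), converged = TRUE, note = "",
                 n_conc = nrow(m)),
            class = "mm_fit")
}

#' Diagnose the dose-response mode of a concentration series
#'
#' Adjacent concentrations are compared with two-sided Mann-Whitney tests at
#' level `alpha` (uncorrected). The series is called `flat_indeterminate`
#' when no adjacent pair differs significantly; `negative_cooperative` when
#' at least one significant pair decreases and none increases (dwell time
#' falls as concentration rises); `michaelis_menten` when significant pairs
#' increase (response rises and saturates). Both curve fits are attached,
#' with the lower-residual model recorded as `support`.
#'
#' @inheritParams fit_first_order_decay
#' @param alpha Significance level for the adjacent-pair tests.
#' @return Object of class `dose_diagnosis`: `mode`, `decay_fit`, `mm_fit`,
#'   `support`, `pairwise` (tibble), `alpha`, `ligand`.
#' @export
diagnose_dose_response <- function(series, response = "dwell_s", alpha = 0.05) {
  series <- as_tibble(series)
  concs <- sort(unique(series$concentration_ng_ml))
  if (length(concs) < 3) {
    abort("need >= 3 concentrations for diagnosis", class = "wntwave_input_error")
  }
  obs <- split(series[[response]], series$concentration_ng_ml)
  if (any(lengths(obs) < 3)) {
    abort("need >= 3 replicates per concentration", class = "wntwave_input_error")
  }
  pairwise <- purrr::map_dfr(seq_len(length(concs) - 1), function(i) {
    a <- obs[[as.character(concs[i])]]
    b <- obs[[as.character(concs[i + 1])]]
    mw <- mann_whitney_u(a, b)
    tibble(
      conc_low = concs[i], conc_high = concs[i + 1],
      direction = sign(median(b) - median(a)),
      u = mw$u, p_value = mw$p_value, method = mw$method,
      significant = mw$p_value < alpha
    )
  })
  sig <- pairwise[pairwise$significant, ]
  mode <- if (nrow(sig) == 0) {
    "flat_indeterminate"
  } else if (all(sig$direction < 0)) {
    "negative_cooperative"
  } else if (all(sig$direction > 0)) {
    "michaelis_menten"
  } else {
    "flat_indeterminate" # non-monotone significant changes: no clean call
  }
  dfit <- fit_first_order_decay(series, response)
  mfit <- fit_michaelis_menten(series, response)
  support <- if (isTRUE(dfit$converged) && isTRUE(mfit$converged)) {
    if (dfit$rss <= mfit$rss) "decay" else "michaelis_menten"
  } else if (isTRUE(dfit$converged)) {
    "decay"
  } else if (isTRUE(mfit$converged)) {
    "michaelis_menten"
  } else {
    "none"
  }
  structure(
    list(mode = mode, decay_fit = dfit, mm_fit = mfit, support = support,
         pairwise = pairwise, alpha = alpha,
         ligand = if ("ligand" %in% names(series)) series$ligand[1] else NA_character_),
    class = "dose_diagnosis"
  )
}

#' @export
print.dose_diagnosis <- function(x, ...) {
  cat(sprintf("Dose-response diagnosis%s: %s (curve support: %s)\n",
              if (is.na(x$ligand)) "" else paste0(" [", x$ligand, "]"),
              x$mode, x$support))
  invisible(x)
}
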