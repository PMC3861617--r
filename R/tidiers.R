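#' Tidiers for wntwave fit objects
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row
#' model summary.
#'
#' @param x A `gaussian_fit`, `decay_fit`, `mm_fit` or `dose_diagnosis`.
#' @param ... Unused.
#' @return A tibble.
#' @name wntwave_tidiers
NULL

#' @rdname wntwave_tidiers
#' @method tidy gaussian_fit
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("y0", "A", "t0", "sigma"),
         estimate = c(x$y0, x$A, x$t0, x$sigma))
}

#' @rdname wntwave_tidiers
#' @method glance gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(y0 = x$y0, A = x$A, t0 = x$t0, sigma = x$sigma, rss = x$rss,
         converged = x$converged, note = x$note, n = x$n)
}

#' @rdname wntwave_tidiers
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("y0", "A1", "t1", "k"),
         estimate = c(x$y0, x$A1, x$t1, x$k))
}

#' @rdname wntwave_tidiers
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(y0 = x$y0, A1 = x$A1, t1 = x$t1, k = x$k, rss = x$rss,
         converged = x$converged, note = x$note, n_conc = x$n_conc)
}

#' @rdname wntwave_tidiers
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("dt_max", "k_half"), estimate = c(x$dt_max, x$k_half))
}

#' @rdname wntwave_tidiers
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(dt_max = x$dt_max, k_half = x$k_half, rss = x$rss,
         converged = x$converged, note = x$note, n_conc = x$n_conc)
}

#' @rdname wntwave_tidiers
#' @method tidy dose_diagnosis
#' @export
tidy.dose_diagnosis <- function(x, ...) x$pairwise

#' @rdname wntwave_tidiers
#' @method glance dose_diagnosis
#' @export
glance.dose_diagnosis <- function(x, ...) {
  tibble(
    ligand = x$ligand, mode = x$mode, support = x$support, alpha = x$alpha,
    decay_k = x$decay_fit$k, decay_rss = x$decay_fit$rss,
    mm_k_half = x$mm_fit$k_half, mm_rss = x$mm_fit$rss
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("First-order decay fit: y0 = %.4g, A1 = %.4g, t1 = %.4g ng/ml (k = %.4g)\n",
                x$y0, x$A1, x$t1, x$k))
  } else {
    cat(sprintf("First-order decay fit: NOT converged (%s)\n", x$note))
  }
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Michaelis-Menten fit: DTmax = %.4g s, K1/2 = %.4g ng/ml\n",
                x$dt_max, x$k_half))
  } else {
    cat(sprintf("Michaelis-Menten fit: NOT converged (%s)\n", x$note))
  }
  invisible(x)
}
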