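# Independent oracles used across the suite. These stay deliberately naive:
# enumeration, closed forms and direct linear algebra, never the package's
# own code paths.

# Closed-form threshold-crossing geometry of the generating waveform
# y0 + A * exp(-(t - t0)^2 / (2 w^2)), rising width sigma, falling width
# sigma * (1 + asymmetry). For a threshold fraction f of A the crossings sit
# at t0 -/+ width * sqrt(-2 log(f)).
oracle_crossings <- function(params, lower = 0.10, upper = 0.90) {
  u <- function(f) sqrt(-2 * log(f))
  s_r <- params$sigma
  s_f <- params$sigma * (1 + params$asymmetry)
  t0 <- params$center_time
  list(
    lower_up = t0 - s_r * u(lower),
    upper_up = t0 - s_r * u(upper),
    upper_down = t0 + s_f * u(upper),
    lower_down = t0 + s_f * u(lower),
    rise = s_r * (u(lower) - u(upper)),
    dwell = (s_r + s_f) * u(upper),
    fall = s_f * (u(lower) - u(upper))
  )
}

# Mann-Whitney U of x against y with mid-ranks for ties
oracle_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided p by enumeration of all C(m+n, m) group assignments
oracle_mw_exact_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  u_obs <- oracle_u(x, y)
  total <- ncol(idx)
  count <- if (u_obs <= m * length(y) / 2) sum(us <= u_obs) else sum(us >= u_obs)
  min(1, 2 * count / total)
}

# OLS by the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2], rss = sum(res^2))
}

# Permutation reference for the slope-equality F test: permute residuals of
# the common-slope model, rebuild responses, recompute the F statistic.
oracle_slope_permutation_p <- function(series_a, series_b, n_perm = 2000,
                                       seed = 1) {
  f_stat <- function(dat) {
    full <- lm(width_um ~ time_h * cond, data = dat)
    red <- lm(width_um ~ time_h + cond, data = dat)
    num <- max(deviance(red) - deviance(full), 0)
    num / (deviance(full) / df.residual(full))
  }
  dat <- rbind(
    data.frame(time_h = series_a$time_h, width_um = series_a$width_um, cond = "a"),
    data.frame(time_h = series_b$time_h, width_um = series_b$width_um, cond = "b")
  )
  f_obs <- f_stat(dat)
  red <- lm(width_um ~ time_h + cond, data = dat)
  fitted_red <- fitted(red)
  res <- residuals(red)
  set.seed(seed)
  f_perm <- replicate(n_perm, {
    d2 <- dat
    d2$width_um <- fitted_red + sample(res)
    f_stat(d2)
  })
  mean(f_perm >= f_obs)
}
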