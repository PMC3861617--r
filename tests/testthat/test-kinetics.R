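sym_params <- transient_params(baseline = 1, amplitude = 1.5, center_time = 200,
                               sigma = 20, noise_sd = 0, sample_interval = 1.1,
                               duration = 600)

test_that("ratio computation is an element-wise quotient with a division guard", {
  expect_equal(compute_ratio(c(2, 4), c(1, 2)), c(2, 2))
  expect_equal(compute_ratio(c(3, 5, 7), c(3, 5, 7)), rep(1, 3))
  expect_error(compute_ratio(c(1, 2), c(1, 0)),
               class = "wntwave_degenerate_channel_error")
  expect_error(compute_ratio(1:3, 1:2), class = "wntwave_input_error")
})

test_that("Gaussian fit recovers noiseless generating parameters", {
  tr <- simulate_trace(sym_params, seed = 1)
  fit <- fit_gaussian(tr)
  expect_true(fit$converged)
  expect_equal(fit$y0, 1, tolerance = 1e-6)
  expect_equal(fit$A, 1.5, tolerance = 1e-6)
  expect_equal(fit$t0, 200, tolerance = 1e-6)
  expect_equal(fit$sigma, 20, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("Gaussian fit degrades gracefully on constant and noisy traces", {
  flat <- tibble::tibble(time_s = seq(0, 100, 1), ratio = rep(1.3, 101))
  fit <- fit_gaussian(flat)
  expect_equal(fit$A, 0)
  expect_equal(fit$y0, 1.3)
  expect_gt(fit$sigma, 0)

  expect_error(fit_gaussian(flat[1:5, ]), class = "wntwave_input_error")

  noisy <- simulate_trace(transient_params(amplitude = 1.5, sigma = 20,
                                           noise_sd = 0.05), seed = 11)
  nfit <- fit_gaussian(noisy)
  expect_true(nfit$converged)
  expect_lt(abs(nfit$sigma - 20) / 20, 0.10)
})

test_that("time constants match the closed-form crossing oracle", {
  tr <- simulate_trace(sym_params, seed = 1)
  tc <- extract_time_constants(tr)
  oc <- oracle_crossings(sym_params)
  expect_lt(abs(tc$dwell_s - oc$dwell), 1e-3)
  expect_lt(abs(tc$rise_s - oc$rise), 1e-3)
  expect_lt(abs(tc$fall_s - oc$fall), 1e-3)
  expect_lt(abs(tc$t_lower_up - oc$lower_up), 1e-3)
  # symmetric Gaussian: rise equals fall, dwell = 2 sigma sqrt(2 log(10/9))
  expect_equal(tc$rise_s, tc$fall_s, tolerance = 1e-4)
  expect_equal(tc$dwell_s, 2 * 20 * sqrt(2 * log(10 / 9)), tolerance = 1e-3)
  # sampled peak: the 1.1 s grid does not hit t0 exactly
  expect_equal(tc$amplitude, 1.5, tolerance = 1e-3)
})

test_that("dwell grows with sigma and stays under its analytic bound", {
  dwells <- sapply(c(10, 20, 30, 40), function(s) {
    p <- transient_params(amplitude = 1.5, sigma = s, noise_sd = 0,
                          duration = 800, center_time = 300)
    extract_time_constants(simulate_trace(p, seed = 1))$dwell_s
  })
  expect_true(all(diff(dwells) > 0))
  expect_true(all(dwells < 2 * c(10, 20, 30, 40) * sqrt(2 * log(10))))
})

test_that("asymmetric transients have fall slower than rise", {
  p <- transient_params(amplitude = 1.2, sigma = 20, asymmetry = 0.4,
                        noise_sd = 0)
  tr <- simulate_trace(p, seed = 1)
  tc <- extract_time_constants(tr)
  expect_gt(tc$fall_s, tc$rise_s)
  oc <- oracle_crossings(p)
  # with ground-truth threshold levels, crossings match the closed form;
  # the single-Gaussian fit to an asymmetric pulse shifts its levels a little
  truth <- list(y0 = 1, A = 1.2, t0 = 200, sigma = 20, converged = TRUE)
  tc_true <- extract_time_constants(tr, truth)
  expect_lt(abs(tc_true$fall_s - oc$fall), 1e-3)
  expect_lt(abs(tc_true$dwell_s - oc$dwell), 1e-3)
  expect_lt(abs(tc$dwell_s - oc$dwell), 0.5)
})

test_that("kinetics are invariant to channel rescaling and equivariant to time shift", {
  tr <- simulate_trace(sym_params, seed = 1)
  for (c_scale in c(0.3, 7)) {
    scaled <- tibble::tibble(time_s = tr$time_s, fluo4 = c_scale * tr$fluo4,
                             furared = c_scale * tr$furared)
    tc0 <- extract_time_constants(tr)
    tc1 <- extract_time_constants(scaled)
    expect_equal(tc1$dwell_s, tc0$dwell_s, tolerance = 1e-9)
    expect_equal(tc1$rise_s, tc0$rise_s, tolerance = 1e-9)
    expect_equal(tc1$amplitude, tc0$amplitude, tolerance = 1e-9)
  }
  shifted <- tibble::tibble(time_s = tr$time_s + 57, ratio = tr$ratio)
  f0 <- fit_gaussian(tr)
  f1 <- fit_gaussian(shifted)
  expect_equal(f1$t0, f0$t0 + 57, tolerance = 1e-6)
  tc0 <- extract_time_constants(tr, f0)
  tc1 <- extract_time_constants(shifted, f1)
  expect_equal(tc1$dwell_s, tc0$dwell_s, tolerance = 1e-6)
  expect_equal(tc1$t_upper_up, tc0$t_upper_up + 57, tolerance = 1e-6)
})

test_that("sub-threshold traces yield a flagged no-transient result, never times", {
  flat <- simulate_trace(transient_params(amplitude = 1e-9, noise_sd = 0),
                         seed = 1)
  tc <- extract_time_constants(flat)
  expect_equal(tc$flag, "no_transient")
  expect_true(is.na(tc$dwell_s))
  on <- detect_onset(flat)
  expect_false(on$detected)

  small <- simulate_trace(transient_params(amplitude = 0.02, noise_sd = 0),
                          seed = 1)
  expect_equal(extract_time_constants(small)$flag, "no_transient")
})

test_that("onset detection matches the closed form and reports shifts as-is", {
  tr <- simulate_trace(sym_params, seed = 1)
  on <- detect_onset(tr)
  expect_true(on$detected)
  expect_lt(abs(on$onset_s - (200 - 20 * sqrt(2 * log(10)))), 1e-3)

  # a 33 s time shift moves onset by exactly 33 s
  p2 <- sym_params
  p2$center_time <- 233
  tr2 <- simulate_trace(p2, seed = 1)
  expect_equal(detect_onset(tr2)$onset_s - on$onset_s, 33, tolerance = 1e-3)

  lag <- onset_lag(tr, tr2)
  expect_true(lag$detected)
  expect_equal(lag$lag_s, 33, tolerance = 1.1) # within one sample interval
  expect_equal(onset_lag(tr, tr)$lag_s, 0)
  # nuclear leading gives a negative lag, reported as-is
  expect_equal(onset_lag(tr2, tr)$lag_s, -33, tolerance = 1.1)
})

test_that("front speed is recovered by regression of onset on distance", {
  # exact inversion of onset = d / v
  onsets <- tibble::tibble(distance_um = c(0, 100, 200, 300),
                           onset_s = c(0, 100, 200, 300) / 23.3)
  fs <- estimate_front_speed(onsets)
  expect_equal(fs$speed_um_s, 23.3, tolerance = 1e-9)

  # equal delays at all distances: slope zero, no propagating front
  flat <- tibble::tibble(distance_um = c(0, 100, 200), onset_s = c(5, 5, 5))
  expect_error(estimate_front_speed(flat), class = "wntwave_front_error")

  # noisy simulation: recovered speed within 2 SE of the true speed
  set.seed(42)
  d <- seq(0, 700, 100)
  noisy <- tibble::tibble(distance_um = d, onset_s = d / 23.3 + rnorm(8, sd = 0.5))
  fs2 <- estimate_front_speed(noisy)
  expect_lt(abs(fs2$speed_um_s - 23.3), 2 * fs2$speed_se + 1e-9)
})

test_that("dish onsets feed the front-speed estimate end to end", {
  lay <- dish_layout(data.frame(x = seq(0, 700, 100), y = 0), front_speed = 23.3)
  dd <- simulate_dish(lay, preset_transient_params("Wnt5A", noise_sd = 0),
                      seed = 1)
  on <- dish_onsets(dd)
  expect_true(all(on$detected))
  fs <- estimate_front_speed(on)
  expect_equal(fs$speed_um_s, 23.3, tolerance = 0.01)
})

test_that("baseline return time flags the thapsigargin recovery", {
  tg <- simulate_thapsigargin_trace(seed = 1, noise_sd = 0)
  br <- baseline_return_time(tg)
  expect_true(br$detected)
  expect_lte(br$return_s, 120)
  # pre-stimulus segment is a constant baseline at zero noise
  pre <- tg$ratio[tg$time_s < attr(tg, "stimulus_time")]
  expect_equal(sd(pre), 0)
  # subsequent ligand addition evokes nothing: amplitude below detection
  seg <- tg[tg$time_s >= attr(tg, "wnt_time"), ]
  tc <- extract_time_constants(seg)
  expect_equal(tc$flag, "no_transient")
})
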