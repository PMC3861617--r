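test_that("noiseless traces are exactly the designed ratio curve", {
  # zero amplitude: constant ratio at baseline
  flat <- simulate_trace(
    transient_params(baseline = 1, amplitude = 1e-12, noise_sd = 0), seed = 1
  )
  expect_equal(flat$ratio, rep(1, nrow(flat)), tolerance = 1e-10)

  # peak of a noiseless Gaussian: baseline + amplitude at the centre
  p <- transient_params(baseline = 1, amplitude = 1.5, center_time = 200,
                        sigma = 20, noise_sd = 0, sample_interval = 1,
                        duration = 600)
  tr <- simulate_trace(p, seed = 1)
  expect_equal(tr$ratio[tr$time_s == 200], 2.5, tolerance = 1e-12)

  # whole curve matches the generating expression
  expected <- 1 + 1.5 * exp(-(tr$time_s - 200)^2 / (2 * 20^2))
  expect_equal(tr$ratio, expected, tolerance = 1e-12)

  # symmetry about the centre when asymmetry = 0
  left <- tr$ratio[match(200 - (1:50), tr$time_s)]
  right <- tr$ratio[match(200 + (1:50), tr$time_s)]
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("traces are reproducible given (params, seed) and channels carry the noise", {
  p <- transient_params(amplitude = 1.2, noise_sd = 0.05)
  a <- simulate_trace(p, seed = 7)
  b <- simulate_trace(p, seed = 7)
  c <- simulate_trace(p, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ratio, c$ratio)))
  # empirical ratio noise close to the requested ratio-units SD
  base <- a$time_s < 100
  expect_lt(abs(sd(a$ratio[base]) - 0.05), 0.02)
})

test_that("invalid transient parameters are rejected", {
  expect_error(transient_params(sigma = -1), class = "wntwave_parameter_error")
  expect_error(transient_params(amplitude = -1), class = "wntwave_parameter_error")
  expect_error(transient_params(duration = 100, center_time = 200),
               class = "wntwave_parameter_error")
})

test_that("dish delays equal distance over front speed", {
  lay <- dish_layout(data.frame(x = c(0, 233), y = c(0, 0)), front_speed = 23.3)
  expect_equal(lay$roi_info$delay_s, c(0, 10))

  # zero distance: no shift of the transient centre
  p <- transient_params(amplitude = 1.5, sigma = 15, noise_sd = 0)
  one <- dish_layout(data.frame(x = 0, y = 0), front_speed = 10)
  d <- simulate_dish(one, p, seed = 1)
  solo <- simulate_trace(p, seed = 2) # same params, direct simulation
  expect_equal(which.max(d$roi01_fluo4), which.max(solo$fluo4))

  # doubling front speed halves every delay
  fast <- dish_layout(data.frame(x = c(0, 100, 300), y = 0), front_speed = 46.6)
  slow <- dish_layout(data.frame(x = c(0, 100, 300), y = 0), front_speed = 23.3)
  expect_equal(slow$roi_info$delay_s, 2 * fast$roi_info$delay_s)

  expect_error(dish_layout(data.frame(x = 0, y = 0), front_speed = 0),
               class = "wntwave_parameter_error")
})

test_that("concentration-series means sit exactly on the preset curve at zero noise", {
  concs <- c(30, 67, 100, 300)
  s <- simulate_concentration_series("Wnt5A", concs, replicates = 4,
                                     noise_fraction = 0, seed = 1)
  m <- aggregate(dwell_s ~ concentration_ng_ml, s, mean)
  expect_equal(m$dwell_s, 20 * concs / (67 + concs), tolerance = 1e-12)
  # half-maximum at the half-maximal concentration, by definition
  expect_equal(m$dwell_s[m$concentration_ng_ml == 67], 20 / 2)

  # negative-cooperative preset decreases monotonically
  s2 <- simulate_concentration_series("Wnt9B", c(30, 100, 300), replicates = 3,
                                      noise_fraction = 0, seed = 1)
  m2 <- aggregate(dwell_s ~ concentration_ng_ml, s2, mean)
  expect_true(all(diff(m2$dwell_s) < 0))

  # flat preset is identical everywhere
  s3 <- simulate_concentration_series("Wnt7A", c(30, 100, 300), replicates = 3,
                                      noise_fraction = 0, seed = 1)
  expect_equal(unique(s3$dwell_s), 27)

  expect_error(
    simulate_concentration_series("Wnt5A", c(300, 30)),
    class = "wntwave_parameter_error"
  )
})

test_that("ligand presets encode the published class table and dose modes", {
  pr <- ligand_presets()
  expect_equal(pr$kinetic_class[match(c("Wnt3A", "Wnt5A"), pr$ligand)],
               rep("short", 2))
  expect_equal(pr$kinetic_class[match(c("Wnt7A", "Wnt10B"), pr$ligand)],
               rep("long", 2))
  expect_equal(pr$kinetic_class[match(c("Wnt4", "Wnt9B"), pr$ligand)],
               rep("very_long", 2))
  expect_equal(pr$kinetic_class[match(c("Wnt11", "vehicle"), pr$ligand)],
               rep("none", 2))
  expect_equal(pr$dose_mode[pr$ligand == "Wnt5A"], "michaelis_menten")
  expect_equal(pr$dose_params[[match("Wnt5A", pr$ligand)]]$k_half, 67)
  expect_equal(pr$dose_mode[pr$ligand == "Wnt7A"], "flat")
  expect_setequal(pr$ligand[pr$dose_mode == "negative_cooperative"],
                  c("Wnt3A", "Wnt4", "Wnt9B", "Wnt10B"))
})

test_that("wound widths follow the linear closure model", {
  p <- wound_params(initial_width = 500, closure_rate = 10, noise_sd = 0,
                    duration = 10)
  s <- simulate_wound_series(p, seed = 1)
  expect_equal(diff(s$width_um), rep(-20, 5)) # 2-h sampling, 10 um/h
  s0 <- simulate_wound_series(wound_params(closure_rate = 0, noise_sd = 0),
                              seed = 1)
  expect_equal(unique(s0$width_um), 500)
  # width is floored at zero before noise
  sf <- simulate_wound_series(wound_params(initial_width = 30, closure_rate = 10,
                                           duration = 10, noise_sd = 0), seed = 1)
  expect_true(all(sf$width_um >= 0))
  expect_equal(sf$width_um[sf$time_h == 8], 0)
})

test_that("synthetic image sets place the stated nuclear fraction", {
  # all immunolabel inside nuclei when fraction is 1 and background 0
  img1 <- simulate_coloc_images(
    coloc_image_params(n_cells = 6, nuclear_fraction = 1, background_sd = 0),
    seed = 1
  )
  expect_equal(sum(img1$cy3[img1$masks == 0]), 0)
  expect_gt(sum(img1$cy3[img1$masks > 0]), 0)

  img0 <- simulate_coloc_images(
    coloc_image_params(n_cells = 6, nuclear_fraction = 0, background_sd = 0),
    seed = 1
  )
  expect_equal(sum(img0$cy3[img0$masks > 0]), 0)

  # nuclei never overlap: all six labels present and centres at least one
  # diameter apart
  counts <- table(img1$masks[img1$masks > 0])
  expect_equal(length(counts), 6)
  d <- as.matrix(dist(img1$cells[, c("y", "x")]))
  expect_gt(min(d[upper.tri(d)]), 2 * 6)

  expect_error(
    simulate_coloc_images(coloc_image_params(image_shape = c(30, 30),
                                             n_cells = 30), seed = 1),
    class = "wntwave_layout_error"
  )
})
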