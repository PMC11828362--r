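test_that("DCM extraction handles peaks, ties and surface-type profiles", {
  z <- seq(0, 150, by = 2)
  peak <- data.frame(depth = z,
                     chlorophyll = exp(-(z - 100)^2 / 450))
  out <- extract_dcm(peak)
  expect_equal(out$depth, 100)
  expect_false(out$surface_type)
  # monotone-decreasing: maximum at the exclusion cap, flagged
  mono <- data.frame(depth = z, chlorophyll = 1 / (1 + z))
  out2 <- extract_dcm(mono)
  expect_equal(out2$depth, min(z[z >= 5]))
  expect_true(out2$surface_type)
  # two equal maxima: shallower reported, tie flagged
  two <- data.frame(depth = c(10, 50, 90), chlorophyll = c(0.2, 1, 1))
  out3 <- extract_dcm(two)
  expect_equal(out3$depth, 50)
  expect_true(out3$tie)
  expect_error(extract_dcm(data.frame(depth = c(10, 5),
                                      chlorophyll = c(1, 2))),
               "strictly increasing")
})

test_that("mixed-layer depth follows the threshold criterion", {
  z <- seq(0, 150, by = 1)
  two_layer <- data.frame(depth = z,
                          temperature = ifelse(z <= 65, 26,
                                               26 - 0.05 * (z - 65)))
  out <- extract_mld(two_layer)
  expect_lt(abs(out$depth - 65), 6)  # 0.2 degC crossing just below the step
  expect_false(out$isothermal)
  # isothermal profile: max depth, flagged
  iso <- data.frame(depth = z, temperature = 26)
  out2 <- extract_mld(iso)
  expect_equal(out2$depth, 150)
  expect_true(out2$isothermal)
  # threshold 0: the reference depth itself
  out3 <- extract_mld(two_layer, delta_t = 0)
  expect_equal(out3$depth, 10)
  expect_error(extract_mld(data.frame(depth = c(0, 5),
                                      temperature = c(26, 26))),
               "shallower")
})

test_that("CEI is exactly zero on uniform fields and 100% for a doubled
           cell", {
  env <- gen_environment(sim_config(seed = 15, n_scenes = 1,
                                    cloud_frac = 0, noise_sd = 1e-12,
                                    lat_gradient = 0, grid_half_km = 100))
  sc <- env$scenes[[1]]
  sc$chl <- 0.5
  out <- compute_cei(sc, env$truth$summit)
  expect_true(all(abs(out$cei) < 1e-9, na.rm = TRUE))
  # double one central cell: its CEI is 100% (annulus excludes itself)
  centre <- which.min(out$dist_km)
  sc2 <- sc
  sc2$chl[centre] <- 1.0
  out2 <- compute_cei(sc2, env$truth$summit)
  expect_equal(out2$cei[centre], 100, tolerance = 1e-6)
})

test_that("cloudy scenes are rejected and mean CEI skips them", {
  env <- gen_environment(sim_config(seed = 16, n_scenes = 2,
                                    cloud_frac = 0.2))
  cloudy <- env$scenes[[1]]
  cloudy$cloud <- runif(nrow(cloudy)) < 0.6
  expect_warning(out <- compute_cei(cloudy, env$truth$summit), "rejected")
  expect_null(out)
  stack <- mean_cei(c(list(cloudy), env$scenes), env$truth$summit)
  expect_equal(attr(stack, "n_accepted"), 2)
})

test_that("radial bin means average out a symmetric gradient", {
  env <- gen_environment(sim_config(seed = 17, n_scenes = 1,
                                    cloud_frac = 0, noise_sd = 1e-12,
                                    lat_gradient = 2e-4))
  sc <- env$scenes[[1]]
  rb <- radial_bin_means(sc, env$truth$summit, value = "chl", max_km = 40)
  # summit-centred bins see the gradient cancel by symmetry
  expect_lt(max(rb$response) - min(rb$response), 0.004)
  # half-open convention: a cell at exactly 1.0 km joins bin 2
  f <- data.frame(lon = c(0, 0), lat = c(0, 1.0000001 / (pi * 6371 / 180)),
                  chl = c(1, 2))
  rb2 <- radial_bin_means(f, c(0, 0), bin_km = 1)
  expect_equal(rb2$distance_km, c(0.5, 1.5))
  # constant field: all bin means equal
  sc$chl <- 0.3
  rb3 <- radial_bin_means(sc, env$truth$summit, value = "chl")
  expect_true(all(abs(rb3$response - 0.3) < 1e-12))
})

test_that("gradient-only fields yield no seamount effect from the CEI
           pipeline", {
  hits <- vapply(1:6, function(seed) {
    env <- gen_environment(sim_config(seed = 1000 + seed, n_scenes = 8,
                                      summit_bump = 0, noise_cor_km = 0))
    stack <- mean_cei(env$scenes, env$truth$summit)
    rb <- radial_bin_means(stack, env$truth$summit, value = "cei",
                           max_km = 40)
    m <- distance_gam(rb, family = "gaussian", weights = rb$n_cells)
    radius_of_influence(m, seed = seed)$method == "none"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # positive control: a planted summit chlorophyll bump is detected
  env <- gen_environment(sim_config(seed = 1234, n_scenes = 8,
                                    summit_bump = 0.02, noise_cor_km = 0))
  stack <- mean_cei(env$scenes, env$truth$summit)
  rb <- radial_bin_means(stack, env$truth$summit, value = "cei",
                         max_km = 40)
  m <- distance_gam(rb, family = "gaussian", weights = rb$n_cells)
  expect_true(radius_of_influence(m, seed = 1)$method != "none")
})

test_that("tidal spectrum recovers planted periodicities", {
  # pure 12.0-h sinusoid
  tt <- seq(0, 120 * 86400 - 600, by = 600)
  th <- tt / 3600
  pure <- data.frame(time_s = tt,
                     temperature = 15 + sin(2 * pi * th / 12))
  out <- tidal_spectrum(pure)
  expect_equal(round(out$peak_period_h, 1), 12.0)
  # two sinusoids, amplitudes 2:1 -> the stronger period wins
  two <- data.frame(time_s = tt,
                    temperature = 15 + 2 * sin(2 * pi * th / 8) +
                      sin(2 * pi * th / 16))
  expect_equal(round(tidal_spectrum(two)$peak_period_h, 0), 8)
  # detrending property: peak invariant to adding a linear trend
  trended <- pure
  trended$temperature <- trended$temperature + 3e-7 * tt
  expect_equal(tidal_spectrum(trended)$peak_period_h, out$peak_period_h)
  # irregular sampling rejected
  bad <- pure[-(5:10), ]
  expect_error(tidal_spectrum(bad), "irregular")
  # too-short series rejected
  expect_error(tidal_spectrum(pure[1:100, ]), "10 times")
})

test_that("the M2 constituent dominates the generated tide series", {
  env <- gen_environment(sim_config(seed = 18, tide_days = 200))
  out <- tidal_spectrum(env$tide)
  expect_equal(round(out$peak_period_h, 1), 12.4)
})
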