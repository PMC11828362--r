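test_that("haversine matches the closed form and is symmetric", {
  expect_equal(haversine(0, 0, 0, 0), 0)
  expect_equal(haversine(10, -5, 10, -4), pi * 6371 / 180,
               tolerance = 1e-6)
  expect_equal(haversine(-14.4, -8.4, -13.9, -8.1),
               haversine(-13.9, -8.1, -14.4, -8.4))
  expect_error(haversine(0, 95, 0, 0), "latitude")
})

test_that("movement parameters capture steps and turns of simple paths", {
  # straight equal-spaced track along a meridian: all turns ~ 0
  tr <- data.frame(lon = 0, lat = seq(0, 1, by = 0.1),
                   timestamp = as.POSIXct("2017-06-01", tz = "UTC") +
                     0:10 * 43200)
  mp <- fit_movement_params(tr)
  expect_length(mp$steps, 10)
  expect_length(mp$turns, 9)
  expect_true(all(abs(mp$turns) < 1e-6))
  expect_equal(mp$steps, rep(0.1 * pi * 6371 / 180, 10), tolerance = 1e-6)
  # square path: turns of +/- pi/2
  sq <- data.frame(lon = c(0, 0.1, 0.1, 0, 0),
                   lat = c(0, 0, 0.1, 0.1, 0),
                   timestamp = as.POSIXct("2017-06-01", tz = "UTC") +
                     0:4 * 43200)
  mps <- fit_movement_params(sq)
  expect_equal(abs(mps$turns), rep(pi / 2, 3), tolerance = 1e-3)
  expect_error(fit_movement_params(sq[1:2, ]))
  dup <- tr; dup$timestamp[2] <- dup$timestamp[1]
  expect_error(fit_movement_params(dup), "duplicate")
})

test_that("simulated walks honour degenerate parameter sets", {
  # all steps zero: endpoints at the start
  p0 <- list(steps = rep(0, 10), turns = rep(0.3, 9), duration_steps = 10,
             start = c(-14.4, -8.4))
  s0 <- simulate_crw(p0, n = 50, seed = 1)
  expect_true(all(abs(s0$final[, 1] + 14.4) < 1e-12))
  expect_true(all(abs(s0$final[, 2] + 8.4) < 1e-12))
  # zero turns, constant step: straight lines of length step * n_steps
  p1 <- list(steps = rep(10, 5), turns = rep(0, 4), duration_steps = 5,
             start = c(0, 0))
  s1 <- simulate_crw(p1, n = 100, seed = 2)
  d <- haversine(s1$final[, 1], s1$final[, 2], 0, 0)
  expect_equal(d, rep(50, 100), tolerance = 0.02)
  # seeded reproducibility
  expect_identical(simulate_crw(p1, n = 20, seed = 9),
                   simulate_crw(p1, n = 20, seed = 9))
  expect_error(simulate_crw(list(steps = numeric(0), turns = numeric(0))),
               "empty")
})

test_that("endpoint distribution is rotation-symmetric for unbiased walks", {
  tr <- gen_tracks(sim_config(seed = 55, n = 1, duration_steps = 40))
  sims <- simulate_crw(fit_movement_params(tr$tracks[[1]]), n = 4000,
                       seed = 3)
  dx <- sims$final[, 1] - tr$summit[1]
  dy <- sims$final[, 2] - tr$summit[2]
  quad <- table(factor(paste0(dx > 0, dy > 0),
                       levels = c("TRUETRUE", "TRUEFALSE", "FALSETRUE",
                                  "FALSEFALSE")))
  expect_gt(stats::chisq.test(quad)$p.value, 1e-4)
})

test_that("fidelity test returns calibrated p-values and bounds", {
  # a track generated by the null itself: p should not be extreme
  tr <- gen_tracks(sim_config(seed = 56, n = 10, duration_steps = 40))
  ps <- vapply(tr$tracks, function(t)
    fidelity_test(t, tr$summit, n = 400, seed = 4)$p_value, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
  # observed endpoint at the summit vs a diffusive null: p near 0
  t_home <- tr$tracks[[1]]
  t_home$lon[nrow(t_home)] <- tr$summit[1]
  t_home$lat[nrow(t_home)] <- tr$summit[2]
  p_home <- fidelity_test(t_home, tr$summit, n = 400, seed = 5)$p_value
  expect_lt(p_home, 0.1)
  # moving the endpoint moderately away raises p (movement sample barely
  # perturbed); p stays a probability
  t_off <- tr$tracks[[1]]
  t_off$lon[nrow(t_off)] <- tr$summit[1] + 0.4
  t_off$lat[nrow(t_off)] <- tr$summit[2]
  p_off <- fidelity_test(t_off, tr$summit, n = 400, seed = 5)$p_value
  expect_gt(p_off, p_home)
  expect_lte(p_off, 1)
  expect_warning(fidelity_test(tr$tracks[[2]], tr$summit, n = 50,
                               seed = 1), "resolution")
})

test_that("fidelity isopleths are monotone in probability level", {
  tr <- gen_tracks(sim_config(seed = 57, n = 1, duration_steps = 30))
  ft <- fidelity_test(tr$tracks[[1]], tr$summit, n = 500, seed = 7)
  iso <- ft$isopleths
  for (i in seq_len(nrow(iso)))
    expect_true(all(diff(as.numeric(iso[i, -1])) >= 0))
})

test_that("distance series matches per-point haversine and collapses for
           zero-variance draws", {
  tr <- data.frame(lon = c(-14.4, -14.2, -14.0), lat = c(-8.4, -8.3, -8.2))
  ds <- distance_series(tr, c(-14.4, -8.4))
  expect_equal(ds$distance_km,
               haversine(tr$lon, tr$lat, -14.4, -8.4))
  # stationary track at the summit: all zero
  st <- data.frame(lon = rep(-14.4, 4), lat = rep(-8.4, 4))
  expect_true(all(distance_series(st, c(-14.4, -8.4))$distance_km == 0))
  # zero-variance draws: interval width zero
  dr <- list(lon = matrix(rep(tr$lon, 5), 3), lat = matrix(rep(tr$lat, 5), 3))
  dsc <- distance_series(tr, c(-14.4, -8.4), draws = dr)
  expect_equal(dsc$lower, dsc$upper)
  expect_equal(dsc$lower, ds$distance_km)
  expect_error(distance_series(tr, c(-14.4, -8.4),
                               draws = list(lon = 1, lat = 2)))
})

test_that("merged utilisation distributions conserve mass with deployment
           weights", {
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  b <- matrix(0, 4, 4); b[3:4, ] <- 1
  ud <- merge_uds(list(a, b), deployment_days = c(3, 1))
  expect_equal(sum(ud$density), 1, tolerance = 1e-12)
  expect_equal(sum(ud$density[1:2, ]) / sum(ud$density[3:4, ]), 3,
               tolerance = 1e-9)
  # single animal: identity up to normalization
  solo <- merge_uds(list(a), 10)
  expect_equal(solo$density, a / sum(a))
  expect_error(merge_uds(list(a, matrix(1, 3, 3)), c(1, 1)), "mismatch")
})

test_that("volume contours take the densest cells and nest in q", {
  ud <- matrix(1, 4, 5)  # uniform on 20 cells
  m50 <- volume_contour(ud, 0.5)
  expect_equal(sum(m50), 10)
  peaked <- matrix(c(10, rep(1, 19)), 4, 5)
  m1 <- volume_contour(peaked, 0.3)
  expect_true(m1[1, 1])
  # nesting
  m95 <- volume_contour(peaked, 0.95)
  m5 <- volume_contour(peaked, 0.5)
  expect_true(all(m5[m5] %in% m95[m5]))
  expect_true(all(!m5 | m95))
  expect_error(volume_contour(peaked, 1.2), "q must")
  # q -> 1 includes all positive cells
  expect_equal(sum(volume_contour(peaked, 0.999999)), 20)
})
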