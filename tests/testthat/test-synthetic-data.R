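test_that("enrichment kernels honour their boundary invariants", {
  for (shape in c("compact-logistic", "half-gaussian-truncated")) {
    k <- enrichment_kernel(0.5, 20, 5, shape = shape)
    expect_equal(predict(k, 0), 10)            # baseline x multiplier
    expect_identical(predict(k, 5), 0.5)       # exactly baseline at R
    expect_identical(predict(k, c(5, 7, 30)), rep(0.5, 3))
    w <- kernel_weight(k, seq(0, 5, by = 0.1))
    expect_true(all(diff(w) <= 1e-12))         # monotone decay
  }
  k1 <- enrichment_kernel(2, 1, 5)
  expect_equal(predict(k1, c(0, 2, 10)), rep(2, 3))  # multiplier 1 = flat
})

test_that("radial survey generator is seed-deterministic and hits the
           requested moments", {
  cfg <- sim_config(seed = 11, n = 5000)
  k <- enrichment_kernel(0.5, 20, 5)
  s1 <- gen_radial_survey(cfg, k, "nb")
  s2 <- gen_radial_survey(cfg, k, "nb")
  expect_identical(s1, s2)

  # mean at the summit ~= 10 within 3 standard errors (NB var = mu + mu^2/theta)
  near <- s1$response[s1$distance_km < 0.5]
  mu <- predict(k, 0.25)
  se <- sqrt((mu + mu^2 / 1.5) / length(near))
  expect_lt(abs(mean(near) - mu), 3 * se + 0.3)

  # no-enrichment identity: summit mean ~= far-field mean
  s0 <- gen_radial_survey(sim_config(seed = 12, n = 5000),
                          enrichment_kernel(2, 1, 5), "nb")
  m_near <- mean(s0$response[s0$distance_km < 5])
  m_far <- mean(s0$response[s0$distance_km > 25])
  expect_lt(abs(m_near - m_far), 0.3)
})

test_that("radial survey generator matches requested family moments at
           large n", {
  k <- enrichment_kernel(3, 1, 5)
  # NB: variance = mu + mu^2/theta
  s <- gen_radial_survey(sim_config(seed = 13, n = 8000, theta = 2), k, "nb")
  expect_lt(abs(mean(s$response) - 3), 4 * sqrt((3 + 9 / 2) / 8000))
  expect_lt(abs(var(s$response) - (3 + 9 / 2)) / (3 + 9 / 2), 0.15)
  # Tweedie: variance = phi * mu^p
  st <- gen_radial_survey(sim_config(seed = 14, n = 8000, tweedie_phi = 1,
                                     tweedie_p = 1.5), k, "tweedie")
  expect_lt(abs(mean(st$response) - 3), 4 * sqrt(3^1.5 / 8000))
  expect_lt(abs(var(st$response) - 3^1.5) / 3^1.5, 0.15)
  expect_true(all(st$response >= 0))
  expect_gt(sum(st$response == 0), 0)  # point mass at zero
})

test_that("survey generator rejects invalid settings", {
  k <- enrichment_kernel(1, 2, 5)
  expect_error(sim_config(seed = 1, theta = -1), "positive")
  expect_error(gen_radial_survey(sim_config(seed = 1, tweedie_p = 2.5), k,
                                 "tweedie"), "tweedie_p")
  expect_error(gen_radial_survey(sim_config(seed = 1), k, "lognormal"))
})

test_that("NASC field generator plants recoverable structure", {
  nf <- gen_nasc_field(sim_config(seed = 2))
  expect_s3_class(nf, "echo_cells")
  expect_identical(nf, gen_nasc_field(sim_config(seed = 2)))
  # zooplankton cells carry the configured dB offset
  z <- nf[nf$true_class == "zooplankton", ]
  expect_true(all(abs((z$Sv120 - z$Sv38) - 10) < 1e-9))
  f <- nf[nf$true_class == "fish", ]
  expect_true(all(abs((f$Sv120 - f$Sv38) + 7) < 1e-9))
  # enrichment off: column-integrated backscatter flat in distance
  flat_ratio <- vapply(1:8, function(s) {
    flat <- gen_nasc_field(sim_config(seed = s, fish_multiplier = 1,
                                      zoop_multiplier = 1,
                                      layer_weaken = 0))
    ni <- integrate_nasc(classify_cells(flat), "zooplankton")
    mean(ni$NASC[ni$distance_km < 3]) / mean(ni$NASC[ni$distance_km > 10])
  }, numeric(1))
  expect_lt(abs(median(flat_ratio) - 1), 0.3)
  # planted fish multiplier recovered from integrated backscatter
  rat <- vapply(1:12, function(s) {
    nf <- gen_nasc_field(sim_config(seed = s, fish_multiplier = 19))
    ni <- integrate_nasc(classify_cells(nf), "fish")
    mean(ni$NASC[ni$distance_km < 0.6]) / mean(ni$NASC[ni$distance_km > 10])
  }, numeric(1))
  expect_lt(abs(median(rat) - 19) / 19, 0.35)
})

test_that("detection log generator produces the planted behaviours", {
  # resident detected every day -> RI 1 downstream
  dl <- gen_detection_log(sim_config(seed = 5, n_resident = 2,
                                     n_transient = 0, study_days = 60,
                                     p_day_resident = 1, p_hour = 1))
  expect_equal(residency_index(dl, "tag01"), 1.0)
  expect_identical(
    gen_detection_log(sim_config(seed = 5, n_resident = 2, n_transient = 0,
                                 study_days = 60, p_day_resident = 1,
                                 p_hour = 1))$events, dl$events)
  # diel amplitude 0: hourly detection proportions flat within binomial error
  hrs <- as.integer(format(dl$events$timestamp, "%H", tz = "UTC"))
  tab <- table(factor(hrs, levels = 0:23))
  expect_lt((max(tab) - min(tab)) / mean(tab), 0.2)
  expect_error(gen_detection_log(
    sim_config(seed = 1, receivers = data.frame(receiver_id = character(),
                                                seamount_id = character()))),
    "empty receiver")
})

test_that("transient departure day drives the downstream residency index", {
  # plant a known departure by setting an (effectively) deterministic
  # exponential: check RI ~= (departure - 1) / window
  dl <- gen_detection_log(sim_config(seed = 9, n_resident = 0,
                                     n_transient = 6, study_days = 300,
                                     departure_mean = 30, p_hour = 0.8))
  for (i in seq_len(6)) {
    tg <- dl$truth$tag_id[i]
    dep <- dl$truth$departure_day[i]
    ri <- residency_index(dl, tg)
    if (is.na(ri)) next  # departed before 2 consecutive days
    days_detected <- dep - 1
    expect_lt(abs(ri - days_detected / 300), 0.02)
  }
})

test_that("track generator is seeded and attraction produces homing", {
  cfg <- sim_config(seed = 21, n = 2, duration_steps = 40)
  t1 <- gen_tracks(cfg, attraction = 0)
  t2 <- gen_tracks(cfg, attraction = 0)
  expect_identical(t1$tracks, t2$tracks)
  expect_error(gen_tracks(sim_config(seed = 1, step_scale = -2)), "positive")

  # unbiased walks disperse; strong attraction keeps endpoints near summit
  free <- gen_tracks(sim_config(seed = 22, n = 40, duration_steps = 60),
                     attraction = 0)
  home <- gen_tracks(sim_config(seed = 23, n = 40, duration_steps = 60),
                     attraction = 5)
  end_d <- function(ts) vapply(ts$tracks, function(tr)
    haversine(tr$lon[nrow(tr)], tr$lat[nrow(tr)],
              ts$summit[1], ts$summit[2]), numeric(1))
  expect_lt(median(end_d(home)), 0.1 * median(end_d(free)))
})

test_that("unbiased walk displacement grows with duration", {
  short <- gen_tracks(sim_config(seed = 24, n = 60, duration_steps = 20))
  long <- gen_tracks(sim_config(seed = 25, n = 60, duration_steps = 120))
  end_d <- function(ts) vapply(ts$tracks, function(tr)
    haversine(tr$lon[nrow(tr)], tr$lat[nrow(tr)],
              ts$summit[1], ts$summit[2]), numeric(1))
  expect_gt(mean(end_d(long)), mean(end_d(short)))
})

test_that("environment generator plants recoverable oceanographic truth", {
  env <- gen_environment(sim_config(seed = 4, n_scenes = 2, tide_days = 30,
                                    dcm_depth = 100, mld = 65))
  # DCM planted at 100 m recovered within one depth step
  dcm <- extract_dcm(env$ctd[[1]])
  expect_lt(abs(dcm$depth - 100), 2 + 1e-9)
  # MLD step at 65 m recovered within a few steps (gradual onset)
  mld <- extract_mld(env$ctd[[1]])
  expect_lt(abs(mld$depth - 65), 6 + 1e-9)
  expect_error(gen_environment(sim_config(seed = 1, cloud_frac = 1.2)),
               "cloud fraction")
  # scene cloud fraction close to configured
  expect_lt(abs(mean(env$scenes[[1]]$cloud) - 0.2), 0.05)
  # range-test truth: analytic 5% point of the logistic
  expect_equal(env$truth$range_p05_m,
               env$truth$range_midpoint_m +
                 env$truth$range_scale_m * log(0.95 / 0.05))
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(seed = 99, n = 50, theta = 2.5, design = "stations")
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$theta, 2.5)
  expect_identical(
    gen_radial_survey(cfg2, enrichment_kernel(1, 2, 5), "nb"),
    gen_radial_survey(cfg, enrichment_kernel(1, 2, 5), "nb"))
})
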