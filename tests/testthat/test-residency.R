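events_from_days <- function(days, tag = "a", receiver = "G1",
                             seamount = "grattan", hour = 12) {
  data.frame(tag_id = tag, receiver_id = receiver, seamount_id = seamount,
             timestamp = as.POSIXct("2017-06-01", tz = "UTC") +
               (days - 1) * 86400 + hour * 3600)
}

test_that("track start requires two consecutive detection days", {
  ev <- events_from_days(c(3, 4, 9))
  expect_equal(track_start(ev, "a"), as.Date("2017-06-03"))
  ev2 <- events_from_days(c(2, 5, 8))
  expect_true(is.na(track_start(ev2, "a")))
  ev3 <- events_from_days(1:30)
  expect_equal(track_start(ev3, "a"), as.Date("2017-06-01"))
})

test_that("residency index counts detection days over the window", {
  ev <- events_from_days(1:300)
  expect_equal(residency_index(ev, "a",
                               window = c("2017-06-01", "2018-03-27")),
               1.0)
  # 30 of 300 days
  ev2 <- events_from_days(1:30)
  win <- c(as.Date("2017-06-01"), as.Date("2017-06-01") + 299)
  expect_equal(residency_index(ev2, "a", window = win), 0.1)
  # additivity of disjoint detection-day sets
  evA <- events_from_days(1:10)
  evB <- events_from_days(101:120)
  both <- rbind(evA, evB)
  expect_equal(residency_index(both, "a", window = win),
               residency_index(evA, "a", window = win) +
                 residency_index(evB, "a", window = win))
  expect_error(residency_index(ev, "a",
                               window = c("2018-01-01", "2017-01-01")),
               "empty")
})

test_that("residency periods are maximal runs of at least 14 days", {
  expect_equal(nrow(residency_periods(events_from_days(1:20), "a")), 1)
  expect_equal(nrow(residency_periods(events_from_days(1:13), "a")), 0)
  # runs of 15, gap, 14 -> two periods
  ev <- events_from_days(c(1:15, 20:33))
  rp <- residency_periods(ev, "a")
  expect_equal(nrow(rp), 2)
  expect_equal(rp$length, c(15, 14))
})

test_that("attrition curve reflects departures", {
  # all residents: flat at 1
  res <- rbind(events_from_days(1:60, "a"), events_from_days(1:60, "b"))
  ac <- attrition_curve(res, study_days = 60)
  expect_true(all(ac$prop == 1))
  # biphasic mixture: half leave by day 90 -> curve stabilizes near 0.5
  dl <- gen_detection_log(sim_config(seed = 33, n_resident = 6,
                                     n_transient = 6, study_days = 250,
                                     departure_mean = 30,
                                     p_day_resident = 0.98))
  ac2 <- attrition_curve(dl)
  late <- ac2$prop[ac2$day > 150]
  expect_lt(abs(mean(late) - 0.5), 0.2)
  expect_true("smooth" %in% names(ac2))
  # single animal: a step function
  expect_warning(ac3 <- attrition_curve(events_from_days(1:10, "solo"),
                                        study_days = 20, smooth = FALSE),
                 "fewer than 2")
  expect_true(all(ac3$prop %in% c(0, 1)))
  expect_true(all(diff(ac3$prop) <= 0))
})

test_that("diel profile recovers planted nocturnal absence and stays flat
           otherwise", {
  # silky-like: detections suppressed at night
  dl <- gen_detection_log(sim_config(seed = 34, n_resident = 6,
                                     n_transient = 0, study_days = 80,
                                     diel_amplitude = 0.9,
                                     diel_peak_hour = 12, p_hour = 0.4))
  dp <- diel_profile(dl)
  curve <- dp$curve
  night <- curve$ri[curve$hour < 4 | curve$hour > 20]
  day <- curve$ri[curve$hour > 8 & curve$hour < 16]
  expect_gt(mean(day), mean(night) * 1.5)
  # cyclic constraint: value at hour 0 equals hour 24
  expect_equal(curve$ri[curve$hour == 0], curve$ri[curve$hour == 24],
               tolerance = 1e-8)
  # flat behaviour: fitted curve nearly constant
  dl0 <- gen_detection_log(sim_config(seed = 35, n_resident = 6,
                                      n_transient = 0, study_days = 80,
                                      diel_amplitude = 0, p_hour = 0.4))
  dp0 <- diel_profile(dl0)
  expect_lt(diff(range(dp0$curve$ri)), 0.12)
})

test_that("receiver-use proportions normalize per animal and bootstrap a
           planted split", {
  # two receivers with a planted 70/30 split
  set.seed(1)
  mk <- function(tag) {
    n <- 400
    data.frame(tag_id = tag,
               receiver_id = sample(c("G1", "G2"), n, TRUE, c(0.7, 0.3)),
               seamount_id = "grattan",
               timestamp = as.POSIXct("2017-06-01", tz = "UTC") +
                 sort(runif(n, 0, 50 * 86400)))
  }
  ev <- rbind(mk("a"), mk("b"), mk("c"), mk("d"))
  ru <- receiver_use(ev, n_boot = 500, seed = 2)
  P <- attr(ru, "per_animal")
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_lt(abs(ru$mean_prop[ru$receiver_id == "G1"] - 0.7), 0.08)
  expect_lt(abs(ru$mean_prop[ru$receiver_id == "G2"] - 0.3), 0.08)
  expect_true(all(ru$lower <= ru$mean_prop & ru$mean_prop <= ru$upper))
  # deterministic given the seed
  ru2 <- receiver_use(ev, n_boot = 500, seed = 2)
  expect_identical(ru$lower, ru2$lower)
  # single receiver: proportion 1, degenerate interval
  one <- events_from_days(1:20)
  r1 <- receiver_use(one, n_boot = 50, seed = 1)
  expect_equal(r1$mean_prop, 1)
})

test_that("bootstrap receiver-use intervals cover a planted split at
           roughly the nominal rate", {
  cover <- vapply(1:12, function(seed) {
    set.seed(seed + 50)
    ev <- do.call(rbind, lapply(letters[1:8], function(tg) {
      n <- 150
      data.frame(tag_id = tg,
                 receiver_id = sample(c("G1", "G2"), n, TRUE, c(0.7, 0.3)),
                 seamount_id = "grattan",
                 timestamp = as.POSIXct("2017-06-01", tz = "UTC") +
                   sort(runif(n, 0, 30 * 86400)))
    }))
    ru <- receiver_use(ev, n_boot = 300, seed = seed)
    g1 <- ru[ru$receiver_id == "G1", ]
    g1$lower <= 0.7 && 0.7 <= g1$upper
  }, logical(1))
  expect_gte(mean(cover), 0.75)
})

test_that("exact k-medoids equals brute-force enumeration on random
           small inputs", {
  # the silky-shark pattern: clear low/high residency groups
  cl <- cluster_ri(c(0.1, 0.2, 0.9, 1.0), k = 2)
  expect_equal(cl$labels, c(1, 1, 2, 2))
  expect_equal(cl$medoids, c(0.1, 0.9))  # either member ties; lowest index

  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    x <- round(runif(n), 3)
    k <- sample(2:3, 1)
    ours <- cluster_ri(x, k = k)
    oracle <- brute_pam(x, k = k)
    expect_equal(ours$cost, oracle$cost, tolerance = 1e-12)
  }
  # all-equal values: deterministic lowest-index tie-break
  tie <- cluster_ri(rep(0.5, 6), k = 2)
  expect_equal(tie$medoid_idx, c(1, 2))
  expect_error(cluster_ri(c(0.1, 0.2), k = 3), "exceeds")
})

test_that("BUILD+SWAP matches enumeration on larger 1-D problems", {
  set.seed(78)
  x <- c(rnorm(20, 0.2, 0.05), rnorm(20, 0.8, 0.05))
  big <- cluster_ri(x, k = 2, exact_limit = 10)  # force BUILD+SWAP
  ref <- cluster_ri(x, k = 2)                    # exact
  expect_false(big$exact)
  expect_equal(big$cost, ref$cost, tolerance = 1e-12)
})

test_that("inter-seamount moves count transitions and switchers", {
  ev <- rbind(
    events_from_days(1:2, "a", "G1", "grattan"),
    events_from_days(3:4, "a", "Y1", "young"),
    events_from_days(5, "a", "G1", "grattan"),
    events_from_days(1:5, "b", "G1", "grattan"))
  mv <- inter_seamount_moves(ev)
  expect_equal(mv$per_animal$n_moves[mv$per_animal$tag_id == "a"], 2)
  expect_equal(mv$per_animal$n_moves[mv$per_animal$tag_id == "b"], 0)
  expect_equal(mv$n_switchers, 1)
  expect_equal(mv$pct_switchers, 50)
  # 5 switchers of 14 -> 36% when rounded
  pa <- data.frame(tag_id = letters[1:14],
                   n_moves = c(rep(1, 5), rep(0, 9)))
  expect_equal(round(100 * mean(pa$n_moves > 0)), 36)
  # unmapped receivers rejected
  bad <- ev; bad$seamount_id[1] <- NA
  expect_error(inter_seamount_moves(bad), "unmapped")
})

test_that("AMDR recovers the analytic 5% point of a logistic range test", {
  est <- vapply(1:10, function(seed) {
    env <- gen_environment(sim_config(seed = 1100 + seed))
    amdr(env$range_test)$amdr_m
  }, numeric(1))
  truth <- 600 + 81 * log(0.95 / 0.05)  # ~839 m
  expect_lt(abs(median(est) - truth) / truth, 0.1)
  # monotonicity: steeper decay -> smaller AMDR
  env_steep <- gen_environment(sim_config(seed = 1200,
                                          range_scale_m = 40))
  expect_lt(amdr(env_steep$range_test)$amdr_m, median(est))
  # perfect detection: censored at the maximum tested distance
  perfect <- env_steep$range_test
  perfect$received <- perfect$expected
  out <- amdr(perfect)
  expect_true(out$censored)
  expect_equal(out$amdr_m, max(perfect$distance_m))
})

test_that("the residency GLM detects planted species gaps and respects
           the null", {
  # planted gap like the observed species means (0.97 vs 0.68)
  power <- vapply(1:10, function(seed) {
    set.seed(seed + 900)
    ri <- c(pmin(rbeta(15, 20, 0.8), 1), rbeta(14, 4, 1.8))
    rec <- data.frame(ri = ri,
                      species = rep(c("galapagos", "silky"), c(15, 14)),
                      n_days = 595)
    out <- compare_ri_glm(rec, "species")
    out$anova[["Pr(>F)"]][2] < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.9)
  # identical distributions: near-nominal type-I rate
  t1 <- vapply(1:30, function(seed) {
    set.seed(seed + 950)
    rec <- data.frame(ri = rbeta(30, 2, 1),
                      species = rep(c("s1", "s2"), 15), n_days = 595)
    compare_ri_glm(rec, "species")$anova[["Pr(>F)"]][2] < 0.05
  }, logical(1))
  expect_lte(mean(t1), 0.2)
  # single level rejected
  expect_error(compare_ri_glm(data.frame(ri = runif(5), species = "s"),
                              "species"), "fewer than 2")
})
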