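#' Generate a synthetic acoustic detection log
#'
#' Simulates time-stamped detections of tagged animals on named receivers
#' over a study period.  Animals follow one of two behaviour profiles:
#' "residents" remain available for detection throughout the study with a
#' high daily detection probability, while "transients" depart permanently
#' after an exponentially distributed number of days.  Within presence
#' days, detections occur in hourly bins with a probability modulated by a
#' diel cycle (cosine in local hour), and each detection is assigned to a
#' receiver according to per-animal receiver-use weights.  Animals can
#' switch between seamounts between days.  Ground-truth labels (behaviour,
#' departure day, diel amplitude) are retained alongside the log.
#'
#' Configuration fields (defaults): `n_resident` (7), `n_transient` (7),
#' `study_days` (595), `p_hour` (0.25, hourly detection probability at the
#' diel mean), `p_day_resident` (0.95, probability a resident is on the
#' array on a given day), `departure_mean` (60 days), `diel_amplitude` (0,
#' in \[0, 1\]; 1 suppresses detection entirely at the trough),
#' `diel_peak_hour` (12, local hour of maximum detectability),
#' `local_offset` (0, hours added to UTC to get local time),
#' `switch_prob` (0.01 per day), `receivers` (7 per seamount on
#' `"grattan"` and `"young"`), `species` (`"silky"`).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"detection_log"` with elements `events` (data
#'   frame: `tag_id`, `receiver_id`, `seamount_id`, `timestamp` in POSIXct
#'   UTC) and `truth` (per-animal data frame with behaviour labels,
#'   `release_day`, `departure_day`, `species`).
#' @export
gen_detection_log <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_res <- cfg_get(cfg, "n_resident", 7L)
  n_tra <- cfg_get(cfg, "n_transient", 7L)
  study_days <- cfg_get(cfg, "study_days", 595L)
  p_hour <- cfg_get(cfg, "p_hour", 0.25)
  p_day_res <- cfg_get(cfg, "p_day_resident", 0.95)
  dep_mean <- cfg_get(cfg, "departure_mean", 60)
  amp <- cfg_get(cfg, "diel_amplitude", 0)
  peak <- cfg_get(cfg, "diel_peak_hour", 12)
  offset <- cfg_get(cfg, "local_offset", 0)
  switch_prob <- cfg_get(cfg, "switch_prob", 0.01)
  receivers <- cfg_get(cfg, "receivers", {
    data.frame(receiver_id = c(paste0("G", 1:7), paste0("Y", 1:7)),
               seamount_id = rep(c("grattan", "young"), each = 7))
  })
  species <- cfg_get(cfg, "species", "silky")
  if (nrow(receivers) == 0) stop("empty receiver set", call. = FALSE)
  stopifnot(amp >= 0, amp <= 1, p_hour >= 0, p_hour <= 1)

  n_animals <- n_res + n_tra
  with_seed(cfg$seed, {
    truth <- data.frame(
      tag_id = sprintf("tag%02d", seq_len(n_animals)),
      species = rep_len(species, n_animals),
      behaviour = rep(c("resident", "transient"), c(n_res, n_tra)),
      release_day = 1L,
      departure_day = NA_real_)
    truth$departure_day[truth$behaviour == "transient"] <-
      pmax(2, ceiling(rexp(n_tra, 1 / dep_mean)))
    truth$diel_amplitude <- amp

    # per-animal receiver-use weights on its current seamount
    seamounts <- unique(receivers$seamount_id)
    ev <- vector("list", n_animals)
    for (i in seq_len(n_animals)) {
      cur_sm <- sample(seamounts, 1)
      dep <- truth$departure_day[i]
      rows <- list(); r <- 0L
      use_w <- lapply(seamounts, function(sm) {
        w <- rexp(sum(receivers$seamount_id == sm)); w / sum(w)
      })
      names(use_w) <- seamounts
      for (day in seq_len(study_days)) {
        if (!is.na(dep) && day >= dep) break
        if (length(seamounts) > 1 && runif(1) < switch_prob)
          cur_sm <- sample(setdiff(seamounts, cur_sm), 1)
        present <- truth$behaviour[i] == "transient" || runif(1) < p_day_res
        if (!present) next
        hours <- 0:23
        local_hour <- (hours + offset) %% 24
        p <- p_hour * (1 + amp * cos(2 * pi * (local_hour - peak) / 24))
        p <- pmin(pmax(p, 0), 1)
        det <- runif(24) < p
        if (!any(det)) next
        rec_pool <- receivers$receiver_id[receivers$seamount_id == cur_sm]
        for (h in hours[det]) {
          r <- r + 1L
          rows[[r]] <- data.frame(
            tag_id = truth$tag_id[i],
            receiver_id = sample(rec_pool, 1, prob = use_w[[cur_sm]]),
            day = day, hour = h)
        }
      }
      ev[[i]] <- if (r > 0) do.call(rbind, rows) else NULL
    }
    events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
    if (is.null(events)) {
      events <- data.frame(tag_id = character(), receiver_id = character(),
                           seamount_id = character(),
                           timestamp = as.POSIXct(character(), tz = "UTC"))
    } else {
      events$seamount_id <- receivers$seamount_id[
        match(events$receiver_id, receivers$receiver_id)]
      origin <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
      events$timestamp <- origin + (events$day - 1) * 86400 +
        events$hour * 3600 + floor(runif(nrow(events), 0, 3600))
      events <- events[order(events$tag_id, events$timestamp),
                       c("tag_id", "receiver_id", "seamount_id", "timestamp")]
      rownames(events) <- NULL
    }
    out <- list(events = events, truth = truth,
                study_days = study_days,
                study_start = as.Date("2017-06-01"), seed = cfg$seed)
    class(out) <- "detection_log"
    out
  })
}

#' @export
print.detection_log <- function(x, ...) {
  cat("Synthetic detection log:", nrow(x$events), "detections,",
      nrow(x$truth), "animals,", x$study_days, "days\n")
  invisible(x)
}

#' Generate synthetic animal tracks
#'
#' Simulates position time series at 12-h intervals as correlated random
#' walks with gamma-distributed step lengths and wrapped-Cauchy turning
#' angles.  With `attraction = 0` the walk is unbiased; with
#' `attraction > 0` each step's heading is pulled toward the summit
#' coordinate with weight `attraction / (1 + attraction)`, producing
#' site-attached tracks for power analyses of the fidelity test.
#'
#' Configuration fields (defaults): `n` tracks (1), `duration_steps` (60,
#' i.e. 30 days), `step_shape` (2) and `step_scale` (12) for gamma step
#' lengths in km per 12 h, `turn_rho` (0.7, wrapped-Cauchy concentration),
#' `start` (`c(lon, lat)`, default the summit), `summit`
#' (default `c(-14.4, -8.4)`).
#'
#' @param cfg A [sim_config()].
#' @param attraction Dimensionless attraction strength >= 0.
#' @return A list of class `"track_set"`: `tracks` (list of data frames
#'   with `lon`, `lat`, `timestamp`), `summit`, `attraction`, `seed`.
#' @export
gen_tracks <- function(cfg, attraction = 0) {
  stopifnot(inherits(cfg, "sim_config"), attraction >= 0)
  n_tracks <- cfg_get(cfg, "n", 1L)
  steps <- cfg_get(cfg, "duration_steps", 60L)
  shape <- cfg_get(cfg, "step_shape", 2)
  scale <- cfg_get(cfg, "step_scale", 12)
  rho <- cfg_get(cfg, "turn_rho", 0.7)
  summit <- cfg_get(cfg, "summit", c(-14.4, -8.4))
  start <- cfg_get(cfg, "start", summit)
  if (scale <= 0 || shape <= 0) stop("non-positive step scale", call. = FALSE)
  stopifnot(rho >= 0, rho < 1)

  with_seed(cfg$seed, {
    origin <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
    a_w <- attraction / (1 + attraction)
    tracks <- lapply(seq_len(n_tracks), function(i) {
      lon <- numeric(steps + 1); lat <- numeric(steps + 1)
      lon[1] <- start[1]; lat[1] <- start[2]
      heading <- runif(1, -pi, pi)
      for (s in seq_len(steps)) {
        heading <- heading + rwrappedcauchy(1, rho)
        if (a_w > 0) {
          b <- bearing_rad(lon[s], lat[s], summit[1], summit[2])
          heading <- atan2((1 - a_w) * sin(heading) + a_w * sin(b),
                           (1 - a_w) * cos(heading) + a_w * cos(b))
        }
        len <- rgamma(1, shape = shape, scale = scale)
        p <- step_destination(lon[s], lat[s], heading, len)
        lon[s + 1] <- p[1]; lat[s + 1] <- p[2]
      }
      data.frame(lon = lon, lat = lat,
                 timestamp = origin + (0:steps) * 43200)
    })
    out <- list(tracks = tracks, summit = summit, attraction = attraction,
                seed = cfg$seed)
    class(out) <- "track_set"
    out
  })
}

# wrapped-Cauchy deviates centred on 0 with concentration rho
rwrappedcauchy <- function(n, rho) {
  if (rho == 0) return(runif(n, -pi, pi))
  u <- runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

# initial bearing (radians, clockwise from north) from p1 to p2
bearing_rad <- function(lon1, lat1, lon2, lat2) {
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) * pi / 180
}

# move `km` on heading `theta` (radians from north) in the local tangent
# plane; adequate at the few-hundred-km scales simulated here
step_destination <- function(lon, lat, theta, km) {
  dlat <- (km / 111.19493) * cos(theta)
  dlon <- (km / 111.19493) * sin(theta) / cos(lat * pi / 180)
  lon2 <- lon + dlon
  lon2 <- ((lon2 + 180) %% 360) - 180
  c(lon2, pmin(pmax(lat + dlat, -90), 90))
}
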