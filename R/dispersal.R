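#' Great-circle distance
#'
#' Haversine great-circle distance on a sphere of radius 6371 km
#' (vectorized, via \pkg{geosphere}).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine(0, 0, 0, 1)  # one degree of latitude ~= 111.195 km
#' @export
haversine <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

# all-pairs distances between two point sets (km), as a matrix
outer_haversine <- function(lon1, lat1, lon2, lat2) {
  t(vapply(seq_along(lon1), function(i)
    haversine(lon1[i], lat1[i], lon2, lat2), numeric(length(lon2))))
}

#' Empirical movement parameters of a track
#'
#' Extracts the step-length (km per interval) and turning-angle (radians)
#' samples of an observed track: steps are successive great-circle
#' distances, turns are signed changes in bearing wrapped to
#' \eqn{(-\pi, \pi]}.  These empirical samples are resampled with
#' replacement by [simulate_crw()], so the null walks share the observed
#' track's movement distributions without any parametric assumption.
#'
#' @param track Data frame with `lon`, `lat`, `timestamp` (strictly
#'   increasing), at least 3 positions.
#' @return A list of class `"movement_params"`: `steps` (n-1 values),
#'   `turns` (n-2 values), `duration_steps`, `start` (`c(lon, lat)`).
#' @export
fit_movement_params <- function(track) {
  stopifnot(all(c("lon", "lat") %in% names(track)), nrow(track) >= 3)
  if ("timestamp" %in% names(track)) {
    if (any(duplicated(track$timestamp)))
      stop("duplicate timestamps", call. = FALSE)
    track <- track[order(track$timestamp), ]
  }
  n <- nrow(track)
  steps <- haversine(track$lon[-n], track$lat[-n],
                     track$lon[-1], track$lat[-1])
  brg <- bearing_rad(track$lon[-n], track$lat[-n],
                     track$lon[-1], track$lat[-1])
  turns <- diff(brg)
  turns <- ((turns + pi) %% (2 * pi)) - pi
  turns[turns == -pi] <- pi
  out <- list(steps = steps, turns = turns, duration_steps = n - 1L,
              start = c(track$lon[1], track$lat[1]))
  class(out) <- "movement_params"
  out
}

#' Simulate correlated random walks
#'
#' Simulates `n` correlated random walks by resampling the observed step
#' lengths and turning angles with replacement, with uniform random
#' initial headings, starting from `start` and propagated on the sphere
#' with local-tangent-plane steps (adequate at the few-hundred-km scales
#' involved).  Duration equals the observed track's number of steps
#' unless overridden.
#'
#' @param params A [fit_movement_params()] object (or a list with `steps`
#'   and `turns`).
#' @param start `c(lon, lat)` start position (defaults to the track's).
#' @param n Number of walks (default 10000).
#' @param seed Optional RNG seed.
#' @param duration_steps Number of steps per walk.
#' @return A list of class `"crw_sims"`: `final` (n x 2 matrix of
#'   lon/lat), `lon`, `lat` (n x (steps+1) position matrices), `n`,
#'   `seed`.
#' @export
simulate_crw <- function(params, start = NULL, n = 10000, seed = NULL,
                         duration_steps = NULL) {
  if (length(params$steps) == 0) stop("empty movement parameters",
                                      call. = FALSE)
  start <- start %||% params$start
  steps <- duration_steps %||% params$duration_steps
  with_seed(seed, {
    lon <- matrix(start[1], n, steps + 1)
    lat <- matrix(start[2], n, steps + 1)
    heading <- runif(n, -pi, pi)
    for (s in seq_len(steps)) {
      turn <- if (s == 1) 0 else sample(params$turns, n, replace = TRUE)
      heading <- heading + turn
      len <- sample(params$steps, n, replace = TRUE)
      dlat <- (len / 111.19493) * cos(heading)
      dlon <- (len / 111.19493) * sin(heading) / cos(lat[, s] * pi / 180)
      lon[, s + 1] <- ((lon[, s] + dlon + 180) %% 360) - 180
      lat[, s + 1] <- pmin(pmax(lat[, s] + dlat, -90), 90)
    }
    out <- list(final = cbind(lon = lon[, steps + 1],
                              lat = lat[, steps + 1]),
                lon = lon, lat = lat, n = n, seed = seed)
    class(out) <- "crw_sims"
    out
  })
}

#' Correlated-random-walk test of site fidelity
#'
#' Tests the null hypothesis that an animal shows no site fidelity: the
#' observed track's movement parameters (step-length and turning-angle
#' distributions) are used to simulate `n` correlated random walks of the
#' same duration from the tagging location, and the one-sided p-value is
#' the proportion of simulations ending at least as close to the summit
#' as the observed final position (ties counted as closer, which is
#' conservative).  Small p indicates the animal ended nearer the seamount
#' than random dispersal predicts.  Per-day distance quantile curves
#' (isopleths) describe how far a randomly dispersing animal would be on
#' each relative tracking day.
#'
#' @param track Data frame with `lon`, `lat` (and `timestamp`).
#' @param summit `c(lon, lat)` of the tagging seamount.
#' @param n Number of simulated walks (default 10000; < 100 triggers a
#'   p-resolution warning).
#' @param seed Optional RNG seed.
#' @param isopleth_p Probability levels of the distance isopleths.
#' @return A list of class `"crw_fidelity"`: `p_value`, `observed_km`
#'   (final distance to summit), `isopleths` (data frame `day`, one
#'   column per level), `n_sims`, `seed`.
#' @export
fidelity_test <- function(track, summit, n = 10000, seed = NULL,
                          isopleth_p = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (n < 100) warning("fewer than 100 simulations: p resolution is coarse")
  params <- fit_movement_params(track)
  sims <- simulate_crw(params, start = params$start, n = n, seed = seed)
  obs <- haversine(track$lon[nrow(track)], track$lat[nrow(track)],
                   summit[1], summit[2])
  sim_final <- haversine(sims$final[, 1], sims$final[, 2],
                         summit[1], summit[2])
  p <- mean(sim_final <= obs)
  # distance-to-summit quantiles per relative day (2 steps per day)
  n_steps <- ncol(sims$lon) - 1
  days <- seq_len(max(1, floor(n_steps / 2)))
  day_cols <- pmin(1 + 2 * days, n_steps + 1)
  iso <- vapply(day_cols, function(cc) {
    d <- haversine(sims$lon[, cc], sims$lat[, cc], summit[1], summit[2])
    quantile(d, probs = isopleth_p)
  }, numeric(length(isopleth_p)))
  isopleths <- data.frame(day = days, t(iso))
  names(isopleths) <- c("day", paste0("p", isopleth_p))
  out <- list(p_value = p, observed_km = obs, isopleths = isopleths,
              n_sims = n, seed = seed)
  class(out) <- "crw_fidelity"
  out
}

#' @export
print.crw_fidelity <- function(x, ...) {
  cat("CRW site-fidelity test:", x$n_sims, "simulations\n")
  cat("  observed final distance to summit:", signif(x$observed_km, 4),
      "km\n")
  cat("  p (null: no site fidelity) =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Distance-from-seamount series of a track
#'
#' Great-circle distance from the tagging seamount at each track point,
#' with percentile confidence intervals across positional posterior draws
#' when supplied.
#'
#' @param track Data frame with `lon`, `lat` (the posterior mean track).
#' @param summit `c(lon, lat)`.
#' @param draws Optional list with `lon` and `lat` matrices
#'   (points x draws) of positional posterior samples.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `point`, `distance_km` and (with draws)
#'   `lower`, `upper`.
#' @export
distance_series <- function(track, summit, draws = NULL, level = 0.95) {
  d <- haversine(track$lon, track$lat, summit[1], summit[2])
  out <- data.frame(point = seq_along(d), distance_km = d)
  if (!is.null(draws)) {
    stopifnot(is.matrix(draws$lon), is.matrix(draws$lat),
              nrow(draws$lon) == nrow(track))
    alpha <- (1 - level) / 2
    qs <- vapply(seq_len(nrow(track)), function(i) {
      dd <- haversine(draws$lon[i, ], draws$lat[i, ], summit[1], summit[2])
      quantile(dd, c(alpha, 1 - alpha))
    }, numeric(2))
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  }
  out
}

#' Merge per-animal utilisation densities
#'
#' Combines individual space-use density surfaces on a common grid into a
#' population utilisation distribution as a weighted average giving
#' greater influence to animals with longer deployments:
#' \eqn{UD = \sum_i w_i f_i} with \eqn{w_i = deployment_i / \sum_j
#' deployment_j}, renormalized to unit mass.
#'
#' @param grids List of matrices (or a 3-D array) of per-animal densities
#'   on one grid; each is normalized internally.
#' @param deployment_days Numeric vector of deployment lengths.
#' @return A list of class `"ud_grid"`: `density` (matrix summing to 1),
#'   `weights`.
#' @export
merge_uds <- function(grids, deployment_days) {
  if (is.array(grids) && length(dim(grids)) == 3)
    grids <- lapply(seq_len(dim(grids)[3]), function(i) grids[, , i])
  stopifnot(length(grids) == length(deployment_days),
            all(deployment_days > 0))
  dims <- lapply(grids, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("grid mismatch across animals", call. = FALSE)
  w <- deployment_days / sum(deployment_days)
  ud <- Reduce(`+`, Map(function(g, wi) wi * g / sum(g), grids, w))
  ud <- ud / sum(ud)
  out <- list(density = ud, weights = w)
  class(out) <- "ud_grid"
  out
}

#' Volume contour of a utilisation distribution
#'
#' The smallest set of grid cells, chosen in order of decreasing density,
#' whose cumulative mass reaches the level `q` -- the standard volume
#' contour enclosing a given proportion of the space-use probability.
#' Masks are nested: `volume_contour(ud, 0.5)` is a subset of
#' `volume_contour(ud, 0.95)`.
#'
#' @param ud A [merge_uds()] result or a density matrix.
#' @param q Mass level in (0, 1).
#' @return Logical matrix marking the contour cells.
#' @export
volume_contour <- function(ud, q) {
  if (inherits(ud, "ud_grid")) ud <- ud$density
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  dens <- ud / sum(ud)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  need <- seq_along(cum) <= which(cum >= q - 1e-12)[1]
  mask <- matrix(FALSE, nrow(dens), ncol(dens))
  mask[ord[need]] <- TRUE
  mask
}
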