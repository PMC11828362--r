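#' Deep chlorophyll maximum of a CTD profile
#'
#' Returns the depth and concentration of the deep chlorophyll maximum
#' (DCM): the global chlorophyll maximum below a near-surface exclusion
#' cap (default 5 m, to avoid surface fluorescence artefacts).  A profile
#' whose maximum sits at the cap is flagged `"surface-type"`; ties are
#' resolved to the shallower depth and flagged.
#'
#' @param profile Data frame with `depth` (m, strictly increasing) and
#'   `chlorophyll` columns.
#' @param exclude_above Surface exclusion cap in m (default 5).
#' @return A list with `depth`, `concentration`, `surface_type`, `tie`.
#' @export
extract_dcm <- function(profile, exclude_above = 5) {
  stopifnot(all(c("depth", "chlorophyll") %in% names(profile)))
  if (is.unsorted(profile$depth, strictly = TRUE))
    stop("depths must be strictly increasing", call. = FALSE)
  p <- profile[profile$depth >= exclude_above, , drop = FALSE]
  chl <- p$chlorophyll
  if (all(is.na(chl))) stop("no chlorophyll data", call. = FALSE)
  mx <- max(chl, na.rm = TRUE)
  at <- which(chl == mx)
  list(depth = p$depth[at[1]], concentration = mx,
       surface_type = p$depth[at[1]] <= min(p$depth),
       tie = length(at) > 1)
}

#' Mixed-layer (isothermal-layer) depth of a CTD profile
#'
#' The shallowest depth at which temperature drops more than `delta_t`
#' (default 0.2 degC) below the temperature at a 10-m reference depth --
#' the standard threshold criterion for the surface mixed layer.  A
#' profile isothermal to its full depth returns the maximum depth,
#' flagged.
#'
#' @param profile Data frame with `depth` and `temperature`.
#' @param ref_depth Reference depth in m (default 10).
#' @param delta_t Temperature offset in degC (default 0.2).
#' @return A list with `depth` and `isothermal` flag.
#' @export
extract_mld <- function(profile, ref_depth = 10, delta_t = 0.2) {
  stopifnot(all(c("depth", "temperature") %in% names(profile)))
  if (max(profile$depth) < ref_depth)
    stop("profile shallower than the reference depth", call. = FALSE)
  t_ref <- approx(profile$depth, profile$temperature, xout = ref_depth,
                  rule = 2)$y
  below <- profile$depth >= ref_depth
  cold <- below & (profile$temperature <= t_ref - delta_t)
  if (!any(cold))
    return(list(depth = max(profile$depth), isothermal = TRUE))
  list(depth = min(profile$depth[cold]), isothermal = FALSE)
}

#' Chlorophyll enrichment index of a satellite scene
#'
#' For each unmasked cell, the CEI is the percentage difference between
#' the cell's chlorophyll concentration and the mean of all unmasked cells
#' in a reference annulus 30--90 km away from that cell:
#' \deqn{CEI = 100 (chl - \bar{chl}_{ref}) / \bar{chl}_{ref}.}
#' Scenes with more than `cloud_max` cloud cover are rejected (returning
#' `NULL` with a warning) to avoid artefacts from spatially uneven
#' sampling; cells whose annulus is entirely masked get `NA`.
#'
#' @param scene Data frame with `lon`, `lat`, `chl` and logical `cloud`.
#' @param summit `c(lon, lat)`; carried through to the output for radial
#'   binning.
#' @param annulus Inner and outer annulus radii in km (default
#'   `c(30, 90)`).
#' @param cloud_max Maximum tolerated cloud fraction (default 0.5).
#' @return `scene` with a `cei` column (percent) and a `dist_km` column
#'   (cell distance to the summit), or `NULL` for a rejected scene.
#' @export
compute_cei <- function(scene, summit, annulus = c(30, 90),
                        cloud_max = 0.5) {
  stopifnot(all(c("lon", "lat", "chl", "cloud") %in% names(scene)),
            annulus[2] > annulus[1])
  cf <- mean(scene$cloud)
  if (cf > cloud_max) {
    warning(sprintf("scene rejected: cloud cover %.0f%% exceeds %.0f%%",
                    100 * cf, 100 * cloud_max))
    return(NULL)
  }
  n <- nrow(scene)
  clear <- !scene$cloud
  cei <- rep(NA_real_, n)
  lons <- sort(unique(scene$lon))
  lats <- sort(unique(scene$lat))
  regular <- length(lons) * length(lats) == n &&
    all(abs(diff(diff(lons))) < 1e-9) && all(abs(diff(diff(lats))) < 1e-9)
  if (regular) {
    # regular grid: annulus membership depends (to < 1% at these scales)
    # only on the cell offset, so the reference mean is a convolution
    ord <- order(scene$lat, scene$lon)
    inv <- order(ord)
    nr <- length(lats); ncg <- length(lons)
    km_deg <- pi * 6371 / 180
    dy <- diff(lats)[1] * km_deg
    dx <- diff(lons)[1] * km_deg * cos(mean(lats) * pi / 180)
    off_i <- matrix(rep(-(nr - 1):(nr - 1), 2 * ncg - 1), 2 * nr - 1)
    off_j <- matrix(rep(-(ncg - 1):(ncg - 1), each = 2 * nr - 1),
                    2 * nr - 1)
    dist_off <- sqrt((off_i * dy)^2 + (off_j * dx)^2)
    mask <- dist_off >= annulus[1] & dist_off <= annulus[2]
    chl_m <- matrix(scene$chl[ord], nr, ncg, byrow = TRUE)
    clr_m <- matrix(as.numeric(clear[ord]), nr, ncg, byrow = TRUE)
    ref_sum <- conv2d(chl_m * clr_m, mask)
    ref_cnt <- conv2d(clr_m, mask)
    ref <- ref_sum / ifelse(ref_cnt > 0.5, ref_cnt, NA)
    cei_m <- 100 * (chl_m - ref) / ref
    cei_m[clr_m == 0] <- NA
    cei <- as.numeric(t(cei_m))[inv]
  } else {
    # irregular layout: exact pairwise distances, blocked to bound memory
    block <- 2000L
    for (i0 in seq(1, n, by = block)) {
      idx <- i0:min(i0 + block - 1L, n)
      dm <- outer_haversine(scene$lon[idx], scene$lat[idx],
                            scene$lon, scene$lat)
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (!clear[i]) next
        ring <- clear & dm[j, ] >= annulus[1] & dm[j, ] <= annulus[2]
        if (!any(ring)) next
        ref <- mean(scene$chl[ring])
        cei[i] <- 100 * (scene$chl[i] - ref) / ref
      }
    }
  }
  scene$cei <- cei
  scene$dist_km <- haversine(scene$lon, scene$lat, summit[1], summit[2])
  scene
}

# 2-D convolution with a centred odd-dimension kernel, via FFT; used for
# annulus reference means on regular grids (kernel symmetric, so
# convolution equals correlation)
conv2d <- function(A, K) {
  ar <- nrow(A); ac <- ncol(A); kr <- nrow(K); kc <- ncol(K)
  pr <- ar + kr - 1; pc <- ac + kc - 1
  Ap <- matrix(0, pr, pc); Ap[1:ar, 1:ac] <- A
  Kp <- matrix(0, pr, pc); Kp[1:kr, 1:kc] <- K
  full <- Re(stats::fft(stats::fft(Ap) * stats::fft(Kp),
                        inverse = TRUE)) / (pr * pc)
  cr <- (kr + 1) / 2; cc <- (kc + 1) / 2
  full[cr:(cr + ar - 1), cc:(cc + ac - 1)]
}

#' Mean CEI over a stack of scenes
#'
#' Applies [compute_cei()] to each scene, skipping scenes rejected for
#' cloud cover, and averages per cell over the accepted scenes.
#'
#' @param scenes List of scene data frames sharing one grid.
#' @inheritParams compute_cei
#' @return A data frame with `lon`, `lat`, `cei` (mean percent),
#'   `n_scenes` used per cell, `dist_km`; attribute `n_accepted`.
#' @export
mean_cei <- function(scenes, summit, annulus = c(30, 90), cloud_max = 0.5) {
  res <- lapply(scenes, function(s)
    suppressWarnings(compute_cei(s, summit, annulus, cloud_max)))
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) stop("all scenes rejected for cloud cover", call. = FALSE)
  res <- res[keep]
  mat <- vapply(res, function(s) s$cei, numeric(nrow(res[[1]])))
  mat <- matrix(mat, nrow = nrow(res[[1]]))
  out <- data.frame(lon = res[[1]]$lon, lat = res[[1]]$lat,
                    cei = rowMeans(mat, na.rm = TRUE),
                    n_scenes = rowSums(!is.na(mat)),
                    dist_km = res[[1]]$dist_km)
  out$cei[out$n_scenes == 0] <- NA
  attr(out, "n_accepted") <- length(res)
  out
}

#' Radial bin means of a gridded field
#'
#' Averages cell values in 1-km (by default) distance increments from the
#' seamount summit, the standard reduction that removes spatial
#' autocorrelation in raw raster values before distance-effect modelling.
#' Bins are half-open `[i, i+1)`; empty bins are omitted.
#'
#' @param field Data frame with `lon`, `lat` and a value column.
#' @param summit `c(lon, lat)`.
#' @param value Name of the value column (default `"chl"`).
#' @param bin_km Bin width in km (default 1).
#' @param max_km Optional maximum distance.
#' @return A data frame of class `"radial_survey"` with `distance_km`
#'   (bin midpoint), `response` (bin mean) and `n_cells`; Gaussian-family
#'   input for [distance_gam()].
#' @export
radial_bin_means <- function(field, summit, value = "chl", bin_km = 1,
                             max_km = NULL) {
  stopifnot(value %in% names(field), bin_km > 0)
  d <- haversine(field$lon, field$lat, summit[1], summit[2])
  v <- field[[value]]
  ok <- !is.na(v)
  if (!is.null(max_km)) ok <- ok & d < max_km
  bin <- floor(d[ok] / bin_km)
  mns <- tapply(v[ok], bin, mean)
  cnt <- tapply(v[ok], bin, length)
  out <- data.frame(distance_km = (as.numeric(names(mns)) + 0.5) * bin_km,
                    response = as.numeric(mns),
                    n_cells = as.integer(cnt))
  out <- out[order(out$distance_km), ]
  rownames(out) <- NULL
  class(out) <- c("radial_survey", "data.frame")
  out
}

#' Tidal periodicity of a moored temperature series
#'
#' Detects periodic oscillations indicative of tidally driven mixing:
#' the series is decimated to regular means (default 10-min), de-trended
#' with a loess smoother whose span covers about `span_days` (default 30)
#' days, and a tapered, smoothed periodogram is computed; the dominant
#' period within `period_range` (default 0--26 h) is returned.  Peak
#' detection is invariant to adding any slow trend, which the loess
#' absorbs.
#'
#' @param series Data frame with `time_s` (regular spacing) and a value
#'   column (temperature or current speed).
#' @param value Value column name (default `"temperature"`).
#' @param decimate_s Averaging interval in s before analysis (default 600;
#'   `NULL` keeps the native resolution).
#' @param span_days Loess trend window in days (default 30).
#' @param period_range Period window searched, in hours (default
#'   `c(0, 26)`).
#' @param spans Modified-Daniell smoother spans for
#'   [stats::spectrum()] (default `c(5, 5)`).
#' @param taper Split-cosine taper fraction (default 0.1).
#' @return A list of class `"tidal_spectrum"`: `peak_period_h`, `density`
#'   (data frame `period_h`, `spec` restricted to `period_range`), and the
#'   settings used.
#' @export
tidal_spectrum <- function(series, value = "temperature", decimate_s = 600,
                           span_days = 30, period_range = c(0, 26),
                           spans = c(5, 5), taper = 0.1) {
  stopifnot(value %in% names(series), "time_s" %in% names(series))
  tt <- series$time_s
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("irregular sampling beyond tolerance", call. = FALSE)
  dt <- dts[1]
  x <- series[[value]]
  if (!is.null(decimate_s) && decimate_s > dt) {
    fac <- round(decimate_s / dt)
    grp <- floor(seq_along(x) / fac)
    x <- as.numeric(tapply(x, grp, mean))
    dt <- dt * fac
  }
  n <- length(x)
  dur_days <- n * dt / 86400
  if (dur_days < 10 * period_range[2] / 24)
    stop("series shorter than 10 times the longest period of interest",
         call. = FALSE)
  day <- (seq_len(n) - 1) * dt / 86400
  lo <- loess(x ~ day, span = min(1, span_days / dur_days), degree = 1,
              control = loess.control(surface = "interpolate"))
  detr <- x - fitted(lo)
  sp <- spectrum(ts(detr, deltat = dt / 3600), spans = spans, taper = taper,
                 detrend = TRUE, plot = FALSE)
  period_h <- 1 / sp$freq
  keep <- period_h > period_range[1] & period_h <= period_range[2]
  dens <- data.frame(period_h = period_h[keep], spec = sp$spec[keep])
  out <- list(peak_period_h = dens$period_h[which.max(dens$spec)],
              density = dens,
              settings = list(decimate_s = decimate_s,
                              span_days = span_days, spans = spans,
                              taper = taper, dt_s = dt))
  class(out) <- "tidal_spectrum"
  out
}

#' @export
print.tidal_spectrum <- function(x, ...) {
  cat("Dominant period:", round(x$peak_period_h, 1), "h\n")
  invisible(x)
}

#' @export
plot.tidal_spectrum <- function(x, ...) {
  plot(x$density$period_h, x$density$spec, type = "l",
       xlab = "Period (h)", ylab = "Spectral density", ...)
  abline(v = x$peak_period_h, lty = 2, col = "tomato")
  invisible(x)
}
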