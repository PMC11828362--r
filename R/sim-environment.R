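#' Generate synthetic oceanographic inputs
#'
#' Produces the four environmental data streams used by the oceanography
#' module, each with planted ground truth recorded in the output:
#'
#' * **Chlorophyll scenes**: daily gridded surface-chlorophyll fields
#'   (cell size ~4 km) composed of a latitudinal gradient, spatially
#'   correlated noise, an optional Gaussian summit bump and a random cloud
#'   mask.
#' * **CTD profiles**: depth/temperature/chlorophyll triples with a
#'   two-layer temperature structure (isothermal surface layer above a
#'   thermocline) and a Gaussian deep chlorophyll maximum (DCM).
#' * **Tide series**: a long moored-temperature series = slow seasonal
#'   trend + sinusoid at a configurable tidal period + Gaussian noise.
#' * **Range-test series**: Bernoulli detection counts per 180-s bin with
#'   logistic decay of detection probability in distance.
#'
#' Configuration fields (defaults): `n_scenes` (10), `grid_half_km` (130,
#' so a 30--90 km reference annulus is fully sampled for cells within
#' 40 km of the summit),
#' `cell_km` (4), `summit` (`c(-14.4, -8.4)`), `chl_base` (0.03 mg m^-3),
#' `lat_gradient` (1e-4 mg m^-3 per km northward), `summit_bump` (0),
#' `bump_sd_km` (10), `cloud_frac` (0.2), `noise_cor_km` (12),
#' `noise_sd` (0.004); `n_profiles` (12), `profile_depth` (150),
#' `depth_step` (2 m), `mld` (65 m), `dcm_depth` (100 m), `dcm_sd` (15),
#' `dcm_conc` (1), `surface_temp` (26), `thermocline_rate` (0.06 degC/m);
#' `tide_days` (595), `tide_dt_s` (600), `tidal_period_h` (12.4206012, M2),
#' `tide_amp` (0.5), `trend_amp` (2), `tide_noise_sd` (0.5);
#' `range_midpoint_m` (600), `range_scale_m` (81), `range_max_m` (1200),
#' `pings_per_bin` (18), `n_range_sites` (5).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"environment_set"` with elements `scenes` (list
#'   of data frames: `lon`, `lat`, `chl`, `cloud`), `ctd` (list of data
#'   frames: `depth`, `temperature`, `chlorophyll`, plus `distance_km` and
#'   `vessel` attributes), `tide` (data frame `time_s`, `temperature`),
#'   `range_test` (data frame `site`, `distance_m`, `expected`, `received`)
#'   and `truth` (the planted parameters).
#' @export
gen_environment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- function(nm, d) cfg_get(cfg, nm, d)
  cloud_frac <- g("cloud_frac", 0.2)
  if (cloud_frac < 0 || cloud_frac > 1)
    stop("cloud fraction outside [0,1]", call. = FALSE)
  summit <- g("summit", c(-14.4, -8.4))

  with_seed(cfg$seed, {
    ## chlorophyll scenes -------------------------------------------------
    half_km <- g("grid_half_km", 130)
    cell_km <- g("cell_km", 4)
    km_per_deg <- 111.19493
    lat0 <- summit[2]; lon0 <- summit[1]
    dlat <- cell_km / km_per_deg
    dlon <- cell_km / (km_per_deg * cos(lat0 * pi / 180))
    nc <- floor(half_km / cell_km)
    lats <- lat0 + (-nc:nc) * dlat
    lons <- lon0 + (-nc:nc) * dlon
    grid <- expand.grid(lon = lons, lat = lats)
    dist_km <- haversine(grid$lon, grid$lat, lon0, lat0)
    north_km <- (grid$lat - lat0) * km_per_deg
    ncell <- nrow(grid)
    side <- 2 * nc + 1

    chl_base <- g("chl_base", 0.03)
    lat_grad <- g("lat_gradient", 1e-4)  # mg m^-3 per km northward
    bump <- g("summit_bump", 0)
    bump_sd <- g("bump_sd_km", 10)
    noise_sd <- g("noise_sd", 0.004)
    cor_cells <- round(g("noise_cor_km", 12) / cell_km)  # 0 = iid cells
    n_scenes <- g("n_scenes", 10L)

    smooth2d <- function(z, k) {
      # separable moving-average smoother; edge-padded
      kern <- dnorm(seq(-2, 2, length.out = 2 * k + 1))
      kern <- kern / sum(kern)
      sm_rows <- t(apply(z, 1, function(r)
        stats::filter(c(rep(r[1], k), r, rep(r[length(r)], k)), kern)[
          (k + 1):(k + length(r))]))
      apply(sm_rows, 2, function(r)
        stats::filter(c(rep(r[1], k), r, rep(r[length(r)], k)), kern)[
          (k + 1):(k + length(r))])
    }
    scenes <- lapply(seq_len(n_scenes), function(s) {
      noise <- matrix(rnorm(ncell), side, side)
      if (cor_cells >= 1) noise <- smooth2d(noise, cor_cells)
      noise <- noise / sd(noise) * noise_sd
      chl <- chl_base + lat_grad * north_km +
        bump * exp(-dist_km^2 / (2 * bump_sd^2)) + as.vector(noise)
      chl <- pmax(chl, 0)
      cl <- matrix(rnorm(ncell), side, side)
      cl <- smooth2d(cl, max(1, cor_cells))
      cloud <- as.vector(cl) > quantile(as.vector(cl), 1 - cloud_frac)
      data.frame(lon = grid$lon, lat = grid$lat, chl = chl, cloud = cloud)
    })

    ## CTD profiles -------------------------------------------------------
    n_prof <- g("n_profiles", 12L)
    zstep <- g("depth_step", 2)
    zmaxp <- g("profile_depth", 150)
    mld <- g("mld", 65)
    dcm_depth <- g("dcm_depth", 100)
    dcm_sd <- g("dcm_sd", 15)
    dcm_conc <- g("dcm_conc", 1)
    t_surf <- g("surface_temp", 26)
    t_rate <- g("thermocline_rate", 0.06)
    depths <- seq(0, zmaxp, by = zstep)
    prof_dist <- seq(0, 20, length.out = n_prof)
    ctd <- lapply(seq_len(n_prof), function(i) {
      temp <- ifelse(depths <= mld, t_surf,
                     t_surf - t_rate * (depths - mld)) +
        rnorm(length(depths), 0, 0.03)
      chl <- 0.05 + dcm_conc * exp(-(depths - dcm_depth)^2 / (2 * dcm_sd^2)) +
        rnorm(length(depths), 0, 0.02)
      p <- data.frame(depth = depths, temperature = temp,
                      chlorophyll = pmax(chl, 0))
      attr(p, "distance_km") <- prof_dist[i]
      attr(p, "vessel") <- if (i %% 2 == 0) "extractor" else "jcr"
      class(p) <- c("ctd_profile", "data.frame")
      p
    })

    ## tide series ---------------------------------------------------------
    tide_days <- g("tide_days", 595)
    dt_s <- g("tide_dt_s", 600)
    period_h <- g("tidal_period_h", 12.4206012)
    tide_amp <- g("tide_amp", 0.5)
    trend_amp <- g("trend_amp", 2)
    tnoise <- g("tide_noise_sd", 0.5)
    tt <- if (tide_days > 0) seq(0, tide_days * 86400 - dt_s, by = dt_s)
          else numeric(0)
    th <- tt / 3600
    temp <- 15 + trend_amp * sin(2 * pi * th / (24 * 365)) +
      0.3 * sin(2 * pi * th / (24 * 30)) +
      tide_amp * sin(2 * pi * th / period_h) + rnorm(length(tt), 0, tnoise)
    tide <- data.frame(time_s = tt, temperature = temp)
    attr(tide, "dt_s") <- dt_s
    attr(tide, "tidal_period_h") <- period_h
    class(tide) <- c("tide_series", "data.frame")

    ## range-test series ---------------------------------------------------
    mid <- g("range_midpoint_m", 600)
    sc <- g("range_scale_m", 81)
    rmax <- g("range_max_m", 1200)
    pings <- g("pings_per_bin", 18L)
    n_sites <- g("n_range_sites", 5L)
    rt <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
      d <- seq(10, rmax, by = 30) + runif(1, -5, 5)
      d <- pmax(d, 0)
      p <- plogis((mid - d) / sc)
      data.frame(site = paste0("site", s), distance_m = d,
                 expected = pings, received = rbinom(length(d), pings, p))
    }))
    truth <- list(chl_base = chl_base, lat_gradient_per_km = lat_grad,
                  summit_bump = bump, cloud_frac = cloud_frac,
                  mld = mld, dcm_depth = dcm_depth, dcm_conc = dcm_conc,
                  tidal_period_h = period_h,
                  range_midpoint_m = mid, range_scale_m = sc,
                  range_p05_m = mid + sc * log(0.95 / 0.05),
                  summit = summit)
    out <- list(scenes = scenes, ctd = ctd, tide = tide, range_test = rt,
                truth = truth, seed = cfg$seed)
    class(out) <- "environment_set"
    out
  })
}

#' @export
print.environment_set <- function(x, ...) {
  cat("Synthetic environment set:", length(x$scenes), "chlorophyll scenes,",
      length(x$ctd), "CTD profiles,",
      nrow(x$tide), "tide samples,",
      length(unique(x$range_test$site)), "range-test sites\n")
  invisible(x)
}
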