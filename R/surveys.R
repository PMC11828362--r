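#' MaxN: maximum pooled frame count
#'
#' Computes the conservative abundance index used for baited-video sets:
#' the maximum, over time bins, of the number of individuals of a species
#' visible simultaneously.  Because cameras on different rigs of a set are
#' not frame-synchronized, counts are pooled across rigs within alignment
#' bins of `bin_width` seconds (default 1 s) before taking the maximum;
#' `mode = "max-rig"` instead takes the maximum single-rig frame count.
#'
#' @param frames Data frame of frame observations with columns `set_id`,
#'   `rig_id`, `time_bin` (seconds from deployment start), `species`,
#'   `count`.
#' @param species Species to count.
#' @param mode `"sum"` (pool counts across rigs within a bin, default) or
#'   `"max-rig"`.
#' @param bin_width Cross-rig alignment bin width in seconds.
#' @return A single count (0, with a warning, for empty input; 0 for a
#'   species never observed).
#' @examples
#' fr <- data.frame(set_id = 1, rig_id = c(1, 1, 1, 2),
#'                  time_bin = c(0, 10, 20, 10),
#'                  species = "silky", count = c(0, 2, 1, 3))
#' compute_maxn(fr, "silky")  # bin at 10 s pools 2 + 3
#' @export
compute_maxn <- function(frames, species, mode = c("sum", "max-rig"),
                         bin_width = 1) {
  mode <- match.arg(mode)
  if (nrow(frames) == 0) {
    warning("empty frame set; MaxN = 0")
    return(0)
  }
  stopifnot(length(unique(frames$set_id)) == 1, all(frames$count >= 0))
  f <- frames[frames$species == species, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  bin <- floor(f$time_bin / bin_width)
  if (mode == "sum") {
    pooled <- tapply(f$count, bin, sum)
  } else {
    per_rig <- tapply(f$count, list(bin, f$rig_id), sum, default = 0)
    pooled <- apply(per_rig, 1, max)
  }
  max(pooled)
}

#' Maximum combined frame biomass
#'
#' The biomass analogue of MaxN: per alignment bin, individual fork lengths
#' are converted to mass with published weight--length relationships
#' (W = a * FL^b) and summed across individuals and rigs; the maximum bin
#' total is returned.  Individuals lacking a stereo length measurement are
#' assigned the species mean length of the set and flagged with a warning.
#'
#' @param frames Data frame with columns `set_id`, `rig_id`, `time_bin`,
#'   `species`, `fork_length` (m; one row per individual, `NA` when
#'   unmeasured).
#' @param coeffs Data frame of length--weight coefficients with columns
#'   `species`, `a` (mass intercept, kg m^-b) and `b` (allometric
#'   exponent).  A warning is issued for exponents outside \[2.5, 3.5\].
#' @param bin_width Cross-rig alignment bin width in seconds.
#' @return Maximum combined mass in kg (0 for empty input).
#' @export
compute_max_biomass <- function(frames, coeffs, bin_width = 1) {
  if (nrow(frames) == 0) return(0)
  stopifnot(all(c("species", "a", "b") %in% names(coeffs)),
            all(coeffs$a > 0))
  if (any(coeffs$b < 2.5 | coeffs$b > 3.5))
    warning("allometric exponent outside the typical [2.5, 3.5] range")
  missing_sp <- setdiff(unique(frames$species), coeffs$species)
  if (length(missing_sp))
    stop("missing length-weight coefficients for: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  fl <- frames$fork_length
  if (anyNA(fl)) {
    warning(sum(is.na(fl)), " unmeasured individuals assigned the species",
            " mean length of the set")
    for (sp in unique(frames$species[is.na(fl)])) {
      msp <- mean(fl[frames$species == sp], na.rm = TRUE)
      if (is.nan(msp))
        stop("no measured lengths for species '", sp, "'", call. = FALSE)
      fl[is.na(fl) & frames$species == sp] <- msp
    }
  }
  stopifnot(all(fl > 0))
  i <- match(frames$species, coeffs$species)
  mass <- coeffs$a[i] * fl^coeffs$b[i]
  bin <- floor(frames$time_bin / bin_width)
  max(tapply(mass, bin, sum))
}

#' Species richness of a survey set
#'
#' Number of distinct species with at least one individual observed,
#' optionally restricted to species above a minimum trophic level (the
#' "large predator" filter: sharks and teleosts at trophic level > 4).
#'
#' @param frames Frame observations (columns `species`, `count`).
#' @param trophic_levels Optional named vector or data frame
#'   (`species`, `trophic_level`) mapping species to trophic level.
#' @param min_trophic Minimum (exclusive) trophic level; `NULL` disables
#'   filtering.  Species missing from the mapping are excluded with a
#'   warning.
#' @return Integer species count.
#' @export
species_richness <- function(frames, trophic_levels = NULL,
                             min_trophic = NULL) {
  obs <- unique(frames$species[frames$count > 0])
  if (is.null(min_trophic)) return(length(obs))
  if (is.data.frame(trophic_levels))
    trophic_levels <- setNames(trophic_levels$trophic_level,
                               trophic_levels$species)
  unknown <- setdiff(obs, names(trophic_levels))
  if (length(unknown))
    warning("species without trophic level excluded: ",
            paste(unknown, collapse = ", "))
  obs <- intersect(obs, names(trophic_levels))
  sum(trophic_levels[obs] > min_trophic)
}

#' Bin visual-transect sightings into fixed observation intervals
#'
#' Pools time-stamped sightings along a vessel transect into fixed windows
#' (default 300 s, the 5-min observation interval), producing one record
#' per species per interval including explicit zeros.  The record's
#' distance from the summit is that of the interval's midpoint position,
#' obtained by linear interpolation of the logged track.  A partial
#' trailing interval is retained with its own duration.
#'
#' @param sightings Data frame with columns `transect_id`, `time_s`
#'   (seconds from transect start, non-decreasing within transect),
#'   `species`, `count`, `lon`, `lat`.
#' @param summit `c(lon, lat)` of the seamount summit.
#' @param window Interval length in seconds (default 300).
#' @param transect_end Optional named vector of transect durations in
#'   seconds; defaults to the last sighting time per transect.
#' @return A data frame of class `"radial_survey"` with columns
#'   `transect_id`, `interval`, `species`, `response` (pooled count),
#'   `distance_km`, `duration_s`.
#' @export
bin_visual_counts <- function(sightings, summit, window = 300,
                              transect_end = NULL) {
  stopifnot(window > 0, length(summit) == 2)
  out <- lapply(split(sightings, sightings$transect_id), function(tr) {
    if (is.unsorted(tr$time_s))
      stop("non-monotone timestamps in transect ", tr$transect_id[1],
           call. = FALSE)
    end_t <- if (!is.null(transect_end))
      transect_end[[as.character(tr$transect_id[1])]] else max(tr$time_s)
    n_int <- max(1L, ceiling(end_t / window))
    idx <- pmin(floor(tr$time_s / window) + 1L, n_int)
    species <- unique(tr$species)
    mids <- (seq_len(n_int) - 0.5) * window
    mids[n_int] <- (window * (n_int - 1) + min(end_t, window * n_int)) / 2
    dur <- rep(window, n_int)
    dur[n_int] <- end_t - window * (n_int - 1)
    # interpolate the midpoint position from the logged positions
    if (nrow(tr) >= 2) {
      mlon <- approx(tr$time_s, tr$lon, xout = mids, rule = 2)$y
      mlat <- approx(tr$time_s, tr$lat, xout = mids, rule = 2)$y
    } else {
      mlon <- rep(tr$lon, length(mids))
      mlat <- rep(tr$lat, length(mids))
    }
    dist <- haversine(mlon, mlat, summit[1], summit[2])
    rec <- expand.grid(interval = seq_len(n_int), species = species,
                       stringsAsFactors = FALSE)
    rec$response <- mapply(function(iv, sp)
      sum(tr$count[idx == iv & tr$species == sp]), rec$interval, rec$species)
    rec$distance_km <- dist[rec$interval]
    rec$duration_s <- dur[rec$interval]
    rec$transect_id <- tr$transect_id[1]
    rec[, c("transect_id", "interval", "species", "response",
            "distance_km", "duration_s")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("radial_survey", "data.frame")
  out
}
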