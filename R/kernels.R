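#' Compact-support enrichment kernel
#'
#' Defines the "ground truth" distance-enrichment curve used by the survey
#' generators.  The kernel has compact support: the mean response equals
#' `baseline_mean * summit_multiplier` at the summit (distance 0), decays
#' smoothly with distance, and is *exactly* `baseline_mean` at and beyond
#' `radius_true`.  A compactly supported truth makes the true radius of
#' influence well-defined, which is what recovery tests need; a fitted
#' spline's radius estimate can then be compared against it.
#'
#' Two shapes are available.  `"compact-logistic"` follows a logistic decay
#' with midpoint `radius_true / 2` and scale `radius_true / 8`, rescaled so
#' it reaches 0 exactly at `radius_true`; `"half-gaussian-truncated"` is the
#' upper half of a Gaussian with standard deviation `0.4 * radius_true`,
#' likewise rescaled.
#'
#' @param baseline_mean Mean response far from the seamount (response units,
#'   > 0).
#' @param summit_multiplier Ratio of the summit mean to the baseline mean
#'   (dimensionless, >= 0).  `1` means no enrichment.
#' @param radius_true Support limit in km: enrichment is exactly zero at
#'   distances >= `radius_true`.
#' @param shape Kernel shape, `"compact-logistic"` (default) or
#'   `"half-gaussian-truncated"`.
#' @return An object of class `"enrichment_kernel"`; evaluate the mean
#'   response at distances in km with [predict()].
#' @examples
#' k <- enrichment_kernel(0.5, 20, 5)
#' predict(k, c(0, 2.5, 5, 10))  # 10 at the summit, 0.5 at and beyond 5 km
#' @export
enrichment_kernel <- function(baseline_mean, summit_multiplier, radius_true,
                              shape = c("compact-logistic",
                                        "half-gaussian-truncated")) {
  shape <- match.arg(shape)
  stopifnot(baseline_mean > 0, summit_multiplier >= 0, radius_true > 0)
  kern <- list(baseline_mean = baseline_mean,
               summit_multiplier = summit_multiplier,
               radius_true = radius_true,
               shape = shape)
  class(kern) <- "enrichment_kernel"
  kern
}

# Normalized weight w(d): w(0) = 1, w(d >= R) = 0, smooth in between.
kernel_weight <- function(kern, distance_km) {
  R <- kern$radius_true
  raw <- switch(kern$shape,
    "compact-logistic" = function(x) 1 / (1 + exp((x - R / 2) / (R / 8))),
    "half-gaussian-truncated" = function(x) exp(-x^2 / (2 * (0.4 * R)^2)))
  w <- (raw(distance_km) - raw(R)) / (raw(0) - raw(R))
  ifelse(distance_km >= R, 0, pmax(w, 0))
}

#' @export
predict.enrichment_kernel <- function(object, distance_km, ...) {
  stopifnot(all(distance_km >= 0))
  m <- object$summit_multiplier
  object$baseline_mean * (1 + (m - 1) * kernel_weight(object, distance_km))
}

#' @export
print.enrichment_kernel <- function(x, ...) {
  cat("Enrichment kernel (", x$shape, ")\n", sep = "")
  cat("  baseline mean    :", x$baseline_mean, "\n")
  cat("  summit multiplier:", x$summit_multiplier, "\n")
  cat("  true radius      :", x$radius_true, "km\n")
  invisible(x)
}

# Allow k(d) syntax via an attached function
#' @export
as.function.enrichment_kernel <- function(x, ...) {
  function(distance_km) predict(x, distance_km)
}
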