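#' Generate a synthetic radial survey
#'
#' Draws survey observations at varying distance from a seamount summit with
#' the statistical structure assumed by the distance-effect models:
#' overdispersed counts (negative binomial), Tweedie-like nonnegative
#' continuous responses (gamma with a point mass at zero arises naturally at
#' power 1 < p < 2), or Gaussian responses; an optional two-level "season"
#' covariate; transect-level random intercepts and AR(1) errors on the link
#' scale for continuous-survey modes; and one or more seamounts, each with
#' its own enrichment kernel.
#'
#' Configuration fields (all optional, with defaults):
#' \describe{
#'   \item{`n`}{number of samples (default 200).}
#'   \item{`distance_range`}{sampled distance range in km (default
#'     `c(0, 40)`).}
#'   \item{`design`}{`"uniform"` (uniform in distance, the default) or
#'     `"stations"` (replicated radial stations, dense near the summit, as
#'     radial BRUV/CTD campaigns are laid out).}
#'   \item{`theta`}{negative-binomial size parameter (default 1.5; smaller =
#'     more overdispersed).}
#'   \item{`tweedie_p`, `tweedie_phi`}{Tweedie power (default 1.5) and
#'     dispersion (default 1) for `family = "tweedie"`.}
#'   \item{`sigma`}{Gaussian response SD (default 0.5).}
#'   \item{`season_effect`}{log-scale (or identity-scale for Gaussian)
#'     coefficient of the second season level (default 0); a share
#'     `season_frac` (default 0.15) of samples get the second level.}
#'   \item{`n_transects`}{if > 0, samples are grouped into transects with
#'     i.i.d. Gaussian random intercepts (`transect_sd`, default 0.3) and
#'     within-transect AR(1) link-scale errors (`ar1_rho`, default 0).}
#'   \item{`n_seamounts`, `summit_multipliers`}{number of seamounts and an
#'     optional per-seamount multiplier overriding the kernel's.}
#' }
#'
#' @param cfg A [sim_config()].
#' @param kernel An [enrichment_kernel()]: the planted truth.
#' @param family `"nb"`, `"tweedie"`, `"gaussian"` or `"poisson"`.
#' @return A data frame of class `"radial_survey"` with columns
#'   `seamount_id`, `distance_km`, `response`, `season`, `transect_id`, and
#'   attributes `kernel` (the planted truth), `family` and `seed`.
#' @examples
#' cfg <- sim_config(seed = 42, n = 100)
#' k <- enrichment_kernel(0.5, 20, 5)
#' s <- gen_radial_survey(cfg, k, family = "nb")
#' head(s)
#' @export
gen_radial_survey <- function(cfg, kernel,
                              family = c("nb", "tweedie", "gaussian",
                                         "poisson")) {
  family <- match.arg(family)
  stopifnot(inherits(cfg, "sim_config"), inherits(kernel, "enrichment_kernel"))
  n <- cfg_get(cfg, "n", 200L)
  rng <- cfg_get(cfg, "distance_range", c(0, 40))
  design <- match.arg(cfg_get(cfg, "design", "uniform"),
                      c("uniform", "stations"))
  theta <- cfg_get(cfg, "theta", 1.5)
  tw_p <- cfg_get(cfg, "tweedie_p", 1.5)
  tw_phi <- cfg_get(cfg, "tweedie_phi", 1)
  sigma <- cfg_get(cfg, "sigma", 0.5)
  season_effect <- cfg_get(cfg, "season_effect", 0)
  season_frac <- cfg_get(cfg, "season_frac", 0.15)
  n_transects <- cfg_get(cfg, "n_transects", 0L)
  transect_sd <- cfg_get(cfg, "transect_sd", 0.3)
  ar1_rho <- cfg_get(cfg, "ar1_rho", 0)
  n_seamounts <- cfg_get(cfg, "n_seamounts", 1L)
  multipliers <- cfg_get(cfg, "summit_multipliers",
                         rep(kernel$summit_multiplier, n_seamounts))
  stopifnot(theta > 0, tw_phi > 0, length(multipliers) == n_seamounts)
  if (tw_p <= 1 || tw_p >= 2)
    stop("tweedie_p must lie in (1, 2)", call. = FALSE)

  with_seed(cfg$seed, {
    d <- switch(design,
      uniform = runif(n, rng[1], rng[2]),
      stations = {
        # replicated radial stations, spacing widening away from the summit
        st <- rng[1] + (rng[2] - rng[1]) *
          c(0, 0.025, 0.05, 0.075, 0.1, 0.125, 0.15, 0.2, 0.25, 0.3,
            0.4, 0.5, 0.625, 0.75, 0.875, 1)
        jit <- runif(n, -0.01, 0.01) * (rng[2] - rng[1])
        pmin(pmax(rep(st, length.out = n) + jit, rng[1]), rng[2])
      })
    seamount <- factor(paste0("sm", rep_len(seq_len(n_seamounts), n)))
    season <- factor(ifelse(runif(n) < season_frac, "scoping", "expedition"),
                     levels = c("expedition", "scoping"))
    sm_idx <- as.integer(sub("sm", "", as.character(seamount)))
    w <- kernel_weight(kernel, d)
    mu <- kernel$baseline_mean * (1 + (multipliers[sm_idx] - 1) * w)

    transect <- factor(rep("t1", n))
    link_err <- numeric(n)
    if (n_transects > 0) {
      transect <- factor(paste0("t", rep_len(seq_len(n_transects), n)))
      # order samples within transect by distance so AR(1) acts along-track
      ord <- order(transect, d)
      b <- rnorm(n_transects, 0, transect_sd)
      link_err <- b[as.integer(transect)]
      if (ar1_rho > 0) {
        innov_sd <- cfg_get(cfg, "ar1_sd", 0.2)
        for (tr in levels(transect)) {
          idx <- ord[transect[ord] == tr]
          e <- as.numeric(stats::arima.sim(list(ar = ar1_rho),
                                           n = length(idx),
                                           sd = innov_sd * sqrt(1 - ar1_rho^2)))
          link_err[idx] <- link_err[idx] + e
        }
      }
    }
    x_season <- as.numeric(season == "scoping")
    if (family == "gaussian") {
      mean_i <- mu + season_effect * x_season + link_err
      y <- rnorm(n, mean_i, sigma)
    } else {
      mean_i <- mu * exp(season_effect * x_season + link_err)
      y <- switch(family,
        nb = rnbinom(n, size = theta, mu = mean_i),
        poisson = rpois(n, mean_i),
        tweedie = rtweedie(n, mu = mean_i, p = tw_p, phi = tw_phi))
    }
    out <- data.frame(seamount_id = seamount, distance_km = d, response = y,
                      season = season, transect_id = transect)
    attr(out, "kernel") <- kernel
    attr(out, "family") <- family
    attr(out, "seed") <- cfg$seed
    class(out) <- c("radial_survey", "data.frame")
    out
  })
}

# Tweedie deviates for 1 < p < 2 via the compound Poisson-gamma
# representation: N ~ Pois(lambda), Y = sum of N gammas.
rtweedie <- function(n, mu, p, phi) {
  stopifnot(p > 1, p < 2, phi > 0, all(mu >= 0))
  lambda <- mu^(2 - p) / (phi * (2 - p))
  alpha <- (2 - p) / (p - 1)
  gam_scale <- phi * (p - 1) * mu^(p - 1)
  N <- rpois(n, lambda)
  y <- numeric(n)
  pos <- N > 0
  y[pos] <- rgamma(sum(pos), shape = N[pos] * alpha,
                   scale = gam_scale[pos])
  y
}
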