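#' Fit a penalized-spline distance-effect model
#'
#' Fits the basic seamount distance-effect model
#' \deqn{g(E(y_i)) = \beta_0 + f_s(distance_i) + \beta_1 x_i}
#' where \eqn{f_s} is a penalized thin-plate regression spline of distance
#' from the nearest seamount summit, \eqn{x} an optional parametric
#' covariate ("season" for survey data, "vessel" for CTD data) and \eqn{g}
#' the identity (Gaussian) or log (non-Gaussian) link.  Fitting is done by
#' \pkg{mgcv} with a REML-type smoothness criterion (use `method = "ML"`
#' when models are to be compared by AICc).  The smooth can be structured
#' per seamount or per depth group as a factor-smooth interaction, a
#' transect-level random intercept can be added as a ridge-penalized term,
#' and depth-stratified responses can be modelled with a 2-D tensor-product
#' smooth of distance and depth.
#'
#' Families: `"gaussian"`, `"nb"` (negative binomial, \eqn{\theta}
#' estimated by outer iteration), `"tweedie"` (power fixed at `tweedie_p`,
#' default 1.5; `tweedie_p = NULL` profiles the power), `"quasibinomial"`,
#' `"quasipoisson"`.
#'
#' With `ar1 = TRUE` the model is estimated through [mgcv::gamm()] with an
#' AR(1) correlation structure nested within transect (Gaussian responses;
#' non-Gaussian responses then use PQL).  Otherwise count families use an
#' independence working model; residual autocorrelation should be checked.
#'
#' @param samples Data frame with columns `response` and `distance_km`,
#'   and optionally `seamount_id`, `depth`, `depth_group`, `season`,
#'   `vessel`, `transect_id` (e.g. from [gen_radial_survey()] or
#'   [bin_visual_counts()]).
#' @param family Response family tag (see Details).
#' @param structure `"global"` (one smooth, default), `"seamount"`
#'   (per-seamount smooths) or `"depth-group"`; `"auto"` delegates to
#'   [select_structure()].
#' @param k Basis dimension of each smooth (default 10).
#' @param random_transect Add a transect random intercept
#'   (`s(transect_id, bs = "re")`).
#' @param ar1 Estimate via `gamm()` with within-transect AR(1) errors.
#' @param tensor_depth Model `te(distance_km, depth)` instead of a 1-D
#'   smooth (requires a `depth` column).
#' @param method Smoothness selection criterion, `"REML"` (default) or
#'   `"ML"`.
#' @param tweedie_p Tweedie power in (1, 2), or `NULL` to profile it.
#' @param weights Optional observation weights (e.g. cells per radial
#'   bin for pre-averaged responses, which restores constant variance).
#' @param min_obs Minimum observations required per fitted smooth.
#' @return An object of class `"distance_gam"` wrapping the \pkg{mgcv} fit,
#'   with `print()`, `summary()`, `coef()`, `vcov()`, `predict()`,
#'   `plot()`, `residuals()`, `simulate()` and [fitted_curve()] methods,
#'   and downstream estimators [derivative_band()],
#'   [radius_of_influence()], [enrichment_magnitude()],
#'   [smooth_difference()] and [posterior_simulate()].
#' @examples
#' s <- gen_radial_survey(sim_config(seed = 1, n = 150),
#'                        enrichment_kernel(0.5, 20, 5), family = "nb")
#' m <- distance_gam(s, family = "nb")
#' m
#' @export
distance_gam <- function(samples,
                         family = c("gaussian", "nb", "tweedie",
                                    "quasibinomial", "quasipoisson"),
                         structure = c("global", "seamount", "depth-group",
                                       "auto"),
                         k = 10, random_transect = FALSE, ar1 = FALSE,
                         tensor_depth = FALSE, method = c("REML", "ML"),
                         tweedie_p = 1.5, weights = NULL, min_obs = 10) {
  family <- match.arg(family)
  structure <- match.arg(structure)
  method <- match.arg(method)
  stopifnot(is.data.frame(samples),
            all(c("response", "distance_km") %in% names(samples)))
  dat <- as.data.frame(samples)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(dat), all(weights > 0))
    dat$.w <- weights
  }
  dat <- dat[!is.na(dat$response) & !is.na(dat$distance_km), , drop = FALSE]
  if (family != "gaussian" && any(dat$response < 0))
    stop("negative responses are incompatible with family '", family, "'",
         call. = FALSE)
  if (structure == "auto")
    structure <- select_structure(dat, family = family, k = k)$structure

  n_per_smooth <- switch(structure,
    global = nrow(dat),
    seamount = min(table(dat$seamount_id)),
    `depth-group` = min(table(dat$depth_group)))
  if (n_per_smooth < min_obs)
    stop("fewer than ", min_obs, " observations per fitted smooth",
         call. = FALSE)

  k <- min(k, max(4, floor(n_per_smooth / 2)))
  for (f in intersect(c("seamount_id", "depth_group", "season", "vessel",
                        "transect_id"), names(dat)))
    dat[[f]] <- factor(dat[[f]])

  smooth_term <- if (tensor_depth) {
    stopifnot("depth" %in% names(dat))
    sprintf("te(distance_km, depth, k = c(%d, 5))", k)
  } else switch(structure,
    global = sprintf("s(distance_km, bs = 'tp', k = %d)", k),
    seamount = sprintf(
      "seamount_id + s(distance_km, by = seamount_id, bs = 'tp', k = %d)", k),
    `depth-group` = sprintf(
      "depth_group + s(distance_km, by = depth_group, bs = 'tp', k = %d)", k))
  terms <- smooth_term
  for (cov in c("season", "vessel"))
    if (cov %in% names(dat) && nlevels(dat[[cov]]) > 1)
      terms <- c(terms, cov)
  if (random_transect && "transect_id" %in% names(dat) &&
      nlevels(dat$transect_id) > 1 && !ar1)
    terms <- c(terms, "s(transect_id, bs = 're')")
  fml <- as.formula(paste("response ~", paste(terms, collapse = " + ")))

  fam <- switch(family,
    gaussian = stats::gaussian(),
    nb = mgcv::nb(),
    tweedie = if (is.null(tweedie_p)) mgcv::tw()
              else mgcv::Tweedie(p = tweedie_p, link = "log"),
    quasibinomial = stats::quasibinomial(),
    quasipoisson = stats::quasipoisson())

  lme_part <- NULL
  if (ar1) {
    if (!"transect_id" %in% names(dat))
      stop("ar1 = TRUE requires a 'transect_id' column", call. = FALSE)
    dat <- dat[order(dat$transect_id, dat$distance_km), , drop = FALSE]
    dat$ar_order <- stats::ave(seq_len(nrow(dat)), dat$transect_id,
                               FUN = seq_along)
    gm <- mgcv::gamm(fml, data = dat, family = fam,
                     random = list(transect_id = ~1),
                     correlation = nlme::corAR1(form = ~ ar_order | transect_id))
    fit <- gm$gam
    lme_part <- gm$lme
    engine <- "gamm"
  } else {
    fit <- tryCatch(
      mgcv::gam(fml, data = dat, family = fam, method = method,
                weights = dat$.w),
      error = function(e) stop("model failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    if (!fit$converged)
      stop("smoothing parameter iteration did not converge (gradient norm ",
           format(max(abs(fit$outer.info$grad %||% NA))), ")", call. = FALSE)
    engine <- "gam"
  }

  out <- list(gam = fit, lme = lme_part, engine = engine,
              family_tag = family, structure = structure, k = k,
              data = dat, ar1 = ar1,
              distance_range = range(dat$distance_km),
              call = match.call())
  class(out) <- "distance_gam"
  out
}

family_is_gaussian <- function(m) m$family_tag == "gaussian"

#' @export
print.distance_gam <- function(x, ...) {
  cat("Seamount distance-effect model (", x$family_tag, " family, ",
      x$structure, " smooth structure)\n", sep = "")
  cat("  n = ", nrow(x$data), ", distance range ",
      paste(signif(x$distance_range, 4), collapse = "-"), " km\n", sep = "")
  edf <- sum(x$gam$edf)
  cat("  total effective degrees of freedom: ", signif(edf, 4), "\n",
      sep = "")
  if (x$ar1) cat("  AR(1) errors within transect (gamm/PQL fit)\n")
  invisible(x)
}

#' @export
summary.distance_gam <- function(object, ...) summary(object$gam, ...)

#' @export
coef.distance_gam <- function(object, ...) coef(object$gam)

#' @export
vcov.distance_gam <- function(object, ...) vcov(object$gam, ...)

#' @export
residuals.distance_gam <- function(object, type = "deviance", ...)
  residuals(object$gam, type = type, ...)

#' @export
formula.distance_gam <- function(x, ...) formula(x$gam)

# Reference newdata: the requested distances with covariates held at
# reference levels (first factor level / median numeric); random-effect
# levels are present but their columns are excluded from prediction.
ref_newdata <- function(m, distance_km, by_level = NULL) {
  nd <- data.frame(distance_km = distance_km)
  dat <- m$data
  for (v in setdiff(names(dat), c("distance_km", "response"))) {
    nd[[v]] <- if (is.factor(dat[[v]])) {
      lv <- if (v == "seamount_id" && !is.null(by_level)) by_level
            else levels(dat[[v]])[1]
      factor(lv, levels = levels(dat[[v]]))
    } else if (is.numeric(dat[[v]])) {
      median(dat[[v]], na.rm = TRUE)
    } else dat[[v]][1]
  }
  nd
}

# terms to exclude from prediction: random-effect smooths
re_terms <- function(m) {
  labs <- vapply(m$gam$smooth, function(s) s$label, character(1))
  cls <- vapply(m$gam$smooth, function(s)
    inherits(s, "random.effect"), logical(1))
  labs[cls]
}

#' Predict from a distance-effect model
#'
#' With `newdata` omitted, predictions are returned for the fitted data;
#' a bare numeric `newdata` is interpreted as distances (km) with other
#' covariates held at reference levels and random effects excluded.
#'
#' @param object A [distance_gam()] fit.
#' @param newdata Data frame, numeric distances, or `NULL`.
#' @param type Passed to [mgcv::predict.gam()] (default `"response"`).
#' @param by_level Seamount level at which to predict for per-seamount
#'   structures.
#' @param ... Passed to [mgcv::predict.gam()].
#' @export
predict.distance_gam <- function(object, newdata = NULL, type = "response",
                                 by_level = NULL, ...) {
  if (is.null(newdata))
    return(predict(object$gam, type = type, ...))
  if (is.numeric(newdata))
    newdata <- ref_newdata(object, newdata, by_level)
  excl <- re_terms(object)
  predict(object$gam, newdata = newdata, type = type,
          exclude = if (length(excl)) excl else NULL,
          newdata.guaranteed = FALSE, ...)
}

#' Fitted distance-response curve with confidence envelope
#'
#' @param m A [distance_gam()] fit.
#' @param grid_n Number of evaluation distances (default 100).
#' @param level Confidence level (default 0.95).
#' @param by_level Seamount level for per-seamount structures.
#' @return Data frame with `distance_km`, `fit`, `lower`, `upper` on the
#'   response scale.
#' @export
fitted_curve <- function(m, grid_n = 100, level = 0.95, by_level = NULL) {
  stopifnot(inherits(m, "distance_gam"))
  grid <- seq(m$distance_range[1], m$distance_range[2], length.out = grid_n)
  nd <- ref_newdata(m, grid, by_level)
  excl <- re_terms(m)
  pr <- predict(m$gam, newdata = nd, type = "link", se.fit = TRUE,
                exclude = if (length(excl)) excl else NULL)
  z <- qnorm(1 - (1 - level) / 2)
  linkinv <- m$gam$family$linkinv
  data.frame(distance_km = grid,
             fit = linkinv(pr$fit),
             lower = linkinv(pr$fit - z * pr$se.fit),
             upper = linkinv(pr$fit + z * pr$se.fit))
}

#' @export
plot.distance_gam <- function(x, grid_n = 200, level = 0.95,
                              by_level = NULL, ...) {
  fc <- fitted_curve(x, grid_n = grid_n, level = level, by_level = by_level)
  plot(x$data$distance_km, x$data$response,
       xlab = "Distance from summit (km)", ylab = "Response",
       col = adjustcolor("grey30", 0.6), pch = 16, ...)
  polygon(c(fc$distance_km, rev(fc$distance_km)),
          c(fc$lower, rev(fc$upper)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(fc$distance_km, fc$fit, col = "steelblue4", lwd = 2)
  invisible(fc)
}

#' Simulate responses from a fitted distance-effect model
#'
#' Draws new response vectors at the observed covariates from the fitted
#' family (negative binomial, Tweedie via compound Poisson-gamma, Gaussian,
#' or binomial/Poisson with the estimated dispersion ignored for quasi
#' families).
#'
#' @param object A [distance_gam()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.distance_gam <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- as.numeric(fitted(object$gam))
  n <- length(mu)
  fam <- object$family_tag
  with_seed(seed, {
    sims <- replicate(nsim, switch(fam,
      gaussian = rnorm(n, mu, sqrt(object$gam$sig2)),
      nb = rnbinom(n, size = object$gam$family$getTheta(TRUE), mu = mu),
      tweedie = {
        p <- get_tweedie_power(object$gam)
        rtweedie(n, mu = mu, p = p, phi = object$gam$scale)
      },
      quasipoisson = rpois(n, mu),
      quasibinomial = rbinom(n, 1, mu)), simplify = FALSE)
    out <- as.data.frame(setNames(sims, paste0("sim_", seq_len(nsim))))
    out
  })
}

get_tweedie_power <- function(gamfit) {
  fam <- gamfit$family
  if (!is.null(fam$getTheta)) {
    th <- fam$getTheta(TRUE)
    # tw() parameterizes p through a logit on (1,2)
    return(if (th > 1 && th < 2) th else 1 + exp(th) / (1 + exp(th)))
  }
  p <- get("p", envir = environment(fam$variance))
  p
}
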