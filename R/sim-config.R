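#' Simulation configuration
#'
#' A lightweight, validated container for generator settings.  Every
#' generator in the package is a pure function of its configuration: the
#' same `sim_config()` (in particular the same `seed`) reproduces output
#' exactly, and the seed is recorded on every generated object so a run
#' manifest can be assembled afterwards.
#'
#' Common fields are `seed` and `n`; any further named setting understood by
#' a specific generator (noise parameters, covariate effects, group
#' structure) can be supplied through `...` and is stored as-is.  All
#' variance-type parameters must be positive; this is checked both here (for
#' known names) and again by the generator that consumes them.
#'
#' @param seed Integer RNG seed.
#' @param n Primary size parameter (number of samples, animals, tracks,
#'   profiles or scenes, depending on the generator).
#' @param ... Further generator-specific settings (see the individual
#'   `gen_*()` help pages for names and defaults).
#' @return An object of class `"sim_config"` (a named list).
#' @seealso [gen_radial_survey()], [gen_nasc_field()],
#'   [gen_detection_log()], [gen_tracks()], [gen_environment()],
#'   [read_sim_config()]
#' @export
sim_config <- function(seed = 1L, n = NULL, ...) {
  cfg <- c(list(seed = as.integer(seed), n = n), list(...))
  variance_names <- c("theta", "sigma", "tweedie_phi", "transect_sd",
                      "noise_sd", "step_scale", "step_shape")
  for (nm in intersect(names(cfg), variance_names)) {
    if (!is.null(cfg[[nm]]) && any(cfg[[nm]] <= 0))
      stop("'", nm, "' must be positive", call. = FALSE)
  }
  if (!is.null(cfg$ar1_rho) && (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1))
    stop("'ar1_rho' must be in [0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in setdiff(names(flds), "seed"))
    cat("  ", nm, ": ", paste(format(flds[[nm]]), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# Pull a field with a generator-specific default.
cfg_get <- function(cfg, name, default) cfg[[name]] %||% default

#' Read or write a simulation configuration as YAML
#'
#' Configurations round-trip through a plain YAML file so that a simulation
#' can be re-run byte-identically from its recorded settings.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()] object;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(sim_config, lst)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()] object.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg[!vapply(cfg, is.null, logical(1))]), path)
  invisible(path)
}
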