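#' Track start date of a tagged animal
#'
#' To allow for behavioural equilibration after tagging, an animal's track
#' is deemed to have started at its first detection on the array on at
#' least 2 consecutive days: the first date `d` such that detections occur
#' on both `d` and `d + 1`.  Animals never satisfying the rule (e.g. never
#' detected after release) return `NA` and are excluded from residency
#' analyses.
#'
#' @param events Detection data frame (`tag_id`, `timestamp`), or a
#'   [gen_detection_log()] object.
#' @param tag_id Animal to evaluate.
#' @param local_offset Hours added to UTC before assigning day boundaries
#'   (diel statistics are local-time phenomena; default 0).
#' @return A `Date`, or `NA` if the rule is never met.
#' @export
track_start <- function(events, tag_id, local_offset = 0) {
  ev <- as_events(events)
  days <- detection_days(ev, tag_id, local_offset)
  if (length(days) == 0) return(as.Date(NA))
  consec <- days[(days + 1) %in% days]
  if (length(consec) == 0) return(as.Date(NA))
  min(consec)
}

as_events <- function(events) {
  if (inherits(events, "detection_log")) events$events else events
}

detection_days <- function(ev, tag, local_offset = 0) {
  ts <- ev$timestamp[ev$tag_id == tag]
  sort(unique(as.Date(ts + local_offset * 3600, tz = "UTC")))
}

#' Residency index
#'
#' The proportion of total tracking days on which an individual was
#' detected at least once on any receiver in the array:
#' `RI = (days with >= 1 detection) / (days in window)`.  The window runs
#' from the animal's [track_start()] through the study end by default,
#' matching a common fixed tracking period for all animals; supply
#' `window` to use tag-specific end dates.
#'
#' @param events Detections or a [gen_detection_log()].
#' @param tag_id Animal.
#' @param window `c(start, end)` dates; `NULL` uses
#'   `c(track_start, max(events$timestamp))` (or the log's recorded study
#'   span).
#' @param local_offset Hours added to UTC for day boundaries.
#' @return RI in \[0, 1\], or `NA` if the track never starts.
#' @export
residency_index <- function(events, tag_id, window = NULL,
                            local_offset = 0) {
  ev <- as_events(events)
  if (is.null(window)) {
    ts0 <- track_start(events, tag_id, local_offset)
    if (is.na(ts0)) return(NA_real_)
    end <- if (inherits(events, "detection_log"))
      events$study_start + events$study_days - 1
    else max(as.Date(ev$timestamp + local_offset * 3600, tz = "UTC"))
    window <- c(ts0, end)
  }
  window <- as.Date(window)
  n_days <- as.integer(window[2] - window[1]) + 1L
  if (n_days <= 0) stop("empty residency window", call. = FALSE)
  days <- detection_days(ev, tag_id, local_offset)
  days <- days[days >= window[1] & days <= window[2]]
  length(days) / n_days
}

#' Attrition curve: proportion of animals still present
#'
#' For each day of the study, the fraction of tagged animals "still
#' present" on the array, where still present means having at least one
#' detection on or after that day (the default) or on that exact day
#' (`rule = "that-day"`).  The raw proportions are optionally smoothed
#' with a binomial penalized spline; with `ar1 = TRUE` the smooth is
#' estimated by [mgcv::gamm()] with an AR(1) working correlation, as
#' appropriate for serially dependent daily proportions.
#'
#' @param events Detections or a [gen_detection_log()].
#' @param study_days Number of days in the study (inferred from a
#'   detection log).
#' @param rule `"on-after"` (default) or `"that-day"`.
#' @param smooth Fit a binomial smooth (default `TRUE`).
#' @param ar1 Use an AR(1) working correlation in the smooth.
#' @param local_offset Hours added to UTC for day boundaries.
#' @return A data frame of class `"attrition_curve"` with `day`,
#'   `n_present`, `n_animals`, `prop` and (if smoothed) `smooth`.
#' @export
attrition_curve <- function(events, study_days = NULL,
                            rule = c("on-after", "that-day"),
                            smooth = TRUE, ar1 = FALSE, local_offset = 0) {
  rule <- match.arg(rule)
  ev <- as_events(events)
  if (is.null(study_days)) {
    if (inherits(events, "detection_log")) study_days <- events$study_days
    else stop("study_days required", call. = FALSE)
  }
  start <- if (inherits(events, "detection_log")) events$study_start
           else min(as.Date(ev$timestamp, tz = "UTC"))
  tags <- unique(ev$tag_id)
  if (length(tags) < 2) warning("attrition curve from fewer than 2 animals")
  day_idx <- lapply(tags, function(tg)
    as.integer(detection_days(ev, tg, local_offset) - start) + 1L)
  grid <- seq_len(study_days)
  present <- vapply(grid, function(d) {
    sum(vapply(day_idx, function(dd) switch(rule,
      `on-after` = any(dd >= d), `that-day` = d %in% dd), logical(1)))
  }, integer(1))
  out <- data.frame(day = grid, n_present = present,
                    n_animals = length(tags),
                    prop = present / length(tags))
  if (smooth && study_days >= 20 && var(out$prop) > 0) {
    if (ar1) {
      out$grp <- factor("all")
      gm <- mgcv::gamm(prop ~ s(day, k = 10), data = out,
                       family = stats::quasibinomial(),
                       weights = out$n_animals,
                       correlation = nlme::corAR1(form = ~ day))
      out$smooth <- as.numeric(predict(gm$gam, type = "response"))
      out$grp <- NULL
    } else {
      g <- mgcv::gam(prop ~ s(day, k = 10),
                     family = stats::quasibinomial(),
                     weights = out$n_animals, data = out, method = "REML")
      out$smooth <- as.numeric(predict(g, type = "response"))
    }
  }
  class(out) <- c("attrition_curve", "data.frame")
  out
}

#' Residency periods
#'
#' Maximal runs of consecutive detection days of length >= `min_length`
#' (default 14): the periods during which an animal is considered present
#' on the array, used to restrict diel and space-use analyses to genuine
#' occupancy.
#'
#' @param events Detections or a [gen_detection_log()].
#' @param tag_id Animal.
#' @param min_length Minimum run length in days (default 14).
#' @param local_offset Hours added to UTC for day boundaries.
#' @return Data frame with `start`, `end` (Dates) and `length` (days);
#'   zero rows if no qualifying run exists.
#' @export
residency_periods <- function(events, tag_id, min_length = 14,
                              local_offset = 0) {
  days <- detection_days(as_events(events), tag_id, local_offset)
  if (length(days) == 0)
    return(data.frame(start = as.Date(character()),
                      end = as.Date(character()), length = integer()))
  brk <- c(0, which(diff(days) > 1), length(days))
  runs <- data.frame(start = days[head(brk, -1) + 1], end = days[brk[-1]])
  runs$length <- as.integer(runs$end - runs$start) + 1L
  runs <- runs[runs$length >= min_length, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Diel detection profile during residency periods
#'
#' Hourly residency indices -- the proportion of hourly bins within an
#' animal's residency periods in which it was detected at least once --
#' summarised per local hour, with a population-level cyclic smooth.  The
#' smooth is a cubic cyclic penalized spline of hour (value and slope
#' continuous across midnight) with an animal-level random intercept and
#' binomial-type variance with estimated dispersion (quasibinomial), so
#' flat profiles fit a constant and diel cycles show as significant hour
#' effects.
#'
#' @param events Detections or a [gen_detection_log()].
#' @param periods Named list of residency-period data frames per tag
#'   ([residency_periods()]); computed automatically if `NULL`.
#' @param local_offset Hours added to UTC (default 0).
#' @param min_period_days Passed to [residency_periods()] when computing
#'   them here.
#' @return A list of class `"diel_profile"`: `hourly` (data frame
#'   `tag_id`, `hour`, `n_bins`, `n_detected`, `ri`), `fit` (the mgcv
#'   smooth, `NULL` if < 2 animals), `curve` (predicted population RI by
#'   hour).
#' @export
diel_profile <- function(events, periods = NULL, local_offset = 0,
                         min_period_days = 14) {
  ev <- as_events(events)
  tags <- unique(ev$tag_id)
  if (is.null(periods)) {
    periods <- lapply(tags, function(tg)
      residency_periods(events, tg, min_period_days, local_offset))
    names(periods) <- tags
  }
  rows <- list()
  for (tg in names(periods)) {
    per <- periods[[tg]]
    if (is.null(per) || nrow(per) == 0) next
    ts <- ev$timestamp[ev$tag_id == tg] + local_offset * 3600
    d <- as.Date(ts, tz = "UTC")
    hr <- as.integer(format(ts, "%H", tz = "UTC"))
    in_per <- rep(FALSE, length(ts))
    n_days <- 0L
    for (i in seq_len(nrow(per))) {
      in_per <- in_per | (d >= per$start[i] & d <= per$end[i])
      n_days <- n_days + per$length[i]
    }
    det <- table(factor(hr[in_per], levels = 0:23),
                 factor(as.character(d[in_per])))
    n_det_hour <- apply(det > 0, 1, sum)
    rows[[tg]] <- data.frame(tag_id = tg, hour = 0:23, n_bins = n_days,
                             n_detected = as.integer(n_det_hour),
                             ri = as.integer(n_det_hour) / n_days)
  }
  if (length(rows) == 0) stop("no residency periods", call. = FALSE)
  hourly <- do.call(rbind, rows)
  rownames(hourly) <- NULL
  fit <- NULL; curve <- NULL
  if (length(unique(hourly$tag_id)) >= 2) {
    hourly$tag_id <- factor(hourly$tag_id)
    fit <- mgcv::gam(ri ~ s(hour, bs = "cc", k = 8) + s(tag_id, bs = "re"),
                     knots = list(hour = c(0, 24)),
                     family = stats::quasibinomial(),
                     weights = hourly$n_bins, data = hourly,
                     method = "REML")
    nd <- data.frame(hour = seq(0, 24, by = 0.25),
                     tag_id = factor(levels(hourly$tag_id)[1],
                                     levels = levels(hourly$tag_id)))
    curve <- data.frame(hour = nd$hour,
                        ri = as.numeric(predict(fit, nd, type = "response",
                                                exclude = "s(tag_id)")))
  }
  out <- list(hourly = hourly, fit = fit, curve = curve)
  class(out) <- "diel_profile"
  out
}

#' @export
print.diel_profile <- function(x, ...) {
  cat("Diel profile:", length(unique(x$hourly$tag_id)), "animals\n")
  if (!is.null(x$curve)) {
    rng <- range(x$curve$ri)
    cat("  population hourly RI range:", signif(rng[1], 3), "-",
        signif(rng[2], 3), "\n")
  }
  invisible(x)
}

#' Receiver-use proportions with bootstrap intervals
#'
#' For each animal, the proportion of its detections (within residency
#' periods and the requested diel phase) recorded on each receiver; then
#' the across-animal mean per receiver with a percentile bootstrap
#' confidence interval obtained by resampling *animals* with replacement
#' (preserving within-animal dependence).  Animals with no detections in
#' the phase are excluded from that phase.
#'
#' @param events Detections or a [gen_detection_log()].
#' @param periods Optional named list of residency periods per tag.
#' @param phase `"all"` (default), `"day"` or `"night"`.
#' @param day_hours Local hours spanning daytime (default `c(6, 18)`,
#'   i.e. 06:00--17:59).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional RNG seed.
#' @param local_offset Hours added to UTC.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `receiver_id`, `mean_prop`, `lower`, `upper`,
#'   `n_animals`; per-animal proportions in attribute `"per_animal"`.
#' @export
receiver_use <- function(events, periods = NULL, phase = "all",
                         day_hours = c(6, 18), n_boot = 1000, seed = NULL,
                         local_offset = 0, level = 0.95) {
  phase <- match.arg(phase, c("all", "day", "night"))
  ev <- as_events(events)
  tags <- unique(ev$tag_id)
  receivers <- sort(unique(ev$receiver_id))
  props <- list()
  for (tg in tags) {
    ts <- ev$timestamp[ev$tag_id == tg] + local_offset * 3600
    rec <- ev$receiver_id[ev$tag_id == tg]
    if (!is.null(periods)) {
      per <- periods[[tg]]
      if (is.null(per) || nrow(per) == 0) next
      d <- as.Date(ts, tz = "UTC")
      keep <- rep(FALSE, length(ts))
      for (i in seq_len(nrow(per)))
        keep <- keep | (d >= per$start[i] & d <= per$end[i])
      ts <- ts[keep]; rec <- rec[keep]
    }
    if (phase != "all") {
      hr <- as.integer(format(ts, "%H", tz = "UTC"))
      is_day <- hr >= day_hours[1] & hr < day_hours[2]
      sel <- if (phase == "day") is_day else !is_day
      rec <- rec[sel]
    }
    if (length(rec) == 0) next
    tab <- table(factor(rec, levels = receivers))
    props[[tg]] <- as.numeric(tab) / length(rec)
  }
  if (length(props) == 0) stop("no detections in the requested phase",
                               call. = FALSE)
  P <- do.call(rbind, props)
  colnames(P) <- receivers
  mean_prop <- colMeans(P)
  alpha <- (1 - level) / 2
  if (nrow(P) >= 2) {
    boots <- with_seed(seed, {
      replicate(n_boot, colMeans(P[sample(nrow(P), replace = TRUE), ,
                                   drop = FALSE]))
    })
    ci <- apply(boots, 1, quantile, probs = c(alpha, 1 - alpha))
  } else {
    ci <- rbind(mean_prop, mean_prop)
  }
  out <- data.frame(receiver_id = receivers, mean_prop = mean_prop,
                    lower = ci[1, ], upper = ci[2, ],
                    n_animals = nrow(P))
  rownames(out) <- NULL
  attr(out, "per_animal") <- P
  out
}

#' Cluster residency indices by exact k-medoids (PAM)
#'
#' Partitions 1-D residency indices around medoids with Euclidean cost.
#' For small problems (`choose(n, k)` enumerable) the globally optimal
#' medoid set is found by exhaustive search; otherwise the classical
#' BUILD + SWAP algorithm is run to convergence.  Ties are broken
#' deterministically in favour of the lexicographically smallest medoid
#' index set.  Clusters are relabelled so cluster 1 has the lowest medoid.
#'
#' @param ri Numeric vector of residency indices (or any 1-D values).
#' @param k Number of clusters (default 2).
#' @param exact_limit Maximum number of medoid combinations enumerated
#'   exhaustively (default 20000).
#' @return A list of class `"ri_clusters"`: `labels` (integer vector),
#'   `medoids` (values), `medoid_idx`, `cost`, `exact` (logical).
#' @export
cluster_ri <- function(ri, k = 2, exact_limit = 20000) {
  n <- length(ri)
  if (k > n) stop("k exceeds the number of observations", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  cost_of <- function(med_idx) {
    dmat <- abs(outer(ri, ri[med_idx], "-"))
    sum(apply(dmat, 1, min))
  }
  assign_to <- function(med_idx) {
    dmat <- abs(outer(ri, ri[med_idx], "-"))
    apply(dmat, 1, which.min)
  }
  n_comb <- choose(n, k)
  if (n_comb <= exact_limit) {
    combs <- utils::combn(n, k)
    costs <- apply(combs, 2, cost_of)
    best <- combs[, which.min(costs)]   # first = lexicographically smallest
    exact <- TRUE
  } else {
    # BUILD
    med <- integer(0)
    for (j in seq_len(k)) {
      cand <- setdiff(seq_len(n), med)
      costs <- vapply(cand, function(i) cost_of(c(med, i)), numeric(1))
      med <- c(med, cand[which.min(costs)])
    }
    # SWAP (steepest descent)
    repeat {
      cur <- cost_of(med)
      best_swap <- NULL; best_cost <- cur
      for (mi in seq_along(med)) for (h in setdiff(seq_len(n), med)) {
        trial <- med; trial[mi] <- h
        cc <- cost_of(trial)
        if (cc < best_cost - 1e-12) { best_cost <- cc; best_swap <- trial }
      }
      if (is.null(best_swap)) break
      med <- best_swap
    }
    best <- med
    exact <- FALSE
  }
  ord <- order(ri[best], best)
  best <- best[ord]
  labels <- assign_to(best)
  out <- list(labels = labels, medoids = ri[best], medoid_idx = best,
              cost = cost_of(best), exact = exact, k = k)
  class(out) <- "ri_clusters"
  out
}

#' @export
print.ri_clusters <- function(x, ...) {
  cat("k-medoids clustering (k = ", x$k, ", ",
      if (x$exact) "exact" else "BUILD+SWAP", ")\n", sep = "")
  for (j in seq_len(x$k))
    cat("  cluster ", j, ": medoid ", signif(x$medoids[j], 3), ", n = ",
        sum(x$labels == j), "\n", sep = "")
  cat("  total cost:", signif(x$cost, 5), "\n")
  invisible(x)
}

#' Inter-seamount movements
#'
#' Counts movements between seamounts in each animal's detection history:
#' a move is a pair of consecutive detections on receivers of different
#' seamounts.  Summarises the number and percentage of "switchers"
#' (animals with at least one move).
#'
#' @param events Detections or a [gen_detection_log()]; rows need
#'   `seamount_id` (or supply `receiver_map`).
#' @param receiver_map Optional data frame (`receiver_id`, `seamount_id`)
#'   used when events lack a seamount column.
#' @return A list of class `"seamount_moves"`: `per_animal` (data frame
#'   `tag_id`, `n_moves`, `switcher`), `n_switchers`, `pct_switchers`.
#' @export
inter_seamount_moves <- function(events, receiver_map = NULL) {
  ev <- as_events(events)
  if (!"seamount_id" %in% names(ev)) {
    if (is.null(receiver_map))
      stop("receiver_map needed to assign seamounts", call. = FALSE)
    ev$seamount_id <- receiver_map$seamount_id[
      match(ev$receiver_id, receiver_map$receiver_id)]
  }
  if (anyNA(ev$seamount_id))
    stop("unmapped receivers present", call. = FALSE)
  ev <- ev[order(ev$tag_id, ev$timestamp), ]
  per <- lapply(split(ev$seamount_id, ev$tag_id), function(sm) {
    if (length(sm) < 2) 0L else sum(sm[-1] != sm[-length(sm)])
  })
  pa <- data.frame(tag_id = names(per), n_moves = unlist(per))
  pa$switcher <- pa$n_moves > 0
  rownames(pa) <- NULL
  out <- list(per_animal = pa, n_switchers = sum(pa$switcher),
              pct_switchers = 100 * mean(pa$switcher))
  class(out) <- "seamount_moves"
  out
}

#' @export
print.seamount_moves <- function(x, ...) {
  cat(x$n_switchers, "of", nrow(x$per_animal),
      sprintf("animals (%.0f%%) moved between seamounts\n",
              x$pct_switchers))
  invisible(x)
}

#' Average maximum detection radius (AMDR)
#'
#' Models detection probability (received / expected transmissions per
#' 180-s bin) as a binomial penalized spline of distance for each
#' range-test site, averages the predicted curves across sites, and
#' returns the smallest distance at which the mean predicted probability
#' first drops below `threshold` (default 5%).  If the mean curve never
#' falls below the threshold within the tested range the result is
#' censored at the maximum distance and flagged.
#'
#' @param series Range-test data frame with `site`, `distance_m`,
#'   `expected`, `received`.
#' @param threshold Detection-probability cutoff (default 0.05).
#' @param grid_m Prediction grid spacing in m (default 1).
#' @param k Spline basis dimension (default 8).
#' @return A list of class `"amdr_estimate"`: `amdr_m`, `censored`,
#'   `curve` (data frame `distance_m`, `p_mean`).
#' @export
amdr <- function(series, threshold = 0.05, grid_m = 1, k = 8) {
  stopifnot(all(c("site", "distance_m", "expected", "received") %in%
                  names(series)),
            all(series$received <= series$expected))
  rng <- range(series$distance_m)
  grid <- unique(c(seq(rng[1], rng[2], by = grid_m), rng[2]))
  preds <- vapply(split(series, series$site), function(s) {
    fit <- mgcv::gam(cbind(received, expected - received) ~
                       s(distance_m, k = k),
                     family = stats::binomial(), data = s,
                     method = "REML")
    as.numeric(predict(fit, data.frame(distance_m = grid),
                       type = "response"))
  }, numeric(length(grid)))
  p_mean <- rowMeans(preds)
  below <- p_mean < threshold
  censored <- !any(below)
  out <- list(amdr_m = if (censored) max(grid) else min(grid[below]),
              censored = censored,
              curve = data.frame(distance_m = grid, p_mean = p_mean),
              threshold = threshold)
  class(out) <- "amdr_estimate"
  out
}

#' @export
print.amdr_estimate <- function(x, ...) {
  cat("AMDR:", round(x$amdr_m), "m",
      if (x$censored) "(censored at the maximum tested distance)" else "",
      "\n")
  invisible(x)
}

#' Quasibinomial GLM of residency indices
#'
#' Tests effects of covariates (species, sex, size class) on residency
#' indices with a logit-link binomial-type GLM with estimated dispersion
#' (quasibinomial), weighting each animal by its number of tracking days
#' when available.  Term significance is assessed by F tests on
#' dispersion-scaled deviance drops.
#'
#' @param records Data frame with an `ri` column, covariate columns, and
#'   optionally `n_days` (weights).
#' @param terms Character vector of covariate names to test.
#' @return A list of class `"ri_glm"`: `fit` (the glm), `anova` (the
#'   F-test table), `separation` (levels within which RI is constant,
#'   flagged).
#' @export
compare_ri_glm <- function(records, terms = c("species")) {
  stopifnot("ri" %in% names(records), all(terms %in% names(records)))
  records <- records[!is.na(records$ri), , drop = FALSE]
  for (tm in terms) {
    records[[tm]] <- factor(records[[tm]])
    if (nlevels(records[[tm]]) < 2)
      stop("covariate '", tm, "' has fewer than 2 levels", call. = FALSE)
  }
  w <- if ("n_days" %in% names(records)) records$n_days
       else rep(1, nrow(records))
  fml <- as.formula(paste("ri ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::quasibinomial(), data = records,
                    weights = w)
  an <- stats::drop1(fit, test = "F")
  sep <- character(0)
  for (tm in terms) {
    v <- tapply(records$ri, records[[tm]], function(x) var(x) == 0)
    if (any(v, na.rm = TRUE))
      sep <- c(sep, paste0(tm, ":", names(v)[which(v)]))
  }
  if (length(sep))
    warning("constant RI within level(s): ", paste(sep, collapse = ", "))
  out <- list(fit = fit, anova = an, separation = sep)
  class(out) <- "ri_glm"
  out
}

#' @export
print.ri_glm <- function(x, ...) {
  cat("Quasibinomial GLM of residency index\n")
  print(x$anova)
  invisible(x)
}
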