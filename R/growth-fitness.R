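#' Maximum growth rate from an OD time series
#'
#' Optical-density readings are first mapped to cell densities through
#' the calibration (identity by default), then log-slopes are computed
#' for every window of `span_points` measurements spaced `spacing_min`
#' minutes apart. With 10-min sampling and the defaults this is the
#' classic rule: seven points spanning 360 min, slope from a
#' least-squares fit of ln(density) on time (per minute). Slopes are
#' sorted in decreasing order (ties broken by earlier window start),
#' the top `discard_top` are discarded as potential artifacts, and the
#' next `keep` are averaged — i.e. the mean of the 3rd to 8th highest
#' slopes under the defaults.
#'
#' @param time_min measurement times in minutes, strictly increasing
#'   and regularly spaced.
#' @param od optical-density values (>= 0).
#' @param calibration optional monotone OD-to-density mapping: a data
#'   frame with columns `od` and `density` (piecewise-linear
#'   interpolation, extrapolated linearly at the ends), or `NULL` for
#'   identity.
#' @param spacing_min spacing between the points of one window
#'   (minutes).
#' @param span_points number of measurements per window.
#' @param discard_top number of highest slopes to discard.
#' @param keep number of slopes averaged after discarding.
#' @param slope_method `"least_squares"` (default) fits ln(density) on
#'   time over the window; `"endpoint"` uses
#'   (ln d_last − ln d_first)/span, which equals the mean of the
#'   per-step Δln/spacing differences.
#' @return a list of class `growth_rate` with `rate` (per minute),
#'   `window_slopes` (the retained slopes, descending),
#'   `all_slopes`, and `n_windows_discarded`.
#' @export
estimate_max_growth_rate <- function(time_min, od, calibration = NULL,
                                     spacing_min = 60, span_points = 7,
                                     discard_top = 2, keep = 6,
                                     slope_method = c("least_squares",
                                                      "endpoint")) {
  slope_method <- match.arg(slope_method)
  stopifnot(length(time_min) == length(od), all(diff(time_min) > 0),
            all(od >= 0))
  density <- apply_calibration(od, calibration)

  dt <- diff(time_min)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 1e-6 * step) {
    stop("time points must be regularly spaced")
  }
  stride <- spacing_min / step
  if (abs(stride - round(stride)) > 1e-6) {
    stop("window spacing_min must be a multiple of the sampling interval")
  }
  stride <- as.integer(round(stride))

  n <- length(time_min)
  if (n <= (span_points - 1L) * stride) {
    stop("no complete windows: need more than ",
         (span_points - 1L) * stride + 1L, " measurements")
  }
  starts <- seq_len(n - (span_points - 1L) * stride)
  if (length(starts) < discard_top + keep) {
    stop(sprintf("only %d windows available; need at least %d",
                 max(0L, length(starts)), discard_top + keep))
  }

  slopes <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i] + stride * (0:(span_points - 1L))
    d <- density[idx]
    if (any(d <= 0)) {
      warning("window with non-positive density skipped")
      next
    }
    y <- log(d); x <- time_min[idx]
    slopes[i] <- if (slope_method == "least_squares") {
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    } else {
      (y[length(y)] - y[1]) / (x[length(x)] - x[1])
    }
  }
  valid <- which(!is.na(slopes))
  if (length(valid) < discard_top + keep) {
    stop("fewer valid windows than discard_top + keep")
  }
  # descending by slope; ties broken by earlier window start
  ord <- valid[order(-slopes[valid], valid)]
  kept <- ord[(discard_top + 1):(discard_top + keep)]
  structure(list(rate = mean(slopes[kept]),
                 window_slopes = slopes[kept],
                 all_slopes = slopes,
                 n_windows_discarded = discard_top),
            class = "growth_rate")
}

apply_calibration <- function(od, calibration) {
  if (is.null(calibration)) return(od)
  stopifnot(all(c("od", "density") %in% names(calibration)))
  o <- order(calibration$od)
  x <- calibration$od[o]; y <- calibration$density[o]
  if (any(diff(y) < 0)) stop("calibration must be monotone")
  f <- stats::approxfun(x, y, rule = 2)
  f(od)
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("max growth rate: %.5g per min (mean of %d window slopes)\n",
              x$rate, length(x$window_slopes)))
  invisible(x)
}

#' Estimate growth rates for a long-format curve table
#'
#' @param curves data frame with columns `sample_id`, `time_min`,
#'   `od` (and optionally `environment_id`, carried through).
#' @param ... passed to [estimate_max_growth_rate()].
#' @return tibble with one row per sample: `sample_id`,
#'   (`environment_id`,) `rate`.
#' @export
growth_rates <- function(curves, ...) {
  stopifnot(all(c("sample_id", "time_min", "od") %in% names(curves)))
  by_sample <- split(curves, curves$sample_id)
  out <- lapply(by_sample, function(d) {
    d <- d[order(d$time_min), ]
    r <- estimate_max_growth_rate(d$time_min, d$od, ...)
    row <- tibble::tibble(sample_id = d$sample_id[1], rate = r$rate)
    if ("environment_id" %in% names(d)) {
      row$environment_id <- d$environment_id[1]
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Relative fitness from growth rates
#'
#' The doubling-based transform `2^(rate/reference − 1)`: equal rates
#' give fitness 1, a doubled rate gives 2, a zero rate gives 0.5.
#'
#' @param rate growth rate(s), per minute.
#' @param reference_mean_rate reference mean growth rate (> 0).
#' @return relative fitness value(s).
#' @export
relative_fitness <- function(rate, reference_mean_rate) {
  if (any(!is.finite(rate)) || any(!is.finite(reference_mean_rate))) {
    stop("non-finite growth rate")
  }
  stopifnot(reference_mean_rate > 0)
  2^(rate / reference_mean_rate - 1)
}

#' Per-environment fitness summary
#'
#' Combines progenitor replicate growth rates, evolved-population
#' growth rates and the base-medium reference into the two
#' environment-level quantities: the stress level `F_ratio` (progenitor
#' fitness in the environment relative to the base medium; lower means
#' more stress) and the extent of adaptation `f_over_F` (evolved
#' fitness relative to the progenitor in the same environment). With
#' `split_rule = "first_two_vs_third"` the first two progenitor
#' replicates are used for `F_ratio` and only the held-out third for
#' the `f_over_F` denominator, so that measurement error of the
#' progenitor rate does not enter both quantities and induce a
#' spurious negative correlation between them.
#'
#' @param progenitor_rates data frame `environment_id, replicate, rate`
#'   (progenitor measured in each environment).
#' @param evolved_rates data frame `environment_id, population, rate`
#'   (evolved populations measured in their own environment).
#' @param sc_reference mean progenitor growth rate in the base medium.
#' @param split_rule `"none"` uses all progenitor replicates for both
#'   quantities; `"first_two_vs_third"` applies the error-avoidance
#'   split (requires >= 3 replicates per environment).
#' @return tibble of class `env_fitness`: one row per environment with
#'   `F_ratio`, `F_ratio_se`, `f_over_F_mean`, `f_over_F_sd`,
#'   `n_populations`, and `stress` (`1 - F_ratio`, so that larger
#'   values mean more stress).
#' @export
environment_fitness_summary <- function(progenitor_rates, evolved_rates,
                                        sc_reference,
                                        split_rule = c("none",
                                                       "first_two_vs_third")) {
  split_rule <- match.arg(split_rule)
  stopifnot(sc_reference > 0)
  envs <- sort(unique(progenitor_rates$environment_id))
  out <- lapply(envs, function(e) {
    pr <- progenitor_rates[progenitor_rates$environment_id == e, ]
    pr <- pr[order(pr$replicate), ]
    if (split_rule == "first_two_vs_third" && nrow(pr) < 3) {
      stop("environment ", e, ": need >= 3 progenitor replicates for the ",
           "first_two_vs_third split")
    }
    f_reps <- if (split_rule == "first_two_vs_third") pr$rate[1:2] else pr$rate
    denom_reps <- if (split_rule == "first_two_vs_third") {
      pr$rate[3:nrow(pr)]
    } else pr$rate
    # per-replicate ratios, then averaged
    ratios <- relative_fitness(f_reps, sc_reference)
    F_ratio <- mean(ratios)
    F_se <- stats::sd(ratios) / sqrt(length(ratios))
    ev <- evolved_rates[evolved_rates$environment_id == e, ]
    fF <- if (nrow(ev)) relative_fitness(ev$rate, mean(denom_reps)) else
      numeric(0)
    tibble::tibble(environment_id = e, F_ratio = F_ratio,
                   F_ratio_se = F_se,
                   f_over_F_mean = if (length(fF)) mean(fF) else NA_real_,
                   f_over_F_sd = if (length(fF) > 1) stats::sd(fF) else NA_real_,
                   n_populations = length(fF),
                   stress = 1 - F_ratio)
  })
  res <- dplyr::bind_rows(out)
  structure(res, split_rule = split_rule,
            class = c("env_fitness", class(res)))
}
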