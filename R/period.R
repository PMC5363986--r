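#' Oscillation period of a species timecourse
#'
#' Detects successive interior maxima of a species series after discarding
#' an initial transient, and reports the mean inter-peak interval over a
#' measurement window.  An amplitude filter is applied: if the
#' peak-to-trough amplitude within the window falls below
#' `amplitude_threshold` the trace is classified as non-oscillating,
#' so small numerical ripples around a steady state are not mistaken for
#' oscillations.
#'
#' @param trajectory A `crypt_trajectory` covering at least
#'   `transient_h + window_h` hours.
#' @param species Species name (default `"H1"`, Hes1).
#' @param cell Cell identifier (default: first cell).
#' @param amplitude_threshold Minimum peak-to-trough amplitude (nM).
#' @param transient_h Initial transient discarded before measurement (h).
#' @param window_h Measurement window following the transient (h).
#' @return A `period_measurement`: list with `oscillating` (logical),
#'   `period_h` (`NA` when not oscillating), `amplitude` (peak-to-trough,
#'   nM), `peak_times_min`, and `indeterminate` (`TRUE` when amplitude is
#'   above threshold but fewer than 3 peaks were found).
#' @export
measure_period <- function(trajectory, species = "H1",
                           cell = trajectory$cells[1],
                           amplitude_threshold = 0.001,
                           transient_h = 2, window_h = 12) {
  stopifnot(inherits(trajectory, "crypt_trajectory"))
  t_min <- trajectory$times
  if (max(t_min) < (transient_h + window_h) * 60 - 1e-9) {
    stop("trajectory must cover at least ", transient_h + window_h,
         " h for period measurement", call. = FALSE)
  }
  y <- species_series(trajectory, species, cell)
  sel <- t_min >= transient_h * 60 & t_min <= (transient_h + window_h) * 60
  tt <- t_min[sel]; yy <- y[sel]
  amp <- max(yy) - min(yy)
  res <- list(oscillating = FALSE, period_h = NA_real_, amplitude = amp,
              peak_times_min = numeric(0), indeterminate = FALSE)
  class(res) <- "period_measurement"
  if (amp < amplitude_threshold) return(res)
  pk <- local_maxima(tt, yy)
  # drop spurious maxima on near-flat stretches: require local prominence
  # relative to the window amplitude
  if (length(pk) >= 2L) {
    keep <- vapply(pk, function(i) {
      lo <- max(1L, i - 10L); hi <- min(length(yy), i + 10L)
      (yy[i] - min(yy[lo:hi])) > amp / 200
    }, logical(1))
    pk <- pk[keep]
  }
  # sub-sample peak timing by a parabola through the three points around
  # each maximum (period sensitivity needs better than grid resolution)
  pt <- vapply(pk, function(i) {
    if (i <= 1L || i >= length(yy)) return(tt[i])
    denom <- yy[i - 1L] - 2 * yy[i] + yy[i + 1L]
    if (denom >= 0) return(tt[i])
    tt[i] + 0.5 * (yy[i - 1L] - yy[i + 1L]) / denom *
      (tt[i + 1L] - tt[i])
  }, numeric(1))
  res$peak_times_min <- pt
  if (length(pk) < 3L) {
    res$indeterminate <- TRUE
    return(res)
  }
  res$oscillating <- TRUE
  res$period_h <- mean(diff(pt)) / 60
  res
}

local_maxima <- function(tt, yy) {
  n <- length(yy)
  if (n < 3L) return(integer(0))
  which(yy[2:(n - 1)] > yy[1:(n - 2)] & yy[2:(n - 1)] >= yy[3:n]) + 1L
}

#' @export
print.period_measurement <- function(x, ...) {
  if (x$oscillating) {
    cat("oscillating: period", signif(x$period_h, 4), "h, amplitude",
        signif(x$amplitude, 4), "nM,", length(x$peak_times_min), "peaks\n")
  } else if (x$indeterminate) {
    cat("indeterminate: amplitude", signif(x$amplitude, 4),
        "nM above threshold but fewer than 3 peaks\n")
  } else {
    cat("not oscillating (amplitude", signif(x$amplitude, 4), "nM)\n")
  }
  invisible(x)
}

#' Regime classification over a theta2 x W grid
#'
#' For every combination of promoter balance `theta2` and Wnt stimulus `W`,
#' runs the healthy two-cell scenario and classifies the late-time Hes1
#' behaviour as `"oscillatory"` (amplitude above the filter in the
#' measurement window ending at the horizon), `"heterogeneous-bistable"`
#' (non-oscillating, but the two cells' Hes1 levels differ by more than
#' `gap_frac` of the larger at the horizon) or `"homogeneous-steady"`.
#'
#' @param theta2_grid,W_grid Numeric grids (`theta2` within `[0, 1]`).
#' @param params A [crypt_params()] object.
#' @param hours Simulation horizon per cell pair (h).
#' @param gap_frac Relative inter-cell Hes1 gap defining bistability.
#' @param amplitude_threshold Oscillation amplitude filter (nM).
#' @param scenario_kind Scenario builder kind (default healthy pair).
#' @return A long-format data.frame with columns `theta2`, `W`, `regime`,
#'   `period_h`, `amplitude`, `hes1_gap`.
#' @export
sweep_regimes <- function(theta2_grid, W_grid, params = crypt_params(),
                          hours = 36, gap_frac = 0.05,
                          amplitude_threshold = 0.001,
                          scenario_kind = "healthy_pair") {
  if (any(theta2_grid < 0 | theta2_grid > 1)) {
    stop("'theta2_grid' must lie within [0, 1]", call. = FALSE)
  }
  if (any(W_grid < 0)) stop("'W_grid' must be non-negative", call. = FALSE)
  out <- NULL
  for (th in theta2_grid) {
    for (w in W_grid) {
      sc <- build_scenario(scenario_kind, params, theta2 = th, W = w,
                           hours = hours)
      tr <- run_deterministic(sc, params)
      pm <- measure_period(tr, "H1", cell = "cell1",
                           amplitude_threshold = amplitude_threshold,
                           transient_h = hours - 12, window_h = 12)
      last <- dim(tr$conc)[1]
      h1 <- tr$conc[last, , "H1"]
      gap <- abs(diff(h1)) / max(max(h1), 1e-12)
      regime <- if (pm$oscillating) {
        "oscillatory"
      } else if (gap > gap_frac) {
        "heterogeneous-bistable"
      } else {
        "homogeneous-steady"
      }
      out <- rbind(out, data.frame(theta2 = th, W = w, regime = regime,
                                   period_h = pm$period_h,
                                   amplitude = pm$amplitude,
                                   hes1_gap = unname(gap)))
    }
  }
  out
}
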