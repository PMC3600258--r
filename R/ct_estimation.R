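#' Baseline-correct an amplification curve
#'
#' Fits a straight line (ordinary least squares) to the fluorescence over
#' the baseline cycle window and subtracts the fitted line from every
#' cycle, removing both the constant background and any linear drift.
#' Corrected values may be negative.
#'
#' @param curve data.frame with columns `cycle` (contiguous, strictly
#'   increasing integers) and `fluorescence`.
#' @param baseline_window length-2 integer vector, first and last cycle of
#'   the baseline window (default cycles 3-15; the first two cycles are
#'   excluded by convention for settling artifacts). Must span at least 3
#'   cycles inside the curve.
#' @return The curve with corrected `fluorescence`, plus attributes
#'   `baseline_mean` and `baseline_sd` (residual SD within the window).
#' @export
baseline_correct <- function(curve, baseline_window = c(3L, 15L)) {
  check_curve(curve)
  w <- curve$cycle >= baseline_window[1] & curve$cycle <= baseline_window[2]
  if (sum(w) < 3) stop_input("baseline window must contain at least 3 cycles")
  x <- curve$cycle[w]
  y <- curve$fluorescence[w]
  # closed-form simple linear regression
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  fitted_all <- intercept + slope * curve$cycle
  resid <- y - (intercept + slope * x)
  out <- curve
  out$fluorescence <- curve$fluorescence - fitted_all
  attr(out, "baseline_mean") <- yb
  attr(out, "baseline_sd") <- stats::sd(resid)
  out
}

#' Compute the threshold cycle (Ct) of an amplification curve
#'
#' Baseline-corrects the curve, sets a fluorescence threshold, and reports
#' the fractional cycle at which the corrected signal first crosses the
#' threshold and stays above it for at least two consecutive cycles (a
#' guard against single-cycle noise spikes), while still growing
#' geometrically (at least 25% per cycle) across the crossing — real
#' amplification is exponential at threshold, so this rejects the slow
#' linear creep left by an imperfectly fitted baseline. The crossing point is
#' interpolated between the last sub-threshold and first supra-threshold
#' cycle; interpolation is done on log fluorescence when both bracketing
#' values are positive (the signal is exponential near threshold), falling
#' back to linear otherwise. If the signal never sustains a crossing the
#' result is UNDETERMINED (`ct = NA`).
#'
#' In `auto` mode the threshold is 10x the baseline residual SD (the
#' classic 10-sigma rule), floored at `1e-6` of the maximum corrected
#' fluorescence among the plate's amplifying wells (`plate_max`; the
#' curve's own maximum when not supplied) so noise-free curves still get a
#' positive threshold.
#'
#' @inheritParams baseline_correct
#' @param mode `"auto"` (threshold from baseline noise) or `"fixed"`.
#' @param fixed_threshold required fluorescence threshold in `fixed` mode.
#' @param plate_max maximum baseline-corrected fluorescence over the
#'   plate's positive wells, used only for the auto-threshold floor.
#' @return An object of class `ct_result`: list with `ct` (fractional
#'   cycle, or `NA` for UNDETERMINED), `undetermined`, `threshold`,
#'   `baseline_mean`, `baseline_sd`.
#' @examples
#' cyc <- 1:45
#' curve <- data.frame(cycle = cyc, fluorescence = 3 / (1 + exp(-1.8 * (cyc - 30))))
#' compute_ct(curve)$ct
#' @export
compute_ct <- function(curve, mode = c("auto", "fixed"), fixed_threshold = NULL,
                       baseline_window = c(3L, 15L), plate_max = NULL) {
  mode <- match.arg(mode)
  corr <- baseline_correct(curve, baseline_window)
  bl_mean <- attr(corr, "baseline_mean")
  bl_sd <- attr(corr, "baseline_sd")
  f <- corr$fluorescence
  if (mode == "fixed") {
    if (is.null(fixed_threshold)) {
      stop_input("fixed mode requires fixed_threshold")
    }
    threshold <- fixed_threshold
  } else {
    pm <- plate_max %||% max(f)
    threshold <- max(10 * bl_sd, 1e-6 * pm, .Machine$double.eps)
  }
  ct <- crossing_point(corr$cycle, f, threshold)
  structure(list(ct = ct, undetermined = is.na(ct), threshold = threshold,
                 baseline_mean = bl_mean, baseline_sd = bl_sd),
            class = "ct_result")
}

# First sustained crossing of `threshold`, interpolated; NA if none.
# Besides staying above threshold for 2 cycles, the signal must keep
# growing geometrically (>= growth_min per cycle) across the crossing:
# true amplification is exponential there, whereas a residual linear
# tilt left by an imperfect baseline fit creeps over the threshold with
# near-zero relative growth and must not be read as a crossing.
crossing_point <- function(cycle, f, threshold, growth_min = 1.25) {
  n <- length(f)
  above <- f >= threshold
  growing <- f[-1] >= growth_min * f[-n]
  sustained <- which(above[-n] & above[-1] & growing)
  if (length(sustained) == 0) return(NA_real_)
  i <- sustained[1]
  if (i == 1) return(cycle[1])
  f_lo <- f[i - 1]; f_hi <- f[i]
  frac <- if (f_lo > 0 && f_hi > f_lo) {
    (log(threshold) - log(f_lo)) / (log(f_hi) - log(f_lo))
  } else if (f_hi > f_lo) {
    (threshold - f_lo) / (f_hi - f_lo)
  } else 0
  cycle[i - 1] + min(max(frac, 0), 1) * (cycle[i] - cycle[i - 1])
}

#' @export
print.ct_result <- function(x, ...) {
  cat("<ct_result>",
      if (x$undetermined) "UNDETERMINED" else sprintf("Ct = %.2f", x$ct),
      sprintf("(threshold %.4g, baseline sd %.4g)\n", x$threshold,
              x$baseline_sd))
  invisible(x)
}

check_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("cycle", "fluorescence") %in% names(curve))) {
    stop_input("curve must be a data.frame with columns cycle, fluorescence")
  }
  d <- diff(curve$cycle)
  if (length(d) > 0 && any(d != 1)) {
    stop_input("curve cycles must be contiguous and strictly increasing")
  }
  invisible(curve)
}

# Ct estimation for every (well, channel) curve of a plate, sharing one
# plate-wide auto-threshold floor.
estimate_cts_df <- function(curves, baseline_window = c(3L, 15L)) {
  key <- interaction(curves$well_id, curves$channel, drop = TRUE)
  groups <- split(curves[c("cycle", "fluorescence")], key)
  corrected <- lapply(groups, function(g) {
    g <- g[order(g$cycle), ]
    baseline_correct(g, baseline_window)
  })
  plate_max <- max(vapply(corrected, function(g) max(g$fluorescence), 0))
  res <- do.call(rbind, lapply(corrected, function(g) {
    bl_sd <- attr(g, "baseline_sd")
    threshold <- max(10 * bl_sd, 1e-6 * plate_max, .Machine$double.eps)
    ct <- crossing_point(g$cycle, g$fluorescence, threshold)
    data.frame(ct = ct, threshold = threshold, baseline_sd = bl_sd)
  }))
  first <- match(levels(key), key)
  data.frame(well_id = curves$well_id[first], channel = curves$channel[first],
             res, stringsAsFactors = FALSE, row.names = NULL)
}
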