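#' Predict an Abeta time course for a new dosing regimen
#'
#' Re-integrates the three components that determine an Abeta profile — the
#' new exposure time course, the fitted intrinsic exposure-response
#' relationship (Imax, IC50, gamma), and the fitted turnover rate (kout) —
#' to predict the response to a regimen that was never studied, e.g.
#' predicting an oral time course from parameters estimated on subcutaneous
#' data. This is how a validated fit replaces studies that would generate no
#' new information.
#'
#' @param fit A converged [fit_turnover()] result.
#' @param new_drive A [conc_profile] for the new regimen.
#' @param times Output time grid, hours, starting at 0.
#' @param force Simulate even from a non-converged fit? Default `FALSE`.
#' @param ... Passed to [simulate_trajectory()] (e.g. `method`).
#' @return An `abeta_trajectory` data frame.
#' @export
predict_regimen <- function(fit, new_drive, times, force = FALSE, ...) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$convergence$status == "non-converged" && !force)
    stop("fit did not converge; pass force = TRUE to simulate anyway")
  simulate_trajectory(fitted_params(fit), new_drive, times, ...)
}

#' Summarize a concentration-effect hysteresis loop
#'
#' Because Abeta responds to drug through its generation rate, the effect
#' lags the exposure: plotting Abeta level against the concurrent
#' concentration traces a loop rather than a curve. This summarizer orders
#' the paired observations by time, closes the polygon, and reports the
#' shoelace signed area (concentration x percent units), an orientation tag,
#' the effect-nadir and drive-peak times, and the lag between them. An area
#' indistinguishable from zero (relative to the data's bounding box) is
#' tagged `"none"` — the memoryless, no-hysteresis case.
#'
#' @param times Sampling times, hours; must be strictly monotone
#'   (increasing, or decreasing for a reversed traversal).
#' @param conc Drive concentrations at `times`.
#' @param effect_pct Abeta percent-of-control at `times`.
#' @param tol Relative tolerance (fraction of the bounding-box area) below
#'   which the loop is called degenerate.
#' @return An object of class `loop_summary` with `area`, `orientation`
#'   (`"clockwise"`, `"counterclockwise"`, `"none"`), `nadir_time_h`,
#'   `peak_time_h` and `lag_h`.
#' @export
hysteresis_loop <- function(times, conc, effect_pct, tol = 1e-6) {
  stopifnot(is.numeric(times), is.numeric(conc), is.numeric(effect_pct),
            length(times) == length(conc),
            length(conc) == length(effect_pct))
  if (length(times) < 4L)
    stop("need >= 4 time points covering effect onset and offset")
  inc <- !is.unsorted(times, strictly = TRUE)
  dec <- !is.unsorted(rev(times), strictly = TRUE)
  if (!inc && !dec) stop("'times' must be strictly monotone")
  x <- conc
  y <- effect_pct
  n <- length(x)
  xi <- c(x, x[1L]); yi <- c(y, y[1L])
  area <- sum(xi[-(n + 1L)] * yi[-1L] - xi[-1L] * yi[-(n + 1L)]) / 2
  box <- diff(range(x)) * diff(range(y))
  orientation <- if (box == 0 || abs(area) < tol * box) "none"
                 else if (area > 0) "counterclockwise" else "clockwise"
  nadir <- times[which.min(effect_pct)]
  peak <- times[which.max(conc)]
  structure(list(area = area, orientation = orientation,
                 nadir_time_h = nadir, peak_time_h = peak,
                 lag_h = nadir - peak),
            class = "loop_summary")
}

#' @export
print.loop_summary <- function(x, ...) {
  cat(sprintf("Hysteresis loop: area %.4g (%s); drive peak %g h, effect nadir %g h, lag %g h\n",
              x$area, x$orientation, x$peak_time_h, x$nadir_time_h, x$lag_h))
  invisible(x)
}

#' Compare intrinsic exposure-response curves across fits
#'
#' Evaluates `Rgen(C)` for each fit on a shared log-spaced concentration
#' grid and measures how far the curves are from overlapping within the
#' 0-50% lowering band (`Rgen` from 1 down to 0.5) — the working range over
#' which CSF Abeta can stand in for brain Abeta when the intrinsic curves
#' coincide. The band is taken per curve (each fit's own concentrations
#' giving at most 50% lowering) and differences are measured on the
#' intersection of all bands. The intrinsic curve contains no kout, so fits
#' differing only in turnover compare as identical.
#'
#' @param fits A list of >= 2 [fit_turnover()] results (or any objects with
#'   `$estimates` holding `imax`, `ic50`, `gamma`), sharing a concentration
#'   unit.
#' @param n_grid Number of log-spaced grid points (default 200).
#' @param conc_range Optional `c(min, max)` grid range; default
#'   `min(ic50)/100` to `max(ic50) * 100` across fits.
#' @param on Compare on `"rgen"` (fraction of control generation, default)
#'   or `"lowering"` (percent lowering, `100 * (1 - Rgen)`); the band is
#'   0-50% lowering either way.
#' @return An object of class `curve_comparison`: the grid, the per-fit
#'   curve matrix, `max_abs_diff` and `rms_diff` over the common band, and
#'   `band_empty` flagging a disjoint-band comparison (differences `NA`).
#' @export
compare_intrinsic_curves <- function(fits, n_grid = 200L, conc_range = NULL,
                                     on = c("rgen", "lowering")) {
  on <- match.arg(on)
  stopifnot(is.list(fits), length(fits) >= 2L)
  pars <- lapply(fits, function(f) {
    e <- if (inherits(f, "fit_result")) f$estimates else f$estimates
    turnover_params(kout = if (is.null(e$kout)) 1 else e$kout,
                    imax = e$imax, ic50 = e$ic50, gamma = e$gamma)
  })
  if (is.null(conc_range)) {
    ic50s <- vapply(pars, function(p) p$ic50, numeric(1L))
    conc_range <- c(min(ic50s) / 100, max(ic50s) * 100)
  }
  grid <- exp(seq(log(conc_range[1L]), log(conc_range[2L]),
                  length.out = n_grid))
  curves <- vapply(pars, function(p) rgen(p, grid), numeric(length(grid)))
  in_band <- curves >= 0.5            # each curve's own 0-50% lowering band
  common <- rowSums(in_band) == ncol(curves)
  vals <- if (on == "rgen") curves else 100 * (1 - curves)
  if (!any(common)) {
    max_d <- rms_d <- NA_real_
    band_empty <- TRUE
  } else {
    sub <- vals[common, , drop = FALSE]
    pair_diff <- abs(sub[, rep(seq_len(ncol(sub)), each = ncol(sub))] -
                     sub[, rep(seq_len(ncol(sub)), times = ncol(sub))])
    max_d <- max(pair_diff)
    rms_d <- sqrt(mean((sub - rowMeans(sub))^2))
    band_empty <- FALSE
  }
  structure(list(grid = grid, curves = vals, scale = on,
                 band_mask = common, max_abs_diff = max_d,
                 rms_diff = rms_d, band_empty = band_empty),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Intrinsic-curve comparison (%d curves, scale: %s)\n",
              ncol(x$curves), x$scale))
  if (x$band_empty) {
    cat("  0-50% lowering bands are disjoint; no common comparison region\n")
  } else {
    cat(sprintf("  common band: %d of %d grid points\n",
                sum(x$band_mask), length(x$grid)))
    cat(sprintf("  max |difference| in band: %.4g\n", x$max_abs_diff))
    cat(sprintf("  RMS difference in band  : %.4g\n", x$rms_diff))
  }
  invisible(x)
}
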