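#' Turnover (indirect-response) parameter set
#'
#' Bundles the pharmacodynamic parameters of the Abeta turnover model for one
#' compartment/analyte: the first-order clearance rate constant `kout`, the
#' maximum fractional inhibition of generation `imax`, the half-maximal drive
#' concentration `ic50`, and the Hill coefficient `gamma`. The zero-order
#' generation rate `kin` is derived, never set: on the percent-of-control
#' scale the vehicle steady state is 100%, so `kin = 100 * kout` (%/h).
#'
#' @param kout First-order clearance rate constant, 1/h. Must be > 0.
#' @param imax Maximum fractional inhibition of generation, in (0, 1].
#'   An `imax` of 1 means the compound can shut generation off completely.
#' @param ic50 Drive concentration at half-maximal inhibition, in the same
#'   (unchecked) units as the concentration drive. Must be > 0.
#' @param gamma Hill coefficient controlling sigmoid steepness. Must be > 0.
#'
#' @return An object of class `turnover_params` with elements `kout`, `imax`,
#'   `ic50`, `gamma` and the derived `kin`.
#' @examples
#' p <- turnover_params(kout = 1.42, imax = 1, ic50 = 50, gamma = 1)
#' p$kin  # 142 %/h
#' @export
turnover_params <- function(kout, imax = 1, ic50, gamma = 1) {
  stopifnot(
    is.numeric(kout), length(kout) == 1L, is.finite(kout),
    is.numeric(imax), length(imax) == 1L, is.finite(imax),
    is.numeric(ic50), length(ic50) == 1L, is.finite(ic50),
    is.numeric(gamma), length(gamma) == 1L, is.finite(gamma)
  )
  if (kout <= 0) stop("'kout' must be > 0 (1/h)")
  if (imax <= 0 || imax > 1) stop("'imax' must lie in (0, 1]")
  if (ic50 <= 0) stop("'ic50' must be > 0")
  if (gamma <= 0) stop("'gamma' must be > 0")
  structure(
    list(kout = kout, imax = imax, ic50 = ic50, gamma = gamma,
         kin = steady_state_kin(kout)),
    class = "turnover_params"
  )
}

#' @export
print.turnover_params <- function(x, ...) {
  cat("Abeta turnover parameters\n")
  cat(sprintf("  kout  : %.4g /h   (offset half-time %.3g h)\n",
              x$kout, offset_halftime(x$kout)))
  cat(sprintf("  kin   : %.4g %%/h (derived, 100 x kout)\n", x$kin))
  cat(sprintf("  Imax  : %.4g\n", x$imax))
  cat(sprintf("  IC50  : %.4g\n", x$ic50))
  cat(sprintf("  gamma : %.4g\n", x$gamma))
  invisible(x)
}

#' Sigmoidal inhibition of the Abeta generation rate
#'
#' Fractional inhibition of the zero-order generation rate at drive
#' concentration `c`: `imax * c^gamma / (ic50^gamma + c^gamma)`. Zero at
#' `c = 0`, half of `imax` at `c = ic50` for any `gamma`, asymptote `imax`.
#'
#' @param p A [turnover_params()] object.
#' @param conc Drive concentration(s), >= 0 (vectorized).
#' @return Fractional inhibition in `[0, imax]`, same length as `conc`.
#' @examples
#' p <- turnover_params(kout = 1, imax = 0.8, ic50 = 10, gamma = 1)
#' hill_inhibition(p, 10)  # 0.4
#' @export
hill_inhibition <- function(p, conc) {
  stopifnot(inherits(p, "turnover_params"), is.numeric(conc))
  if (any(conc < 0)) stop("drive concentration must be >= 0")
  # (c/ic50)^gamma form avoids overflow for large conc and large gamma
  x <- (conc / p$ic50)^p$gamma
  ifelse(is.infinite(x), p$imax, p$imax * x / (1 + x))
}

#' Intrinsic exposure-response relationship (Rgen)
#'
#' Generation rate as a fraction of control at drive concentration `c`:
#' `Rgen = 1 - imax * c^gamma / (ic50^gamma + c^gamma)`. This is the intrinsic
#' PK/PD relationship of a generation inhibitor, free of PK and turnover
#' confounds; at steady state under repeated dosing the time-weighted-average
#' Abeta level equals `100 * <Rgen>`.
#'
#' @inheritParams hill_inhibition
#' @return Fraction of the control generation rate in `[1 - imax, 1]`.
#' @examples
#' p <- turnover_params(kout = 0.49, imax = 0.9, ic50 = 25)
#' rgen(p, 25)  # 0.55
#' @export
rgen <- function(p, conc) {
  1 - hill_inhibition(p, conc)
}

#' Steady-state generation rate on the percent-of-control scale
#'
#' At vehicle steady state the Abeta level is constant at 100% of baseline,
#' so the zero-order generation rate is `kin = 100 * kout` (%/h).
#'
#' @param kout First-order clearance rate constant, 1/h, > 0.
#' @return Generation rate in %/h.
#' @export
steady_state_kin <- function(kout) {
  stopifnot(is.numeric(kout))
  if (any(kout <= 0)) stop("'kout' must be > 0")
  100 * kout
}

#' Half-time of return to baseline after washout
#'
#' After complete drug washout the deviation from baseline decays
#' mono-exponentially at rate `kout`; the deviation halves every
#' `log(2) / kout` hours. Governs the onset/offset speed and the "blunting"
#' of response profiles in species with slow turnover.
#'
#' @param kout First-order clearance rate constant, 1/h, > 0.
#' @return Half-time in hours.
#' @export
offset_halftime <- function(kout) {
  stopifnot(is.numeric(kout))
  if (any(kout <= 0)) stop("'kout' must be > 0")
  log(2) / kout
}
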