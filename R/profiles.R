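#' Concentration drives
#'
#' A concentration drive ("profile") maps time in hours to the drug
#' concentration that drives the inhibition of Abeta generation. The drive
#' may be the plasma, brain, or CSF concentration depending on the data in
#' hand; the model is agnostic and the IC50 inherits whatever unit the drive
#' uses. Available drives:
#' * [constant_profile()] — a fixed concentration (closed-form dynamics).
#' * [bateman_profile()] — one-compartment first-order absorption/elimination.
#' * [tabulated_profile()] — interpolation of an observed table.
#' * [repeated_profile()] — periodic repetition of any base drive (dosing
#'   every `period` hours).
#'
#' All drives are evaluated with [conc_at()].
#'
#' @param profile A `conc_profile` object.
#' @param t Time(s) in hours, >= 0 (vectorized).
#' @return `conc_at()` returns non-negative concentration(s).
#' @name conc_profile
NULL

#' Evaluate a concentration drive
#' @rdname conc_profile
#' @export
conc_at <- function(profile, t) {
  UseMethod("conc_at")
}

new_conc_profile <- function(x, subclass) {
  structure(x, class = c(subclass, "conc_profile"))
}

#' Constant-concentration drive
#' @param conc Constant concentration, >= 0.
#' @rdname conc_profile
#' @export
constant_profile <- function(conc) {
  stopifnot(is.numeric(conc), length(conc) == 1L, is.finite(conc), conc >= 0)
  new_conc_profile(list(conc = conc), "constant_profile")
}

#' @export
conc_at.constant_profile <- function(profile, t) {
  if (any(t < 0)) stop("time must be >= 0")
  rep(profile$conc, length(t))
}

#' One-compartment PK parameters
#'
#' Parameters of a one-compartment model with first-order absorption and
#' elimination, dosed per kg of body weight. Purely scaffolding for synthetic
#' studies and regimen prediction; no claim of mechanistic realism.
#'
#' @param dose Dose amount per kg (e.g. mg/kg), > 0.
#' @param ka Absorption rate constant, 1/h, > 0.
#' @param ke Elimination rate constant, 1/h, > 0. `ka == ke` is handled as
#'   the analytic limiting case, not an error.
#' @param vd Apparent volume of distribution per kg (e.g. L/kg), > 0.
#' @param f_abs Bioavailable fraction, in (0, 1].
#' @return An object of class `one_cmt_params`.
#' @export
one_cmt_params <- function(dose, ka, ke, vd, f_abs = 1) {
  vals <- c(dose = dose, ka = ka, ke = ke, vd = vd, f_abs = f_abs)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals[c("dose", "ka", "ke", "vd")] <= 0))
    stop("'dose', 'ka', 'ke' and 'vd' must all be > 0")
  if (f_abs <= 0 || f_abs > 1) stop("'f_abs' must lie in (0, 1]")
  structure(list(dose = dose, ka = ka, ke = ke, vd = vd, f_abs = f_abs),
            class = "one_cmt_params")
}

#' Bateman concentration-time function
#'
#' First-order absorption/elimination profile
#' `C(t) = f * dose * ka / (vd * (ka - ke)) * (exp(-ke t) - exp(-ka t))`,
#' with the `t * exp(-ke t)` limiting form when `ka` and `ke` coincide.
#' `C(0) = 0`; the peak occurs at `log(ka/ke) / (ka - ke)`.
#'
#' @param pk A [one_cmt_params()] object.
#' @param t Time(s) in hours, >= 0.
#' @return Concentration(s) in `dose/vd` units.
#' @export
bateman_concentration <- function(pk, t) {
  stopifnot(inherits(pk, "one_cmt_params"), is.numeric(t))
  if (any(t < 0)) stop("time must be >= 0")
  with(pk, {
    if (abs(ka - ke) < 1e-9 * ke) {
      f_abs * dose * ka / vd * t * exp(-ke * t)
    } else {
      f_abs * dose * ka / (vd * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
    }
  })
}

#' One-compartment drive
#' @param pk A [one_cmt_params()] object.
#' @rdname conc_profile
#' @export
bateman_profile <- function(pk) {
  stopifnot(inherits(pk, "one_cmt_params"))
  new_conc_profile(list(pk = pk), "bateman_profile")
}

#' @export
conc_at.bateman_profile <- function(profile, t) {
  bateman_concentration(profile$pk, t)
}

#' Tabulated concentration-time data
#'
#' A table of observed (time, concentration) pairs with an explicit
#' interpolation rule: `"linear"` or `"loglinear"` (linear in log
#' concentration, i.e. mono-exponential segments). The rule is a single tag
#' for the whole table; the log-linear rule falls back to linear across any
#' segment touching a zero concentration.
#'
#' @param times Hours, strictly increasing.
#' @param concs Concentrations, >= 0, same length as `times`.
#' @param interp Interpolation rule, `"linear"` (default) or `"loglinear"`.
#' @return An object of class `conc_table`.
#' @export
conc_table <- function(times, concs, interp = c("linear", "loglinear")) {
  interp <- match.arg(interp)
  stopifnot(is.numeric(times), is.numeric(concs),
            length(times) == length(concs), length(times) >= 1L)
  if (anyDuplicated(times)) stop("table times must be unique")
  if (is.unsorted(times, strictly = TRUE)) stop("table times must be ascending")
  if (any(concs < 0)) stop("concentrations must be >= 0")
  structure(list(times = as.numeric(times), concs = as.numeric(concs),
                 interp = interp),
            class = "conc_table")
}

#' Interpolate a concentration table
#'
#' Evaluates a [conc_table()] at arbitrary times per its interpolation rule.
#' At a node the node value is returned exactly. Queries outside the table's
#' time range are an error unless `extrapolate = TRUE`, in which case times
#' before the first node return the first value and times after the last node
#' decay log-linearly at the rate of the final segment (or hold the last
#' value if that segment is flat or touches zero).
#'
#' @param tab A [conc_table()].
#' @param t Query time(s) in hours.
#' @param extrapolate Allow queries outside the table range? Default `FALSE`.
#' @return Interpolated concentration(s).
#' @export
tabulated_concentration <- function(tab, t, extrapolate = FALSE) {
  stopifnot(inherits(tab, "conc_table"), is.numeric(t))
  tt <- tab$times
  cc <- tab$concs
  out_of_range <- t < tt[1L] | t > tt[length(tt)]
  if (any(out_of_range) && !extrapolate) {
    stop(sprintf("time(s) outside table range [%g, %g] h; set extrapolate = TRUE to allow",
                 tt[1L], tt[length(tt)]))
  }
  res <- numeric(length(t))
  inside <- !out_of_range
  if (any(inside)) {
    ti <- t[inside]
    if (tab$interp == "linear" || length(tt) == 1L) {
      res[inside] <- stats::approx(tt, cc, xout = ti, ties = "ordered")$y
    } else {
      res[inside] <- vapply(ti, interp_loglinear_one, numeric(1L),
                            times = tt, concs = cc)
    }
  }
  if (any(out_of_range)) {
    res[t < tt[1L]] <- cc[1L]
    after <- t > tt[length(tt)]
    if (any(after)) {
      res[after] <- extrapolate_terminal(tab, t[after])
    }
  }
  res
}

interp_loglinear_one <- function(t, times, concs) {
  i <- findInterval(t, times, rightmost.closed = TRUE)
  if (t == times[i]) return(concs[i])
  c0 <- concs[i]; c1 <- concs[i + 1L]
  w <- (t - times[i]) / (times[i + 1L] - times[i])
  if (c0 <= 0 || c1 <= 0) {
    (1 - w) * c0 + w * c1            # linear fallback across zeros
  } else {
    exp((1 - w) * log(c0) + w * log(c1))
  }
}

extrapolate_terminal <- function(tab, t) {
  n <- length(tab$times)
  c_last <- tab$concs[n]
  if (n == 1L) return(rep(c_last, length(t)))
  c_prev <- tab$concs[n - 1L]
  dt <- tab$times[n] - tab$times[n - 1L]
  if (c_last <= 0 || c_prev <= 0 || c_last >= c_prev) {
    rep(c_last, length(t))           # no decaying terminal slope to use
  } else {
    kz <- log(c_prev / c_last) / dt
    c_last * exp(-kz * (t - tab$times[n]))
  }
}

#' Tabulated drive
#' @param tab A [conc_table()].
#' @param extrapolate Allow evaluation outside the table's time range?
#' @rdname conc_profile
#' @export
tabulated_profile <- function(tab, extrapolate = FALSE) {
  stopifnot(inherits(tab, "conc_table"))
  new_conc_profile(list(tab = tab, extrapolate = isTRUE(extrapolate)),
                   "tabulated_profile")
}

#' @export
conc_at.tabulated_profile <- function(profile, t) {
  tabulated_concentration(profile$tab, t, extrapolate = profile$extrapolate)
}

#' Periodic repetition of a base drive
#' @param base A `conc_profile` defined at least on `[0, period]`.
#' @param period Dosing interval in hours, > 0.
#' @rdname conc_profile
#' @export
repeated_profile <- function(base, period) {
  stopifnot(inherits(base, "conc_profile"), is.numeric(period),
            length(period) == 1L, period > 0)
  new_conc_profile(list(base = base, period = period), "repeated_profile")
}

#' @export
conc_at.repeated_profile <- function(profile, t) {
  if (any(t < 0)) stop("time must be >= 0")
  conc_at(profile$base, t %% profile$period)
}

#' Read / write a concentration table as CSV
#'
#' The CSV schema is two columns, `time_h` and `conc`, plus the
#' interpolation rule passed separately (it is not stored in the file).
#'
#' @param path CSV file path.
#' @param interp Interpolation rule for the resulting [conc_table()].
#' @return `read_conc_table()` returns a [conc_table()];
#'   `write_conc_table()` returns `path` invisibly.
#' @export
read_conc_table <- function(path, interp = c("linear", "loglinear")) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "conc") %in% names(df)))
    stop("concentration CSV must have columns 'time_h' and 'conc'")
  conc_table(df$time_h, df$conc, interp = match.arg(interp))
}

#' @param tab A [conc_table()] to write.
#' @rdname read_conc_table
#' @export
write_conc_table <- function(tab, path) {
  stopifnot(inherits(tab, "conc_table"))
  utils::write.csv(data.frame(time_h = tab$times, conc = tab$concs),
                   path, row.names = FALSE)
  invisible(path)
}
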