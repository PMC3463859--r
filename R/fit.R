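#' Fit specification for turnover parameter estimation
#'
#' Collects every estimation choice the analyst must make explicit: starting
#' values, which parameters are fixed (e.g. `imax = 1` and `gamma = 1` for a
#' full inhibitor), the loss scale, and the multistart policy. Parameters are
#' estimated on transformed scales — `log(kout)`, `logit(imax)`,
#' `log(ic50)`, `log(gamma)` — so the turnover-model constraints hold
#' smoothly without hard box constraints.
#'
#' @param start Named list of starting values on the natural scale; any of
#'   `kout`, `imax`, `ic50`, `gamma`. Defaults: `kout = 1`, `imax = 0.95`,
#'   `ic50 = 1`, `gamma = 1`. Choose `ic50` near the drive's concentration
#'   scale.
#' @param fixed Named numeric vector of parameters to hold fixed, e.g.
#'   `c(imax = 1, gamma = 1)`. Fixed values must satisfy the
#'   [turnover_params()] invariants.
#' @param loss `"percent"` (additive residuals on the percent-of-control
#'   scale, default) or `"log"` (residuals on log percent).
#' @param n_restarts Number of jittered multistart restarts (default 5);
#'   restart sub-seeds are derived deterministically from `seed`.
#' @param jitter_sd Standard deviation of the Normal jitter applied to the
#'   transformed starting values for restarts.
#' @param seed Seed controlling the restart jitter only.
#' @param grid_dt Integration grid spacing in hours for model predictions
#'   during fitting (the `"grid"` method of [simulate_trajectory()]).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(start = list(), fixed = numeric(0),
                     loss = c("percent", "log"),
                     n_restarts = 5L, jitter_sd = 0.3, seed = 1L,
                     grid_dt = 0.05) {
  loss <- match.arg(loss)
  default_start <- list(kout = 1, imax = 0.95, ic50 = 1, gamma = 1)
  bad <- setdiff(names(start), names(default_start))
  if (length(bad)) stop("unknown parameter(s) in 'start': ",
                        paste(bad, collapse = ", "))
  start <- utils::modifyList(default_start, as.list(start))
  if (length(fixed)) {
    if (is.null(names(fixed)) || any(!names(fixed) %in% names(default_start)))
      stop("'fixed' must be a named vector over kout/imax/ic50/gamma")
    start[names(fixed)] <- as.list(fixed)
  }
  # validates ranges of start + fixed together
  do.call(turnover_params, start)
  structure(list(start = start, fixed = fixed, loss = loss,
                 n_restarts = as.integer(n_restarts), jitter_sd = jitter_sd,
                 seed = as.integer(seed), grid_dt = grid_dt),
            class = "fit_spec")
}

PAR_NAMES <- c("kout", "imax", "ic50", "gamma")

to_transformed <- function(values, free) {
  tr <- c(kout = log(values$kout),
          imax = stats::qlogis(min(values$imax, 1 - 1e-12)),
          ic50 = log(values$ic50),
          gamma = log(values$gamma))
  tr[free]
}

from_transformed <- function(theta, free, fixed_values) {
  full <- fixed_values
  for (nm in free) {
    full[[nm]] <- switch(nm,
      kout = exp(theta[[nm]]),
      imax = stats::plogis(theta[[nm]]),
      ic50 = exp(theta[[nm]]),
      gamma = exp(theta[[nm]]))
  }
  full[PAR_NAMES]
}

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Precompute everything residuals need: per-group integration grids, drive
# concentrations on them, and observation indices.
prepare_fit_layout <- function(data, drives, grid_dt) {
  data <- as.data.frame(data)
  treated <- data[data$dose > 0, , drop = FALSE]
  if (nrow(treated) == 0L)
    stop("unidentifiable: no treated (dose > 0) observations")
  if (length(unique(treated$time_h)) < 2L)
    warning("fewer than 2 distinct treated sampling times; ",
            "turnover and potency are poorly identified from this design")
  groups <- unique(as.character(treated$group))
  missing_drive <- setdiff(groups, names(drives))
  if (length(missing_drive))
    stop("no concentration drive supplied for treated group(s): ",
         paste(missing_drive, collapse = ", "))
  layout <- list()
  for (g in groups) {
    rows <- which(as.character(data$group) == g & data$dose > 0)
    obs_t <- data$time_h[rows]
    grid <- sort(unique(c(obs_t, seq(0, max(obs_t), by = grid_dt))))
    layout[[g]] <- list(rows = rows, obs = data$pct_of_control[rows],
                        grid = grid, conc = conc_at(drives[[g]], grid),
                        idx = match(obs_t, grid))
  }
  veh_rows <- which(data$dose == 0)
  list(groups = layout, veh_rows = veh_rows,
       veh_obs = data$pct_of_control[veh_rows], n_obs = nrow(data))
}

residuals_for <- function(pars, layout, loss) {
  res <- numeric(0)
  for (g in layout$groups) {
    x <- (g$conc / pars$ic50)^pars$gamma
    r <- 1 - pars$imax * ifelse(is.infinite(x), 1, x / (1 + x))
    a <- integrate_turnover_grid(pars$kout, r, g$grid, a0 = 100)
    pred <- a[g$idx]
    res <- c(res, if (loss == "log") log(g$obs) - log(pred) else g$obs - pred)
  }
  if (length(layout$veh_rows)) {
    res <- c(res, if (loss == "log") log(layout$veh_obs) - log(100)
             else layout$veh_obs - 100)
  }
  res
}

numeric_jacobian <- function(fn, theta) {
  p <- length(theta)
  f0 <- fn(theta)
  jac <- matrix(NA_real_, length(f0), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    jac[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  jac
}

#' Estimate turnover and drug-effect parameters from normalized data
#'
#' Naive pooled nonlinear least squares: all animals' percent-of-control
#' values are treated as independent observations of the turnover-model
#' trajectory for their dose group (destructive sampling yields one
#' observation per animal, so there is no within-animal information to
#' model). The loss between observations and [simulate_trajectory()]
#' predictions is minimized simultaneously across all dose groups by
#' Levenberg-Marquardt, from `n_restarts` jittered starts; the best
#' converged loss wins. Standard errors come from the Jacobian at the
#' optimum (delta method back to the natural scale); Wald confidence
#' intervals are built on the transformed scale, so they respect the
#' parameter constraints and always contain the point estimate.
#'
#' @param data A [normalize_to_vehicle()] result restricted to one
#'   (compartment, analyte) stratum — pass `compartment`/`analyte` to
#'   subset, or use [fit_all_strata()].
#' @param drives Named list of [conc_profile] drives keyed by treated group
#'   label.
#' @param spec A [fit_spec()].
#' @param compartment,analyte Optional stratum selectors.
#' @return An object of class `fit_result`: `estimates` (natural scale,
#'   including derived `kin`), `se`, `ci` (95% Wald), `residuals` summary,
#'   `convergence` (status `"converged"`, `"non-converged"` or
#'   `"at-bound"`, message, multistart loss table, multimodality note),
#'   plus the spec, data and drives used (enabling [bootstrap_uncertainty()]
#'   and [predict_regimen()]).
#' @export
fit_turnover <- function(data, drives, spec = fit_spec(),
                         compartment = NULL, analyte = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  data <- as.data.frame(data)
  if (!is.null(compartment)) data <- data[data$compartment %in% compartment, ]
  if (!is.null(analyte)) data <- data[data$analyte %in% analyte, ]
  strata <- unique(data[, c("compartment", "analyte")])
  if (nrow(strata) > 1L)
    stop("data span multiple (compartment, analyte) strata; subset with ",
         "'compartment'/'analyte' or use fit_all_strata()")
  if (!"pct_of_control" %in% names(data))
    stop("'data' must be a normalized dataset (see normalize_to_vehicle)")
  layout <- prepare_fit_layout(data, drives, spec$grid_dt)

  free <- setdiff(PAR_NAMES, names(spec$fixed))
  if (!length(free)) stop("all parameters fixed; nothing to estimate")
  fixed_values <- as.list(spec$start)
  theta0 <- to_transformed(spec$start, free)
  obj <- function(theta) {
    residuals_for(from_transformed(stats::setNames(theta, free), free,
                                   fixed_values),
                  layout, spec$loss)
  }

  starts <- list(theta0)
  if (spec$n_restarts > 1L) {
    jitters <- run_with_seed(spec$seed, lapply(seq_len(spec$n_restarts - 1L),
      function(i) stats::rnorm(length(theta0), 0, spec$jitter_sd)))
    starts <- c(starts, lapply(jitters, function(j) theta0 + j))
  }
  runs <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = obj,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("optimizer failed from every start")
  losses <- vapply(runs, function(r) r$deviance, numeric(1L))
  best <- runs[[which.min(losses)]]

  multimodal <- FALSE
  if (length(runs) > 1L) {
    ord <- order(losses)
    l1 <- losses[ord[1L]]; l2 <- losses[ord[2L]]
    p1 <- best$par; p2 <- runs[[ord[2L]]]$par
    if (is.finite(l1) && l1 > 0 && (l2 - l1) / l1 < 0.01 &&
        any(abs(p2 - p1) > log(1.1)))
      multimodal <- TRUE
  }

  theta_hat <- stats::setNames(best$par, free)
  est <- from_transformed(theta_hat, free, fixed_values)
  n <- layout$n_obs
  p <- length(free)
  rss <- best$deviance
  sigma <- if (n > p) sqrt(rss / (n - p)) else NA_real_

  jac <- numeric_jacobian(obj, unname(theta_hat))
  cov_t <- tryCatch(sigma^2 * solve(crossprod(jac)),
                    error = function(e) matrix(NA_real_, p, p))
  se_t <- sqrt(pmax(diag(cov_t), 0))
  z <- stats::qnorm(0.975)
  ci <- se <- stats::setNames(rep(NA_real_, 4L), PAR_NAMES)
  ci <- matrix(NA_real_, 4L, 2L,
               dimnames = list(PAR_NAMES, c("lower", "upper")))
  for (i in seq_along(free)) {
    nm <- free[i]
    lo_t <- theta_hat[[nm]] - z * se_t[i]
    hi_t <- theta_hat[[nm]] + z * se_t[i]
    back <- function(v) from_transformed(
      stats::setNames(replace(theta_hat, i, v), free), free, fixed_values)[[nm]]
    ci[nm, ] <- c(back(lo_t), back(hi_t))
    deriv <- switch(nm, imax = est$imax * (1 - est$imax), est[[nm]])
    se[nm] <- abs(deriv) * se_t[i]
  }

  at_bound <- any(abs(theta_hat) > 15)
  status <- if (!best$info %in% 1:3) "non-converged"
            else if (at_bound) "at-bound" else "converged"
  if (status == "non-converged")
    warning("optimizer did not converge (info = ", best$info,
            "); returning best point found")
  if (at_bound)
    warning("estimate(s) pinned at a transform boundary; interpret with care")

  structure(list(
    estimates = c(est, list(kin = steady_state_kin(est$kout))),
    se = se, ci = ci, free = free,
    residuals = list(n = n, rss = rss, sigma = sigma, df = n - p),
    convergence = list(status = status, info = best$info,
                       message = best$message, niter = best$niter,
                       multistart_losses = sort(losses),
                       multimodal = multimodal),
    stratum = list(compartment = strata$compartment[1L],
                   analyte = strata$analyte[1L]),
    spec = spec, data = data, drives = drives
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Turnover model fit [%s %s], status: %s\n",
              x$stratum$compartment, x$stratum$analyte,
              x$convergence$status))
  est <- x$estimates
  for (nm in PAR_NAMES) {
    fixed <- !nm %in% x$free
    cat(sprintf("  %-5s %10.4g %s\n", nm, est[[nm]],
                if (fixed) "(fixed)"
                else sprintf("(SE %.3g, 95%% CI %.4g-%.4g)",
                             x$se[nm], x$ci[nm, 1L], x$ci[nm, 2L])))
  }
  cat(sprintf("  kin   %10.4g %%/h (derived)\n", est$kin))
  cat(sprintf("  n = %d, RSS = %.4g, sigma = %.3g\n",
              x$residuals$n, x$residuals$rss, x$residuals$sigma))
  if (isTRUE(x$convergence$multimodal))
    cat("  note: near-tied restarts with >10% parameter spread (multimodal?)\n")
  invisible(x)
}

#' Extract fitted parameters as a turnover_params object
#' @param fit A `fit_result`.
#' @return A [turnover_params()] built from the point estimates.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  est <- fit$estimates
  turnover_params(kout = est$kout, imax = est$imax, ic50 = est$ic50,
                  gamma = est$gamma)
}

#' Fit every (compartment, analyte) stratum independently
#'
#' Convenience wrapper running [fit_turnover()] once per stratum present in
#' the data, each with its own kout/Imax/IC50/gamma, as brain and CSF are
#' governed by distinct turnover kinetics.
#'
#' @inheritParams fit_turnover
#' @return A named list of `fit_result`, names `"<compartment>.<analyte>"`.
#' @export
fit_all_strata <- function(data, drives, spec = fit_spec()) {
  data <- as.data.frame(data)
  strata <- unique(data[, c("compartment", "analyte")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    cmp <- strata$compartment[i]; an <- strata$analyte[i]
    out[[paste(cmp, an, sep = ".")]] <-
      fit_turnover(data, drives, spec, compartment = cmp, analyte = an)
  }
  out
}

#' Joint fit with shared potency across strata
#'
#' Fits two or more (compartment, analyte) strata simultaneously with a
#' common intrinsic exposure-response relationship (shared Imax, IC50,
#' gamma) and a stratum-specific kout. This is the model implied by the
#' hypothesis that brain and CSF share the same drug effect on generation
#' and differ only in clearance kinetics; comparing its fit to independent
#' per-stratum fits probes intrinsic-curve overlap.
#'
#' @inheritParams fit_turnover
#' @return A named list of `fit_result` objects (one per stratum) whose
#'   potency parameters are constrained equal; each carries the joint
#'   residual summary.
#' @export
fit_turnover_shared <- function(data, drives, spec = fit_spec()) {
  stopifnot(inherits(spec, "fit_spec"))
  data <- as.data.frame(data)
  strata <- unique(data[, c("compartment", "analyte")])
  k <- nrow(strata)
  if (k < 2L) stop("shared-potency fit needs >= 2 strata")
  layouts <- lapply(seq_len(k), function(i) {
    d <- data[data$compartment == strata$compartment[i] &
              data$analyte == strata$analyte[i], ]
    prepare_fit_layout(d, drives, spec$grid_dt)
  })
  shared_free <- setdiff(c("imax", "ic50", "gamma"), names(spec$fixed))
  fixed_values <- as.list(spec$start)
  theta0 <- c(rep(log(spec$start$kout), k),
              to_transformed(spec$start, shared_free))
  obj <- function(theta) {
    kouts <- exp(theta[seq_len(k)])
    shared <- from_transformed(
      stats::setNames(theta[-seq_len(k)], shared_free),
      shared_free, fixed_values)
    unlist(lapply(seq_len(k), function(i) {
      pars <- shared; pars$kout <- kouts[i]
      residuals_for(pars, layouts[[i]], spec$loss)
    }))
  }
  best <- minpack.lm::nls.lm(par = theta0, fn = obj,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 300, ftol = 1e-12, ptol = 1e-12))
  kouts <- exp(best$par[seq_len(k)])
  shared <- from_transformed(
    stats::setNames(best$par[-seq_len(k)], shared_free),
    shared_free, fixed_values)
  n <- sum(vapply(layouts, function(l) l$n_obs, numeric(1L)))
  p <- length(best$par)
  status <- if (best$info %in% 1:3) "converged" else "non-converged"
  out <- list()
  for (i in seq_len(k)) {
    est <- shared; est$kout <- unname(kouts[i])
    d_i <- data[data$compartment == strata$compartment[i] &
                data$analyte == strata$analyte[i], ]
    out[[paste(strata$compartment[i], strata$analyte[i], sep = ".")]] <-
      structure(list(
        estimates = c(est[PAR_NAMES], list(kin = steady_state_kin(kouts[i]))),
        se = stats::setNames(rep(NA_real_, 4L), PAR_NAMES),
        ci = matrix(NA_real_, 4L, 2L,
                    dimnames = list(PAR_NAMES, c("lower", "upper"))),
        free = c("kout", shared_free),
        residuals = list(n = n, rss = best$deviance,
                         sigma = sqrt(best$deviance / (n - p)), df = n - p),
        convergence = list(status = status, info = best$info,
                           message = best$message, niter = best$niter,
                           multistart_losses = best$deviance,
                           multimodal = FALSE),
        stratum = list(compartment = strata$compartment[i],
                       analyte = strata$analyte[i]),
        spec = spec, data = d_i, drives = drives,
        shared_potency = TRUE
      ), class = "fit_result")
  }
  out
}

#' Case-resampling bootstrap for fitted turnover parameters
#'
#' Resamples animals with replacement within each (dose group, time,
#' compartment, analyte) stratum — the exchangeable unit under destructive
#' sampling — re-runs the full estimator pipeline on each resample, and
#' returns percentile confidence intervals. Vehicle animals are resampled
#' too and the resample is re-normalized to its own vehicle means, so the
#' uncertainty in the concurrent-control denominators propagates into the
#' intervals. Refits start from the point estimates with no multistart. A
#' resample that by chance contains no treated observations carries no
#' signal and is redrawn. Fully reproducible under a fixed seed.
#'
#' @param fit A converged [fit_turnover()] result.
#' @param n_boot Number of bootstrap resamples; fewer than 50 triggers a
#'   warning.
#' @param seed Integer seed; per-replicate sub-seeds are derived from it.
#' @param level Confidence level for the percentile intervals (default 0.90).
#' @return An object of class `bootstrap_result` with `ci` (per free
#'   parameter), the matrix of replicate `estimates`, `n_boot`, `level`,
#'   and the number of replicates that failed to refit.
#' @export
bootstrap_uncertainty <- function(fit, n_boot = 200L, seed = 1L,
                                  level = 0.90) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$convergence$status == "non-converged")
    stop("refusing to bootstrap a non-converged fit")
  if (n_boot < 50L) warning("n_boot < 50: percentile CIs will be unstable")
  data <- fit$data
  stratum <- interaction(data$dose, data$time_h, data$compartment,
                         data$analyte, drop = TRUE)
  idx_by_stratum <- split(seq_len(nrow(data)), stratum)
  # refit from the point estimate, single start
  spec_b <- fit$spec
  spec_b$start <- fit$estimates[PAR_NAMES]
  spec_b$n_restarts <- 1L

  draws <- run_with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      repeat {
        take <- unlist(lapply(idx_by_stratum,
                              function(ix) ix[sample.int(length(ix),
                                                         length(ix),
                                                         replace = TRUE)]))
        if (any(data$dose[take] > 0)) return(take)
      }
    })
  })
  reps <- lapply(draws, function(take) {
    d <- data[take, , drop = FALSE]
    # re-normalize to the resample's own vehicle means (pct scale is
    # already vehicle-relative, so this is the estimator's normalization
    # step applied to the bootstrap world)
    st <- interaction(d$time_h, d$compartment, d$analyte, drop = TRUE)
    veh <- d$dose == 0
    if (any(veh)) {
      vm <- tapply(d$pct_of_control[veh], st[veh], mean)
      denom <- as.numeric(vm[as.character(st)])
      ok <- !is.na(denom) & denom > 0
      d$pct_of_control[ok] <- 100 * d$pct_of_control[ok] / denom[ok]
    }
    tryCatch(
      suppressWarnings(fit_turnover(d, fit$drives, spec_b))$estimates,
      error = function(e) NULL)
  })
  ok <- !vapply(reps, is.null, logical(1L))
  est_mat <- do.call(rbind, lapply(reps[ok], function(e)
    unlist(e[PAR_NAMES])))
  alpha <- (1 - level) / 2
  ci <- t(apply(est_mat[, fit$free, drop = FALSE], 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(ci = ci, estimates = est_mat, n_boot = n_boot,
                 n_failed = sum(!ok), level = level, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%d resamples, %d failed), %g%% percentile CIs:\n",
              x$n_boot, x$n_failed, 100 * x$level))
  print(round(x$ci, 4L))
  invisible(x)
}
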