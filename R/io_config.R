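#' Read a fit specification from YAML
#'
#' Recognized fields: `start` (map of kout/imax/ic50/gamma), `fixed` (map),
#' `loss`, `n_restarts`, `jitter_sd`, `seed`, `grid_dt`. Absent fields take
#' the [fit_spec()] defaults.
#'
#' @param path YAML file path.
#' @return A [fit_spec()].
#' @export
read_fit_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fit_spec(start = if (is.null(y$start)) list() else y$start,
           fixed = if (is.null(y$fixed)) numeric(0) else unlist(y$fixed),
           loss = if (is.null(y$loss)) "percent" else y$loss,
           n_restarts = if (is.null(y$n_restarts)) 5L else y$n_restarts,
           jitter_sd = if (is.null(y$jitter_sd)) 0.3 else y$jitter_sd,
           seed = if (is.null(y$seed)) 1L else y$seed,
           grid_dt = if (is.null(y$grid_dt)) 0.05 else y$grid_dt)
}

#' Read a synthetic study design from YAML
#'
#' Fields mirror [study_design()] arguments; `measures` is a list of
#' `{compartment, analyte}` maps.
#'
#' @param path YAML file path.
#' @return A [study_design()].
#' @export
read_study_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("species", "bw_kg", "doses", "times",
                                  "n_per_group", "route", "destructive"))]
  if (!is.null(y$measures))
    args$measures <- do.call(rbind, lapply(y$measures, as.data.frame))
  do.call(study_design, args)
}

#' Read a generative truth configuration from YAML
#'
#' `params` maps `"<compartment>.<analyte>"` to kout/imax/ic50/gamma maps;
#' `pk` gives one-compartment constants (`ka`, `ke`, `vd`, optional
#' `f_abs`) from which each dose's drive is built as a Bateman profile with
#' `dose` passed through; optional `baseline` and `noise` maps mirror
#' [truth_config()].
#'
#' @param path YAML file path.
#' @return A [truth_config()].
#' @export
read_truth_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  params <- lapply(y$params, function(p) do.call(turnover_params, p))
  pk <- y$pk
  drive_for <- function(dose) {
    bateman_profile(one_cmt_params(
      dose = dose, ka = pk$ka, ke = pk$ke, vd = pk$vd,
      f_abs = if (is.null(pk$f_abs)) 1 else pk$f_abs))
  }
  truth_config(params = params, drive_for = drive_for,
               baseline = y$baseline,
               noise = if (is.null(y$noise))
                 list(prop_cv = 0.1, add_sd = 0) else y$noise)
}

#' Serialize a fit result to JSON
#'
#' Writes the point estimates (including derived kin), standard errors,
#' Wald intervals, residual summary and convergence diagnostics.
#'
#' @param fit A [fit_turnover()] result.
#' @param path Output JSON path.
#' @export
write_fit_result_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    stratum = fit$stratum,
    estimates = fit$estimates,
    se = as.list(fit$se),
    ci = apply(fit$ci, 1L, as.list, simplify = FALSE),
    free = fit$free,
    residuals = fit$residuals,
    convergence = fit$convergence[c("status", "info", "niter", "multimodal")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
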