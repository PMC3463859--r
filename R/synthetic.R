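#' Synthetic preclinical study design
#'
#' Describes a destructive-sampling animal study: one species, a dose ladder
#' including vehicle, a sampling-time grid, and the compartment/analyte
#' pairs measured in every animal. In destructive mode (the rodent default)
#' each animal contributes a single terminal observation per measure; in
#' repeated-sampling mode (dog/monkey/human CSF emulation) each animal is
#' followed across all times with a shared baseline.
#'
#' @param species Species label.
#' @param bw_kg Body weight, kg, > 0.
#' @param doses Numeric dose levels per kg, must include 0 (vehicle).
#' @param times Sampling times in hours, >= 0.
#' @param n_per_group Animals per dose x time cell (destructive) or per dose
#'   (repeated sampling).
#' @param route Route tag (e.g. `"po"`, `"sc"`); bookkeeping only.
#' @param measures Data frame with columns `compartment` and `analyte`;
#'   default brain Abeta42 and CSF Abeta40, the usual pairing in rodent
#'   secretase-inhibitor studies.
#' @param destructive One terminal sample per animal? Default `TRUE`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(species = "mouse", bw_kg = 0.025,
                         doses = c(0, 1, 3, 10, 30, 100),
                         times = c(1, 3, 6, 9, 12, 24),
                         n_per_group = 4L, route = "sc",
                         measures = data.frame(
                           compartment = c("brain", "CSF"),
                           analyte = c("Abeta42", "Abeta40")),
                         destructive = TRUE) {
  stopifnot(bw_kg > 0, n_per_group >= 1L, all(times >= 0), all(doses >= 0))
  if (!0 %in% doses) stop("'doses' must include 0 (a vehicle group)")
  if (!all(c("compartment", "analyte") %in% names(measures)))
    stop("'measures' needs columns 'compartment' and 'analyte'")
  structure(list(species = species, bw_kg = bw_kg,
                 doses = sort(unique(doses)), times = sort(unique(times)),
                 n_per_group = as.integer(n_per_group), route = route,
                 measures = measures, destructive = isTRUE(destructive)),
            class = "study_design")
}

#' Generative truth configuration
#'
#' The generating twin of the analysis model: per-measure turnover
#' parameters, a per-dose concentration drive, a between-animal baseline
#' distribution, and an observation-noise model. Observation noise is
#' multiplicative lognormal (biomarker assay values are positive and
#' right-skewed) with an optional additive Gaussian floor.
#'
#' @param params Named list of [turnover_params()] keyed
#'   `"<compartment>.<analyte>"`, covering every measure in the design.
#' @param drive_for Either a function `dose -> conc_profile` or a named list
#'   of [conc_profile] objects keyed by `as.character(dose)` for every
#'   nonzero dose.
#' @param baseline Named list keyed like `params`, each
#'   `list(mean = <absolute Abeta>, cv = <between-animal CV>)`. Default mean
#'   100 (arbitrary pg/g-scale units) with 20% CV.
#' @param noise `list(prop_cv = <lognormal CV>, add_sd = <additive floor
#'   SD>)`. Default `prop_cv = 0.1`, `add_sd = 0`.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(params, drive_for,
                         baseline = NULL,
                         noise = list(prop_cv = 0.1, add_sd = 0)) {
  stopifnot(is.list(params), length(params) >= 1L)
  for (p in params) stopifnot(inherits(p, "turnover_params"))
  if (is.null(baseline))
    baseline <- stats::setNames(
      rep(list(list(mean = 100, cv = 0.2)), length(params)), names(params))
  noise <- utils::modifyList(list(prop_cv = 0.1, add_sd = 0), noise)
  if (noise$prop_cv < 0 || noise$add_sd < 0) stop("noise terms must be >= 0")
  structure(list(params = params, drive_for = drive_for,
                 baseline = baseline, noise = noise),
            class = "truth_config")
}

drive_for_dose <- function(truth, dose) {
  d <- truth$drive_for
  prof <- if (is.function(d)) d(dose) else d[[as.character(dose)]]
  if (is.null(prof))
    stop("no concentration drive configured for dose ", dose)
  stopifnot(inherits(prof, "conc_profile"))
  prof
}

# Deterministic 31-bit hash of string components; used to derive per-animal
# sub-seeds so that adding a dose group or measure never shuffles the draws
# of existing animals.
subseed <- function(...) {
  s <- paste(..., sep = "\x1f")
  x <- 7
  for (code in utf8ToInt(s)) x <- (x * 31 + code) %% 2147483629
  as.integer(x + 1)
}

sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic destructive-sampling study
#'
#' For each animal, draws a between-animal baseline (lognormal with the
#' configured mean and CV), computes the turnover-model percent-of-control
#' at the animal's sampling time under its dose's drive (vehicle animals sit
#' at 100% before noise), applies multiplicative lognormal observation noise
#' (plus any additive floor), and emits the absolute value
#' `baseline * pct / 100`. Per-animal sub-seeds are derived from the master
#' seed by hashing the animal's (dose, time, replicate) coordinates, so the
#' same seed always reproduces the same dataset and extending the design
#' leaves existing animals' draws untouched.
#'
#' @param design A [study_design()].
#' @param truth A [truth_config()] covering every measure in the design.
#' @param seed Master integer seed.
#' @return A [raw_study_data()] data frame, one record per animal x measure
#'   (destructive) or per animal x time x measure (repeated sampling).
#' @export
generate_study <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_config"))
  measures <- design$measures
  keys <- paste(measures$compartment, measures$analyte, sep = ".")
  missing_keys <- setdiff(keys, names(truth$params))
  if (length(missing_keys))
    stop("truth config lacks parameters for measure(s): ",
         paste(missing_keys, collapse = ", "))

  # model pct-of-control per (measure, dose) on the full sampling grid
  tgrid <- sort(unique(c(0, design$times)))
  pct <- list()
  for (k in keys) {
    for (dose in design$doses) {
      pct[[k]][[as.character(dose)]] <-
        if (dose == 0) rep(100, length(tgrid))
        else simulate_trajectory(truth$params[[k]],
                                 drive_for_dose(truth, dose),
                                 tgrid, method = "grid")$abeta_pct
    }
  }

  noise <- truth$noise
  sdlog_obs <- sdlog_from_cv(noise$prop_cv)
  rows <- list()
  emit <- function(animal_id, group, dose, time, base, pct_val,
                   compartment, analyte) {
    eps <- if (noise$prop_cv > 0) exp(stats::rnorm(1L, 0, sdlog_obs)) else 1
    add <- if (noise$add_sd > 0) stats::rnorm(1L, 0, noise$add_sd) else 0
    data.frame(animal_id = animal_id, group = group, dose = dose,
               route = design$route, time_h = time,
               compartment = compartment, analyte = analyte,
               value = max(base * pct_val / 100 * eps + add, 0))
  }
  draw_baseline <- function(key) {
    b <- truth$baseline[[key]]
    if (b$cv > 0) {
      sl <- sdlog_from_cv(b$cv)
      stats::rlnorm(1L, meanlog = log(b$mean) - sl^2 / 2, sdlog = sl)
    } else b$mean
  }

  for (dose in design$doses) {
    group <- if (dose == 0) "vehicle" else sprintf("dose_%g", dose)
    if (design$destructive) {
      for (time in design$times) {
        for (i in seq_len(design$n_per_group)) {
          animal_id <- sprintf("%s_t%g_a%02d", group, time, i)
          run_with_seed(subseed(seed, dose, time, i), {
            for (m in seq_len(nrow(measures))) {
              k <- keys[m]
              base <- draw_baseline(k)
              pv <- pct[[k]][[as.character(dose)]][match(time, tgrid)]
              rows[[length(rows) + 1L]] <-
                emit(animal_id, group, dose, time, base, pv,
                     measures$compartment[m], measures$analyte[m])
            }
          })
        }
      }
    } else {
      for (i in seq_len(design$n_per_group)) {
        animal_id <- sprintf("%s_a%02d", group, i)
        run_with_seed(subseed(seed, dose, "repeated", i), {
          bases <- stats::setNames(lapply(keys, draw_baseline), keys)
          for (time in design$times) {
            for (m in seq_len(nrow(measures))) {
              k <- keys[m]
              pv <- pct[[k]][[as.character(dose)]][match(time, tgrid)]
              rows[[length(rows) + 1L]] <-
                emit(animal_id, group, dose, time, bases[[k]], pv,
                     measures$compartment[m], measures$analyte[m])
            }
          }
        })
      }
    }
  }
  raw_study_data(do.call(rbind, rows))
}

#' Generate cross-species kout points around a power law
#'
#' `kout_i = a * BW_i^b * exp(eps_i)` with `eps_i ~ Normal(0, sd^2)`;
#' `sd = 0` returns exact power-law points, so [fit_power_law()] recovers
#' `a` and `b` to machine precision.
#'
#' @param a Coefficient (kout at 1 kg), > 0.
#' @param b Exponent.
#' @param species Data frame with columns `species` and `bw_kg`.
#' @param sd Lognormal noise SD on the log scale.
#' @param seed Integer seed.
#' @return A [species_kout()] data frame.
#' @export
generate_multispecies_kout <- function(a, b, species, sd = 0, seed = 1L) {
  if (a <= 0) stop("'a' must be > 0")
  if (any(species$bw_kg <= 0)) stop("body weights must be > 0")
  if (sd < 0) stop("'sd' must be >= 0")
  eps <- if (sd > 0)
    run_with_seed(seed, stats::rnorm(nrow(species), 0, sd))
  else rep(0, nrow(species))
  species_kout(species$species, species$bw_kg,
               a * species$bw_kg^b * exp(eps))
}
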