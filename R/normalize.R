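#' Raw animal study data
#'
#' Animal-level Abeta observations from a destructive-sampling study: one
#' terminal record per animal per compartment/analyte. Expected columns:
#' `animal_id`, `group`, `dose` (0 for vehicle), `route`, `time_h`,
#' `compartment` (`"brain"` or `"CSF"`), `analyte` (`"Abeta40"` or
#' `"Abeta42"`), `value` (absolute concentration, pg/g or pg/mL).
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame of class `raw_study_data`.
#' @export
raw_study_data <- function(df) {
  req <- c("animal_id", "group", "dose", "route", "time_h",
           "compartment", "analyte", "value")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing study data columns: ", paste(missing_cols, collapse = ", "))
  if (any(df$value < 0, na.rm = TRUE)) stop("Abeta values must be >= 0")
  if (any(df$dose < 0)) stop("doses must be >= 0")
  if (any(df$time_h < 0)) stop("times must be >= 0")
  class(df) <- unique(c("raw_study_data", class(df)))
  df
}

#' Read / write raw study data as CSV
#' @param path CSV file path with the [raw_study_data()] schema.
#' @return `read_study_csv()` returns a `raw_study_data` data frame.
#' @export
read_study_csv <- function(path) {
  raw_study_data(utils::read.csv(path))
}

#' @param raw A `raw_study_data` data frame to write.
#' @rdname read_study_csv
#' @export
write_study_csv <- function(raw, path) {
  utils::write.csv(as.data.frame(raw), path, row.names = FALSE)
  invisible(path)
}

#' Express Abeta values as percent of the concurrent vehicle control
#'
#' Within each (time, compartment, analyte) stratum, every value — treated
#' and vehicle alike — is divided by the mean of the concurrent vehicle
#' (dose 0) values in that stratum and multiplied by 100. Vehicle records
#' are retained (they carry residual-variance information and normalize to
#' mean 100 within each stratum). Normalizing an already-normalized dataset
#' is the identity.
#'
#' @param raw A [raw_study_data()] data frame. Every stratum holding treated
#'   records must also hold at least one concurrent vehicle record.
#' @return A data frame of class `normalized_abeta` with columns
#'   `animal_id`, `group`, `dose`, `route`, `time_h`, `compartment`,
#'   `analyte`, `pct_of_control`.
#' @export
normalize_to_vehicle <- function(raw) {
  raw <- raw_study_data(as.data.frame(raw))
  stratum <- interaction(raw$time_h, raw$compartment, raw$analyte, drop = TRUE)
  is_veh <- raw$dose == 0
  veh_mean <- tapply(raw$value[is_veh], stratum[is_veh], mean)
  missing <- names(veh_mean)[is.na(veh_mean)]
  if (length(missing)) {
    labs <- unique(raw[stratum %in% missing,
                       c("time_h", "compartment", "analyte")])
    stop("no concurrent vehicle animals in stratum (time_h, compartment, analyte): ",
         paste(apply(labs, 1L, paste, collapse = "/"), collapse = "; "))
  }
  denom <- as.numeric(veh_mean[as.character(stratum)])
  if (any(denom <= 0))
    stop("vehicle mean is zero in at least one stratum; cannot normalize")
  out <- data.frame(
    animal_id = raw$animal_id, group = raw$group, dose = raw$dose,
    route = raw$route, time_h = raw$time_h, compartment = raw$compartment,
    analyte = raw$analyte, pct_of_control = 100 * raw$value / denom
  )
  class(out) <- c("normalized_abeta", "data.frame")
  out
}
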