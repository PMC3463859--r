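# Shared fixtures: mouse turnover parameters (CSF Abeta40 kout 1.42/h,
# brain Abeta42 kout 0.49/h), a one-compartment drive builder, and a
# generate -> normalize round-trip helper used across estimation tests.

mouse_csf_params <- function(ic50 = 10, imax = 1, gamma = 1) {
  turnover_params(kout = 1.42, imax = imax, ic50 = ic50, gamma = gamma)
}

mouse_brain_params <- function(ic50 = 10, imax = 1, gamma = 1) {
  turnover_params(kout = 0.49, imax = imax, ic50 = ic50, gamma = gamma)
}

mk_drive <- function(dose, ka = 3, ke = 1, vd = 1) {
  bateman_profile(one_cmt_params(dose = dose, ka = ka, ke = ke, vd = vd))
}

drive_list <- function(doses, ka = 3, ke = 1, vd = 1) {
  lapply(stats::setNames(doses, sprintf("dose_%g", doses)),
         mk_drive, ka = ka, ke = ke, vd = vd)
}

# destructive-sampling study for one compartment/analyte; noiseless unless
# noise terms are supplied
make_study <- function(p, compartment = "CSF", analyte = "Abeta40",
                       doses = c(1, 3, 10, 30, 100),
                       times = c(0.5, 1, 1.5, 2, 3, 4, 6, 9),
                       n_per_group = 3L, prop_cv = 0, baseline_cv = 0,
                       seed = 1L, ka = 3, ke = 1, vd = 1) {
  key <- paste(compartment, analyte, sep = ".")
  design <- study_design(
    doses = c(0, doses), times = times, n_per_group = n_per_group,
    measures = data.frame(compartment = compartment, analyte = analyte))
  truth <- truth_config(
    params = stats::setNames(list(p), key),
    drive_for = function(d) mk_drive(d, ka = ka, ke = ke, vd = vd),
    baseline = stats::setNames(list(list(mean = 5000, cv = baseline_cv)), key),
    noise = list(prop_cv = prop_cv, add_sd = 0))
  raw <- generate_study(design, truth, seed = seed)
  list(raw = raw, norm = normalize_to_vehicle(raw),
       drives = drive_list(doses, ka = ka, ke = ke, vd = vd),
       design = design, truth = truth)
}
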