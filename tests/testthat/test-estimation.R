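test_that("vehicle normalization divides by the concurrent control mean", {
  raw <- raw_study_data(data.frame(
    animal_id = c("v1", "v2", "t1"),
    group = c("vehicle", "vehicle", "dose_10"),
    dose = c(0, 0, 10), route = "po", time_h = 3,
    compartment = "brain", analyte = "Abeta42",
    value = c(4.0, 6.0, 2.5)))
  norm <- normalize_to_vehicle(raw)
  expect_equal(norm$pct_of_control[norm$dose == 10], 50)    # 2.5 / 5.0
  expect_equal(mean(norm$pct_of_control[norm$dose == 0]), 100)
  # a treated value equal to the vehicle mean normalizes to 100%
  raw$value[3L] <- 5.0
  expect_equal(normalize_to_vehicle(raw)$pct_of_control[3L], 100)
})

test_that("normalization errors name the stratum lacking concurrent vehicle", {
  raw <- raw_study_data(data.frame(
    animal_id = c("v1", "t1"), group = c("vehicle", "dose_10"),
    dose = c(0, 10), route = "po", time_h = c(3, 6),
    compartment = "CSF", analyte = "Abeta40", value = c(4, 2)))
  expect_error(normalize_to_vehicle(raw), "6/CSF/Abeta40")
  raw0 <- raw_study_data(data.frame(
    animal_id = c("v1", "t1"), group = c("vehicle", "dose_10"),
    dose = c(0, 10), route = "po", time_h = 3,
    compartment = "CSF", analyte = "Abeta40", value = c(0, 2)))
  expect_error(normalize_to_vehicle(raw0), "zero")
})

test_that("normalization is idempotent on already-normalized data", {
  st <- make_study(mouse_csf_params(), n_per_group = 2L, prop_cv = 0.1,
                   baseline_cv = 0.2, seed = 4L)
  renorm <- normalize_to_vehicle(
    within(as.data.frame(st$norm), value <- pct_of_control))
  expect_equal(renorm$pct_of_control, st$norm$pct_of_control)
})

test_that("noiseless synthetic data return the generating parameters", {
  st <- make_study(mouse_csf_params(ic50 = 10))
  fit <- fit_turnover(st$norm, st$drives,
                      fit_spec(start = list(kout = 1, ic50 = 3),
                               fixed = c(imax = 1)))
  expect_identical(fit$convergence$status, "converged")
  expect_equal(fit$estimates$kout, 1.42, tolerance = 1e-4)
  expect_equal(fit$estimates$ic50, 10, tolerance = 1e-4)
  expect_equal(fit$estimates$gamma, 1, tolerance = 1e-4)
  expect_equal(fit$estimates$kin, 100 * fit$estimates$kout)
  # Wald intervals contain the point estimates
  for (nm in fit$free) {
    expect_gte(fit$estimates[[nm]], fit$ci[nm, "lower"])
    expect_lte(fit$estimates[[nm]], fit$ci[nm, "upper"])
  }
})

test_that("fitting refuses vehicle-only data and missing drives", {
  st <- make_study(mouse_csf_params())
  veh <- st$norm[st$norm$dose == 0, ]
  expect_error(fit_turnover(veh, st$drives, fit_spec()), "unidentifiable")
  expect_error(fit_turnover(st$norm, st$drives["dose_1"], fit_spec()),
               "no concentration drive")
})

test_that("estimates are invariant to record order and animal relabeling", {
  st <- make_study(mouse_csf_params(), prop_cv = 0.1, seed = 9L)
  sp <- fit_spec(start = list(kout = 1, ic50 = 3), fixed = c(imax = 1),
                 n_restarts = 1L)
  f1 <- fit_turnover(st$norm, st$drives, sp)
  shuffled <- st$norm[rev(seq_len(nrow(st$norm))), ]
  shuffled$animal_id <- paste0("relabel_", seq_len(nrow(shuffled)))
  f2 <- fit_turnover(shuffled, st$drives, sp)
  expect_equal(f1$estimates$kout, f2$estimates$kout, tolerance = 1e-5)
  expect_equal(f1$estimates$ic50, f2$estimates$ic50, tolerance = 1e-5)
})

test_that("single-time-point dose-response designs yield degenerate uncertainty", {
  st <- make_study(mouse_csf_params(ic50 = 10), times = 3, prop_cv = 0.05,
                   n_per_group = 4L, seed = 2L)
  expect_warning(
    fit1 <- fit_turnover(st$norm, st$drives,
                         fit_spec(start = list(kout = 1, ic50 = 5),
                                  fixed = c(imax = 1, gamma = 1),
                                  n_restarts = 1L)),
    "distinct treated sampling times")
  st2 <- make_study(mouse_csf_params(ic50 = 10), prop_cv = 0.05,
                    n_per_group = 4L, seed = 2L)
  fit2 <- fit_turnover(st2$norm, st2$drives,
                       fit_spec(start = list(kout = 1, ic50 = 5),
                                fixed = c(imax = 1, gamma = 1),
                                n_restarts = 1L))
  # relative CI width for kout explodes without time-course information
  rel_width <- function(f)
    diff(f$ci["kout", ]) / f$estimates$kout
  expect_gt(rel_width(fit1), 5 * rel_width(fit2))
})

test_that("strata are fit independently and recover distinct kout values", {
  design <- study_design(doses = c(0, 1, 3, 10, 30, 100),
                         times = c(0.5, 1, 1.5, 2, 3, 4, 6, 9),
                         n_per_group = 2L)
  truth <- truth_config(
    params = list(brain.Abeta42 = mouse_brain_params(ic50 = 10),
                  CSF.Abeta40 = mouse_csf_params(ic50 = 10)),
    drive_for = function(d) mk_drive(d),
    baseline = list(brain.Abeta42 = list(mean = 800, cv = 0),
                    CSF.Abeta40 = list(mean = 4000, cv = 0)),
    noise = list(prop_cv = 0, add_sd = 0))
  norm <- normalize_to_vehicle(generate_study(design, truth, seed = 1L))
  sp <- fit_spec(start = list(kout = 1, ic50 = 3), fixed = c(imax = 1),
                 n_restarts = 1L)
  fits <- fit_all_strata(norm, drive_list(c(1, 3, 10, 30, 100)), sp)
  expect_named(fits, c("brain.Abeta42", "CSF.Abeta40"))
  expect_equal(fits$brain.Abeta42$estimates$kout, 0.49, tolerance = 1e-3)
  expect_equal(fits$CSF.Abeta40$estimates$kout, 1.42, tolerance = 1e-3)
  # fitting a multi-stratum frame without subsetting is refused
  expect_error(fit_turnover(norm, drive_list(c(1, 3, 10, 30, 100)), sp),
               "strata")

  shared <- fit_turnover_shared(norm, drive_list(c(1, 3, 10, 30, 100)), sp)
  expect_equal(shared$brain.Abeta42$estimates$ic50,
               shared$CSF.Abeta40$estimates$ic50)
  expect_equal(shared$brain.Abeta42$estimates$kout, 0.49, tolerance = 1e-3)
  expect_equal(shared$CSF.Abeta40$estimates$kout, 1.42, tolerance = 1e-3)
})

test_that("bootstrap is deterministic under a fixed seed and narrows with n", {
  sp <- fit_spec(start = list(kout = 1, ic50 = 5),
                 fixed = c(imax = 1, gamma = 1), n_restarts = 1L,
                 grid_dt = 0.1, loss = "log")
  st4 <- make_study(mouse_csf_params(ic50 = 10), n_per_group = 4L,
                    prop_cv = 0.1, seed = 5L)
  fit4 <- fit_turnover(st4$norm, st4$drives, sp)
  b1 <- bootstrap_uncertainty(fit4, n_boot = 60L, seed = 7L)
  b2 <- bootstrap_uncertainty(fit4, n_boot = 60L, seed = 7L)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_uncertainty(fit4, n_boot = 60L, seed = 8L)
  expect_false(identical(b1$ci, b3$ci))
  expect_warning(bootstrap_uncertainty(fit4, n_boot = 10L, seed = 1L),
                 "n_boot")

  st16 <- make_study(mouse_csf_params(ic50 = 10), n_per_group = 16L,
                     prop_cv = 0.1, seed = 5L)
  fit16 <- fit_turnover(st16$norm, st16$drives, sp)
  b16 <- bootstrap_uncertainty(fit16, n_boot = 60L, seed = 7L)
  expect_lt(diff(b16$ci["kout", ]), diff(b1$ci["kout", ]))
})
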