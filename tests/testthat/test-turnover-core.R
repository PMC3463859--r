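test_that("Hill inhibition has the right anchors and shape", {
  p <- turnover_params(kout = 1, imax = 0.8, ic50 = 10, gamma = 1)
  expect_equal(hill_inhibition(p, 10), 0.4)            # half-maximum at IC50
  expect_equal(hill_inhibition(p, 0), 0)
  p2 <- turnover_params(kout = 1, imax = 1, ic50 = 10, gamma = 2)
  expect_equal(hill_inhibition(p2, 30), 0.9)           # 900 / (100 + 900)

  # strictly increasing in concentration, asymptote imax, for varied gamma
  for (g in c(0.5, 1, 2, 4)) {
    pg <- turnover_params(kout = 1, imax = 0.8, ic50 = 10, gamma = g)
    conc <- c(0, 0.1, 1, 5, 10, 20, 100, 1e4)
    inh <- hill_inhibition(pg, conc)
    expect_true(all(diff(inh) > 0))
    expect_true(all(inh <= 0.8))
    expect_equal(hill_inhibition(pg, 10), 0.4)          # IC50 anchor any gamma
    expect_equal(hill_inhibition(pg, 1e12), 0.8, tolerance = 1e-5)
  }
  expect_error(hill_inhibition(p, -1), "concentration")
})

test_that("Rgen is the complement of inhibition and monotone non-increasing", {
  p <- turnover_params(kout = 0.49, imax = 0.9, ic50 = 25, gamma = 1.7)
  expect_equal(rgen(p, 0), 1)
  expect_equal(rgen(p, 25), 0.55)                       # 1 - Imax/2 at IC50
  p3 <- turnover_params(kout = 1, imax = 0.8, ic50 = 3, gamma = 1)
  expect_equal(rgen(p3, 1e6 * 3), 0.2, tolerance = 1e-5)
  conc <- 10^seq(-2, 4, length.out = 50)
  expect_true(all(diff(rgen(p, conc)) <= 0))
})

test_that("kin derivation and offset half-time are consistent with kout", {
  expect_equal(steady_state_kin(1.42), 142)
  expect_equal(steady_state_kin(0.49), 49)
  expect_equal(steady_state_kin(1), 100)
  expect_error(steady_state_kin(0), "kout")
  expect_equal(offset_halftime(log(2)), 1)
  expect_equal(offset_halftime(0.49), log(2) / 0.49)
  p <- turnover_params(kout = 1.42, imax = 1, ic50 = 5)
  expect_equal(p$kin, 142)
})

test_that("closed-form constant-concentration trajectory matches its anchors", {
  p <- turnover_params(kout = 0.49, imax = 1, ic50 = 10, gamma = 1)
  # c = ic50 gives I = 0.5; at t = ln2/kout the deviation has halved: 75%
  t_half <- log(2) / 0.49
  tr <- constant_conc_trajectory(p, 10, c(0, t_half, 50))
  expect_equal(tr$abeta_pct[1L], 100)
  expect_equal(tr$abeta_pct[2L], 75)
  expect_equal(tr$abeta_pct[3L], 50, tolerance = 1e-6)  # new steady state
  expect_error(constant_conc_trajectory(p, -1, 0:5), "concentration")
})

test_that("ODE simulation preserves baseline and matches the analytic oracle", {
  times <- seq(0, 12, by = 0.5)
  p <- turnover_params(kout = 1.42, imax = 1, ic50 = 10)
  flat <- simulate_trajectory(p, constant_profile(0), times)
  expect_equal(flat$abeta_pct, rep(100, length(times)), tolerance = 1e-7)

  # lsoda vs closed form under constant drive, across a parameter grid
  for (kout in c(0.2, 1.42)) {
    for (gamma in c(0.7, 2)) {
      pg <- turnover_params(kout = kout, imax = 0.9, ic50 = 8, gamma = gamma)
      num <- simulate_trajectory(pg, constant_profile(12), times)
      ana <- constant_conc_trajectory(pg, 12, times)
      expect_equal(num$abeta_pct, ana$abeta_pct, tolerance = 1e-7)
    }
  }

  # the fast grid integrator agrees with the analytic solution too
  g <- simulate_trajectory(p, constant_profile(12), times, method = "grid")
  a <- constant_conc_trajectory(p, 12, times)
  expect_equal(g$abeta_pct, a$abeta_pct, tolerance = 1e-9)

  expect_error(simulate_trajectory(p, constant_profile(1), c(0, 2, 1)),
               "increasing")
  expect_error(simulate_trajectory(p, constant_profile(1), c(1, 2, 3)),
               "start at 0")
})

test_that("trajectories stay in (0, 100] and recover after washout at rate kout", {
  p <- turnover_params(kout = 1.42, imax = 1, ic50 = 5)
  drv <- mk_drive(30)
  tr <- simulate_trajectory(p, drv, seq(0, 24, by = 0.25))
  expect_true(all(tr$abeta_pct > 0 & tr$abeta_pct <= 100 + 1e-8))
  # late phase: drug gone, deviation halves every ln2/kout
  late <- tr$abeta_pct[tr$time_h >= 18]
  dev <- 100 - late
  expect_true(all(diff(dev) < 0))
})

test_that("slower turnover delays the nadir and blunts short-pulse responses", {
  drv <- mk_drive(30)
  times <- seq(0, 24, by = 0.1)
  fast <- simulate_trajectory(turnover_params(kout = 1.42, imax = 1, ic50 = 10),
                              drv, times)
  slow <- simulate_trajectory(turnover_params(kout = 0.49, imax = 1, ic50 = 10),
                              drv, times)
  expect_gt(times[which.min(slow$abeta_pct)], times[which.min(fast$abeta_pct)])

  # short pulse: smaller kout gives smaller maximum deflection
  pulse <- tabulated_profile(conc_table(c(0, 0.25, 0.5, 0.75, 24),
                                        c(0, 40, 40, 0, 0)))
  defl <- sapply(c(0.2, 0.49, 1.42, 3), function(k) {
    p <- turnover_params(kout = k, imax = 1, ic50 = 10)
    100 - min(simulate_trajectory(p, pulse, times)$abeta_pct)
  })
  expect_true(all(diff(defl) > 0))
})

test_that("periodic steady state obeys the mass-balance identity", {
  p <- turnover_params(kout = 0.8, imax = 1, ic50 = 10, gamma = 1.3)
  expect_equal(average_level_at_periodic_ss(p, constant_profile(0), 24)$avg_pct,
               100, tolerance = 1e-6)
  # constant drive: degenerate period, level 100 * (1 - I)
  res_c <- average_level_at_periodic_ss(p, constant_profile(10), 24)
  expect_equal(res_c$avg_pct, 100 * (1 - hill_inhibition(p, 10)),
               tolerance = 1e-3)
  # pulsatile drive
  res <- average_level_at_periodic_ss(p, mk_drive(30), 12)
  expect_equal(res$avg_pct, res$avg_rgen_pct, tolerance = 1e-3)
  expect_error(
    average_level_at_periodic_ss(turnover_params(kout = 1e-4, imax = 1,
                                                 ic50 = 10),
                                 mk_drive(30), 12, max_periods = 3L),
    "periodic steady state")
})
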