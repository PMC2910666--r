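coupled_untreated <- function(t_end = 100)
  model_spec(logistic_normal(), logistic_tumor(), interaction = default_ia(),
             t_end = t_end)

test_that("rhs has the expected fixed points and Figure-1-state values", {
  spec <- coupled_untreated()
  expect_equal(unname(rhs(0, N = 0, T = 0, spec)), c(0, 0))
  dec <- decoupled_spec()
  expect_equal(unname(rhs(0, N = 1e6, T = 0, dec)), c(0, 0))
  # coupled state at (K_N, K_T): logistic fluxes vanish, interactions remain
  v <- rhs(0, N = 1e6, T = 1.2e6, spec)
  expect_equal(unname(v[1]), -5.995e6, tolerance = 1e-3)
  expect_equal(unname(v[2]), -1, tolerance = 1e-2)
  expect_error(rhs(0, N = -1, T = 0, spec), "invalid state")
  expect_error(rhs(0, N = NaN, T = 0, spec), "invalid state")
})

test_that("decoupled system trajectories match the analytic growth curves", {
  spec <- decoupled_spec(t_end = 100)
  traj <- simulate_model(spec)
  idx <- seq(1, length(traj$times), by = 20)
  expect_equal(traj$N[idx],
               closed_form_population(logistic_normal(), 1, traj$times[idx]),
               tolerance = 1e-6)
  expect_equal(traj$T[idx],
               closed_form_population(logistic_tumor(), 1, traj$times[idx]),
               tolerance = 1e-6)
  # Gompertz tumor against its closed form
  gspec <- decoupled_spec(t_end = 60, tumor = gompertz_lovo())
  gtraj <- simulate_model(gspec)
  gidx <- seq(1, length(gtraj$times), by = 20)
  expect_equal(gtraj$T[gidx],
               closed_form_population(gompertz_lovo(), 1, gtraj$times[gidx]),
               tolerance = 1e-6)
})

test_that("an extinct initial state stays extinct and the grid starts at the initial state", {
  spec <- model_spec(logistic_normal(), logistic_tumor(),
                     interaction = default_ia(), N0 = 0, T0 = 0, t_end = 20)
  traj <- simulate_model(spec)
  expect_true(all(traj$N == 0))
  expect_true(all(traj$T == 0))
  spec2 <- coupled_untreated(t_end = 20)
  traj2 <- simulate_model(spec2)
  expect_identical(traj2$times[1], 0)
  expect_identical(c(traj2$N[1], traj2$T[1]), c(1, 1))
  expect_true(all(diff(traj2$times) > 0))
})

test_that("threshold crossings are located and refined against the closed form", {
  traj <- simulate_model(decoupled_spec(t_end = 100))
  # critical-size crossing of the decoupled logistic tumor
  t_star <- first_crossing_time(traj, "T", 3e5)
  expect_equal(t_star, log((1.2e6 - 1) / 3) / 0.3, tolerance = 1e-4)
  # half-capacity crossing: analytic t = log(K - 1) / r
  t_half <- first_crossing_time(traj, "T", 6e5)
  expect_equal(t_half, log(1.2e6 - 1) / 0.3, tolerance = 1e-4)
  # never crossed and crossed-at-start conventions
  expect_true(is.na(first_crossing_time(traj, "T", 2e6)))
  expect_identical(first_crossing_time(traj, "T", 1), 0)
  expect_error(first_crossing_time(traj, "T", -5), "threshold")
})

test_that("peaks use the earliest-tie convention and dense refinement", {
  # monotone increasing path peaks at the horizon
  traj <- simulate_model(decoupled_spec(t_end = 30))
  pk <- trajectory_peak(traj, "T")
  expect_identical(pk$time, 30)
  expect_identical(pk$value, traj$T[length(traj$T)])
  # constant path peaks at its first sample
  const <- simulate_model(model_spec(logistic_normal(), logistic_tumor(),
                                     N0 = 1e6, T0 = 0, t_end = 10))
  pkc <- trajectory_peak(const, "N")
  expect_identical(pkc$time, 0)
  expect_equal(pkc$value, 1e6)
  # interior peak of the coupled system is refined beyond the grid
  coup <- simulate_model(coupled_untreated())
  pki <- trajectory_peak(coup, "N")
  expect_gt(pki$time, 40)
  expect_lt(pki$time, 45)
  expect_gte(pki$value, max(coup$N))
})

test_that("dense evaluation agrees with the grid and refines between samples", {
  traj <- simulate_model(coupled_untreated(t_end = 60))
  i <- which(traj$times == 35)
  expect_identical(trajectory_eval(traj, 35, "N"), traj$N[i])
  mid <- trajectory_eval(traj, 35.05, "T")
  expect_gt(mid, traj$T[i])
  expect_lt(mid, traj$T[i + 1])
  expect_error(trajectory_eval(traj, 61, "T"), "outside")
})

test_that("no-drug mode and a zero-dose static drug produce the same trajectory", {
  none <- simulate_model(coupled_untreated(t_end = 60))
  zero <- simulate_model(model_spec(logistic_normal(), logistic_tumor(),
                                    interaction = default_ia(),
                                    drug = drug_program("static", u0 = 0,
                                                        a_T = 0.1, t_rx = 40),
                                    t_end = 60))
  # the only difference is the integrator restart at the (inert) onset point
  expect_equal(zero$N, none$N, tolerance = 1e-6)
  expect_equal(zero$T, none$T, tolerance = 1e-6)
})

test_that("event times converge under grid refinement", {
  spec_c <- coupled_untreated(t_end = 60)
  coarse <- simulate_model(spec_c)
  spec_f <- spec_c; spec_f$dt <- 0.05
  fine <- simulate_model(spec_f)
  expect_lt(abs(first_crossing_time(coarse, "T", 3e5) -
                first_crossing_time(fine, "T", 3e5)), 1e-3)
  expect_lt(abs(trajectory_peak(coarse, "N")$time -
                trajectory_peak(fine, "N")$time), 1e-3)
})

test_that("stronger tumor kill postpones the critical-size crossing", {
  crossings <- vapply(c(0, 0.01, 0.05, 0.1), function(kill) {
    drug <- if (kill == 0) drug_program("none") else
      drug_program("static", t_rx = 40, lumped_kill_N = 0, lumped_kill_T = kill)
    spec <- model_spec(logistic_normal(), logistic_tumor(),
                       interaction = default_ia(), drug = drug, t_end = 100)
    first_crossing_time(simulate_model(spec), "T", 3e5)
  }, numeric(1))
  expect_true(all(diff(crossings) > 0))
})

test_that("trajectory distance is a symmetric scale-free premetric on a shared grid", {
  a <- simulate_model(coupled_untreated(t_end = 60))
  b <- simulate_model(model_spec(logistic_normal(), logistic_tumor(),
                                 interaction = default_ia(),
                                 drug = drug_program("static", t_rx = 40,
                                                     lumped_kill_T = 0.1,
                                                     lumped_kill_N = 0),
                                 t_end = 60))
  expect_identical(trajectory_distance(a, a), 0)
  d_ab <- trajectory_distance(a, b)
  expect_gt(d_ab, 0)
  expect_identical(d_ab, trajectory_distance(b, a))
  short <- simulate_model(coupled_untreated(t_end = 30))
  expect_error(trajectory_distance(a, short), "grid")
})

test_that("inhibition-onset delay is zero against itself and censors at the horizon", {
  untreated <- simulate_model(coupled_untreated(t_end = 100))
  expect_identical(inhibition_onset_delay(untreated, untreated), 0)
  # overwhelming kill: tumor never reaches T*, normal cells still rising at t_end
  crushed <- simulate_model(model_spec(logistic_normal(), logistic_tumor(),
                                       interaction = default_ia(),
                                       drug = drug_program("static", t_rx = 40,
                                                           lumped_kill_T = 1,
                                                           lumped_kill_N = 0),
                                       t_end = 100))
  expect_true(is.na(first_crossing_time(crushed, "T", 3e5)))
  expect_identical(inhibition_onset_delay(crushed, untreated), Inf)
})

test_that("populations stay non-negative along every preset trajectory", {
  for (name in list_presets()$name) {
    traj <- run_scenario(name)$trajectory
    expect_true(all(traj$N >= 0), label = paste(name, "normal non-negative"))
    expect_true(all(traj$T >= 0), label = paste(name, "tumor non-negative"))
  }
})
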