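test_that("the registry resolves presets with the canonical parameters", {
  spec <- get_preset("fig1_right")
  expect_s3_class(spec, "conjoint_model")
  expect_equal(spec$interaction$t_crit, 3e5)
  expect_equal(spec$interaction$beta, 2)
  expect_equal(spec$interaction$k_scale, 1.2e6)   # defaults to K_T
  expect_equal(spec$normal$rate, 0.4)
  expect_equal(spec$tumor$capacity, 1.2e6)

  black <- get_preset("fig2_row1_black")
  expect_identical(black$drug$mode, "static")
  expect_equal(black$drug$lumped_kill_T, 0.1)
  expect_equal(black$drug$lumped_kill_N, 0)
  expect_equal(black$drug$t_rx, 40)

  strong <- get_preset("fig4_treated_strong")
  expect_equal(strong$tumor$shape, 0)
  expect_equal(strong$tumor$rate, 0.083)
  expect_equal(strong$tumor$capacity, 1e5)
  expect_equal(strong$drug$lumped_kill_T, 0.17)
  expect_identical(strong$therapy_trigger, "tumor_exceeds_tcrit")

  expect_error(get_preset("nope"), "fig1_right")   # error lists the registry
  expect_true(all(c("fig3_row2_brown", "fig4_consistent_strong") %in%
                  list_presets()$name))
})

test_that("overriding the decoupled preset reproduces the coupled one", {
  a <- run_scenario("fig1_left",
                    overrides = list(beta = 2, k = 1, t_end = 60))
  b <- run_scenario("fig1_right", overrides = list(t_end = 60))
  expect_identical(a$trajectory$N, b$trajectory$N)
  expect_identical(a$trajectory$T, b$trajectory$T)
})

test_that("static tumor-kill scenarios order crossings, peaks and delays by strength", {
  res <- lapply(paste0("fig2_row1_", c("red", "green", "black")), run_scenario)
  crossings <- vapply(res, `[[`, numeric(1), "tcrit_crossing")
  peaks <- vapply(res, function(r) r$normal_peak$time, numeric(1))
  delays <- vapply(res, `[[`, numeric(1), "inhibition_delay")
  expect_true(all(diff(crossings) > 0))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(delays) > 0))
  expect_true(all(delays > 0))
})

test_that("normal-cell kill shrinks the normal population while the tumor is still held back", {
  res <- lapply(paste0("fig2_row2_", c("red", "green", "black")), run_scenario)
  peaks <- vapply(res, function(r) r$normal_peak$value, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # the fixed tumor kill still postpones the T* crossing — the glossary sense
  # of delayed inhibition — even when the drug also depletes normal cells
  # directly (which can pull the normal-cell peak itself earlier)
  untreated_cross <- run_scenario("fig1_right")$tcrit_crossing
  crossings <- vapply(res, `[[`, numeric(1), "tcrit_crossing")
  expect_true(all(crossings > untreated_cross))
})

test_that("faster drug decay moves the treated system toward the untreated one", {
  untreated <- run_scenario("fig1_right")$trajectory
  d1 <- vapply(paste0("fig3_row1_", c("red", "green", "black", "brown")),
               function(p) trajectory_distance(run_scenario(p)$trajectory, untreated),
               numeric(1))
  expect_true(all(diff(d1) < 0))
  # a higher initial dose keeps the treated system further from untreated
  d2 <- vapply(paste0("fig3_row2_", c("red", "green", "black", "brown")),
               function(p) trajectory_distance(run_scenario(p)$trajectory, untreated),
               numeric(1))
  expect_true(all(diff(d2) < 0))
  expect_true(all(d2 > d1))
})

test_that("Gompertzian tumors grow faster early and push normal cells into inhibition sooner", {
  # initial per-capita growth: gamma * log(plateau) versus r_T
  expect_gt(growth_flux(1, gompertz_lovo(1.2e6)) / 1,
            growth_flux(1, logistic_tumor()) / 1)
  g <- run_scenario("fig4_consistent_untreated")
  l <- run_scenario("fig1_right")
  expect_lt(g$normal_peak$time, l$normal_peak$time)
  expect_lt(g$tcrit_crossing, l$tcrit_crossing)
})

test_that("the literal Gompertz plateau never reaches the critical size; the consistent one does", {
  lit <- run_scenario("fig4_untreated")
  expect_true(is.na(lit$tcrit_crossing))
  expect_false(is.finite(run_scenario("fig4_treated_moderate")$trajectory$t_rx))
  cons <- run_scenario("fig4_consistent_moderate")
  expect_true(is.finite(cons$trajectory$t_rx))
  expect_equal(cons$trajectory$t_rx, run_scenario("fig4_consistent_untreated")$tcrit_crossing,
               tolerance = 1e-6)
})

test_that("scenario results echo a configuration that round-trips bit-exactly", {
  res <- run_scenario("fig3_row2_green")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(res$config, path)
  back <- read_config(path)
  expect_identical(back$model, res$config)
})
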