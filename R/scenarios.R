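# Named scenario presets.
#
# Model 1: logistic tumor (r_T = 0.3, K_T = 1.2e6) and logistic normal cells
# (r_N = 0.4, K_N = 1e6), coupled through beta = 2, k = 1, rho0 = 1,
# rho1 = 1000, T* = 3e5, started from N0 = T0 = 1; therapy (when present)
# starts at t = 40. Model 2 swaps the tumor law for Gompertz growth
# (gamma = 0.083) and starts therapy when the tumor first exceeds T*.
#
# The printed Gompertz plateau h = 1e5 sits below T* = 3e5, so under the
# literal fig4 presets the tumor never reaches the critical size and
# triggered therapy never fires; the fig4_consistent_* presets re-use the
# logistic plateau 1.2e6 for a tumor that does cross T*. Both are kept:
# which plateau the original simulations used cannot be recovered from the
# printed parameters.

model1_normal <- function() growth_law(rate = 0.4, capacity = 1e6)
model1_tumor  <- function() growth_law(rate = 0.3, capacity = 1.2e6)
model1_coupling <- function(beta = 2, k = 1)
  interaction_params(beta = beta, k = k, t_crit = 3e5, rho0 = 1, rho1 = 1000)
gompertz_tumor <- function(capacity) growth_law(rate = 0.083, capacity = capacity,
                                                shape = 0)

model1_spec <- function(drug = drug_program("none"), beta = 2, k = 1,
                        t_end = 100) {
  model_spec(normal = model1_normal(), tumor = model1_tumor(),
             interaction = model1_coupling(beta = beta, k = k),
             drug = drug, N0 = 1, T0 = 1, t_end = t_end)
}

model2_spec <- function(capacity, drug = drug_program("none"), beta = 2,
                        k = 1, t_end = 60,
                        therapy_trigger = "fixed_time") {
  model_spec(normal = model1_normal(), tumor = gompertz_tumor(capacity),
             interaction = model1_coupling(beta = beta, k = k),
             drug = drug, N0 = 1, T0 = 1, t_end = t_end,
             therapy_trigger = therapy_trigger)
}

static_drug <- function(kill_N, kill_T)
  drug_program("static", t_rx = 40, lumped_kill_N = kill_N,
               lumped_kill_T = kill_T)

decay_drug <- function(u0, d)
  drug_program("exp_decay", u0 = u0, d = d, m = 1, a_N = 0, a_T = 0.1,
               t_rx = 40)

# One entry per preset: a spec factory, the untreated twin used for delay
# metrics, and a one-line description.
preset_registry <- function() {
  reg <- list(
    fig1_left = list(
      spec = function() model1_spec(beta = 0, k = 0),
      twin = NA_character_,
      desc = "Model 1, decoupled (beta = 0, k = 0), no drug"),
    fig1_right = list(
      spec = function() model1_spec(),
      twin = NA_character_,
      desc = "Model 1, coupled, untreated")
  )
  kills <- c(red = 0.01, green = 0.05, black = 0.1)
  for (col in names(kills)) {
    local({
      kk <- kills[[col]]
      reg[[paste0("fig2_row1_", col)]] <<- list(
        spec = function() model1_spec(drug = static_drug(0, kk)),
        twin = "fig1_right",
        desc = sprintf("Model 1, static drug, tumor kill %g, normal kill 0", kk))
      reg[[paste0("fig2_row2_", col)]] <<- list(
        spec = function() model1_spec(drug = static_drug(kk, 0.1)),
        twin = "fig1_right",
        desc = sprintf("Model 1, static drug, tumor kill 0.1, normal kill %g", kk))
      reg[[paste0("fig2_row3_", col)]] <<- list(
        spec = function() model1_spec(drug = static_drug(0.1, kk)),
        twin = "fig1_right",
        desc = sprintf("Model 1, static drug, normal kill 0.1, tumor kill %g", kk))
    })
  }
  decays <- c(red = 0.1, green = 0.5, black = 1, brown = 2)
  for (col in names(decays)) {
    local({
      dd <- decays[[col]]
      reg[[paste0("fig3_row1_", col)]] <<- list(
        spec = function() model1_spec(drug = decay_drug(1, dd)),
        twin = "fig1_right",
        desc = sprintf("Model 1, decaying drug, u0 = 1, d = %g, a_T = 0.1", dd))
      reg[[paste0("fig3_row2_", col)]] <<- list(
        spec = function() model1_spec(drug = decay_drug(3, dd)),
        twin = "fig1_right",
        desc = sprintf("Model 1, decaying drug, u0 = 3, d = %g, a_T = 0.1", dd))
    })
  }
  gomp <- function(capacity, drug = drug_program("none"), beta = 2, k = 1,
                   trigger = "fixed_time")
    function() model2_spec(capacity, drug = drug, beta = beta, k = k,
                           therapy_trigger = trigger)
  reg$fig4_decoupled <- list(
    spec = gomp(1e5, beta = 0, k = 0),
    twin = NA_character_,
    desc = "Model 2, decoupled Gompertz tumor (h = 1e5), no drug")
  reg$fig4_untreated <- list(
    spec = gomp(1e5),
    twin = NA_character_,
    desc = "Model 2, coupled, untreated (literal plateau h = 1e5)")
  reg$fig4_treated_moderate <- list(
    spec = gomp(1e5, drug = static_drug(0, 0.1), trigger = "tumor_exceeds_tcrit"),
    twin = "fig4_untreated",
    desc = "Model 2 (h = 1e5), tumor kill 0.1, therapy at T* crossing")
  reg$fig4_treated_strong <- list(
    spec = gomp(1e5, drug = static_drug(0, 0.17), trigger = "tumor_exceeds_tcrit"),
    twin = "fig4_untreated",
    desc = "Model 2 (h = 1e5), tumor kill 0.17, therapy at T* crossing")
  reg$fig4_consistent_untreated <- list(
    spec = gomp(1.2e6),
    twin = NA_character_,
    desc = "Model 2, coupled, untreated, consistency plateau 1.2e6")
  reg$fig4_consistent_moderate <- list(
    spec = gomp(1.2e6, drug = static_drug(0, 0.1), trigger = "tumor_exceeds_tcrit"),
    twin = "fig4_consistent_untreated",
    desc = "Model 2 (plateau 1.2e6), tumor kill 0.1, therapy at T* crossing")
  reg$fig4_consistent_strong <- list(
    spec = gomp(1.2e6, drug = static_drug(0, 0.17), trigger = "tumor_exceeds_tcrit"),
    twin = "fig4_consistent_untreated",
    desc = "Model 2 (plateau 1.2e6), tumor kill 0.17, therapy at T* crossing")
  reg
}

#' Retrieve a named scenario preset
#'
#' Returns the fully resolved [model_spec()] of a registered scenario. The
#' registry covers the untreated and treated regimes of both model variants:
#' decoupled and coupled untreated systems (`fig1_left`, `fig1_right`),
#' static-drug treatments varying tumor and normal kill constants
#' (`fig2_row1/2/3_{red,green,black}`), exponentially decaying drugs over
#' decay rates 0.1/0.5/1/2 at initial levels 1 and 3
#' (`fig3_row1/2_{red,green,black,brown}`), and Gompertzian-tumor scenarios
#' (`fig4_*`, including `fig4_consistent_*` variants with the tumor plateau
#' raised to 1.2e6 so the tumor can cross the critical size; see
#' [list_presets()]).
#'
#' @param name Preset name; see [list_presets()].
#' @return A [model_spec()] with attributes `preset` (the name) and
#'   `untreated_twin` (name of the matching untreated preset, or `NA`).
#' @examples
#' get_preset("fig1_right")
#' @export
get_preset <- function(name) {
  reg <- preset_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop(sprintf("unknown preset %s; available: %s",
                 deparse(name), paste(names(reg), collapse = ", ")),
         call. = FALSE)
  spec <- reg[[name]]$spec()
  attr(spec, "preset") <- name
  attr(spec, "untreated_twin") <- reg[[name]]$twin
  spec
}

#' List the scenario presets
#'
#' @return A data.frame with one row per preset: its name, untreated twin
#'   (for delay metrics) and description.
#' @export
list_presets <- function() {
  reg <- preset_registry()
  data.frame(name = names(reg),
             untreated_twin = vapply(reg, function(e) e$twin, character(1)),
             description = vapply(reg, function(e) e$desc, character(1)),
             row.names = NULL)
}

#' Run a scenario and summarize it
#'
#' Integrates a preset (or an explicit [model_spec()]), optionally with
#' parameter overrides, and extracts the derived metrics: the tumor's first
#' crossing of the critical size, the normal-cell peak (time and value),
#' terminal sizes at the horizon, and — when the preset names an untreated
#' twin — the [inhibition_onset_delay()] against that twin. Everything is
#' deterministic: there is no randomness anywhere in the model.
#'
#' Overrides use dotted configuration keys, e.g.
#' `list("interaction.beta" = 0, "drug.u0" = 3, "t_end" = 200)`; see
#' [read_config()] for the key set.
#'
#' @param x A preset name or a [model_spec()].
#' @param overrides Named list of dotted-key overrides.
#' @return An object of class `conjoint_scenario` with elements `name`,
#'   `trajectory`, `tcrit_crossing` (`NA` if never crossed),
#'   `normal_peak` (list `time`, `value`), `terminal` (named `N`, `T`),
#'   `inhibition_delay` (`NA` when no twin, `Inf` when censored at the
#'   horizon) and `config` (the fully resolved configuration).
#' @examples
#' res <- run_scenario("fig1_left", overrides = list(t_end = 50))
#' res$terminal
#' @export
run_scenario <- function(x, overrides = list()) {
  if (is.character(x)) {
    spec <- get_preset(x)
    name <- x
    twin <- attr(spec, "untreated_twin")
  } else if (inherits(x, "conjoint_model")) {
    spec <- x
    name <- attr(spec, "preset")
    if (is.null(name)) name <- "custom"
    twin <- attr(spec, "untreated_twin")
    if (is.null(twin)) twin <- NA_character_
  } else stop("`x` must be a preset name or a model_spec", call. = FALSE)

  if (length(overrides)) {
    cfg <- apply_overrides(model_to_config(spec), overrides)
    spec <- config_to_model(cfg)
  }

  traj <- tryCatch(simulate_model(spec), error = function(e)
    stop(sprintf("scenario %s: %s", name, conditionMessage(e)), call. = FALSE))

  tcrit <- if (!is.null(spec$interaction))
    first_crossing_time(traj, "T", spec$interaction$t_crit) else NA_real_
  pk <- trajectory_peak(traj, "N")
  n <- length(traj$times)
  delay <- NA_real_
  if (!is.na(twin)) {
    twin_spec <- get_preset(twin)
    twin_spec$t_end <- spec$t_end
    twin_spec$dt <- spec$dt
    delay <- inhibition_onset_delay(traj, simulate_model(twin_spec))
  }
  structure(list(name = name,
                 trajectory = traj,
                 tcrit_crossing = tcrit,
                 normal_peak = pk,
                 terminal = c(N = traj$N[n], T = traj$T[n]),
                 inhibition_delay = delay,
                 untreated_twin = twin,
                 config = model_to_config(spec)),
            class = "conjoint_scenario")
}

#' @export
print.conjoint_scenario <- function(x, ...) {
  cat(sprintf("<conjoint_scenario> %s\n", x$name))
  cat(sprintf("  T* crossing: %s\n",
              if (is.na(x$tcrit_crossing)) "never" else format(x$tcrit_crossing)))
  cat(sprintf("  normal peak: %g cells at t = %g\n",
              x$normal_peak$value, x$normal_peak$time))
  cat(sprintf("  terminal: N = %g, T = %g\n", x$terminal["N"], x$terminal["T"]))
  if (!is.na(x$untreated_twin))
    cat(sprintf("  inhibition delay vs %s: %s\n", x$untreated_twin,
                if (is.infinite(x$inhibition_delay)) "censored at horizon"
                else format(x$inhibition_delay)))
  invisible(x)
}
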