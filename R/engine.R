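#' Full conjoint model specification
#'
#' Assembles the coupled system: growth laws for the normal and tumor
#' compartments, the bidirectional interaction (or `NULL` for a fully
#' decoupled system), a drug program, initial sizes and the simulation
#' horizon. The model is
#' \deqn{dN/dt = g_N(N) + f_N(T)\,N - F_N(u(t))\,N,}
#' \deqn{dT/dt = g_T(T) + f_T(N, T) - F_T(u(t))\,T,}
#' where \eqn{g} are the intrinsic [growth_flux()] terms, \eqn{f} the
#' interaction terms and \eqn{F} the fractional-cell-kill rates.
#'
#' If the interaction's `k_scale` is unset it resolves to the tumor
#' compartment's carrying capacity.
#'
#' @param normal,tumor [growth_law()] objects for the two compartments.
#' @param interaction An [interaction_params()], or `NULL` for no coupling.
#' @param drug A [drug_program()]; default no drug.
#' @param N0,T0 Initial population sizes in cells; non-negative.
#' @param t_end Simulation horizon (time units); positive.
#' @param dt Output sampling step; default 0.1 time units.
#' @param therapy_trigger `"fixed_time"` (therapy starts at the drug
#'   program's `t_rx`) or `"tumor_exceeds_tcrit"` (therapy starts when the
#'   tumor first reaches the critical size `t_crit`, i.e. when the normal
#'   cells enter the inhibition phase).
#' @return An object of class `conjoint_model`.
#' @examples
#' spec <- model_spec(normal = growth_law(0.4, 1e6),
#'                    tumor = growth_law(0.3, 1.2e6),
#'                    interaction = interaction_params(),
#'                    t_end = 100)
#' @export
model_spec <- function(normal, tumor, interaction = NULL,
                       drug = drug_program("none"), N0 = 1, T0 = 1,
                       t_end = 100, dt = 0.1,
                       therapy_trigger = c("fixed_time", "tumor_exceeds_tcrit")) {
  therapy_trigger <- match.arg(therapy_trigger)
  stopifnot(is_growth_law(normal), is_growth_law(tumor),
            inherits(drug, "drug_program"))
  if (!is.null(interaction)) {
    stopifnot(inherits(interaction, "interaction_params"))
    if (is.null(interaction$k_scale)) interaction$k_scale <- tumor$capacity
  }
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 < 0)
    stop("`N0` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0) || T0 < 0)
    stop("`T0` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("`t_end` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single finite number > 0", call. = FALSE)
  if (therapy_trigger == "tumor_exceeds_tcrit" && is.null(interaction))
    stop("therapy_trigger \"tumor_exceeds_tcrit\" needs an interaction (t_crit)",
         call. = FALSE)
  structure(list(normal = normal, tumor = tumor, interaction = interaction,
                 drug = drug, N0 = N0, T0 = T0, t_end = t_end, dt = dt,
                 therapy_trigger = therapy_trigger),
            class = "conjoint_model")
}

#' @export
print.conjoint_model <- function(x, ...) {
  cat("<conjoint_model>\n")
  cat("  normal: "); print(x$normal)
  cat("  tumor:  "); print(x$tumor)
  if (is.null(x$interaction)) cat("  interaction: none (decoupled)\n")
  else { cat("  "); print(x$interaction) }
  cat("  "); print(x$drug)
  cat(sprintf("  N0 = %g, T0 = %g, t_end = %g, dt = %g, trigger = %s\n",
              x$N0, x$T0, x$t_end, x$dt, x$therapy_trigger))
  invisible(x)
}

# Integration tolerances (absolute tolerance in cells; kept far below one
# cell so trajectories started from a single cell stay accurate in relative
# terms from the outset).
.rtol <- 1e-8
.atol <- 1e-8

# Core right-hand side; drug_on gates the kill terms so each integration
# segment sees a smooth RHS across the therapy-onset discontinuity.
rhs_core <- function(t, N, T, spec, drug_on) {
  dN <- growth_flux(N, spec$normal)
  dT <- growth_flux(T, spec$tumor)
  if (!is.null(spec$interaction)) {
    dN <- dN + normal_interaction_flux(N, T, spec$interaction)
    dT <- dT + tumor_modifier(N, T, spec$interaction)
  }
  if (drug_on && spec$drug$mode != "none") {
    dN <- dN - percapita_kill(t, spec$drug, "N") * N
    dT <- dT - percapita_kill(t, spec$drug, "T") * T
  }
  c(dN, dT)
}

#' Right-hand side of the coupled system
#'
#' Evaluates \eqn{(dN/dt, dT/dt)} at a state. With the interaction absent and
#' no drug this reduces exactly to the two decoupled growth laws.
#'
#' @param t Time.
#' @param N,T Population sizes in cells; non-negative.
#' @param spec A [model_spec()].
#' @return Named numeric vector `c(dN, dT)` in cells per unit time.
#' @examples
#' spec <- model_spec(growth_law(0.4, 1e6), growth_law(0.3, 1.2e6))
#' rhs(0, N = 1e6, T = 0, spec)   # joint fixed point: c(0, 0)
#' @export
rhs <- function(t, N, T, spec) {
  stopifnot(inherits(spec, "conjoint_model"))
  if (!is.finite(N) || !is.finite(T) || N < 0 || T < 0)
    stop(sprintf("invalid state at t = %g: N = %g, T = %g (must be finite, >= 0)",
                 t, N, T), call. = FALSE)
  out <- rhs_core(t, N, T, spec, drug_on = TRUE)
  names(out) <- c("dN", "dT")
  out
}

# deSolve-facing wrapper. Small negative excursions (within solver
# tolerance) are floored at 0; anything non-finite aborts with the state.
desolve_rhs <- function(t, y, parms) {
  if (any(!is.finite(y)))
    stop(sprintf("integration produced a non-finite state at t = %g (N = %g, T = %g)",
                 t, y[1], y[2]), call. = FALSE)
  y <- pmax(y, 0)
  list(rhs_core(t, y[1], y[2], parms$spec, parms$drug_on))
}

# Integrate one smooth segment over an ordered time vector.
integrate_segment <- function(y0, times, spec, drug_on, rtol = .rtol, atol = .atol) {
  y0 <- unname(y0)
  if (length(times) == 1L)
    return(matrix(c(times, y0), nrow = 1,
                  dimnames = list(NULL, c("time", "N", "T"))))
  out <- deSolve::ode(y = c(N = y0[1], T = y0[2]), times = times,
                      func = desolve_rhs,
                      parms = list(spec = spec, drug_on = drug_on),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integrator failure; last valid state t = %g, N = %g, T = %g",
                 out[nrow(out), 1], out[nrow(out), 2], out[nrow(out), 3]),
         call. = FALSE)
  unclass(out)[, 1:3, drop = FALSE]
}

# Resolve the effective therapy start time for a spec (may require a
# drug-free pre-run when triggered by the T* crossing). Inf = never.
resolve_t_rx <- function(spec) {
  if (spec$drug$mode == "none") return(Inf)
  if (spec$therapy_trigger == "fixed_time") {
    if (spec$drug$t_rx > spec$t_end) return(Inf)
    return(spec$drug$t_rx)
  }
  untreated <- spec
  untreated$drug <- drug_program("none")
  untreated$therapy_trigger <- "fixed_time"
  traj <- simulate_model(untreated)
  tc <- first_crossing_time(traj, "T", spec$interaction$t_crit)
  if (is.na(tc)) Inf else tc
}

#' Simulate the coupled system
#'
#' Integrates the model adaptively (lsoda, relative tolerance 1e-8, absolute
#' tolerance 1e-8 cells), piecewise on `[0, t_rx]` and `[t_rx, t_end]` so the
#' drug-onset step discontinuity falls on a segment boundary. Output is
#' sampled on a uniform grid of step `dt` (with `t_rx` and `t_end` inserted);
#' sampled populations are floored at 0 and values within the absolute
#' tolerance of 0 are reported as 0. Arbitrary times in `[0, t_end]` can be
#' evaluated afterwards with [trajectory_eval()] (used internally to refine
#' event times).
#'
#' With `therapy_trigger = "tumor_exceeds_tcrit"` the therapy start is first
#' located by a drug-free run as the tumor's earliest crossing of the
#' critical size; if the tumor never reaches it, the drug is never applied.
#'
#' @param spec A [model_spec()].
#' @return An object of class `conjoint_trajectory` with elements `times`,
#'   `N`, `T`, `u` (drug level), `kill_N`, `kill_T` (per-capita kill rates),
#'   the resolved therapy start `t_rx` (`Inf` if never) and the `spec`.
#' @examples
#' spec <- model_spec(growth_law(0.4, 1e6), growth_law(0.3, 1.2e6), t_end = 50)
#' traj <- simulate_model(spec)
#' tail(traj$N, 1)
#' @export
simulate_model <- function(spec) {
  stopifnot(inherits(spec, "conjoint_model"))
  t_rx <- resolve_t_rx(spec)
  times <- seq(0, spec$t_end, by = spec$dt)
  if (times[length(times)] < spec$t_end - 1e-12) times <- c(times, spec$t_end)
  y0 <- c(spec$N0, spec$T0)

  if (!is.finite(t_rx) || t_rx <= 0) {
    # single smooth segment (drug never on, or on from the start)
    drug_on <- is.finite(t_rx)
    path <- integrate_segment(y0, times, spec, drug_on = drug_on)
  } else {
    # piecewise at therapy onset; the output grid itself stays uniform
    on_grid <- any(abs(times - t_rx) < 1e-12)
    pre <- times[times < t_rx - 1e-12]
    post <- times[times > t_rx + 1e-12]
    seg1 <- integrate_segment(y0, c(pre, t_rx), spec, drug_on = FALSE)
    y_rx <- pmax(seg1[nrow(seg1), 2:3], 0)
    seg2 <- integrate_segment(y_rx, c(t_rx, post), spec, drug_on = TRUE)
    if (!on_grid) seg1 <- seg1[-nrow(seg1), , drop = FALSE]
    path <- rbind(seg1, seg2[-1, , drop = FALSE])
  }

  N <- path[, "N"]; T <- path[, "T"]
  N[N <= .atol] <- 0
  T[T <= .atol] <- 0
  drug <- spec$drug
  if (is.finite(t_rx)) drug$t_rx <- t_rx
  u <- if (drug$mode == "none") numeric(length(times)) else drug_level(times, drug)
  kN <- if (drug$mode == "none") numeric(length(times)) else percapita_kill(times, drug, "N")
  kT <- if (drug$mode == "none") numeric(length(times)) else percapita_kill(times, drug, "T")
  structure(list(times = times, N = N, T = T, u = u,
                 kill_N = kN, kill_T = kT, t_rx = t_rx, spec = spec),
            class = "conjoint_trajectory")
}

#' @export
print.conjoint_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<conjoint_trajectory> %d samples on [%g, %g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  terminal: N = %g, T = %g cells", x$N[n], x$T[n]))
  if (is.finite(x$t_rx)) cat(sprintf("; therapy from t = %g", x$t_rx))
  cat("\n")
  invisible(x)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Dense-output access: re-integrates from the nearest stored grid state
#' with tight tolerances, so event refinement is not limited by the sampling
#' step. Times must lie within the simulated interval.
#'
#' @param traj A [simulate_model()] trajectory.
#' @param t Time(s) in `[0, t_end]`.
#' @param compartment `"N"` or `"T"`.
#' @return Population size(s) in cells at `t`.
#' @export
trajectory_eval <- function(traj, t, compartment = c("N", "T")) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(traj, "conjoint_trajectory"), is.numeric(t))
  tms <- traj$times
  if (any(t < tms[1] - 1e-12) || any(t > tms[length(tms)] + 1e-12))
    stop("evaluation time outside the simulated interval", call. = FALSE)
  spec <- traj$spec
  vapply(t, function(ti) {
    i <- findInterval(ti, tms)
    i <- min(max(i, 1L), length(tms))
    if (abs(tms[i] - ti) < 1e-12)
      return(if (compartment == "N") traj$N[i] else traj$T[i])
    spec_eff <- spec
    t_rx <- traj$t_rx
    if (is.finite(t_rx)) spec_eff$drug$t_rx <- t_rx
    y0 <- c(traj$N[i], traj$T[i])
    t0 <- tms[i]
    if (is.finite(t_rx) && t0 < t_rx && ti > t_rx) {
      # interval straddles therapy onset: split there
      seg <- integrate_segment(y0, c(t0, t_rx), spec_eff, drug_on = FALSE,
                               rtol = 1e-10, atol = 1e-8)
      y0 <- pmax(seg[nrow(seg), 2:3], 0)
      t0 <- t_rx
    }
    drug_on <- is.finite(t_rx) && ti >= t_rx
    seg <- integrate_segment(y0, c(t0, ti), spec_eff, drug_on = drug_on,
                             rtol = 1e-10, atol = 1e-8)
    max(seg[nrow(seg), if (compartment == "N") "N" else "T"], 0)
  }, numeric(1))
}
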