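#' First time a compartment reaches a threshold
#'
#' Scans the sampled trajectory for the earliest grid time at which the
#' compartment is at or above `threshold`, then refines the crossing by
#' bracketed root finding on the dense output (to about 1e-7 in time). By
#' convention a trajectory that starts at or above the threshold crosses at
#' its first sample.
#'
#' @param traj A [simulate_model()] trajectory.
#' @param which Compartment, `"N"` or `"T"`.
#' @param threshold Population size in cells; positive.
#' @return Crossing time, or `NA_real_` if the threshold is never reached.
#' @examples
#' spec <- model_spec(growth_law(0.4, 1e6), growth_law(0.3, 1.2e6), t_end = 60)
#' traj <- simulate_model(spec)
#' first_crossing_time(traj, "T", 3e5)   # about 43.0
#' @export
first_crossing_time <- function(traj, which = c("N", "T"), threshold) {
  which <- match.arg(which)
  stopifnot(inherits(traj, "conjoint_trajectory"),
            is.numeric(threshold), length(threshold) == 1L)
  if (!is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be a single finite number > 0", call. = FALSE)
  x <- if (which == "N") traj$N else traj$T
  hit <- which(x >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(traj$times[1])
  lo <- traj$times[i - 1]; hi <- traj$times[i]
  if (x[i] == threshold) return(hi)
  f <- function(t) trajectory_eval(traj, t, which) - threshold
  root <- stats::uniroot(f, lower = lo, upper = hi,
                         f.lower = x[i - 1] - threshold,
                         f.upper = x[i] - threshold, tol = 1e-7)
  root$root
}

#' Peak of a compartment
#'
#' Time and value of the first global maximum of the sampled path (ties
#' broken by the earliest time), refined on the dense output when the
#' maximum is interior.
#'
#' @inheritParams first_crossing_time
#' @return A list with elements `time` and `value`.
#' @export
trajectory_peak <- function(traj, which = c("N", "T")) {
  which <- match.arg(which)
  stopifnot(inherits(traj, "conjoint_trajectory"))
  x <- if (which == "N") traj$N else traj$T
  n <- length(x)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  i <- which.max(x)
  if (i == 1L || i == n)
    return(list(time = traj$times[i], value = x[i]))
  opt <- stats::optimize(function(t) trajectory_eval(traj, t, which),
                         lower = traj$times[i - 1], upper = traj$times[i + 1],
                         maximum = TRUE, tol = 1e-6)
  if (opt$objective >= x[i])
    list(time = opt$maximum, value = opt$objective)
  else
    list(time = traj$times[i], value = x[i])
}

#' Delay of inhibition-phase onset under therapy
#'
#' The normal-cell population enters its inhibition phase at its peak. This
#' returns the treated peak time minus the untreated peak time: positive
#' when therapy delays the decline. The onset is censored (`Inf`) when the
#' treated system never enters the inhibition phase within the horizon:
#' either its tumor never reaches the critical size (the drug suppresses
#' the tumor outright), or its normal population is still rising at the
#' final sample.
#'
#' @param treated,untreated Trajectories on the same sampling grid.
#' @return Time difference (possibly `Inf` when censored at the horizon).
#' @export
inhibition_onset_delay <- function(treated, untreated) {
  stopifnot(inherits(treated, "conjoint_trajectory"),
            inherits(untreated, "conjoint_trajectory"))
  check_same_grid(treated, untreated)
  ia <- treated$spec$interaction
  if (!is.null(ia) &&
      is.na(first_crossing_time(treated, "T", ia$t_crit)))
    return(Inf)
  pk_t <- trajectory_peak(treated, "N")
  pk_u <- trajectory_peak(untreated, "N")
  n <- length(treated$times)
  if (pk_t$time >= treated$times[n]) return(Inf)
  pk_t$time - pk_u$time
}

check_same_grid <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("trajectories are not on the same sampling grid", call. = FALSE)
  invisible(TRUE)
}

#' Scale-free distance between two trajectories
#'
#' Symmetric L2 distance over both compartments on a shared grid, each
#' compartment's difference normalized by the larger of the two path norms
#' (so the measure is scale-free and 0 exactly when the sampled paths
#' coincide). Used to quantify how closely a treated system tracks its
#' untreated reference.
#'
#' @param a,b Trajectories on the same sampling grid.
#' @return A dimensionless non-negative number.
#' @export
trajectory_distance <- function(a, b) {
  stopifnot(inherits(a, "conjoint_trajectory"),
            inherits(b, "conjoint_trajectory"))
  check_same_grid(a, b)
  comp <- function(xa, xb) {
    den <- max(sqrt(sum(xa^2)), sqrt(sum(xb^2)))
    if (den == 0) return(0)
    sqrt(sum((xa - xb)^2)) / den
  }
  sqrt(comp(a$N, b$N)^2 + comp(a$T, b$T)^2)
}

#' Plot a trajectory
#'
#' Two stacked panels: population sizes (normal and tumor, with the critical
#' size and therapy start marked when applicable) and the drug level.
#'
#' @param x A [simulate_model()] trajectory.
#' @param ... Passed to [graphics::matplot()] for the population panel.
#' @return Invisibly, `x`.
#' @export
plot.conjoint_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$times, cbind(x$N, x$T), type = "l", lty = 1,
                    col = c("blue", "purple"), xlab = "time",
                    ylab = "cells", ...)
  if (!is.null(x$spec$interaction))
    graphics::abline(h = x$spec$interaction$t_crit, lty = 2, col = "grey40")
  if (is.finite(x$t_rx))
    graphics::abline(v = x$t_rx, lty = 3, col = "grey40")
  graphics::legend("topleft", c("normal", "tumor"), lty = 1,
                   col = c("blue", "purple"), bty = "n")
  graphics::plot(x$times, x$u, type = "l", xlab = "time", ylab = "drug level u")
  invisible(x)
}
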