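#' Intrinsic growth law
#'
#' Parametrizes the per-compartment intrinsic growth of a cell population as
#' a generalized-logistic (Richards) law
#' \deqn{dx/dt = (r/\nu)\, x \,\left(1 - (x/K)^\nu\right),}
#' where `rate` is the per-time growth coefficient \eqn{r}, `capacity` the
#' carrying capacity (asymptotic plateau) \eqn{K}, and `shape` the
#' dimensionless exponent \eqn{\nu \ge 0}. `shape = 1` is the plain logistic
#' law \eqn{r x (1 - x/K)}; `shape = 0` is the Gompertz limit
#' \eqn{r x \ln(K/x)} (the \eqn{\nu \to 0} limit of the family, exact under
#' this normalization).
#'
#' @param rate Per-time intrinsic growth coefficient; must be positive.
#' @param capacity Carrying capacity in cells; must be positive.
#' @param shape Dimensionless exponent \eqn{\nu \ge 0}. Default 1 (logistic).
#' @return An object of class `growth_law`.
#' @examples
#' logistic_tumor <- growth_law(rate = 0.3, capacity = 1.2e6)
#' gompertz_tumor <- growth_law(rate = 0.083, capacity = 1e5, shape = 0)
#' @seealso [growth_flux()], [closed_form_population()]
#' @export
growth_law <- function(rate, capacity, shape = 1) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate),
            is.numeric(capacity), length(capacity) == 1L, is.finite(capacity),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (capacity <= 0) stop("`capacity` must be > 0", call. = FALSE)
  if (shape < 0) stop("`shape` (nu) must be >= 0", call. = FALSE)
  structure(list(rate = rate, capacity = capacity, shape = shape),
            class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  fam <- if (x$shape == 0) "Gompertz (nu = 0)"
         else if (x$shape == 1) "logistic (nu = 1)"
         else sprintf("generalized logistic (nu = %g)", x$shape)
  cat(sprintf("<growth_law> %s: rate = %g /time, capacity = %g cells\n",
              fam, x$rate, x$capacity))
  invisible(x)
}

is_growth_law <- function(x) inherits(x, "growth_law")

#' Growth flux of a generalized-logistic law
#'
#' Evaluates the instantaneous growth rate \eqn{dx/dt} of a population of
#' size `x` under a [growth_law()]. For `shape > 0` this is
#' \eqn{(r/\nu) x (1 - (x/K)^\nu)}; for `shape = 0` the Gompertz limit
#' \eqn{r x \ln(K/x)}, with flux 0 at \eqn{x = 0} by continuity. The flux is
#' exactly 0 at \eqn{x = K} for every shape, positive on \eqn{(0, K)} and
#' negative above \eqn{K}.
#'
#' @param x Population size in cells; non-negative, may be a vector.
#' @param law A [growth_law()].
#' @return Growth flux in cells per unit time, same length as `x`.
#' @examples
#' growth_flux(6e5, growth_law(0.3, 1.2e6))   # logistic mid-curve: 9e4
#' growth_flux(1, growth_law(0.083, 1e5, shape = 0))
#' @export
growth_flux <- function(x, law) {
  stopifnot(is_growth_law(law), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0))
    stop("population size `x` must be finite and >= 0", call. = FALSE)
  r <- law$rate; K <- law$capacity; nu <- law$shape
  if (nu > 0) {
    (r / nu) * x * (1 - (x / K)^nu)
  } else {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- r * x[pos] * log(K / x[pos])
    out
  }
}

#' Closed-form population trajectory
#'
#' Analytic solution of the generalized-logistic growth ODE, used as an
#' independent oracle for the numerical engine. For `shape` \eqn{\nu > 0}
#' \deqn{x(t) = K\left[1 + ((K/x_0)^\nu - 1)\, e^{-r t}\right]^{-1/\nu},}
#' and in the Gompertz limit \eqn{\nu = 0}
#' \deqn{x(t) = K \exp\!\left(\ln(x_0/K)\, e^{-r t}\right).}
#' The solution is monotone non-decreasing in \eqn{t} when \eqn{x_0 < K} and
#' converges to the capacity as \eqn{t \to \infty}.
#'
#' @param law A [growth_law()].
#' @param x0 Initial population size in cells; must be positive.
#' @param t Time(s) at which to evaluate; non-negative, may be a vector.
#' @return Population size(s) in cells.
#' @examples
#' closed_form_population(growth_law(0.3, 1.2e6), x0 = 1, t = c(0, 43, 100))
#' @export
closed_form_population <- function(law, x0, t) {
  stopifnot(is_growth_law(law), is.numeric(x0), length(x0) == 1L, is.numeric(t))
  if (!is.finite(x0) || x0 <= 0)
    stop("initial size `x0` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("time `t` must be finite and >= 0", call. = FALSE)
  r <- law$rate; K <- law$capacity; nu <- law$shape
  if (nu > 0) {
    K * (1 + ((K / x0)^nu - 1) * exp(-r * t))^(-1 / nu)
  } else {
    K * exp(log(x0 / K) * exp(-r * t))
  }
}
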