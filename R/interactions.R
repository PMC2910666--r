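#' Bidirectional tumor-normal interaction parameters
#'
#' Houses the coupling constants of the conjoint model: the tumor population
#' modifies normal-cell growth through a growth-modification-factor (GMF)
#' term that stimulates below a critical tumor size `t_crit` and inhibits
#' above it, while normal cells restrain the tumor through a saturating
#' suppression term with ceiling `k`.
#'
#' Setting `beta = 0` and `k = 0` decouples the two compartments exactly.
#'
#' @param beta Per-time stimulation/inhibition coefficient of the tumor's
#'   effect on normal cells. Non-negative.
#' @param k Suppression ceiling (cells per time) of the normal cells' effect
#'   on the tumor; the magnitude of the tumor modifier never exceeds `k`.
#'   Non-negative.
#' @param t_crit Critical tumor size \eqn{T^*} in cells at which the tumor's
#'   effect on normal cells switches sign from stimulation to inhibition.
#' @param rho0 Half-saturation (cells) of the normal-cell effect on the tumor.
#' @param rho1 Half-saturation (cells) in tumor size; gives both modifiers a
#'   smooth onset at small tumor burden.
#' @param k_scale Tumor-size normalization (cells) of the stimulation term;
#'   defaults, when a scenario is assembled, to the tumor carrying capacity
#'   of that scenario. Must be positive.
#' @param variant Interaction rule for the normal compartment: `"default"`
#'   (logistic-shaped in tumor size) or `"hill"` (Hill terms of degree
#'   `hill_m`).
#' @param hill_m Hill degree for the `"hill"` variant; integer-valued
#'   \eqn{\ge 1}.
#' @return An object of class `interaction_params`.
#' @examples
#' interaction_params(beta = 2, k = 1, t_crit = 3e5, rho0 = 1, rho1 = 1000,
#'                    k_scale = 1.2e6)
#' @export
interaction_params <- function(beta = 2, k = 1, t_crit = 3e5, rho0 = 1,
                               rho1 = 1000, k_scale = NULL,
                               variant = c("default", "hill"), hill_m = 1) {
  variant <- match.arg(variant)
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    v
  }
  beta <- num1(beta, "beta"); k <- num1(k, "k")
  t_crit <- num1(t_crit, "t_crit"); rho0 <- num1(rho0, "rho0")
  rho1 <- num1(rho1, "rho1")
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (t_crit <= 0) stop("`t_crit` must be > 0", call. = FALSE)
  if (rho0 <= 0) stop("`rho0` must be > 0", call. = FALSE)
  if (rho1 <= 0) stop("`rho1` must be > 0", call. = FALSE)
  if (!is.null(k_scale)) {
    k_scale <- num1(k_scale, "k_scale")
    if (k_scale <= 0) stop("`k_scale` must be > 0", call. = FALSE)
  }
  hill_m <- num1(hill_m, "hill_m")
  if (hill_m < 1) stop("`hill_m` must be >= 1", call. = FALSE)
  structure(list(beta = beta, k = k, t_crit = t_crit, rho0 = rho0,
                 rho1 = rho1, k_scale = k_scale, variant = variant,
                 hill_m = hill_m),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf(
    "<interaction_params> variant = %s: beta = %g, k = %g, T* = %g, rho0 = %g, rho1 = %g, k_scale = %s\n",
    x$variant, x$beta, x$k, x$t_crit, x$rho0, x$rho1,
    if (is.null(x$k_scale)) "(tumor capacity)" else format(x$k_scale)))
  invisible(x)
}

check_populations <- function(N, T) {
  if (any(!is.finite(N)) || any(N < 0) || any(!is.finite(T)) || any(T < 0))
    stop("population sizes must be finite and >= 0", call. = FALSE)
}

resolved_k_scale <- function(p) {
  if (is.null(p$k_scale))
    stop("`k_scale` unresolved: set it or assemble the params in a model spec",
         call. = FALSE)
  p$k_scale
}

#' Tumor effect on normal-cell growth (GMF term)
#'
#' The extra flux \eqn{f_N(T)\,N} added to the normal-cell equation. The
#' default rule is logistic-shaped in tumor size,
#' \deqn{f_N(T) = \beta \frac{T}{K_{scale}} \left(1 - \frac{T}{T^*}\right)
#'   \frac{T}{\rho_1 + T},}
#' so the flux is zero with no tumor, positive (stimulation by the
#' growth-modification factor) for \eqn{0 < T < T^*}, zero exactly at the
#' critical size \eqn{T^*}, negative (inhibition, ultimately kill) beyond it,
#' and proportional to `N`. Any pluggable variant must preserve this sign
#' contract.
#'
#' @param N,T Normal and tumor population sizes in cells (non-negative;
#'   vectors recycle as usual).
#' @param p An [interaction_params()] with `k_scale` resolved.
#' @return Flux in cells per unit time (added to dN/dt).
#' @examples
#' p <- interaction_params(k_scale = 1.2e6)
#' normal_modifier(1e6, 1.2e6, p)   # above T*: strongly negative
#' normal_modifier(1e6, 3e5, p)     # at T*: exactly 0
#' @export
normal_modifier <- function(N, T, p) {
  stopifnot(inherits(p, "interaction_params"))
  check_populations(N, T)
  ks <- resolved_k_scale(p)
  p$beta * (T / ks) * (1 - T / p$t_crit) * (T / (p$rho1 + T)) * N
}

#' Normal-cell suppression of the tumor
#'
#' The saturating restraint the normal population exerts on tumor growth,
#' \deqn{f_T(N) = -k \frac{N}{\rho_0 + N} \frac{T}{\rho_1 + T}.}
#' It is never positive, vanishes when either population is absent, and its
#' magnitude saturates at the ceiling `k` as \eqn{N \to \infty} (the
#' "constant effect" of large normal populations).
#'
#' @inheritParams normal_modifier
#' @return Flux in cells per unit time (added to dT/dt; \eqn{\le 0}).
#' @examples
#' p <- interaction_params()
#' tumor_modifier(1, 1e6, p)    # N = rho0: half the ceiling, -k/2
#' tumor_modifier(1e12, 1e6, p) # saturated: approx -k
#' @export
tumor_modifier <- function(N, T, p) {
  stopifnot(inherits(p, "interaction_params"))
  check_populations(N, T)
  -p$k * (N / (p$rho0 + N)) * (T / (p$rho1 + T))
}

#' Hill-function variant of the normal-cell modifier
#'
#' Replaces the default rule's tumor-size dependence with Hill terms of
#' degree `m = hill_m`:
#' \deqn{f_N(T)\,N = \beta \frac{T^m}{\rho_1^m + T^m}
#'   \left(1 - (T/T^*)^m\right) N.}
#' The zeros at \eqn{T = 0} and \eqn{T = T^*} and the sign contract of
#' [normal_modifier()] are preserved for every degree.
#'
#' @inheritParams normal_modifier
#' @return Flux in cells per unit time.
#' @export
hill_normal_modifier <- function(N, T, p) {
  stopifnot(inherits(p, "interaction_params"))
  if (p$hill_m < 1) stop("`hill_m` must be >= 1", call. = FALSE)
  check_populations(N, T)
  m <- p$hill_m
  p$beta * (T^m / (p$rho1^m + T^m)) * (1 - (T / p$t_crit)^m) * N
}

# Dispatch on the configured variant.
normal_interaction_flux <- function(N, T, p) {
  switch(p$variant,
         default = normal_modifier(N, T, p),
         hill = hill_normal_modifier(N, T, p))
}
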