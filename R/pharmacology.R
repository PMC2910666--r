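#' Chemotherapy exposure schedule and response coefficients
#'
#' Describes the drug program: the exposure level \eqn{u(t)} at the tumor
#' site and the pharmacodynamic response of each compartment. Exposure is 0
#' before the therapy start `t_rx`; from `t_rx` on it is either constant
#' (`mode = "static"`) or decays exponentially,
#' \eqn{u(t) = u_0 e^{-d (t - t_{rx})}} (`mode = "exp_decay"`). The decay
#' clock is referenced to therapy start, where `u0` — the initial value of
#' the drug — is administered.
#'
#' The per-capita kill applied to compartment \eqn{i} is the fractional-cell-
#' kill law \eqn{F(u) = a_i (1 - e^{-m u})}. For a static drug this is a
#' constant, and configurations may instead supply the lumped constants
#' `lumped_kill_N` / `lumped_kill_T` directly (the style in which treated
#' scenarios are usually reported); the two entry styles produce identical
#' dynamics.
#'
#' @param mode `"none"` (no drug, kill rates identically zero), `"static"`,
#'   or `"exp_decay"`.
#' @param u0 Initial/constant drug amount (dimensionless concentration
#'   units); non-negative.
#' @param d Per-time exponential decay rate (used by `"exp_decay"`);
#'   non-negative.
#' @param m Dimensionless pharmacokinetic exponent of the kill law; default 1.
#' @param a_N,a_T Per-time response coefficients (kill-rate asymptotes) of
#'   the normal and tumor compartments; non-negative.
#' @param t_rx Therapy start time; non-negative.
#' @param lumped_kill_N,lumped_kill_T Optional static shorthand: the constant
#'   per-capita kill \eqn{a_i (1 - e^{-m u_0})} given directly. Only valid
#'   with `mode = "static"`; overrides the `(a, u0)` pair for that
#'   compartment.
#' @return An object of class `drug_program`.
#' @examples
#' drug_program("static", lumped_kill_T = 0.1, t_rx = 40)
#' drug_program("exp_decay", u0 = 3, d = 0.5, a_T = 0.1, t_rx = 40)
#' @export
drug_program <- function(mode = c("none", "static", "exp_decay"),
                         u0 = 0, d = 0, m = 1, a_N = 0, a_T = 0, t_rx = 40,
                         lumped_kill_N = NULL, lumped_kill_T = NULL) {
  mode <- match.arg(mode)
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    v
  }
  u0 <- num1(u0, "u0"); d <- num1(d, "d"); m <- num1(m, "m")
  a_N <- num1(a_N, "a_N"); a_T <- num1(a_T, "a_T"); t_rx <- num1(t_rx, "t_rx")
  if (u0 < 0) stop("`u0` must be >= 0", call. = FALSE)
  if (d < 0) stop("`d` must be >= 0", call. = FALSE)
  if (m <= 0) stop("`m` must be > 0", call. = FALSE)
  if (a_N < 0 || a_T < 0) stop("response coefficients must be >= 0", call. = FALSE)
  if (t_rx < 0) stop("`t_rx` must be >= 0", call. = FALSE)
  for (nm in c("lumped_kill_N", "lumped_kill_T")) {
    v <- get(nm)
    if (!is.null(v)) {
      v <- num1(v, nm)
      if (v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
      if (mode != "static")
        stop(sprintf("`%s` is a static-drug shorthand; mode is \"%s\"", nm, mode),
             call. = FALSE)
      assign(nm, v)
    }
  }
  structure(list(mode = mode, u0 = u0, d = d, m = m, a_N = a_N, a_T = a_T,
                 t_rx = t_rx, lumped_kill_N = lumped_kill_N,
                 lumped_kill_T = lumped_kill_T),
            class = "drug_program")
}

#' @export
print.drug_program <- function(x, ...) {
  desc <- switch(x$mode,
    none = "no drug",
    static = sprintf("static from t = %g", x$t_rx),
    exp_decay = sprintf("u0 = %g decaying at d = %g /time from t = %g",
                        x$u0, x$d, x$t_rx))
  cat(sprintf("<drug_program> %s", desc))
  if (x$mode == "static") {
    kn <- static_kill(x, "N"); kt <- static_kill(x, "T")
    cat(sprintf("; per-capita kill N = %g, T = %g", kn, kt))
  } else if (x$mode == "exp_decay") {
    cat(sprintf("; a_N = %g, a_T = %g, m = %g", x$a_N, x$a_T, x$m))
  }
  cat("\n")
  invisible(x)
}

#' Drug level at a given time
#'
#' @param t Time(s); non-negative.
#' @param prog A [drug_program()].
#' @return Drug amount \eqn{u(t)}: 0 before `t_rx` (and always for
#'   `mode = "none"`); `u0` for a static drug; `u0 * exp(-d (t - t_rx))` for
#'   an exponentially decaying one. Non-negative and non-increasing after
#'   therapy start.
#' @examples
#' prog <- drug_program("exp_decay", u0 = 3, d = 0.5, t_rx = 40)
#' drug_level(c(0, 40, 42), prog)
#' @export
drug_level <- function(t, prog) {
  stopifnot(inherits(prog, "drug_program"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time `t` must be finite and >= 0", call. = FALSE)
  if (prog$mode == "none") return(numeric(length(t)) + 0 * t)
  on_rx <- t >= prog$t_rx
  u <- numeric(length(t))
  u[on_rx] <- switch(prog$mode,
    static = prog$u0,
    exp_decay = prog$u0 * exp(-prog$d * (t[on_rx] - prog$t_rx)))
  u
}

#' Fractional-cell-kill rate
#'
#' The pharmacodynamic law \eqn{F(u) = a (1 - e^{-m u})}: zero without drug,
#' strictly increasing in exposure, saturating at the response coefficient
#' `a` for large `u`.
#'
#' @param u Drug amount(s); non-negative.
#' @param a Per-time response coefficient (the kill-rate asymptote).
#' @param m Pharmacokinetic exponent; default 1.
#' @return Per-capita kill rate(s), per unit time.
#' @examples
#' kill_rate(1, a = 0.1)        # 0.1 * (1 - exp(-1))
#' kill_rate(1e3, a = 0.1)      # saturated near 0.1
#' @export
kill_rate <- function(u, a, m = 1) {
  stopifnot(is.numeric(u), is.numeric(a), is.numeric(m))
  if (any(!is.finite(u)) || any(u < 0))
    stop("drug amount `u` must be finite and >= 0", call. = FALSE)
  if (any(a < 0)) stop("`a` must be >= 0", call. = FALSE)
  if (any(m <= 0)) stop("`m` must be > 0", call. = FALSE)
  a * (1 - exp(-m * u))
}

# Constant per-capita kill of a static program for one compartment,
# honouring the lumped shorthand so both entry styles match bit for bit.
static_kill <- function(prog, compartment = c("N", "T")) {
  compartment <- match.arg(compartment)
  lump <- if (compartment == "N") prog$lumped_kill_N else prog$lumped_kill_T
  if (!is.null(lump)) return(lump)
  a <- if (compartment == "N") prog$a_N else prog$a_T
  kill_rate(prog$u0, a, prog$m)
}

# Per-capita kill applied to a compartment at time t (0 before therapy).
percapita_kill <- function(t, prog, compartment = c("N", "T")) {
  compartment <- match.arg(compartment)
  if (prog$mode == "none") return(numeric(length(t)) + 0 * t)
  out <- numeric(length(t))
  on_rx <- t >= prog$t_rx
  if (!any(on_rx)) return(out)
  if (prog$mode == "static") {
    out[on_rx] <- static_kill(prog, compartment)
  } else {
    a <- if (compartment == "N") prog$a_N else prog$a_T
    out[on_rx] <- kill_rate(drug_level(t[on_rx], prog), a, prog$m)
  }
  out
}
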