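---
title: "Modeling conjoint tumor-normal cell dynamics under chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conjoint tumor-normal cell dynamics under chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjointgrowth)
```

## The model and its assumptions

`conjointgrowth` simulates two cell populations growing in one
environment: normal (aging, fibroblast-like) cells `N(t)` and tumor cells
`T(t)`, both in units of cells, time in arbitrary culture-time units. The
model is a deterministic, well-mixed ODE system — no spatial structure, no
demographic stochasticity, no immune compartment — so populations are
continuous and values below one cell are reported as-is.

Each compartment has an intrinsic generalized-logistic (Richards) growth
law

$$\frac{dx}{dt} = \frac{r}{\nu}\, x \left(1 - (x/K)^\nu\right),$$

normalized so that $\nu = 1$ is the plain logistic law and the limit
$\nu \to 0$ is *exactly* the Gompertz law $r\,x \ln(K/x)$. This
normalization was chosen (over Richards forms whose small-$\nu$ limit
degenerates) precisely so the logistic and Gompertzian tumor variants are
two members of one family; `growth_flux()` and `closed_form_population()`
implement the flux and its analytic solution for every $\nu \ge 0$, and
the analytic solution doubles as the oracle for the numerical engine in
the test suite. Zero is an absorbing state for every shape: the Gompertz
flux is defined as 0 at $x = 0$ by continuity.

On top of intrinsic growth sit two interaction terms:

* **Tumor on normal cells** (the growth-modification-factor, GMF, effect):
  a tumor-secreted factor stimulates normal-cell proliferation at
  intermediate tumor burden and inhibits or kills at high burden. This is
  represented phenomenologically through tumor size: the default rule adds
  $f_N(T)\,N$ to $dN/dt$ with
  $$f_N(T) = \beta\,\frac{T}{K_{scale}}\left(1 - \frac{T}{T^*}\right)\frac{T}{\rho_1 + T}.$$
  The contract any variant must satisfy: zero effect without tumor,
  stimulation for $0 < T < T^*$, a sign switch exactly at the critical
  size $T^*$, inhibition beyond it, and proportionality to $N$. A
  Hill-function variant of degree $m \ge 1$ (`variant = "hill"`) keeps the
  same zeros and signs with sharper switching.
* **Normal cells on the tumor**: a saturating restraint
  $$f_T(N, T) = -k\,\frac{N}{\rho_0 + N}\,\frac{T}{\rho_1 + T},$$
  never positive, ceiling $k$ (cells/time) as $N \to \infty$ — beyond a
  point, more normal cells exert no additional control.

Chemotherapy enters as the fractional-cell-kill law
$F(u) = a_i(1 - e^{-m u})$ applied per capita to each compartment, with
exposure $u(t)$ either static or decaying exponentially from therapy
start.

## Parameters, defaults, and why

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `r_N`, `r_T` | intrinsic per-capita growth rates | 1/time | 0.4, 0.3 |
| `K_N`, `K_T` | carrying capacities | cells | 1e6, 1.2e6 |
| `γ`, `h` | Gompertz rate and plateau (tumor) | 1/time, cells | 0.083, 1e5 |
| `β` | GMF stimulation/inhibition coefficient | 1/time | 2 |
| `T*` | critical tumor size (sign switch) | cells | 3e5 |
| `k` | tumor-suppression ceiling | cells/time | 1 |
| `ρ0`, `ρ1` | half-saturations in `N` and `T` | cells | 1, 1000 |
| `a_N`, `a_T` | kill-rate asymptotes | 1/time | scenario |
| `m` | pharmacokinetic exponent | — | 1 |
| `u0`, `d` | initial drug level, decay rate | —, 1/time | scenario |
| `t_rx` | therapy start | time | 40 |
| `N0`, `T0` | initial sizes | cells | 1, 1 |

These defaults are the canonical conditions this family of conjoint-growth
models is studied under: both populations seeded from a single cell, the
tumor's capacity slightly above the normal cells', and a critical size
well below both capacities so the stimulation-then-inhibition transition
happens mid-growth. The static-drug scenarios store the *lumped* constants
$a_i(1-e^{-m u_0}) \in \{0.01, 0.05, 0.1, 0.17\}$ directly, because that
per-capita kill is the only quantity the dynamics see; entering an
equivalent $(a_i, u_0)$ pair produces identical trajectories.

Two genuinely open choices deserve explanation:

* **The normalization `k_scale`.** The stimulation rule divides $T$ by the
  tumor's carrying capacity (of the active scenario) so that the
  per-capita stimulation is of order $\beta (T/K_T)(1 - T/T^*)$. Without
  this normalization a per-capita boost of order $\beta = 2$ would drive
  the normal cells toward $(1 + \beta/r_N) K_N = 6\times10^6$ — far
  outside the regime this model describes, where the normal cells rise
  only modestly above $K_N$ (to about $1.15\times10^6$ at $t = 40$ in the
  default coupled scenario) before the tumor passes $T^*$ and pushes them
  into decline.
* **`ρ1` appears in both interaction terms.** With $\rho_1 = 1000 \ll T^*$
  it acts only as a smooth onset at very small tumor burden; in
  particular it prevents the suppression term from extinguishing a tumor
  seeded at $T_0 = 1$ cell, which would contradict the coupled system's
  entire untreated narrative.

* **The drug decay clock** is referenced to therapy start:
  $u(t) = u_0 e^{-d(t - t_{rx})}$, so $u_0$ — the *initial* value of the
  drug — is the level actually administered at $t_{rx}$. Before $t_{rx}$
  there is no drug.

## Therapy triggers and event semantics

Model-1 scenarios start therapy at a fixed time ($t_{rx} = 40$, by which
the untreated tumor is approaching $T^*$). Model-2 (Gompertzian tumor)
scenarios start therapy when the tumor first exceeds $T^*$ — the moment
the normal cells enter their inhibition phase — located by a drug-free
pre-run and refined by root finding.

Derived metrics:

* `first_crossing_time()` — earliest grid time at or above a threshold,
  refined on dense output to ~1e-7 in time; a path starting at or above
  the threshold crosses at its first sample; `NA` if never.
* `trajectory_peak()` — first global maximum (ties broken earliest),
  interior peaks refined by golden-section search on dense output.
* `inhibition_onset_delay()` — treated minus untreated normal-cell peak
  time. Censored (`Inf`) when the treated system never enters inhibition
  within the horizon: its tumor never reaches $T^*$, or its normal cells
  are still rising at the final sample. Note that when the drug itself
  kills normal cells the treated peak can come *earlier* than the
  untreated one (the drug, not the tumor, ends the rise) even while the
  $T^*$ crossing — the tumor-driven sense of inhibition onset — is
  delayed; the scenario summaries expose both quantities.
* `trajectory_distance()` — per-compartment L2 distance normalized by the
  larger of the two path norms, combined across compartments. Chosen to
  be symmetric and scale-free; in all treated-versus-untreated
  comparisons the reference is the shared untreated path, so orderings in
  the decay rate are unaffected by the choice of normalization.

## Numerical choices

* **Integrator**: `deSolve::ode` (lsoda), rtol $10^{-8}$, atol $10^{-8}$
  cells. The absolute tolerance sits far below one cell because every
  canonical scenario is seeded at a single cell and relative accuracy
  matters from the first time step.
* **Piecewise integration**: drug onset is a step discontinuity in the
  right-hand side, so the engine integrates $[0, t_{rx}]$ and
  $[t_{rx}, t_{end}]$ as separate smooth segments; adaptive steppers lose
  their error control across interior discontinuities otherwise. The
  output grid itself stays uniform (default step 0.1 time units) so
  treated and untreated trajectories are directly comparable.
* **Dense output**: arbitrary-time evaluation re-integrates from the
  nearest stored grid state at rtol $10^{-10}$, splitting at $t_{rx}$ when
  an interval straddles it. Event refinement (crossings, peaks) runs on
  this dense output, so event times are accurate to well below the
  sampling step (halving the step moves them by less than $10^{-3}$).
* **Non-negativity**: the solver state is floored at zero inside the
  right-hand side (tolerance-sized negative excursions are numerical),
  sampled values within the absolute tolerance of zero are reported as
  exactly zero, and non-finite states abort with the last valid state in
  the error. Extinction is therefore representable and absorbing.
* **Degenerate inputs**: $N_0 = T_0 = 0$ yields the identically zero
  trajectory; zero-dose static drug and `mode = "none"` agree to
  integrator accuracy; `beta = k = 0` decouples the system bit-exactly
  (the interaction terms evaluate to literal zero).

## The Gompertz plateau question

The Model-2 parameter set pairs a Gompertz plateau $h = 10^5$ with the
critical size $T^* = 3\times10^5$ and with the statement that the
Gompertzian and logistic tumors reach nearly the same long-run size. These
cannot all hold: a tumor with plateau $10^5$ never reaches $3\times10^5$,
so triggered therapy never fires — which the literal `fig4_*` presets
faithfully reproduce. Because the three statements are mutually
inconsistent under any plateau interpretation, the registry also carries
`fig4_consistent_*` presets with the plateau raised to the logistic
capacity $1.2\times10^6$; these reproduce the described Model-2 narrative
(very fast early tumor growth, inhibition onset much earlier than in the
logistic model, therapy from the $T^*$ crossing, stronger kill needed to
protect the normal cells). The package deliberately does not guess which
parametrization produced the original figures; both are first-class.

## What the scenarios do and do not show

The preset registry *is* the study design: deterministic, well-mixed,
two-compartment dynamics under the canonical parameters above, with
horizons $t_{end} = 100$ (Model 1) and 60 (Model 2) at sampling step 0.1
— long enough to contain every described event (plateaus, $T^*$
crossings, peaks, extinctions) at negligible cost (each scenario
integrates in well under a second). Passing the suite shows the
implementation honors the model's analytic structure (closed forms,
limits, sign contracts, orderings under treatment). It says nothing about
real tumor-fibroblast cultures: the interaction rules are
phenomenological, the GMF is not mechanistically modeled, drug
pharmacokinetics are reduced to one exponent, and no parameter here was
fit to data.

## Known limitations

* Single drug program per run; no multi-dose schedules, absorption delay,
  or linear/bell-shaped decay profiles.
* No immune compartment, age-structured parameter drift, spatial
  structure, or stochastic effects.
* The interaction algebra is a reconstruction satisfying the model
  family's published verbal constraints; both modifiers are pluggable
  strategies (`variant`, or a custom wrapper around `model_spec()`) so an
  alternative algebra can be swapped in without touching the engine.
* `hill_normal_modifier()` with very high degrees on large tumor sizes
  can overflow double precision; degrees up to ~50 are safe for the
  default scales.
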