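---
title: "Models and methods behind mstbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mstbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstbind)
```

`mstbind` quantifies antibody–small-molecule affinities from microscale
thermophoresis (MST) and equilibrium dialysis data. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate — the information a user needs to judge when the package's
assumptions hold for their data.

## From trace to F_norm

Each capillary yields a fluorescence time series: a pre-laser baseline,
a thermophoretic depletion phase while the IR laser heats the spot, and
back-diffusion after the laser stops. The readout is

$$F_{norm} = \frac{F_h}{F_c}\times 1000 \quad (\text{permille}),$$

with $F_c$ and $F_h$ computed as **window means**, never single samples,
because the quantity of interest is the mean steady-state level on each
side of the temperature jump. Defaults: the cold window spans
laser-on − 4.5 s to laser-on − 0.5 s (the last half-second is dropped to
stay clear of the jump); the hot window is 1 s wide.

Operators traditionally pick the hot-window time point by eye.
`select_hot_window()` automates the choice for reproducibility: it scans
a grid of 1-s windows between laser-on + 1 s and laser-off, computes the
F_norm series for each, runs a preliminary log-logistic fit against
titrant concentration, and keeps the window maximizing
|response amplitude| / residual SD. Ties go to the earliest window
start, so the selection is deterministic. The 1-s width and 1-s grid
step are implementation choices; nothing in the analysis depends
delicately on them because later windows differ only through residual
equilibration and noise.

Capillary QC (`qc_capillaries()`) annotates rather than deletes:

* `BASELINE_OUTLIER` when a capillary's cold mean deviates from the
  series median by more than `baseline_tol` (default ±10%). Instrument
  vendors publish recommended limits but not their values; 10% is a
  conservative round figure and is configurable.
* `BLEACHING` when the least-squares slope of the cold-phase counts
  exceeds `bleach_tol` (default 1% of the cold mean per second) in
  magnitude.
* `EXCLUDED_TOP_POINT` on request, for the common case where the highest
  serum concentration distorts baseline fluorescence and bleaching (an
  abrupt buffer-composition change).

Flagged points are retained in tables but excluded from fits. Fraction
bound, $(x - F_{norm,U})/(F_{norm,B} - F_{norm,U})$, is deliberately
**not clipped** to [0, 1]: clipping noisy values before least squares
would bias estimates; clipping is presentation-only.

## Binding models

**Saturation (conventional MST).** Tracer concentrations (0.25–1 nM)
are comparable to the dissociation constants being measured (sub-nM to
tens of nM), so the hyperbolic `A/(A+Kd)` isotherm is wrong — bound
tracer depletes the titrant. The package always uses the exact 1:1
depletion solution

$$f = \frac{(A + T_0 + K_d) - \sqrt{(A + T_0 + K_d)^2 - 4AT_0}}{2T_0},$$

implemented in the cancellation-free form $2A/(A+T_0+K_d+\sqrt{\cdot})$
(the textbook form loses precision when $A \ll K_d$). The fitted model
is $F_{norm}(A) = U + (B-U)f(A)$ with plateaus $U, B$ free. "Antibody
concentration" always means **binding-site** concentration; converting
IgG molarity (two sites each) is the caller's responsibility.

**Ternary competitive equilibrium.** One site class, two ligands
(labeled tracer, unlabeled competitor). With free sites $F$, mass action
reduces the three balances to a single monotone equation

$$F + \frac{T_0 F}{K_d + F} + \frac{L_0 F}{K_i + F} = I_0,$$

solved by bracketed root-finding on $[0, I_0]$ (relative tolerance
1e-10, followed by Newton polishing to machine precision). Root-finding
was chosen over the closed-form cubic because the bracket makes failure
impossible for physical inputs and one code path covers all parameter
regimes; the test suite cross-checks it against an independent bisection
oracle formulated on bound tracer instead of free sites. Free and bound
amounts are always computed as $T_0 K_d/(K_d+F)$ and $T_0 F/(K_d+F)$ so
that no mass balance suffers cancellation.

**IC₅₀ and K_i.** The IC₅₀ is defined on *total* competitor: the $L$ at
which bound tracer is midway between its zero-competitor value and zero
(the infinite-competitor limit). `ki_from_ic50()` inverts this map by
root-finding on $\log K_i$ over [1e-6, 1e9] nM. The inversion is exact
under the ternary model — no Cheng–Prusoff approximation — but agrees
with $IC_{50} = K_i(1 + T_0/K_d)$ to <0.5% when the site concentration
is negligible, which the tests verify. An IC₅₀ above the highest
titrated concentration is declared unidentifiable rather than
extrapolated.

**Displacement-curve fitting and the Hill slope.** The competition
curve is fitted with a log-logistic in total competitor. The slope
question is genuinely open: displacement is chemically 1:1, but site
depletion *steepens* the observed curve far beyond unit slope when
$K_i \ll I_0$ (approaching a stoichiometric titration), while for weak
competitors ($K_i \gg I_0$) the true curve has exactly unit slope and a
free slope parameter only adds variance — especially when the titration
cannot reach the displaced plateau. Fixing $s=1$ biases the midpoint of
steep curves low by >10%; always freeing it degrades shallow-curve
fits. The default `slope = "auto"` fits both and keeps the extra
parameter only when the extra-sum-of-squares F test supports it
(α = 0.05), the standard model-comparison approach in dose–response
software. Both constrained modes remain selectable, and
`fit_ki_direct()` offers a shape-exact one-step alternative that fits
$K_i$ directly through the ternary model; it is used in the tests as a
cross-check on the two-step route.

Residual caveat: for near-stoichiometric competitors ($K_i \ll I_0$),
*any* smooth symmetric displacement family slightly misplaces the
midpoint, and the IC₅₀ → K_i map is extremely sensitive there (the IC₅₀
sits just above the zero-$K_i$ floor $\approx$ the site-saturation
point). The two-step route then carries a median bias of order 10–20%
on $K_i$ — well inside the replicate scatter such assays report, but
users wanting sub-10% accuracy in that regime should use
`fit_ki_direct()`.

**Optimization.** All nonlinear fits use Levenberg–Marquardt
(`minpack.lm::nlsLM`) with the scale parameter ($K_d$, IC₅₀, $K_i$, …)
on the log scale — affinities here span 0.4 to 6500 nM — and
multi-start over a log-spaced grid (0.01–1000 nM for $K_d$; the
observed concentration range for IC₅₀). Least squares is unweighted
(constant variance): no weighting scheme is standard for F_norm data.
Confidence intervals are asymptotic (linearized) on the log-scale
parameter, then exponentiated; this matches common practice and keeps
CIs positive. Profile or bootstrap intervals are out of scope. A fit
whose amplitude is under 3 residual SDs is refused as a flat curve
rather than reported with a meaningless estimate.

## Equilibrium dialysis

Antibody is confined to the 100 µL sample chamber; tracer and
competitor equilibrate across the membrane to one uniform free
concentration, so the 300 µL buffer chamber shifts the free/bound
balance — the volume asymmetry is modelled explicitly, not absorbed
into an effective concentration. Binding-site concentrations come from
Müller's equation

$$[Ab_t] = b[T_t] + \frac{bK_d}{1-b},$$

with $b$ the bound fraction of sample-chamber tracer at equilibrium and
$[T_t]$ the sample-chamber total **after** equilibration (computed from
the mass balance); the equation is the exact algebraic inverse of the
depletion isotherm, which the tests verify to 1e-9. $K_d$ estimation
from a competition series assumes the homologous case — the deuterated
tracer and the competitor share one dissociation constant — and
least-squares fits the forward dialysis model over $\log K_d$.
Nonspecific binding to membrane or serum proteins is not modelled;
antibody-free runs behave as pure volume partitioning and serve as the
negative control.

## Degradation kinetics

Percent heroin, $100\,[H]_t/[H]_0$, is fitted with one-phase decay
$Y = (Y_0 - P)e^{-kt} + P$, plateau fixed at 0 by default (complete
hydrolysis), $t_{1/2} = \ln 2/k$, and a 99% CI on the half-life obtained
by transforming the asymptotic CI of $k$ (reported as a range, with an
infinite upper bound if the rate CI touches zero). A course is declared
`NON_FIRST_ORDER` — half-life undefined — when the decay $r^2$ falls
below a threshold (default 0.95, configurable) or the fitted rate is
non-positive. The threshold is an explicit operationalization of the
reporting convention that serum courses "follow" first-order kinetics
at $r^2 \gtrsim 0.975$ and do not at lower values; it is approximate by
construction and sits between the observed exemplars of the two
classes.

The synthetic protected-decay model integrates
$d[H]/dt = -k_{free}[H]_{free}$ with $[H]_{free}$ given instantaneously
by the binary rapid-equilibrium isotherm of (sites, total heroin,
$K_d^{eff}$) — antibody-bound heroin is invisible to serum esterases.
This mechanistic form is an extension beyond what degradation
experiments directly report. Two parameter choices matter:

* `k_free` defaults to 1.65 h⁻¹ (half-life ≈ 0.42 h), matching the
  mid-range of reported heroin half-lives in dilute pre-immune serum.
* `kd_heroin` defaults to **0.02 nM**, deliberately ~100× tighter than
  the monovalent solution affinity (~1.6–2.3 nM). Under rapid
  equilibrium a monovalent constant leaves a ≈15% free fraction at
  half-site occupancy and cannot reproduce the observed near-complete
  protection of heroin at or below the binding-site concentration; an
  avidity-level effective constant does, and also reproduces the
  partial-loss pattern at twice the site concentration and uninhibited
  first-order decay at 400×. It should be read as a phenomenological
  protection parameter, not a measured affinity.

## What the generators emulate — and what they do not

Generators are pure functions of (parameters, seed); identical calls are
bit-identical and the caller's RNG stream is untouched.

The trace model is **phenomenological**: cold plateau, instantaneous
temperature jump, exponential approach to the hot plateau (time constant
linearly interpolated between bound, 1.5 s, and unbound, 1.0 s species),
exponential recovery after laser-off, optional photobleaching, and
multiplicative Gaussian noise (default CV 0.5%, reflecting
signal-proportional fluorescence noise). Defaults: baseline 1000 counts,
unbound plateau 1000 ‰, response amplitude −50 ‰ (bound complexes
deplete further; sign configurable), 0.25 s sampling over 40 s with the
laser on from 5 s to 35 s. The true thermophoretic time constants and
amplitudes of cyanine-labeled haptens are not published; these are
order-of-magnitude choices, trivially overridable, and the pipeline
consumes only window means, so higher physical fidelity (Soret physics,
temperature-jump optics) would add nothing testable.

Dilution arithmetic mirrors the bench procedure: a working solution is
serially diluted 1:1 *into buffer* (so the first tube is already halved)
and each dilution is mixed at equal volume with the tracer or complex
solution — a 16,000 nM working solution therefore tops out at 4,000 nM
in the capillary. Dialysis measurements carry 2% multiplicative noise on
the bound fraction (chromatographic quantitation precision); degradation
courses carry 5% on concentrations.

What passing recovery tests demonstrate is therefore *estimator
correctness under the stated noise model*, not robustness to everything
real capillaries do: aggregation, adsorption to capillary walls,
capillary-to-capillary optical variation beyond the QC scenarios,
ligand-induced fluorescence quenching, and pipetting error on the
dilution series are all absent. Polyclonal sera are treated as a single
apparent-affinity site population; bivalent avidity and heterogeneous
site mixtures are out of scope everywhere except through the effective
protection constant above.

## Mass utility

`monoisotopic_mh()` sums most-abundant-isotope masses (CODATA/NIST
values, 22 elements). Published "[M+H]⁺ calculated" formulas follow two
conventions: the formula may be the neutral molecule (add one proton,
1.00727647 u) or the already-protonated ion composition (plain atom
sum). The two differ by the electron mass (0.00055 u) — visible at four
decimals. Both are supported; the ion-composition convention is the
default because it reproduces published calculated values for the
maleimide-linked cyanine tracer this package was validated against.

## Problem sizes and numerical tolerances

The test suite validates solver-vs-oracle agreement on 10³ random
ternary systems (relative error < 1e-8; observed agreement is at
machine precision), mass conservation on 10³ draws, noiseless
generator→fitter round trips to 1e-6 relative, and Monte Carlo recovery
medians with 100 seeds per published design (34 per tracer
concentration for the pooled three-tracer study), 20–200 seeds for
secondary properties. These sizes keep the full suite under a minute
while leaving median estimates with sampling error well below the
tolerances being asserted. `scripts/acceptance.R` re-runs the recovery
studies from scratch at the same sizes.

## Known limitations

* The IC₅₀ → K_i route loses accuracy for near-stoichiometric
  competitors (see above); `fit_ki_direct()` is the remedy.
* Asymptotic CIs undercover slightly for strongly curved likelihoods
  (very weak or very tight binders at the edge of the titrated range).
* The non-first-order verdict is a threshold rule on $r^2$; it exists to
  match a reporting convention, not to test kinetic mechanism.
* The dialysis estimator presumes the homologous-tracer design; a
  heterologous tracer would need a second dissociation constant that
  the single-parameter fit cannot identify.
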