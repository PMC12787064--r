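---
title: "Phi-order kinetics of bimolecular photoreactions: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phi-order kinetics of bimolecular photoreactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phikin)
```

## Why thermal kinetic models fail for photoreactions

The rate of a light-driven reaction depends on how many photons the
reactant absorbs, not on how many reactant molecules exist. Only the
excited fraction X\* can react with a ground-state partner, and that
fraction is set by the incident photon flux `P0`, the reactant absorbance,
and the competition for light among all absorbing species. The classical
second-order law `dC/dt = -k C_X C_X'` contains none of these, so fitting
it to photoreaction traces produces rate "constants" that silently absorb
the lamp intensity, the path length and the absorptivity — and that change
with the illumination geometry.

`phikin` instead starts from the photon-absorption rate

$$P_a^X(t) = A_X(t)\, P_0\, \mathrm{PKF}(A_{tot}), \qquad
\mathrm{PKF}(A) = \frac{1 - 10^{-A}}{A},$$

with the photokinetic factor `PKF` expressing absorption saturation: it is
strictly decreasing, bounded in `(0, ln 10]`, and tends to `ln 10` as the
total absorbance vanishes.

## The four schemes

| scheme | topology | constants | integrated law |
|---|---|---|---|
| a | X + hv -> X\*; X\* + X' -> Y' | `k_bim` (M^-1) | closed form |
| b | (a) + direct photolysis X -> Y | `k_bim`, quantum yield Φ | closed form |
| c | X -> Y' + Y'' (Φ), then Y' + X' -> Y''' | Φ, `k_bim` (M^-1 s^-1) | none (RK4) |
| d | X\* + X -> Y | `k_bim` (M^-1) | none (RK4) |

Under four conditions — (i) only X absorbs at the irradiation wavelength,
(ii) the beam is monochromatic and collimated at a non-isosbestic
wavelength, (iii) the reactant absorbance stays within the linearity range
of its calibration, (iv) the co-reactant is in large excess so its
concentration is effectively frozen — the reactant of schemes (a) and (b)
follows the Phi-order law

$$A_X(t) = \log_{10}\!\left(1 + (10^{A_0} - 1)e^{-k_r t}\right), \qquad
k_r = (k_{bim} C_{X'}(0) + \Phi)\, P_0\, \varepsilon_X l_{irr} \ln 10 .$$

The logarithm is decadic (a consequence of extracting the absorbance from
a power of ten); the `ln 10` inside `k_r` is natural. The two product
channels of scheme (b) share the same logarithmic clock and split the
initial reactant amount by the branching ratio
`Φ : k_bim C_X'(0)` — their asymptotes sum to `C_X(0)` exactly, which the
`mass_balance_residual()` check exploits.

```{r limits}
kr <- 1e-3
t <- seq(0, 3 / kr, length.out = 7)
# small A0: mono-exponential to well under 1%
max(abs(phi_order_absorbance(t, 0.005, kr) / (0.005 * exp(-kr * t)) - 1))
# large A0, early window: linear decay of slope -kr/ln10
limit_regime(2.5)
```

The regime classifier uses `A0 <= 0.01` for the first-order side — the
absorbance below which the one-term series linearisation of `1 - 10^{-A}`
is conventionally trusted — and `A0 >= 2` for the zeroth-order side, with
boundaries assigned to the limiting regime and both thresholds
configurable. Between them no classical model applies; that is the point
of the package.

## Parameters that matter

- `P0` (einstein dm^-3 s^-1): volumetric photon delivery rate; `k_r` is
  strictly linear in it.
- `epsilon_X` (M^-1 cm^-1) and `l_irr` (cm): set the absorbance scale; the
  observation path `l_obs` of a spectrophotometer may differ, and
  `convert_pathlength()` rescales measured absorbances.
- `k_bim`: thermal bimolecular constant. For the photon-coupled step of
  schemes (a), (b), (d) it multiplies a photon rate and a concentration,
  so it carries M^-1; for the ground-state thermal step of scheme (c),
  dimensional closure of its rate law requires M^-1 s^-1. The literature
  prints M^-1 in both contexts; `scheme_spec()` records the per-scheme
  convention and carries a note rather than resolving the ambiguity.
- `phi_direct` (dimensionless, 0..1): quantum yield of the direct
  photoprocess; defined only for monochromatic light.
- Temperature enters only through `k_bim` and is carried as a text label;
  no Arrhenius model is applied.

Polychromatic irradiation is out of scope throughout: the rate law then
becomes an integro-differential equation over the lamp profile with no
closed form, and none of the quantities above are well defined per
wavelength.

## Numerical choices

**Photokinetic factor near zero.** `1 - 10^{-A}` is evaluated with
`expm1`, which keeps the direct quotient accurate down to tiny
absorbances; below `A = 1e-6` a three-term series in `A ln 10` is used so
the value is finite and continuous at zero. The three-term truncation
keeps the switchover discontinuity at ~1e-18, far below the 1e-12
continuity budget the tests enforce (a two-term series would leave ~2e-12
at the threshold).

**Integrator.** Schemes (c) and (d) — and every cross-check of the closed
forms — use classical fixed-step fourth-order Runge–Kutta, the method of
record for these systems, with the number of substeps per output interval
doubled until halving the step changes the final state by less than 1e-8
relative to the initial-concentration scale. The achieved step-halving
error is stored in the trace metadata (`self_consistency`) and reused as
the integrator's error floor when judging model misfit. The initial step
is chosen so that `max|rate| * h <= 1e-3` of the state scale. For schemes
(a) and (b) the integration state is the reactant absorbance — the natural
variable of their rate laws — avoiding a spurious `eps*l` round trip;
concentrations are derived afterwards.

**Degenerate inputs.** `kr * t > 700` underflows the exponential;
evaluation then returns the asymptote exactly rather than warning.
Concentrations that undershoot zero by less than 1e-12 are clipped (an
integration artefact), anything larger raises an error because it would
signal an integrator bug, not chemistry. A length-one time grid returns
the initial state.

**Fitting.** The Phi-order fit is nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`, which also handles the
zero-residual noiseless case) with `A0` fixed at the first observation by
default, leaving `k_r` as the unique parameter. The starting value comes
from the exact linearisation — `ln(10^A - 1)` is globally linear in time
with slope `-k_r` — floored at `1e-3` per observation window so the
gradient stays well scaled even for non-reacting traces. The loss is
unweighted least squares on absorbance (spectrophotometric noise is
approximately homoscedastic in absorbance units); per-point weights are
accepted. Uncertainties are Gauss–Newton covariance approximations at the
optimum and are approximate. For schemes (c) and (d), `k_bim` is the only
unknown once Φ is known, and is found by derivative-free bounded scalar
minimisation of the RSS between the trace and repeated RK4 integrations;
for scheme (c) only the Y' and Y''' columns inform the objective (X and
Y'' evolve independently of `k_bim`), and a reactant-only trace is
reported as unidentifiable rather than fitted.

**Initial rate and quantum yield.** The initial rate is taken from the
fitted model, `r0 = -k_r (1 - 10^{-A_0}) / (ln 10\, \varepsilon_X
l_{irr})`, not from raw early-time differencing: the fit uses the whole
trace and is far less noise-sensitive. Raw differencing remains available
by differentiating the trace directly. The quantum yield follows as
`Φ = -r0 / (P0 (1 - 10^{-A_0}))`, written here as the ratio that
dimensional analysis requires.

**A note on the pseudo-first-order constant.** The product
`k_bim C_X'(0) P0 eps l` (no `ln 10`) is sometimes quoted as the
first-order constant of these reactions. The small-`A0` limit of the
Phi-order law decays with the full `ln 10`-bearing `k_r`, so the package
exposes the bare product only as `pseudo_first_order_constant()`, a named
diagnostic that is never conflated with `k_r`.

## What the synthetic-data generator emulates — and what it does not

`generate_trace()` produces the traces the fitting procedures assume:
a model trace (closed form where one exists, RK4 otherwise) plus additive
Gaussian noise, either in the absorbance domain (spectrophotometer-like,
default sigma 0.002 AU, a typical instrument repeatability — the
underlying study prints no noise magnitudes, so this is a package choice
made once) or in the concentration domain (HPLC-like, per species). The
seed is part of the noise model and is stamped into the provenance;
regeneration is bit-identical. Negative noisy values are kept, not
clipped, so estimators see realistic measurement error; a warning fires
when more than 10% of reactant observations go negative.

Real data additionally show baseline drift, wavelength jitter, photon
shot noise, thermal drift of `k_bim`, and deviations from Beer–Lambert
linearity at high absorbance. None of these are modelled. Passing
recovery tests therefore demonstrate estimator correctness under the
stated noise model, not robustness to instrument pathology.

The validity audit (`check_conditions()`) mirrors conditions (i)–(iv):
absorbing non-reactant species are named; the linearity ceiling defaults
to 2 decadic units (the linearity range is instrument- and
compound-specific; no universal number exists, so the bound is
configurable, checked, and never silently enforced); the co-reactant
excess gate is `C_X(0)/C_X'(0) <= 0.10`. `validity_sweep()` quantifies
the frozen-co-reactant approximation by integrating the general model
(co-reactant depleting, multi-species absorbance) and reports the maximum
deviation of the reactant trace relative to `C_X(0)` — strictly
increasing in the ratio, about 1.7% at the 0.10 gate under the default
parameter set.

## Problem sizes

The shipped tests and the acceptance script use 25–80 point grids over
five characteristic decay times, 100-seed recovery ensembles at sigma =
0.002 AU, and 40–60 point sweeps — sizes at which every check completes in
seconds to a couple of minutes on a single core while leaving the
measured quantities (closed-form agreement ~1e-15, recovery errors well
inside their tolerances) orders of magnitude clear of their thresholds.

## Known limitations

- Monochromatic, collimated, well-stirred slab geometry only.
- No stiff or adaptive embedded integrators; the fixed-step RK4 with
  halving is ample for these smooth, non-stiff systems but would be slow
  for genuinely stiff extensions.
- No global multi-trace fitting, no Bayesian uncertainty, no model
  selection beyond an RSS ranking (`compare_classical_models()` is a
  diagnostic, not an arbiter).
- The excited state X\* is never an explicit state variable: its physics
  is folded into the absorbed-photon rate and the quantum yield, as in
  the underlying kinetic formalism.
- Absorptivity spectra are taken as known inputs; reconstructing them
  from measured spectra is out of scope.
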