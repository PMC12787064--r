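# phikin — Φ-order kinetics of bimolecular photoreactions

`phikin` models the kinetics of light-driven bimolecular reactions under
continuous, monochromatic, collimated irradiation, for photochemists and
photostability analysts who need rate constants and yields from measured
kinetic traces — and who would otherwise reach for thermal second-order or
pseudo-first-order equations that do not describe a photosystem.

## The model

A reactant X absorbs at the irradiation wavelength; only its excited
fraction can react. The photon absorption rate is

    Pa_X(t) = A_X(t) · P0 · PKF(A_tot),    PKF(A) = (1 − 10^(−A)) / A

with `A_X` the reactant absorbance along the irradiation path, `P0` the
incident photon flux (einstein dm⁻³ s⁻¹), and `PKF` the photokinetic
factor (limit ln 10 as `A → 0`). Four reaction topologies are covered:

- **(a)** X + hν → X\*; X\* + X′ → Y′ — thermal step with constant `k_bim`;
- **(b)** as (a) plus a concurrent direct photolysis X → Y (quantum yield Φ);
- **(c)** X → Y′ + Y″ photochemically, then Y′ + X′ → Y‴ thermally;
- **(d)** X\* + X → Y (photodimerisation-type).

When only X absorbs, the absorbance stays in the Beer–Lambert linearity
range, and the co-reactant X′ is in large excess (validity up to
C_X(0)/C_X′(0) = 0.10), schemes (a) and (b) integrate in closed form to the
**Φ-order law**

    A_X(t) = log₁₀( 1 + (10^{A₀} − 1) e^{−k_r t} ),
    k_r = (k_bim C_X′(0) + Φ) · P0 · ε_X · l_irr · ln 10

a decadic logarithm bearing an exponential: first-order-like at small `A₀`,
zeroth-order-like (linear, slope −k_r/ln 10) at large `A₀`, and genuinely
Φ-order between. Schemes (c) and (d) have no closed form and are integrated
by classical fixed-step fourth-order Runge–Kutta with step-halving
refinement; their thermal constant `k_bim` is recovered by fitting repeated
integrations to the trace. Quantum yields follow from fitted initial rates,
Φ = −r₀ / (P0 (1 − 10^{−A₀})); overall efficiency is quantified by the
photonic yield PY = ΔC / (P0 · t).

All quantities use one fixed unit system: s, mol dm⁻³ (M), cm,
einstein dm⁻³ s⁻¹, decadic absorbance.

## Worked example: the two-regime scheme (c)

```r
library(phikin)

setup   <- irradiation_setup(lambda_irr = 365, P0 = 1.2e-6, l_irr = 0.86)
species <- default_species("c", C_X0 = 8.1e-6, C_Xprime0 = 1.3e-4, epsilon_X = 7211)
scheme  <- scheme_spec("c", k_bim = 1.7e-2, phi_direct = 5.3e-4)

check_conditions(scheme, species, setup)
#> Validity conditions for the closed-form (solvable) cases:
#>   (i)   only X absorbs:        pass
#>   (ii)  monochromatic beam:    pass
#>   (iii) within linearity:      pass  [A0 = 0.05023 vs ceiling 2]
#>   (iv)  co-reactant excess:    pass  [C_X0/C_X'0 = 0.06231 vs 0.1]
#>   overall: VALID

kr <- rate_constant_scheme_b(0, 1.3e-4, 5.3e-4, setup, 7211)   # photochemical step
#> 9.082e-06  (s^-1: the reactant X decays Phi-order with this constant)

trace <- integrate_scheme(scheme, species, setup, seq(0, 5/kr, length.out = 80))
scheme_c_shape_diagnostics(trace)
#> $Yprime_has_interior_max  TRUE      # intermediate Y' rises then falls
#> $Yprime_max_time          209073    # s
#> $Ytprime_sigmoid          TRUE      # end product Y''' grows as a sigmoid
#> $inflection_time          216042    # s

fit_numeric_kbim(trace)
#> Fit [numeric_scheme_c]: converged, RSS = 1.017e-21 over 80 points
#>   k_bim  = 0.017  (se 1.74e-09)
```

The condition audit passes (the co-reactant excess ratio is 0.062, inside
the 0.10 gate), the reactant decays with the Φ-order constant
9.08 × 10⁻⁶ s⁻¹ set by the photochemical step alone, the intermediate Y′
passes through an interior maximum near 2.1 × 10⁵ s where the thermal
channel overtakes its photochemical production, and refitting the trace by
repeated numerical integration returns the thermal constant
k_bim = 1.7 × 10⁻² that generated it.

A command-line interface wraps the same functions
(`system.file("cli", "phikin", package = "phikin")`):

```sh
phikin simulate -c config.yaml -o trace.csv [--seed N]
phikin fit      -c config.yaml -i trace.csv -o fit.json [--model phi_order|reciprocal|...]
phikin check    -c config.yaml
phikin sweep    -c config.yaml --ratios 0.01,0.05,0.1,0.5
```

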