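# asdsol

Drug–polymer solubility limits from dielectric relaxation and
calorimetric data.

## The problem

Amorphous solid dispersions (ASDs) — a drug molecularly dispersed in an
amorphous polymer — dissolve better than crystals, but only stay amorphous
while the drug load is below its equilibrium solubility in the polymer at
the storage temperature.  Measuring that limit is done by annealing a
supersaturated dispersion above its glass transition until the excess drug
recrystallizes, then reading the composition of the remaining amorphous
phase from its glass-transition temperature (Tg).  `asdsol` implements the
complete inference chain for such studies, at ambient and elevated
pressure, for broadband dielectric spectroscopy (BDS) and differential
scanning calorimetry (DSC) inputs:

1. **Spectral fitting.** Each dielectric loss spectrum ε″(f) is fitted
   with the Havriliak–Negami function,
   ε″(ω) = −Im[Δε / (1 + (iωτ_HN)ᵃ)ᵇ] (+ optional σ_dc/(ε₀ω)),
   and converted to the model-free relaxation time τ_α via the analytic
   peak-position formula (`fit_hn()`, `tau_alpha_from_hn()`).  Drops in
   the dielectric strength Δε(t) flag recrystallization onset and
   cessation (`detect_recrystallization()`).
2. **Glass-transition extrapolation.** τ_α(T) is parameterized with the
   Vogel–Fulcher–Tammann law τ = τ∞·exp(B/(T−T₀)) and extrapolated to the
   conventional τ_α = 100 s to give Tg (`fit_vft()`, `extrapolate_tg()`);
   sparse conditions use horizontal displacement of a neighbouring fit
   (`horizontal_shift_tg()`).
3. **Composition inversion.** The Gordon–Taylor curve
   Tg = (W₁Tg₁ + K·W₂Tg₂)/(W₁ + K·W₂) is fitted to the measured
   composition–Tg table and inverted in closed form at the post-annealing
   Tg (`fit_gordon_taylor()`, `gt_invert()`).
4. **Liquidus modelling.** The solubility points (annealing T, wt%) are
   fitted with the Flory–Huggins solid–liquid line,
   1/T − 1/T_m⁰ = −(R/ΔH_fus)[ln φ + (1 − 1/m)(1 − φ) + χ(T)(1 − φ)²],
   with χ constant (approach I) or χ(T) = A + B/T (approach II), and
   solved for the solubility at any temperature
   (`fit_fh_chi_constant()`, `fit_fh_chi_temperature()`,
   `solve_liquidus_wtpct()`).
5. **Pressure transposition.** Elevated-pressure Tg curves are displaced
   vertically by a constant ΔTg; high-pressure solubility points are
   referred to ambient by the difference of the pure-drug melting points
   and pooled into combined fits (`transpose_tg_curve()`,
   `transpose_solubility_points()`, `combined_fh_fit()`), including the
   variant with the enthalpic constant B held pressure-independent.

A synthetic-data module (`synthetic_config()`, `generate_*()`,
`simulate_study()`) generates every input with the statistical structure
the analysis assumes, so the entire pipeline is testable without
experimental spectra.  The printed study tables of the
nimesulide (NMS) + Kollidon VA64 (KVA) system ship as plain-text fixtures
(`nms_kva_data()`, `nms_kva_constants()`).

## Worked example

```r
library(asdsol)
d  <- nms_kva_data()

# Tg -> composition: Gordon-Taylor fit of the calorimetric table
gt <- fit_gordon_taylor(d$composition_tg_dsc)
gt
#> <gt_params> Tg(drug) = 294.00 K, Tg(poly) = 377.00 K, K = 0.7062 (fitted)
100 * gt_invert(gt, 330)       # composition after annealing at 398 K
#> [1] 47.97075

# Flory-Huggins liquidus with chi(T) = A + B/T (approach II)
fit <- fit_fh_chi_temperature(d$solubility_bds_ambient, nms_kva_constants())
fit
#> <fh_model> Tm0 = 421.0 K, m = 175.32, chi(T) = 6.606 + (-2992 K)/T
#>   fit: n = 7, R^2 = 0.9833 (temperature residuals)
solve_liquidus_wtpct(298, fit)  # room-temperature solubility, wt%
#> [1] 13.93451
```

The Gordon–Taylor constant K = 0.706 reproduces the measured mixture Tg
values; inverting at the post-annealing Tg of 330 K gives 48 wt% drug —
the equilibrium solubility at the 398 K annealing temperature.  The
approach-II liquidus extrapolates the seven annealing points down to room
temperature, predicting ~14 wt% solubility; the strongly negative
χ(298 K) ≈ −3.4 indicates a miscible pair.

A command-line front end over the same functions is installed at
`system.file("cli", "asdsol.R", package = "asdsol")`, with subcommands
`simulate | fit-hn | fit-vft | tg-map | invert-tg | fit-fh | transpose |
pipeline`.

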