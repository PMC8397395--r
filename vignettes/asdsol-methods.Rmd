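---
title: "Methods: inferring drug-polymer solubility limits from relaxation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring drug-polymer solubility limits from relaxation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdsol)
```

`asdsol` implements the annealing-protocol determination of the
equilibrium solubility of an amorphous drug in a polymer matrix.  This
vignette is the package's own account of the models it uses, the
conventions it adopts where the underlying methodology leaves choices
open, and what its synthetic-data tests do and do not demonstrate.

## The measurement model

The protocol rests on four physical relations.

**Havriliak–Negami (HN) loss.**  An isothermal dielectric loss spectrum
of a supercooled drug–polymer liquid shows one structural
(α-relaxation) peak, modelled as

$$\varepsilon''(\omega) = -\mathrm{Im}\!\left[\frac{\Delta\varepsilon}
  {(1+(i\omega\tau_{HN})^a)^b}\right] + \frac{\sigma_{dc}}{\varepsilon_0\omega},
  \qquad \omega = 2\pi f,$$

with symmetric and asymmetric broadening exponents $a, b \in (0,1]$.
The model-free relaxation time is defined by the loss-peak position,
$2\pi f_{max}\tau_\alpha = 1$, and computed analytically from the HN
parameters; the package verifies this formula against a brute-force
argmax of the model loss rather than trusting it (the printed form of
the peak-time formula is easy to mistranscribe, so oracle equivalence is
part of the test suite).  The dc-conductivity term is supported but off
by default: whether the original spectra required one is not knowable
from the published record, so the choice is recorded in every fit's
metadata.  Only single-peak spectra are modelled; β-relaxations, excess
wings and ε′ fitting are out of scope.

**Vogel–Fulcher–Tammann (VFT) extrapolation.**
$\tau_\alpha(T) = \tau_\infty \exp[B/(T-T_0)]$ is fitted per annealing
condition and extrapolated to the conventional
$T_g = T(\tau_\alpha = 100\,\mathrm{s})$.  Because the closed form
$T_g = T_0 + B/\ln(\tau_{ref}/\tau_\infty)$ inverts the VFT equation
exactly, a longer reference time is reached closer to $T_0$ and
therefore yields a *lower* $T_g$ — the familiar cooling-rate dependence
of the glass transition.  When a condition yields fewer than three
usable relaxation times (e.g. a sample too close to its glass
transition), the VFT curve of the nearest well-parameterized condition
is displaced horizontally through the single available
$(T_a, \tau_a)$ anchor and the displaced curve supplies $T_g$.

**Gordon–Taylor (G–T) inversion.**  Mixture $T_g$ versus drug weight
fraction $W_1$ follows
$T_g = (W_1 T_{g1} + K W_2 T_{g2})/(W_1 + K W_2)$.  The curve is
strictly monotone for $K > 0$, so the composition of an annealed sample
follows uniquely from its measured $T_g$ by the closed-form inverse.

**Flory–Huggins (FH) liquidus.**  Each annealing temperature and its
equilibrium composition is a point on the solid–liquid line

$$\frac{1}{T} - \frac{1}{T_m^0} = -\frac{R}{\Delta H_{fus}}
  \left[\ln\phi + \Big(1-\frac{1}{m}\Big)(1-\phi) + \chi(T)(1-\phi)^2\right],$$

with $\phi$ the drug volume fraction, $m$ the polymer/drug molar-volume
ratio and $\chi$ the interaction parameter, either constant
(approach I) or $\chi(T) = A + B/T$ (approach II).  The line passes
through the pure-drug melting point $(\phi = 1, T_m^0)$ identically, so
that anchor is enforced by construction and never fitted.

## Fitting conventions

* **All nonlinear fits** use Levenberg–Marquardt (`minpack.lm`), with no
  weighting; the FH fits use a chi-square (`ftol`) tolerance of
  $10^{-9}$.
* **HN residuals are computed on $\log_{10}\varepsilon''$** — the loss
  spans decades, and linear residuals would let the peak dominate the
  wings.  Initialization is peak-based
  ($\tau_{HN} = 1/(2\pi f_{argmax})$,
  $\Delta\varepsilon = 2\varepsilon''_{max}$, $a = 0.9$, $b = 0.7$),
  which converges for single-peak spectra from starting values at least
  a decade off in $\tau_{HN}$.
* **VFT fits work in $\log_{10}\tau$** for the same leverage reason, with
  a profiled-$T_0$ linearization as initialization.  Points flagged as
  crystallization onset are excluded.
* **FH residuals are temperatures**: the predicted liquidus temperature
  at each observed composition minus the observed annealing temperature.
  The relation is affine in $1/T$ at fixed composition — also under
  $\chi = A + B/T$ — so the predicted temperature has a closed form and
  both approaches share one objective.  This convention matches how the
  data are plotted (temperature against composition) and is the main
  declared sensitivity of reproducing published interaction parameters:
  published tables round compositions to integer weight percent, and
  with only 4–11 points the fitted $(A, B)$ pair moves noticeably along
  its correlation valley under rounding or a change of residual
  variable.  The package therefore reports $R^2$ (computed on the
  temperature residuals) and parameter standard errors with every fit.
* **Liquidus root selection**: the solubility reported is the largest
  root $\phi \in (0,1)$ — the drug-rich branch.  Roots are located by a
  sign-change scan over a composition grid that is log-spaced in $\phi$
  on the dilute side and log-spaced in $1-\phi$ on the drug-rich side
  (the root approaches $\phi = 1$ arbitrarily closely near $T_m^0$),
  refined by bisection to $10^{-12}$.  For strongly positive $\chi$ the
  drug-rich branch genuinely detaches from the anchor just below
  $T_m^0$ (retrograde behaviour of immiscible lattice solutions); the
  solver then reports the largest existing root.
* **Horizontal VFT displacement** solves for the shift by 1-D bracketing
  with a tolerance of $10^{-6}$ K.
* **G–T endpoints** are fixed to the measured pure-component $T_g$
  values by default; $K$ is the single free parameter.  When
  heat-capacity increments are supplied instead, the adopted convention
  is $K = \Delta C_{p2}/\Delta C_{p1}$ and is recorded in the result,
  since more than one convention circulates in the literature.

## Pressure operations

Elevated pressure enters through three constants per condition: the
pressure itself, the pure-drug melting point at that pressure (a
supplied literature value, e.g. 435 K at 50 MPa for nimesulide versus
421 K ambient), and a single $\Delta T_g$ offset (e.g. 12 K at 50 MPa).
The $T_g$–composition curve is displaced vertically by $\Delta T_g$
(per-composition deviations are surfaced as a diagnostic spread, not
modelled); solubility points measured at pressure are referred to
ambient by shifting their temperatures by the melting-point difference,
then pooled with the ambient points for combined fits.  Following the
view that the enthalpic constant $B$ is pressure-insensitive while the
free-volume-related $A$ is not, the combined fit also supports holding
$B$ at the ambient-only value.  Pressure dependence of $\Delta H_{fus}$
and of the densities is neglected throughout, and no equation of state
for $T_m(P)$ is attempted.

## The synthetic-data generator

The generator exists so that every stage, and the pipeline end to end,
is testable against a known ground truth.  It emulates:

* HN-shaped loss spectra on the instrument-typical grid of 10 points per
  decade from $10^{-1}$ to $10^6$ Hz, with **multiplicative lognormal
  noise** (loss is positive and spans decades; additive noise would
  distort the wings) — default 2% relative;
* VFT-distributed $\tau(T)$ with **additive noise in $\log_{10}\tau$**
  (relaxation times span 8+ decades) — default 0.05 decades;
* G–T-shaped $T_g$(composition) points with Gaussian noise — default
  0.5 K, matching the precision typical of the tabulated $T_g$ values;
* FH-liquidus solubility points with Gaussian noise — default 0.5 wt%;
* logistic-in-time $\Delta\varepsilon(t)$ decays for onset/cessation
  detection (no crystallization-kinetics model is implied — only the
  onset/plateau structure is used downstream);
* sigmoidal calorimetric steps for midpoint-$T_g$ extraction.

Published instrument noise levels for these measurements are rarely
stated; the defaults above are assumptions, deliberately configurable,
chosen to represent careful broadband-dielectric and DSC work.  The
full-study simulator couples the stages the way the experiment does: a
generating FH model fixes the equilibrium composition at each annealing
temperature, the G–T curve fixes that composition's $T_g$ (plus
$\Delta T_g$ under pressure), and a VFT curve anchored at that $T_g$
produces the relaxation times the spectra encode.

What passing synthetic tests show: the estimators invert their own
generating models accurately (noiseless round trips to solver
tolerance; noisy recovery within propagated uncertainty over 50 seeded
replicates), and the pipeline wiring is correct end to end.  What they
do not show: that real spectra contain a single HN process, that real
noise is lognormal, that equilibrium was actually reached during
annealing, or that the FH lattice model with a two-parameter $\chi(T)$
is the right physics for a given drug–polymer pair.

## Problem sizes and determinism

The test suite runs synthetic studies at desk scale — 7 ambient plus 4
elevated-pressure annealing conditions, 4 spectra per condition, 71
frequency points per spectrum, and 50-replicate noise studies — which
keeps the whole suite around a few seconds while leaving every code
path exercised.  All generators draw from a seeded RNG and the pipeline
itself is deterministic: identical configuration and seed give
byte-identical numeric summaries.

## Known limitations

* Reproduction of published FH parameters from rounded printed tables
  is exact only up to the rounding and the (unstated) residual
  convention of the original analysis; with 4 high-pressure points the
  fitted $A$ can differ by several times its nominal standard error
  between conventions.  The constants reported here are the
  least-squares optima of the shipped tables under the temperature
  -residual convention stated above.
* $\tau_\alpha$ uncertainties are not propagated from the spectral fits
  into the VFT covariance (each stage reports its own uncertainties).
* Only one relaxation process per spectrum; no multi-peak
  deconvolution.
* No PC-SAFT or activity-coefficient alternatives to FH; no
  amorphous–amorphous miscibility-gap construction; no modelling of
  crystallization kinetics beyond onset/cessation detection.
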