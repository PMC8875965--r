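---
title: "Predicting arsenate toxicity to plants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting arsenate toxicity to plants: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asblm)
```

## The problem

Total dissolved arsenic is a poor predictor of As(V) phytotoxicity: the
same total produces very different effects depending on pH, phosphate, and
the major-cation composition of the solution. `asblm` implements a biotic
ligand model (BLM) view of this problem. As(V), present at circumneutral pH
as H~2~AsO~4~^−^ and HAsO~4~^2−^, competes with the chemically analogous
phosphate species for active binding sites (the "biotic ligand", X) on the
root-cell plasma membrane; toxicity is a function of the fraction of sites
occupied by As(V). On top of this equilibrium picture, the electrical
potential at the outer membrane surface (Ψ~0~, negative for plant roots)
controls how strongly the As(V) *anions* are attracted to or repelled from
the membrane: raising Ca^2+^ makes Ψ~0~ less negative, concentrates
H~2~AsO~4~^−^/HAsO~4~^2−^ at the surface, and *increases* As(V) toxicity —
the opposite of the protective effect Ca^2+^ has against cationic metals.

The package chains four stages, each usable on its own:

1. **Speciation** (`speciate_medium`): ionic strength, Davies activity
   coefficients, and acid–base speciation of the arsenate and phosphate
   systems for a defined medium.
2. **Membrane electrostatics** (`solve_psi0`): a Gouy–Chapman–Stern (GCS)
   model of the plasma-membrane surface, solved for Ψ~0~.
3. **BLM algebra** (`environmental_modulator`, `inherent_sensitivity`,
   `predict_ec50_site`, `psi0_adjust`): EC50 = IS × EM, plus a linear Ψ~0~
   correction.
4. **Dose–response** (`compute_rre`, `fit_dose_response`, `ec50_from_fit`):
   relative root elongation and sigmoidal EC50 fitting for hydroponic
   assays.

A seeded generator (`simulate_study`) produces complete synthetic studies
so the whole chain can be validated end to end without experimental data.

## The BLM: EC50 as inherent sensitivity times an environmental modulator

All model EC50s are expressed as the bulk activity of HAsO~4~^2−^ (mol/L).
The site-occupancy model gives

$$\mathrm{EC50}\{\mathrm{HAsO_4^{2-}}\} \;=\;
\underbrace{\frac{f^{50\%}_{mix}}{1-f^{50\%}_{mix}}}_{\text{IS}}
\times
\underbrace{\frac{1 + K_{XH_2PO_4}\{\mathrm{H_2PO_4^-}\}
                  + K_{XHPO_4}\{\mathrm{HPO_4^{2-}}\}}
                 {K_{XH_2AsO_4}\{\mathrm{H^+}\}/K_{As} + K_{XHAsO_4}}}_{\text{EM}}$$

where $f^{50\%}_{mix}$ is the fraction of sites that must be occupied by
As(V) species to cause a 50% effect. The four conditional binding constants
(log K 3.067, 4.802, 3.424, 4.588 L/mol) and the conditional
$\mathrm{p}K_{As} = 6.76$ were derived from bacterial bioluminescence
assays and are treated as species-independent: As(V) enters cells through
phosphate transporters in both prokaryotes and plants, which is the
mechanistic basis of the interspecies extrapolation. Everything
species-specific is collapsed into the single number IS (equivalently
$f^{50\%}_{mix}$), calibrated from **one** measured EC50 in a chemically
characterised medium:

```{r calibrate}
sens <- run_calibrate(45.1e-6, species = "Hordeum vulgare",
                      endpoint = "5 d relative root elongation")
sens
```

The registry values shipped with the package (`sensitivity_registry()`)
put barley (f = 0.626) almost on top of the bacterial reference
(f = 0.616), while wheat (f = 0.015) is far more sensitive — IS is doing
exactly the job it was designed for.

## The GCS membrane model

The surface charge density is computed two ways and matched. The diffuse
double layer gives the Graham equation

$$\sigma^2 = 0.00345\sum_i [I^{Z}]_b\!\left(e^{-Z_iF\Psi_0/RT}-1\right),$$

with bulk free-ion concentrations in mol/L at 25 °C, and σ carrying the
sign of Ψ~0~. The Stern layer comprises negatively charged sites R^−^ and
neutral sites P^0^ that bind cations 1:1; with surface-local ion levels
from the Boltzmann factor $[I^Z]_0 = [I^Z]_b e^{-Z F \Psi_0/RT}$, the site
mass balances give

$$\sigma = F\Big({-[R^-]} + \sum_i (Z_i-1)[RI^{Z-1}] + \sum_i Z_i[PI^{Z}]\Big).$$

`solve_psi0` finds the unique Ψ~0~ in [−300, +100] mV where the two
expressions agree, by bracketed root finding on their difference
(deterministic, residual below 10^−9^ C/m²; a failed bracket is an error,
never a silent result).

Two numerical choices deserve emphasis:

* **Concentrations, not activities, feed the electrostatics.** The Graham
  equation is derived for an electroneutral bulk. Free-ion concentrations
  satisfy $\sum c_i z_i = 0$ exactly (the speciation stage closes charge
  with Na^+^/Cl^−^, mirroring the counter-ions of the real salts), whereas
  Davies-corrected activities do not — divalent ions are discounted more
  than monovalent ones, which makes the radicand of the Graham equation go
  negative in a neighbourhood of Ψ~0~ = 0 and destroys the root there. The
  activity column is still what the BLM stage consumes; only the
  electrostatics run on concentrations.
* **The parameter set is calibrated, and labelled as such.** The site
  densities and binding constants of published plant-membrane work are not
  available to this package in transcribable form. We therefore fixed the
  structure (R^−^ and P^0^ sites; H^+^, Ca^2+^, Mg^2+^, K^+^, Na^+^
  binding; log K~H,R~ = 4.33 held at its literature value; Mg tied to Ca
  and K tied to Na; no proton binding to P) and calibrated the remaining
  six values by least squares against four published surface potentials:
  the plant test medium at 0.2 / 20 mM Ca^2+^ (−53.8 / −3.3 mV) and a
  0.342 M NaCl medium at 0 / 25 mM added Ca^2+^ (−13.7 / −0.4 mV). The
  frozen set (`default_membrane_params()`) reproduces all four anchors to
  better than 0.002 mV and is explicitly marked as a synthetic stand-in in
  its config file. Predictions far outside the calibrated composition
  range (exotic electrolytes, pH extremes) inherit no guarantee.

```{r psi0}
solve_psi0(speciate_medium(background_medium(ca_mM = 0.2)),
           default_membrane_params())
solve_psi0(speciate_medium(background_medium(ca_mM = 20)),
           default_membrane_params())
```

## The Ψ~0~ correction of EC50

Within one species, measured EC50 falls approximately linearly as Ψ~0~
rises toward zero; the package applies

$$\mathrm{EC50}_{site} = \mathrm{EC50}_{ini} + p\,(\Psi_{0,site} - \Psi_{0,ini}),$$

with the slope $p$ in µM/mV. Published slopes ship in
`psi_slope_registry()` (−0.615 µM/mV for barley, −0.003 for wheat; their
underlying per-calcium points were published only graphically, so the
slopes are consumed as constants, and `fit_psi0_slope()` exists for data
of your own). Dividing EC50 by the fit's y-intercept (its Ψ~0~ = 0 value)
removes the species-sensitivity scale; the published normalized slope
(−0.055 per mV) is common to both plant species, supporting the view that
the Ψ~0~ effect is physicochemical rather than species-specific
(`normalized_ec50()`). An affine correction can cross zero outside the
calibrated range; `psi0_adjust` floors the result at 1% of the initial
EC50 with a loud warning (or errors, if flooring is disabled). Both the
direct published slope and the normalized-slope route
(slope = −0.055 × intercept) are available to the user; the latter is an
extension for species without their own regression and is not used by any
default path.

## Speciation: scope and accuracy

The engine handles the species that matter for this model: H^+^/OH^−^, the
major cations, Cl^−^/NO~3~^−^/SO~4~^2−^, and the full arsenate and
phosphate protonation ladders. pKa sets are 25 °C critical-compilation
values (arsenate 2.24 / 6.76 / 11.60 — the second step being the model's
conditional value — and phosphate 2.148 / 7.198 / 12.35). Activity
corrections use the Davies equation (A = 0.509, b = 0.3); above
I = 0.5 mol/L a warning marks the validity edge. Ionic strength is
iterated on a fixed 2-cycle (totals → speciation → refined I →
re-speciation), which converges to well below the reporting precision for
these media. Deliberate omissions, each sub-percent at the compositions in
scope but real deviations from a full thermodynamic-database code: ion
pairs (CaHPO~4~^0^, CaSO~4~^0^, NaHAsO~4~^−^), the carbonate system, redox
(As(III)), and temperature corrections (assays run at 20 °C; constants are
25 °C values, consistent with the 0.00345 Graham coefficient). The MOPS
buffer is treated as chemically inert and excluded from ionic strength
(zwitterionic at pH 7). Against the published MINTEQ-based value of the
environmental modulator for the background medium (2.70 × 10^−5^ M) the
simplified engine lands within 1%.

## Dose–response stage

Relative root elongation is computed on treatment means,
$RRE = 100(\bar L_{f,t}-\bar L_{i,t})/(\bar L_{f,c}-\bar L_{i,c})$, and
fitted with the four-parameter sigmoid
$y = y_0 + a/(1+e^{-(x-x_0)/b})$ in $x = \ln$ HAsO~4~^2−^ activity.
Choices worth knowing:

* **EC50 is the 50%-of-control crossing** (y = 50 absolute), not the curve
  midpoint $x_0$; the two coincide for a full-range curve and the tests
  assert that reduction.
* **Initialisation is deterministic** (y~0~ = min y, a = range y,
  x~0~ = median x, |b| = range x / 6, sign from the data trend), so a
  given table always produces the same fit. Non-convergence and curves
  that never cross 50% are errors, not silent fallbacks.
* **Uncertainty** is a parametric bootstrap from the fit covariance
  (default 1000 draws, fixed seed 20220208). With 6 usable doses and 4
  parameters the fit has 2 residual df; confidence intervals should use
  the t quantile, and the test suite does.
* Fitting is done on per-treatment means, matching the RRE definition;
  per-seed weighting is a documented alternative we did not take.

## The synthetic-study generator

`simulate_study` emulates the hydroponic design itself: a calcium ladder
(0.2, 1, 5, 10, 20 mM) over the standard background medium, seven As(V)
doses (0, 0.5, 2, 10, 50, 200, 1000 µM), six seeds per treatment. For each
calcium level the *forward model of this package* supplies the truth: EM
from speciation, Ψ~0~ from the GCS solve, EC50 = IS × EM plus the linear
Ψ~0~ shift relative to the lowest-calcium medium. Expected RRE follows the
logistic curve (y~0~ = 0, a = 100, shape b = −0.5 on the ln-activity
axis — a transition width of about two natural-log units, typical of root
elongation assays); per-seed elongation adds Gaussian noise combining an
assay floor (default 5 RRE points, the spread typical of replicate
hydroponic tests) with growth variability proportional to the expected
elongation (control 55 ± 5 mm over the test period, initial roots
6 ± 0.5 mm), truncated at zero. A fixed seed makes the emitted CSVs
byte-identical.

Because generator and estimator share one forward model, parameter
recovery tests validate the *code path* — speciation, solver, fitting,
calibration algebra — not the biological adequacy of the model. Features
of real assays deliberately not emulated: hormesis at low doses,
between-beaker effects, non-Gaussian seed mortality, and measurement
rounding beyond 0.01 mm.

## Problem sizes and determinism

Everything in the default test suite is desk-scale: single speciations and
GCS solves are milliseconds, a full synthetic study is a fraction of a
second, and the largest routine analysis — 200 seeded replicate studies
for the recovery checks — runs in about a minute. All stochastic steps
(generator, bootstrap) take explicit seeds; all solvers are bracketed and
deterministic.

## Known limitations

* The membrane parameter set is a calibrated stand-in validated only at
  the four anchor compositions; treat Ψ~0~ outside pH ≈ 7 media or exotic
  electrolytes as extrapolation.
* The speciation engine is not a thermodynamic-database code; at high
  phosphate + calcium its ignored ion pairs will bias EM upward by a few
  percent.
* The Ψ~0~–EC50 relation is linear by construction and floored ad hoc
  outside its range.
* IS calibration inherits the full uncertainty of the single EC50 it is
  derived from; the package propagates no uncertainty through IS.
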