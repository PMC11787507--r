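---
title: "The triheme microstate model: thermodynamics, observables, and joint NMR/visible fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The triheme microstate model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triheme)
```

## The model

A triheme c-type cytochrome with one protonatable acid-base ("redox-Bohr")
center occupies one of 16 microstates: every subset of the hemes
{I, III, IV} may be oxidized, and the redox-Bohr center may be protonated or
deprotonated. A microstate is labelled `P` + the numeric aliases of its
oxidized hemes (1, 3, 4; `0` if none) + `H` if protonated — `P0H` is the
fully reduced protonated protein, `P134` the fully oxidized deprotonated one.
The microstates with the same number of oxidized hemes form an oxidation
stage, S0 to S3.

The free energy of a microstate relative to `P0H`, in meV, is additive over
interacting centers:

* one oxidation energy $g_i$ per oxidized heme — numerically the heme's
  reduction potential in mV vs SHE in the fully reduced, protonated protein
  (one electron per heme, so 1 mV corresponds to 1 meV);
* one redox interaction $I_{ij}$ per pair of simultaneously oxidized hemes —
  positive values mean oxidizing one heme raises the apparent potential
  requirement of the other, i.e. stabilizes its reduced form;
* if deprotonated, the deprotonation energy $g_H$ plus one redox-Bohr
  interaction $I_{iH}$ per oxidized heme — negative values mean deprotonation
  stabilizes the oxidized hemes.

Ten parameters therefore specify a protein. The Boltzmann log-weight of a
microstate at solution potential $E$ (mV vs SHE) and pH is

$$\ln w = \frac{n_\mathrm{ox} E - G}{k_B T} + d \, \ln(10)\,\mathrm{pH},$$

where $n_\mathrm{ox}$ is the stage, $d$ the deprotonation flag, and
$G$ the microstate energy above. Populations are the normalized weights over
the 16 states. The pH term is the proton chemical potential: at fixed
oxidation pattern the deprotonated/protonated ratio is
$10^{\mathrm{pH} - \mathrm{p}K_a}$ with
$\mathrm{p}K_a = (g_H + \sum_{i \in \mathrm{ox}} I_{iH}) / (k_B T \ln 10)$,
and for a lone non-interacting heme the oxidized/reduced ratio reduces to the
Nernst form $\exp((E - g_i)/k_B T)$.

The default temperature is 288.15 K (15 °C, the temperature of the
measurements), giving $k_B T = 24.83$ meV and $k_B T \ln 10 = 57.18$ meV.
Reproducing the published macroscopic pKa tables is insensitive to the exact
choice within a few kelvin; the temperature is nevertheless an explicit
parameter of every object.

## Observables

All derived quantities are exact functionals of the 16-state ensemble:

* **Heme oxidation curves** (`heme_oxidation_fraction()`,
  `oxidation_curves()`): the marginal probability each heme is oxidized vs
  potential, at fixed pH.
* **Stage-conditional fractions** (`stage_conditional_fraction()`): the
  probability a heme is oxidized given the stage. Within a stage every
  microstate shares $n_\mathrm{ox}$, so the potential cancels; the function
  deliberately takes no potential argument. These fractions close exactly:
  summed over the three hemes they equal the stage number.
* **Macroscopic stage pKa** (`stage_pka()`, `pka_table()`): the acid
  constants of a stage's members averaged with the Boltzmann weights of the
  protonated forms; identical to the pH at which the protonated and
  deprotonated stage populations balance (the test suite checks both routes
  against each other to 1e-9 pH units). The total redox-Bohr effect
  `delta_pka()` has the closed form $-\sum_i I_{iH} / (k_B T \ln 10)$.
* **Midpoint potentials** (`midpoint_potential()`): the potential at which a
  heme is half oxidized, by bisection to 0.01 mV on [-1000, 1000] mV. The
  published "apparent microscopic potential" insets are not defined
  operationally in the source material; this package deliberately defines the
  apparent potential as the 50%-oxidation point at the stated pH and makes no
  quantitative claim about the printed inset values or the potential
  "separation" figures, which admit several inequivalent definitions.
* **Deprotonated-form potentials** (`deprotonated_potentials()`):
  $g_i + I_{iH}$ per heme.
* **Dominant-microstate routes** (`dominant_microstate_route()`): the
  deduplicated sequence of globally most-populated microstates along a
  potential sweep at fixed pH. The grid must span full oxidation (total
  oxidized fraction below 1% at the start, above 99% at the end). Exact ties
  resolve toward the lower-stage microstate; this matters only for exactly
  degenerate synthetic parameter sets, never for the published ones.

## The two experimental channels

**Stage-resolved NMR shifts** (`predicted_shift()`). Intramolecular electron
exchange is fast on the chemical-shift time scale and intermolecular exchange
slow, so a partially oxidized sample shows one signal set per stage, each a
population average over the stage-restricted ensemble. A heme-methyl probe
contributes `delta_red` when its heme is reduced (protonation-independent —
the stage-0 signals do not move with pH) and `delta_ox_prot` or
`delta_ox_deprot` when oxidized, according to the protonation of the
redox-Bohr center. Distinct oxidized shifts for the two protonation forms are
required: the stage-3 signals do move with pH, which a purely
oxidation-proportional model cannot produce; their sigmoid in pH inflects at
the stage-3 pKa. Shifts of probes on reduced hemes are taken independent of
the oxidation of the neighboring hemes — the methyls chosen experimentally
point outward from the heme core — so extrinsic paramagnetic contributions
are neglected. No lineshape or exchange-kinetics modelling is attempted.

**Visible titration curves** (`predicted_reduced_fraction()`). The optical
reduced fraction integrates an alpha-band area to which the three hemes
contribute indistinguishably, so the model observable is one minus the mean
of the three marginal oxidation fractions. Uncertainties follow the
3%-of-signal rule (`visible_sigma()`), floored at a signal of 0.05: a pure
relative error gives fully oxidized points infinite weight, and the floor
(sigma 0.0015 at zero signal) keeps the weighting proper without materially
changing any fit.

## Simultaneous fitting

`simultaneous_fit()` minimizes the combined weighted sum of squares over NMR
records (inverse linewidth-derived variances) and visible records
(inverse 3%-rule variances). Free parameters: the ten thermodynamic energies
plus, per probe, the two oxidized-state shifts; the reduced-state shifts are
fixed by the stage-0 data and not fitted. There is no inter-dataset
rebalancing by default (`nmr_weight = 1`), since inverse-variance weighting
is already the maximum-likelihood weighting under the generator's noise
model; a multiplier is exposed for sensitivity analysis.

Identifiability: the NMR channel constrains only energy differences within
stages — adding a constant to all three oxidation energies (with the matching
shift of the potential scale) changes no NMR prediction. The absolute
potential scale comes entirely from the visible channel, and constructing an
NMR-only problem with free oxidation energies is an error by design.

The optimizer is Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with optional box bounds — the standard damped Gauss–Newton/trust-region
approach for a smooth 16-parameter problem. Convergence uses a relative cost
tolerance of 1e-12 and a parameter tolerance of 1e-10 with a 500-iteration
budget; non-convergence is flagged on the result, not thrown. The default
initialization places the oxidation energies at the half-reduction potential
of the visible curve, redox interactions at +20 meV, the deprotonation energy
at 500 meV, redox-Bohr interactions at −30 meV, and the oxidized shifts at
the observed stage-3 shifts at the pH extremes; this sits inside the basin of
attraction for all four published parameter regimes, which noiseless data
reproduce to machine precision. An all-zero initialization, by contrast, is
structurally hopeless for any smooth optimizer: with $g_H = 0$ the pKa lies
~6 units below the measured pH range, the protonated population is ~1e-6,
and the cost surface is flat in $g_H$ while oxidation and redox-Bohr energies
become gauge-degenerate — the fit stops with a singular-Jacobian error naming
the degenerate combination. `multi_start()` (first start unperturbed, further
starts Gaussian-perturbed, seeded) is provided for unfamiliar regimes.

Standard errors are asymptotic: $(J^\top J)^{-1}$ scaled by the reduced
chi-square, with $J$ a central-difference Jacobian at the optimum (relative
step 1e-4). On synthetic data at experimental noise they come out at a few
meV, the order of the published uncertainties; the match is in order of
magnitude only, since the original optimizer and weighting are unpublished.

## The synthetic-data generator

`generator_spec()` / `generate_nmr()` / `generate_visible()` emulate the
study design: three heme-methyl probes observed at stages 1–3 over pH 6.0–9.0
in 0.5 steps (63 records), and visible titrations at pH 7 and 8 over −250 to
+50 mV in 15 mV steps (42 records). Noise is independent Gaussian — 0.005 ppm
on shifts, 3%-of-signal on fractions (clipped to [0, 1]) — matching the
least-squares error model exactly. Every draw is seeded and reproducible;
`make_fixture_bundle()` writes a complete on-disk study (params, probes,
both CSVs, manifest with seed and truth) for recovery tests.

The probe truth shifts shipped in `synthetic_probes()` are synthetic:
reduced-state shifts near 3 ppm, oxidized-state shifts of 13–23 ppm and
protonation offsets of 0.3–0.5 ppm, on the scale typical of low-spin ferric
heme methyls. The measured shift tables are not publicly deposited, so
recovery studies demonstrate the estimator's behavior under the model's
assumptions — correctly specified forward model, independent Gaussian noise,
no baseline or referencing drift, no linewidth variation across pH, perfect
stage assignment — and not the idiosyncrasies of real spectra. Passing
recovery tests therefore validate the inference machinery, not the
experimental pipeline upstream of it.

## Numerical choices

* All ensemble computations run in log space with a log-sum-exp
  normalization; populations are overflow-free at least for |E| ≤ 1000 mV and
  pH 0–14 (tested to 1e-12 normalization error on that envelope).
* `stage_pka()` averages acid constants in a max-shifted log-space weighted
  mean rather than naively exponentiating energies.
* Bisection tolerances: 0.01 mV for midpoints; the stage-pKa
  population-balance cross-check uses `uniroot` at 1e-12.
* Display rounding is half-away-from-zero to one decimal for pKa tables and
  integer meV for energy matrices; machine outputs (CSV/JSON) always carry
  full precision and round-trip losslessly.
* Seeds: every stochastic routine takes an explicit seed (default 20241214);
  the NMR and visible noise streams are decoupled by a fixed offset.

## Problem sizes

The shipped tests run the full property suite on all four published
parameter sets (normalization, stage closure, detailed balance, Nernst
limits, monotone curves at 1 mV resolution), noiseless recovery on all four
fixtures, and a 20-replicate recovery study at experimental noise for
PpcA of *G. uraniireducens* — about 105 records and 16 free parameters per
fit, a second or less each. These sizes were chosen to exercise every
contract at full precision while keeping the suite quick to run during
development.

## Known limitations

* Fixed topology: exactly three hemes and one redox-Bohr center. The
  construction generalizes, but nothing beyond the 16-state case is tested.
* No enthalpy/entropy decomposition or temperature-dependence fitting.
* No Bayesian posterior; uncertainties are asymptotic and symmetric.
* Raw-spectrum processing (alpha-band integration, mediator corrections,
  EXSY peak assignment) is out of scope: datasets enter as already-reduced
  tables.
* The equal-optical-weight assumption of the visible model is untested
  against heme-specific extinction differences; a systematic violation would
  bias the absolute potential scale of all three oxidation energies
  together, the direction the NMR channel cannot correct.
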