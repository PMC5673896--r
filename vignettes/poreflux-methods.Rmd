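---
title: "poreflux: methods and design notes"
author: "poreflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poreflux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

# The experiment this package models

`poreflux` analyses laboratory soil-core rewetting experiments of the
kind used to study the Birch effect — the pulse of CO2 released when
dry soil is rewet — and its pore-scale chemical controls. The design it
targets is a full factorial: antecedent moisture (field moisture vs
laboratory drought) crossed with wetting direction (simulated
precipitation from above vs simulated groundwater rise from below),
measured on intact cores and repeated on the same cores after
homogenization (sieving and repacking, which removes physical carbon
protection). Core-scale CO2 and CH4 fluxes are monitored through
rewetting (200 min) and a 20-h post-wetting incubation; pore water is
then extracted at three suctions (1.5, 15 and 50 kPa), which by the
capillary law sample water held behind pore throats of roughly 200, 20
and 6 um, and characterized by negative-mode FT-ICR mass spectrometry.

The package implements the full analysis chain for such data plus a
synthetic-data generator with known ground truth, so that every stage
can be verified without access to instrument data.

# FT-ICR-MS processing

## Peak filtering and internal calibration

Peaks are retained when S/N strictly exceeds 7 (`filterSNR()`). Mass
calibration follows the standard internal-recalibration idea for
natural organic matter: homologous series whose members differ by
exactly one CH2 unit (14.0156500642 Da) are detected by chaining peaks
at a 3 ppm spacing tolerance (`detectHomologousSeries()`); members of
series of length three or more become calibration anchors. Anchors are
given provisional assignments restricted to CHO-only compositions at a
relaxed 3 ppm tolerance — CHO space is sparse enough that these are
essentially unambiguous — and the anchor mass errors are regressed on
m/z to fit a linear ppm correction `ppm(m) = a + b m`, with three
MAD-trimmed refits to reject stray anchors. The correction is applied
as `m' = m / (1 + ppm(m) 1e-6)`. If fewer than five anchors are found
the peak list is returned unchanged with a warning flag.

## Formula assignment

For each peak inside the open window 200 < m/z < 1200 the neutral mass
is `m/z + 1.00727646677` (deprotonated [M-H]- ions). An exhaustive
search over CHONSP compositions is performed within element bounds
C <= 70, H <= 140, O <= 40, N <= 4, S <= 2, P <= 2, with candidates
required to have |mass error| strictly below 1 ppm, C >= 1, H >= 1 and
an integer double-bond equivalent `DBE = C - H/2 + N/2 + P/2 + 1 >= 0`
(even-electron neutrals only). Monoisotopic masses are fixed constants
(C = 12 exactly, H = 1.00782503207, O = 15.9949146196,
N = 14.0030740048, S = 31.97207100, P = 30.97376163).

Elemental sanity bounds prune chemically implausible candidates:
0.2 <= H/C <= 3.1, O/C <= 2.5, N/C <= 1.3, S/C <= 0.8, P/C <= 0.3, a
combined heteroatom cap N+S+P <= 5, and a phosphate constraint
O >= 4P (organic phosphorus occurs as phosphate esters). These follow
the "golden rules" tradition of formula filtering. They matter
quantitatively: the sub-ppm search space contains sub-mDa isobaric
doublets built from heteroatom-rich substitutions (for example C5O6
versus H5N4S2P1 differs by ~0.3 mDa), and without the sanity bounds
such candidates frequently win on mass error alone.

Ties among surviving candidates are broken by smallest |error|, then
fewest heteroatoms (N+S+P), then lowest DBE — a parsimony heuristic in
the spirit of compound-identification pipelines, without their
network-based refinement step.

**Known limitation.** With zero mass error the planted formulas of the
synthetic generator are recovered exactly (100% in the test suite).
At a realistic sub-ppm random error (0.2 ppm SD), a minority of peaks
— mostly above m/z ~600 — lose the smallest-|error| tie-break to close
isobars, capping exact recovery near 85% and leaking counts between
compound classes beyond pure sampling error. Resolving these requires
homologous-network consistency arguments that are intentionally out of
scope here; the behaviour is asserted as a bounded property in the
test suite rather than hidden.

## Van Krevelen classification

Assigned formulas are classified by their O/C and H/C ratios into
eight boxes: lipids (0 < O/C <= 0.3, 1.5 <= H/C <= 2.5), unsaturated
hydrocarbons (0 <= O/C <= 0.125, 0.8 <= H/C < 2.5), proteins
(0.3 < O/C <= 0.55, 1.5 <= H/C <= 2.3), amino sugars
(0.55 < O/C <= 0.7, 1.5 <= H/C <= 2.2), carbohydrates
(0.7 < O/C <= 1.5, 1.5 <= H/C <= 2.5), lignin
(0.125 < O/C <= 0.65, 0.8 <= H/C < 1.5), tannins
(0.65 < O/C <= 1.1, 0.8 <= H/C < 1.5) and condensed hydrocarbons
(0 <= O/C <= 0.95, 0.2 <= H/C < 0.8). Open and closed interval ends
are honored exactly. Formulas outside all boxes are "unnamed" but
still count toward richness and the relative-abundance denominator.

The printed lipid and unsaturated-hydrocarbon ranges overlap for
O/C <= 0.125, 1.5 <= H/C < 2.5. No resolution rule is conventionally
stated, so the package resolves the overlap by precedence — the more
specific unsaturated-hydrocarbon box is evaluated first by default —
and records the precedence order in every run manifest. A grid scan in
the test suite verifies this is the only overlap and that every
(O/C, H/C) point receives exactly one label.

Relative abundances are count-based (each assigned formula counts
once, intensities ignored), normalized by the total number of
assignments including unnamed, so the nine fractions sum to one.
Richness defaults to the number of *assigned* peaks; the number of
detected peaks is available from the unfiltered `PeakList` if the
alternative convention is wanted.

# Chamber fluxes and cumulative emissions

Fluxes follow the ideal-gas closed-chamber equation

$$A = \frac{dC}{dt} \cdot \frac{V}{M} \cdot \frac{P_a}{R\,T}$$

with A in umol (g soil)^-1 s^-1, dC/dt the OLS slope of the gas mole
fraction against time, V the chamber volume (cm^3), M dry soil mass
(g), Pa pressure (kPa), T temperature (K) and R = 8.3e3 cm^3 kPa
mol^-1 K^-1. As written the right-hand side yields mol g^-1 s^-1; a
single factor of 1e6 converts to umol. Negative slopes (uptake) are
preserved.

Slopes are fitted in contiguous windows — 5 min during rewetting,
30 min post-wetting by default. No windowing convention is universal;
these widths resolve a pulse with a decay constant of hours while
averaging over instrument noise, and both are configurable. Cumulative
emissions integrate the windowed flux series by the trapezoid rule
(ends padded with the first/last window mean), times soil mass, times
12.011 ug C per umol C; CO2-C is reported in mg and CH4-C in ug per
core. Refining the sampling grid changes the result by well under
0.1% for smooth profiles (verified in the tests). The package
integrates discrete flux estimates rather than differencing raw
concentrations end-to-end; for a noiseless closed chamber the two
agree to the quadrature error.

Pore-water suction maps to the largest water-filled pore-throat
diameter by the capillary law `d = 4 sigma cos(theta) / P` with
sigma = 0.072 N m^-1 and theta = 0: 1.5, 15 and 50 kPa give 192, 19.2
and 5.76 um, i.e. the nominal ~200, 20 and 6 um after rounding to one
significant figure (`nominalDiameter()`).

# The synthetic-data generator

The generator is first-class, tested code. Its defaults encode the
study conditions of the emulated experiment:

* **Design**: 16 cores, 4 per moisture x wetting cell, each measured
  intact then homogenized (paired, same `core_id`), pore water at
  1.5/15/50 kPa — 96 peak lists and 32 gas series.
* **Formula library** (`genFormulaLibrary()`): rejection-sampled
  CHONSP formulas strictly inside each class region (the lipid region
  starts above O/C = 0.125 so labels survive the precedence rule),
  neutral mass in (201, 1199) Da, integer DBE >= 0, element bounds
  C 4-70, H 4-140, O 0-40, N 0-4, S 0-2, P 0-2. Each accepted formula
  is extended into a CH2 homologous series (up to 8 members) — both
  because real organic-matter spectra are dominated by such series and
  because the calibration stage needs them. The "unnamed" region is
  placed at O/C 1.15-1.45, H/C 0.85-1.45, outside all eight boxes.
* **Peak lists** (`genPeakList()`): [M-H]- positions with Gaussian
  ppm error (0.2 ppm SD by default, emulating sub-ppm instrument
  accuracy), optional linear miscalibration `ppm(m) = a + b m`
  removable by `calibrateInternal()`, signal S/N > 7.5, and a
  configurable fraction of noise peaks with S/N in [1, 7] so the S/N
  filter is genuinely exercised.
* **Gas series** (`genConcentrationSeries()`): the flux equation is
  inverted exactly; the stock Birch pulse is
  `A(t) = baseline + amplitude exp(-t/tau)` (tau = 4 h by default),
  the simplest shape matching observed rewetting pulses, with
  `calibrateBirchAmplitude()` pinning the time-integral to a target
  emission. Cell means default to published treatment means (e.g.
  intact drought+precipitation 245.1 mg CO2-C), with 20% lognormal
  between-core variation.
* **Class mixtures** (`defaultClassMixture()`): fine-pore water is
  enriched in lignin and tannins, coarse-pore water in lipid-like,
  unsaturated-hydrocarbon and unnamed signal; drought depletes lipids
  (x0.6) and enriches lignin (x1.15) and tannins (x1.3); drought,
  homogenization and groundwater rise raise richness by 10/10/5%.
  The emulated experiment reports directions and significance for
  these effects, not magnitudes, so the magnitudes are free
  parameters chosen once to be plainly detectable at the design's n;
  they are recorded in every run manifest.

What the generator does **not** emulate: ionization efficiency,
isotopologues, instrument transients, water-vapor or leak corrections,
3D pore networks or water movement. Passing tests therefore
demonstrate the correctness of the processing chain, not instrument
realism.

# Inference layer

* **PCA** (`pcaProfiles()`): on centered, unit-variance class
  fractions; reported "loading correlations" are Pearson correlations
  (in percent) between each variable and the axis scores; axis signs
  are fixed so the largest-|correlation| variable is positive.
* **Mixed models** (`fitLMM()`): REML random-intercept-per-core
  models via `lme4`/`lmerTest`, marginal (type III) F tests.
  Denominator df use the Satterthwaite approximation by default
  (Kenward-Roger available); the containment method of some
  commercial packages is not implemented in the available stack, and
  the method used is recorded in the fit. One-observation-per-core
  layouts are permitted; the core variance then estimates at the
  boundary and the F tests reduce to fixed-effects ANOVA (the test
  suite verifies the interaction test holds its nominal size there).
* **Transformations**: `log` (with a recorded offset, half the
  smallest positive value, when zeros occur — applied only on
  explicit request) and `reciprocal_log`, implemented as
  `1/log(y + c)` with c chosen so every log argument exceeds 1 and
  recorded; the name alone does not pin down a formula, so the
  constant is always surfaced rather than guessed silently.
* **LSD letters** (`lsdGroups()`): cell means from `emmeans`, all
  pairwise t tests at alpha = 0.05 with no multiplicity adjustment
  (classical protected-LSD convention; raw P-values are the
  convention in this literature and this is noted in output), letters
  by insert-and-absorb, verified against an all-pairs oracle.
* **Ratios** (`ratioTable()`): the four conventional treatment
  contrasts at two significant figures.
* Per-fraction models are separate fits on suction subsets; no
  multiple-testing correction is applied, matching field convention.

# Numerical choices and degenerate inputs

Strict inequalities follow the printed conventions (S/N > 7,
|error| < 1 ppm, open m/z window). Duplicate m/z values, non-finite
or nonpositive masses/volumes/temperatures, empty assignment sets,
zero-variance responses, degenerate slope windows and aliased fixed
effects all raise immediate, named errors rather than propagating.
Random draws are seeded explicitly everywhere; two runs with the same
seed are byte-identical.

# Problem sizes used in the packaged checks

The test suite and the acceptance script run on deliberately modest
sizes chosen to exercise every code path with comfortable margins:
200-300-peak samples for assignment and mixture recovery, a
0.005-step grid scan of the classification plane, 60-s gas sampling
over the full 1400-min incubation, and 200-400 simulated experiments
at the design's n = 16 for the size and power of the interaction F
test. These sizes are the package's own choices and can be scaled up
freely.

# Known limitations

* Isobaric collisions at sub-ppm random error (discussed above).
* The flux chain assumes a sealed, unvented chamber; headspace
  concentrations therefore grow without bound for sustained fluxes,
  which is mathematically consistent but not a physical chamber
  protocol over 20 h.
* No attempt is made to reproduce measured P-values or means of any
  particular field dataset; the statistical layer is validated by
  parameter recovery, size and power on synthetic data, and by ratio
  arithmetic on published summary tables used as inputs.
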