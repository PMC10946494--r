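---
title: "Mapping and predicting 1H NMR chemical shifts in serum and plasma"
author: "shiftmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and predicting 1H NMR chemical shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftmap)
```

## The problem

In 1D ^1^H NMR profiling of blood serum and plasma, the resonance position
(chemical shift, $\delta$, in ppm) of a metabolite signal is not fixed:
pH, ionic composition, and protein binding — collectively "matrix
effects" — move signals over ranges commonly up to ~0.05 ppm, i.e. about
50 linewidths ($\Delta\nu_{1/2} \approx 0.001$ ppm at 600 MHz). This
variability is the main obstacle to fully automated metabolite
identification: database matching over a wide search window is slow and
prone to mis-assignment, especially for singlets that carry no J-coupling
constraint.

The premise of this package is that chemically homologous protons (methyl
protons of aliphatic amino acids, aliphatic protons of small carboxylic
acids, ...) experience *similar* matrix effects, so their shifts across
samples are very close to linearly related. If that holds, knowing where
one well-recognised anchor signal sits in a given spectrum pins down where
everything else must be.

## The model

For every ordered pair of spin systems (a *response* $y$ and a *predictor*
$x$) the package fits, on pairwise-complete samples, the ordinary
least-squares model

$$ y = a\,x + b, $$

and records $R^2$, the RMSE (here $\sqrt{SS_{res}/n}$), the relative RMSE

$$ \mathrm{rRMSE} = 100 \cdot \frac{\mathrm{RMSE}}{|\bar y|}\ (\%), $$

the maximum absolute training residual (an error envelope in ppm), and the
classical slope standard error. With $k$ spin systems and sufficient
co-detection this gives $k(k-1)$ models — 240 for the 16-system
serum/plasma panel shipped with the package.

Two definitional choices are not forced by convention and are therefore
configurable and worth stating:

* **rRMSE denominator.** rRMSE is RMSE relative to the mean observed
  response shift. An RMSE of $10^{-4}$ ppm on a signal near 1 ppm thus
  reads as 0.01%. (On mean-centered data this quantity is meaningless and
  reported as `NA`; weight maps by RMSE instead.)
* **RMSE denominator.** $n$ by default, $n-2$ via `rmseDenom = "df"`.

Pairs co-detected in fewer than `minN` samples (default 50) are flagged
*unstable*: with, say, an ethanol analogue detected in ~17% of spectra and
a sparse 3-hydroxybutyrate, their mutual models rest on a few dozen points
and are excluded from predictor selection and map construction (while
still being recorded).

## From models to a prediction map

A *prediction map* is a spanning arborescence over the spin systems: a
rooted directed tree in which every non-root system has exactly one
incoming model edge and is reachable from the root anchor. Two
constructions are provided:

* `publishedMap()` — the fixed literature topology for the 16-system
  panel: the valine methyl doublet anchors the amino acids (alanine,
  leucine, isoleucine, tyrosine, glycine directly; phenylalanine via
  tyrosine; histidine via glycine); leucine bridges to lactate, which
  anchors the carboxylic acids and the glucose anomeric doublet; leucine
  also predicts ethanol, which predicts acetone; pyruvate carries an
  *alternate* edge to acetone for spectra without ethanol. It predicts 15
  systems from one anchor.
* `buildMap()` — the minimum-total-weight spanning arborescence
  (Chu–Liu/Edmonds cycle contraction) over the stable, usable models, with
  |rRMSE| (or RMSE) as edge weight. Ties are broken by lower weight, then
  higher $R^2$, then lexicographic (predictor, response), so construction
  is deterministic. `classGuided = TRUE` restricts candidate edges to
  same-class pairs plus designated bridge predictors, reproducing the
  sub-map-then-join strategy a spectroscopist would follow.

The literature map was assembled manually, guided by chemistry; the
algorithmic builder makes that step reproducible and applicable to new
panels. On data satisfying the model's assumptions the built tree is never
heavier than the fixed topology bound to the same models (a property the
test suite checks), but the fixed topology remains available because its
edges are chemically interpretable.

`bindMap()` attaches fitted coefficients to a topology and computes two
chained error estimates per node from the training metrics: a quadrature
estimate $\sqrt{\sum_{\text{path}} \mathrm{RMSE}^2}$ and a conservative
envelope $\sum_{\text{path}} \max|\text{resid}|$. The envelope is what
`ShiftPredictions` exposes per system; both are in `chainErrors()`.

## Prediction modes

* **Semi-automated** (`predictSemi`): each response is predicted from its
  predictor's *observed* shift in that sample. If the primary predictor
  signal is absent, the alternate edge is tried (this fallback is this
  package's extension of the manual procedure; `useAlternates = FALSE`
  restores the strict behaviour); otherwise the value is `unavailable`.
* **Automated** (`predictAuto`): only the anchor's observed shift is
  needed; the map is traversed in topological order and each node uses its
  parent's *predicted* value, so a depth-$d$ node is a composition of $d$
  affine maps. At zero residual noise this is exactly the semi-automated
  result; empirically the two agree closely at realistic noise because the
  single-edge errors are a fraction of a linewidth.

Predictions are quantized at 4 decimals of ppm, matching the recording
convention; `digits = NULL` exposes the unrounded compositions.
Predictions are *not* clamped to the training shift range; extrapolation
is the user's responsibility (validation reports make it visible).
Validation (`validatePredictions`) reports per-system maximum absolute
error and RMSE in ppm and in linewidth units (error / `linewidthPpm`,
default 0.001 ppm at 600 MHz; rescale for other fields).

## The synthetic-data generator

Testing every stage without downloading cohort data requires a generator
that encodes exactly the assumption the method rests on. A
`SyntheticShiftSpec` draws, per sample $j$, standard-normal latent factor
values $f_{jf}$ and sets

$$ \delta_{ij} = \mu_i + \sum_f L_{if} f_{jf} + \epsilon_{ij}, \qquad
   \epsilon_{ij} \sim N(0, \sigma_i^2), $$

keeps each value with probability `detectProb`$_i$, and rounds to 4
decimals *after* noise, so the ~$2.9\times10^{-5}$ ppm quantization error
of 4-decimal recording is part of the simulated measurement.

`serumPanelSpec()` instantiates the 16-system panel with values chosen
once to match the study conditions the method targets:

* global matrix-effect sensitivities of 0.0060–0.0083 ppm per unit factor,
  so per-system ranges over ~940 spectra are ~0.05 ppm;
* class factors of 0.0003 ppm (amino acids; carboxylic acids + glucose;
  ethanol + acetone), making within-class correlations tightest while
  cross-class correlations stay high, as observed in serum;
* residual noise $\sigma_i = 10^{-4}$ ppm, putting single-edge RMSE at
  ~$10^{-4}$ ppm (~0.1 linewidth);
* a private 0.0010 ppm factor for the histidine imidazole proton, whose
  shift is dominated by pH: its best attainable $R^2$ drops to ~0.97,
  emulating the panel's known outlier while keeping within-class
  $R^2 \ge 0.96$ with sampling margin at $n = 940$;
* detection probability 1 except ethanol (157/940, its typical serum
  prevalence as a mostly exogenous metabolite) and 3-hydroxybutyrate
  (0.25), so that pair's co-detection (~39 spectra) falls below the
  stability threshold.

What the generator deliberately does **not** emulate: the irregular,
sometimes multimodal shape of real shift distributions (linear-model
behaviour depends only on second moments, so Gaussian factors suffice for
calibration, but heavy tails in real data can push maximum errors beyond
Gaussian envelopes); nonlinearity of shift–pH response outside the
observed ~0.05 ppm windows; and between-cohort differences in sample
preparation. Green tests on synthetic data therefore demonstrate
correctness of the machinery and calibration under the stated model, not
performance on any particular spectrometer's output.

`recoveryReport()` closes the loop: fitted slopes are compared with the
population slopes $\mathrm{cov}(x,y)/\mathrm{var}(x)$ implied by the
loadings; under the generative model the OLS fit is correctly specified,
so ~95% of z-scores within ±2 is the expected calibration. Note that the
slope estimates within one simulated cohort share the same factor draws
and are strongly correlated, so the |z| ≤ 2 fraction should be judged
pooled over several seeds, not per cohort.

## Spectrum handling

The `spectra_io` layer is intentionally minimal — enough to go from a 1D
trace to table entries:

* `readSpectrum()` reads two-column text and JCAMP-DX `(X++(Y..Y))`
  blocks in AFFN/fixed form. Packed SQZ/DIF tables and vendor raw
  directories are out of scope; convert with standard tools first.
* `calibrate()` applies the rigid shift that places a reference signal
  (glucose anomeric doublet at 5.2410 ppm, or TMSP at 0) at its target;
  shifts over 0.5 ppm are applied but flagged as suspicious.
* `pickPeaks()` reports local maxima whose topographic prominence exceeds
  a fraction of the *window* maximum (so crowded aliphatic and sparse
  aromatic regions can share one threshold), at the axis position of the
  sampled maximum, quantized to 4 decimals. At >65k points over ~20 ppm
  the grid spacing (~3×10^-4 ppm) already locates maxima below the third
  decimal; an optional 3-point parabolic refinement exists but defaults
  off to keep the recorded value an observed axis point.
* `multipletCenter()` records a multiplet at the arithmetic mean of its
  component positions. Overlap resolution via J-coupling arithmetic is not
  automated: the caller supplies the visible components.

## Numerical conventions and degenerate inputs

* Ingest rounding is IEEE half-to-even at `precision` decimals (default
  4); write/read round trips are bit-identical at that precision.
* Mean-centering (`centerColumns`) is exact to 1e-12 ppm, idempotent, and
  leaves missingness untouched; variance scaling is available but off by
  default, matching the usual display convention for shift distributions.
* A constant predictor is a degenerate design (error); a constant response
  leaves $R^2$ undefined and the model unusable. Pairs with fewer than 2
  complete observations are absent; with 2 ≤ n < `minN`, present but
  unstable.
* Arborescence tie-breaking is fully specified (see above); identical
  inputs give identical maps and, through the command-line layer,
  byte-identical artifacts.

## Problem sizes used in the checks

The package's own test battery runs at the scale the method is meant for:
pairwise fitting and map construction on simulated cohorts of 940 training
and 1,052 held-out spectra over the 16-system panel, repeated over ten
seeds for the calibration checks (slope recovery, within-class
correlation, depth-1 error envelopes ≤ 1.5 linewidths), with exhaustive
enumeration oracles at small sizes (≤ 6-node arborescences, brute-force
local-maxima scans, normal-equation OLS) pinning down the algorithms.
`scripts/acceptance.R` reruns the full pipeline at these sizes and writes
the headline numbers as JSON.

## Known limitations

* Linear shift–shift relationships are an approximation valid over the
  observed ranges; behaviour outside them is untested here.
* The shipped registry's nominal positions are standard values for pH 7.4
  phosphate-buffered serum/plasma at 600 MHz; other matrices or SOPs
  need their own training tables (the registry's formate entry records a
  known group-label discrepancy in the source literature: it is treated
  as a one-proton CH singlet).
* Real-cohort accuracy claims require real assigned cohorts;
  `validateOnCohort()` is the entry point for applying a bound map to any
  external assigned-shift table.
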