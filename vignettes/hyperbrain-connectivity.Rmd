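---
title: "Hyperbrain connectivity from lagged phase synchronization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbrain connectivity from lagged phase synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hyperlps)
```

This vignette is the package's account of its science: the estimator it
implements, the synthetic data it validates itself on, the numerical
choices behind both, and what the passing test suite does and does not
establish about real recordings.

## 1. The analysis problem

Dyadic EEG hyperscanning records two interacting people simultaneously.
After source reconstruction, each brain is represented by 26 cortical
ROIs (13 labels × 2 hemispheres), each carrying a three-dimensional
current-density time series at 1024 Hz. The analysis asks how
functional networks — within each brain, between the brains, and over
the joint 52-node *hyperbrain* — differ between solo and paired
performance and between dyads of similar and dissimilar skill.

Trials of at least 20 s are trimmed to their central 10 s (equal amounts
removed from both ends), which discards the unsteady start and finish of
each performance.

## 2. Lagged phase synchronization

### The estimator

Each trimmed trial is segmented into 2 s windows stepped by 1 s — nine
windows covering the trial exactly. Each window and ROI yields a complex
3-vector per 0.5 Hz frequency bin; dividing by its Euclidean norm leaves
phase information only. Averaging outer products across segments gives,
for every ROI pair at every bin, a 6×6 Hermitian block covariance
$S = \begin{pmatrix} S_{xx} & S_{xy} \\ S_{yx} & S_{yy}\end{pmatrix}$
with unit-trace auto blocks. The dependence decomposition is
determinant-based:

$$F_{tot} = \ln\frac{\det S_{xx}\,\det S_{yy}}{\det S},\qquad
  F_{inst} = \ln\frac{\det \mathrm{Re}(S_{xx})\,\det \mathrm{Re}(S_{yy})}
  {\det \mathrm{Re}(S)},$$

with the lagged component $F_{tot} - F_{inst}$ mapped to $[0,1]$ as
$1 - e^{-F}$ (for one-dimensional series this map recovers squared
coherence). Instantaneous dependence — real-valued coherency, the
signature of volume conduction, which spreads activity through tissue
with no measurable delay — is computed from the real part of $S$ and
subtracted; genuinely time-lagged interaction survives. The same
estimator is applied verbatim to intra-brain and inter-brain pairs, so a
single threshold can compare them. Note one consequence of the
definition: coupling at exactly half a cycle (phase difference π) is
also purely real and is therefore assigned to the instantaneous
component; "lagged" means *quadrature* dependence.

Per-bin lagged values are averaged over the 8 bins of the alpha band
(8.5–12 Hz inclusive) and the *mean* is then clipped to $[0,1]$.
Clipping per bin before averaging would fold sampling noise upward and
bias the null positively.

### Small-sample behavior, ridge and jackknife

Nine segments are few relative to a 6×6 complex covariance, and the
dipolar sources make the 3×3 blocks nearly rank-1, so naive plug-in
log-determinants are dominated by noise in the small eigenvalues: the
naive estimator's null mean exceeds 0.6 and is useless. Two numerical
choices fix this:

* **Ridge** — every matrix receives `ridge × mean(diag)` on its
  diagonal before eigendecomposition; default `ridge = 0.005`. This is
  deliberately larger than a pure conditioning guard: it floors the
  noise eigenvalues at a common level in the total and instantaneous
  terms so their contributions cancel. It is configurable, and the
  total/instantaneous components are exposed for diagnostics.
* **Jackknife** — leave-one-segment-out debiasing,
  $F^{jack} = nF - (n-1)\overline{F_{loo}}$, removes the remaining
  first-order bias of both F terms.

With both (package defaults), measured on the simulator at the study's
own geometry (26 dipolar ROIs, 9 segments, band average): independent
sources give mean LPS ≈ 0.03, strength-0.9 quarter-cycle coupling ≈
0.65, and pure zero-lag mixing ≈ 0.03 lagged against ≈ 1.0 total. The
compiled (RcppArmadillo) and plain-R code paths implement the identical
computation and are cross-checked in the tests.

Degenerate inputs: an all-zero window cannot be phase-normalized; its
bins are flagged and excluded from the segment average, and a bin with
fewer than two valid segments is an error.

## 3. Binarization

All informative LPS values of a trial — 325 for a single brain, all
1326 jointly for a hyperbrain matrix — form one value set; the threshold
is `median + MAD` with the MAD unscaled (no 1.4826 normal-consistency
factor), and ties at the threshold become edges. Thresholding is
per-trial by default (each trial's matrix is binarized on its own value
set, consistent with per-trial matrices being averaged later); a pooled
mode accepting an externally computed threshold exists for sensitivity
analyses. Self-connections are stored on the diagonal but excluded from
every count, threshold set and measure: the graph theory operates on
simple graphs.

## 4. Graph measures and surrogate normalization

`L` is the mean shortest-path length over *reachable* pairs —
thresholded networks can fragment, and excluding unreachable pairs keeps
the normalization finite (the choice is documented rather than silently
assumed). `C_raw` is the mean local clustering coefficient with
degree-<2 nodes contributing 0.

Normalization compares each network with 100 random and 100 lattice
surrogates produced by degree-preserving double-edge swaps (10 attempts
per edge): every surrogate preserves the degree sequence exactly, and on
hyperbrain input the intra-J1, intra-J2 and inter edge classes rewire
only within themselves, preserving the intra- and inter-brain degree
sequences separately. Latticization accepts a swap only when it does not
increase ring-lattice cost (ring distance within a brain's own ordering;
band offset for inter edges) — a single global ring would be ill-defined
under the block constraint. Ensemble summaries use the mean over
surrogates.

Two normalization conventions are implemented; the default is the ratio
form

$$G = L_{rand}/L, \qquad C = C_{raw}/C_{latt},$$

so G reads "as efficient as random" and C reads "as clustered as
lattice", with an interpolation form
($ (L_{latt}-L)/(L_{latt}-L_{rand}) $, analogously for C) selectable.
Both are clipped to $[0,1]$ — excursions occur in very sparse or dense
networks. `SWI = G × C` is 1 only when both small-world characteristics
are jointly maximal. Density uses the exact denominators 325 (26 nodes)
and 1326 (52 nodes). IIR divides total intra-brain edges by inter-brain
edges; with zero inter-brain edges it is returned as flagged-missing
rather than infinite so aggregation can skip it.

The calibration of this machinery is checked against brute-force
path/triangle counting on random graphs, and against the canonical
ordering experiment: ring-lattice, Watts–Strogatz (n = 100, k = 4,
p = 0.1) and density-matched random graphs, where the Watts–Strogatz
networks score SWI ≈ 0.83 against ≈ 0.36 (random) and ≈ 0.28 (lattice).

## 5. Asymmetry indices

All four indices are edge-count ratios $(A-B)/(A+B) \in [-1, 1]$.
Intra-brain lateralization counts edges lying entirely within the right
vs entirely within the left hemisphere; inter-hemispheric edges belong
to neither class and are excluded from numerator and denominator (a
50/50 split option exists for sensitivity analysis). Regional asymmetry
does the same for fronto-limbic vs occipito-parietal edges. Inter-brain
variants classify each inter-brain edge by the hemisphere (or region
class) of its endpoint in the chosen brain. Zero classified edges yield
0 with an explicit flag, keeping session aggregation total.

The fronto-limbic map {SPFC, OFC, APFC, LPFC, ACC, INS, PHG} vs
occipito-parietal {SPL, IPC, PVC, FUS, PCC, SMA} is shipped as a JSON
config, not a constant: the assignment of SMA (a sensorimotor label),
PCC, PHG and INS is a defensible judgment call, not an established fact,
so it is overridable. SMA and PCC are grouped with the parietal class by
anatomical position; PHG and INS with the limbic class.

## 6. Session-level statistics

The session is the experimental unit (seven sessions; the individual who
appears in two sessions is treated as independent across them, matching
the design's degrees of freedom). Split-plot ANOVAs take condition
(SOLO/PAIRED) and skill (less/more experienced, J1 vs J2) as 2-level
within-session factors and dyad matching (experience gap ≤ 3 years) as
the between-session factor; with 2-level within factors sphericity holds
trivially. Partial η² is $F\,df_1/(F\,df_1+df_2)$; observed power uses
the fixed-effects post-hoc convention λ = F·df1 on the noncentral F —
the convention was validated by back-computing all four published
effect-size/power pairs from their F values. Follow-up paired t tests
are Bonferroni-multiplied and capped at 1; hyperbrain measures get
independent equal-variance t tests between dyad groups. A 2000-rep
null simulation of the full 2×2×(3-vs-4) design rejects each effect at
5.0% ± 1% at α = 0.05, and the single-within-factor reduction satisfies
F = t² to 10⁻¹⁰.

Constant-response cells (possible after heavy clipping of G or C) would
make aov return 0/0; the package reports F = 0, p = 1 for effects whose
sum of squares is numerically zero.

## 7. The synthetic dyad generator

The generator is an explicit stand-in — no claim is made that it models
juggling EEG — but it reproduces the features that matter to the
estimator:

* latent ROI oscillators are **narrowband-filtered Gaussian noise**
  (brick-wall 8.5–12 Hz), not sinusoids, so phase diffuses and LPS
  estimates have realistic variance;
* planted coupling follows a generative forest: each coupled node is a
  strength-weighted copy of its single parent delayed by the edge lag
  plus an independent innovation scaled by $\sqrt{1-s^2}$ (unit
  variance preserved); lags are integer sample shifts (rounding is
  warned about), and filtering is circular so shifts are exact;
* each ROI's 3D moment is a fixed random unit orientation times its
  latent signal plus isotropic broadband noise (`noise_sd = 0.1` of the
  latent SD by default — high-SNR source estimates);
* orientations are drawn once per session seed; trial content derives
  from a per-trial stream, so any trial regenerates independently and
  bit-identically;
* zero-lag mixing replaces each ROI by
  $(1-m)\,x_i + m\,\langle x_{j\ne i}\rangle$ (the leaked average
  rescaled to the ROI's own RMS), strictly within one brain — the
  volume-conduction confound with no lagged content.

What it does **not** emulate: scalp mixing followed by an inverse
solution, non-stationarity, artifacts, 1/f background, or realistic
anatomy of coupling. Passing tests therefore demonstrate that the
pipeline's mathematics is correct and its detection behavior is as
designed under its stated assumptions — not that any real dataset would
yield the published group effects.

### Scenario parameters (fixed, with rationale)

* **Volume-conduction check**: mixing 0.7, no coupling. At this level
  the zero-lag shared variance clearly dominates the private signal
  (expected zero-lag coherence² ≈ 0.7), a deliberately severe leakage
  regime; the measured outcome is total synchronization ≈ 1.0 with mean
  lagged LPS ≈ 0.07 over 20 trials.
* **Recovery check**: a two-phase "traveling rhythm" — one reference
  oscillator copied by every node at strength 0.9, either in phase or a
  quarter cycle (0.025 s) later. Cross-group pairs are genuinely lagged;
  within-group pairs are zero-lag coupled and *should* be invisible.
  The split (38 in-phase / 14 shifted of 52) puts lagged pairs at ~40%
  of the 1326: the mixture median then falls inside the zero-lag
  population and the MAD matches that population's deviation scale, so
  the median+MAD threshold lands in the gap between the populations.
  (At a ~50% split the median sits at the boundary, both populations
  deviate strongly from it, and the threshold climbs into the coupled
  cluster — a thresholding artifact, not an estimator failure.)
  Measured: precision ≈ 0.98, recall ≈ 0.99 over 10 trials.
* **Study simulation**: `simulate_study()` uses a three-group phase
  stagger (1/64 s steps — 16 samples exactly) interleaved across both
  brains, so intra- and inter-brain blocks are all populated and the
  resulting networks contain triangles (a two-group stagger is
  bipartite and has zero clustering by construction).

## 8. Problem sizes and formats

The shipped tests and the acceptance script use 10–20 s trials, 10–20
trials per stochastic check, 12–100 surrogates per ensemble depending on
the check, 2000 ANOVA null replications, and a 7-session end-to-end
study with 2 trials per condition and 50 surrogates; these sizes give
stable estimates for every property tested while keeping a full run in
the minutes range. Trials are stored as plain CSV with a JSON metadata
sidecar (one file per trial); matrices as labeled CSV; networks
optionally as GraphML; statistics as CSV/JSON with the run
configuration serialized alongside.

## 9. Known limitations

* The exact multivariate variant behind the published connectivity
  values is not fully specified by its description; this package fixes
  one member of the determinant-based family (with the ridge/jackknife
  estimator above) and documents it. Absolute LPS levels are therefore
  convention-dependent; comparisons across conditions within this
  package are not.
* The stated segment overlap ("2 s windows, 0.5 s overlap") and segment
  count (nine per 10 s trial) are mutually inconsistent; the package
  fixes the segment count, which the averaging step depends on, and
  makes the step configurable (default 1 s).
* π-phase coupling is classified as instantaneous by construction (see
  §2); a study in which half-cycle delays are meaningful needs a
  different measure.
* Whether thresholding was applied per trial or per pooled condition is
  ambiguous; per-trial is the default, pooled mode exists.
* Session-level ANOVAs on 7 sessions have little power; the package
  reports observed power precisely so that null results are read with
  that in mind.
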