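# hyperlps

Source-level functional connectivity analysis for dyadic EEG
hyperscanning — two people recorded simultaneously while performing an
interactive motor task — with the emphasis on *hyperbrain* networks:
graphs whose 52 nodes span the 26 cortical regions of interest (ROIs) of
both participants, containing intra-brain and inter-brain edges.

The package is written for researchers who have source-reconstructed EEG
(three-dimensional current-density time series per ROI) and want to go
from per-trial time series to session-level statistics, and for method
developers who need a fully synthetic, seeded test bed with known
coupling ground truth.

## What it computes

**Lagged phase synchronization (LPS).** For each 10 s trial, each ROI's
3D current densities are cut into nine 2 s segments, Fourier-transformed
at 0.5 Hz resolution, and phase-normalized (the complex 3-vector at each
frequency is scaled to unit norm, discarding amplitude). From the
segment-averaged 6×6 Hermitian covariance *S* of an ROI pair the package
computes the determinant-based dependence measures

F_total = ln det(S_xx) + ln det(S_yy) − ln det(S),
F_inst = the same expression on Re(S),
lagged = 1 − exp(−(F_total − F_inst)),

averaged over the alpha band (8.5–12 Hz, 8 bins). The instantaneous
(zero-lag, purely real-coherency) component — the part that volume
conduction inflates — is subtracted; what remains is dependence at
nonzero lag. A leave-one-segment-out jackknife removes the small-sample
bias of the log-determinants.

**Networks.** Each trial's 325 intra-brain (or 1326 hyperbrain) LPS
values are binarized at the threshold *median + MAD* (unscaled), giving
binary adjacency matrices with intra-J1 / intra-J2 / inter blocks.

**Graph measures.** Characteristic path length L and mean clustering
C_raw, normalized against 100 degree-preserving random and lattice
surrogate networks (block-restricted rewiring preserves intra- and
inter-brain degree sequences separately): global efficiency
G = L_rand/L, normalized clustering C = C_raw/C_latt, small-world index
SWI = G·C, density D, and the intra/inter edge ratio IIR. Hemispheric
lateralization and fronto-limbic vs occipito-parietal regional asymmetry
indices ((A−B)/(A+B) edge counts) complete the measure set.

**Statistics.** Session-level means enter split-plot ANOVAs (condition
and skill level within sessions, dyad matching between sessions) with
partial η², post-hoc observed power (λ = F·df1), Bonferroni-corrected
follow-up t tests, and independent t tests on hyperbrain measures.

**Simulator.** `generate_dyad_trial()` produces narrowband (8.5–12 Hz)
latent oscillators with planted lagged coupling along a ground-truth
graph, fixed random dipole orientations, additive broadband noise, and
optional zero-lag within-brain mixing that emulates volume conduction.

## Worked example

```r
library(hyperlps)

cfg   <- simulation_config(trial_duration = 20, seed = 5)
truth <- truth_two_phase()          # traveling alpha rhythm, 2 phase groups
dyad  <- generate_dyad_trial(cfg, truth, trial_index = 1)
dyad$J1
#> <source_trial> S1 J1 PAIRED trial 1: 26 ROIs x 3 x 20480 samples @ 1024 Hz

lps <- lps_matrix_for_trial(list(trim_trial(dyad$J1), trim_trial(dyad$J2)))
adj <- binarize(lps)
n_edges(adj); attr(adj, "threshold")
#> [1] 541
#> [1] 0.1658758

network_metrics(adj, n_surrogates = 100, seed = 1)
#> # A tibble: 1 x 7
#>       L  C_raw     G     C   SWI     D   IIR
#>   <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1  1.59 0.0512     1 0.105 0.105 0.408 0.466
```

The 541 recovered edges are almost exactly the two-phase truth's 532
lagged pairs (precision 0.98, recall 1.00 for this seed): pairs a
quarter cycle apart are detected, zero-lag pairs are ignored. Because
that truth is near-bipartite the network has few triangles, hence the
low C and SWI — the multi-group `truth_phase_groups()` used by
`simulate_study()` produces clustered networks instead. A full
synthetic study runs with

```r
trials <- simulate_study(n_trials = 2)
res    <- run_pipeline(trials, pipeline_config(seed = 2), out_dir = "run1")
res$anova$G          # three-factor mixed ANOVA on global efficiency
res$hyperbrain_tests # matched vs unmatched dyads, five measures
```

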