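---
title: "Methods: ROI connectomics with roinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI connectomics with roinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

roinet implements a complete resting-state ROI connectomics analysis —
temporal denoising, correlation (FUN) and regression (EFF) connectivity,
thresholded binary-graph topology, and two-group inference under FDR
control — together with a synthetic cohort generator that gives every
stage a known ground truth. This vignette records the model, the
parameters that matter, the numerical conventions, and the design choices
made where several defensible options existed.

```{r setup}
library(roinet)
```

## The analysis model

A subject enters the pipeline as a T × N table of ROI signals (T volumes,
N regions) plus a confound set: six rigid-body motion parameters (three
translations in mm, three rotations in rad) and ten nuisance component
series standing in for principal components of white-matter and CSF
signals. The stages run strictly in this order:

1. **Outlier detection.** Volume t is flagged when its framewise
   displacement exceeds 0.9 mm or the z-scored change of the mean-over-ROIs
   signal exceeds 5 in absolute value. FD converts rotation changes to arc
   displacement on a 50 mm sphere (small-angle approximation):
   FD(t) = Σ|Δd(t)| + 50 · Σ|Δθ(t)|, FD(1) = 0. The 0.9 mm / z = 5 pair
   mirrors common "intermediate" artifact-detection settings; both are
   `denoise_config()` fields.
2. **Nuisance regression.** Each ROI series is replaced by its
   least-squares residual against: intercept, the 6 motion parameters,
   their first differences (first row 0), the first 10 nuisance
   components, and one indicator column per flagged volume. Scrubbing by
   indicator regressors — rather than deleting volumes — zeroes the
   flagged volumes' residuals while preserving series length, which keeps
   the subsequent spectral filtering well defined. Rank-deficient designs
   drop aliased columns with a warning; a design with as many columns as
   timepoints is a hard error.
3. **Detrending and band-pass.** The linear trend is removed by least
   squares, then an ideal rectangular frequency-domain filter retains
   discrete bins with 0.008 Hz ≤ f ≤ 0.09 Hz (inclusive at both edges)
   and zeroes everything else. An ideal filter matches the sharp interval
   the band states; the spectral mask is linear and exactly idempotent.
   Whether regression and filtering should be simultaneous rather than
   sequential is a known ambiguity in this workflow; roinet implements the
   sequential order above and asserts it in its tests.

**Connectivity.** FUN is the Pearson correlation of each ROI pair; EFF is
the bivariate regression slope b(i→j) = cov(i, j)/var(i) of target j on
seed i, asymmetric by construction. Series are deliberately *not*
variance-normalised before EFF — normalising would collapse the slope onto
the correlation and destroy the asymmetry the EFF analysis exists for.
Both are Fisher z-transformed, z = arctanh(v), after clipping v into
[−(1−10⁻⁶), 1−10⁻⁶]: regression slopes can exceed 1 in magnitude, where
arctanh is undefined, so the clip maps them to a finite ceiling
(≈ 7.25) while preserving sign and order; every clip is counted and
surfaced. Diagonals are masked and never thresholded into graphs.

**Graph topology.** An edge requires |z| > 0.4, a strict inequality, so a
value exactly at the threshold is excluded and strong anticorrelations
count like strong correlations. Directed EFF pass patterns are symmetrized
before the undirected metrics — by default an OR rule (edge if either
direction passes), with AND and mean available, since directed handling is
not standardised for these metrics. Seven node metrics are computed on the
binary graph: degree; cost = degree/(N−1) (the proportion of *possible*
neighbours — the standard definition, which keeps cost = 1 for a fully
connected node); betweenness centrality by Brandes' accumulation,
normalized by (N−1)(N−2)/2 (the Freeman pair count; a raw variant is a
config switch); average path length over *reachable* nodes, undefined for
isolated nodes; global efficiency as the mean of 1/d with 1/∞ = 0; local
efficiency as the global efficiency of the neighbour-induced subgraph
(the node itself excluded); and the clustering coefficient, 0 when a node
has fewer than two neighbours. Undefined path lengths are excluded from
group statistics rather than imputed with a finite surrogate.

**Group inference.** Per tested connection (or per node and metric), a
pooled-variance two-sample t — the [1, −1] contrast of a two-group GLM —
with the patients-minus-controls sign convention, then Benjamini–Hochberg
adjustment; findings are retained at p-FDR < 0.05. BH (not the more
conservative Benjamini–Yekutieli) is the default reading of "FDR
correction". The adjustment scope defaults to all tested connections
jointly, with a per-seed scope available. Degenerate rows follow fixed
conventions: zero pooled variance with equal means gives t = 0, p = 1;
with unequal means an infinite-t row at the p → 0 limit, flagged rather
than silently dropped. Seed restriction tests each unordered seed–other
pair once for FUN (seed–seed pairs not double-counted) and both directions
for EFF; with the shipped 132-label set and its 36 seeds this is
36·96 + C(36,2) = 4086 FUN connections, verified combinatorially in the
tests.

## The synthetic cohort generator

The generator is the package's study stand-in, not a fixture: it emulates
a two-group resting-state design of 28 subjects per group and 220 volumes
at TR 3.2 s (the reference acquisition), over a configurable parcellation.
Per group it builds a block-structured correlation matrix — communities
with a common within-block correlation (default 0.3) over a between-block
floor (default 0.05) — and, for the patient group only, adds planted
deltas on designated seed–target edges. Innovations are multivariate
Gaussian with that covariance, combined by a common AR(1) recursion
(default coefficient 0.3, a realistic BOLD-like autocorrelation; a
20-volume burn-in makes the kept series effectively stationary — since the
innovation covariance is shared, the implied correlations equal the target
for any AR coefficient). On top come: a linear drift (default total rise
of 1 signal-SD per scan), a slow sinusoid (default 0.5 SD at 0.003 Hz,
below the pass-band, so correct filtering removes it), scheduled motion
steps (default 2 mm at volumes 55 and 145) with a coincident one-volume
global signal artifact so scrubbing is exercised, smooth AR(1) motion
noise (0.02 mm innovation scale), and ten nuisance components injected
into the signals with known per-ROI loadings (SD 0.3) — the loadings are
reproducible from the subject seed, so confound regression has an exact
ground truth. No reference values existed for these nuisance magnitudes;
they were chosen once as plausible resting-state contamination levels and
are reported here rather than tuned.

Everything is a pure function of the spec including its master seed:
per-subject seeds derive deterministically, and two runs produce
byte-identical files.

If the raw covariance construction is not positive definite it is repaired
on the correlation scale, R ← (R + sI)/(1 + s), the smallest uniform
eigenvalue shift that restores PD while keeping the unit diagonal; the
shift bounds every correlation change by s/(1+s), the applied shift is
recorded, and a repair that would move any correlation by more than 0.05
is an error rather than a silent distortion.

What the generator does *not* emulate: hemodynamic convolution,
voxel-level structure (so the nuisance components are injected stand-ins,
not true tissue principal components), spatially heterogeneous noise,
between-subject variation in the connectivity structure itself (all
subjects of a group share one covariance), and any clinical event
structure. Passing tests therefore demonstrate correctness of the
pipeline's operations and calibration of its inference under this
idealised model — not performance on real fMRI.

## Verification strategy and problem sizes

- **Graph metrics** are checked against a brute-force oracle —
  Floyd–Warshall distances plus exhaustive geodesic enumeration by
  depth-first search — over every labeled graph on 1–5 nodes (1,099
  graphs, covering all 34 isomorphism classes on 5 nodes) and 200 random
  6–8-node graphs, to 1e−10, with igraph as an additional independent
  cross-check; canonical cases (K4, the 4-star, the 5-cycle, the 3-path)
  are asserted against hand-derived values.
- **Inference calibration** uses 200 replicate cohorts at the reference
  design (28/group, 220 volumes, 40 ROIs in four blocks, 10 disjoint
  planted edges of +0.3 between the seed and second blocks): the mean
  false-discovery proportion among retained connections must stay at or
  below the 0.05 retention level (within Monte-Carlo error), and the
  planted edges must be recovered with the planted sign in at least 80%
  of replicates. A 20-replicate global-null run checks that BH keeps the
  significant-edge count near zero. The 40-ROI, 200-replicate scale keeps
  a full calibration run in the low minutes on a single core while leaving
  per-subject estimation error realistic.
- **Generator fidelity** is verified at T = 10,000 with the AR switched
  off: empirical Fisher-z correlations fall within 3/√(T−3) of their
  targets for ≥99% of edges across 20 replicates, and the lag-1
  autocorrelation reproduces the AR coefficient to ±0.03.
- **Denoising** is verified against the generator's ground truth: injected
  components correlate < 0.01 with the residuals, residuals are orthogonal
  to the design to 1e−8, scrubbed volumes are exactly zeroed, a 0.05 Hz
  probe sinusoid passes the filter with amplitude ratio > 0.9 while a
  0.12 Hz probe is attenuated below 0.1.

`scripts/acceptance.R` recomputes the replicate-study operating
characteristic end to end from a command-line seed.

## Numerical conventions and edge cases

- Frequency bins are retained iff low ≤ f ≤ high — inclusive at both band
  edges; the DC bin is removed whenever low > 0 (detrending removes the
  mean anyway).
- A constant ROI yields NA correlations (with a warning) and a
  zero-variance seed an NA EFF row; NA connectivity entries never produce
  graph edges and are excluded from group tests.
- Betweenness for graphs with fewer than 3 nodes is defined as 0.
- Nodes with fewer than 2 finite metric values in either group are
  excluded from node-wise tests, with the exclusion count recorded.
- All text formats serialize doubles with 17 significant digits; reading
  uses base-R strtod parsing, so write-then-read round-trips are exact and
  cohort generation is reproducible across processes.

## Known limitations

- Inference assumes independent subjects and uses the pooled (not Welch)
  t; strong group-variance differences are not modelled.
- BH control is exact under independence and positive dependence; the
  edge-wise statistics are correlated through the shared block structure,
  which the replicate calibration covers empirically but not analytically.
- The threshold |z| > 0.4 is taken as a fixed design constant; no
  threshold-sweep or density-matched graph construction is provided.
- No partial correlations, lagged models, dynamic connectivity, weighted
  metrics, community detection, covariate adjustment or permutation
  inference — the pipeline deliberately stops at the classical workflow it
  implements.
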