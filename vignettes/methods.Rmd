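---
title: "Methods: quantifying microglial morphodynamics and anesthesia EEG states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microglial morphodynamics and anesthesia EEG states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorphdyn)
```

`gliamorphdyn` measures two complementary readouts of microglial state —
process motility in vivo and ramified morphology ex vivo — together with an
EEG characterization of the anesthesia state under which imaging happens.
This vignette documents the models and conventions behind each stage, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## In vivo chain: registration, projection, binarization

A time-lapse acquisition is a T×Z×Y×X stack: one z-volume every
`frame_interval_s` seconds (30 s is typical for this kind of imaging, with
~1 µm optical sectioning). Three conditioning steps precede any metric:

1. **Drift registration.** Each volume is aligned to a reference volume
   (the first, by default) by translating it by the negative of the peak
   location of their FFT-based cross-correlation. Shifts are *integer
   voxels*: slow mechanical drift is well approximated by whole-voxel
   offsets, integer shifts need no interpolation model, and the downstream
   metrics count discrete pixel changes that interpolation would blur.
   Voxels shifted in from outside the field are zero-filled, never wrapped
   — rolled-in data would fabricate signal at the ROI border. An all-zero
   volume has no defined correlation and is rejected explicitly.
2. **SD projection.** Each registered volume collapses to a 2D image by the
   per-pixel *population* standard deviation across z (divisor Z). The
   divisor is a convention that had to be fixed; the population form treats
   the stack as the complete object being projected rather than a sample
   from a longer one. Structured signal spanning several sections survives;
   flat background projects to zero.
3. **Binarization.** Projections are thresholded per image with Otsu's
   method (the parameter-free standard when no threshold is prescribed);
   a fixed threshold can be supplied instead, and the threshold actually
   used is recorded on every mask for provenance.

## Complexity: box-counting fractal dimension

Ramified cells occupy space between a line and a filled plane, which makes
a fractal dimension a natural complexity measure. For each box size *s*
(default: powers of two from 2 px to a quarter of the shorter image side,
on a grid anchored at the image origin), the number N(s) of occupied s×s
boxes is counted; the dimension is the negative slope of the least-squares
fit of log N(s) on log s, with the fit R² reported as a quality diagnostic.
The box schedule is a free choice and is therefore fixed and recorded: at
least three sizes are required for a meaningful fit, and anchoring at the
origin makes counts deterministic. Reference sets recover their known
dimensions (filled square → 2, line → 1, Sierpinski triangle → log 3/log 2
≈ 1.585) to within 0.05. A per-cell complexity is the arithmetic mean of
per-frame dimensions — the mean, not the median, because the series is
short (tens of frames) and outlier frames should be visible, not hidden.

## Motility index

Consecutive binarized projections are subtracted and the changed pixels
counted — the symmetric difference, since after binarization "subtraction"
can only mean disagreement between masks. Per-pair counts are the pairwise
motility coefficients (arbitrary unit); their *sum* over all consecutive
pairs is the global coefficient, normalized by the physical stack volume
(field area × z-extent, from voxel metadata) to an index per µm³. The
sum-over-pairs convention makes the index additive over concatenated
series and proportional to recording length for stationary dynamics;
absolute values are therefore comparable only between acquisitions of the
same geometry and duration, and only relative (pre/post) changes carry
meaning across setups. The index is translation-invariant, symmetric under
time reversal, and zero for a static scene.

## Ex vivo morphometry

Sections are segmented per cell with two thresholds: the soma is the
bright core above a high threshold (a fraction of the image maximum,
default 0.9, morphologically opened to drop speckle), and the arbor is the
Otsu-foreground connected component containing that soma. The proximal
cytoplasm is the soma geodesically dilated along the arbor for a fixed
reach (default 5 µm) — an auditable stand-in for "cytoplasm within the
primary branches" that preserves soma ⊆ cytoplasm ⊆ arbor by construction.
Cells touching the image border are flagged and excluded from batch
statistics by default.

The arbor is thinned to a one-pixel skeleton (iterative two-subfield
boundary peeling that preserves 8-connectivity and endpoints), the soma
interior is removed, and the remaining skeleton becomes a graph:

- **roots** — skeleton branches incident to the soma boundary (one
  attachment point per contact cluster, the pixel nearest the soma
  centroid);
- **junction nodes**, ranked by topological order outward from the soma:
  the first junction on a path from a root has rank 1, the next rank 2.
  Junctions deeper than rank 2 are counted but excluded from the
  complexity index, which is defined on rank-1/rank-2 nodes only. Rank is
  computed as hop count from the nearest root over the node graph
  (endpoints are leaves, so hops count junctions);
- **segments** — maximal skeleton paths between nodes, with geodesic
  length as the sum of 8-connected steps (1 or √2 pixels) times the pixel
  size. Terminal spurs shorter than 1.5 µm — a known thinning artefact at
  process edges — are pruned, and any pass-through pseudo-junction left
  with exactly two incident segments is dissolved, its segment lengths
  merged.

From segmentation and graph together come the per-cell record: areas as
pixel count × pixel area; CI = n_segments × (rank-1 + rank-2 nodes) /
n_roots (dimensionless and scale-invariant; an unbranched cell scores 0; a
soma-only cell has no defined CI and is recorded as NA); CEA as the convex
hull of the process endpoints via the shoelace formula (a concave reading
of "linking the extremities" is conceivable, but the convex hull is the
canonical surveillance-territory measure; fewer than three non-collinear
endpoints give area 0 with a warning); and total ramification length as
the sum of segment lengths.

Two readings of the CI prose were possible — per-ramification-then-summed
versus whole-cell counts; the whole-cell reading shown in the displayed
formula is implemented. Likewise "nodes 1/2" could mean a branching-degree
classification; topological rank is adopted as the natural outward order.

## EEG profiling

Traces are sampled at 1 kHz and band-passed to [0.5, 300] Hz with a
4th-order Butterworth applied forward-backward (zero phase) as separate
high- and low-pass sections — phase preservation matters because amplitude
distributions are part of the readout, and cascaded sections stay
numerically stable at a 0.0005 normalized cutoff. Power spectra use
Welch's averaged periodogram with 4 s Hann segments at 50% overlap,
mirroring the 4 s analysis window of the spectrogram (no estimator is
canonical here; the choice is recorded). Scaling is per-bin power summing
to the signal variance (Parseval-consistent for the rectangular-window
option). The spectral width at mid-height (WHM) is the width of the
contiguous band around the global maximum where power stays ≥ half the
maximum, measured on a 3-bin moving average — width at half maximum is
ill-defined on raw periodograms, whose single-bin spikes would otherwise
set the reference level. Amplitude distributions are normalized histograms
with moment-based excess kurtosis: burst suppression shows a sharp peak at
baseline with long wings (strongly positive excess kurtosis), wake
activity is near Gaussian. The spectrogram is a sliding FFT (4 s window,
0.5 s step, Hann taper, mean removed per window), displayed as
log-amplitude normalized to its per-record maximum, giving
floor((duration − window)/step) + 1 time bins.

## Statistics

The in vivo design is paired (the same cells pre- and post-anesthesia):
two-tailed paired t-tests, preceded by a d'Agostino–Pearson omnibus screen
on the differences. The screen is implemented from the standard skewness
(D'Agostino 1970) and kurtosis (Anscombe–Glynn 1983) z-transforms,
K² = z₁² + z₂² ~ χ²(2), requiring n ≥ 8; it *records and flags* violations
but never gates the test — both pieces of information are reported so the
branching logic stays transparent and reproducible. (One boundary
convention differs from some implementations: at exactly zero sample
skewness the skew z is 0 here, as the transform dictates.)

The ex vivo design is multi-group (control vs anesthetics, per region):
Shapiro–Wilk per group as a recorded screen, Kruskal–Wallis across groups
(tie-corrected, via `stats::kruskal.test`), and pairwise Wilcoxon rank-sum
post-hoc comparisons corrected with Sidak's formula p_adj = 1 − (1 − p)^m
over the m pairwise comparisons. Because "adjusting alpha for the number
of comparisons" and "Sidak-adjusted p" are not quite the same operation,
both are emitted: adjusted p-values and the family-wise adjusted alpha
1 − (1 − α)^(1/m). Summaries use sample SD (divisor n − 1) and report
n, mean, SD and SEM per metric per group. The statistical unit is the
cell, matching the paired design's n = 18 cells; pooling cells across
animals is a known pseudo-replication risk, so records carry image and
condition labels for cluster-aware sensitivity analyses.

## The synthetic generator

The generator exists to give every stage a ground-truthed input; it is a
geometric emulation, not a biophysical simulation.

- **Cells** grow recursively: `n_roots` primary branches leave the soma at
  quasi-even angles (jitter bounded to a quarter of the angular spacing so
  arbors of different roots cannot collide at the angular level — a
  requirement for deterministic renders to be exactly recoverable), each
  segment branches dichotomously with probability `branch_prob` up to
  `max_depth` orders, children deviating 15–60° from the parent direction
  on either side. The lower bound keeps sibling branches from rendering on
  top of each other at 2 px line width; purely uniform ±60° deviations
  would occasionally produce collinear children that no skeletonizer could
  separate. Segments are ~`segment_len_um` long (±20% uniform jitter).
  Processes render as 2 px anti-aliased-free polylines and the soma as a
  filled disk — a geometry that survives binarization and thinning
  cleanly. The ground truth records every root, segment, junction rank and
  endpoint.
- **Time lapses** place the 2D cell into a z-stack with a Gaussian axial
  intensity profile, then evolve it: each frame toggles a random set of
  tip pixels (expected toggled fraction of arbor pixels =
  `motility_level`), restricted to the terminal 30% of each branch where
  microglial process dynamics concentrate; then the cumulative integer
  drift is applied with zero fill; then Gaussian intensity noise, clipped
  at zero, the simplest photon-noise stand-in. Programmed motility and
  recovered index are monotonically related (Spearman ρ > 0.9 across
  levels), which is the property the motility metric needs; absolute index
  values are not calibrated to any real acquisition.
- **Paired cohorts** reuse one acquisition spec across `n_cells` cells
  (independent arbors and toggle streams, seeds derived from the cohort
  seed), with the post condition at `pre × (1 + effect)` motility. An
  effect of −0.17 mirrors the scale of reported anesthesia-induced
  motility reductions (~715 vs ~861 index/µm³, i.e. −17%).
- **EEG presets** synthesize the three states from their published
  signatures: *wake* is frequency-shaped Gaussian noise whose power
  spectrum is flat at low frequency and falls steeply through half-maximum
  at `wake_whm_hz` (default 10 Hz) — the steep shoulder makes the
  half-power point, hence the measured WHM, sharply defined; *ketamine/
  xylazine* is 0.5 Hz and 2 Hz sinusoids over low noise, with the 2 Hz
  amplitude decaying linearly to 30% across the record (the decay rate is
  not quantified anywhere and is a free generator parameter); and
  *pentobarbital* is a near-isoelectric floor with Poisson-timed
  Hann-enveloped oscillatory bursts (default 0.12 bursts/s, 0.8 s, 180 µV,
  3–9 Hz intra-burst frequency — chosen as typical burst-suppression
  figures; none is quantified in the source material).

What the generator does **not** emulate: optics (no PSF, no depth
attenuation), photon statistics (additive Gaussian only), anatomy (no
tortuosity, taper, or volume exclusion beyond the angular-jitter bound),
EMG, or within-state EEG nonstationarity beyond the 2 Hz decay. Passing
tests therefore demonstrate that the *computational chain* is correct and
sensitive at realistic effect sizes — not that the segmentation or
thresholds are tuned for any particular microscope.

## Numerical choices and degenerate inputs

- Coordinates are (z, y, x) with 1-based indexing in R; shifts are
  reported as displacements of each frame relative to the reference.
- FFT cross-correlation peaks above the Nyquist fold wrap to negative
  shifts; axes shorter than twice the largest drift are ambiguous, so
  drift recovery needs adequate z-depth (the z-extent should exceed twice
  the cumulative drift).
- Dense deep arbors (branch order ≥ 3) can genuinely self-overlap in the
  render; graph counts then differ from truth by the merged junctions.
  Exact round-trip recovery holds for the collision-free configurations
  (unbranched cells at any root count; two-root dichotomous cells), and
  that is what the validation suite asserts exactly.
- Degenerate inputs fail loudly: all-zero volumes (registration), empty
  masks (fractal dimension), constant images (binarization warns and
  returns an empty mask), constant traces (amplitude histograms), zero
  difference variance (paired test), < 3 distinct box sizes, < 3
  non-collinear endpoints (CEA = 0 with warning), soma-only cells (empty
  graph with warning, CI = NA).

## Problem sizes in the validation suite

The suite validates on deliberately small synthetic problems — 64–256 px
rasters, 3–4 frame stacks, 4–10 z-slices, 40–120 s EEG traces, cohorts of
18 cells × 50 replicates — sizes at which every oracle (exhaustive shift
search, brute-force box and XOR counts, hull membership grids, 1000-fold
null simulations) is computable exactly. The operations are size-generic;
production data at 521×521 px × 30+ stacks simply scale the same code.

## Known limitations

- Integer-only registration (subpixel drift below 1 voxel is invisible);
  acceptable at this pixel size, and consistent with pixel-count metrics.
- The motility index conflates extension, retraction and residual
  misregistration; it is a global scalar by design and performs no
  filopodia-level tracking.
- Segmentation thresholds are simple and global; heavily overlapping cells
  in dense tissue would need the flagged-cell path or manual ROIs.
- The paired t-test assumes independent cells; with few animals the
  effective sample size is smaller than n cells (labels are carried for
  sensitivity analyses, not silently modelled).
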