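---
title: "Methods: from ultrafast Doppler and confocal stacks to hippocampal vascular statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ultrafast Doppler and confocal stacks to hippocampal vascular statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippovasc)
```

`hippovasc` quantifies hippocampal vasculature from two complementary
modalities: in vivo cerebral blood volume (CBV) from ultrafast power
Doppler, and post mortem vascular structure from confocal fluorescence
z-stacks of lectin-labelled vessels. This vignette explains the models and
procedures, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical conventions that make
results reproducible.

## The Doppler arm: SVD clutter filtering and quartile CBV segmentation

A compound acquisition is a complex stack $s(x, z, t)$ of $N_x \times N_z$
pixels over $N_t$ frames (the reference protocol uses $128 \times 92 \times
350$ at 500 Hz with 0.1 mm pitch). Reshaping space into rows gives the
Casorati matrix $S \in \mathbb{C}^{N_x N_z \times N_t}$ (depth-fastest row
order, documented in `to_casorati()`), which factors as $S = U D V^*$ with
singular values $\lambda_1 \ge \lambda_2 \ge \dots$ Tissue clutter —
high-energy, spatially coherent, slowly moving — concentrates in the leading
components; spatiotemporally incoherent noise in the trailing ones; blood
flow occupies a middle band. The clutter filter keeps the closed index band
$[N_\text{tissue}, N_\text{noise}]$:
$S_\text{blood} = U (D F) V^*$, where $F$ is diagonal with ones inside the
band. The band is closed on both ends so that the full band
$[1, N_t]$ is exactly the identity and $N_\text{tissue} = N_\text{noise}$
still keeps one component.

The power-Doppler image is the temporal mean of squared magnitude of the
filtered stack, $I(x, z) = \overline{|s_\text{blood}|^2}$, proportional to
CBV. Band selection maximizes the ratio of mean filtered power in a blood
ROI (inside the hippocampus, containing at least one vessel) to that in a
noise/tissue ROI (no vessels), both on linear power — the ratio of two ROI
means, not of dB values. `optimize_band()` scores every candidate pair on a
rectangular grid. Because $V$ is unitary, the per-pixel temporal mean power
of a band equals $\frac{1}{N_t}\sum_{i \in B} \lambda_i^2 |U_{pi}|^2$, so
the whole grid is scored from one SVD with cumulative per-component ROI
energies; this is algebraically identical to filtering and re-imaging per
band (a test asserts the equality), just much cheaper. Ties break to the
smallest $N_\text{tissue}$, then the largest $N_\text{noise}$. The default
grid, $N_\text{tissue} \in [5, 60]$ and $N_\text{noise} \in [50, 120]$,
brackets the thresholds typical of 350-frame hippocampal acquisitions
(means near 30 and 78); how the original selection searched the plane is
not documented, so an exhaustive grid is the safe choice. An all-zero noise
ROI raises an error rather than returning an infinite ratio, which would
otherwise silently win every comparison.

One numerical caveat, asserted in the tests in its stable form: re-running
the filter on an already filtered stack is a no-op only if the second band
is anchored at 1 (e.g. $[1, N_\text{noise}]$). A fresh SVD re-sorts the
kept components into the leading positions, so re-applying an interior band
to its own output would cut different components — idempotence in the
strict sense does not hold for interior bands, by construction of the SVD.

The final image of a plane averages repeated acquisitions (twenty in the
reference protocol) in linear power, before any dB conversion. Within each
hippocampus ROI the image is converted to decibels referenced to the in-ROI
maximum, $10 \log_{10}(I / I_\text{max})$ (power quantity, hence the factor
10), so the brightest pixel is exactly 0 dB and cut-offs are invariant to
any global or per-hemisphere gain; zero-power pixels clamp to a documented
floor of −120 dB. Left and right hippocampi are processed independently
with their own reference maxima and enter the cohort as independent
measurements.

Quartile segmentation takes the 25th, 50th, 75th percentiles and the
maximum of the in-ROI distribution (Q1–Q4). Percentiles interpolate
linearly between closest order statistics (R type 7); the convention is
recorded in the output because different conventions move cut-offs by
fractions of a dB on small ROIs. Classes are lower-open/upper-closed with
class 1 taking everything $\le$ Q1, which guarantees a total partition
under ties; a constant ROI collapses into class 1 and is flagged degenerate
rather than erroring. Classes are named by cut-off percentile — Q1 is the
lowest-intensity quarter. Published figures sometimes color the
highest-intensity central region as "Q1"; whether that label denotes a
display order or the percentile index is ambiguous in figure/caption
pairings, so this package reports percentile-indexed cut-offs and leaves
any display mapping to the caller. Likewise, whether reported per-quartile
values are cut-offs or class means is not fully explicit in the field;
`hippovasc` reports cut-offs, which are well-defined and
hemisphere-reference-invariant. Note one consequence: Q4 referenced to the
in-ROI maximum is identically 0 dB, so Q4 carries no between-cohort
information under this convention — a between-group comparison of Q4 is
degenerate and reported as such.

## The confocal arm: thresholding, 3-d labeling and VVF ranges

A fluorescence volume is an $(x, y, \text{plane})$ stack with strongly
anisotropic voxels (0.28–0.56 µm lateral, 5 µm z-step, ten planes). Each
plane is binarized with its own automatic threshold computed over in-ROI
pixels by the iterative intermeans (IsoData) rule — the classic default of
image-analysis software: starting from the plane mean, the threshold moves
to the midpoint of the two class means until fixed. Otsu's criterion is
available behind a flag. A constant plane has no separable classes; it
yields an empty foreground and a warning flag, a deliberate fail-soft for
quality control. Thresholding a vessel-free plane of pure noise is
meaningless under any automatic rule, so phantoms used in pipelines keep
vessel-free planes constant.

Foreground voxels are partitioned into maximal 3-d connected components
(`label_vessels()`), each an individual vessel. The default neighborhood is
26-connected (faces, edges, corners): vessels are elongated and often run
diagonally through the anisotropic grid, and the reference plug-in's
connectivity is unspecified; 6-connectivity is available. The labeling is a
vectorized minimum-label propagation with pointer jumping, verified
voxel-for-voxel against a breadth-first flood fill on hundreds of random
volumes. Component volume is voxel count times the full anisotropic voxel
volume in µm³ — counts alone are meaningless with 5 µm z-steps. Components
touching the volume border are kept (no edge-exclusion rule is imposed) but
recorded, and no minimum size filter is applied by default (`min_voxels =
1`); both are sensitivity knobs, not defaults.

Each vessel's volume is normalized by the hippocampal reference volume —
in-plane hippocampal surface area times coronal section height (e.g.
50 µm) — and scaled by 1000:
$\mathrm{VVF} = 1000 \cdot V_\text{vessel} / V_\text{hippocampus}$.
Vessels are classified into four caliber ranges aligned with
capillary-venule, arteriole, venule and artery-vein reserve levels:
$[0, 0.0003)$, $[0.0003, 0.003)$, $[0.003, 1]$ and $(1, \infty)$. The third
range closes at 1 so that the last is strictly "greater than 1", matching
the printed range list. Per-range summaries are the vessel count, mean VVF,
total VVF and the total-VVF-per-vessel ratio. Two consecutive coronal
slices (together roughly the Doppler beam width in elevation) are combined
by averaging their per-range summaries pairwise — averaging summaries, not
pooling vessels, is one of two defensible readings of "averaging the VVF
distribution"; the implemented choice is recorded in the output provenance.

## Cohort statistics

Each hippocampus contributes one value per quartile or per VVF range.
Normality is gated per sample by Shapiro–Wilk at $\alpha = 0.05$ (per
comparison, on each sample separately — pooled gating is the other
defensible reading; per-sample is implemented and logged). Between age
groups, gated samples go to the unpaired pooled-variance Student's t test
($df = n_a + n_b - 2$; 12 vs 12 hippocampi gives $df = 22$) or the
Mann–Whitney U (midranks; exact enumeration for tie-free samples up to
n = 8, normal approximation with continuity correction otherwise). Within a
group, levels are compared by one-way ANOVA with Bonferroni pairwise post
hoc when every level passes the gate — treating each hippocampus-level
value as an independent observation, the printed design (4 levels of 12
values give $F$ on $(3, 44)$ df) — or by the Friedman test on
per-hippocampus blocks otherwise.

The Friedman statistic is computed from its rank formula with within-block
midranks, $\chi^2 = \frac{12}{nk(k+1)} \sum_j R_j^2 - 3n(k+1)$ on $k - 1$
degrees of freedom, with the chi-square approximation for the p-value (no
exact permutation null). At $n$ blocks and $k$ conditions its maximum is
$n(k-1)$, attained exactly when every block orders the conditions
identically and strictly — for ten hippocampi over four ranges that
saturation value is 30. Note that the saturated four-condition statistic is
sometimes quoted as "$\chi^2(4)$"; the degrees of freedom of a $k = 4$
Friedman test are $k - 1 = 3$, and this package reports 3.

The Friedman post hoc runs all pairwise paired Wilcoxon signed-rank tests
and passes their raw p-values through the Benjamini–Krieger–Yekutieli
two-stage linear step-up: stage one applies the linear step-up at
$q' = q/(1+q)$; its rejection count $r_1$ estimates the number of true
nulls $\hat m_0 = m - r_1$; stage two re-runs the step-up at
$q' \, m / \hat m_0$ (the published two-stage definition — the commonly
paraphrased "$q \, m / m_0$" omits the prime). The estimated $\hat m_0$ and
stage-two level are attached to the output. All tests are two-tailed at
$\alpha = 0.05$.

## What the synthetic generators emulate — and what they do not

The Doppler generator builds scenes as tissue + blood + noise with known
spectral structure. Tissue is a rank-$r$ clutter term: orthonormal spatial
modes (randomly rotated low-order 2-d polynomials — smooth, global support,
so clutter reaches every ROI as real tissue does) times QR-orthonormalized
slow complex oscillations below 5 Hz. Both factors are orthonormalized
deliberately: over a sub-second acquisition, oscillations below 5 Hz are
nearly collinear, and without orthogonalization the clutter collapses
numerically onto fewer components than its nominal rank, making the tissue
cut-off unidentifiable. With it, tissue singular value $i$ is exactly
$A_\text{tissue} \cdot 0.9^{i-1} \sqrt{N_t}$. Blood is confined to a vessel
mask; each vessel pixel advances in phase at the Doppler frequency
$f = 2 v f_0 / c$ ($f_0$ = 15 MHz, $c$ = 1540 m/s) of its own velocity
drawn from 2–10 mm/s, spectrally separated from the near-DC clutter. Noise
is circularly symmetric complex Gaussian. Defaults
($A_\text{tissue} = 40$, $A_\text{blood} = 4$, $\sigma = 0.5$) were chosen
once to satisfy the tissue > blood > noise spectral ordering with a blood
band roughly 18 dB above the noise floor, a plausible in vivo figure; no
published amplitude ratios exist to calibrate against. The generator does
not simulate acoustics: no speckle statistics, no point-spread function, no
attenuation, no motion artifacts. Passing tests therefore demonstrate that
the filtering and segmentation machinery is correct under the stated
spectral model, not that thresholds transfer to any particular scanner.

The confocal generator rasterizes cylindrical tubes: a voxel is foreground
iff its center lies within the tube radius of the centerline — a simple,
exactly auditable rule whose voxel counts are compared against analytic
$\pi r^2 L$ volumes (agreement within ~10% at 1 µm voxels for
radius-5 tubes). Per-tube voxel counts and multi-tube overlap are recorded
exactly. It does not model the confocal point-spread function beyond
optional Gaussian intensity noise, nor staining heterogeneity. The cohort
generator draws per-hippocampus values from Gaussian group distributions —
two groups, configurable mice per group, two hippocampi each — and is used
both for calibration nulls and for effect-size scenarios.

## Numerical and design conventions at a glance

- Percentiles: type 7 (linear interpolation); recorded in outputs.
- dB: $10 \log_{10}$, per-hemisphere in-ROI maximum reference, −120 dB floor.
- Band: 1-based closed interval; exhaustive grid; ties to smallest
  $N_\text{tissue}$, largest $N_\text{noise}$; zero noise-ROI mean errors.
- Labeling: 26-connectivity default; components numbered by smallest linear
  index (deterministic); anisotropic voxel volumes everywhere.
- Ranges: $[0, 3\!\times\!10^{-4})$, $[3\!\times\!10^{-4}, 3\!\times\!10^{-3})$,
  $[3\!\times\!10^{-3}, 1]$, $(1, \infty)$.
- Friedman: midranks, chi-square approximation, $df = k - 1$.
- BKY: published two-stage definition with $q' = q/(1+q)$.
- Degenerate inputs fail soft where a flag is more useful than an error
  (constant ROI, constant plane) and fail fast where silence would corrupt
  results (zero noise ROI, overlapping hemisphere masks, inverted bands).

## Reproducibility and problem sizes

Every generator takes an explicit seed and is bit-reproducible; the
pipeline fans a single master seed out to per-stage seeds through a fixed
affine derivation, and reruns produce byte-identical CSV outputs. The test
suite exercises the package at deliberately desk-sized scales, chosen so
properties are sharp but cheap: 32 × 24 × 80 Doppler scenes for band
recovery (20 seeded scenes, tissue ranks 2–6), 16 × 16 × 8 random volumes
for the flood-fill equivalence (200 volumes, both connectivities), 10 × 4
blocks for Friedman calibration (10⁴ null replicates), and a demo pipeline
of two 3-mouse groups with 96 × 96 × 10 phantoms. In-vivo headline values
(mean quartile cut-offs, per-range mean VVF, age-comparison p-values)
depend on undeposited animal data and are not reproduced; what is
reproduced are the design-determined statistics (the saturated Friedman
value of 30; $df = 22$) and the method's invariants.

## Known limitations

Quartile cut-offs referenced to the in-ROI maximum make Q4 uninformative
between cohorts (always 0 dB). The SNR-maximizing band is only as good as
the ROI placement: if the blood ROI misses a vessel, components carrying
that vessel are legitimately trimmed by the objective. The chi-square
Friedman p-value is approximate at small block counts (measured null
rejection ≈ 4.3% at $n = 10$, $k = 4$). Range boundaries are fixed
constants on the VVF scale, so absolute placement of phantom vessels into
ranges depends on the chosen hippocampal reference volume; phantoms here
use a reference volume that spreads the four caliber classes across all
four ranges. The mouse/hemisphere hierarchy is deliberately not modelled
with mixed effects — hippocampi enter as independent measurements, matching
the cohort design the statistics reproduce.
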