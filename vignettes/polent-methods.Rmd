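---
title: "Polarimetric entropy analysis of PS-OCT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarimetric entropy analysis of PS-OCT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polent)
```

## The measurement model

Polarization-sensitive OCT measures, at every voxel, a 2×2 complex Jones
matrix $J$ describing how the sample transforms polarized light. Tissues
whose sub-resolution structure scrambles polarization — above all the
melanin-rich retinal pigment epithelium (RPE) — produce Jones matrices that
vary randomly from voxel to voxel, while ordered tissue transforms light
coherently. `polent` quantifies this randomness with the Cloude–Pottier
entropy of the local coherency matrix.

Writing $c = \mathrm{vec}(J) \in \mathbb{C}^4$ (row-major: $J_{11}, J_{12},
J_{21}, J_{22}$), the local coherency is the window average

$$ T = \left\langle c\,c^\dagger \right\rangle_{k_z \times k_x}, $$

taken over a $k_z$ (axial) × $k_x$ (lateral, within one B-scan) neighborhood
(`entropy_volume()`, default 3×3, truncated at volume edges). Additive
detector noise of per-element variance $\sigma^2$ contributes an isotropic
term $\sigma^2 I_4$ to $T$; the noise bias is removed by subtracting it
before eigen-decomposition, clamping any negative eigenvalues at zero. With
normalized eigenvalues $p_i = \lambda_i / \sum_j \lambda_j$,

$$ H = -\sum_{i=1}^{4} p_i \log_4 p_i \in [0, 1], $$

so $H = 0$ for a spatially uniform (fully polarized) field and $H = 1$ for
completely random polarization. The log base 4 matches the four-dimensional
target vector. Voxels whose clamped spectrum sums to zero, or that fall
below the intensity detection threshold, are marked invalid rather than
assigned $H = 0$, so they can never bias layer averages. $H$ is invariant
under a global unitary transformation of all Jones matrices and under
global complex scaling (with $\sigma^2$ rescaled accordingly); both
invariances are exercised by the test suite.

Intensity is reported as dB over the noise floor:
$I_{dB} = 10\log_{10}(\lVert J\rVert_F^2 / P_{\text{noise}})$ with
$P_{\text{noise}} = 4\sigma^2$ estimated from a signal-free axial range
(`estimate_noise_power()`). Absolute (instrument-calibrated) dB is out of
scope; the detection threshold defaults to +3 dB over the floor.

### Small-kernel estimation bias

The eigenvalue spectrum of a coherency matrix estimated from $N$ samples is
dispersed around the true spectrum. For a completely random field the 3×3
kernel ($N = 9$) yields $\mathbb{E}[\hat H] \approx 0.85$, not 1; the bias
shrinks roughly like $1/N$ and falls below 0.02 for $N \gtrsim 80$. The
default kernel stays 3×3 — it preserves spatial resolution, and threshold-
based uses ($H > 0.1$) and longitudinal contrasts are unaffected by a
monotone compression — but quantitative recovery of the closed-form layer
entropy is validated with ≈81-sample kernels (9×9 in homogeneous volumes;
3×27 inside the 6 px RPE band, which a 9-row axial window would straddle).
Conversely, entropy estimated over an arbitrarily large sample (e.g. the
$10^5$-draw random-field endpoint) goes through `coherency_entropy()` on the
explicitly averaged matrix.

## The layered-eye phantom

No public PS-OCT volumes accompany this analysis, so validation rests on a
synthetic eye with analytically known truth (`phantom_spec()`,
`generate_phantom()`). Depolarization is modeled as a Gaussian mixture: a
voxel of layer $L$ draws

$$ c \sim \mathcal{CN}\!\left(0,\; P_L\left[(1 - d_L)\, c_0 c_0^\dagger +
\tfrac{d_L}{4} I_4\right] + \sigma^2 I_4\right), $$

with $c_0$ the vectorized identity Jones matrix, $P_L$ the layer backscatter
power and $d_L \in [0,1]$ the mixing (depolarization) parameter. The
eigen-spectrum of the unit-power mixture is $(1 - 3d/4, d/4, d/4, d/4)$, so
the layer's expected entropy has the closed form `expected_entropy(d)` —
exactly 0 at $d = 0$, exactly 1 at $d = 1$, strictly increasing, with
`inverse_expected_entropy()` available to prescribe target entropies.
Detector noise is folded into the isotropic term (identical distribution,
fewer draws). This choice trades tissue realism for exact ground truth: the
validation surface is estimator correctness, not wave-optics fidelity.

Geometry (defaults follow the instrument: 512×512 A-scans over 6×6 mm,
axial pitch 13/3 µm so that 3 px = 13 µm): a noise-only vitreous above the
ILM (doubling as the noise-estimation region), retina down to 3 px above the
RPE line, a 6 px RPE band centered on the line, choroid down to the CSI, and
noise below. The foveal pit is a Gaussian thickness reduction (defaults
130 µm deep, 0.75 mm radius on a 350 µm retina). Default layer parameters:
power 1 / 4 / 0.5 and $d$ = 0.02 / 0.6 / 0.3 for retina / RPE / choroid,
30 dB SNR. Optional features: sector-confined edema (smooth added
thickness), a per-A-scan RPE depolarization map for treatment effects, and
hyperreflective foci (HRF) — 3 px cubes of 30× retina power and $d = 0.7$
seeded in the foveal B-scan plane with a minimum mutual separation, placed
by greedy packing over a shuffled lattice (deterministic under the seed).
The HRF defaults are set so foci are separable from fully developed speckle,
whose per-pixel intensity fluctuations are exponential and would otherwise
make any threshold-based count irreproducible.

What the phantom does *not* emulate: correlated speckle (voxels draw
independently), eye motion, vessel shadows, serous detachments, disorganized
retinal layers, or instrument roll-off. Passing tests therefore demonstrate
correctness of the estimators and statistics under the stated model, not
robustness to clinical pathology.

### Longitudinal series

`longitudinal_series()` emulates a treated eye imaged at baseline and 1, 2,
3 and 6 months: RPE depolarization follows a per-visit schedule only inside
the laser-irradiated ETDRS sectors, sector edema can shrink on its own
schedule, and geometry is otherwise fixed (volumes co-registered by
construction). Each visit adds one global depolarization offset drawn from
$\mathcal{N}(0, 0.04^2)$ (`d_jitter_sd`), representing session-to-session
repeatability (alignment, instrument state). This term matters: a decline
confined to one inner sector occupies only ≈5% of the grid area, and without
between-visit variability its dilution into the whole-grid mean would be
trivially significant at $n \approx 11$ — the opposite of the clinically
observed pattern (sector-level decline, whole-grid stability) the package is
designed to reproduce. The default was chosen analytically: dilution
(≈0.01 entropy units) well below the noise, sector-level effects (≈0.2)
well above it.

## Segmentation, en-face maps, sectors, B-scan metrics

Surfaces (`segment_surfaces()`): per A-scan on the axially smoothed
intensity, the ILM is the first depth with `m = 3` consecutive
supra-threshold pixels (run detection on the raw profile — centered
smoothing would shift the edge up by one pixel); the RPE maximizes smoothed
linear intensity × entropy below the ILM (the bright, depolarizing band);
the CSI is the last supra-threshold depth below the RPE. Surfaces are
median-filtered laterally (window 11) and the ordering ILM < RPE < CSI is
enforced; an error is raised when more than half the A-scans fail (e.g.
pure noise). This threshold/argmax design is sufficient for phantom
geometry; graph-search segmentation of clinical pathology is explicitly out
of scope. On flat phantoms at 30 dB SNR each surface lands within 1 px of
truth on ≥99% of A-scans, and the error grows monotonically as SNR falls.

En-face maps (`enface_entropy_map()`) average valid-voxel entropy over
pixel-defined slabs: retina $[z_{ILM}, z_{RPE} - 3)$, RPE
$[z_{RPE} - 3, z_{RPE} + 3)$ (6 px = 26 µm; an even count cannot be
symmetric about one row, so the extra row lies on the choroid side), choroid
$[z_{RPE} + 3, z_{CSI})$. The slabs are contiguous, disjoint, and partition
$[z_{ILM}, z_{CSI})$ by construction. A pixel is masked when its slab is
empty or fewer than 50% of its voxels are valid. Maps inherit the raster's
lateral dimensions (512×512 at full scale).

The ETDRS grid (`etdrs_grid()`) partitions the 6 mm disk into the central
1 mm disk plus inner (3 mm) and outer (6 mm) rings split at the ±45°
diagonals — nine sectors. Radius boundaries are half-open (the ring owns its
inner circle) and diagonal pixels belong to the superior/inferior wedges, a
tie-break chosen because it is symmetric under the OD/OS mirror, so masks
are disjoint, cover exactly the disk, and swap nasal↔temporal cleanly
between eyes. `sector_means()` reports per-sector means plus two pooled
scopes: the pixel-weighted whole grid and the union of irradiated sectors
(whole-grid pooling is pixel-weighted; the sector-mean-weighted alternative
is recoverable from the returned table).

B-scan metrics (`rpe_entropy_area_percent()`, `detect_hrf()`): the RPE
entropy-area percentage counts band pixels with $H > 0.1$ (strict) in a
7-row band — the RPE line ±3 px, deliberately one row more than the 6 px
en-face slab; both definitions are kept in their own contexts — across
columns within 1500 µm of the fovea. HRF counting is an automated surrogate
for expert reading: connected components of 3×3-smoothed intensity ≥ 8 dB
over the median retinal level, within the sensory-retina slab; entropy dots
are components of the depolarization mask in the same slab eroded by the
kernel half-height (windows of the outermost slab rows straddle neighboring
layers and would smear a spurious fringe). Components count if their
centroid column lies within the radius — a focus is in or out as a whole.
Overlap pairs HRF and dot components greedily one-to-one, guaranteeing
`n_overlap <= min(n_hrf, n_dots)`. The surrogate is validated only on
phantoms; it does not reproduce manual counts on clinical images.

## Statistics

The longitudinal analysis uses the Friedman rank test (computed from the
mid-rank formula and cross-checked in tests against both
`stats::friedman.test` and exact permutation enumeration at $n = 8, k = 3$)
plus per-timepoint paired contrasts against baseline — Wilcoxon signed-rank
(normal approximation) or paired $t$ — with Bonferroni adjustment
$p_{adj} = \min(1, m\,p)$ and complete-case restriction per contrast, which
accommodates dropout (e.g. eyes leaving after 3 months). A linear mixed
model is deliberately not fit: the package's validation questions (null
safety, sector-confined effect recovery) are answered by the nonparametric
pair, and REML machinery would add nothing testable here. Cross-sectional
comparisons (`group_compare()`) wrap Student's $t$, Mann–Whitney with
normal approximation and tie correction, and the 2×2 chi-squared without
continuity correction. Correlations between change rates
($(v_t - v_0)/v_0$, `change_rate()`) use the product-moment $r$ with
$r^2$ and the $t$-based $p$-value; the correlation unit is one point per
eye over the irradiated-sector means, with pooling across sectors or
timepoints left to the caller's table construction.

## Validation design and problem sizes

The test suite generates everything it needs at run time. The main
simulation studies, with sizes chosen to resolve the questions at desk
scale:

- **Null safety.** 200 replicate cohorts of 9 eyes × 5 visits
  (44×20×20-voxel eyes), no treatment effect: the fraction of cohorts with
  any Bonferroni-adjusted irradiated-sector contrast significant at 0.05
  must stay ≤ 0.05.
- **Effect recovery.** 12 cohorts of 11 eyes (two eyes leave after 3
  months, mirroring the source cohort), RPE depolarization declining from
  0.6 to 0.3 inside one inner sector: the irradiated-sector contrasts at
  2/3/6 months must be significant in ≥10/12 cohorts while the whole-grid
  and a non-irradiated sector stay null in most (bounds 4/12 and 2/12;
  a single-cohort null assertion would fail with probability equal to its
  own family-wise error rate, so the pattern is asserted over replicates).
- **Linked-change recovery.** Per seed, 12 eyes whose entropy change rate
  $x \sim \mathcal{N}(-0.2, 0.15^2)$ drives the follow-up RPE
  depolarization through the inverse closed form, and whose thickness
  change rate is $y = 0.05 + x + \varepsilon$, $\varepsilon \sim
  \mathcal{N}(0, 0.15^2)$ (population $r^2 = 0.5$); over 100 seeds the mean
  pipeline-recovered $r^2$ must lie within ±0.05. The generator scales are
  set so the generated variance dominates the estimator's sector-mean
  measurement noise (≈0.03 in change-rate units at the 3×3 kernel);
  otherwise the experiment would measure estimator noise, not parameter
  recovery. The whole inner ring is irradiated for the same reason (more
  measurement pixels), the geometry is deepened (64 axial px, no pit) to
  accommodate the generated thickness range, and $y$ is truncated at 2.5
  standard deviations to respect the minimum 6 px retina.

Numerical details worth knowing: coherency window sums use integral images
(exact up to cancellation ≈ $10^{-12}$ at test scales); the per-voxel 4×4
Hermitian eigenvalues come from a cyclic complex Jacobi iteration with a
scale-aware stopping rule (machine precision; near-zero corrected matrices
exit immediately); voxel-level agreement with a brute-force R `eigen()`
oracle is asserted to $10^{-10}$. Surfaces are integer-valued (pixel
indices); thickness is therefore quantized at 13/3 µm, which matters only
for exactly flat geometry. Volumes stored externally use 8 multi-page
32-bit TIFF stacks (real/imaginary per Jones element) with a JSON sidecar
holding pitches and affine scale factors.

## Known limitations

- The entropy estimator's small-kernel bias is not corrected, only
  documented; quantitative absolute entropy at the default kernel is
  compressed (monotonically) relative to the closed form.
- Segmentation assumes phantom-like anatomy (monotone boundaries, a single
  bright depolarizing band).
- The HRF surrogate's agreement with expert manual counting on clinical
  images is unknown and untested by design.
- Sampling is voxel-independent; spatially correlated speckle would enlarge
  the effective-sample correction needed for sector-mean standard errors.
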