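# polent

Polarimetric entropy analysis for polarization-sensitive optical coherence
tomography (PS-OCT) of the macula.

PS-OCT measures a 2×2 complex Jones matrix per voxel. Melanin-bearing
tissue — above all the retinal pigment epithelium (RPE) — scrambles the
polarization state from voxel to voxel, and the degree of scrambling is a
marker of RPE integrity that conventional OCT cannot see. `polent` turns
Jones-matrix volumes into that marker and carries it through a full
longitudinal analysis:

- **Per-voxel entropy** (`entropy_volume()`): the local coherency matrix
  `T = ⟨c c†⟩` (with `c = vec(J)`) is averaged over a small axial×lateral
  window, the detector-noise bias `σ² I₄` is subtracted, and the
  Cloude–Pottier entropy `H = −Σ pᵢ log₄ pᵢ` of its eigenvalue spectrum is
  computed: 0 for uniform polarization, 1 for completely random
  polarization. Depolarizing pixels are flagged at the strict threshold
  `H > 0.1` (`depolarization_mask()`).
- **Surfaces** (`segment_surfaces()`): ILM, RPE and chorioscleral interface
  per A-scan from intensity and entropy.
- **En-face layer maps** (`enface_entropy_map()`): retina (ILM to 3 px above
  the RPE), RPE (6 px / 26 µm centered at the RPE line), choroid (3 px below
  the RPE to the CSI).
- **ETDRS sectors** (`etdrs_grid()`, `sector_means()`): nine-zone macular
  grid (1 / 3 / 6 mm circles), per-sector and pooled (whole-grid,
  irradiated-sector) means.
- **B-scan metrics** (`rpe_entropy_area_percent()`, `detect_hrf()`): the
  percentage of entropy signal per unit RPE area within 1500 µm of the
  fovea, and automated hyperreflective-foci / entropy-dot / overlap counts.
- **Longitudinal statistics** (`friedman_test()`,
  `paired_tests_bonferroni()`, `pearson_corr()`, `longitudinal_stats()`):
  Friedman rank test, Bonferroni-adjusted baseline contrasts with
  complete-case dropout handling, and change-rate correlations.
- **A synthetic layered-eye phantom** (`phantom_spec()`,
  `generate_phantom()`, `longitudinal_series()`) with analytically known
  per-layer entropy (`expected_entropy()`), foveal pit, sector edema,
  seeded HRF, and sector-confined longitudinal treatment effects — the
  validation stand-in for patient data.

`run_config()` / `run_pipeline()` chain everything for one eye and export
CSV tables, TIFF/PNG maps and a run log.

## Worked example

```r
library(polent)

# a small synthetic eye: 48 x 48 A-scans over 6 x 6 mm, RPE depolarization 0.6
spec <- phantom_spec(nz = 96, n_ascans = 48, n_bscans = 48,
                     ilm_depth_um = 120, retina_thickness_um = 160,
                     pit_depth_um = 50, choroid_thickness_um = 80,
                     snr_db = 30, seed = 42)
ph <- generate_phantom(spec)
ph$truth
#> <phantom_truth> fovea (24, 24), layer H: retina 0.068 rpe 0.853 choroid 0.563, 0 HRF

an <- analyze_jones_volume(ph$jones,
                           background_rows = ph$truth$background_rows)
an$entropy
#> <entropy_volume> 96 x 48 x 48 px, kernel 3x3, sigma2 0.00025
#>   valid 61.5%, H in [0.000, 0.944], mean 0.279

grid <- etdrs_grid(an$fovea, ph$jones$lateral_pitch_um, "OD", c(48, 48))
sector_means(an$maps$rpe, grid, sectors = c("C", "TI", "NO"))
#> # A tibble: 4 × 3
#>   sector      mean n_valid
#>   <chr>      <dbl>   <int>
#> 1 C          0.696      45
#> 2 TI         0.705      92
#> 3 NO         0.693     330
#> 4 whole_grid 0.700    1789

expected_entropy(0.6)  # closed-form layer entropy at d = 0.6
#> [1] 0.8530038
```

Reading the output: the generator placed a three-layer eye whose RPE mixing
parameter 0.6 corresponds to a true entropy of 0.853. The pipeline estimated
noise from the vitreous, computed entropy with the default 3×3 kernel,
segmented the surfaces, located the fovea at the true pit center, and
averaged the 6 px RPE slab into sector means around 0.70. The gap to 0.853
is the documented small-kernel estimation bias (a 9-sample eigenvalue
spectrum is dispersed, compressing high entropies); it is monotone in the
true value, and quantitative recovery within 0.03 is achieved with
~81-sample kernels (see the methods vignette). `plot_enface(an$maps$rpe,
grid)` and `plot_bscan(an, 24, "overlay")` draw the standard displays.

A longitudinal cohort is one call per eye:

```r
ser <- longitudinal_series(spec, irradiated_sectors = "TI",
                           d_rpe_schedule = c(0.6, 0.45, 0.35, 0.3, 0.3))
```

and `longitudinal_stats()` on the combined sector tables yields the
Friedman test and Bonferroni-adjusted baseline contrasts per layer and
scope.

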