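# mitomorph

Nanoscale morphometry and functional-state analysis of mitochondria and
mitochondrial-derived structures (MDSs) in STED-resolution images of
neuronal processes — for microscopists and image analysts quantifying
outer-membrane-labeled organelles at 20–30 nm pixel sizes.

STED imaging of an outer mitochondrial membrane (OMM) label shows each
organelle as a hollow outline: a cross-section through a tubule has two
membrane peaks whose distance is the tube width. `mitomorph` turns such
images into per-object statistics:

* **Segmentation** — global (triangle-rule) or local Bernsen
  binarization, morphological refinement that strips the PSF halo, soma
  exclusion.
* **Morphometry** — per object: area *A*; ellipse length/width/angle from
  second moments; skeleton branch length; the selected length *L*
  (ellipse for *A* < 0.2 µm², else the longer of ellipse and skeleton);
  classification as MDS iff *A* < *A*<sub>th</sub> = 0.086 µm²; aspect
  ratio AR = *W*/*L* with vesicles at AR ∈ [0.5, 1] and sticks below.
* **Widths** — three perpendicular 0.75-µm line profiles per object
  (center + both ends, 5-px average); a Gaussian decision tree: one peak →
  single-Gaussian FWHM = 2√(2 ln 2)·σ, two peaks → double-Gaussian center
  distance, 3–4 peaks → side-by-side flag, > 4 peaks or R² < 0.80 →
  rejected. Center width *W*<sub>m</sub>, outer width *W*<sub>o</sub>, and
  *W*<sub>o</sub>/*W*<sub>m</sub> per object.
* **Functional calls** — per-image histograms of per-object mean channel
  intensity fitted with *a*·e<sup>−bx</sup> + *A*·e<sup>−(x−µ)²/2σ²</sup>
  (exponential background + Gaussian signal); the valley of the fitted
  curve is the +/− threshold; Otsu fallback when bimodality fails.
* **Spatial statistics** — neurite process length from background
  fluorescence (triangle threshold → remove < 20 px → dilate ×20 → erode
  ×15 → largest component → skeleton) and number densities per µm;
  pulse-chase refreshment ratio Σ<sub>new</sub>/(Σ<sub>old</sub>+Σ<sub>new</sub>)
  in concentric 30-µm rings from the soma edge; protrusion tip/side
  classification by the quarters rule with marker calls against
  background + 2 SD; contact-site linear densities.
* **Synthetic fields** — a generator that renders hollow-membrane capsules
  along simulated neurites with full ground truth (geometry, classes,
  functional states, turnover ratios, protrusion anchors), used by every
  validation test.

## Worked example

```r
library(mitomorph)

cfg   <- sim_config(n_mitochondria = 15, n_mds = 10, seed = 31)
field <- generate_field(cfg)

res <- run_pipeline(list(structural = field$structural,
                         functional = field$functional,
                         soma       = field$soma_mask),
                    pixel_size_nm = cfg$pixel_size_nm, min_call_n = 20)

res$summary[c("n_mds", "n_mitochondria", "width_mode_nm", "area_median_mds")]
#> $n_mds
#> [1] 10
#> $n_mitochondria
#> [1] 15
#> $width_mode_nm
#> [1] 133
#> $area_median_mds
#> [1] 0.0272

head(res$records[, c("id", "area_um2", "length_um", "width_nm", "ar", "class", "shape")], 3)
#>   id area_um2 length_um width_nm         ar         class  shape
#> 1  1 0.152500 1.4462767 136.8523 0.09462389 mitochondrion   <NA>
#> 2  2 0.138750 1.1755192 151.1222 0.12855781 mitochondrion   <NA>
#> 3  3 0.159375 2.4936917 172.9028 0.06933607 mitochondrion   <NA>
```

All 25 planted objects are recovered and classified (10 MDSs, 15
mitochondria). `width_nm` is the fitted center width from the profile
decision tree — the cohort mode of 133 nm reflects the generator's
~140 nm planted width mode measured through the full pipeline. `ar` is
width over selected length: elongated mitochondria score ≈ 0.1, round
MDS vesicles ≈ 0.95 and are classed accordingly. `res$calls` holds the
per-object +/− table against the per-image fitted threshold.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | render the default noisy field + ground-truth bundle |
| `02_segment_morphometry.R` | masks, labeling, morphometry tables |
| `03_width_calibration.R` | width recovery vs planted widths, FWHM overestimate below the resolution limit |
| `04_functional_calls.R` | per-image threshold fit and +/− call table |
| `05_spatial_turnover.R` | process density, 30-µm turnover rings, protrusion classes |

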