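# comboloc

Single-molecule localization microscopy (SMLM/SPDM) analysis for
COMBO-FISH-labelled ALU repeats combined with heterochromatin
immunostaining. The package covers the full computational pipeline from raw
blinking-fluorophore image stacks to nanoscale chromatin statistics:

* **Localization** — spot detection (peak ≥ 4× background, square ROI,
  2× background subtraction) and moment-based sub-pixel position
  estimation. For an ROI with background-subtracted pixel intensities
  *qᵢ* at positions *xᵢ* and per-pixel background *N_B*:

  *Q* = Σ *qᵢ*,  *μ* = Σ *qᵢ xᵢ* / *Q*,  *σ²* = Σ *qᵢ* (*xᵢ* − *μ*)² / *Q*,

  Δ*μₓ* = √( 1/(12*Q*) + Σ ((*xᵢ* − *μₓ*)/*Q*)² (*qᵢ* + *N_B*) )

  evaluated per axis in pixel units and scaled to nm.
* **Rendering** — pointillist (binary), neighbourhood-density (radius *R*,
  Gaussian σ) and standard localization images (per-point precision as σ).
* **Cluster analysis** — DBSCAN (default radius 100 nm, minimum 10 points)
  to find ALU-dense clusters; cluster centres via the Surveyor's
  (shoelace) formula on the convex hull; heterochromatin density profiled
  in concentric 10-nm shells around the centres, in points/nm²; two-channel
  nearest-neighbour colocalization fractions.
* **Probe design** — exact k-mer scanning of genomes (both strands),
  500-kb bin density maps, annotation specificity scores, and ranking of
  all k-mers of the ~300-bp ALU consensus; the reference 17-mer
  `TAATCCCAGCACTTTGG` is built in (`alu_probe()`).
* **Dosimetry** — the quadratic dose-effect calibration
  *N*(*D*) = a·*D*² + b·*D* + c for per-nucleus ALU point counts, with
  prediction and dose inversion on the decreasing branch.
* **Synthetic data** — seeded generators for blinking-emitter stacks,
  two-channel nuclei (Neyman–Scott ALU clusters plus an annular
  heterochromatin environment that associates with, but never enters, the
  clusters), planted-repeat genomes, and dose–response count series, all
  with ground truth.

## Worked example

```r
library(comboloc)

# a synthetic nucleus: 200 planted ALU clusters + annular heterochromatin
nuc <- generate_nucleus(nucleus_model(seed = 42))
res <- find_clusters(nuc$points[nuc$points$channel == "alu", ],
                     radius_nm = 100, min_points = 10)
nrow(res$clusters)
#> [1] 200

prof <- mean_shell_profile(res$clusters,
                           nuc$points[nuc$points$channel == "het", ],
                           shell_width_nm = 10, max_radius_nm = 400)
prof[c(5, 15, 35), ]
#>   shell_inner_nm shell_outer_nm count density_per_nm2
#> 1             40             50  0           0
#> 2            140            150  5.46        0.000599
#> 3            340            350  5.19        0.000239
```

The profile shows the planted structure the analysis is built to detect:
no heterochromatin inside the cluster core (0–100 nm), a 3× elevated
density band at 100–300 nm, and the background level beyond.

```r
counts <- generate_dose_series(seed = 42)   # 35 cells per dose, 0-2 Gy
fit <- fit_dose_response(counts)
fit
#> Quadratic dose-effect fit N(D) = a D^2 + b D + c (per_dose_mean)
#>   a = 3137.5, b = -11690.1, c = 21441, rss = 6461.33
#>   doses (Gy): 0, 0.1, 0.5, 1, 2

estimate_dose(fit, 15000)
#> [1] 0.672
```

The fitted coefficients recover the generating calibration curve
(a = 3054, b = −11480, c = 21390) within the sampling noise of 35 cells
per dose, and the inversion reads a dose in Gy off an observed
per-nucleus count.

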