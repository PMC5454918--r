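---
title: "comboloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{comboloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboloc)
```

This vignette explains the models behind each stage of the package, the
parameters that matter, the numerical conventions, and the places where
the design was genuinely open and a choice had to be made.

## Localization model

SPDM-type localization microscopy acquires thousands of frames in which
only a few fluorophores are "on" at a time (reversible photobleaching
produces stochastic blinking). Each blink images to a diffraction-limited
spot. The localizer processes a stack frame by frame:

1. **Background.** A per-frame scalar background is estimated as the
   median pixel intensity. The median is parameter-free and unaffected by
   the tiny fraction of pixels occupied by spots; the imaging model the
   generator uses (Poisson background plus isolated PSFs) is exactly the
   regime where this is adequate.
2. **Spot detection.** A candidate is a local intensity maximum at least
   four times the background whose square ROI (default side 7 pixels)
   fits inside the frame. Four-times-background is the classical
   registration threshold for this microscopy mode; the ROI side is
   chosen so that a PSF of σ ≈ 1 pixel fits within ±3σ. When two
   candidates are closer than one ROI side along both axes, only the
   brighter is kept — one PSF must not be counted twice.
3. **Moment estimation.** Twice the background is subtracted from every
   ROI pixel (clamped at zero: intensities are counts) and the photon sum
   Q, intensity-weighted centroid μ and variance σ² are computed from
   pixel centres. The localization precision per axis is

   Δμ = sqrt( 1/(12Q) + Σ ((xᵢ − μ)/Q)² (qᵢ + N_B) )

   in pixel units, scaled by the pixel size. The first term is the usual
   pixelation variance a²/(12Q); the second propagates shot noise of the
   signal plus background through the centroid sum. N_B is the per-pixel
   background *before* the 2× subtraction — the subtraction removes the
   background's mean, not its noise. The grouping of this expression is a
   deliberate reading of the standard centroid-precision error
   propagation; it is fixed here as the package's definition and verified
   in the tests against a literal double-loop evaluation of the sums, and
   against the worked one-dimensional example (Q = 4, μ = 0.75,
   σ² = 0.1875, Δμ ≈ 0.2602).

Coordinates follow the raster convention: pixel (row r, column c),
1-based, has its centre at ((c − 0.5)·p, (r − 0.5)·p) for pixel size p,
origin at the top-left frame corner, x along columns. The default camera
pixel size is 100 nm and is always explicit in the API.

Out of scope by design: iterative Gaussian MLE fitting, drift correction,
multi-emitter deconvolution and 3D localization. Moment estimation is
slightly biased toward the ROI centre for emitters off the peak pixel;
with ≥ 500 photons per blink this bias is well inside the reported
precision, which is what the round-trip test checks (≥ 90% of planted
blinks recovered within 3Δμ on a 2000-frame stack at peak-to-background
≥ 4).

## Rendering

Three visualizations are produced from the localization table. The
pointillist image is binary with half-open pixel binning. The density
image assigns every point the number of further points within a radius R
(defaults R = 1000 nm, output pixel 10 nm, σ = 50 nm) and renders each
point with count k > 0 as a Gaussian weighted by k; isolated points
vanish, which is the feature that suppresses background and emphasizes
contiguous structure. Whether the count should scale the Gaussian's
amplitude or its integral is not fixed by the verbal description;
**integral scaling** was chosen so that image mass equals total
neighbour count and profiles remain comparable across σ. The
localization image uses each point's own precision as its Gaussian σ, so
the discrete image integral approximates the number of points. Gaussians
are truncated at 4σ (relative mass error < 1e-4) and integrated exactly
over pixels via normal CDF differences rather than sampled at pixel
centres, which keeps the unit-integral property at any pixel size.

## DBSCAN clustering and shell profiles

A localization is a *cluster-point* (core point) when at least
`min_points` localizations lie within `radius_nm` of it, **counting the
point itself** — the convention of the DBSCAN literature, and the one
that makes a tight blob of exactly 10 points a cluster at the default
(100 nm, 10). Core points within the radius of each other share a
cluster; non-core points within the radius of a core point join that
core's cluster as border points. Ties (a border point in reach of two
clusters) go to the cluster of its first core neighbour in row order, so
labels are deterministic. Clusters are numbered by their smallest core
row index. The implementation uses cell-binned fixed-radius neighbour
search plus graph components; the test suite holds it equal to a naive
O(n²) density-reachability reference on hundreds of random mixed fields.

Cluster centres use the Surveyor's (shoelace) centroid of the **convex
hull** of the member points. The hull is the canonical simple polygon of
an unordered point set; the shoelace centroid of that polygon is
area-weighted and thus insensitive to how densely the interior is
sampled. Collinear or < 3-point clusters fall back to the arithmetic
mean. The centroid is invariant to member order and frame rotation to
floating-point accuracy.

Shell profiles count target points (typically the heterochromatin
channel) in concentric half-open annuli [k·w, (k+1)·w) around a centre
and divide by the annulus area, giving points/nm². Defaults: w = 10 nm,
maximum radius 1000 nm. Half-open intervals count every target exactly
once, so shell counts sum to the points within the maximum radius. For
many clusters, `mean_shell_profile()` averages per-cluster densities
arithmetically (each cluster weighted equally, the reading used for
per-cell mean curves); a pooled mode (count-weighted) is exposed because
pooling over all clusters of all cells is the other defensible order of
averaging when combining dose groups — the two differ only when cluster
environments vary strongly.

Colocalization between channels is measured as the fraction of points of
one set whose nearest neighbour in the other lies within a threshold; it
is reported per direction since the measure is asymmetric. No
significance testing (Ripley's K, pair correlation) is attempted.

All distances are Euclidean in the 2D projection; the data model treats
an optical section of a few hundred nm as a plane and makes no 3D
correction.

## Probe design

A COMBO-FISH probe is a k-mer (default k = 17) of the ~300-bp ALU
consensus that should occur as often as possible genome-wide but only
inside annotated ALU elements. `scan_kmer()` reports every exact,
possibly overlapping occurrence; the default strand policy is **both** —
the probe hybridizes wherever either orientation of its sequence occurs —
with minus-strand hits recorded at the forward coordinate of the site.
Coordinates are 0-based half-open (BED convention) throughout. N never
matches; soft-masked lowercase matches by default (masking is annotation,
not absence) and can be excluded by converting masked bases to N on
input. Specificity is the fraction of hits fully contained in an
annotation interval — full containment, not partial overlap, because a
probe straddling an element boundary hybridizes to a site that is not the
element. Element coverage is the fraction of annotation intervals holding
at least one contained hit. `design_probe()` ranks all consensus k-mers:
candidates at or above the specificity floor (default 0.99) first, then
by hit count, ties by consensus offset.

The published genome-wide totals for the reference probe are
assembly-version-dependent and need a multi-gigabase download, so they
are not part of the automated tests; `scripts/probe_hg_comparison.R`
documents the offline comparison. The automated checks instead use
planted-copy genomes with exact ground truth and a naive sliding-window
oracle up to 1 Mb.

## Dosimetry

Per-nucleus ALU point counts decrease with dose; the calibration model is
N(D) = a·D² + b·D + c, fitted by unweighted ordinary least squares on the
per-dose mean counts (a per-cell fit is exposed; the per-dose-mean fit is
the default because dose groups may have unequal cell numbers and the
calibration is defined on group means). No sign or monotonicity
constraint is imposed on the coefficients. Three distinct noiseless dose
means are interpolated exactly, which the tests exploit: evaluating the
reference coefficients (a = 3054, b = −11480, c = 21390) on the design
{0, 0.1, 0.5, 1, 2} Gy and refitting returns them to 1e-6 relative.
Dose estimation inverts the quadratic on its calibrated decreasing branch
[0, −b/(2a)] (capped at the largest calibrated dose); counts unattainable
on that branch raise an out-of-calibration error rather than
extrapolating.

## What the generators emulate — and what they do not

* **Stacks.** Bernoulli blinking (one ON probability per frame), Poisson
  photon statistics, Gaussian PSF integrated over pixels, Poisson
  background. Not modelled: triplet-state kinetics, irreversible
  bleaching over the acquisition, EMCCD gain noise, drift. Defaults:
  2000 frames, 1000 photons/blink, background 10 counts/pixel, PSF σ
  100 nm — a peak-to-background ratio of ~15, safely above the
  4× detection threshold.
* **Nuclei.** The ALU channel is a Neyman–Scott process: 200 parent
  centres uniform in a 7000-nm-radius nucleus (a typical ~14-µm
  epithelial tumour-cell nucleus), each with 10 + Poisson(10) offspring
  scattered with σ = 40 nm, plus 5% uniform noise, plus 10-nm
  localization jitter on every point. Parents keep a 500-nm hard-core
  separation and a 300-nm edge margin: the model describes *well
  separated* clusters, and without a hard core ~200 unconstrained
  parents in a nucleus would merge dozens of pairs under a 100-nm
  clustering radius, which would test parent placement, not cluster
  detection. The heterochromatin channel is an exact inhomogeneous
  Poisson construction: uniform background (2e-4 points/nm²), zero
  within 100 nm of any centre, 3× elevated in the 100–300-nm annulus
  (ratios below 1 model post-irradiation de-compaction by thinning the
  band). Annuli of distinct clusters may overlap slightly; cores cannot
  (the hard core exceeds inner + outer radius of adjacent cores). Real
  nuclei have chromatin territories, nuclear lamina structure, and
  spatially varying labelling efficiency — none of which is modelled, so
  a green cluster-recovery test says the *algorithm* is calibrated on the
  stated geometry, not that real nuclei contain exactly 200 clusters.
* **Genomes.** I.i.d. background bases with uniform composition and
  non-overlapping consensus copies placed by the spacing construction
  (uniform conditional on no overlap), each independently mutated per
  site. Real repeat landscapes have families, fragments and GC structure;
  the generator provides exact ground truth instead.
* **Dose series.** Counts are round(N(D) + Gaussian noise), floored at
  zero, 35 cells per dose at {0, 0.1, 0.5, 1, 2} Gy with σ = 500 counts;
  a Poisson option exists. The decrease is modelled purely as count
  thinning — the generator takes no position on its mechanism.

## Numerical choices and degenerate inputs

* Post-subtraction ROI pixels are clamped at 0; an all-zero ROI is an
  error (zero total intensity has no centroid).
* Empty point sets render to all-zero images; an empty localization file
  with a valid header is an empty set, not an error; malformed rows are
  rejected with their physical line numbers.
* Shell and pixel bins are half-open everywhere, so boundary points are
  counted exactly once and a hit exactly on a 500-kb boundary falls in
  the following bin.
* DBSCAN noise is label 0; determinism is part of the contract (fixed
  input → identical labels, images, tables).
* Quadratic inversion treats |a| < 1e-12 as linear.
* All generators accept a seed and are bit-reproducible; the pipeline
  manifest records config and input digests so identical runs produce
  identical outputs.

## Problem sizes used in the automated checks

The suite calibrates its simulations to desk scale: 20 default nuclei
(~4200 ALU + ~50000 heterochromatin points each) for cluster-count
calibration; 200 random fields up to n = 1000 for the DBSCAN oracle;
1000 random ROIs for the moment-formula oracle; one 2000-frame 64×64
stack for the localization round trip; ~130000 CSR points over 400
centres for shell-profile flatness; 1-Mb genomes for the scanning oracle.
These sizes give the statistical headroom the assertions need (for
example, the flatness bound sits > 3 standard errors above the sampling
noise of the innermost shell) while keeping a full run in the minutes
range.

## Known limitations

* Moment localization is not maximum-likelihood; at very low photon
  counts its precision is worse than the Cramér–Rao bound and the
  reported Δμ underestimates the error of truncation-biased estimates.
* DBSCAN cluster counts depend on (radius, min_points) jointly with the
  true cluster geometry; the defaults are a calibration choice, not a
  biological constant.
* The shell profile attributes all density around a centre to that
  centre; overlapping annuli of nearby clusters are not deconvolved.
* Probe scoring is purely combinatorial — no melting temperature, ΔG, or
  secondary-structure screening.
* Dose inversion assumes the observed count comes from the calibrated
  cell system and acquisition efficiency; the calibration constants are
  not transferable across protocols.
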