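---
title: "Methods: dSTORM movie reconstruction, KDE segmentation and EV boundary colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dSTORM movie reconstruction, KDE segmentation and EV boundary colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcoloc)
```

# The problem

Extracellular vesicles (EVs) bind extracellular-matrix (ECM) fibrils —
laminin, fibronectin, collagen — on living cell surfaces. Both partners
move on the seconds time scale, so the question "is this EV at an ECM
structure?" needs a super-resolved, *time-resolved* picture of the ECM
channel and a statistic that is honest about chance colocalization.
`evcoloc` implements that analysis chain and a synthetic ground-truth
generator that exercises every stage.

# Model and procedure

## Existence-probability maps

Each single-molecule localization $i$ carries coordinates $(x_i, y_i)$ and
an uncertainty $u_i$ (nm), the per-spot precision estimate reported by
localization software. The spot's *existence probability* is modeled as an
isotropic Gaussian kernel centered at $(x_i, y_i)$ with SD $A u_i$; the
window's map is the average of its $N$ unit-mass kernels, optionally mixed
with a background term:

$$p(x,y) \;=\; \alpha \frac{1}{N}\sum_{i=1}^{N}
  \frac{1}{2\pi (A u_i)^2}
  e^{-\frac{(x-x_i)^2+(y-y_i)^2}{2 (A u_i)^2}}
  \;+\; (1-\alpha)\, p_{bg}(x,y).$$

Assumptions: localizations inside a structure occur with spatially uniform
probability, localization errors are isotropic Gaussian with the reported
per-spot SD, and the scale factor $A$ absorbs the mismatch between nominal
uncertainty and the effective spread of repeated blinking of boundary
fluorophores.

## Sliding windows and synchronization

Windows of $W$ frames advance by $S$ frames; window $k$ covers frames
$[1+(k-1)S,\; (k-1)S + W]$ and the number of windows is
$\lfloor (T-W)/S \rfloor$. For $T = 3504$, $W = 1002$, $S = 6$ this gives
417 reconstructed images. Note the deliberate convention: the enumeration
"every start $1+kS$ whose window fits" would give 418; the floor form
reproduces the published 417 and pairs one window with one averaged
particle-movie frame, so we drop the final fittable window rather than
guess a different intent.

The particle channel is converted to the movie rate by averaging
*non-overlapping* blocks of $S$ original frames (200 → 33.3 frames/s for
$S=6$); window $k$ is paired with the averaged frame whose center original
frame is nearest the window's middle frame, ties to the earlier frame.
With block averaging the pairing advances by exactly one averaged frame
per window, which is the property that makes a synchronized two-channel
movie possible; `sync_index()` refuses `avg_block != S` for that reason.
(A *rolling* 6-frame average would advance six averaged frames per window
and could not stay aligned; `rolling_average()` is still provided for the
counting assay, which specifies a sliding 10-frame average.)

## Segmentation

A structure exists where $p(x,y) \ge \theta$. The threshold is Otsu's: let
$S_{in} = \{p \ge \theta\}$, $S_{out} = \{p < \theta\}$ with sizes
$N_{in}, N_{out}$ and population variances $\sigma^2[S_{in}],
\sigma^2[S_{out}]$; $\hat\theta$ minimizes

$$\sigma^2[S_{in}, S_{out}] =
  \frac{N_{in}\sigma^2[S_{in}] + N_{out}\sigma^2[S_{out}]}
       {N_{in}+N_{out}},$$

equivalently maximizes the between-class variance (the classical
total-variance decomposition; both argmins agree, and the suite asserts
this on random maps). One threshold is computed per movie from the pooled
values of all windows, then applied to every frame.

Contours are traced by marching squares at level 0.5 on the binary grid,
giving sub-pixel polylines — necessary for 50-nm distance bins to be
meaningful on a 10-nm raster.

## The colocalization statistic

For each window and each tracked particle present at the synchronized
frame, the signed distance to the nearest contour segment is recorded,
negative when the particle's containing pixel is in-structure. Distances
are binned at 50 nm (half-open bins $[lo, hi)$, default range
$-300\ldots600$ nm). The *normalized relative frequency* is the per-bin
ratio of the observed relative frequency to that of uniformly random
spots (`n_per_window` = 1000 by default) subjected to the identical
distance measurement; a ratio above 1 means enrichment at that distance
from the edge. The percentile bootstrap CI (default 95%, 1000 resamples)
resamples the observed records with replacement against the fixed null —
the null's own Monte-Carlo noise is excluded by construction, which is
conservative for detecting enrichment but means null-vs-null coverage is
below nominal; consistency of the null itself is checked separately by
doubling its size. Bins with zero null frequency are flagged undefined
(`NA`), never silently zero. Distances are pooled across windows before
binning; per-window histograms can be formed by splitting the distance
table on `window` if a per-window average is preferred.

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `A` | 6 | — | kernel SD per unit uncertainty |
| `pixel` | 10 | nm | reconstruction raster |
| `W`, `S` | 1002, 6 | frames | window length and step |
| `u_min`, `u_max` | 2, 100 | nm | uncertainty filter |
| `truncation_radius` | 4 | kernel SDs | per-axis kernel cutoff |
| `alpha` | 1 | — | spot/background mixture weight |
| `display_sigma` | 24 | nm | display rendering only |
| bin width | 50 | nm | distance histogram |
| `n_per_window` | 1000 | spots | null model size |
| `max_disp` | 500 | nm | linking gate per step |
| `avg_n` (counting) | 10 | frames | counting preprocess |

The uncertainty filter bounds are configurable and logged because the
source procedure excludes "extremely small or large" uncertainties without
stating numbers; [2, 100] nm discards sub-nanometer artifacts and spots
worse than the diffraction limit. `alpha = 1` is the default because no
estimator for the background weight or its moments is specified; the
mixture (constant or per-pixel sampled background) is implemented and
exposed for sensitivity analysis.

# Numerical choices

- **Kernel evaluation**: at pixel centers, not integrated over pixels. At
  10-nm pixels against kernel SDs of ≥ 24 nm the difference is far below
  other error sources, and the brute-force oracle in the tests uses the
  same rule so the equivalence check is exact.
- **Truncation**: per-axis at 4 SD (a box, not a disk, so the separable
  accumulation and the naive double loop agree bit-for-bit). Mass error
  per kernel < 1.4e-4; the single-kernel map mass is asserted within 1e-3
  of 1. Kernels clipped by the field edge are *not* renormalized.
- **Otsu candidates**: 256 equally spaced values spanning [min, max] of
  the pooled values; ties break to the smallest threshold. The in-class
  comparison is $\ge \theta$ so a two-valued map is classifiable. Constant
  input raises a `DegenerateHistogram` error rather than returning an
  arbitrary threshold. Pooled values above 2e7 are stride-subsampled;
  below that cap the pooled computation is exact.
- **Binarization** uses $\ge$, matching the threshold search.
- **Marching squares**: the base contouring routine on a zero-padded grid,
  so every contour closes, including structures touching the field edge.
  A single in-structure pixel yields the half-pixel diamond (perimeter
  $2\sqrt2 \cdot$ pixel).
- **Empty boundary sets** give `+Inf` distances with an explicit flag.
- **Rasters on disk**: TIFF stores samples scaled to [0, 1], so
  probability maps (tiny densities in nm⁻²) are written as 32-bit TIFF
  after rescaling by their maximum, with the factor in the JSON sidecar;
  round-trip error is ~2e-10 relative. Masks are 8-bit {0, 255}. The
  sidecar carries pixel size and origin and is required on read.
- **Welch's t**: the statistic and Welch–Satterthwaite degrees of freedom
  are computed directly from their definitions; the two-sided p value uses
  R's `pt()`, whose accuracy exceeds any hand-rolled incomplete-beta
  evaluation we could justify maintaining. The suite cross-checks against
  `t.test()` and a permutation Monte Carlo.
- **Seeds** are explicit arguments everywhere; generators save and restore
  the global RNG state, and per-window/per-stream sub-seeds are derived
  deterministically from the user seed.

# What the synthetic generator emulates — and what it does not

`filament_scene()` produces random-walk polyline fibrils with a fixed
half-width; `blink_model()` turns them into localization tables with
per-length Poisson blinking (default 0.03 µm⁻¹ frame⁻¹ per filament
micron, chosen so a 1,002-frame window accumulates a few hundred
localizations per structure — a realistic sparse-blinking regime),
lognormal per-spot uncertainties (median 20 nm, geometric SD 1.4, a
typical SMLM precision scale) and uniform false localizations (5e-4 µm⁻²
frame⁻¹). `simulate_tracks()` plants a chosen fraction of EVs within
±50 nm of a filament boundary (slow diffusion, D = 0.002 µm²/s, with
rejection of excursions out of the band) while the rest diffuse freely
(D = 0.2 µm²/s) with reflecting field edges. `render_spot_stack()` draws
pixel-integrated Gaussian PSFs with constant background, Gaussian read
noise, and sub-threshold free-dye spots at 30% of the particle intensity
so the free-dye threshold is genuinely exercised.

Not emulated: PSF astigmatism and defocus, EMCCD/sCMOS gain statistics,
stage drift, fluorophore photophysics beyond per-frame Poisson blinking,
and chromatic offsets between channels. Passing tests therefore show the
*analysis* recovers what the model plants; they do not certify performance
under drift or strongly non-Gaussian noise, which real acquisitions must
control upstream.

# Design choices on open points

- **Transverse blinking profile**: uniform across the filament width —
  the simplest testable choice consistent with "spots appear uniformly
  inside the structures".
- **Null-model region**: the full reconstructed field by default, with an
  optional mask ROI, since it is unstated whether random spots were
  confined to the cell footprint.
- **Linking**: greedy ascending-distance nearest-neighbor assignment with
  gap closing (≤ 2 frames). The original tracker is unpublished in
  detail; greedy matching is transparent and, at the particle densities
  of these assays (tests show ≥ 95% identity agreement at 20 particles
  per 400 µm²), adequate. No motion model is fitted.
- **Detection threshold**: an absolute intensity, supplied as the measured
  free-dye brightness, because the source protocol measures free dye but
  does not state a multiplier.
- **Calibration**: proportional through the origin (`count = a/df`), as
  the dilution series shows counts tracking 1/df with no intercept.
- **Minimum structure size**: no size filter is applied to segmented
  structures (none is described); the segmentation output is what the
  threshold gives.

# Known limitations

- **Boundary bias of order the kernel SD.** With median uncertainty 20 nm
  and $A=6$, kernels have ~120-nm SD. Structures narrower than the kernel
  are dilated by tens of nm at the Otsu threshold; filament *ends* are
  rounded by about one kernel SD, and *crossings* are blurred into blobs
  whose boundary can sit 100–200 nm from the true edges. The planted-bound
  recovery tests therefore use well-separated long fibrils (pairwise
  > 0.9 µm apart): that is the regime in which a boundary-distance
  statistic is interpretable. Enrichment detection itself (ratio > 1 at
  the edge, monotone in the bound fraction) is robust to these artifacts.
- The normalized frequency pools all windows; temporal correlation of a
  single particle across overlapping windows inflates the effective n of
  the bootstrap CI slightly.
- No drift correction, channel registration, 3-D reconstruction or
  duplicate-localization merging is performed.

# Problem sizes used by the test and acceptance suites

The suites favor small fields so the whole chain stays fast while every
stage runs at realistic per-µm statistics: scenes of 3–4 fibrils in
6.4–9.6 µm fields (640–960 px at 10 nm), movies of 8–20 windows of 300
frames (the full 1,002-frame window is exercised where the published
counts matter), 40–60 particles, nulls of 1,000–5,000 spots per window,
and counting fields of 256² pixels at 80 nm with 50 emitters over 200
free-dye spots per frame. The acceptance script reports each quantity
with the problem size it used.
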