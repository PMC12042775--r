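# evcoloc

Quantitative single-molecule imaging of extracellular vesicle (EV) binding
to extracellular-matrix (ECM) structures.

Small EVs (sEVs, ~30–150 nm vesicles) bind ECM components such as laminin
on the surface of recipient cells. Observing that interaction on a *living*
cell requires super-resolving the ECM structures while they move: `evcoloc`
implements the pseudo real-time "dSTORM movie" approach — sliding-window
reconstruction of super-resolution images from single-molecule localization
tables — together with kernel-density segmentation of the reconstructed
structures, single-particle tracking of the EV channel, and a signed
boundary-distance colocalization statistic calibrated against a random-spot
null model. It also covers the companion single-particle binding assay:
frame-averaged spot counting above a free-dye threshold, casein background
subtraction, dilution-series calibration of particle concentrations, and a
two-channel antibody colocalization ratio. A synthetic-data generator with
known ground truth (filament scenes, blinking localizations, diffusing or
boundary-bound EV tracks, rendered camera frames) makes every stage
testable end to end.

It is intended for microscopists and image analysts working with
ThunderSTORM-style localization CSVs and TIRFM image stacks.

## The method

**Reconstruction.** Each localization *i* (coordinates x_i, y_i, per-spot
uncertainty u_i in nm) contributes a Gaussian *existence probability*
kernel with SD `A·u_i` (default A = 6, an empirically estimated scale).
The map for one window is the average of its N unit-mass kernels,
optionally mixed with a background term:

    p(x, y) = α · (1/N) Σᵢ N((xᵢ, yᵢ), (A·uᵢ)² I)(x, y) + (1 − α) · p_bg

evaluated at the centers of 10-nm pixels. Windows of W = 1,002 frames
advance by S = 6 frames, so a 3,504-frame acquisition at 200 frames/s
yields 417 reconstructed images — a super-resolution movie at the same
33.3 frames/s as the block-averaged EV particle channel, with which it is
synchronized window-middle-frame to averaged-frame.

**Segmentation.** One threshold per movie is chosen by Otsu's criterion on
the pooled map values: θ̂ minimizes the count-weighted average of the two
intraclass variances of {p ≥ θ} and {p < θ}. Sub-pixel structure contours
are extracted from the binary masks by marching squares at level 0.5.

**Colocalization statistic.** For every reconstruction window and every
tracked EV present at the synchronized frame, the signed distance from the
EV centroid to the nearest structure contour is recorded (negative inside
the structure). Distances are binned at 50 nm and the per-bin relative
frequency is divided by that of uniformly random computer-generated spots:
a *normalized relative frequency* above 1 indicates enrichment at that
distance from the structure edge. Percentile-bootstrap confidence
intervals come from resampling the observed records.

**Binding assay.** Counting fields are preprocessed by a 10-frame average
and 3×3 smoothing; spots brighter than a free-dye molecule are counted;
specific binding subtracts the casein-coated control; counts scale as
`a / df` with dilution factor df, giving a calibration line used to
standardize concentrations.

## Worked example

Simulate a scene of three laminin-like fibrils, reconstruct and segment a
10-window movie, track 60 EVs of which half are bound at the fibril
boundaries, and compute the normalized relative frequency:

```r
library(evcoloc)

scene <- filament_scene(3, field = c(9600, 9600), half_width = 200,
                        curvature = 0.08, length = 9000, seed = 45)
locs <- sample_localizations(scene, blink_model(per_frame_density = 0.5),
                             n_frames = 360, seed = 11)
scheme <- window_scheme(T = 360, W = 300, S = 6)
movie  <- build_movie(locs, scheme, render_params(), field = scene$field)
seg    <- segment_movie(movie)
bounds <- lapply(seg$masks, extract_boundaries)
sync   <- sync_index(scheme)

tracks <- simulate_tracks(scene, n_particles = 60, fraction_bound = 0.5,
                          n_frames = max(sync), dt = 0.03, seed = 12)
obs  <- distance_histogram(pair_distances(tracks, seg$masks, bounds, sync))
null <- distance_histogram(null_distances(seg$masks, bounds,
                                          n_per_window = 2000, seed = 13))
nf <- normalize_frequency(obs, null, seed = 14)
subset(as.data.frame(nf), bin_lo >= -100 & bin_lo < 150)
```

This prints (among other bins):

```
 bin_lo bin_hi obs_freq null_freq ratio ci_lo ci_hi defined
   -100    -50  0.16710    0.0715 2.339 1.871 2.878    TRUE
    -50      0  0.30077    0.0658 4.572 3.869 5.275    TRUE
      0     50  0.25707    0.0685 3.751 3.113 4.390    TRUE
     50    100  0.05656    0.0666 0.849 0.501 1.234    TRUE
    100    150  0.00771    0.0594 0.130 0.000 0.303    TRUE
```

The bins straddling the structure edge (−50 to +50 nm) show ratios of
4.6 and 3.8 with confidence intervals excluding 1 — the planted bound
fraction is detected as enrichment at the boundary — while bins further
out fall back to or below 1 (bound particles are *at* the edge, so the
mid-distance bins are relatively depleted). `mean_enrichment(nf,
c(-100, 150))` summarizes the near-edge window (2.33 here).

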