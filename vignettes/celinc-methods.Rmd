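---
title: "Methods: quantifying light-induced protein coclustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying light-induced protein coclustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and what the package computes

In a light-induced coclustering (LINC-style) interaction assay, a bait
protein is trapped into bright optogenetic clusters — in *C. elegans*, a
GFP-binding nanobody fused to CRY2(olig) oligomerises under blue light and
drags the GFP-tagged bait with it. A second-colour (prey) protein is then
scored for recruitment into those clusters: prey signal in the bait clusters
indicates a physical interaction. The readout is object-based colocalization
on maximum projections: detect spots independently in the bait and prey
channels, pair them by distance, and report the fraction of prey spots that
cocluster with a bait spot (and the converse fraction).

Because any single detection threshold is arbitrary, the assay's statistic
re-runs detection over an intensity-threshold sweep of 1, 2, ..., 25
background SD units and plots the coclustering percentage against the
threshold. Interacting pairs show a *rising* prey-with-bait curve — as the
threshold climbs, surviving prey detections are increasingly the bright,
recruited ones sitting on bait clusters — while non-interacting pairs give
flat or rapidly decreasing curves. This package turns that qualitative,
read-by-eye criterion into a reproducible classifier, and adds the cluster
kinetics analyses that accompany the assay (decay half-life, per-cell
density, intensity/area relationships).

## Spot detection

The detector honours the parameter surface of the ImageJ plugin used in the
assay protocol (approximate particle size; intensity threshold in SD;
"include larger" / "segment larger" flags), but the algorithm is this
package's own; bit-exact agreement with the Java plugin is a non-goal. Per
channel and region of interest (ROI):

1. **Band-pass.** Difference of Gaussians with
   $\sigma_\text{small} = \max(\text{particle\_size}/4,\ 0.5)$ and
   $\sigma_\text{large} = 2 \times \text{particle\_size}$, replicate-padded
   at the borders.
2. **Robust background.** Median and MAD-derived SD of the *filtered* image
   inside the ROI. Median/MAD rather than mean/SD because the spots
   themselves contaminate moment estimates at high density. (Whether the
   original plugin thresholds raw or filtered intensities, ROI-wise or
   image-wise, is unpublished; filtered-within-ROI is this package's declared
   dialect and is echoed in output provenance.)
3. **Candidates.** Pixels with filtered value above
   $\text{median} + k \cdot \text{SD}$, 8-connected into components;
   components smaller than `min_pixels` (default 3) are discarded.
4. **Seeds.** Spots are seeded from 3×3 local maxima of the filtered image
   among candidate pixels. A maximum is suppressed when a *brighter*
   surviving maximum lies within `particle_size_px`. This design makes the
   spot count provably non-increasing in the threshold: a suppressor is
   brighter than its suppressee, so it always outlives it as the threshold
   rises, and component support can only shrink. (Counting raw connected
   components is *not* monotone — a merged blob at a low threshold splits in
   two at a higher one — which would put noise wiggles into the sweep
   statistic.)
5. **Size handling.** Components larger than
   $\pi \cdot \text{particle\_size}^2$ pixels are dropped when
   `include_larger = FALSE` (this is what vetoes gut-granule
   autofluorescence in colocalization mode), kept as their single brightest
   seed when `include_larger = TRUE, segment_larger = FALSE`, or split among
   all seeds when `segment_larger = TRUE`. The size veto is the one exception
   to monotonicity: a shrinking component can re-enter at a higher threshold.
6. **Measurement.** Component pixels are partitioned among seeds by
   proximity (ties to the brighter seed). Per spot: intensity-weighted
   centroid on the *raw* image, pixel area, local background as the median of
   a 2-px-wide annulus around the component (excluding all candidate
   pixels), and integrated intensity as the background-corrected pixel sum.

A zero-variance region returns an empty, warning-flagged table rather than
dividing by zero. Spots are ordered deterministically by centre.

## Colocalization

A bait spot coclusters iff at least one prey centre lies within
centre-to-centre Euclidean distance `max_distance_px` (default 3 px, the
protocol's value), boundary inclusive, and symmetrically for prey. The two
one-sided fractions are reported; "colocalized" is presence-within-radius,
not exclusive matching, which is what per-channel colocalized counts in the
original result tables measure. Mutual nearest-neighbour pairs are listed
for downstream intensity correlations only.

## The threshold sweep and the interaction call

For each replicate animal and threshold: detect both channels (the band-pass
and ROI statistics are computed once and reused across the sweep),
colocalize, pool multiple ROIs within an animal by a spot-count-weighted
average, and *exclude* the threshold for that animal when an image yields
fewer than `min_spots = 15` spots (default: in either channel; a prey-only
switch exists since the protocol does not name the channel). Excluded cells
are absent, never zero. Replicates aggregate into a mean curve with a
Student-t confidence band (95% default) — small-n across animals (3–7) is
the norm, so a t band is the honest choice.

The protocol's verdict criterion is curve shape read by eye; the
quantitative rule here is the package's own definition, fully parameterised
and echoed in the evidence trace:

* Theil–Sen slope of the mean prey-with-bait fraction over the *defined*
  thresholds, with a percentile bootstrap interval over replicate animals
  (`n_boot = 500`, `slope_alpha = 0.05`);
* **positive** iff the slope interval sits above 0 *and* the final-threshold
  mean fraction is at least `min_final_fraction = 0.25` *and*, when a
  GFP-only control curve is given, the final fraction exceeds the control's
  final CI upper bound;
* **negative** iff the slope interval is at or below 0 *or* the final
  fraction is under the floor;
* **indeterminate** otherwise, including when fewer than 3 thresholds are
  defined.

Two deliberate robustness choices: the floor (0.25) is a package decision —
the protocol states no numeric positivity threshold — and a threshold only
enters the call when at least `min_replicates = 2` animals contribute
(capped at the number available). The latter matters: at tail thresholds a
single animal can survive with ~15 spots dominated by granule fragments,
which appear identically in both channels and therefore "cocluster"
perfectly; gating on one animal's tail point produced exactly this false
signal in simulation. The bait-with-prey curve is computed and reported but
never used for the verdict — the prey-with-bait direction is the informative
one.

## Cluster kinetics

Counts over time are normalised by subtracting the pre-illumination count
and dividing by the post-subtraction maximum, so the series is exactly 0
before illumination and exactly 1 at peak cluster formation (ties resolve to
the earliest timepoint). Decay after the peak is modelled as first order,
$N(t) = N_0 (1/2)^{(t - t_\text{peak})/t_{1/2}}$ with $N_0$ the
baseline-subtracted peak count. Two estimators are exposed, since the
protocol prints the equation but not the fitting pathway:

* **pointwise** — solve for $t_{1/2}$ at each usable post-peak point and
  average (a single point at normalized 0.5, 34 min after the peak, gives
  exactly 34 min);
* **loglinear** (default) — least squares on $\log N$ versus time since
  peak, anchored at the peak; more robust under Poisson count noise.

They agree exactly on noiseless exponentials; post-peak points at or below
zero are skipped with a warning. Per-cell cluster density is
$10 \cdot n_\text{spots} / \text{area}_{\mu m^2}$ (spots per 10 µm²), and
the intensity/area report gives Pearson and Spearman correlations of bait
versus prey integrated intensity over coclustered pairs plus the difference
in mean pixel area between coclustered and non-coclustered bait spots.

## The synthetic world

Every stage is validated against a seeded generator whose ground truth
records each placement. The default scene is a 256×256 px field at
0.2 µm/px holding two large rectangular "intestinal" cells: uniform
cytoplasmic background (100 counts) with Gaussian read noise (sd 10); bait
clusters as isotropic 2D Gaussians (sd 1 px — a point-spread proxy
for compact puncta) placed uniformly per cell with Poisson
counts of mean `cluster_density`/100 µm² × area × expression level;
truncated-normal peak amplitudes (mean 80, sd 40) scaled by the cell's
expression level, so mosaic expression modulates both number and brightness.
Those numbers were fixed a priori so the 1–25 SD sweep spans the amplitude
distribution (the band-pass passes ≈0.61 of a spot's peak and ≈0.38 of the
read-noise sd, putting 1 SD ≈ amplitude 6 and 25 SD ≈ amplitude 156).

Prey structure carries the assay's statistical signal. Each bait cluster
recruits prey with probability $p_i$,
$\operatorname{logit}(p_i) = \operatorname{logit}(\rho) + c \cdot z_i$,
where $z_i$ is the bait amplitude standardised by the configured
distribution and $c \ge 0$ is the intensity coupling (brighter baits recruit
more — the size/intensity effect seen in the source data). Recruited prey
sit on the bait centre plus 0.5 px isotropic jitter — well inside the 3-px
pairing radius — with amplitude equal to the bait's times a tight gain
(N(1, 0.1²), reflecting the tightly correlated bait/prey intensities of
coclustered spots). Free (non-recruited) prey are placed uniformly at
`prey_free_density` with amplitudes scaled by `prey_native_scale = 0.5`:
recruited clusters carry roughly twice the signal of a prey's native
localization, and without that asymmetry the sweep has nothing to
discriminate on and positive curves do not rise. Gut-granule
autofluorescence is rendered as flat disks (radius 6 px) identically in both
channels — the confounder the size veto and the replicate gate exist for.
The decay simulator is flat at baseline before illumination, rises linearly
to the peak (the rise phase is not analysed), then decays exponentially,
with Poisson or Gaussian count noise.

What a green test does *not* establish: the generator has no photophysics
(bleaching, blinking), no 3D PSF, no camera gain model, no reaction–diffusion
cluster kinetics, and real tissue autofluorescence is neither flat nor
disk-shaped. Green means the pipeline recovers the statistical structure it
claims to measure, at realistic SNR and density — not that it reproduces any
particular published curve, which would require the original microscope
images.

## Numerical conventions and degenerate inputs

Pixel coordinates are 0-based `(y, x)` pixel centres; pixel `(i, j)` covers
`[i-0.5, i+0.5] × [j-0.5, j+0.5]`, and ROI rasterisation includes a pixel
iff its centre is inside the polygon (even-odd rule). Distances are
boundary-inclusive. Ties: peak index to the earliest timepoint, watershed
assignment to the brighter seed, seed suppression by brightness then pixel
index. Curves with every threshold excluded produce an indeterminate call
with a reason, not an error; colocalization with an empty denominator
reports an absent fraction, never 0/0. Scenes are simulated directly in 2D
(analysis operates on maximum projections); a thin z-stack wrapper with
per-slice noise exists for I/O testing only. Configuration files are JSON
(YAML accepted); verdicts are data in the outputs, never exit codes, so
batch screens of many pairs can be post-processed uniformly.

## Known limitations

Detection is 2D-only and spots are not tracked across time (kinetics uses
counts, not identities). The SD-threshold dialect (filtered-within-ROI) and
the seed-based monotone counting are documented departures from the
unpublished plugin internals. Dim granules whose above-threshold footprint
fragments below the size cutoff can escape the veto at mid thresholds; the
replicate gate in the call rule is the mitigation. The half-life estimate
assumes a single exponential after the peak; multi-phase decay will bias it.
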