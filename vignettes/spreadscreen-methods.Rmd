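---
title: "Methods: from fluorescence fields to hit lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence fields to hit lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadscreen)
```

spreadscreen implements a complete high-content screening analysis for cell
spreading and adhesion assays run in 96-well plates: cells are plated on two
substrates (an uncoated control and an inhibitory coating), incubated with
one compound per plate column, fixed, stained for nuclei and F-actin, and
imaged at 24 fields per well. The readout is the mean cytoplasm area of
*separated* cells — cells with no contact to any neighbour — because cell
aggregation distorts the spreading phenotype unpredictably. This vignette
explains each stage's model, its tunable parameters, and the design choices
made where the procedure was genuinely open.

## The synthetic study system

Every stage is exercised against synthetic data with exact ground truth, at
two levels.

**Image level** (`field_spec()`, `generate_field()`). Cells are rendered as
radially perturbed ellipses: the boundary radius is
$r(\theta) = r_0\,(1 + \sum_{k=2}^{5} a_k \cos(k\theta + \phi_k))$, with the
total perturbation amplitude drawn from 0.15–0.30 for spread cells (large,
irregular; areas 600–1500 px²) and 0–0.08 for unspread cells (small, round;
areas 200–450 px²). Each cell carries one circular nucleus (60–150 px²,
shrunk if necessary so it fits strictly inside the cell). Nuclei render
bright (~0.8) on a dim background (0.05) in the nuclear channel; whole cells
render at ~0.5 in the actin channel. A multiplicative radial falloff
(default amplitude 0.15, corners dimmest — shading physically acts
multiplicatively, so division-based correction can recover a flat field) and
additive Gaussian noise (sd 0.02) complete the image model. Non-pair cells
are placed by bounded rejection sampling with a two-pixel guard ring, so
they touch neither each other nor the image border; contact pairs are
constructed by sliding the partner along a ray from its anchor until the
masks just stop overlapping, which leaves them adjacent at Chebyshev
distance 1. The generator returns the label maps, per-cell phenotype,
contact graph and marker-positive set as exact truth.

What the generator deliberately does *not* emulate: realistic textures,
point-spread-function optics, debris and staining artifacts, clumps of more
than two cells, or out-of-focus fields. Passing tests therefore demonstrate
the correctness of the operators (thresholds, propagation, filters,
features) and of the statistical pipeline — not robustness to every failure
mode of real microscopy.

**Well level** (`plate_stack_spec()`, `generate_plate_stack()`). The
normalization and statistics modules are tested without paying segmentation
cost. Raw well values compose exactly as

> baseline × substrate × compound × positive-control multipliers
> + row + column + stack-position additive biases + Gaussian noise,

so zero-noise, zero-artifact plates reproduce the parameters identically.
Defaults mirror the assay's study conditions: 9 plates per stack, a control
baseline of 1500 µm² cytoplasm area, a coated-substrate effect of 0.5
(halved spreading), a positive control enhancing spreading (×1.5, pinned to
column 10), 2500 cells plated per well yielding about 350 separated cells,
and well noise of 40 µm² (≈2.7% CV, a realistic well-level reproducibility
for a one-hour spreading assay). Test scenarios add row/column/stack biases
and spiked compounds on top.

## Image normalization

`estimate_illumination()` averages all images of a channel, smooths the
average with a Gaussian of σ = image width / 10 (the kernel must be much
larger than any cell so object texture is removed; the σ value is a
package choice, exposed as an argument) and rescales to mean 1. Correction
divides by this gain. A single-image ensemble is allowed with a warning.

`rescale_minmax()` maps the darkest pixel to 0 and the brightest to 1; a
constant image returns zeros with a warning. `otsu_log_threshold()`
computes Otsu's between-class-variance threshold on a 256-bin histogram of
`log(1/65536 + x)` after min–max scaling; the log transform makes the split
insensitive to how much of the field is covered by cells, and the ε guard
handles zeros while keeping the threshold exactly scale-equivariant
(thresholding `k·x` yields `k·t`). The chosen boundary is mapped back to
the original intensity scale.

## Three-tier segmentation

Nuclei (primary objects) are detected by a fixed threshold on the rescaled
nuclear channel — default 0.2 of the [0, 1] range, a package default since
only "fixed thresholding" is prescribed — followed by 8-connected
labelling, hole filling, exclusion of components with equivalent diameter
outside 8–40 px (staining artifacts) and of components touching the image
border. No declumping is applied: clumped cells are removed later by the
separated-cell filter, which is the point of the assay design.

Whole cells (secondary objects) grow from the nuclear seeds by seeded
propagation over the actin foreground (log-domain Otsu threshold by
default): each foreground pixel joins the seed with the cheapest path,
where the path cost blends local intensity steps with Euclidean distance
under the regularization λ (default 0.05; λ → ∞ degenerates to a
nearest-seed Voronoi partition, λ → 0 follows intensity ridges). The
propagation uses `EBImage::propagate()`, the reference implementation of
this cost semantics. Cells touching the border are dropped together with
their nuclei, and tiers are relabelled so cell *k* contains nucleus *k*.
Cytoplasm (tertiary objects) is the exact pixel-set difference, so
`area_cell = area_nucleus + area_cytoplasm` holds identically — the
cytoplasm area is the screen's readout because the nuclear area is
unchanged between spread and unspread cells and would only dilute the
signal.

## Neighbour analysis and the separated-cell filter

Two cells are neighbours iff any pixel of one lies within Chebyshev
distance 1 of the other (strict 8-connected touching; the distance is
configurable). `percent_touching` is the fraction of an object's boundary
pixels that have a foreign object within that distance. The filter keeps
cells with `neighbor_count <= 0` and `percent_touching <= 0` by default —
only fully single cells enter the analysis — and both cutoffs are exposed.
The marker variant (`filter_marker_positive()`, for siRNA-style screens)
detects marker blobs above a manual threshold, discards punctate background
below a minimum area, and retains cells containing a marker-blob centroid;
centroid-in-cell was chosen over pixel-overlap fractions as the simplest
rule that matches an object-relating step.

## Features and the rule-based classifier

Per separated cell we record areas, perimeter, form factor ($4\pi A/P^2$),
eccentricity (moment ellipse), solidity (area over convex-hull area) and
compactness. Perimeter uses corner-corrected chain-code weights (0.948 per
axial, 1.340 per diagonal step): the naive unit/√2 walk overestimates
smooth boundaries by ~5%, which would push the form factor of an ideal disk
to ~0.91. With the correction a rasterised disk measures ~1.01, and the
form factor is capped at 1 (a discrete disk cannot be rounder than a
circle); compactness is defined as its exact reciprocal. Solidity uses the
hull of pixel *corners*, not centres — the centre hull underestimates the
covered area and can push solidity above 1 on rectangles.

The phenotype classifier is a gentle-boosting ensemble of decision stumps
capped at 20 rules, the classical rule-based discriminator for this kind of
assay. Each round picks the feature/threshold minimising the weighted
squared error of per-class ±1 vote targets over midpoints of sorted unique
values, assigns each side its weighted-mean vote, and reweights
multiplicatively. Ties break by feature name, then threshold, making
training fully deterministic and order-invariant; duplication of the
training set leaves the model unchanged. Multi-class problems are handled
by per-class vote columns. Accuracy is estimated by stratified k-fold
cross-validation (pooled held-out accuracy; with k = n this is
leave-one-out).

## Plate layout and normalization

The layout model fixes the screen geometry: outer ring empty (36 wells,
filled with medium only), rows B–D on control substrate, rows E–G coated,
ten inner columns with one treatment per column so every compound is
measured in triplicate on both substrates. Without a positive control the
nine compounds occupy columns 2–10 and DMSO column 11; with one, the
positive control is pinned to column 10, eight compounds occupy columns
2–9 and DMSO stays in 11 — the only assignment that keeps one treatment
per column, a DMSO column (required for POC) and exactly one
positive-control column. The library manifest maps 13 stock plates × 80
compounds through 9-compound + 3-DMSO mother rows onto 9 assay plates per
sub-experiment (1040 compounds, each exactly once); 80 does not divide by
9, so the ninth row of each sub-experiment runs one slot short, and that
slot holds the positive control when enabled (an extra DMSO otherwise).

Normalization is two-step. **POC**: every well is divided by the mean of
its plate's control-substrate DMSO wells (×100), removing plate-to-plate
scale; on a noiseless plate the coated DMSO wells read exactly
100 × substrate effect. **B-score with virtual row shuffling**: B-scoring
assumes most wells are inactive, which a triplicate, two-substrate layout
violates. Replicate rows of one substrate are therefore reassembled across
the plates of a stack group into replicate-free, single-substrate virtual
plates before Tukey median polish. The assignment is a cyclic Latin
square — virtual plate *v* of a group of *g* plates takes replicate row *r*
from plate ((v + r − 2) mod g) + 1 — the simplest bijection that keeps each
row's plate position, mixes only comparable stack positions (groups of 3
consecutive positions in a 9-plate stack; group size configurable) and puts
each compound exactly once per virtual plate. The shuffle map is carried
with the data, and `reverse_shuffle()` is its exact inverse.

`median_polish()` alternates row- and column-median sweeps (missing wells
allowed; medians over present cells — flagged wells are never entered as
zeros) until the adjustments fall below `tol`, the total absolute residual
stagnates (the sweeps can cycle on matrices with even dimensions without
improving the fit), or `max_iter` (default 20). The decomposition
reconstructs the input exactly. B-scores divide the residuals by
1.4826 × median(|residual|), the Gaussian-consistent MAD. One numerical
choice matters on this geometry: a 3 × 10 virtual plate leaves about a
third of the residuals structurally zero after polishing, so the per-plate
MAD is unstable and inflates scores plate-by-plate. `normalize_stack()`
therefore pools the MAD over the virtual plates of one substrate × stack
group (90 wells), which is steadier and uniform across compounds;
`bscore()` keeps the per-plate MAD as its default for standalone use and
accepts the pooled scale as an argument. A perfectly additive plate has
MAD 0 and is flagged degenerate with all scores 0. The positive-control
column is excluded from the polish by default — a whole column of strong
genuine effect distorts the row/column fits — and its wells then carry `NA`
B-scores; inclusion is a flag.

## Assay quality and hit selection

`ssmd()` computes the strictly standardized mean difference
$\beta = (\mu_\mathrm{pos} - \mu_\mathrm{neg}) / \sqrt{\sigma_\mathrm{pos}^2 + \sigma_\mathrm{neg}^2}$
with sample (method-of-moments) estimators — the common screening default;
the difference to the UMVUE variant is negligible at the well counts of
this design. β above 7 against a strong positive control indicates an
excellent assay. A zero denominator returns signed infinity with a flag,
never `NaN`.

Hit selection replaces interactive scatter-plot picking with an explicit
rule: per compound and substrate, the mean B-score over the replicates;
selected iff |mean| ≥ cutoff (default 5) *and* at least 3 of 3 replicates
agree in sign. The replicate-agreement clause strengthens a consistency
check that manual picking applies implicitly. Raising the cutoff can only
remove hits (monotonicity), and a rank-based top-k mode is available.
Exports are long CSV (round-trip exact), a compounds × substrates pivot
with replicate columns and mean ± SEM, and the hit list.

## Problem sizes and reproducibility

The shipped tests run on 192–448 px synthetic fields with 10–50 cells and
on full 9-plate stacks (540 measured wells), sizes at which every stage's
behaviour — including exact count recovery and hit-map recovery — is
already observable; the whole suite completes in well under a minute.
All generators take explicit integer seeds and are bit-reproducible; the
stage runners (`run_simulate()` → `run_segment()` → `run_normalize()` →
`run_report()`) write JSON manifests with the seed and a configuration
hash, and a thin command-line wrapper (`inst/cli/spreadscreen.R`) exposes
them as subcommands with file handoffs so stages can be rerun
independently.

## Known limitations

Segmentation accuracy statements are relative to the synthetic image
model; real images need per-assay tuning of the nuclear threshold, the
diameter range and λ. The propagation regularization used in the original
assay is not documented, so λ is a free parameter here. Virtual-plate
B-scoring removes additive row/column/stack structure; multiplicative
artifacts are only removed to the extent POC linearises them. With three
replicate rows per substrate the replicate-agreement rule is all-or-none;
screens with more replicates should raise `min_replicates_agreeing`
proportionally rather than keeping 3.
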