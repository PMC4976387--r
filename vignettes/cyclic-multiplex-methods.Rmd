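---
title: "Methods: occupancy colocalization statistics for cyclic multiplexed immunofluorescence"
author: "cycloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy colocalization statistics for cyclic multiplexed immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloc)
```

## The measurement problem

Cyclic immunofluorescence protocols image one specimen through repeated
label/image/elute/relabel cycles: a resin-stabilized specimen is stained
with an antibody, imaged, stripped with a high-pH/detergent wash, and
stained again, so that an arbitrary panel of proteins can be accumulated
on a single membrane or cell. Turning those image stacks into biology
requires a small set of quantitative operations:

* **Elution efficiency** — how much of a round's fluorescence the wash
  actually removed.
* **Labeling reproducibility** — when the *same* epitope is relabeled in a
  later round, how similar is the picture? Each labeling round is a
  stochastic draw (not every available epitope binds an antibody every
  time), and successive rounds gain overall intensity through incidental
  antigen retrieval.
* **Multi-protein colocalization** — after binarizing each channel into
  occupied/empty pixels, do the channels co-occupy pixels more often than
  independent placement would allow?
* **Label penetration** — how does labeling intensity fall off with depth
  into the embedded specimen?

`cycloc` implements this chain end to end, together with a synthetic
scene generator that reproduces the statistical structure the analysis
assumes, so every stage is testable without microscope data.

## The synthetic scene model

`scene_config()`/`generate_scene()` realize a punctate epitope field:

* `n_sites` (default 300) sites are attached to `n_domains` (default 40)
  "domains" — shared structures (membrane microdomains, protein
  complexes) whose member sites carry the epitope of channel $c$ with
  probability $\pi_c$ (`channel_affinities`, default 0.9 per channel),
  independently across channels given the domain. Domain centers are
  uniform over the frame and members scatter around them with
  `domain_sigma` = 2 px. This is the simplest generative model with the
  qualitative property under study: joint occupancy above chance.
* `background_site_rate` (default 60 per channel) adds sites that belong
  to exactly one channel — label that has nothing to do with the shared
  domains.
* Each round labels every available epitope independently with
  probability `label_prob` (default 0.9): the stochastic relabeling that
  makes two rounds of the *same* stain similar but not identical.
* Rendering: Gaussian spots (`psf_sigma` = 1.5 px) of amplitude
  `spot_amplitude` $\times$ `round_gain`$^{r-1}$ (default 12000 and 1.15)
  on a 256$\times$256 16-bit frame; a static per-channel smooth
  background field (bilinear interpolation of a 3$\times$3 coarse grid,
  amplitude 1500) standing in for vignetting and out-of-focus glow;
  additive Gaussian noise (`noise_sigma` = 40); cumulative rigid drift
  `drift_per_round` = (2, −1) px. The literature leaves the
  antigen-retrieval gain per round unquantified, so `round_gain` is a
  free parameter; 1.15 gives a visible but unsaturated increase over
  three rounds. The spot amplitude was fixed so the 99.9th intensity
  percentile of a round-3 frame stays below 16-bit saturation.
* Elution: `render_round(..., post_elution = TRUE)` thins the round's
  labeled sites, each surviving with probability `residual_fraction`
  (default 0.055, i.e. the ~94.5%-stripped regime). The surviving-spot
  model matches the punctate appearance of residual signal; the same
  labeling draw is reused so pre/post images describe the same round.

One root `seed` is split deterministically per (purpose, round, channel),
so identical configurations are bit-identical and any single image can be
regenerated in isolation.

**What the generator does not emulate:** spot brightness heterogeneity,
photobleaching, spatially varying PSFs, nonrigid deformation, spectral
bleed-through, and — importantly — it produces spatially clustered but
otherwise well-behaved signal. Tests passing on these scenes show the
*operators* are correct, not that real tissue satisfies the model.

## Preprocessing

**Background subtraction.** `rolling_ball_subtract()` subtracts a
grayscale morphological opening with a disc of radius 50 px (the
conventional kernel for this preparation; configurable). The opening is
an exact flat-disc erosion/dilation pair (`gray_opening()`), computed by
running minima/maxima over the disc's row decomposition, and is verified
in the tests against a brute-force neighborhood scan. Because a plain
opening of a noisy image tracks local noise *minima* (biasing the
subtracted image upward by a few noise standard deviations), the
background is by default estimated from a 3×3 mean-filtered copy — the
same presmoothing used by the familiar desktop implementations;
`presmooth = 0` disables it, making the background exactly the opening.

**Registration.** Rounds drift rigidly (the specimen is physically
re-mounted between cycles), so `register_rounds()` estimates a
translation by FFT cross-correlation: exact integer recovery for planted
shifts up to a quarter of the frame, and optional subpixel refinement by
an upsampled discrete Fourier transform evaluated in a 1.5-px
neighborhood of the integer peak (default resolution 1/50 px; planted
band-limited shifts are recovered to ~0.01 px, comfortably inside the
0.2 px contract). The reported shift is the translation carried by the
moving image; `apply_shift()` applies its negation and flags shifted-in
border pixels invalid, and that validity mask is honoured by every
downstream statistic. All rounds are aligned to round 1 of a reference
channel rather than chained pairwise, so registration errors do not
accumulate. Rotation and nonrigid warps are out of scope.

**Mean equalization.** Because of the round-over-round gain, rounds are
compared after `equalize_means()`: `b * mean(a)/mean(b)` over the valid
mask.

## Round comparison: minmax decomposition

For two equalized rounds $a, b$ of the same stain, the composite image
has a *shared* channel $\min(a, b)$ — signal reproduced in both rounds —
and a *difference* channel $|a - b|$ — round-specific signal; their sum
reconstructs $\max(a, b)$ exactly. The defining equations of this
construction circulate in figure form in the source literature; pixelwise
min/absolute difference is the reading consistent with the name and with
the two-color composites shown, and the signed variant is exposed via
`signed_difference = TRUE` for display purposes. `minmax_decompose()`
reports the Pearson correlation of the two rounds over valid pixels, and
`ratio_histogram()` bins $\log_2((\mathrm{shared} +
1)/(\mathrm{difference} + 1))$ on an axis symmetric about zero (the
pseudocount of 1 intensity unit stabilizes empty pixels and is
configurable).

`elution_efficiency()` is $100 (1 - \sum \mathrm{post} / \sum
\mathrm{pre})$ over the valid mask. On noise-free simulations it recovers
the configured residual fraction to Monte-Carlo error (0.055 residual
$\to$ 94.5% stripped). On noisy frames the global-sum estimator is biased
a few percent downward: clipped noise and imperfect background removal
contribute positive intensity to the dim post-elution frame. The
pipeline reports the estimator as defined rather than masking or
debiasing it; users wanting a sharper number should restrict the mask to
pre-round puncta.

## Occupancy statistics

Each channel is binarized — `otsu_threshold()` (minimum intra-class
variance over a 256-bin histogram; the threshold returned is the bin
edge, and equals exhaustive search by construction and by test) or
`percentile_threshold()` (smallest attainable fraction of pixels
strictly below the threshold at least $p$, ties resolved toward more
pixels below; on heavily tied data the attainable fractions jump, and an
unattainable request returns `Inf`, i.e. empty occupancy).

`build_occupancy_table()` counts valid pixels into the $2^k$ binary
occupancy patterns. `chi2_mutual_independence()` forms expected counts
from the empirical marginal occupancy probabilities,

$$X^2 = \sum_{\mathrm{patterns}} \frac{(O - E)^2}{E}, \qquad
\mathrm{df} = 2^k - 1 - k,$$

with the upper-tail chi-squared p-value ($k = 3$ gives 4 degrees of
freedom). Cells with expected counts below a configurable floor
(default 1) are flagged in the result. The sampling unit is the pixel,
exactly as in the conventional analysis; diffraction makes neighbouring
pixels correlated, so `n_pixels` overstates the effective sample size
and p-values on blurred images are anti-conservative. The result object
reports `n_pixels` so this can be judged; no silent correction is
applied (a permutation null would be the natural extension). On
i.i.d.-pixel simulations the test is calibrated: the acceptance suite
checks a 4–6% rejection rate at $\alpha = 0.05$ over 2000 simulated
independent triples of 10^4 pixels.

`exceedance_sweep()` varies the threshold percentile from 1% to 95% (1
point steps by default; endpoints are the conventional sweep range) and
reports, per channel subset, the *exceedance ratio*

$$\frac{P(\text{jointly occupied})}{\prod_{c \in S} P(\text{occupied in } c)},$$

which is 1 under independence. Each channel is thresholded at its own
percentile (a common *fraction of pixels*, not a common intensity), the
reading consistent with sweeping each channel across its dynamic range.
Ratios where a marginal is empty are recorded as missing, never 0 or
infinity. Default subsets are all pairs plus the full set: with planted
triple-colocalized domains ($\pi_c = 0.9$) the triple ratio exceeds
every pairwise ratio across the upper half of the sweep — the
diagnostic signature that more simultaneously imaged proteins buy more
discriminating power.

## Depth profiling

`exterior_distance_map()` computes the exact Euclidean distance of every
in-mask voxel to the nearest exterior voxel (separable
lower-envelope-of-parabolas transform; 2-D or 3-D; anisotropic voxel
spacing respected, e.g. coarser axial than lateral sampling).
`profile_by_depth()` bins in-mask voxels by that distance (default bin
width 1 distance unit) and reports mean intensity and voxel count per
bin, with an optional exclusion mask for structures that would dominate
the mean (a mitotic spindle, the nucleus). Masks may be supplied by the
user — how specimen masks are drawn is a judgment call — or generated
with `make_cell_mask()` (Otsu on a smoothed copy, largest connected
component, holes filled).

## Numerical and design choices

* Intensities are read from 16-bit TIFF as stored and promoted to
  doubles at the module boundary; coordinates are row-major with
  1-based R indexing in code and 1-based TIFF pages in manifests.
* Registration quality is the normalized cross-correlation at the peak;
  all-zero images are refused rather than returning an arbitrary shift.
* Otsu ties (equal between-class variance) resolve to the lowest cut;
  constant images are refused.
* The chi-squared statistic uses no continuity correction, matching the
  plain form conventionally reported.
* Degenerate inputs fail loudly by design: zero-variance correlation,
  zero pre-elution signal, all-true masks (no exterior), empty subsets.

## Problem sizes used by the tests

The test and acceptance suites run entirely on simulated data at desk
scale: 96–256 px frames, 2000 independence simulations of 10^4 pixels,
100-seed elution and 20-seed registration replicates, and exhaustive
distance-transform enumeration up to 12×12 masks. The reference values
of the source experiments (e.g. specific Pearson correlations or
chi-squared magnitudes on particular micrographs) depend on images that
are not redistributable, so the suite checks the *properties* of each
estimator — calibration, exactness, ordering — rather than those
image-specific numbers.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(list(seed = 1, output_dir = "demo_run"))
res$summary
```

The pipeline writes per-round TIFFs with a manifest, the minmax
composite and summary, the occupancy table, chi-squared summary,
exceedance curve, depth profile, a YAML echo of the full configuration
and a JSON summary; rerunning with the same configuration and seed
reproduces the CSV/JSON artifacts byte-identically.
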