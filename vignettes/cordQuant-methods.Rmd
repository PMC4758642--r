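---
title: "cordQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cordQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordQuant)
```

cordQuant quantifies fluorescence readouts of membrane trafficking in
*C. elegans*: receptor puncta along ventral-cord dendrites, colocalization
of organelle markers, GFP signals buried in intestinal autofluorescence, and
vesicle transport in time-lapse movies. This vignette explains the models
behind each analysis stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the underlying workflow left the choice open.

## Coordinate and unit conventions

Images are matrices (rows = y, columns = x) with non-negative intensities in
arbitrary camera units. Coordinates are 0-based, x increases rightward along
the nerve cord with the anterior of the animal at the left, y increases
downward. The centre of storage column *j* lies at x = (j − 0.5) ×
`pixelSizeUm`. The default pixel size is 0.16 µm/px — a 100X objective with
an EMCCD camera, under which a 512-px frame spans 81.92 µm of cord — but it
is a parameter everywhere, because acquisition geometry varies between
set-ups. All lengths are reported in µm, times in s, velocities in µm/s.

## Synthetic data generator

The generator (`makePunctaImage`, `makeTwoChannelImage`, `makeLambdaStack`,
`makeMovie`) emulates the package's target acquisitions closely enough that
every analysis stage can be validated against recorded ground truth:

- **Puncta** are isotropic 2D Gaussians evaluated at pixel centres (no
  integration over the pixel area), with default σ = 0.6/2.355 µm so the
  FWHM is 0.6 µm — the middle of the 0.5–0.7 µm range of dendritic receptor
  clusters. Amplitude defaults to 100 over a background of 10 with additive
  Gaussian noise (σ = 2), roughly the contrast of a well-exposed 12-bit
  acquisition. Puncta are placed on jittered evenly spaced slots along the
  cord midline, which keeps them separated and their ground truth
  recoverable; real cords have clustered, overlapping puncta, so detection
  performance on synthetic data is an upper bound.
- **Two-channel images** share a controlled fraction of puncta positions
  between channels; non-shared puncta are channel-exclusive or, for
  adjacency tests, displaced by a fixed offset in channel 2.
- **Lambda stacks** are per-pixel linear mixtures of a GFP and an
  autofluorescence emission profile plus noise, clipped at zero. The
  built-in profiles are sampled at the nine 500–580 nm bands: GFP peaks at
  510 nm and decays toward the red; the gut-granule autofluorescence
  reference is broad and red-shifted (peak 570 nm), which is precisely what
  makes the linear system well conditioned.
- **Movies** render vesicles moving at constant programmed speed with
  stochastic pauses (default probability 0.05/frame, length 8 frames) and
  reversals (default 0.01/frame), at 3.1 frames/s over up to 500 frames.
  Negative velocity means anterior-directed (retrograde) motion. A
  photobleached stretch of cord has its background multiplied by 0.2 — the
  bleach depth is not documented for the original acquisitions, so it is a
  parameter. Intensities are constant per vesicle; photobleaching decay over
  time, focus drift and out-of-plane excursions are not simulated, so
  tracking results on synthetic movies say nothing about those failure
  modes.

Everything is deterministic given the spec and its seed: the same seed
reproduces images bit-exactly, and ground truth (true centroids, per-frame
trajectories, classes, directions) accompanies every dataset.

## Thresholding and puncta detection

`autoThreshold()` implements Otsu's method as an exhaustive search over all
256 split levels of the min–max-rescaled intensity histogram, maximizing the
between-class variance w₁w₂(μ₁ − μ₂)². Empty histogram bins tie exactly with
the preceding split; ties resolve to the midpoint of the first and last
maximizing bins. A constant image has no Otsu threshold and raises an
explicit error. The alternative percentile mode retains the brightest
fraction of pixels (default 5%) with deterministic tie-breaking by value
then index; this is the mode used for colocalization channel masks, where
the original workflow thresholded "typically <5% of pixels for each
channel". That phrasing is ambiguous between *eliminating* and *retaining*
5%; cordQuant reads it as retaining the brightest 5% — the reading under
which the mask contains the puncta rather than everything else — and makes
the fraction configurable.

`detectPuncta()` labels connected components (default 8-connectivity,
configurable to 4) via the pixel-adjacency graph and filters them by a
minimum area of 4 px; both defaults reject single-pixel noise and are
otherwise unconstrained by the original workflow, which left them
unspecified. Centroids are intensity-weighted, which gives sub-pixel
accuracy on symmetric spots. Two spots whose masks touch merge into one
component: detection does not split touching objects, a documented
limitation. Density is count × 100 / cord length (puncta per 100 µm).
`integratedDensity()` sums pixels strictly above the active threshold
("detectable" intensities) within a mask or a circular ROI (default radius
50 px, the ROI used for intestinal cell measurements); whether the original
analysis reused the detection threshold here is unstated, so the threshold
is an explicit argument defaulting to 0.

## Colocalization

The tolerance estimator compares per-channel min–max rescaled intensities
over each channel's above-threshold pixels: a pixel is colocalized when it
is above threshold in both channels and |r₁ − r₂| ≤ tolerance (default 0.1).
Rescaling makes one tolerance meaningful across exposures; whether the
original scatter-plot tolerance was absolute or rescaled is not documented,
and the rescaled reading is the one that generalizes. The fraction is
normalized to above-threshold channel-1 pixels, matching the convention of
normalizing to the GFP channel; an empty channel-1 mask yields a flagged NA,
not an error. The binary colocalization mask is returned for overlay
figures. The Pearson estimator is the sample correlation over a joint
thresholded mask with at least 3 pixels; a constant channel is flagged
undefined. For intestinal images, pixels flagged as autofluorescent (by
`unmix()` or by a third-channel mask) can be removed from both masks via
`excludeMask` before any statistic. Analysis is single-focal-plane by
construction — these are 2D estimators.

`adjacencyFraction()` reports the fraction of A-puncta whose nearest
B-centroid lies within 1 µm (default) — the "adjacent but not overlapping"
relationship between markers on neighbouring organelles.

## Spectral unmixing

Per pixel, the 9-band spectrum s is decomposed as s ≈ a·g + b·f with
non-negative abundances, where g and f are unit-sum reference profiles
(built-in defaults, or measured from control animals with
`buildReferenceProfile()`, which averages the spectrum over a mask of ≥ 10
pixels and normalizes). For two endmembers the non-negative least-squares
solution is closed-form: take the unconstrained 2×2 solution; if a
coefficient is negative the optimum lies on an axis, so clamp each
coefficient in turn and keep the single-component fit with the smaller
residual. The residual image is computed from the reconstruction itself
rather than the expanded quadratic form, which loses all precision near
exact fits. Collinear profiles raise an error. An alternative
"classify-then-zero" mode assigns each pixel wholly to the more correlated
profile and zeroes autofluorescent pixels; the original description —
autofluorescence "filtered out" using profile differences — does not say
whether pixels were subtracted, masked or reclassified, so both readings
are exposed and labelled.

**Noise propagation.** The least-squares GFP coefficient has standard error
σ·√((M⁻¹)₁₁), with M the 2×2 Gram matrix of the profiles and σ the per-band
noise. Because the profiles are normalized to unit *sum* over 9 bands,
‖g‖² ≈ 0.16 for a realistic GFP emission curve, so even perfectly orthogonal
references give a coefficient error floor of ≈ σ/0.4. At σ = 0.01 the 99th
percentile of the absolute abundance error is therefore ≈ 0.06–0.08
depending on profile overlap — an intrinsic property of the model
normalization, not an estimator deficiency; the unit tests assert that the
estimator attains (and does not exceed) this floor, and the acceptance
script reports the computed percentile. Only peak-normalized (max = 1)
profiles, which concentrate more norm per band, would push this percentile
an order of magnitude lower.

## Kymographs and transport metrics

`buildKymograph()` collapses each frame onto a horizontal line ROI by taking
the per-position maximum over the averaging width (default: the full strip
height), producing a frames × positions matrix with anterior (retrograde) at
the left. `detectAndLink()` finds per-row local maxima above a threshold
(default: Otsu on the kymograph; plateaus collapse to their centre) and
links them greedily to the nearest maximum in the next row within
`maxLinkPx` (default 6 px, comfortably above the 2 µm/s ≈ 4 px/frame fastest
vesicles; never below 3 px so linking cannot preclude the mobility
criterion). Unlinked maxima start new tracks. Where two tracks compete for
one maximum — crossings — the nearer track wins, ties break toward the
smaller column index, and both tracks are flagged `ambiguous-link`, since
identities may swap there. Greedy linking is deliberately simple and
auditable; multi-hypothesis tracking is out of scope.

**Classification.** The transport criteria are: mobile = "displaced by at
least three pixels in successive time frames"; stationary = "immobile for
more than three consecutive frames". cordQuant reads the mobile criterion as
*displacement accumulated over successive same-direction frames reaching
3 px*, with a single ≥ 3 px step as the limiting case. The naive per-frame
reading (any single step ≥ 3 px) would be internally inconsistent with the
rest of the workflow: at 0.16 µm/px and 3.1 frames/s a vesicle moving at a
typical 1.0 µm/s advances only 2.0 px/frame and would never count as mobile,
although such vesicles are exactly what the transport assays measure. The
cumulative reading reproduces all the boundary cases — (10,13,16,19) is
mobile, (10,10,10,10,10) is stationary, (10,11,12) is excluded (too short to
progress 3 px or to dwell more than 3 frames) — while making 0.5–2.0 µm/s
vesicles classifiable at this acquisition geometry. Tracks that neither
progress nor dwell are "excluded" and reported as such. Direction comes from
the sign of the net displacement (decreasing x = retrograde); zero net
displacement gives "none".

**Runs and velocity.** Movement events are maximal constant-sign stretches
of nonzero steps with cumulative |Δx| ≥ 3 px, delimited by pauses
(zero-displacement frames), direction reversals, or the movie end. Run
length is |Δx| × pixel size; event velocity is run length over event
duration (steps / frame rate); a track's velocity is the mean over its
events, so pauses do not dilute it. Flux is the number of mobile tracks
(optionally restricted to those intersecting a stated window) divided by
region length (15–20 µm in the emulated assays) and duration in minutes.
Direction fractions are taken over directed mobile tracks. Reversal
statistics are reported both per track (fraction of mobile tracks with at
least one reversal) and per event, since either convention is defensible and
the original report does not say which it used.

## Summary statistics

`meanSem()` uses the n−1 sample standard deviation. `chiSquare2x2()`
computes the uncorrected χ² = n(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) with p from
χ²₁ — the closed form used for mobile-fraction comparisons; degenerate
marginals raise errors rather than returning NaN. `twoSampleT()` defaults to
the pooled Student form (matching "Student's t test") with Welch as an
option; zero-variance degeneracies resolve explicitly (equal means → t = 0,
p = 1; unequal → ±Inf, p = 0). `anovaBonferroni()` fits a one-way ANOVA and
follows with pooled pairwise t tests, Bonferroni-adjusted (multiplied by the
number of comparisons, capped at 1) either all-pairs or versus a reference
group. The versus-reference mode is a conservative stand-in for Dunnett's
many-to-one procedure: exact multivariate-t critical values are out of
scope, and Bonferroni never under-rejects relative to Dunnett. All tests are
two-sided.

## Rab6 sequence analysis

Pairwise global alignment uses Needleman–Wunsch with BLOSUM62 and affine gap
penalties (open 10, extend 0.5; a gap of length L costs open + L·extend),
via Biostrings. Pairwise alignment replaces a progressive multiple
alignment: for two-sequence statistics it is optimal and deterministic, and
reference-coordinate bookkeeping absorbs any column-numbering differences.
Conservation is 100 × qualifying columns / ungapped columns; the default
mode counts identical plus similar residues — similarity groups ST, DE, KR,
NQ, ILVM, FYW, AG, the black-plus-gray highlighting convention of published
alignments — with an identity-only mode provided because published
"conservation" percentages do not always say which they count.

The subfamily call reads the query residues aligned to Rab6A positions 63,
106 and 139 (1-based ungapped Rab6A numbering): threonine at 106 with serine
at 139 → Rab6A-like; serine at 106 with threonine at 139 → Rab6B-like;
anything else, including a gap at a diagnostic column, is ambiguous.
Position 63 is reported but deliberately excluded from the call: the
valine/isoleucine split at 63 does not co-segregate with the 106/139
subfamily split across the isoforms, so it carries no additional
classification signal.

`syntheticRab6Set()` provides seven clearly labelled synthetic stand-in
sequences built from a random 200-residue scaffold. They encode only the
comparative structure the classifier exercises — each isoform's diagnostic
residues, exactly three residue differences between Rab6A and Rab6A′, and
10% dissimilar divergence (90% conservation) between RAB-6.1 and RAB-6.2 —
and nothing else about the real proteins. They exist so the sequence
pipeline is testable offline; analyses of the real proteins should load the
database sequences through `readFastaProteins()`.

## Pipeline, I/O and reproducibility

`runPipeline()` executes the stages (simulate → puncta → coloc → unmix →
kymo) in dependency order inside a run directory, writing TIFFs, per-object
CSVs, and a JSON manifest containing the fully resolved configuration, the
seed, the package version and every produced file. Configurations are flat
YAML `key: value` files following the `defaultRunConfig()` schema; unknown
keys are rejected and round trips are lossless. A stage whose input is
neither configured nor produced upstream fails with a dependency error
naming the stage. TIFFs are 32-bit float with intensities scaled by a
full-scale constant (default 4095, the 12-bit camera range), because the
TIFF writer stores samples in [0, 1]; multi-page stacks order pages by
ascending wavelength (lambda stacks) or time (movies).

## Test and validation scale

The test suite validates each operation against independent oracles:
exhaustive-search Otsu against a brute-force double loop (and EBImage's
implementation to within a bin width — EBImage's vectorised formulation
includes the boundary bin in both classes, so its tie handling differs from
the canonical definition), alignment scores against exhaustive enumeration
of all alignments for short peptides, NNLS against grid search and a
reference implementation, and the statistics against closed forms and base
R. End-to-end recovery experiments use 50 single-vesicle 150-frame movies
per velocity condition at 0.5–2.0 µm/s (8 × 512 px frames keep rendering
fast while preserving the kymograph geometry), 25 stationary-only movies,
five colocalization fractions at 16 puncta per channel, and 64 × 64 lambda
stacks — sizes chosen so the full suite completes in a couple of minutes on
one CPU while keeping Monte-Carlo error well inside the asserted
tolerances. Synthetic data are idealized (well-separated spots, constant
amplitudes, Gaussian noise); passing these tests demonstrates correctness of
the estimators under the stated models, not robustness to every pathology of
real micrographs.
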