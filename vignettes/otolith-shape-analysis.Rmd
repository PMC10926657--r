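---
title: "Otolith outline morphometrics with otoshape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Otolith outline morphometrics with otoshape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoshape)
```

## The problem

Teleost fish carry three pairs of calcified ear stones — sagittae, lapilli
and asterisci. Their outline shape integrates growth history and is widely
used to separate stocks, sexes and size cohorts. `otoshape` implements the
full outline-analysis chain for this kind of study: binarise a photograph,
trace the outer contour, measure it, condense it into shape descriptors,
remove fish-size dependence, and test whether side (left/right), sex or
TL-defined size class structures the shapes.

The package is organised around base-R S3 objects: each stage returns a
classed object (`oto_contour`, `oto_descriptors`, `oto_test`, `oto_lda`,
`oto_meanshape`, `oto_run`) with `print`/`plot` methods, and
`run_pipeline()` ties the stages together.

## Contour extraction

Images are thresholded at a normalised intensity (default 0.05, bright
object on a dark stage; both configurable), small components below
`min_object_px = 64` are discarded, and the outer boundary of the largest
component is traced as a **sub-pixel iso-contour at level 0.5**
(marching-squares style via `grDevices::contourLines`) rather than a
pixel-edge chain code. The iso-contour crosses halfway between foreground
and background pixel centres, which halves the quantisation bias of
perimeter estimates. Pixel centres sit at integer coordinates, x rightward
and y upward (the image row axis is flipped on read), which makes signed
area and the counter-clockwise convention unambiguous. Components touching
the image border are refused (`oto_border_touch`), because their outline is
incomplete; scenes with several otoliths are out of scope — the largest
component wins by design.

## Size measures and shape indices

`measure_contour()` reports OL (maximum length), OW (maximum width), OP
(perimeter) and OS (area), all in the contour's unit (mm). OL and OW are
box extents along the principal axis, obtained from **exact line-integral
second moments of the closed curve** (not from sampled vertices), so the
axis — and with it OL/OW — is independent of vertex density and exactly
rotation-equivariant; a maximal Feret-diameter variant is available via
`axis = "feret"`. From these, `shape_indices()` computes

* circularity `C = OP^2 / OS` (lower bound `4*pi` for a circle),
* rectangularity `Re = OS / (OL * OW)` (1 for a rectangle),
* ellipticity `E = (OL - OW) / (OL + OW)`,
* aspect ratio `AR = OW / OL`,
* form factor `FF = 4*pi*OS / OP^2` (1 for a circle), and
* roundness `Ro = 4*OS / (pi * OL^2)`.

`FF * C = 4*pi` is an algebraic identity and is asserted on every synthetic
record in the test suite. `E` is kept **signed**: asterisci are wider than
long in the anatomical frame, so their ellipticity is negative and is
conventionally reported as a magnitude under a negative-sign header; `Ro`
may exceed 1 in the same situation and is not clamped. `AR` is reported as
a ratio, not a percentage, matching how such tables are conventionally
printed. Size classes follow fixed TL thresholds (I: TL ≤ 240 mm, II:
240 < TL ≤ 290 mm, III: TL > 290 mm, upper bounds closed); a 1-D k-means
utility (`kmeans_classes()`, many restarts, labels ordered by centre) is
provided for exploratory cut-finding but the thresholds are authoritative.

## Shape descriptors

Two complementary descriptor families are computed per outline.

**Wavelet descriptors.** The polar radius profile — distance from the area
centroid sampled at 512 equal angles, starting at the principal-axis
direction oriented toward the farther (anterior) tip — is normalised to
`r / mean(r) - 1` and decomposed with a **periodized orthonormal
Daubechies-4 transform** over 5 levels. Orthonormality gives a Parseval
identity and exact inversion, both asserted at the 1e-9 level. The
descriptor vector retains the approximation band plus the two coarsest
detail bands (64 coefficients), comparable in dimensionality to common
practice for outline studies; `keep_details = 5:1` retains everything. The
radius profile requires a star-shaped outline; contours that back-track by
more than 0.02 rad around the centroid fail loudly (`oto_non_star_shaped`)
rather than silently switching metric, because a silent switch would break
cross-specimen comparability. Backtracks at or below that tolerance
(sub-pixel jitter of traced outlines) are dropped.

**Elliptic Fourier descriptors.** The (x, y) parameterisation by chord
length is expanded into harmonics (default 20, enough to capture the
crenation scales the generator produces while keeping `n >> p` at
study-like sample sizes) and normalised the standard way: DC dropped
(translation), start point rotated to the first-harmonic semi-major axis,
spatial rotation removed, scale divided out, leaving `4H - 3` informative
values. The residual 180° start/rotation ambiguity is resolved by the sign
of the dominant second-harmonic element. The descriptors are computed on
the vertices as given — a deliberate choice: on the raw polygon the
normalisation is *exactly* invariant to the starting vertex, whereas
resampling from a shifted start perturbs the polygon at second order in the
vertex spacing. Note that under chord-length parameterisation even a
perfect ellipse retains small odd harmonics (about 2.5e-3 at axis ratio
1.2); the "harmonic 1 only" intuition holds exactly only in the
circular limit.

Reconstruction diagnostics report the per-point deviation between a
truncated reconstruction and the source outline (radial for wavelets,
matched-parameter Euclidean for EFD); the root-mean-square deviation is
non-increasing in the number of retained coefficients by orthogonality.
`position_variation()` decomposes the across-specimen radius variance at
each outline position into wavelet-band attributions
`cov(band component, profile)`, which sum exactly to the total variance
(attributions may be negative where bands covary negatively).

Left/right handling: right-side outlines are mirrored into left orientation
before descriptor extraction (configurable off), so both sides share one
shape space and the side-symmetry test compares like with like.

## Allometric adjustment

Otolith shape drifts with fish size. `adjust_for_length()` regresses each
coefficient on TL and, where the slope is significant at `alpha = 0.05`,
replaces the column by its residuals plus the grand mean; other columns are
untouched and constant columns are flagged. The adjustment is pooled across
groups and idempotent. One consequence worth knowing: when a shape effect
is itself a function of size class — and class is defined by TL — the
linear TL trend of that effect is removed together with genuine allometry.
Multi-directional class effects (different harmonics per class) survive;
a purely monotone one-harmonic gradient is largely absorbed. Sex
comparisons on adjusted coefficients also inherit any sampling imbalance in
TL between the sexes, a caveat shared by any residual-based design.

## Statistical testing

Univariate comparisons use standard machinery: Welch's t (pooled-variance
optional) for side and sex, one-way ANOVA with Tukey HSD (familywise
adjusted p and 95% CIs of pairwise differences) across classes, and Pearson
correlations with Fisher-z intervals against TL and BW. Test results carry
a significance flag at `alpha = 0.05`.

Multivariate descriptor matrices are compared with a **distance-based
permutation pseudo-F** (PERMANOVA-style): columns standardised, pseudo-F =
(between-group SS / (k−1)) / (within-group SS / (n−k)) on squared Euclidean
distances, and an add-one permutation p-value `(1 + #{F* ≥ F}) / (1 +
n_perm)` with `n_perm = 999` by default, fully seeded. The exact statistic
behind an "ANOVA-like permutation test" is a declared design choice here,
not an inference about any particular prior analysis. Because each fish
contributes two otoliths, permutations respect the pairing: fish-level
factors (sex, size class) permute whole fish; side permutes within fish.
Ignoring this pseudo-replication demonstrably inflates type-I error.

LDA (`oto_lda()`) fits Fisher discriminants with leave-one-out
cross-validated confusion matrices. When coefficients approach or exceed
the specimen count the matrix is first reduced by PCA retaining 95% of
variance (capped at `n - k - 1` components); when reduction is needed only
to shed exact null directions — the zero-mean constraint of the normalised
radius profile induces one — all non-null components are kept, so no signal
is discarded. `lda_accuracy_test()` compares LOO accuracy against the
1/k chance rate with an exact binomial test.

## The synthetic generator

`synth_config()`/`generate_otolith_set()` emulate the study design the
analyses assume: three TL-defined size classes crossed with two sexes
(default 20 fish per cell), paired left/right otoliths of one type.
Contours are positive radius functions
`r(theta) = R0 (1 + sum_k a_k cos(k theta + phi_k) + crenation + noise)`:
a fixed harmonic template per otolith type (elongated sagitta with an
anterior bump; rhomboid lapillus; wider-than-long asteriscus with a notch),
allometric size `R0 ~ TL^0.8` (so OL/TL falls with TL, the classical
negative allometry), additive group effects on specific harmonics,
high-order crenation (amplitude 0.012, frequency 26) and per-specimen
harmonic noise (sd 0.008 on harmonics 2–8). TL is uniform within class
(the simplest distribution with exact class closure) and BW follows
`a TL^b` (a = 5e-7, b = 3) with lognormal noise. A positive single-valued
radius function cannot self-intersect, so validity reduces to a positivity
check — amplitudes pushing the relative radius below 0.05 raise a
generation error. Every random draw is governed by one seed plus a
collision-resistant per-otolith hash, so sets are bitwise reproducible.

Default effects encode the reference scenario: a **class** effect that is
deliberately multi-directional (class II adds amplitude on harmonic 3,
class III on harmonics 3 and 4) so that it is not a single TL-monotone
gradient the allometric adjustment would absorb; **no sex and no side
effect**, making those comparisons null. Effect sizes are free parameters
chosen once so that the planted structure is comfortably recoverable at
20 fish per cell; no published effect sizes exist to calibrate against.

What the generator does *not* emulate: real margin texture (lobes and
sculpturing are a single cosine ripple), imaging artefacts (shading,
debris, broken edges), measurement error in TL/BW, or biologically
realistic template geometry. Passing tests therefore demonstrate that the
pipeline recovers planted structure of the assumed form and finds none
where none was planted — not that any particular wild population behaves
this way.

## Mean shapes

Group mean shapes average full wavelet coefficient vectors and invert the
mean; by linearity this equals the pointwise mean of the normalised radius
profiles (asserted to 1e-9), and the per-position dispersion band is the
radius sd across specimens. Overlays are aligned on a common centroid with
the principal axis horizontal and the anterior tip to the left, the usual
display convention for left otoliths.

## Numerical choices and degenerate inputs

* Contours are stored counter-clockwise; any input orientation is
  normalised by the signed-area test.
* Equal-arc resampling is idempotent to discretisation accuracy (~1e-6
  relative for a 512-gon), not to machine precision: arc positions drift
  by the accumulated chord-length variation.
* The principal axis of a square (or circle) is inherently ambiguous;
  box extents are then axis-choice dependent. Real otoliths are far from
  this degeneracy.
* Two constant groups with equal means give t = 0, p = 1 by convention;
  an all-identical descriptor matrix gives pseudo-F 0 with p = 1 and a
  degenerate flag; k-means refuses k above the number of distinct values.
* Tables are rounded half-up to 2 decimals, matching conventional
  morphometric reporting.

## Problem sizes used in tests

The test-suite studies use 512-point contours, 20 fish per cell (240
otoliths) for recovery runs with 499 permutations, 200 seeded null
replicates (99 permutations each) for type-I calibration, and 50 seeded
recovery runs for the headline pattern — sizes chosen to give stable
Monte-Carlo rates while keeping a full run in minutes on one CPU.

## Limitations

Star-shapedness is required for the wavelet path; strongly re-entrant
outlines (deep excisura, broken margins) need the EFD path instead.
The permutation and LDA machinery assumes one otolith type at a time;
cross-type comparisons are a join away but not first-class. No spatial
(between-population) analysis is included — only within-population
side/sex/class structure.
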