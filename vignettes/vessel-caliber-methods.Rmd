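---
title: "Measuring retinal vessel caliber by profile model fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel caliber by profile model fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vesselcaliber)
```

## The measurement problem

A retinal blood vessel in a fundus photograph appears on the green channel
as a dark, roughly Gaussian dip across its cross-section, often interrupted
by a bright central ridge (the *central light reflex*, CLR) caused by
specular reflection, and frequently asymmetric at its edges. The caliber of
the vessel — its diameter in pixels — is a clinically meaningful biomarker,
and for clinical use *precision* matters more than accuracy: a constant bias
can be compensated, a fluctuating one cannot. The package therefore treats
the standard deviation of the per-profile width errors,
$\sigma_{error} = \mathrm{sd}(\omega_i - \psi_i)$ over measured widths
$\omega_i$ and ground-truth widths $\psi_i$ (with an $n_p - 1$ denominator),
as the primary criterion.

The pipeline assumes a binary vessel segmentation is available (any
segmentation algorithm can produce it; producing it is out of scope) and
proceeds: centerline extraction, spline smoothing, profile extraction,
profile-length determination, anisotropic smoothing, parametric model
fitting, and width regression.

## Centerlines and geometry

The mask is thinned with an 8-connected Zhang–Suen-type iteration. Only the
topology of the result is contractual — skeleton inside the mask,
connectivity preserved, unit width — not the exact pixel set; different
standard thinning routines disagree by a pixel here and there and all
shorten blunt vessel ends by about half the local width. After thinning, a
cleanup pass removes pixels that are redundant for connectivity (their true
neighbors remain mutually 8-connected without them). Without it, staircase
corners left by thinning carry three neighbors and would be wrongly cut as
junctions, fragmenting long segments. Genuine bifurcations and crossings
connect otherwise separate branches, so they survive the cleanup and are
then removed by the junction rule (≥ 3 true 8-neighbors). Remaining simple
paths become segments; closed loops (no endpoints) are discarded with a
warning since only endpoint-bounded segments are defined; segments shorter
than 10 px (strictly) are pruned as thinning spurs.

Each segment is smoothed with a least-squares cubic spline. Parameter
increments follow the centripetal scheme (square root of chordal distance),
which behaves well at tight turns. The number of polynomial pieces is
`round(points / 20)` with a floor of one — "length" here is the point count
of the 8-connected path, which differs from Euclidean arclength by at most a
factor $\sqrt 2$; at a smoothing granularity of 20 px the distinction is
immaterial. Endpoints are treated like all other points (pure least squares,
no interpolation constraint). Normals are tangents rotated +90°; profiles
are sampled symmetrically about the centerline, so the sign convention never
affects results.

## Profiles and the CLR rules

Profiles are sampled on the green channel (highest vessel/background
contrast; intensities are normalized to $[0,1]$ by the image bit depth) at
1 px spacing with bilinear interpolation, over an initial half-length of
$\lceil 1.5 \times D_{max} \rceil$ where $D_{max}$ is twice the maximum of
the mask's Euclidean distance transform — guaranteeing coverage of the
widest vessel in the image. Samples falling outside
the image are nearest-edge filled and flagged; profiles with more than 25%
flagged samples are excluded from the length statistics.

The vessel extent within a profile is found by peak search on the mean of
11 adjacent profiles (truncated at segment ends), smoothed with a
Savitzky–Golay filter. The filter uses a **fixed 5-sample window, order
2**. A window that grows with the search span (e.g. a quarter of the
initial profile length) was tried and rejected: it flattens the narrow
background maxima that delimit the vessel and its equivalent-kernel ringing
manufactures spurious outer peaks, inflating profile lengths by tens of
pixels for wide vessels. Local extrema are interior sign changes of the
first difference, plateaus reported at their midpoints.

The search tries CLR regions first: the candidate CLR center is the lowest
maximum (vessel maxima are assumed lower than background maxima), replaced
by the maximum closest to the profile center when that one is close in value
(within 0.1 of the dynamic range) and near the center (within 0.25 of the
profile length). Its flanking minima and the next maxima out are the
candidate limits, validated by: minima at least 3 px apart; bump depths
differing by at most 50% (relative); center-to-limit distances differing by
at most 50%; limits within 0.8 of the initial half-length (one far side is
mirrored from the other); CLR elevation not exceeding the limit maxima; and
the region containing the profile center. If no CLR region is accepted, the
plain branch takes the minimum nearest the profile center and its adjacent
maxima, mirroring a missing or too-close side (closer than 1.5 px) and
searching outward when both sides are too close. In both branches

$$prof\_length = 2 \times \mathrm{mean}(|x_{maxL} - x_c|,\; |x_{maxR} - x_c|),$$

with $x_c$ the CLR central *maximum* in the CLR branch and the central
minimum otherwise. When nothing is found the full current span is returned, which
deliberately overestimates: losing vessel tails is worse for the fit than
keeping background. All rule thresholds above are experimentally chosen defaults, exposed in
`clr_rules()` and overridable via the config.

The segment's profile length is the median of its per-profile lengths (even
counts: mean of the middle two); profiles are cut symmetrically to
`2 * round(length / 2) + 1` samples and smoothed with a separable
anisotropic Gaussian, $\sigma_{across} = 0.1 \times prof\_length$ and
$\sigma_{along} = 1.5 \times prof\_length$, reflecting at the borders — more
smoothing along the vessel than across it, so edges stay sharp and wider
vessels get proportionally more smoothing.

## The profile models

All models are extrusions along the vessel: 2D fitting pools the points of
the 11 neighboring profiles into one plane and fits the 1D curve. The
Gaussian factors use the exponent $e^{-((x-\mu)/(2\sigma))^2}$, which
differs from the conventional $e^{-(x-\mu)^2/(2\sigma^2)}$ by a factor 2 in
the variance ($\sigma = \sigma_{conv}/\sqrt2$); `standard_gaussian = TRUE`
switches conventions throughout.

The adapted Hermite model (6 parameters) multiplies a Gaussian (with
density prefactor $1/\sqrt{2\pi\sigma^2}$) by a shifted parabola; its CLR
spread is tied to the main Gaussian's and its asymmetry term rescales the
whole profile, which limits its flexibility. DoG-L7 subtracts an
independent CLR Gaussian from the main one and multiplies by a line
$\lambda(x-\mu)+t$, giving edge asymmetry; DoG-L8 frees the CLR center
$\mu_2$, adding central asymmetry. Nesting gives the expected fit-quality
ordering (DoG-L8 ≤ DoG-L7 ≤ Hermite in SSE), which the test suite checks on
asymmetric-CLR profiles.

Fitting minimizes the sum of squared residuals under box bounds with
`minpack.lm::nls.lm`, a bounded Levenberg–Marquardt trust-region solver
(400 iterations, function tolerance $10^{-10}$; failures are reported as
`converged = FALSE`, never raised). The admissible parameter boxes and
starting points are derived from the profile itself and deserve three
remarks:

* the DoG background level is $t^2$, not $t$ (the line factor), so `t`
  starts at $\sqrt{\max(\text{end samples})}$ and the dip height at
  $-\mathrm{range}/t$;
* with a CLR the profile minimum sits on a flank, so the center starts at
  the dip-weighted centroid rather than the argmin;
* the Hermite dip height is scaled by its $1/\sqrt{2\pi\sigma^2}$
  prefactor, without which the admissible box cannot contain the optimum.

Because the DoG family admits dip-swap local minima (the CLR Gaussian
turning into a second broad dip), the solver restarts from three
deterministic initializations — CLR off, CLR bright, CLR dark — and keeps
the lowest SSE. With these choices, 100 of 100 noiseless DoG-L7 profiles
drawn inside the default bounds are recovered to better than 1% in every
parameter; single-start fitting recovered only about half. At noise level
0.01 the *exact* least-squares optimum itself wanders several percent away
from the generating $\sigma_1$ in roughly one draw in ten (verified by
starting the solver at the truth), so the noisy-recovery check asserts the
typical (median) error, not a per-fit guarantee.

Goodness of fit is reported as SSE, $R^2 = 1 - SSE/SST$ (computed from
residuals — the decomposition $SST = SSR + SSE$ does not hold for nonlinear
fits, so the $SSR/SST$ form is not used), adjusted
$R^2 = 1 - SSE(n-1)/(SST\,v)$ and $RMSE = \sqrt{SSE/v}$ with $v = n - m$.

## Width regression and validation

The mapping from best-fit parameters to width is learned by an ensemble of
bagged regression trees with random predictor selection (`ranger`,
single-threaded and seeded for bit-reproducibility). The hyperparameters are
unpublished; defaults are 100 trees, $\max(1, N/3)$ predictors per split,
minimum leaf 5, bootstrap with replacement, all overridable via
`regressor_config()`. Ground truth per profile is the Euclidean distance
between its two annotated edge points. Annotated and detected center points
are matched uniquely: candidate pairs under 5 px (exclusive) are accepted
greedily in ascending distance, which resolves ties globally in favor of
the closest pair.

Two validation schemes are provided: 10-fold cross-validation at the
profile level (random folds from the run seed) and leave-one-segment-out,
which withholds all profiles of one segment per iteration and is the harder
test, since neighboring profiles are highly correlated — LOSO
$\sigma_{error}$ exceeding CV $\sigma_{error}$ is expected and asserted.
Segment similarity is quantified by pairwise correlations of per-segment
mean profiles, aligned at their maxima and normalized by the larger
autocorrelation peak, so identical profiles score 1; for $n$ segments there
are $n(n-1)/2$ pairs (190 for 20 segments). Bland–Altman points
$(\psi_i, \omega_i - \psi_i)$ support the diameter-independence check.

## The synthetic data generator

The generator renders what the method needs to see, not photorealism: a
flat background (default 0.8) with dark tubes of diameter 3–25 px along
line, sine or arc centerlines; cross-section
$B - C\,g(d;\,D/4) + c_{clr}\,g(d;\,f\,D/4) + 0.35\,C\,g(|d|-D/2;\,0.8)$
in the profile models' exponent convention, where $d$ is distance to
the centerline, $C$ the contrast, $c_{clr}$ the CLR ridge height and $f$
its width fraction. The third term is a faint bright rim centered on each
edge, standing in for the perivascular halo and neighboring background
structure of real images. It is load-bearing: the peak-search rules look
for background maxima flanking the vessel, and an idealized dip with
monotone tails has none — every profile would fall back to the full window.
The rim constants (height 0.35 C, spread 0.8 px) were fixed once by a
design calculation on the integer-sampled cross-section so that a discrete
local maximum exists just outside each edge across the full diameter range,
giving profile lengths 1–3 px above the true diameter (overestimation
being the tolerated direction). Additive Gaussian pixel noise and exact edge points at $\pm D/2$ along the
analytic normals complete a scene; red/blue channels are scaled copies of
green so RGB readers work.

CLR ridges are only rendered as study conditions on vessels of at least
10 px: clinically the light reflex is a feature of larger vessels, and
below that the ridge spans under ±2 px, so its two flanking minima fall
within the 3 px minimum-separation rule — such a ridge is by definition of
the rules not a detectable CLR.

The model-based profile generator draws parameters from realistic ranges
and *rejects draws that leave the default fitting bounds of their own
profile* — the bounds are data-driven, and a strong CLR compresses the
observed range until the drawn $h_2$ falls outside the admissible box, a
configuration the fit is not allowed to reach. The "true width" of a model
curve is the distance between its flanking intensity maxima where they
exist; on sides where the model tail is monotone (no maximum) the
extreme-gradient point is used — a numerical edge definition that is
deterministic in the parameters, which is all the regression target needs.

The reference end-to-end study (`synthetic_study_records()`) renders 30
vessels, one per 90×110 image, diameters uniform on 4–20 px, contrast
0.35–0.5, noise sd 0.02, shapes cycling line/sine/arc at random
orientations, CLR on every other vessel of ≥ 10 px. On these conditions
10-fold CV reaches $\sigma_{error} < 0.1$ px with near-zero bias, and LOSO
roughly 0.8–0.9 px: with one vessel per segment, withholding a segment
withholds a diameter, so LOSO measures pure interpolation across vessels.
These sizes keep the whole study around a minute of CPU; they are
deliberately modest, and the numbers they produce are recomputed (never
stored) by the test suite and the acceptance script.

**What passing on synthetic data does and does not show.** The generator
exercises geometry (curvature, orientation, off-grid centers), CLR
morphology, noise and the full measurement chain, so it validates the
algorithmic contracts end to end. It does not emulate uneven illumination,
the optic disc and lesions, vessel branching, resolution diversity, or
observer-marked ground truth with human variability — absolute performance
on real fundus datasets cannot be inferred from these tests.

## Numerical choices and degenerate inputs

Coordinates are 0-based `(x = column, y = row)` in every table, origin at
the top-left pixel center (R matrix row arguments remain 1-based).
Bilinear sampling clamps out-of-image positions to the edge value and flags
them. `round()` half-to-even is used wherever a count is rounded (piece
counts, cut half-lengths), i.e. plain base R semantics. Flat profiles
(zero dynamic range) raise a degenerate-profile error at bound derivation
and fall back to the full span in limit detection; fits with fewer pooled
points than parameters raise; solver failures return the last iterate
flagged unconverged. Duplicate consecutive centerline points would make the
centripetal parameter non-increasing and are dropped before spline fitting
(they cannot arise from the integer path tracer). All randomness — noise,
fold assignment, bootstrap — flows from explicit seeds; identical inputs
and seeds give bit-identical outputs.

## Known limitations

Closely parallel vessels can imitate a CLR profile (a dark-bright-dark
triplet), the known failure mode of the rules; the validity thresholds
reduce but do not eliminate it. The thinning shortens segment ends by about
half the vessel width, so the first/last few annotated cross-sections of a
segment are typically unmeasured (visible as success rates below 100% on
synthetic scenes). Widths beyond the training range cannot be predicted by
regression trees, which average leaf values — a caution when applying a
regressor trained on narrow-range data. The CLR-rule thresholds and fitting
bounds are engineering defaults standing in for unpublished values; both
are exposed in the configuration so better-calibrated values can be
substituted without code changes.
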