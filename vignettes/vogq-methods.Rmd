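---
title: "Quantifying fluorescently tagged virions on glass: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescently tagged virions on glass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vogq)
```

## The measurement problem

Validating a fluorescently tagged HIV-1 integrase (IN) construct requires
answering three quantitative questions about the viral preparation, none of
which can be read off an image by eye:

1. **Labeling frequency** — what fraction of *bona fide* mature virions
   carry the fluorescent label? In trans-complementation systems a particle
   may package no labeled protein at all, so the labeled puncta must be
   compared against an independent marker of mature particles (an
   anti-capsid immunostain that only recognizes mature cores).
2. **Label stoichiometry** — how bright is a single labeled virion? Gag
   fusions ride the most abundant structural protein (>1500 copies per
   virion), whereas Gag-Pol fusions are packaged at roughly a 1:20
   Pol-to-Gag ratio, so the two labeling systems should differ about
   20-fold in per-particle intensity.
3. **Infectivity** — does the tag impair function? Read out as the percent
   of GFP-positive cells by flow cytometry against a non-infected control,
   or as p24-normalized luciferase signal.

The virus-on-glass (VOG) assay spins a viral preparation onto a coated
coverslip, producing a thin layer of diffraction-limited puncta. `vogq`
implements the full analysis for such data — deconvolution, projection,
detection, colocalization, and the companion infectivity statistics — and,
because public raw data for this assay do not exist, ships a synthetic-data
generator with exact ground truth so every stage can be validated by
parameter recovery.

## The synthetic VOG field

`simulate_field()` draws particle positions from a uniform spatial Poisson
process (expected count = density × area; clumps are allowed — chance
colocalization is handled downstream by a randomization null, not by the
generator). Particles sit in a thin layer near the focal plane with 0.05 µm
axial jitter, emulating virions immobilized on the coverslip.

Per-particle copy numbers follow a log-normal law around `gag_copy_mean`
(default 2000 — the literature states ">1500 copies", so the default sits
comfortably above that floor) with CV 0.25. A construct's labeled-IN copy
number is then determined by its anchoring mode:

* `gag_anchored` — one labeled IN per labeled Gag: copies = Gag copies;
* `pol_anchored` — copies = round(Gag copies × `pol_to_gag_ratio`), with
  the ratio defaulting to 1/20 (the Pol:Gag packaging ratio);
* `vpr_anchored` — treated like `pol_anchored` with a user-supplied ratio
  (Vpr incorporation is capped well below Gag);
* `none` — dark particles.

In trans configurations each construct labels a particle independently with
probability `incorporation_prob`; `dual_label_fraction` instead pins the
joint probability that a particle carries all labels (per-construct
probability = fraction^(1/k)). A `mature_fraction` (default 0.9) of
particles is flagged mature; only these carry signal in the reference
immunostain channel (4000 expected photons each), emulating an antibody
specific to mature capsids.

Photon yield is a single per-channel gain (default 2 photons per labeled-IN
copy). With the default background of 10 photons/pixel and 2 photons read
noise this puts Gag-anchored particles far above the detection floor
(peak SNR ≈ 20) and Pol-anchored particles near it — mirroring the
qualitative brightness ordering the two real labeling systems show. Each
particle is rendered as a separable 3-D Gaussian normalized over its
support, so the integrated rendered flux equals the ground-truth photon
count exactly before noise; shot noise is Poisson, read noise Gaussian,
and negative values are clipped at zero (photon-counting cameras report
non-negative ADUs).

The default pixel pitch is 0.108 µm/px (a 60× objective with 6.5 µm camera
pixels); only the magnification is documented for the original instrument,
so the pitch is exposed in `field_params()`. One user seed expands into
named per-purpose sub-streams (placement, labeling, maturity, noise), so
adding one noise source never shifts the draws of another, and a fixed seed
reproduces the field bit-for-bit.

**What the generator does not emulate:** optical aberrations and field
inhomogeneity, camera fixed-pattern noise, antibody off-target binding,
overlapping-particle clusters at high density (the generator refuses
densities beyond a cap), and any intracellular biology. Passing recovery
tests on these fields therefore demonstrates that the *estimators* are
correct and unbiased under the stated noise model — not that any particular
real microscope meets that model.

## Optics: PSF, deconvolution, projection

The point-spread function is a separable Gaussian approximation on the
voxel grid: σ~lateral~ = 0.21 λ/NA and σ~axial~ = 0.66 λ n/NA², discretized
at pixel centers, truncated at 3σ and normalized to unit sum. For
diffraction-limited puncta this is an adequate stand-in for a full
vectorial model and has the advantage of being analytically checkable
(width laws, unit sum, non-negativity are all asserted in the tests).

`richardson_lucy()` is the standard multiplicative-update restoration. The
image is padded reflectively by one kernel radius before iterating —
without padding, edge ringing would bias detections near the border, which
are excluded downstream anyway. The iteration count defaults to 15
(exposed in the run configuration); on noiseless blurred point sources the
restored flux is within 2% of truth by 20 iterations, and the re-blurred
residual is non-increasing, both asserted in tests. Convolutions run in
compiled code (separable 1-D passes for Gaussian PSFs, dense correlation
for arbitrary kernels) with reflective boundaries throughout.

Detection operates on the Z **maximum**-intensity projection of the
deconvolved stack. Photometry is different: iterative restoration sharpens
high-contrast spots faster than dim ones, so after a finite number of
iterations a bright particle concentrates more of its flux into its peak
plane than a dim one, and masses read off the maximum projection become
superlinear in photon count (we measured a 20-fold true intensity ratio
reading as ~29-fold through the max projection). When intensities are
compared across preparations the pipeline therefore measures mass on the
**sum** projection of the same deconvolved stack
(`locate(photometry_image = )`), which is exactly linear in flux. With
this split the recovered Gag:Gag-Pol median intensity ratio is ~18,
within 20% of the true 20.

## Detection

Candidate peaks are 8-neighborhood local maxima of a difference-of-Gaussians
bandpass (σ = 1 px noise scale minus σ = spot-diameter background scale,
negatives clipped) lying above the 99.7th percentile of the bandpassed
image. Candidates closer than `separation_px` (default = diameter, 7 px)
are resolved greedily, brightest first. Each kept peak is refined by
iterated intensity-weighted center of mass in a circular mask of radius
diameter/2 until the shift falls below 0.005 px (max 10 iterations).
Features inside the mask — background-corrected integrated mass (local
background = median of a 2 px annulus, per-pixel floor at zero), radius of
gyration in µm, eccentricity from second central moments — are recorded
per detection, and detections within diameter/2 of the border are
discarded.

Two defaults deserve justification:

* **Candidate threshold.** The 99.7th percentile of the full bandpassed
  image self-scales: on a deconvolved field the upper 0.3% of pixels is
  dominated by particle cores, so noise maxima rarely qualify; on blank
  input nothing does. A much lower percentile (some trackers default to
  the 64th) floods the refiner with noise maxima at this stage.
* **Mass floor.** With no user-supplied `min_mass`, Otsu's threshold over
  candidate masses separates noise peaks from particles — but only when
  both classes are actually present. On clean fields every candidate is a
  real particle and a blind Otsu split would discard the dim half of the
  population (we measured recall dropping from ~0.98 to ~0.55). The
  package therefore measures the image's own noise floor — the mask mass
  at a fixed 10×10 lattice of off-peak positions — and applies the Otsu
  cut only if the lower candidate class is consistent with that floor
  (mean below 4× the floor median). Dim-channel fields (Pol-anchored
  labels) keep precision ≥ 0.9 this way without sacrificing bright-field
  recall.

Coordinates are 0-based with pixel centers at integers; physical positions
are pixel × pixel size, and all downstream distances are in µm. On
synthetic fields at SNR ≥ 10 and ≤ 0.02 particles/µm² the chain reaches
recall and precision ≥ 0.95 with ≤ 0.05 µm centroid RMSE (asserted in the
test suite; typical RMSE is ~0.004 µm).

## Colocalization

Pairing is reference-anchored: for every detection in the mature-capsid
immunostain channel, the nearest query-channel detection is accepted iff
the centroid distance is strictly below 0.500 µm. Matching is many-to-one
by default — "all nearest neighbours of mature particles" — with an
optional greedy one-to-one mode for sensitivity analysis. The spatial
index is a threshold-sized grid with 3×3 bucket lookup; its output is
asserted equal to exhaustive O(n²) search over 50 random instances.
Reference detections within one threshold of the field border have
censored neighbourhoods and are excluded from the denominator.

Chance colocalization is estimated by resampling the query positions
uniformly over the field (with toroidal distances, so no edge correction
is needed in the null) and recomputing the fraction per shuffle; for a
uniform query process of intensity λ the null mean approaches the Poisson
void-probability complement 1 − exp(−λπr²), which the tests verify to
within 3 standard errors.

## Infectivity statistics

Singlet gating keeps events whose FSC-W/FSC-H and SSC-W/SSC-H ratios fall
within median ± 3 MAD-scaled robust SDs, fitted on all events. A gated
table records its gate in an attribute and re-gating at the same tolerance
is a no-op — refitting the band on an already-truncated sample would trim
a sliver more on every pass, which is never the analyst's intent.

The GFP gate is the 0.999 quantile of the gated non-infected control — the
conventional "0.1% of control is positive" rule, exposed as
`gate_quantile`. The synthetic event generator draws log-normal scatter, a
doublet subpopulation with 2× width-to-height ratio, and a two-component
log-GFP mixture: the infected component sits `separation` negative-SDs
above the negative mean with a spread 0.4× the negative component's. That
spread ratio is a deliberate choice: an integrated reporter forms a tight
bright population over a broad autofluorescence cloud, and it is what
makes a 0.999-quantile gate (+3.09 SD) recover the true infected fraction
at a 4 SD separation — with equal spreads, ~18% of the infected population
would sit below the gate and a 70% infection would read as 57%. The price
is a small asymmetry in the mixture: at 50% infection the fraction of
events above the inter-mean midpoint is ~0.511 rather than exactly 0.5
(the broad negative tail crosses the midpoint more than the tight
infected tail does), which the corresponding test acknowledges with a
±0.02 band.

`kruskal_wallis()` delegates to the tie-corrected `stats::kruskal.test`;
the test suite checks its χ² p-value against an exhaustive permutation
oracle at n = 8. Dunn's post-hoc comparisons are computed from mean-rank
differences on the pooled ranking with tie-corrected pooled variance and
Holm adjustment by default (the adjustment is configurable; the original
report names Dunn's test but not the correction). Luciferase tables are
background-subtracted (mean of the designated uninfected wells) and
normalized to p24 input per condition.

## Problem sizes and numerical choices

The recovery experiments run at sizes chosen to give stable estimates on a
single CPU: ~1000 particles across ten 512² fields for dual-label
colocalization recovery, ~2400 particles across twenty fields for the
either-or-both labeling frequency, 50,000 events for the flow recovery,
and five 256² fields per construct for the stoichiometry ratio. Particle
densities of 0.02–0.04/µm² correspond to the sub-confluent VOG regime
where nearest true neighbours sit several µm apart while chance
colocalization stays below ~3%.

Degenerate inputs are contracts, not crashes: zero density yields an empty
ground truth and a background-only image; an empty reference table is an
error (the colocalized fraction is undefined) while an empty query table
yields zero pairs; an all-zero feature mask reports mass 0 with a
degeneracy flag; ties at exactly the distance threshold are excluded
(strict inequality); a zero-sum PSF is an error. Richardson–Lucy guards
divisions with a 1e-12 floor. The run configuration rejects unknown keys,
and every output artifact embeds a hash of the full configuration.

## Known limitations

Localization is 2-D (projected); axial positions are neither estimated nor
used. The PSF is an isotropic Gaussian — adequate for colocalization at a
0.5 µm threshold, not for super-resolution claims. Intensity comparisons
assume both preparations were imaged under identical optics and gain, as
the assay prescribes. The flow model has no compensation/spillover and the
luciferase model no dose-response curvature; both exist to exercise the
statistics, not to simulate instruments. Printed per-construct
colocalization values for the original experiments exist only as graphical
ranges (70–90%), so recovery is validated against ground truth and checked
to land at or above the printed lower bounds, not point-matched.
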