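---
title: "Quantifying spot-assay plate images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spot-assay plate images: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotlag)
```

## The measurement problem

Detecting *Brettanomyces bruxellensis* on cycloheximide-supplemented agar is
slow: tolerant strains form colonies in days, sensitive ones take weeks or
never grow. The spot assay spots 2 µL drops of serial dilutions onto
12 × 12 cm plates and photographs them every 2–3 days for 20 days. spotlag
turns those photographs into two phenotypes per drop:

* **lag phase** — the first imaging day on which the colony-covered area of
  the drop strictly exceeds a detection threshold: 500 px for all but the
  lowest inoculum density, 250 px for the lowest (at the package's reference
  scale of 10 px/mm). A drop that never crosses its threshold is
  right-censored at the incubation horizon and carried through every table
  as an explicit `>20`-style value, never silently dropped.
* **Amax** — the maximum area the drop reaches over the whole series. We use
  the series maximum rather than strictly the final frame: identical for
  monotone curves, robust to a final-frame artifact.

Lags are reported on the discrete imaging grid with no interpolation between
photographs — the assay's own day-level resolution — and are normalized by
subtracting the matched control lag of the same strain: the 0 g/L plate in
the plain screening, or the same-residence-time sample from unmodified wine
plated without drug in the wine design.

## Registration

All frames of a plate are quantified on the pixel grid of the reference
frame (the last time point, where colonies are most visible for template
picking). Each earlier frame is realigned by a plane-projective
transformation anchored to the four plate corners. Four point
correspondences determine a homography exactly, so the eight unknown matrix
entries are solved from the eight incidence equations; when the fitted
matrix falls within 1e-9 of the affine or identity subfamily, it is
classified as such. We chose the full projective family because four anchor
points determine it with no residual freedom; an affine-only mode would
discard information the four corners provide, and perspective error from a
hand-held or repositioned camera is exactly what the fourth degree of
freedom absorbs.

Resampling is bilinear with out-of-frame pixels filled with background 0 —
the fill must never create foreground. Corner anchors come either from
bright fiducial marks, located as intensity-weighted centroids inside a
110 px search window at each image corner (the synthetic rig draws such
marks; the window must cover the fiducial without reaching the first drop
ROI), or from coordinates supplied in the layout for real photographs where
corners were picked by hand. RGB input is reduced to Rec. 709 luminance
before any processing so that one pipeline serves grayscale and color rigs.

## Segmentation and area measurement

Foreground is separated from agar per frame — illumination drifts over an
incubation that lasts weeks, so a per-series fit would be biased — by a
two-component Gaussian mixture on pixel intensities. The EM runs on a
512-bin histogram of the frame (weighted by bin counts), which keeps every
pixel's evidence while making the fit cost independent of frame size. The
fit is deterministic: components are initialized at the intensity extremes,
which converges whether background or foreground dominates the histogram,
and iterated at most 100 times to a relative log-likelihood tolerance of
1e-6. Pixels are hard-assigned by maximum posterior responsibility (areas
are integer pixel counts), with the colony component being the brighter one
under the default dark-field polarity (a configuration flag flips this for
rigs where colonies image darker than agar).

Two guards prevent hallucinated growth: if the component means are closer
than 0.05 intensity units the frame is declared growth-free (an empty mask),
and if the nominal foreground would cover more than 90 % of the frame the
mask is zeroed with a warning — that is a saturated or degenerate image, not
colonies.

A drop's area is the count of foreground pixels within its circular ROI
(default radius 40 px = 4 mm at 10 px/mm), a deterministic integer. The unit
tests hold this count to exact integer equality against an exhaustive
per-pixel distance scan.

## Statistics

Group comparisons use the Kruskal–Wallis test on midranks with tie
correction, followed by Dunn's pairwise z statistics on the same pooled
ranks. Published protocols for such assays rarely state the p-adjustment;
we default to Benjamini–Hochberg (Holm and none are options) and condense
the adjusted-p matrix into a compact-letter display by insert-and-absorb, so
that two levels share no letter exactly when they differ at the chosen
alpha (default 0.05). A graph-theoretic test re-checks this equivalence on
every run.

Variance in normalized lag is partitioned by multifactorial ANOVA (main
effects plus interactions), reporting each term's share of the total sum of
squares. Type II sums of squares are the default because dropping censored
lags unbalances the design and Type II is invariant to term order;
sequential Type I is available for comparison with legacy analyses.
Censored lags are excluded from both procedures by default (with a logged
count): rank tests and linear models on mixed censored data would need
survival machinery that is out of scope here. An optional flag instead
treats censored lags as horizon + 1 days in summaries.

## The synthetic generator

Raw plate photographs for this assay are typically distributed on request
only, so the package ships a generator that emulates the study design with
known ground truth; every pipeline stage is validated against it.

* **Strains.** Three tolerance archetypes are sampled (defaults 15 % low
  tolerance / 60 % intermediate / 25 % resistant). Baseline detection lags
  are uniform on 2.2–7.5 d, which lands grid lags on 3–8 days at dose 0 —
  the range the assay reports. Low-tolerance strains carry a finite
  complete-inhibition dose (0.1/0.25/0.5 g/L); intermediate strains grow
  everywhere but lose 35–55 % of Amax at 0.5 g/L with 3–6 d of lag
  extension per log-dose unit; resistant strains stay within ~2 extra days
  and lose at most 15 % of Amax. With these defaults the mean
  top-dose-to-control Amax ratio sits in the 0.5–0.7 band — the 30–50 %
  mean reduction regime the assay describes.
* **Kinetics.** Per-drop area follows a logistic
  `A(t) = Amax(dose) / (1 + exp(-k (t - t_mid)))`. A logistic matches the
  sigmoid area curves the assay produces and has a closed-form threshold
  crossing, which doubles as the test oracle. Dose enters the midpoint
  through `log10(1 + dose/0.005)` — the tested doses span two orders of
  magnitude — and each tenfold increase of inoculum density shortens the
  lag by `density_effect` days (default 0.3–0.8 d/decade, matching the
  observed ~2-day gap between high- and low-density spots).
* **Rendering.** Colony counts are Poisson at the nominal density of the
  class (5/50/500/5000 per drop; at the undiluted density only 60 colony
  centers are rendered — per-drop area, not colony morphology, is the
  quantity under test). Each frame switches on exactly `ceiling(A(t))` ROI
  pixels, grown outward from the colony centers by nearest-pixel ordering.
  The ceiling makes pixel-count > threshold equivalent to continuous area >
  threshold for the integer thresholds 250/500, so on noise-free input the
  pipeline lag equals the true crossing rounded up to the next imaging day
  exactly; the fixed ordering makes masks nested over time, which is the
  monotonicity invariant the tests check. Fiducials, a linear illumination
  gradient (default ±0.03), per-frame jitter (±5 px translation, ±2°
  rotation, up to ~1 % projective distortion; the reference frame is never
  jittered, since it *is* the template) and additive Gaussian noise
  (default sd 0.02, a mild camera-noise level) complete the frame. All
  draws are deterministic for a fixed seed, and the generator restores the
  caller's RNG state.
* **Wine stresses.** Residence in stressed wine adds a per-strain lag
  offset at the top dose — 3–5 d for 14.5 % vol ethanol, 2–3 d for
  sulfite-containing modalities, 0–1 d for acidification alone — scaling
  linearly to lower doses, preserving the stress hierarchy
  ethanol > SO2 > pH 3.0 > original wine at every dose.

What the generator does **not** emulate: agar texture, colony merging
biology, condensation, lighting vignettes beyond a linear gradient, or
camera distortion beyond a homography. Tests passing on synthetic data
therefore validate the geometry, segmentation and bookkeeping of the
pipeline, not its robustness to every artifact of real photographs — real
rigs should start from the config-supplied-corner path and inspect
segmentation masks before trusting areas.

## Molecular SO2

Wine conditions are characterized by the biologically active molecular
fraction of free SO2 via the first dissociation equilibrium,
`mSO2 = free / (1 + 10^(pH - pKa_eff))`. The effective pKa uses the water
value 1.81 at 20 °C with a mild linear temperature term and a linear
ethanol correction, the standard oenological form. The ethanol slope is
calibrated once so that a single pKa_eff (≈ 2.02 at 20 °C, 12.91 % vol)
reproduces both published anchor pairs (7 mg/L at pH 3.0 → 0.65 mg/L;
15 mg/L at pH 3.76 → 0.27 mg/L) within ±0.01 mg/L; the two pairs solved
independently give pKa 2.010 and 2.023, and the package pins their mean.
Only the equilibrium fraction is computed — SO2 binding kinetics over time
in wine are out of scope.

## Tolerance profiles

The three-class taxonomy is descriptive, so its cutoffs are configuration,
not biology: a strain is *low tolerance* if any tested dose fully
suppresses growth (censored lag), *resistant* if at the top dose its
normalized lag is ≤ 2 days and it retains ≥ 80 % of its control Amax, and
*intermediate* otherwise. Replicates are collapsed by medians before
classification; replicate lags disagreeing by more than one imaging
interval are flagged rather than averaged away.

## Numerical edge cases

* Exactly-threshold areas do not count as detection (the definition is
  strict inequality); the boundary case is pinned by a unit test.
* A blank or uniform frame has no separable mixture: empty mask, no error.
* Collinear corner anchors and non-convex corner quadrilaterals are
  geometry errors, not silent misfits; drop ROIs must sit strictly inside
  the corner quadrilateral and be pairwise disjoint.
* A censored control makes a normalized lag undefined (warning), not zero.
* Areas above the ROI's pixel capacity are clipped with a warning in the
  generator.

## Problem sizes used in validation

The shipped tests validate pixel-exact area equality on 50+ rendered
frames; registration recovery on 25 random homographies of jitter magnitude
plus every frame of a rendered noisy series; lag recovery on a 20-strain ×
7-dose × 2-density experiment (280 drops) in both a noise-free arm (exact
recovery required) and a noisy jittered arm (σ = 0.05; ≥95 % within one
imaging interval); the type-I error of the rank test over 1000 null
simulations; and a balanced two-factor variance partition with known 2:1:1
components at 20 replicates per cell. These sizes exercise every code path
at full plate resolution (1200 × 1200 px) while staying desk-scale.
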