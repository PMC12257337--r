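---
title: "Statistical methods behind the automated LCOD score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the automated LCOD score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrlcod)
```

## The detection model

The LCOD insert of the large ACR phantom is a known geometry: 10 spokes of
three holes each, hole centers at 12.5, 25 and 38 mm from the insert
center, diameters falling linearly from 7 mm (spoke 1) to 1.5 mm
(spoke 10) in a clockwise sequence, and per-sheet hole/background contrasts
of 1.4, 2.5, 3.6 and 5.1 % on slices 8–11. `acrlcod` turns "is this spoke
visible?" into a regression question: the 90-sample radial intensity
profile through a spoke is modeled as

$$ y = \beta_1 h_1 + \beta_2 h_2 + \beta_3 h_3
     + \gamma_0 + \gamma_1 r + \gamma_2 r^2 + \varepsilon, $$

where $h_i$ is the binary indicator of hole $i$'s radial support on the
sample grid and the polynomial terms absorb smooth intensity
non-uniformity (shading from coil sensitivity or disabled pre-scan
normalization). Each hole is tested with $t_i = \hat\beta_i /
\mathrm{SE}(\hat\beta_i)$ on $n - 6 = 84$ degrees of freedom, two-sided by
default: a hole "exists" when its mean intensity differs from the local
baseline in either direction, which keeps the test agnostic to the
hyper-/hypo-intense polarity of the holes in a given weighting. A
one-sided mode with configurable polarity is available where the polarity
is known and extra sensitivity is wanted.

Multiplicity is controlled in two layers. The family-wise level 0.05 is
Bonferroni-divided across the four LCOD slices, giving the per-slice level
0.0125; within a slice the 30 hole p-values are pooled and passed through
the Benjamini–Hochberg step-up at q = 0.0125. We pool *holes*, not
spokes, because holes are the tested hypotheses; the pool is a
configuration knob for sites that prefer spoke-level pooling. A spoke
passes when all three of its holes are rejected — a conjunction, so the
weakest hole always governs.

## Geometric search

The nominal spoke angles assume a perfectly positioned phantom. Two
searches relax that:

* **angle**: every candidate in ±8° around the nominal angle in 0.5°
  steps. The half-range is part of the method definition; the 0.5° step is
  our choice — at the outermost hole radius (38 mm) 0.5° is ≈0.33 mm,
  well below the narrowest hole diameter, so a finer grid cannot change
  which template samples a hole covers.
* **jitter**: the resampled profile is shifted by −5…+5 whole samples
  (≈±2.5 mm), compensating residual COG error and gradient-distortion
  stretch. Vacated edge samples replicate the boundary value; zero-filling
  would fabricate exactly the kind of step the hole regressors detect.

Among all candidates the fit maximizing $\min_i |t_i|$ is kept (signed
$t$ in one-sided mode); ties keep the first candidate in scan order, so
results are exactly reproducible. Searching before testing makes the
selected p-values optimistic — see *Limitations*.

## Segmentation and profile extraction

Slices are affinely normalized to [0, 1]; Otsu's criterion on a 256-bin
histogram separates phantom from background without tunable parameters.
Among the labeled foreground components, the inner contrast disk is the
component whose equivalent radius $\sqrt{A/\pi}$ is within ±20 % of the
45 mm design radius and whose centroid is nearest the image center (larger
area breaks ties); anything else — rim, artifacts — is rejected, and if no
component qualifies the slice is scored 0 and flagged rather than silently
dropped. Holes are filled before the unweighted centroid is taken so the
low-contrast holes cannot bias the COG.

Rays are sampled at half the pixel pitch with bilinear interpolation
(Nyquist-safe for 256 × 256 / 250 mm acquisitions), truncated at the first
step outside the disk mask — the mask, not a literal zero-intensity test,
because normalized backgrounds are near but not exactly zero — and
linearly resampled to 90 evenly spaced samples spanning COG to edge,
≈0.5 mm per sample on a 45 mm disk. Resampling to a fixed grid is what
makes profiles comparable across fields of view, matrix sizes and mild
distortion.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha_total` | 0.05 | — | conventional family-wise level |
| `n_lcod_slices` | 4 | — | Bonferroni divisor, gives 0.0125/slice |
| `angle_search_deg` | ±8 | deg | rotation compensation half-range |
| `angle_step_deg` | 0.5 | deg | ≈0.33 mm at the outer hole, sub-template resolution |
| `max_jitter_samples` | 5 | samples | ≈2.5 mm alignment slack |
| `n_profile_samples` | 90 | — | ≈0.5 mm grid on a 45 mm disk |
| `sidedness` | two-sided | — | polarity-agnostic detection |
| `scoring_mode` | all-passing | — | count every passing spoke; `acr-consecutive` mimics manual reading, counting from spoke 1 to the first failure |

The phantom geometry itself ships as an editable `phantom_layout()` /
YAML config. The per-slice angles of spoke 1 are **assumptions** (90° —
3 o'clock — on every slice): they are fixed by each physical phantom's
construction but not standardized in print, so sites should calibrate them
once against a well-positioned scan and persist their own layout file. The
±8° search absorbs moderate errors in this assumption.

## The synthetic phantom

`simulate_volume()` renders what the detector assumes: a 256 × 256,
250 mm-FOV slice stack (5 mm nominal thickness) with a uniform phantom
body (95 mm radius), the inner contrast disk delimited by a thin dark
membrane ring (2 mm wide at 15 % intensity — the plastic rim that lets
histogram thresholding isolate the insert in real scans), and 30 holes per
LCOD sheet at intensity `background × (1 + contrast)` with 4 × 4
sub-pixel area-weighted anti-aliasing; 1.5 mm holes are ≈1.5 px wide, and
hard rasterization would alias them away entirely. Slice 7 is the uniform
section used for SNR. Configurable degradations: additive Gaussian noise
with σ = background/SNR (Rician optionally, indistinguishable from
Gaussian at the SNR ≥ 100 of clinical phantom scans), in-plane rotation of
the hole pattern, sub-pixel translation, and a multiplicative second-order
polynomial bias field. Bandwidth changes are emulated purely as noise-level
changes; there is no k-space model, no ghosting, no Gibbs ringing, and
distortion is only affine. Passing tests on simulated volumes therefore
demonstrate the statistical engine and its geometric robustness — not
immunity to structured artifacts of real acquisitions.

Seeding is hierarchical: each slice's noise derives deterministically from
the volume seed and the slice index, and the simulator restores the
caller's RNG state, so studies are reproducible and slices mutually
independent.

## Numerical choices

* Hole indicators use inclusive edges ($|r - c| \le d/2$) without
  fractional weighting: on a 0.5 mm grid the two boundary samples
  contribute negligibly next to the hole interior.
* The nuisance polynomials enter as design columns (equivalent up to
  column span to pre-fitting and subtracting them) so each candidate is a
  single least-squares solve; the basis is orthogonalized for conditioning
  and, being affine-invariant, cached per grid length.
* Zero-residual fits are treated as the limit of vanishing noise:
  p = 0 for a nonzero hole effect, p = 1 for a zero one, so noise-free
  fixtures behave continuously.
* A constant image cannot be normalized and a sub-41.5 mm ray cannot
  contain the outermost hole; both are hard errors. A failed segmentation
  scores the slice 0 *with a flag*, keeping study totals defined.
* BH rejection is computed through `p.adjust(·, "BH") <= q`, which is
  algebraically the step-up rule; the test suite cross-checks it against an
  exhaustive step-up oracle, and the GLM against an independent
  normal-equations solver.

## Problem sizes in the test suite

The statistical suites run at sizes chosen to give stable Monte-Carlo
estimates while keeping the default test run comfortably interactive:
null-control uses 500 simulated zero-contrast slices; the
monotonicity-in-quality checks use 50 seeds per condition at SNR 60/150/400;
oracle comparisons use dozens of randomized small cases with fixed seeds.

## Limitations

* **Selection optimism.** The angle/jitter search maximizes the weakest
  hole's statistic over ~360 candidates *before* testing, and no
  search-multiplicity correction is applied — deliberately, as part of the
  method's definition. Under a global null (0 % contrast) the selected
  per-hole tests are therefore markedly anti-conservative, and the
  per-hole false-rejection proportion after BH exceeds the nominal q; the
  acceptance suite measures this honestly and the corresponding check
  documents the gap. The spoke-level conjunction (all three holes must
  pass) tempers, but does not remove, the effect. Users comparing scores
  across sites should treat the per-slice level as an operational
  constant, not a calibrated type-I error rate.
* **Borderline spokes flip.** At the standard contrasts the smallest
  spokes on the 1.4 % slice sit near the decision threshold at clinical
  SNR, so exact score equality between two acquisitions — including two
  rotations of the same phantom — is not guaranteed even when the method
  tracks the rotation perfectly; the rotation-robustness check therefore
  runs on a clearly-detectable volume, where totals are invariant across
  the search range and degrade only beyond it.
* **Geometry assumptions.** Per-slice base angles default to an assumed
  value (above); severely tilted or off-center phantoms violate the
  radial-profile model and surface as segmentation failures rather than
  wrong scores.
* **Scope.** Only the large-phantom LCOD geometry is encoded; the other
  six ACR tests and the medium/small phantom variants are out of scope.
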