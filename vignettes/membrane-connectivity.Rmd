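---
title: "Membrane connectivity scoring of HER2 immunohistochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane connectivity scoring of HER2 immunohistochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memconn)
```

## The problem

HER2 immunohistochemistry (IHC) on breast-cancer tissue is conventionally
read by a pathologist as an ordinal score — 0/1+ (negative), 2+ (equivocal,
reflexed to FISH), 3+ (positive) — based on how complete and intense the
brown DAB staining of tumour-cell membranes appears. Visual scoring is
semi-quantitative and subject to intra- and inter-observer variation.
`memconn` implements a digital-analysis alternative: a continuous
*membrane connectivity* estimate computed from the geometry of the stained
membrane network in a tissue-microarray (TMA) spot image, together with the
statistical toolkit needed to test its concordance with visual scores and
with HER2 FISH.

A deliberate property of the approach is that it is *not* cell-based: it
requires no nucleus detection, no tumour/non-tumour classification and no
manual annotation. The only tissue-level prerequisite is a sufficient
amount of tissue in the analyzed region, which is enforced by an explicit
area control.

## The measurement model

### From RGB to stain densities

Brightfield transmission follows the Beer–Lambert law, so each pixel is
converted to per-channel optical densities
`OD_c = -log10((I_c + eps) / 255)` (with `eps = 1` intensity unit guarding
`log 0`) and decomposed onto unit stain vectors for hematoxylin and DAB
(the standard published H-DAB basis; `stain_vectors_hdab()`), plus their
orthogonal complement as a residual channel. Negative decomposition
coefficients are clipped at zero, so a pure-white (glass) pixel carries no
stain. `stain_od_to_rgb()` is the exact forward model; the round trip is
accurate to numerical precision and is asserted at `1e-6` in the tests.

### Membrane enhancement and segmentation

Stained membranes appear as thin brown curvilinear ridges. They are
enhanced with a single-scale Hessian ridge measure on the DAB density: at
scale `sigma = ridge_scale_um / mpp` the eigenvalues `l1 >= l2` of the
Gaussian Hessian are computed and the response is
`sigma^2 * max(0, -l2) * exp(-(l1/l2)^2 / (2 * 0.5^2))`, i.e. the bright
cross-ridge curvature damped where the two eigenvalues are similar
(isotropic blobs). The response is zero on constant images, shift
equivariant, and invariant to adding a constant to the density. The default
`ridge_scale_um = 1.0` is of the order of a stained membrane's thickness.

The binary membrane mask is then obtained by a single global bimodal
threshold — Otsu's two-class criterion over the response values of pixels
that carry any DAB — intersected with a DAB-density floor
(`min_dab_od = 0.15` OD) so that chromogen-free ridges cannot enter the
mask. A constant response map is treated as degenerate and yields an empty
mask.

### Fragments and the connectivity statistic

The mask is thinned to a one-pixel-wide skeleton with a Guo–Hall
two-subiteration scheme (topology preserving: loops stay loops, components
stay connected), and 8-connected skeleton components become *membrane
fragments*. The size of a fragment is the number of skeleton pixels it is
composed of. Two post-processing steps mirror how stained membranes behave
in real sections: fragments whose skeletons approach within `gap_px`
(default 3 px) are merged — membranes that are imperfectly stained are
rarely perfectly connected — and fragments below `min_fragment_px`
(default 10 px) are discarded as noise.

The connectivity of the region is the size-weighted mean of a per-fragment
ramp weight:

$$C = \frac{\sum_i a_i\, w(a_i)}{\sum_i a_i}, \qquad
  w(a) = \mathrm{clamp}\!\left(\frac{a - c_{low}}{c_{high} - c_{low}},\ 0,\ 1\right)$$

so that `C = 0` when no fragment exceeds the low cut-off and `C = 1` when
every fragment is at or above the high cut-off, exactly the two boundary
behaviours that define the statistic; between them the size-weighted ramp
is the simplest continuous interpolation, and we document it explicitly as
an interpretation (the published description of the method fixes only the
two boundary conditions). `C` is continuous and non-decreasing in every
fragment size, invariant to rescaling all sizes and both cut-offs together,
and never decreased by merging two fragments.

The ordinal HER2 score follows from fixed thresholds with the boundary in
the lower category: 0/1+ for `C <= 0.12`, 2+ for `0.12 < C <= 0.56`, 3+
above 0.56.

### Cut-off defaults

The numeric fragment-size cut-offs of the original instrument are not
published. The package defaults, `c_low = 50` and `c_high = 500` skeleton
pixels, were chosen at 0.25 um/px scale: 50 px is about 12.5 um of
membrane — well below one cell perimeter, so isolated flecks carry no
weight — and 500 px (about 125 um) is several cell perimeters, i.e. a
chain of cells with confluent staining. They are calibrated such that the
synthetic generator's complete-membrane spots score 3+ and its
membrane-free spots score 0/1+ under the default configuration, and both
are ordinary configuration keys. They are declared substitutes for the
unpublished values, not reconstructions of them.

## Region of interest and adequacy

A spot's tissue is detected as pixels whose mean per-channel OD exceeds
`tissue_od_floor = 0.1`, with hole filling and removal of connected specks
under 100 px. The region of interest is the tissue eroded so that every
ROI pixel lies at least `margin_px = 100` px (about 25 um at 0.25 um/px)
from the nearest non-tissue pixel, which guards against edge-staining
artifacts. A spot enters the analysis only if the ROI area strictly
exceeds `min_roi_area_um2 = 37000` — about 5% of the ROI of an intact 1-mm
spot. Spots excluded by a pathologist (inadequate sample, DCIS) are
honored from the input metadata before any processing.

## Concordance statistics

Agreement between two raters on the 3-category scale is summarized by
weighted kappa with **linear** weights `w_ij = 1 - |i - j| / 2`. The weight
scheme matters: on the bundled reference cross-tabulations linear weights
reproduce every published kappa (0.91/0.86/0.87 by spot, 0.88/0.80/0.86 by
patient) to two decimals, while quadratic weights give, e.g., 0.95 instead
of 0.91 for the first table — which is how the linear scheme was
identified. The standard error is the Fleiss–Cohen–Everitt large-sample
value with a normal-theory 95% interval; the reference intervals are
matched within ±0.02, and since the original variance estimator is
unstated, that tolerance is part of the package's acceptance checks rather
than an exact claim.

Patient-level scores are the **maximum** over the patient's adequate spots
(2–4 spots required by default, `min_spots = 2`): with heterogeneous
tissue and limited TMA sampling, the maximum is more sensitive than the
mode or median (both available as alternative aggregators). FISH
positivity uses the strict rule HER2/CEP17 ratio > 2.0; polysomy is
CEP17 > 3 and copy-number amplification HER2 > 6, both strict, used for
reporting. Note that per-patient FISH ratios reported by counting 20 cells
are means of per-cell ratios, so they track but do not exactly equal the
ratio of the mean copy numbers; `aggregate_patients()` keeps the supplied
ratio and only reports discrepancies beyond `ratio_tol`.

Correlations between the continuous connectivity summary
(`connect_max`, the per-patient maximum) and FISH variables are Pearson
correlations on (optionally) log-transformed values with two-sided t
p-values; non-positive values under a log are an input error.

## The synthetic generators

No public image set accompanies the method, so the package ships
generators that define the conditions under which it is validated.

**Spot images** (`generate_spot_image()`): a 1-mm tissue disc (default
scale 0.25 um/px) holding round cells of radius 8 um on a hexagonal
lattice at one-cell-diameter spacing, grouped into compact nests of
heterogeneous sizes (exponential weights, at least 3 cells per nest, about
one nest per 10 cells). Within a nest adjacent cells share their membrane
band — rasterized tangency between non-overlapping discs is numerically
fragile, whereas shared membranes are both robust and biologically the
norm in cohesive carcinoma nests. Each cell carries a hematoxylin nucleus;
a DAB membrane arc (OD 0.8, thickness 1 um) covers the `completeness`
fraction of its perimeter, contiguously — the worst case for connectivity
at a fixed stained fraction. Gaussian OD noise (sd 0.02) is added and
pixels are rendered through the forward Beer–Lambert model into 8-bit RGB.
All random draws happen before completeness is applied, so images at the
same seed and different completeness share their layout and the stained
set grows monotonically — which is what makes the completeness →
connectivity dose–response measurable without confounding.

The minimum nest size matters for one subtle reason: the connectivity is a
size-*weighted mean*, so completing the ring of an isolated single cell
adds a long-but-light fragment that can slightly *lower* `C` of an
otherwise saturated spot. Nests of three or more cells keep the smallest
stained unit inside the ramp zone, where its weight grows with
completeness, and the measured dose–response is then strictly increasing
(rank correlation 1.0 on the 0–1 completeness grid, checked in the
acceptance tests at spot diameter 600 um, 0.5 um/px, 200 cells — sizes
chosen so the full grid runs in about a minute on one CPU).

What the generator does **not** emulate: scanner color variation,
out-of-focus blur, stromal texture, cytoplasmic DAB, necrosis, folded
tissue. Passing the synthetic suite therefore shows that the pipeline
measures what it claims on clean membrane geometry with realistic stain
physics; it does not certify performance on real slides.

**Cohorts** (`generate_cohort()`): a latent per-patient HER2 burden drives
a true 3-category score (marginals 0.845/0.050/0.105); each patient
contributes 1–4 spots (census 16/15/55/91 out of 177 patients, about 575
spots); each of three raters observes a spot with an independent
one-category flip probability (visual raters 0.02 — about 96% raw
agreement and linear kappa near 0.91 at these marginals; digital 0.05 —
kappa near 0.86). Per-spot connectivity is drawn from a category-
conditional logit-normal (centers `qlogis(0.03, 0.30, 0.92)`, sd 0.8),
which produces the characteristic bimodal distribution of per-patient
maxima. FISH copy numbers are lognormal, coupled to the standardized
per-patient log maximum connectivity through a Gaussian copula: HER2 with
loading `rho = 0.67` (sd-log 0.8 around median 3.5 copies/cell) and CEP17
with loading 0.4 (sd-log 0.3 around median 2.6), putting the raw-CEP17
correlation near 0.39. Category-dependent FISH means arise through the
shared latent rather than being set per category. At this operating point
152-patient cohorts recover the HER2 log-correlation within ±0.15 and
575-spot cohorts recover the visual-visual kappa within ±0.05, seed by
seed.

## Numerical choices and degenerate inputs

* Distances are Euclidean in pixels; pixel (0,0) is the top-left corner.
* The ridge scale is clamped to one pixel (with a warning) when
  `ridge_scale_um < mpp`.
* Second-derivative Gaussian kernels are mean-corrected so a constant
  image yields an exactly zero response.
* Thinning tie-breaks are those of the Guo–Hall subiteration order and are
  pinned by regression tests on programmatic rings and segments.
* An empty membrane mask, an all-background image, or a degenerate
  response histogram all yield a connectivity of 0 without error; an empty
  contingency table or degenerate kappa marginals are errors.
* Fragment linking is implemented as dilation by `ceiling(gap_px / 2)`,
  reconnection and re-thinning; `gap_px = 0` is the exact identity.
* All randomness is owned by the generators' `seed` parameters; the image
  pipeline itself is deterministic, and identical image + configuration
  give bit-identical results.

## Known limitations

* The pre-processing/segmentation operators of the original instrument are
  unpublished; the stain-OD + Hessian-ridge + Otsu chain here is a
  declared substitute, chosen as the field-standard minimal operators, and
  is configuration-swappable.
* Only the DAB/hematoxylin chromogen pair is supported; there is no color
  normalization across scanners.
* Image-level published numbers (per-spot connectivity values) are not
  reproducible without the original images; image-level validation is
  therefore property-based on synthetic data, while the statistical layer
  is validated exactly against the bundled reference tables.
* The per-patient analysis assumes one observer rating twice plus one
  digital read; multi-observer models are out of scope.
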