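---
title: "Attenuation correction of the nasal sinus region for brain PET-MRI"
author: "sinusMRAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation correction of the nasal sinus region for brain PET-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusMRAC)
```

## The problem

Quantitative PET requires correcting the emission data for photon
attenuation, which needs a map of linear attenuation coefficients at
511 keV (a mu-map, cm^-1). CT measures electron density directly and a
CT-derived mu-map (CTAC) is the accepted reference; MRI does not, so
MR-based attenuation correction (MRAC) on PET-MRI systems typically
segments the anatomical MR image into a few tissue classes and assigns
each class a fixed coefficient. That works well for most of the head, but
the nasal and paranasal sinuses are a fine mixture of air, thin bone and
mucosal soft tissue. Unified MR segmentation has no class for this
mixture and mostly labels it bone, which badly overestimates attenuation
in a region that is, by volume, mostly air. This package implements and
evaluates three treatments of the sinus region on top of a conventional
four-class segmentation-based MRAC:

* **bulk** -- assign the whole sinus region one fixed coefficient,
  0.100 cm^-1;
* **cuboid** -- fit an axis-aligned box to each subject's own anatomy by
  maximising a bone-coverage score, then convert the bone-labelled voxels
  inside it through an MRI-to-CT intensity model;
* **template** -- define the box once in a canonical (MNI-like) space and
  pull it back to the subject through an inverse deformation field, then
  convert as above.

## The four-class attenuation map

Six tissue probability maps (grey matter, white matter, CSF, scalp/soft
tissue, skull/bone, air) are inputs; producing them (e.g. with a unified
segmentation tool) is out of scope, and the upstream segmentation
parameters are treated as provenance metadata only. Classification
thresholds are 0.25 for air, 0.50 for soft tissue, 0.25 for bone and 0.5
for brain (grey + white + CSF pooled). The thresholded masks are combined
innermost-out with precedence **brain > bone > soft > air**: the
probability maps are not mutually exclusive, the brain must be protected
from skull leakage, and air is the natural fallback for voxels passing no
threshold. Class coefficients are 0.0 (air), 0.096 (soft tissue), 0.0985
(brain) and 0.151 cm^-1 (bone). A brain coefficient ten times the water
value is physically impossible at 511 keV, so the brain slot defaults to
0.0985 cm^-1; it is configurable in `muCoefficients()` should a different
convention be needed.

The CT reference map uses a continuous two-segment (bilinear) HU-to-mu
scaling for a 120 kVp acquisition, parameterised so that -1000 HU maps to
0, 0 HU (water) to the soft-tissue class value 0.096 cm^-1, and 157 HU --
the bone/non-bone boundary used throughout the evaluation -- to
0.105 cm^-1. The implied slope above the break reaches 0.153 cm^-1 at
1000 HU, consistent with the single bone class value. Voxels the CT
acquisition did not cover are flagged NaN and complemented with the
soft-tissue coefficient where the MR-based map marks soft tissue.

## Sinus delineation

**Air cavities.** The initial mask is the air-classified voxels inside
the head envelope (the morphological fill of the union of the soft, bone
and brain masks). Literally intersecting the air and soft probability
masks voxelwise would be near-empty; the operative notion is *interior
air*, which the envelope construction captures while excluding the
background air around the head. The per-slice voxel counts of this mask
form an axial profile; scanning the profile in ascending slice order, the
seed slice is the largest local maximum at or before the largest single
inter-slice drop (ties: earliest drop, then the maximum closest to it;
boundary slices count as maxima against a virtual -Inf neighbour). Each
8-connected 2-D component in the seed slice contributes one seed at its
centre of mass snapped to the nearest in-component voxel, and 26-connected
3-D region growing from the seeds delineates the cavities. Pockets not
connected to any seed -- the throat, stray misclassifications -- are
excluded by construction. 26/8-connectivity is deliberate: fine sinus
channels are diagonal-connected at 2 mm resolution. All tie-break and
connectivity choices are configurable at the function level.

**Cuboid fit.** Candidate boxes C are scored by the cuboid goodness

$$CG = \frac{\sum_{i \in C} p_i}{(c/4)^2},$$

where $p_i$ is the bone probability of voxel $i$ and $c$ the perimeter of
the cuboid. A 3-D solid has no canonical perimeter; the default reading
takes $c$ as the total edge length $4(a+b+h)$ of an $a \times b \times h$
box, giving the dimensionally coherent penalty $(a+b+h)^2$; a per-slice
rectangle reading $c = 2(a+b)$ is available as an option. The search
region is anchored on the delineated air cavities: the anterior half of
the head box in the anterior-posterior axis, with the lateral and axial
extents given by the cavity bounding box padded by 5 voxels and clipped to
the head. Bounding the lateral extent to the cavity neighbourhood matters:
with the full head width in the window, the goodness optimum can latch
onto the temporal skull shell -- a compact all-bone slab -- rather than
the sinus. Within the region, all boxes with corners on a stride-2 lattice
are scored via a 3-D summed-volume table (constant-time box sums by
inclusion-exclusion), followed by a stride-1 refinement within one stride
of each corner. Ties resolve to the smaller volume, then the
lexicographically smallest corners, making the search fully deterministic;
no box tilting is attempted. At stride 1 the search is exactly the
exhaustive argmax, which the tests verify against a brute-force oracle.

**Template warp.** The canonical-space cuboid is pulled back to the
subject by adding the inverse deformation field's displacement (mm, world
coordinates) to each target voxel and looking up the template mask at the
nearest template voxel. Nearest-neighbour interpolation keeps the mask
crisp; the warped region need not remain a cuboid. For phantom work the
canonical cuboid is the generator's canonical sinus compartment; for real
deployments the template bounds are a versioned asset.

## The MRI-CT conversion model

Inside the chosen region, every bone-labelled voxel is converted. The
model is a three-segment piecewise-linear curve in the (MRI intensity,
HU) plane: a plateau at -1000 HU (air) up to the breakpoint `mLow`, a
diagonal to the second breakpoint `mHigh`, and a plateau at 0 HU (soft
tissue) beyond. Genuine bone is deliberately not modelled: sinus bone
cannot be separated reliably by T1 intensity, and capping at 0 HU
minimises the bias for a random bone voxel.

Fitting minimises the summed squared *orthogonal* distance from the data
points to the curve. The two axes are incommensurable, so both are
normalised first: HU by 1000 and MRI by the sample's 99th-percentile
intensity, making both O(1); without this the HU axis dominates any
shortest-distance criterion. (A vertical-residual alternative can be
swapped in behind `pointCurveDistance()`.) The minimiser is an exhaustive
64 x 64 lattice over the sample's MRI range with `mLow < mHigh`, followed
by one 8x refinement around the optimum -- a deterministic choice that
avoids derivative-free-optimiser nondeterminism on a smooth 2-D loss.
Ties resolve to the smallest span, then the smallest `mLow`. Samples with
no points between the plateaus leave one breakpoint unidentified; they
are flagged with an ill-posed warning and resolved by the tie rules.

Per subject, 100 voxels are drawn without replacement from the
bone-labelled voxels inside the subject's region and fitted; this is
repeated 100 times and the per-repeat breakpoints averaged (a bootstrap
estimate). The cohort model averages the per-subject models with equal
weight. Out-of-sample behaviour is assessed leave-one-out: each subject
is converted with the model fitted on the remaining subjects only.
Converted voxels receive $\mu = \mu_{soft}(HU + 1000)/1000$, clamped to
$[0, \mu_{soft}]$ -- the model's output spans exactly [-1000, 0] HU, so
this is the air/soft-tissue mixing line through the class values.

## The digital head phantom

The generator emulates the study inputs so the whole pipeline is testable
without patient data: an ellipsoidal head (background air -1000 HU, scalp
about 0 HU, skull shell about 1000 HU, brain about 30 HU) on a 96^3 grid
of 2 mm isotropic voxels, with an anterior sinus compartment. Inside the
compartment, two roughened ellipsoidal air cavities are carved by
quantile sublevel sets of a cavity potential (hitting the requested air
fraction by construction), surrounded by a fine-bone mixture band, with
soft tissue outermost; a separate enclosed throat pocket acts as a decoy
that correct region growing must exclude. Default composition is 55% air,
33% bone mixture, 12% soft tissue -- a majority-air sinus. Mixture-voxel
MRI intensities are drawn uniformly over the full
[`mLow` - margin, `mHigh` + margin] range and their CT numbers generated
through the true three-segment law (breakpoints 120 and 320 in arbitrary
MRI units, margin 80) plus Gaussian noise (MRI sd 10, HU sd 40). This
reproduces the characteristic scatter the conversion model targets --
concentration lines at -1000 and 0 HU with a diagonal between -- and
makes the fitting problem well-posed by construction. Probability maps
are one-hot on the true class except that mixture voxels are labelled
bone with probability 0.9, reproducing the upstream segmenter's failure
mode; a small renormalised uniform perturbation (amplitude 0.02) keeps
the maps from being exactly binary.

The facial skeleton is thinned to a roughly one-voxel bone sheet in the
anterior-inferior sector of the shell (facial bones are far thinner than
calvarium), and a 2-voxel mucosal soft-tissue lining separates the
compartment from any adjacent bone, as real sinus walls are lined by
mucosa. Together these keep the conversion pool dominated by the
mixture scatter. The failure mode it avoids is instructive: a concentrated
cluster of genuine bone voxels (MRI about 80, HU about 1000) inside the
fitting pool pulls the upper breakpoint toward the cluster's intensity,
because the orthogonal distance from points far above the curve decreases
as the soft-tissue corner approaches their MRI value. Thin, dispersed
bone -- as in real sinus walls -- does not do this; a few percent of such
voxels in the pool (as the warped template produces) only biases the
breakpoints mildly.

Deformation fields are a constant pull-back (matching each subject's
compartment jitter) plus a smooth sinusoidal component of amplitude 3 mm
and wavelength 250 mm, whose negation approximates its inverse to well
under a quarter voxel on average -- testable warp accuracy without any
registration software. Per-subject seeds are `seed * 10007 + index`, so
cohorts are reproducible and collision-free.

What the phantom does *not* emulate: MR bias fields and Rician noise,
PET emission physics and reconstruction (evaluation operations accept any
co-registered PET-like pair), scanner geometry, and real anatomical
variability beyond box jitter and smooth warps. Passing tests therefore
demonstrate algorithmic correctness and parameter recovery under the
stated conditions, not clinical performance. One visible consequence:
the phantom's near-one-hot probability maps make skull-bone delineation
essentially perfect for every method, so the bone-mask Dice
coefficients cluster near 1 and the differences between methods
concentrate in the sinus-VOI attenuation statistics; on real data, where
segmentation is noisy, the same comparison also separates the methods in
Dice. Likewise the correlation sampling pool (CT voxels above 157 HU)
contains only genuine skull on the phantom, which all methods treat
identically, so their sampled correlations coincide by construction.

## Evaluation suite

* **Dice** $2|A \cap B| / (|A| + |B|)$ between the CT bone mask
  (HU > 157, strictly) and the MRAC bone mask (mu > 0.105 cm^-1, which
  selects exactly the bone class), over the sinus window -- axial slices
  50-70 inclusive, 21 slices = 4.2 cm at 2 mm -- and over the whole
  volume. Two empty masks score 1 (perfect agreement on absence;
  configurable).
* **Correlation sampling**: per subject, 100 repeats of 200 voxels drawn
  without replacement from the CT bone mask; Pearson correlation between
  the paired CT-mu and MRAC-mu values. The pool is CT-only by choice (the
  union with the MRAC mask is a plausible alternative).
* **Sinus VOI attenuation**: mean mu over the sinus volume of interest,
  per map; converted methods use each subject's leave-one-out model.
* **Per-VOI PET differences**: for each atlas label, restricted to
  voxels with grey-matter probability >= 0.8,
  $(\overline{PET}_{MRAC} - \overline{PET}_{CTAC}) / \overline{PET}_{CTAC}$.
* **Bias atlas**: voxelwise relative difference per subject, averaged
  voxelwise across subjects within a brain mask. Undefined statistics
  (zero reference) are NA sentinels, serialized as null, never silently
  dropped.

Indexing is 1-based throughout, as native to R; the slice window 50-70 is
used directly as inclusive 1-based indices. Gaussian smoothing to PET
resolution (5 mm FWHM) uses separable normalized convolution: the kernel
has unit mass and is renormalized where truncated at the array boundary,
so constants are preserved exactly and interior mass is conserved; heads
are surrounded by zero-attenuation air, so the boundary treatment is
inconsequential.

## Problem sizes and determinism

The test suite and the acceptance script run a 10-subject cohort at the
default 96^3 / 2 mm conditions with the full 100 x 100 bootstrap and all
ten leave-one-out refits; structural tests use 48^3 or 64^3 phantoms.
Every stochastic step (phantom generation, bootstrap resampling,
correlation draws) takes an explicit seed and restores the caller's RNG
state, so pipeline reruns are byte-identical including serialized
reports.

## Known limitations

* The cuboid goodness is sensitive to compact off-target bone structures;
  the cavity-anchored search region mitigates but does not eliminate
  this, and no tilted boxes are considered.
* The conversion model ignores genuine bone inside the sinus; high-HU
  voxels in the pool bias the breakpoints (quantified above).
* The template method inherits any deformation-field error and does not
  consult the bone probabilities; its region overlaps the true
  compartment less tightly than the fitted cuboid, though on phantoms
  the mucosal lining around the compartment keeps its fitting pool free
  of genuine-bone voxels and both converted methods clearly outperform
  the bulk assignment in the sinus VOI.
* Whole-volume affines are assumed grid-aligned (diagonal); oblique
  acquisitions should be resampled upstream.
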