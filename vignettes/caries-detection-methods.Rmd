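---
title: "Methods: mask-algebra caries detection and five-feature classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask-algebra caries detection and five-feature classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carieslens)
```

`carieslens` analyses color photographs of single-tooth occlusal surfaces in
two stages: a deterministic mask-algebra pipeline that isolates the
carious-lesion region, and a feature-based classifier comparison that
separates early (visually non-cavitated, VNC) from late (cavitated, C)
lesions. This vignette documents the procedure, its assumptions, the
parameters that matter, and the design decisions taken where more than one
reasonable construction existed.

## The detection pipeline

`extract_lesion()` runs ten steps, recording every intermediate:

1. **Contrast enhancement.** An optional global contrast factor
   `v → clip(128 + f·(v − 128))` is applied per RGB channel, then the
   luminance (Y) channel of a BT.601 YCbCr decomposition is histogram
   equalized with the classic discrete CDF mapping
   `T(v) = round(255·(F(v) − F_min)/(n − F_min))`; the chroma channels pass
   through unchanged so the hue of the restored lesion crop is preserved.
2. **Grayscale.** BT.601 luma, `round(0.299 R + 0.587 G + 0.114 B)`.
3. **Binarization.** Otsu's rule by default: the threshold maximizing the
   between-class variance of the grayscale histogram; pixels strictly above
   the threshold become 255. A fixed threshold is available in
   `detect_config()`.
4. **Tooth contour.** The external boundary of the connected foreground
   component with the largest enclosed area (holes filled).
5. **Thick mask.** Everything outside that contour — boundary included — is
   set to 255; the interior stays 0.
6. **Inversion** gives the tooth-interior image.
7. **Saturated subtraction** `max(interior − binary, 0)` leaves foreground
   exactly where the tooth interior is *dark*: the candidate lesion image.
8. **Lesion contour.** The largest-contour search is applied again to the
   candidate image. An optional 3×3 morphological opening (default off)
   can despeckle the candidate image first.
9. **Lesion mask.** The area outside the lesion contour is filled white.
10. **Restoration.** Inside the contour the original image pixels are
    restored, producing the extracted-lesion crop.

The pipeline is a pure function: identical bytes and configuration give
identical results, which the suite asserts.

**Assumptions.** One tooth per frame, brighter than its background; lesions
appear as regions darker than sound enamel after enhancement; the occlusal
surface is the largest bright connected component. Restored teeth
(sealants, fillings, silver diamine fluoride) and full-arch photographs are
out of scope.

### Why the default contrast factor is 2.8

Full-histogram equalization alone is a poor partner for a *global* Otsu
threshold on low-texture images: equalization redistributes intensity mass
uniformly by rank, so the equalized tooth occupies the whole intensity
range and Otsu then splits *inside* the enamel mode, labelling a large
fraction of sound enamel "dark". The package therefore defaults the
pipeline's pre-equalization contrast factor to 2.8
(`detect_config(contrast_factor = 2.8)`): the saturating contrast step
collapses sound enamel to a single white level, after which equalization
maps any genuinely darker structure (lesions, stains, under-exposed
regions) toward the dark extreme and Otsu lands cleanly in the gap between
enamel and everything else. `enhance_contrast()` itself keeps `factor = 1`
as its argument default, so the plain equalize-only behaviour remains one
call away, and the factor is an ordinary config field for images with
different exposure characteristics.

### Detection parameters

| parameter | default | units | role |
|---|---|---|---|
| `contrast_factor` | 2.8 | — | saturating pre-equalization contrast (see above) |
| `equalize` | TRUE | — | luminance histogram equalization |
| `binarize_method` | `"otsu"` | — | parameter-free, standard for bimodal tooth/background histograms |
| `min_tooth_area` | 100 | px | smallest enclosed area accepted as the tooth |
| `min_lesion_area` | 25 | px | detection gate; suppresses noise contours a few pixels wide |
| `opening` | FALSE | — | optional 3×3 despeckling before the lesion contour search |

`caries_detected` is true exactly when the filled lesion region reaches
`min_lesion_area` foreground pixels.

### Numerical and tie-break conventions

* Coordinates are 0-based, row-major, origin top-left; mask foreground
  is 255; all binary images contain only {0, 255}.
* "Largest boundary" means largest by enclosed area of *external* contours
  (holes filled); ties are broken by the component whose first foreground
  pixel occurs first in row-major scan order.
* Contour interiors are rasterized by even-odd scanline counting at pixel
  centers with a half-open edge rule; boundary-chain pixels are never
  interior. On 64×64 images the candidate lesion image equals a brute-force
  point-in-polygon set difference computed with an independent
  implementation, which the suite asserts pixel-for-pixel.
* Step 7's subtraction is saturated (clipped at zero) — the only reading
  that keeps the result binary.
* Degenerate inputs: a constant image passes through enhancement unchanged
  with a warning; Otsu on a constant image warns and yields an all-zero
  mask; an image with no qualifying tooth component raises
  `"no tooth located"`; a missing lesion contour is a valid no-caries
  result, not an error.
* Metric tables print at two decimals, half-up (87.385 → 87.39); full
  precision is kept internally.

## Feature quantification

For a detected lesion, `extract_features()` computes, in Table order:

* **Length, Width** — longer and shorter side of the minimal axis-aligned
  bounding rectangle, in raw pixels. An axis-aligned (not rotated
  minimum-area) rectangle is the simplest reading of a drawn rectangular
  boundary; pixels rather than normalized units are reported because no
  normalization is implied by the feature definition, and a tooth-box
  normalization would be trivial to add downstream for cross-photo use.
* **Smoothness** — no formula is fixed by the original feature list, so the
  package uses the standard first-order texture descriptor
  `S = 1 − 1/(1 + σ²)` with `σ²` the population variance of lesion-pixel
  intensities rescaled to [0, 1]. `S ∈ [0, 1)`, is 0 for a flat lesion and
  monotone in intensity spread. Texture is measured on the *original*
  grayscale, not the enhanced one, so the descriptor is not distorted by
  the saturating enhancement.
* **Ratio** — |lesion ∩ tooth| / |tooth|.
* **Convex area** — the convex hull of the lesion's foreground pixel
  centers, rasterized, divided by the tooth area. Normalizing by tooth
  area (rather than reporting raw hull pixels) puts the value on the same
  scale as Ratio, so `ratio ≤ convex_area ≤ 1` always holds and the pair is
  comparable across photographs.

A non-detection yields the all-zero feature row, matching the convention
that correctly identified sound teeth carry zeros for all five features.
Lesion depth is not computable from a 2-D photograph and is deliberately
absent.

## Classification stage

`filter_for_classification()` drops all sound-tooth records and every
caries record the detector missed, then binarizes the labels VNC vs C;
`balance_undersample()` removes randomly chosen majority-class records to
equalize the classes. `run_cv()` evaluates a classifier with stratified
k-fold cross-validation (default k = 10):

* **Folds** are assigned by a deterministic class-blocked scheme (per-class
  shuffle, then cyclic deal), which guarantees both per-class counts and
  total fold sizes differ by at most one. Stratification is used because a
  deliberately balanced design implies per-fold balance was intended.
* **Scaling.** Features are standardized with training-fold statistics
  only — SVM, k-NN and logistic regression are scale-sensitive.
* **Pooling.** Held-out predictions are pooled and the metrics computed
  once from the pooled confusion matrix. This yields a single well-defined
  confusion matrix per model and makes recall equal sensitivity by
  construction. (Per-fold averaging is the other defensible choice; pooled
  metrics were chosen because each model then has one confusion matrix.)
* **Positive class** defaults to C (late caries) — the evaluated report
  does not name its positive class, and recall equals sensitivity in every
  row either way; the choice is a config field.
* **AUCROC** is the Wilcoxon rank statistic on the pooled continuous scores
  (SVM decision margins, class probabilities elsewhere), ties counting one
  half; the suite checks it against pairwise enumeration and an independent
  ROC implementation.

Declared hyperparameters (all overridable in `classifier_spec()`): SVM with
RBF kernel, cost 1, `γ = 1/(p · mean feature variance)`; random forest, 100
trees; 5-nearest-neighbours; gradient boosted trees, 100 rounds, depth 3,
learning rate 0.1; logistic regression fit by unpenalized `glm` — on five
standardized features the conventional weak L2 penalty is numerically
irrelevant, so the canonical R call is used.

## Evaluation protocol

A detection on a caries-category image counts as correct when its overlap
with the expert annotation is *strictly greater than* 0.60. The default
overlap is **coverage** — |detected ∩ annotated| / |annotated| — because
projecting detections onto the annotation and asking "how much of the
marked lesion did we find" is the clinically meaningful reading; symmetric
IoU is available via config. Outcomes: caries image with an accepted
detection → TP; caries image with no or insufficient overlap → FN;
sound-tooth image with any detection → FP; without → TN.
`metrics_from_confusion()` computes accuracy, sensitivity (= recall),
specificity, precision and F1 as percentages; a zero denominator yields
`NA` with a warning, never a silent zero.

The package's worked example (`worked_example_metrics()`) feeds the
reference confusion matrix (462, 22, 52, 51) through exactly this code.
Note the documented inconsistency: those counts give specificity
51/73 = 69.86%, while the reference report prints 68.86%. The package
reports the arithmetic value and flags the difference; it is not tuned to
the printed figure.

## The phantom generator

`phantom_spec()` / `generate_phantom()` render, in order: dark background;
a bright elliptical tooth (base RGB (232, 222, 210)) with a gentle radial
shading gradient (8% at the rim); two to four wobbly dark fissure lines in
the inner occlusal region (depth 10–18 intensity units); a
class-conditioned irregular lesion blob; optional artifacts; then Gaussian
pixel noise (σ = 2.5). Ground-truth masks are rendered before noise and are
noise-independent. All randomness is drawn in `phantom_spec()`, so
rendering is a pure function of the spec and bit-reproducible from a seed.

Class conditioning: VNC lesions have radius 0.10–0.21 of the tooth's minor
semi-axis and contrast depth 60–90 intensity units; C lesions 0.19–0.33
and 120–170. The ranges are disjoint in depth and overlap only slightly in
radius, so late lesions are darker and on average more than twice the area
of early ones — the geometry the classification stage is meant to exploit.
Blob boundaries are modulated by first- and second-order angular harmonics
(up to 20%) so lesions are irregular but star-convex.

Artifacts reproduce the documented confounders: a **specular highlight** is
a near-white disc with an under-exposed surrounding ring (depth 65–85) —
on glossy curved enamel the hotspot's surround reads darker than sound
enamel, and it is this surround the detector mistakes for a lesion,
reproducing the known false-positive failure mode; **extrinsic stains** are
small dark brownish speckles; **plaque** is a translucent enamel-colored
patch that can mask a lesion. Artifact layers are drawn with configurable
Bernoulli rates, default 0.

**What the phantoms do not emulate:** real enamel texture and translucency,
demineralization gradients (white-spot halos), wet-surface glare beyond the
disc model, camera optics (blur, vignetting, JPEG artifacts), anatomical
cusp geometry, and inter-tooth variation in color. Clean phantoms are
consequently *easier* than clinical photographs: a perfect detection score
on them demonstrates correctness of the mask algebra and the end-to-end
plumbing, not clinical performance. The reference clinical metrics
(accuracy 87.39%, sensitivity 89.88%) remain the relevant yardstick for
real images, which cannot be shipped.

## Benchmark problem sizes

The packaged studies use: a 400-phantom set (50 NSC / 150 VNC / 200 C,
roughly the 73 : 220 : 294 balance of the reference dataset) for the
end-to-end detect → features → 10-fold-CV benchmark; 200 artifact-free
lesioned phantoms for detection recall at the strict >0.60 coverage
criterion; and 100 paired sound-tooth phantoms (with vs without a forced
specular highlight) for the false-positive comparison. Phantoms are
160×160 px, large enough for ~40–55 px tooth semi-axes and lesions from
~25 px up. `scripts/acceptance.R` recomputes all of these from a single
seed.

## Known limitations

* The detection stage has no mechanism to distinguish dark *non-carious*
  structure from lesions: sufficiently dark stains and under-exposed
  regions fire it by design, as in the system it reimplements.
* A single lesion contour is kept (the largest); multifocal caries is
  reduced to its dominant lesion.
* The saturating default enhancement assumes sound enamel is the brightest
  extended structure; heavily discolored whole teeth would need a lower
  contrast factor or a fixed threshold.
* Smoothness, the convex-area denominator and the length/width units are
  package decisions (documented above), to be revisited if reference data
  with published feature values becomes available.
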