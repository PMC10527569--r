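---
title: "Methods: enhancement, fusion, and antlion-optimized selection in dermalo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement, fusion, and antlion-optimized selection in dermalo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermalo)
```

`dermalo` implements the computational stages of a multiclass skin-lesion
classification pipeline for dermoscopy images: contrast enhancement, flip
augmentation, multi-extractor feature tables, serial correlation-based
fusion, genetic-algorithm (GA) hyperparameter tuning, wrapper feature
selection with an antlion optimizer extended by a mean-deviation step
(ALO-MD), and a multiclass cross-validation harness. This vignette
documents the models, the tunable parameters, the numerical conventions,
and the design choices made where several readings were possible.

## 1. Contrast enhancement

Dermoscopy images of low-contrast lesions behave like hazy scenes: a
semi-transparent veil lifts intensities toward a global light term and
compresses contrast. We model this with the standard haze image equation

$$ I(x) = J(x)\,T(x) + A\,(1 - T(x)), $$

where $I$ is the observed image, $J$ the scene radiance we want, $A$ the
(global) atmospheric light, and $T \in (0, 1]$ the per-pixel transmission.

**Dark channel.** Haze-free patches contain at least one color channel
with near-zero intensity; the *dark channel*
$\min_{c \in \{R,G,B\}} \min_{y \in \Omega(x)} I_c(y)$ over a
`patch_size` window is therefore a proxy for the haze veil.
`estimate_atmospheric_light()` averages the image colors at the top
`light_fraction` quantile of the dark channel (the most veil-opaque
pixels); `estimate_transmission()` sets
$T = 1 - \omega \cdot \mathrm{dark}(I / A)$ clamped into $[t_0, 1]$; and
`recover_radiance()` inverts the model as
$J = (I - A)/\max(T, t_0) + A$, clipped to $[0,1]$. With the true $A$ and
$T$ this inversion is exact, which the test suite verifies against the
synthetic forward model at better than 40 dB PSNR.

**Morphological stage.** After dehazing, small-scale lesion structure is
amplified with flat grayscale morphology per channel:
$\mathrm{tophat}(J) = J - \mathrm{opening}(J, s)$ collects bright details
smaller than the structuring element $s$,
$\mathrm{bothat}(J) = \mathrm{closing}(J, s) - J$ collects dark details,
and the enhanced image is

$$ F = \mathrm{clip}_{[0,1]}\big(J + \mathrm{tophat}(J) - \mathrm{bothat}(J)\big). $$

This is the standard top-/bottom-hat contrast enhancement: it brightens
small bright structures, darkens small dark ones, and leaves flat regions
untouched (both residuals vanish on constant images). We apply haze
reduction first and morphology second; the dehazed image is the better
substrate for local contrast work because the veil otherwise suppresses
both residuals.

**Parameters.** All neighborhood operations use replicate (edge-clamp)
padding. Morphology is applied per channel; the dark channel is taken
across channels. Images are processed as doubles in $[0,1]$; 8-bit
quantization happens only at PNG read/write.

| parameter | default | meaning |
|---|---|---|
| `patch_size` | 15 px | dark-channel minimum-filter window |
| `omega` | 0.95 | fraction of estimated haze removed; keeps a natural depth cue |
| `t0` | 0.1 | transmission floor guarding the division |
| `light_fraction` | 0.001 | brightest dark-channel pixels used for $A$ |
| `se_shape`, `se_radius` | disk, 9 px at 256 px | structuring element; radius scales with the shorter image side |

The `omega`/`t0`/`patch_size`/`light_fraction` defaults are the ones
customary for dark-channel dehazing; the disk radius was chosen so the
element is larger than pigment-network texture but smaller than the
lesion itself at 256-pixel resolution.

## 2. Augmentation

`augment_flips()` expands every image into exactly four variants —
identity, left-right flip, up-down flip, both — replicating labels
accordingly. In the pipeline, augmentation is **fold-aware**: folds are
assigned to base images first and flips inherit their source image's
fold, so a validation fold never contains a flip of a training image.
Augmenting before splitting would leak near-duplicates across folds and
inflate accuracy; for that reason the pipeline's `augment` toggle
defaults to off for evaluation runs.

## 3. Feature extraction contract

The selection and fusion stages consume `feature_matrix` objects
(samples × features + labels) and are agnostic to their origin. Real
pipelines load CNN embeddings from CSV via `read_feature_csv()`. For
testing without pretrained weights, the bundled *toy extractor* computes
a 56-dimensional deterministic descriptor per image (global and
4×4-patch means/SDs, a 16-bin intensity histogram, per-channel moments)
and maps it through a fixed Gaussian random projection followed by a
`tanh` squash. The projection matrix is seeded from the extractor *name*,
so differently named extractors give systematically different embeddings
of the same images — emulating distinct backbones. The toy extractor is a
contract stand-in, not a claim about deep features: passing tests
demonstrate the pipeline's mechanics, not ISIC-level accuracy.

## 4. Serial correlation-based fusion

`fuse_select()` implements four steps:

1. **Serial fusion**: horizontally concatenate the per-extractor tables
   into one table of width $k_1 + k_2 + \dots$ (`serial_fuse()`).
2. **Pairing**: partition the fused columns into consecutive disjoint
   pairs $(1,2), (3,4), \dots$; an odd final column pairs with itself.
   The pairing operates on feature *columns* across the $N$ samples — a
   correlation needs two variables observed jointly, and samples are the
   observations.
3. **Correlation**: Pearson $r$ for each pair via the raw-sum formula
   $r = (n\sum xy - \sum x \sum y) / \sqrt{(n\sum x^2 - (\sum x)^2)(n\sum y^2 - (\sum y)^2)}$,
   with $r = 0$ assigned to constant-column pairs (zero denominator).
4. **Partition and fitness**: both members of a pair with $r$ strictly
   above `threshold` (default 0.5) go to the positively correlated set,
   all other columns to the weakly correlated set. Both sets are scored
   by stratified cross-validated 1-nearest-neighbor accuracy
   (`knn_fitness()`), and the higher-scoring set wins; ties favor the
   positive set, and an empty partition scores 0.

Both members of a correlated pair are kept (the partition routes
features, it does not deduplicate them); the subsequent ALO-MD stage is
the mechanism that removes redundancy. The threshold is configurable
because "positive" is a design choice: $r \le$ threshold — including
negative correlations — counts as weak.

## 5. ALO-MD wrapper feature selection

The antlion optimizer is a population metaheuristic: *ants* (candidate
solutions) perform random walks inside adaptively shrinking intervals
centered on *antlions* (incumbent solutions) selected by a roulette
wheel, with a globally preserved *elite*.

**Continuous dynamics.** The search space is the unit box $[0,1]^d$.
Each iteration $s$ of $S$:

- the walk interval is the global box divided by
  $I = \max(1, 10^u \, s/S)$, with the exploitation exponent $u$
  stepping through $1, 2, 3, 4, 5, 6$ as $s/S$ crosses
  $0.1, 0.5, 0.75, 0.9, 0.95$ (`shrink_bounds()`); the width is
  therefore non-increasing;
- each ant picks an antlion by roulette (probability proportional to
  min-shifted fitness plus a vanishing $\varepsilon$, uniform for equal
  fitness), recenters the shrunk interval on it (`shift_bounds()`,
  clipped to the box), builds a $\pm 1$ random walk per dimension
  (`random_walk()`), min-max rescales it into the interval
  (`normalize_walk()`, constant walks map to the midpoint), and reads
  the walk at index $s$;
- the ant's position is the elementwise average of this antlion-guided
  walk and an identically constructed walk around the elite
  (`elitism_combine()`); the elite walk uses the same shrunk interval,
  recentered on the elite;
- an antlion whose assigned ant scores strictly better relocates to the
  ant's position, and the elite is updated whenever beaten
  (`catch_and_rebuild()`); ties keep the incumbent.

**Binary encoding.** A position becomes a feature mask by thresholding
at 0.5 (`binarize()`); an all-zero mask is rescued by switching on the
largest coordinate, so every evaluated subset is non-empty. The wrapper
fitness (lower is better) is

$$ \alpha\,(1 - \mathrm{acc}_{CV}) + (1-\alpha)\,\frac{|mask|}{d}, $$

with cross-validated 1-NN accuracy on the masked columns and
$\alpha = 0.99$ by default: accuracy-dominant with weak sparsity
pressure. Scores are cached per mask within a run, since the fitness is
a pure function of the subset.

**The mean-deviation (MD) step.** After each cohort of ants is scored,
the population mean $\mu$ and mean absolute deviation
$\mathrm{MAD} = \mathrm{mean}(|f_i - \mu|)$ are computed; every ant
scoring worse than $\mu + \mathrm{MAD}$ is relocated to the elite with
**one coordinate redrawn uniformly** in $[0,1]$, then re-scored. In mask
space this is a single-bit probe of the elite's neighborhood. Two design
notes. First, the trigger ($\mu + \mathrm{MAD}$) spends the probes on
ants whose walk outcome was wasted anyway. Second, the probe must be a
coordinate redraw rather than a re-draw inside the current shrunk
interval: the interval contracts to $\pm 10^{-2}$ within the first tenth
of the run, so interval-bounded re-seeding reproduces the elite's mask
verbatim and diversifies nothing — a measurable failure mode (the
optimizer plateaus one redundant feature above the optimum) that the
coordinate probe repairs, giving the optimizer true single-bit descent.
The step never touches the elite, so the elite-score trace is
non-increasing by construction; `md_enabled = FALSE` disables it for
ablation.

For $d \le 20$, `exhaustive_mask_search()` provides the exact optimum
over all $2^d - 1$ subsets and is used in the tests to certify that the
metaheuristic attains the global optimum on small problems.

## 6. GA hyperparameter tuning

`ga_evolve()` replaces manual hyperparameter assignment with a
generational GA over a declared space (`ga_space()` of continuous
linear/log, integer, and categorical parameters): binary tournament
selection, uniform crossover (rate 0.8), per-gene mutation (rate 0.1;
Gaussian with SD = 10% of the range on linear/integer genes, log-space
Gaussian on log genes, resampling on categoricals), bound clipping, and
2-elitism, so the best-so-far fitness never decreases. A chromosome
whose fitness evaluation throws is scored $-\infty$ and the run
continues. `ga_tune_classifier()` applies this to any classifier preset
with hold-out accuracy as fitness; the per-preset default spaces are
small and documented (`default_tune_space()`). GA internals are
conventional defaults (population 20, 30 generations), chosen once; the
pipeline uses a reduced budget (12 × 10) appropriate to fixture-scale
data.

## 7. Evaluation harness

`crossval_classify()` assigns stratified folds (degrading gracefully to
fewer folds than requested when the smallest class is small), pools
out-of-fold predictions and class scores, and computes the panel once —
never averaging metrics over folds. The classifier roster mirrors the
naming of common GUI presets; the mapping is documented and
configurable: unpruned shallow tree (`fine_tree`), degree-2
polynomial-kernel SVM (`quadratic_svm`), $k{=}10$ k-NN plain and
distance-weighted (`medium_knn`, `weighted_knn`), bagged trees via a
full-`mtry` random forest (`bagged_tree`), and one- and two-hidden-layer
softmax perceptrons (`narrow_nn` 10, `medium_nn` 25, `bilayered_nn`
10+10; the two-layer network is trained by BFGS with analytic backprop
gradients, since no installed package provides a two-hidden-layer
classifier).

The panel: accuracy; macro sensitivity/precision/F1 (averaged over
classes present in the truth; a truth-present class never predicted
contributes precision 0; classes absent from both truth and prediction
are excluded with a warning); $\mathrm{FNR} = 1 - $ macro sensitivity;
Fowlkes–Mallows index $\sqrt{\mathrm{precision} \cdot \mathrm{recall}}$
on the macro averages; Cohen's kappa $(p_o - p_e)/(1 - p_e)$; the
multiclass Matthews correlation coefficient computed from the confusion
matrix (equal to the correlation of one-hot indicator matrices); macro
one-vs-rest AUC from pooled class scores; and micro-averaged
precision/recall for transparency (these equal accuracy for single-label
problems). Degenerate conventions: $p_e = 1$ gives kappa 0, and a zero
MCC denominator gives 0 — so a single-class diagonal matrix does *not*
score as perfect agreement. Macro averaging is used because one rate per
classifier is reported for 7-class problems; the per-class breakdown is
always attached.

## 8. Synthetic fixtures: what they emulate, and what they do not

`make_hazy_images()` builds class-colored elliptical lesion blobs on a
skin-toned background and degrades them with the *same forward model the
enhancement inverts*: a smooth radial depth field, transmission
$T = e^{-\beta\,\mathrm{depth}}$, atmospheric light 1, plus optional
Gaussian sensor noise (default SD 0.005). Returning the clean images and
true transmission makes dehazing quality directly measurable. The
generator does not model hair, rulers, specular highlights, or realistic
pigment texture — results on it validate the algebra and the pipeline
mechanics, not clinical performance.

`make_feature_dataset()` (defaults: 200 samples, 7 classes, 5
informative + 40 noise + 5 redundant features) draws class centers in
the informative subspace rescaled so their minimum pairwise distance is
`class_separation` (default 6) within-class SDs; noise features are
class-independent standard normals; redundant features are jittered
copies (SD 0.1, pairwise $r > 0.9$) of informative ones placed
immediately after their source column, so consecutive-pair correlation
discovers them by construction. Seven classes and separation 6 were
chosen once as the study conditions: seven is the class count of the
public dermoscopy benchmarks this pipeline targets, and separation 6
makes the informative subspace cleanly classifiable so selection quality
is attributable to the optimizer rather than to class overlap. The
ground-truth column roles are returned for recovery scoring. All
generators are pure functions of (spec, seed).

## 9. Problem sizes used by the test suite

The tests and the acceptance script run the full stack at fixture scale,
chosen so each property is exercised meaningfully: 20 hazy 64×64 images
for the inverse-model and contrast checks; 100 random 50×20 matrices for
correlation exactness ($10^{-10}$); 20 replicate 200×50 tables for the
fusion partition; a 140×10 seven-class table for exhaustive-optimum
equivalence (20 optimizer seeds, 20 ants, 50 iterations); the 200×50
five-informative table for recovery (20 seeds); 1000 random confusion
matrices for the metric oracle; and the default 7×30-image pipeline for
the end-to-end comparison. The end-to-end claim mirrored at this scale
is qualitative: the fused table should match or beat the best individual
extractor, and the ALO-selected subset should retain the fused accuracy
(within 0.02) with strictly fewer features.

## 10. Known limitations

- The toy extractor is a deterministic stand-in; no transfer learning or
  CNN fine-tuning is performed, and accuracies on fixtures say nothing
  about accuracies on dermoscopy benchmarks.
- The wrapper fitness is 1-NN while the final evaluation may use a
  different classifier. On the default fixtures this mismatch is visible
  for roughly a quarter to a third of pipeline seeds: the optimizer
  settles on a very small subset (10–20 of ~140 columns) that is
  1-NN-adequate but costs a polynomial SVM 5–10 accuracy points. The
  remaining seeds retain the fused accuracy within 0.02. Matching the
  fitness classifier to the deployment classifier, or raising the
  selection budget (`iters`, `n_ants`), reduces the effect at extra
  cost.
- Feature selection is performed on the full table before
  cross-validated evaluation (as is common in this literature); the
  reported post-selection accuracies therefore carry selection bias.
  Nested CV would remove it at roughly `folds`-fold cost.
- Transmission maps are not refined (no guided filter); block artifacts
  of the patch-wise dark channel can appear at strong haze.
- Lesion localization is out of scope; the pipeline classifies whole
  images.
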