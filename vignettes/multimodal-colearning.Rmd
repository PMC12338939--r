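---
title: "Multimodal co-learning for skin-lesion classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal co-learning for skin-lesion classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermcolearn)
```

## The problem

Public skin-lesion collections are rich in images but almost never ship
paired clinical reports, which blocks multimodal training even though
reports are the more informative modality. `dermcolearn` implements a
co-learning strategy for this setting: reports are synthesized from image
*metadata*, the two modalities are trained jointly against a composite
alignment objective, and at inference only images are used. The aim is for
the image representation to inherit structure from the text so that
image-only classification improves.

The classification target is five lesion classes: benign keratosis (BEK),
benign nevus (NEV), actinic keratosis (ACK, pre-malignant), basal-cell
cancer (BCC) and melanoma (MEL).

## Architecture

Two modality-specific encoders produce fixed-width embeddings
$E_{\mathrm{img}}, E_{\mathrm{txt}} \in \mathbb{R}^{N \times d}$, which feed
a *shared* projection ($d \to h$) and a *shared* 5-class linear classifier.
One parameter set serves both branches — weight sharing is itself an
alignment mechanism, since both modalities must become classifiable by the
same head.

The reference encoders are deliberately small so that a full experiment
runs in minutes on one CPU:

* **image branch** — three strided $3\times3$ convolution blocks
  (channels 8, 16, 32, stride 2, zero padding, ReLU), global average
  pooling, and a linear map to width $d = 32$. Forward and backward passes
  are implemented directly (im2col + matrix products), with gradients
  verified against finite differences in the test suite;
* **text branch** — a token-hash bag-of-words (512 buckets, L2-normalized
  counts, the usual normalization for hashing vectorizers) followed by a
  linear map to the same width $d$.

Heavyweight pretrained backbones (a DenseNet-class CNN, a biomedical BERT)
occupy this slot in full-scale work; the package treats the encoder as
pluggable — anything that produces width-$d$ embeddings can feed
`classify()` — and nothing in the tests requires downloaded weights.

## The composite objective

Training minimizes

$$
L = w_{ce}^{img}\,\mathrm{CE}(\mathrm{img}) + w_{ce}^{txt}\,\mathrm{CE}(\mathrm{txt})
  + w_{L1}\,L_1 + w_{cos}\,L_{cos} + w_{ssl}\,L_{ssl},
$$

where the alignment terms operate on the post-projection embeddings
$H = E W_p + b_p$:

* $L_1$ — mean absolute entrywise difference between paired rows (mean,
  not sum, so the weight is comparable across widths);
* $L_{cos}$ — mean of $1 - \cos(h_i^{img}, h_i^{txt})$;
* $L_{ssl}$ — a temperature-scaled contrastive loss, either **NT-Xent**
  (all $2N$ stacked views; negatives are both intra- and cross-modality)
  or **InfoNCE** (symmetric cross-modal form; negatives are the other
  modality's rows only). Similarities are cosine in both cases. The two
  differ exactly in their negative pools, which is what makes comparing
  them meaningful.

Default weights are 1 everywhere except the contrastive term: 0.5 with
temperature 0.5 for NT-Xent, 0.25 with temperature 0.07 for InfoNCE.
Unimodal training zeroes every text-dependent weight, reducing the
objective to image cross-entropy; the text branch then receives no
gradient updates at all.

Whether alignment should act on pre- or post-projection embeddings is
genuinely open; the package aligns post-projection, the convention of the
contrastive-learning literature the losses come from, and the silhouette
evaluation uses the same space for consistency.

## Reports from metadata

Two report renditions exist per record:

* **structured** — the exact template
  `"The image includes a {benign|pre-malignant|malignant} skin lesion,
  specifically a {class}"`, with `" (specifically a {subclass})"` appended
  only when a subclass string is available in the metadata. The
  three-way malignancy wording follows the class table (ACK renders as
  "pre-malignant").
* **synthesized** — the structured sentence extended with one clause per
  descriptor field (skin structure, image colour, dermoscopic structures,
  symmetry). Every clause draws its value from a *closed* vocabulary, the
  mechanism that rules out hallucinated findings; choices are uniform over
  each field's options and deterministic given the seed. The synthesizer
  is a backend interface: the shipped implementation is the deterministic
  template filler, and an external language model could be registered in
  its place provided it respects the same closed-vocabulary contract.

Descriptor choices are deliberately *not* conditioned on the class, only
on metadata and seed, so all class information in a report lives in the
class name and malignancy words. During multimodal training, the text fed
for a record "turns over" between the two renditions with probability 0.5
per draw.

## Training protocol

Mini-batch optimization (Adam, batch 32) with:

* **class balancing** — records are drawn with inverse-frequency weights,
  so the per-draw class probability is uniform and minority classes are
  seen more often (each time with fresh augmentation) rather than
  physically duplicated. Each mini-batch is drawn *without replacement
  within the batch*: with small cohorts, sampling the epoch with
  replacement would place duplicate records in almost every batch, and a
  duplicated record acts as an identical-positive false negative in the
  contrastive pool, corrupting the NT-Xent/InfoNCE terms;
* **image augmentation** — a sampled right-angle rotation
  ({0°, 90°, 180°, 270°}; right angles avoid interpolation artifacts on
  small images), optional horizontal/vertical flips, and a light RGB shift
  (default ±0.05 of the dynamic range, clipped);
* **model selection** — after every epoch the image-only cross-entropy on
  the validation partition is computed (text plays no role in validation,
  matching image-only deployment), and the checkpoint minimizing it is
  returned;
* **seeding** — one integer seed determines initialization, sampling,
  augmentation and turnover, so a run is exactly reproducible.

### Optimization budgets at desk scale

The full-scale defaults (`train_config()`: 10 epochs, learning rate 1e-4,
weight decay 1e-5) describe conservative fine-tuning of large pretrained
backbones — a *fixed optimization budget*, deliberately far from training
the image branch to convergence. The reference encoders train from random
initialization, so `desk_config()` rescales the optimizer while keeping
that character: learning rate 1e-3 and 40 epochs, applied identically to
both training modes.

The budget matters for what the comparison measures. Co-learning is an
optimization and regularization effect: the text branch (whose task is
easy, since reports name the class) shapes the shared head and, through
the alignment terms, steers the image representation while the image
branch is still far from fitting the data on its own. In sweeps over
budgets we observe exactly this: under the conservative budget the
multimodal runs lead, while with substantially longer schedules the
unimodal branch continues to improve until it matches or overtakes the
multimodal one, whose alignment terms then act as a constraint on pure
image fitting. Desk-scale results should therefore be read as
budget-conditional, like the full-scale protocol they emulate.

Separately from the comparison, the training machinery itself is
validated by a learnability check: on a noise-free, fully separated
synthetic cohort, unimodal training with an extended 60-epoch schedule
must reach held-out $\kappa \ge 0.9$ (it reaches 1.0). That check asks
"can this implementation learn at all, given budget", which is a
different question from the budget-matched mode comparison.

## Evaluation protocol

* **Cohen's $\kappa$** on image-only test predictions,
  $\kappa = (p_o - p_e)/(1 - p_e)$, computed per test source and never
  pooled across sources (sources differ in difficulty, and pooling would
  mix marginals);
* **silhouette score** of the projected image embeddings under the true
  labels (Euclidean distance; singleton classes contribute 0);
* **repetitions** — each setup is retrained under consecutive seeds
  (ten in full-scale work; five in the desk-scale acceptance runs to fit a
  CPU budget), reported as mean ± sample standard deviation ($n-1$);
* **significance** — a paired two-sided Wilcoxon signed-rank test on the
  per-seed $\kappa$ values of two setups, paired by seed within each
  source. The null distribution is enumerated exactly (all $2^n$ sign
  assignments, midranks for ties) up to $n = 12$ pairs and approximated
  normally with tie correction beyond; no continuity correction is
  applied. Zero differences are dropped, and an all-zero comparison
  returns $p = 1$ with a warning.

## The synthetic cohort

`generate_cohort()` emulates a paired cohort: each class is a parametric
motif on a skin-tone background — ellipse (NEV), ragged polygon (MEL),
ring (BCC), stippled patch (ACK), scaly grid (BEK) — with a class base
colour, per-image shape jitter, additive Gaussian pixel noise
(`noise_sd`), and a `motif_separation` dial interpolating the lesion
colours between background (0) and fully distinct (1). Metadata carries
the class display name as `raw_class`, plus a subclass string for a
configurable fraction of records, and reports are synthesized from that
metadata — so reports are genuinely informative about image class, as in
the real setting where metadata encodes the diagnosis.

Defaults are 40 records per class at 64×64, `noise_sd = 0.1`,
`motif_separation = 0.7`, `subclass_rate = 0.3`: enough degradation that
image classification is imperfect while the reports remain exact, which
is the regime co-learning targets. These values were fixed once as the
package's study conditions.

What the generator does *not* model: photorealistic lesion morphology,
dermoscopic artifacts (hairs, rulers, gel bubbles), skin-tone distribution
shift, source heterogeneity (one synthetic "source" only), or label
noise. Passing tests on this cohort therefore demonstrate that the
machinery — losses, balancing, augmentation, selection, evaluation — is
correct and that class signal flows from text into the image branch; they
do not by themselves establish clinical performance on real dermoscopy
collections.

## Numerical choices and degenerate inputs

* Contrastive losses use the log-sum-exp trick with per-row maxima; with a
  single pair ($N = 1$) both losses are exactly 0 (no negatives).
* Zero-norm embedding rows are an error for the cosine-based losses rather
  than silently regularized.
* Cohen's $\kappa$ returns 1 for perfect agreement even when the marginal
  chance agreement is 1 (constant vectors), and 0 for imperfect agreement
  in that case.
* The silhouette convention sets $s(i) = 0$ for singleton clusters and for
  coincident points ($a = b = 0$).
* Manifest partitions are fixed at build time; unknown partition strings
  fail with the offending row, and duplicate record ids are rejected.
* The classifier's argmax breaks ties toward the first class to keep
  prediction deterministic.
* One published per-source composition cell is internally inconsistent
  with its own row and column totals; the shipped table reconciles it to
  the value implied by the totals.

## Known limitations

* The reference encoders are far below the capacity of the pretrained
  backbones used in full-scale work; desk-scale effect sizes and
  variances are not comparable to published ones, and only the *direction*
  of the multimodal-vs-unimodal comparison is even a candidate for
  reproduction at this scale.
* Training from random initialization at a conservative budget sits on an
  optimization plateau whose escape time varies strongly with the seed;
  held-out $\kappa$ is correspondingly volatile between runs of either
  mode. With small test partitions (40 images) $\kappa$ is additionally
  coarse-grained. Five repetitions are often not enough to resolve a
  small multimodal-vs-unimodal difference from this noise, so the
  desk-scale comparison should be read as a direction check with wide
  uncertainty, not as an effect-size estimate — `repeat_experiment()`
  reports the per-run spread and `compare_experiments()` the paired
  significance precisely so that this uncertainty is visible.
* Reports synthesized from metadata can never contain information absent
  from the metadata; the co-learning gain hinges on metadata quality.
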