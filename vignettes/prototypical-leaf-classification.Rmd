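---
title: "Prototypical-part classification of leaf disease images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototypical-part classification of leaf disease images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Deep classifiers for crop-leaf disease images are usually black boxes: they
name the disease but not the image evidence behind the call. `leafproto`
implements an intrinsically interpretable alternative — a prototypical-part
network. A convolutional extractor $f$ maps an image $x$ to a latent volume
$Z = f(x) \in \mathbb{R}^{H\times W\times D}$, every value squashed into
$(0,1)$ by a final sigmoid. The model owns $m$ learnable prototypes
$p_1,\dots,p_m \in \mathbb{R}^{D}$ (ten per class by default), each of
$1\times1$ spatial extent, each permanently assigned to one class. For a
prototype $p$ and every latent patch $\tilde z$ of $Z$ the prototype layer
computes the log-ratio similarity

$$ g_p(Z) \;=\; \max_{\tilde z \in Z}\;
   \log\frac{\lVert \tilde z - p\rVert_2^2 + 1}
            {\lVert \tilde z - p\rVert_2^2 + \varepsilon}, $$

a strictly decreasing transform of the squared Euclidean distance, bounded
by $\log(1/\varepsilon)$ at an exact match and falling to $0$ as the patch
moves away. The $H\times W$ map of these similarities is the prototype's
activation map; its maximum (global max pooling) is the prototype's
similarity score $s_j$. A linear head turns the score vector $s$ into class
logits $s^\top W_h + b$, and a softmax into probabilities. Because the head
is linear, every logit decomposes exactly into per-prototype contributions
$s_j \cdot W_{h,jc}$ — the package's reasoning reports verify this identity
to $10^{-6}$ on every explained image, which is the operational meaning of
"the model explains its own decision". After projection (below) each
prototype *is* a patch of a real training image, so each contribution can be
shown as: this region of the test image (evidence box from the upsampled
activation map) looked like that patch of that training image.

$\varepsilon$ defaults to $10^{-4}$, bounding similarities at
$\log 10^4 \approx 9.21$, the magnitude regime of published
prototypical-part scores.

## Training objective

Four terms are combined into
$\mathcal{L} = \mathcal{L}_{ce} + \lambda_1 \mathcal{L}_{clst}
 + \lambda_2 \mathcal{L}_{sep} + \lambda_3 \mathcal{L}_{q}$:

* **Cross-entropy** on the softmax probabilities.
* **Cluster loss**: the batch mean of the minimal squared distance between
  any latent patch of an image and any *own-class* prototype. Minimizing it
  makes every training image carry at least one patch close to an own-class
  prototype.
* **Separation loss**: minus the batch mean of the minimal squared distance
  to any *wrong-class* prototype — nonpositive by construction, so with
  $\lambda_2 > 0$ the optimizer pushes patches away from other classes'
  prototypes.
* **Supervised contrastive loss**: each image is embedded by global max
  pooling of $Z$, a linear projection to $E = 64$ dimensions and L2
  normalization. A momentum ("key") copy of the encoder embeds the same
  images; its outputs are pushed into a FIFO dictionary with their labels.
  For a query $q$ the InfoNCE loss
  $-\log\!\big(e^{q\cdot v_+/\tau} \big/ \sum_k e^{q\cdot v_k/\tau}\big)$
  is averaged over all same-class keys $v_+$ in the dictionary, with all
  different-class keys as negatives; queries that lack a same-class or a
  different-class key are skipped and counted. With exactly one positive
  this reduces to the textbook single-positive form — a tested property.

Weights default to $\lambda_1 = 0.8$, $\lambda_2 = 0.08$ (the
prototypical-part convention, consistent with the separation term carrying
its own sign) and $\lambda_3 = 0.1$ as a neutral default; the desk profile
raises $\lambda_3$ to 3 (see below).

## Schedule, projection, head fine-tuning

Plain SGD (no momentum, no weight decay) updates the convolutional stack,
the projection and the prototypes; the head keeps its initialization
(own-class weights $+1$, other-class $-0.5$, zero bias) during the joint
phase. Every `push_every` epochs, and once more after the last epoch, each
prototype is *projected* (pushed) onto the nearest latent patch among
training images of its own class, recording provenance (source image,
latent cell, aligned pixel box). Projection is what lets explanations show
real training patches. After the final push the extractor and prototypes
are frozen — every image's similarity vector is then constant — so head
fine-tuning is the convex multinomial-logistic problem in $(W_h, b)$; it is
minimized by BFGS on the ridge-stabilized (ridge $10^{-4}$) cross-entropy,
warm-started from the current head, with an iteration budget scaled by
`head_tune_epochs`. Tests assert the stage leaves extractor and prototype
parameters bit-identical.

Two numerical guards keep plain SGD stable. First, each accumulated
mini-batch gradient tensor is clipped to an L2 norm of 5. Second, the
similarity kernel's derivative w.r.t. the squared distance approaches
$1/\varepsilon = 10^4$ as a patch coincides with a prototype — which is
*always* true right after a push — so the cross-entropy path caps that
factor at 100. The cap only distorts gradients within distance
$\sim 10^{-2}$ of a prototype; finite-difference gradient checks run on
random instances where distances are $O(1)$ and the analytic gradients are
exact.

Model selection is by *training* accuracy, at two levels. Within a run,
the epoch snapshot with the highest training accuracy (ties to the later
epoch) is the model that receives the final push and head fine-tuning.
Across runs, `restarts` independent trainings from deterministically
derived seeds are compared by final training accuracy and the best is
kept (the desk profile uses two). Desk-scale plain-SGD trajectories
oscillate; both selection rules use only the training split, never the
test split.

## Feature extractor

The built-in `tiny` backbone is four convolution blocks (channels 16, 32,
64, 64, ReLU): two 3×3 stride-2 blocks, a 3×3 stride-1 block and a 1×1
block, so a side-64 input yields a 16×16 latent grid (side over 4 in
general; verified for sides 32, 64 and 224) with a receptive field of about
15 pixels per cell. The receptive field is a deliberate choice: it matches
the size of a single lesion. An earlier variant with four stride-2 blocks
(4×4 grid, 31-pixel receptive field) classified well but could not
localize — lesion evidence bled into every cell's receptive field, so
activation maps peaked on arbitrary leaf regions and the evidence-box
localization rate sat near chance. Shrinking the receptive field to lesion
scale forces discriminative features to live where the lesions are, which
is what makes the explanation maps meaningful. Inputs are
standardized inside the extractor — $(x - 0.5) \times 4$ — because raw
$[0,1]$ pixels are DC-dominated and condition the first layer poorly; this
one change moved desk-scale feature learning from chance-level to
functional. Two add-on 1×1 convolutions follow (ReLU, then sigmoid), fixing
the latent depth $D$ (default 32). The sigmoid is clamped to
$[10^{-7}, 1-10^{-7}]$: in double precision the raw sigmoid rounds to
exactly 1.0 near preactivation 37, and exact 0/1 values would make the
log-ratio kernel degenerate. Named large backbones (`vgg19`, `resnet152`,
`densenet161`) are adapter slots behind the same contract for externally
supplied weights; nothing in the package or its tests depends on them.

The receptive-field mapping from latent cells to pixel boxes uses the
uniform scale `input_side / H`; it is used only for evidence boxes, which
mirrors upsampled-activation practice rather than exact receptive-field
inversion.

## Synthetic data: what it emulates and what it does not

The generator emulates the *structure* of field datasets of diseased crop
leaves: C classes of leaf images where each diseased class is set apart by
a localized visual motif on a leaf-shaped background. Class 0 is a healthy
leaf (rotated elliptical silhouette with boundary wobble, per-image colour
variation, mild sensor noise). Each diseased class draws
Poisson(`lesion_count_mean`, truncated to at least 1) lesions of its motif
— circular brown spots, elongated yellow stripes, or clustered dark blobs,
cycling for more classes — with centers uniform inside the leaf, radii
uniform in `lesion_size_range`, and motif colours jittered with s.d.
`color_jitter_sd`. The lesion mask is exactly the union of drawn supports,
which is what makes localization claims quantitatively testable: real
datasets have no pixel ground truth at all.

Defaults: 3 classes, 70 images per class, side 64, mean 3 lesions of radius
4–8 px, jitter 0.03. The radii put single lesions at roughly 15–25% of the
leaf width, several per leaf — the scale of visible field lesions — and
were fixed when the generator was written. A deliberately held property is
that the classes are *not* trivially separable by global colour statistics:
a mean-colour classifier sits well below the desk-scale accuracy criterion,
so passing it requires genuinely localized features. What the generator
does **not** emulate: photorealistic leaf texture, background clutter and
illumination taxonomies, within-class pathology progression, multiple
diseases per leaf, or label noise. Test results on it bound implementation
correctness, not field performance.

Ten-fold offline augmentation reproduces the stated policy: skew uniform in
±45° (realized as a projective keystone tilt), shear up to 10°, elastic
grid distortion with control-point displacement 5 px at the 224 reference
resolution (scaled proportionally), left-right flips with probability 0.5,
and HSV shifts bounded by (0.1, 0.3, 0.2). "Ten-fold" keeps the original
plus nine transformed copies — the standard offline convention. Geometric
transforms are applied identically to lesion masks (nearest-neighbour);
photometric ones are not. Augmentation applies to the training split only.
The desk-scale pipeline runs the stage at fold 3 (originals plus two
transformed copies): offline augmentation is part of the reference
procedure, and at desk scale it is also the single largest stabilizer of
training — it roughly triples the SGD steps per epoch and lifted both
worst-seed accuracy and localization in development probes. Fold 10 is
retained as the policy default for full-scale runs.

## Desk-scale profile and problem sizes

The reference hyper-parameters (batch 80, 50 epochs, SGD at $10^{-4}$,
input 224²×3) target pretrained backbones at GPU scale and remain the
package defaults. The desk profile (`desk_train_config()`,
`desk_run_config()`) trains the tiny backbone from scratch on one CPU in
a few minutes: side 64, batch 16, 30 epochs, learning rate 0.02, three-fold
offline augmentation of the training split, pushes at epochs 10, 20 and 30,
five head-tune units. Small batches matter at this scale — 300 SGD steps
per epoch set instead of 150 was the difference between fragile and
dependable runs before augmentation tripled the count again. Its
contrastive settings
deserve a note: at 150 SGD steps a key-encoder momentum of 0.999 would
leave the dictionary frozen at its random initialization, so the desk
profile uses momentum 0.5 and $\tau = 0.2$, and raises $\lambda_3$ to 3 —
at this scale the contrastive term, not the cross-entropy, is the main
driver of representation learning. The test suite and the acceptance
script train on 3 classes × (50 train + 20 test) images; k-fold
cross-validation in the unit tests runs 2 folds at side 32.

## Degenerate inputs, ties, and other fixed choices

* Squared distances use the expanded form
  $\lVert z\rVert^2 - 2 z\cdot p + \lVert p\rVert^2$ clamped at 0.
* Argmax cells of similarity fields break ties to the first cell in
  row-major order; nearest-patch projection breaks ties to the first
  candidate in enumeration order.
* Cross-entropy clips probabilities below at $10^{-12}$.
* Evidence boxes threshold the upsampled map strictly above its 95th
  percentile, fall back to ties-included when the map is constant, and keep
  the largest 4-connected component.
* Prototypes initialize uniformly in $[0,1]^D$, matching the sigmoid range;
  seeds fan out from one global seed through fixed per-stage offsets, and
  every stage restores the caller's RNG state.
* Zero-denominator metrics (e.g. precision with no positive predictions)
  are reported as 0 with an explicit flag rather than NaN.

## Known limitations

Prototypes are spatially rigid 1×1 latent cells: scattered or diffuse
symptoms are represented only through multiple independent prototypes, and
an evidence box marks the single strongest region. The from-scratch tiny
backbone is a desk-scale device — on real data one would start from a
pretrained extractor and the reference hyper-parameters. The contrastive
dictionary stores embeddings produced by a stale encoder copy; at very
small queue sizes or high momentum it can stall, which is why the desk
profile lowers both. Training cost is dominated by the hand-written
convolutions; they are exact but make no claim to GPU-class speed.
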