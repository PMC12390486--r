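---
title: "Sensitivity-guided pruning with collaborative distillation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-guided pruning with collaborative distillation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-stage detectors used for field-pest monitoring are routinely too
large for the edge devices they are meant to run on. Two compression
families address this: *structured channel pruning*, which removes whole
convolutional channels and yields a genuinely smaller dense network, and
*knowledge distillation*, which trains the compact (student) network to
imitate the original (teacher). prunekd implements a combined workflow:
BatchNorm-scale-guided global channel pruning followed by a collaborative
distillation finetune, exercised end to end on a synthetic pest-scene
benchmark with mAP-based evaluation.

## The model and its components

### Channel importance from BatchNorm scales

Every prunable conv is followed by BatchNorm,

$$y = \gamma \cdot \frac{z - \mu}{\sqrt{\sigma^2 + \varepsilon}} + \beta ,$$

whose learnable per-channel scale $\gamma$ multiplies the whole channel.
When $|\gamma| \to 0$ the channel output degenerates to the constant
$\beta$ and carries no signal, so $|\gamma|$ is a cheap proxy for channel
importance. The global importance score of channel $c$ is

$$S_c = \frac{|\gamma_c|}{\sum_i |\gamma_i|},$$

with the sum over *all* prunable channels in the model, so scores always
sum to one (`channel_scores()`). We use $|\gamma|$ throughout: the
magnitude is what measures reconstruction amplitude, and a sign flip can
be absorbed by downstream weights.

To concentrate importance into few channels before pruning, training adds
an L1 penalty $\lambda \sum |\gamma|$ to the task loss
(`train_sparse()`; subgradient $\lambda\,\mathrm{sign}(\gamma)$). The
default $\lambda = 10^{-4}$ is the standard network-slimming magnitude;
it is exposed in every config. Per-layer mean $|\gamma|$ is the
*pruning-sensitivity* statistic (`sensitivity_report()`): layers with high
mean stay channel-dependent and deserve conservative pruning; low-mean
layers carry redundancy.

### Global-threshold pruning with coupled channels

`make_pruning_plan()` sets the threshold at the lower empirical
`ratio`-quantile of all $|\gamma|$ (no interpolation — the value at index
$\lfloor \mathrm{ratio}\cdot C\rfloor$ of the sorted vector) and keeps a
channel iff $|\gamma| >$ threshold; strict inequality keeps ties
deterministic. Three adjustments follow, in this order:

1. **Protection caps.** Layers listed in the protection map keep at least
   their top-$|\gamma|$ channels up to a maximum prune fraction (default:
   0.5 for the first backbone BN and for every BN feeding a detection-head
   projection). This is our explicit reconciliation of a single global
   threshold with non-uniform, sensitivity-aware aggressiveness: the
   threshold does the global work, the caps bound the damage in layers
   whose function is known to be fragile.
2. **Minimum one channel** per layer (the largest-$|\gamma|$ one).
3. **Coupled-group merge.** Channels tied through the graph — residual
   adds force the two summands to share channel indices; a concat consumer
   ties its input slices to their producers — are merged by elementwise OR
   (keep if any member needs the channel). Coupling is tracked with a
   union–find over *individual channels*, not whole layers, so concat
   offsets and channel-split blocks are handled exactly. Caps are applied
   *before* the merge: merging last is what guarantees the tied masks come
   out identical, at the cost of extra kept channels. The achieved ratio
   is recomputed after all adjustments and the slack (target minus
   achieved) is reported in the plan.

`apply_pruning()` performs the surgery: each pruned BN loses its dropped
channels, its producing conv loses those output filters, every consumer
loses the matching input slices (concat consumers at the correct offsets,
channel-splits re-indexed into kept-channel coordinates), and surviving
weights are copied verbatim. A ratio-0 plan is an exact identity rebuild,
and removing channels whose $\gamma$ and $\beta$ are both zero leaves
model outputs unchanged to float tolerance — both properties are tested.

Whether a "70% pruning ratio" counts channels or parameters is a genuine
ambiguity; we define the ratio over channels and report both channel and
parameter counts.

### Collaborative distillation (mask-free generative + logit)

After surgery the student's channels are few and its features sparse;
forcing them to match teacher features channel-by-channel is ill-posed.
Instead a *generative module* — per tap point, a 3×3 conv from student to
teacher width, ReLU, and a second 3×3 conv at teacher width — reconstructs
teacher-shaped features from raw student features (no random masking; the
pruned features are already sparse, and reconstruction alone aligns them).
The feature loss is

$$L_f = \frac{1}{N}\sum_{i=1}^N \lVert G(F_s^i) - F_t^i\rVert_2^2$$

over the $N$ tap points (the three neck output scales — exactly the
features the detection heads consume, which also makes the logit loss
below well-posed). A `normalize_feature_loss` flag divides each term by
its element count, making $L_f$ invariant to tap spatial size; the
literal squared norm is the default.

The *logit* term feeds the generated features through the **frozen**
teacher detection head, $p = T_H(G(F_s))$, and penalizes the mean
per-sample squared distance to the teacher's own raw head outputs:

$$L_l = \frac{1}{B}\sum_{b=1}^B \lVert p_b - t_{p,b}\rVert^2 .$$

This is deliberately a plain L2 on raw head outputs rather than a
temperature-softened KL, although "logit distillation" classically means
the latter; the L2 form needs no temperature hyperparameter and treats
box, objectness and class channels uniformly. The generated feature, not the raw student feature, is
what enters the teacher head: the pruned student's channel count cannot
match the head's input channels, and the generation module is defined as
the preceding stage.

The total finetune objective is

$$L = \alpha_1 (L_{bbox} + L_{conf} + L_{cls}) + \alpha_2 L_f + \alpha_3 L_l,$$

with modes `none` / `feature` / `logit` / `both` zeroing terms for
ablations. **Weight calibration:** the $\alpha$'s are free
parameters; we calibrate them once so that the three weighted terms are
of the same order at the start of a finetune on the default benchmark,
where the literal norms sit near $2\times10^3$ against a task loss near
$0.5$: $\alpha_1 = 1$, $\alpha_2 = 10^{-4}$ ($1.0$ normalized),
$\alpha_3 = 2\times10^{-4}$. All are config-exposed. With badly scaled
weights (e.g. $\alpha_3 = 0.1$ against literal norms) the logit term is
hundreds of times the task loss and the finetune demonstrably degrades
the student.

Teacher invariance is structural: the teacher runs in eval mode, its head
backward pass is used only to propagate gradients to the generated
features, and its parameters never enter the optimizer (tested bitwise).
With `mode = "none"` the finetune consumes the same RNG stream as plain
training and reproduces it bitwise — the generator is seeded separately.

### MiniDet: the trainable testbed

The teacher/student pair is MiniDet (`build_minidet()`), a deliberately
small anchor-free detector that keeps every architectural property the
compression method needs: conv-BN-SiLU blocks everywhere (so every conv is
prunable), residual stages (channel coupling through adds), an SPPF block
(coupling through concat of pooled copies of one tensor), a top-down plus
bottom-up neck (coupling through concat of different tensors), and
decoupled heads at strides 8/16/32 with class, box and an explicit
objectness/confidence branch. Box regression is per-cell
left/top/right/bottom distances, $d = \mathrm{softplus}(t)\cdot
\mathrm{stride}$, so an initial prediction always overlaps its own cell
and the IoU loss has gradient from step one. An object is assigned to the
scale whose stride best matches its size
($\arg\min_k |\log_2(\sqrt{wh}/4s_k)|$, ties to the lower stride) and to
the cell containing its center. The loss is mean $(1-\mathrm{IoU})$ over
positives, objectness BCE over all cells, and class BCE at positives.

The training engine (im2col convolution, exact BatchNorm backward in both
batch and running-statistics mode, SiLU/ReLU, nearest upsampling, max
pooling with argmax backprop, Adam) is part of the package and its
gradients are verified against central finite differences through the
whole graph. A separate YOLOv8-small *accounting graph*
(`build_yolov8s_graph()`) reproduces the canonical small-variant scaling —
depth ×0.33, width ×0.50 with make-divisible-8, C2f split/shortcut
blocks, SPPF, decoupled head with a 16-bin distribution-focal box branch —
for parameter/FLOP bookkeeping and pruning-plan construction; it is not
trainable and its weights are zero-initialized. FLOPs are counted as
2×multiply–accumulates plus one op per element for BatchNorm/activation/
add/pooling, the convention under which this graph totals ≈28.7 G at
640×640. Published FLOP figures for this architecture vary by counting
convention, which is why the package reports FLOPs but pins only the
parameter count in its own regression checks.

## Evaluation

Detections are decoded per cell (confidence = objectness × best class
probability), filtered at a low floor (0.001) so the full
precision–recall curve is available, and reduced by greedy per-class NMS
(IoU 0.45). Matching is greedy per class in descending confidence, each
detection to the unmatched ground truth of highest IoU ≥ threshold within
the same image. AP uses the all-points precision-envelope integral —
exact for the integral $\int_0^1 p(r)\,dr$ of the interpolated curve — and
a 101-point option is available behind a flag. mAP is the unweighted
class mean; classes absent from the ground truth of a split are excluded
from the mean (with a warning) rather than scored zero. Precision/recall
are additionally reported at a fixed operating confidence of 0.25
(config-exposed; a fixed threshold, not the F1-optimal point).

## The synthetic benchmark

The field-pest image collections this kind of workflow targets are
rarely publicly deposited, so the package ships a generator (`scene_spec()`, `generate_scene()`) that emulates the
*statistical structure* such a dataset assumes: five classes of distinct
shape family (ellipse, capsule, cluster-of-dots), pairwise-distinct colors
(minimum RGB distance 0.25, enforced), per-class scale ranges, 1–4 objects
per image with at least 40% of every painted object left visible, on a
green gradient background with low-frequency sinusoidal mottling so plain
thresholding cannot find the objects. Boxes are the analytic axis-aligned
extents of the painted shapes, tested to enclose the painted pixels within
2 px. The standard augmentations are provided with the conventional
ranges: Gaussian noise, rotation ±30°, translation ±20%, scale 0.8–1.2×,
brightness ±30%; geometric augmentation replaces each box by the
axis-aligned hull of its transformed corners, clipped, and drops boxes
with less than 20% of their transformed area visible (slivers at the
border are labels no detector should be trained on). Splitting is
stratified 7:2:1 with train = round(0.7n), val = round(0.2n) (half rounds
up), test = remainder — the unique simple rounding rule consistent with
every row of the reference per-class split counts the tests encode — and
a seeded
permutation assigns items.

What the generator does **not** emulate: photorealistic insect appearance,
occlusion by foliage, lighting variation beyond a global brightness
factor, class imbalance (configurable but uniform by default), or label
noise. Passing tests on this benchmark therefore demonstrate that the
*mechanics* of pruning and distillation behave as specified — not that
the pipeline reaches any particular accuracy on real field imagery.

## Desk-scale study conditions

All training-dependent properties are exercised at a fixed desk scale,
chosen once: 64×64 scenes (objects scaled 0.18–0.42 of the image so they
span several stride-8 cells, 1–2 per image), 200 training and 60
validation images, MiniDet width 0.25, Adam at learning rate 5×10⁻³ with
batch size 8, and 30 epochs per stage (task training, sparsity training,
distillation finetune). Under these conditions the full pipeline
(`run_experiment()`) runs in a few minutes on one CPU, the teacher reaches
mAP@0.5 well above 0.7, pruning at ratio 0.5 with the default protections
removes roughly a third of channels (the gap to the target is coupling/
protection slack, reported in the plan), and the distillation finetune
recovers the pruned model to within two mAP points of the teacher while
the plain finetune of the same student stays clearly below it.

## Numerical and degenerate-case decisions

- Rounding of split counts is half-away-from-zero, not banker's rounding,
  so counts do not depend on floating parity.
- BatchNorm uses biased batch variance in training and running statistics
  (momentum 0.1) in eval; $\varepsilon = 10^{-5}$.
- The IoU gradient is computed analytically with indicator terms for
  which box side binds; boxes with zero overlap contribute zero gradient
  (assignment guarantees overlap at initialization).
- All-zero $\gamma$ tables are rejected as degenerate rather than scored.
- Precision and recall are defined as 0 when their denominators vanish;
  AP for a class with no ground truth is undefined and the class is
  excluded from the mean.
- Objectness biases initialize at −2 so the confidence loss starts from a
  low-detection prior.
- Checkpoints are single JSON documents (graph structure plus all arrays)
  so every artifact is plain text and reconstructable.
- An optional round-keep-to-multiple-of-4 is deliberately **not**
  implemented; keeping the kept-channel arithmetic exactly auditable was
  judged more valuable at this scale than hardware-friendly channel
  counts.

## Known limitations

- The training engine is CPU-only and sized for small models; it is a
  faithful, tested implementation of the method's training mathematics,
  not a performance-oriented framework.
- The accounting graph supports bookkeeping and plan construction only;
  training it (and distribution-focal/task-aligned label assignment) is
  out of scope.
- One prune + one finetune pass; iterative prune–retrain schedules are
  not implemented.
- The masked variant of generative distillation and alternative
  distillation baselines are out of scope beyond the mode toggles.
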