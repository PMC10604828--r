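---
title: "Methods: metaheuristic configuration search for transfer-learning classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaheuristic configuration search for transfer-learning classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotune)
```

## The model

`histotune` treats transfer-learning (TL) classifier configuration as a
continuous optimization problem on the unit hypercube. Each candidate is a
vector $x \in [0,1]^D$; coordinate $i$ is decoded against the $i$-th
hyperparameter *span*. With the augmentation spans included $D = 15$
(loss function, batch size, dropout, TL learn ratio, parameter optimizer,
scaling technique, augmentation gate, rotation, width/height shift, shear,
zoom, two flip markers, brightness); without them $D = 7$.

A population of $N$ such vectors is initialized uniformly
($X = \mathrm{rand} \cdot (UB - LB) + LB$ with $LB = 0$, $UB = 1$),
evaluated through a fitness backend, ranked best-first, and updated for
$T_{\max}$ iterations by one of two population-based metaheuristics. The
fitness convention throughout is maximization; by default the scalar is
the test-partition accuracy, with the equal-weight twelve-metric weighted
sum available as an alternative.

### Decoding

Discrete spans (categorical, boolean, stepped-numeric with $L$ options)
use the span-index mapping
$$\mathrm{index} = \mathrm{clamp}(\lceil x_i \cdot L \rceil,\, 1,\, L),$$
1-based; continuous spans map linearly to their interval. The ceiling rule
with a clamp at 0 was chosen among the possible rounding conventions
because it reproduces the canonical worked example exactly: $0.75$ over
the 12-option batch span $4, 8, \ldots, 48$ gives index 9 and batch size
36. Boolean spans decode in the order (yes, no), so an all-zero vector
turns every flag on — consistent with reference configurations in which
all-zero augmentation settings coincide with enabled flips. Two
consequences worth noting:

* The TL learn ratio span is $1 \to 100$ (step 1), so its decoded minimum
  is 1 %, never 0.
* The brightness span is a single element but the consumer needs a
  (low, high) multiplier pair. We decode deterministically:
  $\mathrm{low} = 0.5 + 1.5\,x$, $\mathrm{high} = \mathrm{low} +
  x\,(2 - \mathrm{low})$. At $x = 0$ this degenerates to $(0.5, 0.5)$.
  Any single-element rule loses one degree of freedom, so arbitrary
  printed pairs cannot all be reproduced; we prefer a reproducible
  deterministic widening over a hidden second random draw.

When the augmentation gate (index 7) decodes to "no", indices 8–15 are
ignored and absent from the decoded configuration, making the effective
search 7-dimensional on that side of the gate.

## The optimizers

Both algorithms share the loop: evaluate, rank descending by fitness,
generate one candidate per member, clip to $[0,1]^D$, evaluate, accept
greedily (keep the better of old/new). Greedy acceptance is our choice
where the originating descriptions specify ranking but not replacement; it
guarantees a monotone best-so-far trajectory. Out-of-bounds candidates are
repaired by clipping rather than resampling — the simplest reproducible
rule.

**Aquila Optimizer (AO).** While $t \le \frac{2}{3} T_{\max}$ exploration
is active, afterwards exploitation; within each phase the two moves are
chosen by a fair coin per member (the phase interiors are not specified by
the headline equations, and a fair coin is the symmetric default):

* expanded exploration: $X_{best}(1 - t/T) + (X_M - X_{best})\,\mathrm{rand}$,
  with $X_M$ the mean position;
* narrowed exploration: $X_{best}\cdot\mathrm{Levy}(D) + X_R + (y - x)\,\mathrm{rand}$,
  with $X_R$ a random member and $(x, y)$ the spiral terms
  $x = r\sin\theta$, $y = r\cos\theta$, $r = r_1 + 0.00565\,i$,
  $\theta = -0.005\,i + 3\pi/2$;
* expanded exploitation: $(X_{best} - X_M)\,\alpha - \mathrm{rand} +
  ((UB - LB)\,\mathrm{rand} + LB)\,\delta$, $\alpha = \delta = 0.1$. The
  circulating printed form of this move is dimensionally inconsistent
  (it multiplies the bound difference by the lower bound); we implement
  the original algorithm's expression, which is well defined on the unit
  cube;
* narrowed exploitation: $QF\,X_{best} - G_1 X\,\mathrm{rand} -
  G_2\,\mathrm{Levy}(D) + \mathrm{rand}\,G_1$ with
  $QF = t^{(2\,\mathrm{rand}-1)/(1-T)^2}$, $G_1 = 2\,\mathrm{rand} - 1$,
  $G_2 = 2(1 - t/T)$.

Lévy steps use the Mantegna algorithm with stability $\beta = 1.5$ and
scale $s = 0.01$; for $\beta = 1.5$ the Mantegna constant is
$\sigma \approx 0.6966$.

**Gorilla Troops Optimizer (GTO).** Each iteration runs an exploration
sweep then an exploitation sweep. Exploration per member: with probability
$p = 0.03$ migrate to an unknown location (fresh uniform draw); otherwise
with probability $\tfrac12$ move toward another gorilla
$(r_2 - C)X_r + L H$; otherwise
$X - L(L(X - X_r) + r_3 (X - X_r))$. Exploitation: follow the silverback
$L M (X - X_{sb}) + X$ when $C \ge W$ ($W = 0.8$), else competition
$X_{sb} - (X_{sb} Q - X Q) A$. Auxiliaries follow the original
formulation: $C = F(1 - t/T_{\max})$ with $F = \cos(2 r_4) + 1$,
$L = C\,\ell$, $\ell \sim U(-1,1)$, $H = Z X$ with $Z \sim U(-C, C)$,
$M = (|\overline{X}|^g)^{1/g}$ with $g = 2^L$, $Q = 2 r_5 - 1$,
$A = \beta E$ ($\beta = 3$, $E$ a standard-normal vector or scalar with
probability $\tfrac12$ each). The headline equations alone omit these
auxiliary definitions and the exploitation entry condition; adopting the
original published defaults is the only reconstruction that does not
invent new algorithm behavior.

## Preprocessing

Images are resized to $128 \times 128 \times 3$ by separable bicubic
(Catmull–Rom, $a = -0.5$) interpolation with center-aligned coordinates;
edge taps are clamped and rows renormalized, so constants are preserved
exactly and identity resizes are exact. The four scaling transforms are
computed per image over all pixels — the transforms are defined on a
single input image $X$, and per-image statistics keep evaluation
independent of dataset composition. Degenerate denominators (constant
image under standardize/min–max, all-zero under normalize/max-abs) return
an all-zero image with a warning rather than an error: synthetic fixtures
may legitimately contain constant tiles and a mid-pipeline crash would be
worse than a flagged degenerate record.

Augmentation draws its transform parameters uniformly within the
configured magnitudes (rotation $\pm r$, shifts $\pm s$, shear, zoom
$1 \pm z$, enabled flips applied with probability $\tfrac12$, brightness
multiplier in $[\mathrm{low}, \mathrm{high}]$ clipped to the 8-bit range).
Geometric resampling is inverse-mapped bilinear with nearest-edge fill —
the fill mode is unspecified by the reference procedure; nearest-edge
avoids introducing artificial black borders that a classifier could key
on.

Class balancing precedes partitioning (matching the reference phase
order): each class is raised to the largest class's size by augmented
copies of uniformly resampled originals, never removing records — class
sizes (2494, 2698) become (2698, 2698), 5396 in total. Partitioning is a
nested ratio-0.85 split of the shuffled records: 15 % test, then 15 % of
the remainder validation, i.e. 72.25 / 12.75 / 15 %. It is class-agnostic
by default because the reference procedure describes plain ratio splits;
stratification is an opt-in flag.

## Metrics

All count metrics are computed from micro-averaged one-vs-rest confusion
counts as exact unrounded percentages; rounding (half-up, two decimals) is
presentation-only. For two classes micro-averaging forces TP = TN and
FP = FN, which makes accuracy, precision, recall, specificity, F1 and NPV
coincide — the reason reference reports print identical rows for these
six metrics. Aggregation across models averages the *unrounded* values:
averaging the printed rounded rows differs in the second decimal for one
of the reference tables, while unrounded aggregation reproduces all
printed averages. AUC is the Mann–Whitney rank statistic (ties at one
half); cosine similarity is the mean per-sample cosine between one-hot
truth and predicted probabilities. Both require per-sample scores and are
merged into the report by the prediction pathway, not derived from
counts. The reference tables' IoU/Dice/cosine rows are not reproducible
from their printed counts by the stated formulas (the computation behind
them is not stated); we implement the formulas and do not chase those
rows.

## Fitness backends

A backend maps (configuration, split data, epochs, seed) to confusion
counts, per-sample probabilities and an accuracy score.

**Analytic surrogate.** For optimizer testing we need a landscape whose
optimum is known by enumeration. The surrogate ignores the data and
scores $100\,(1 - \bar d)$, where $\bar d$ is the mean normalized
option-index distance from a designated optimum over the five coarse
discrete spans (loss, batch size, parameter optimizer, scaling,
augmentation gate). Dropout and the TL learn ratio are neutral in this
landscape by design: a "within one discrete step" recovery check is only
a meaningful desk-scale oracle on spans with few options, and a 100-option
span would turn it into a precision test of the optimizer's final
polishing rather than of configuration search. Recovery is therefore
judged on the five scored spans (`surrogate_distance()`), decided before
any optimizer experiments were run.

**Tiny trainable classifier.** A softmax head over a frozen, seeded bank
of random convolution filters (ReLU, grid-pooled), with one trainable
hidden layer. The decoded hyperparameters are honored literally: batch
size partitions each epoch's shuffled sample, dropout is applied inverted
to hidden activations, the six losses are differentiated through the
softmax Jacobian (cross-entropy and KL divergence short-circuit to
$p - y$), all eleven parameter-optimizer update rules are implemented
(SGD, Nesterov, Adam, NAdam, AdaMax, AMSGrad, AdaGrad, AdaDelta, RMSProp,
centered RMSProp, FTRL), and the TL learn ratio fixes the percentage of
hidden units whose input weights are trainable — the frozen remainder
plays the role of untouched pretrained layers. This backend is a
desk-scale stand-in for full ImageNet-pretrained networks: it preserves
the *interface semantics* of every searched hyperparameter, not the
training dynamics of deep networks. Conclusions about which specific
configurations are optimal for real histopathology data therefore do not
transfer; conclusions about the framework's mechanics do.

## Synthetic data

`make_synthetic_imageset()` emulates only the shape/label contract of
histopathology patches: 8-bit RGB arrays with a tinted textured background
and, for the positive class, dark elliptical blobs (a cartoon of nuclei
density) whose amplitude scales with `separability`; Gaussian pixel noise
on top; fully seeded. At separability 0 the classes are identically
distributed. It does not model H&E stain statistics, spatial tissue
architecture, staining artifacts or scanner variation — so passing tests
demonstrate the pipeline and optimizers work as specified, not that any
accuracy level would be achieved on real slides.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| Population size $N$ | 10 | reference common configuration |
| Repetitions | 10 | reference common configuration; exposed as independent restarts with derived seeds (base seed + index), since the reference leaves open whether "repetitions" means restarts or iterations — both knobs exist |
| Epochs per evaluation | 5 | reference common configuration |
| Split ratio | 0.85 (nested) | reference partitioning scheme |
| AO $\alpha, \delta$ | 0.1 | original algorithm defaults |
| AO Lévy $\beta$, $s$ | 1.5, 0.01 | original algorithm defaults |
| GTO $p$, $W$, $\beta$ | 0.03, 0.8, 3 | original algorithm defaults |
| Balancing augmentation | rotation 30°, shifts/shear/zoom 20 %, brightness [0.8, 1.2], both flips | reference balancing configuration |

## Numerical choices and degenerate inputs

* Element value exactly 0 on a discrete span clamps to index 1
  ($\lceil 0 \rceil$ would be out of range).
* Ranking is a stable descending sort, so ties preserve submission order
  and re-ranking is idempotent.
* Fitness ties are not accepted (strict improvement), keeping runs
  deterministic under a fixed seed.
* Zero denominators in metric ratios yield `NA` markers, never crashes;
  the weighted sum refuses to aggregate undefined components.
* All randomness flows through locally scoped seeding that restores the
  caller's RNG state, so library calls do not perturb user sessions.

## Problem sizes in the test suite

The shipped tests run the optimizers at desk scale — 5-D benchmark
objectives with $N = 20$, $T = 200$ over 10 seeds; surrogate recovery at
$N = 15$, $T = 100$ over 10 seeds; the trainable backend on synthetic sets
of 40–160 images at $16^2$–$32^2$ pixels — sizes chosen so the full suite
exercises every pathway, including end-to-end experiments, in about a
minute while keeping the statistical assertions (median convergence,
8-of-10 seed wins) well-powered.

## Known limitations

* The tiny classifier is linear-ish in its frozen features; it cannot
  express the accuracy differences between deep architectures, and the
  nine named ImageNet models are deliberately out of scope.
* The decoded brightness pair is a one-parameter family (see Decoding);
  configurations requiring independent low/high bounds are not reachable.
* The image reader/writer supports PNG; other formats should be converted
  on ingest.
* Fitness evaluation is sequential and deterministic; there is no
  parallel evaluation contract.
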