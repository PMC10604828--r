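# histotune

Metaheuristic hyperparameter search for transfer-learning histopathology
classifiers.

## The problem

Configuring a transfer-learning (TL) image classifier — which loss, which
batch size, how much dropout, which weight optimizer, how much of the
pretrained network to fine-tune, whether and how to augment — is a mixed
categorical/continuous search problem that manual tuning and grid search
handle poorly. For binary histopathology classification (normal tissue vs.
oral squamous cell carcinoma patches), population-based metaheuristics can
search this space efficiently: every candidate configuration is encoded as
a vector in the unit hypercube, decoded into concrete hyperparameters,
scored by briefly training and evaluating a classifier, and evolved by the
optimizer's update rules.

`histotune` implements this framework end to end, at desk scale, for
researchers studying metaheuristic configuration search and for anyone who
wants a reproducible, dependency-light harness for it:

* **Search space** — the 15-dimensional (or 7 without augmentation) ordered
  hyperparameter space: loss function (6 options), batch size (4→48, step
  4), dropout [0, 0.6], TL learn ratio 1→100 %, parameter optimizer
  (11 options), scaling technique (4 options), an augmentation on/off gate,
  and eight augmentation spans. Discrete spans decode by the span-index
  mapping `index = clamp(⌈value · Length⌉, 1, Length)`; e.g. the element
  0.75 over the 12-option batch span gives index 9, batch size 36.
* **Optimizers** — the Aquila Optimizer (AO), with expanded/narrowed
  exploration while `t ≤ (2/3)·T` and expanded/narrowed exploitation
  afterwards (Lévy-flight steps via the Mantegna algorithm), and the
  artificial Gorilla Troops Optimizer (GTO), with its migration /
  follow-another-gorilla / silverback-following / competition moves. Both
  operate on `[0,1]^D` with clipping repair and greedy acceptance.
* **Pipeline** — bicubic resize to 128×128×3, the four per-image scaling
  transforms (`X/max`, `(X−μ)/σ`, min–max, max-abs), augmentation-based
  class balancing, and the nested 72.25 / 12.75 / 15 % split (ratio 0.85
  applied twice).
* **Metrics** — micro-averaged confusion counts and the twelve-metric
  suite (accuracy, F1, precision, recall, specificity, AUC, sensitivity,
  IoU, Dice, cosine similarity, Youden index, NPV) with the equal-weight
  weighted sum `WS = (1/12) Σ metrics`.
* **Fitness backends** — a deterministic analytic surrogate (for optimizer
  testing with a known optimum) and a small trainable softmax classifier
  over a frozen convolutional feature bank that honors the decoded batch
  size, dropout, loss, optimizer and TL learn ratio.
* **Fixtures** — a seeded synthetic two-class image generator with
  controllable separability, plus sphere/Rastrigin benchmark objectives.

## Worked example

```r
library(histotune)

space <- build_default_space(include_augmentation = TRUE)  # D = 15
vec <- init_population(10, space, seed = 42)[1, ]
decode_solution(vec, space)
#> <decoded_configuration>
#>   loss: hinge | batch: 24 | dropout: 0.542 | TL ratio: 74%
#>   optimizer: sgd | scaling: standard | augmentation: no

res <- run_experiment(run_config(algorithm = "GTO", backend = "surrogate",
                                 n_solutions = 15, t_max = 50,
                                 repetitions = 3, seed = 42))
res
#> <experiment_result> GTO, 3 repetitions, best fitness 100.000
#> <decoded_configuration>
#>   loss: poisson | batch: 24 | dropout: 0.339 | TL ratio: 86%
#>   optimizer: sgd | scaling: minmax | augmentation: no
surrogate_distance(res$best$best_configuration)
#> [1] 0
```

The surrogate backend scores a configuration by its distance from a known
optimum (`poisson` loss, batch 24, `sgd`, min–max scaling, augmentation
off), so fitness 100 and distance 0 mean the optimizer recovered the
optimum exactly; `res$best_evaluation$report` carries the full
twelve-metric report of the final re-evaluation. Swap
`backend = "tiny_classifier"` and a `data_source` (a directory-per-class
PNG tree or a synthetic-set spec) to score candidates by actually training
the small classifier. A command-line wrapper with the same knobs is in
`inst/scripts/histotune`.

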