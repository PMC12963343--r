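---
title: "Quality-aware federated aggregation with a large-small kernel backbone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware federated aggregation with a large-small kernel backbone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fllsnet)
```

## The problem

Plant-disease image collections are gathered by many parties on
heterogeneous devices and cannot always be pooled: acquisition protocols,
sensor quality, and class composition differ sharply from farm to farm.
Federated learning trains a shared classifier by exchanging model
parameters instead of images, but the standard size-weighted average
(FedAvg) degrades when client data are non-IID — a large shard dominated by
one disease class can drag the global model toward its local optimum.

`fllsnet` is a desk-scale simulation framework for studying one remedy:
weighting clients by *learning quality* rather than data volume. It
contains four interlocking pieces:

1. a lightweight convolutional backbone built on LS (large-small)
   convolution, with forward and backward passes implemented in base R;
2. a federated training loop with FedAvg, FedProx, and the quality-aware
   strategy;
3. the quality metrics, composite scoring, softmax weighting, and a linear
   convergence-bound checker;
4. a synthetic lesion-image generator with class imbalance, per-client
   sensor models, and Dirichlet label-skew partitioning, so everything is
   testable without downloads.

## The backbone: see large, focus small

LS convolution couples two operators at every spatial position `i`:

* **Large-kernel perception (LKP)** computes position-wise dynamic kernels
  from a wide context: a pointwise convolution compresses channels `C` to
  `C/2`, a depthwise `K_L x K_L` convolution (default 7x7) gathers the
  neighborhood, and a second pointwise convolution emits
  `D = G * K_S^2` weights per position — one `K_S x K_S` kernel (default
  3x3) for each of `G` channel groups. The dimensionality `D` is the
  minimal choice consistent with reshaping one small kernel per group.
* **Small-kernel aggregation (SKA)** applies those kernels as a grouped
  dynamic convolution: every channel in group `g` at position `i` is
  filtered with the same position-specific `K_S x K_S` kernel. Kernels are
  applied raw (no per-kernel normalization), as a sliding inner product,
  with zero padding so spatial size is preserved.

An LS block is `x + SKA(LKP(norm(x)))` followed by a pointwise
feed-forward (2x expansion, GELU) with its own residual, i.e.
normalization -> LS convolution -> residual -> FFN -> residual. The full
network is a stem of two overlapping stride-2 3x3 convolutions (224 -> 56
before stage 2), four stages of LS blocks with stride-2
depthwise+pointwise downsampling between stages, and a global-average-pool
plus dense head. With the default table configuration (widths
96/192/384/768, groups 4/8/16/32) the tensors entering stages 2-4 are
56x56, 28x28, and 14x14 at 224x224 input:

```{r}
lsnet_stage_resolutions(lsnet_table_config())
```

Per-stage block depths are not fixed by the stage table; the defaults here
are (1, 1, 2, 1) and configurable. Published parameter totals for this
family are therefore not reproducible from the stage table alone, and
`count_params_flops()` reports exact counts for whatever configuration is
built (FLOPs as multiply-accumulates of the convolutions and head). The
"micro" variant (widths 8/16, 32x32 input) keeps every structural feature
at desk scale:

```{r}
m <- build_lsnet(lsnet_micro_config(), seed = 1)
count_params_flops(m)[c("param_count", "flop_count")]
```

All gradients are hand-derived per layer and verified against central
finite differences (relative tolerance 1e-4 on an 8x8x8 input); the
forward primitives are verified against brute-force nested-loop
convolution oracles.

## Federated optimization

Each round the server broadcasts global parameters; sampled clients run
`E` local epochs (default 1) of mini-batch optimization; the server
aggregates. Defaults follow the reference recipe: batch 8, learning rate
0.01, decoupled weight decay 5e-5, Adam, 3 clients, participation ratio
0.8, 70 rounds. Two conventions the source material leaves open:

* **Optimizer.** The local-update equation is written for SGD while the
  hyperparameter table says Adam. The optimizer is configurable; Adam is
  the default for image experiments, and plain gradient descent is used
  wherever the convergence theory is exercised (the theory assumes it).
* **Participant count.** `round-half-up(C*K)` with a floor of one client,
  re-sampled uniformly each round; with `K = 3, C = 0.8` exactly 2 clients
  train per round.

FedProx adds `mu/2 * ||w - w_global||^2` to every batch objective
(`mu = 0.01` default, configurable; with `mu = 0` it reproduces FedAvg
bitwise). The loop is driven through a small model interface, so the same
machinery runs the image backbone and analytic toy objectives; federated
averaging of per-client quadratic losses is tested against the closed-form
weighted optimum, and a single-client run reproduces centralized training
exactly.

## Quality-aware aggregation

At round `t` each participating client `k` reports its loss
`L_k(w_t)` on the broadcast parameters; the server accumulates these into
a loss history and computes three metrics:

* convergence velocity `c_k = |L_k(w_T) - L_k(w_0)| / T` over the client's
  recorded history (T = history span);
* training stability `s_k`, the population variance of the recorded
  trajectory; its reciprocal `1/(s_k + eps)` rewards smooth optimization
  (`eps = 1e-8` guards zero variance);
* data reliability `q_k`, the mean prediction confidence on the client's
  local validation split (10% of its shard). Confidence defaults to the
  maximum predicted class probability *of the broadcast global model*: a
  locally trained model rates its own shard over-confidently, whereas the
  global model's confidence reflects how well that shard is represented.
  An evidential mode (confidence `1 - K/S` from a non-negative evidence
  head with Dirichlet strength `S`) is available for models that emit
  evidence.

Each metric is z-scored across the client population (population standard
deviation; a metric with zero spread contributes 0 for everyone), combined
as `gamma1*c + gamma2*(1/s) + gamma3*q` on the normalized scale (defaults
`gamma = 1`, unpublished in the source and configurable), and passed
through an overflow-safe softmax to give weights `alpha_k` on the
probability simplex. Until every pooled client has at least
`min_history_rounds = 2` loss observations — velocity and stability are
undefined on shorter histories — aggregation falls back to
size-proportional FedAvg weights.

Two structural choices deserve emphasis:

* **Aggregation pool.** The weighted update sums over the *server's stored
  parameter set* — every client's most recent upload, stale for clients
  skipping the round — rather than over the round's participants only.
  This follows the system architecture (the server maintains a parameter
  set per client) and the update equation's sum over all `K` clients. It
  also matters numerically: with only 2 participants, a pairwise z-score
  is always +-1 whatever the actual metric gap, so participants-only
  weighting quantizes to a near-binary choice and discards all magnitude
  information.
* **Normalization population.** The z-score statistics are likewise
  computed over all clients with sufficient history, and the softmax is
  renormalized over the aggregation pool.

A caveat the tests document: strict per-client monotonicity ("raising my
velocity can never lower my weight") does *not* hold exactly under
cross-client z-scoring — raising an already-dominant client's metric
inflates the shared standard deviation and can shrink its normalized gap
(about 4.5% of random configurations, worst observed change ~0.04). The
test suite asserts the exactly-true sub-property (a client's own z-score
is nondecreasing in its own metric, by Samuelson's inequality) plus a
directional check over random configurations.

## Convergence bound

For `mu`-strongly-convex, `L`-smooth objectives under full-batch gradient
descent, the expected optimality gap after round `t` is bounded by
`(1 - eta*mu)^(t+1) * (L(w_0) - L(w*))`, contractive for `0 < eta*mu < 1`.
`convergence_bound()` evaluates it and warns outside the stated regime
(`eta >= 2/L` or `eta*mu >= 1`). The empirical verification runs gradient
descent on random anisotropic quadratics with eigenvalues in `[mu, L]` and
checks the measured gap at every round against the bound; step sizes are
drawn in `(0.05, 0.95)/L`, the sub-range of the admissible interval where
the classical linear rate holds for all modes (near `2/L` the stiffest
mode's contraction factor `|1 - eta*L|` approaches 1 and the one-sided
bound no longer dominates it).

## Synthetic data

The generator renders green-dominant textured backgrounds (bilinear value
noise plus fine grain) and composites class-parameterized lesions:
anti-aliased rotated ellipses, solid or annular, with angular boundary
wobble ("roughness"), per-class count/radius/color distributions. The
defaults give three visually distinct phenotypes (small brown spots, large
dark rings, yellow blotches); up to ten are provided. Everything is a
deterministic function of the spec seed, bitwise reproducible.

What it emulates: multi-class lesion phenotypes, printed class-imbalance
ratios of three public tomato collections (`imbalance_profile()`; when
fewer classes are requested than a profile holds, the largest ratios are
kept and renormalized, preserving dominance structure), per-client sensor
heterogeneity (rescale -> noise -> gain -> gamma, clamped), and Dirichlet
label-skew partitions (per-class client proportions from
`Dirichlet(alpha)`, largest-remainder rounding, empty shards repaired from
the largest shard). What it does not emulate: real lesion morphology,
correlated backgrounds, annotation noise. A random-forest probe separates
the default classes well above chance, so passing tests show the federated
machinery can exploit real signal — they do not certify performance on
field imagery.

Image default is 32x32 for speed; 224x224 is supported for shape tests.

## The headline experiment

`strategy_comparison()` encodes the package's main study: 600 synthetic
3-class images under the CCMT imbalance profile, Dirichlet `alpha = 0.3`
partition over 3 clients, 20% held-out test split, micro backbone, 20
rounds with the default recipe, comparing final-round global test accuracy
of FedAvg against the quality-aware strategy, across 5 seeds. Label skew
is the heterogeneity under study; per-client sensor distortion can be
layered on via `sensor_heterogeneity = TRUE`. At this scale both
strategies are volatile — one local epoch is ~25 Adam steps, enough to
pull each client far toward its skewed shard, so the aggregated model's
accuracy swings between rounds — and the comparison is directional only:
the quality-aware strategy matches or beats FedAvg in a majority of seeds,
with visibly smoother weight and accuracy traces, but individual seeds can
go either way. (Centralized training of the same micro network on the same
data reaches ~99% test accuracy in 20 epochs, so the volatility is client
drift, not a defect of the backbone or optimizer.)

Problem sizes throughout the test suite (8x8 oracle inputs, n = 600
images, 20 rounds, 5 seeds, 10 bound configurations) are the package's
chosen desk-scale study conditions.

## Known limitations

* The weighting scheme's softmax over z-scored metrics produces
  high-contrast weights for small client counts regardless of how similar
  the clients are; the stored-parameter aggregation pool mitigates but
  does not remove this.
* Stability and confidence can *favor* heavily skewed clients at small
  scale (homogeneous shards optimize smoothly and are predicted
  confidently), which is one reason the desk-scale margin over FedAvg is
  thin.
* The convergence bound applies to full-batch gradient descent on strongly
  convex objectives; nothing is claimed for Adam on the nonconvex image
  model.
* The gamma coefficients are equal by default; the source procedure
  selects them by validation but does not publish values.
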