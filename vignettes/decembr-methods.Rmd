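---
title: "Joint embedding learning and t-mixture clustering: models, choices, limitations"
author: "decembr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint embedding learning and t-mixture clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(decembr)
```

## The problem

Predictive models of sensory neurons in the core–readout family factor each
neuron's stimulus–response function into a shared nonlinear feature space
(the *core*, mapping a stimulus to an H × W × K feature map) and a
per-neuron linear *readout*: a receptive-field position and a K-dimensional
weight vector $z_i$. The weight vector is the neuron's *functional
embedding* — a compact description of what the neuron computes. If discrete
functional cell types exist, embeddings should form clusters; in practice,
clusterings of embeddings from independently trained models agree poorly
across random seeds, which undermines any biological reading of the
clusters.

`decembr` implements a training-time remedy: an auxiliary clustering loss
on the embeddings whose cluster parameters are refined by
expectation–maximization (EM) of a Student's $t$-mixture model, jointly with
gradient training of the predictive model. The package also implements the
two diagnostic experiments that motivate the design — a linear-neuron toy
problem where the fixed-scale variant of deep embedding clustering provably
fails, and a planted-cluster Poisson population on which cross-seed
consistency can be measured against ground truth.

## The model

### Soft assignments and the sharpened target

Given embeddings $z_1,\dots,z_N \in \mathbb{R}^K$ and a $J$-component
$t$-mixture with centers $\mu_j$, diagonal scale matrices $\Sigma_j$ and
shared degrees of freedom $\nu$, the soft assignment of neuron $i$ to
cluster $j$ is

$$q_{ij} = \frac{f_t(z_i;\mu_j,\Sigma_j,\nu)}
                {\sum_{j'} f_t(z_i;\mu_{j'},\Sigma_{j'},\nu)},$$

with equal mixing weights $1/J$ (they cancel in the ratio). The target
distribution squares and frequency-normalizes Q:

$$p_{ij} = \frac{q_{ij}^2/f_j}{\sum_{j'} q_{ij'}^2/f_{j'}},
  \qquad f_j = \sum_i q_{ij},$$

which strengthens confident assignments and keeps large clusters from
dominating. The clustering loss is the displayed Kullback–Leibler sum

$$L_{cluster} = \sum_{i}\sum_{j} p_{ij}\log\frac{p_{ij}}{q_{ij}},$$

with P treated as a constant (recomputed from Q each batch, no gradient
through it — the self-training scheme; differentiating through the target
destabilizes it).

### EM updates of the cluster parameters

Cluster centers and scales receive no gradients. After each minibatch the
package performs one E-step and one M-step over **all** N embeddings, using
the shape-rate (gamma-mixture-of-Gaussians) representation of the
$t$-distribution: the latent scale $u_{ij} = (\nu + K)/(\nu + \delta_{ij})$
with Mahalanobis distance $\delta_{ij}$, then

$$\mu_j = \frac{\sum_i q_{ij} u_{ij} z_i}{\sum_i q_{ij} u_{ij}},\qquad
  \Sigma_j = \mathrm{diag}\frac{\sum_i q_{ij} u_{ij} (z_i-\mu_j)(z_i-\mu_j)^\top}
                               {\sum_i q_{ij}},$$

with the *updated* $\mu_j$ in the scale update (the standard $t$-mixture
M-step; the alternative with the previous center is not an ascent step).
With $\nu$ fixed and equal weights, one E/M cycle never decreases the
mixture log-likelihood; the suite asserts this over many random starts.

Every scale entry is clamped from below at `clampFloor` (default $10^{-6}$,
matching the variance regularization of the GMM baseline). The clamp is a
heuristic guard against ill-conditioned scale matrices in high dimensions,
not a principled prior; when it activates, the EM ascent guarantee no
longer applies.

### Degrees of freedom

$\nu$ is shared across clusters and fixed at 2.1 — just above the $\nu > 2$
threshold at which the component variance $\tfrac{\nu}{\nu-2}\Sigma_j$
exists. Heavy tails make the M-step robust to stragglers: distant points
get small $u_{ij}$ and barely move the center. There is no $\nu$ update;
the state class rejects $\nu \le 2$.

### The training loop

`pretrain()` first trains the predictive model alone (mean squared error
for the linear toy model; Poisson likelihood plus a small L2 penalty on
readout weights for the core–readout model). `initClusters()` then seeds
the mixture with k-means centroids (10 restarts, best inertia) and
within-cluster variances. `decemberFit()` interleaves, per minibatch:
E-step over all N, M-step over all N, then one Adam step on
$L = w_{model} L_{model}(\text{batch}) + \beta L_{cluster}$. The gradient
of the clustering loss with respect to an embedding has the closed form
$\sum_j (p_{ij}-q_{ij})\,u_{ij}\,\Sigma_j^{-1}(z_i-\mu_j)$, verified in the
suite against finite differences.

## Why the fixed-unit-scale variant collapses

With a unit-scale kernel ($\nu = 1$, $\Sigma = I$) and data whose
within-cluster spread is far below 1, the soft assignments are far from
one-hot: a unit kernel cannot express "this point belongs to the near
cluster with near-certainty" when the clusters themselves are only a few
scale units apart. The position update then mixes the groups: each center
moves to a q-weighted mean of *all* embeddings, and the centers contract
geometrically to the common weighted mean. Once coincident, every
$q_{ij} = 1/J$, the target is uniform too, the KL loss is exactly 0, and
every gradient vanishes — a degenerate optimum that absorbs the run.
Adapting the scales (the EM $\Sigma_j$ update) removes the failure: the
kernel tightens to the actual cluster width, assignments become crisp, and
the weighted means stay on their groups.

`decUnitScaleFit()` reproduces this ablation. Its default
`centerUpdate = "soft-mean"` is exactly the unit-scale position update
without scale adaptation described above, and on the toy data it collapses
within a handful of iterations while `decemberFit()` on identical data
separates the groups perfectly. The alternative
`centerUpdate = "gradient"` updates centers by SGD with momentum 0.9 (the
optimizer of the original deep-embedding-clustering method) on the KL loss
itself. That variant does *not* collapse on the toy geometry — the
frequency-normalized target suppresses cross-cluster responsibilities, so
the (p − q)-weighted pull on each center points *away* from the opposite
cluster — and we keep it available precisely because the contrast between
the two center-update rules isolates what the collapse does and does not
depend on. An adaptive-moment optimizer is deliberately not used for the
gradient variant: sign-normalized steps let the N embeddings move as fast
as the J centers and change the dynamics qualitatively.

## Choosing the clustering weight

`betaHeuristic()` returns $10^{\mathrm{round}(\log_{10}(|L_{model}|/L_{cluster}))}$
evaluated once at clustering start — the power of ten that puts
$\beta L_{cluster}$ on the same order of magnitude as the model loss. The
magnitude is used because the Poisson loss omits the constant
$\log r!$ term and can be negative. Treat the heuristic as the *upper
anchor* of the useful range: when the embeddings already carry tight
cluster structure at initialization, $L_{cluster}$ is very small, the
anchor lands where the clustering force erases functionally relevant
heterogeneity, and predictive performance drops. The package's consistency
experiment therefore runs at two orders below the anchor, which preserved
validation correlation (within 0.02 of the $\beta = 0$ model, per seed)
while still improving cross-seed consistency over the GMM baseline. On
diffuse real-data embeddings the anchor itself is typically usable.

## Synthetic data: what it emulates, and what it does not

Three generators, all pure functions of (spec, seed):

* `genToyLinear()` — the linear-neuron benchmark: 8000 stimuli uniform on
  $(-1,1)^{30}$; 2500 neurons, 2000 with weights $1 + U(-1/300, 1/300)$
  per coordinate and 500 with $1.5 + U(-1/120, 1/120)$; responses
  $y_i = z_i^\top x$, noise-free, exactly as the formula is written. The
  true center norms are $\sqrt{30} \approx 5.48$ and
  $\sqrt{30 \cdot 1.5^2} \approx 8.22$. No train/test split is prescribed
  for this benchmark; the package trains on all 8000 stimuli and monitors
  the final 10% (a toy-scale choice).
* `genPoissonPopulation()` — a planted-cluster core–readout population.
  Defaults (chosen once as a realistic desk-scale regime, and documented
  here because nothing upstream constrains them): 200 neurons, K = 8
  feature channels, 3 clusters with per-coordinate center separation of 8
  within-cluster standard deviations (spread 0.15), 1500 grayscale
  stimuli of 20 × 20 pixels, mean rate 5 spikes per trial. The stimuli
  are white noise smoothed by two passes of a 3 × 3 box filter —
  spatially correlated input drives convolutional features far more
  strongly than white noise, giving a per-neuron noise ceiling of about
  0.83 mean correlation; with raw white noise the ceiling is ~0.19 and no
  comparison is informative. Rates come from a *fixed, known* random core
  (kernels scaled by `coreGain = 4`), counts are Poisson.
* `genTMMSamples()` — exact draws from a t-mixture via the shape-rate
  form: $u \sim \Gamma(\nu/2, \nu/2)$, $z \sim N(\mu_j, \Sigma_j/u)$.

What passing tests on these data do **not** show: anything about calcium-
imaging noise, behavioral modulation, temporal dynamics, or whether real
cortical embeddings contain discrete types. The synthetic population
plants the very structure the method is designed to find; it validates the
machinery, not the biology.

One measured property of the heavy-tailed generator deserves emphasis: at
$\nu = 2.1$ and a center separation of 5 pooled scale units, about 6% of
draws land on the far side of the decision boundary. Even the
Bayes-optimal rule with the true parameters misassigns them
(label-recovery ARI ≈ 0.78); no fitting procedure can do better, and the
suite asserts the attainable property — agreement between the EM MAP rule
and the true-parameter MAP rule — alongside center recovery.

## Evaluation protocol

Cross-seed consistency is the mean pairwise Adjusted Rand Index between
MAP labelings of models trained with different seeds (data and clustering
seeds held fixed; only the model seed varies). The GMM baseline follows
the post-hoc protocol: diagonal covariances, a $10^{-6}$ variance floor,
fitted on the embeddings of the *converged* $\beta = 0$ model with a fixed
clustering seed. The k-means baseline is single-start by design so that
its sensitivity to initialization is visible rather than averaged away.
Predictive performance is the per-neuron Pearson correlation between
predicted and observed responses across held-out stimuli, averaged over
neurons; constant neurons are excluded with a warning rather than
zero-filled, so the metric is a mean over defined correlations.

`tsneEmbed()` is exact ($O(N^2)$) t-SNE for figures only: perplexity
N/100, an early-exaggeration phase (factor N/10, learning rate 1,
momentum 0.5) over the first 30% of iterations, then a standard phase at
learning rate N/12 with momentum 0.8. The two-phase schedule matters: at
learning rate 1 throughout, the layout never converges past the
exaggeration stage.

## Numerical choices

* All densities, responsibilities and mixture likelihoods are computed in
  log space with log-sum-exp; quadratic forms as per-dimension sums
  (diagonal scales throughout — full covariances are out of scope).
* The degenerate uniform optimum yields a clustering loss of 0 up to
  double rounding (~1e-15): Q is produced by `exp(log q)` and P by
  renormalized ratios, which differ in the last ulp.
* Ties in MAP assignment break toward the lowest cluster index.
* Clusters whose total responsibility falls below $10^{-8} N$ are
  re-initialized at the embedding with the lowest maximum responsibility,
  with a warning.
* One master seed fans out to independent named streams (`data`, `init`,
  `kmeans`, `batch-<epoch>`, `counts`, `tsne`) via a deterministic string
  hash, so consistency experiments vary only the model seed. Epoch-wise
  batch shuffling keys on the *global* epoch index, which makes a run
  continued at epoch m bit-identical to the tail of a longer run — this is
  what the $\beta = 0$ equivalence test checks.
* Optimizers: Adam (default rate 0.02 for the bundled experiments) for
  pretraining and the joint loop; plateau-halving of the learning rate and
  early stopping activate only when `patience > 0`. Divergence (non-finite
  loss) raises an error naming the epoch and learning rate.

## Problem sizes used by the bundled experiments

The toy protocol runs at its canonical size (8000 × 2500, 25 + 25 epochs,
batch 256). The consistency experiment uses the planted-population
defaults above with 3 model seeds, 15 pretraining epochs and 12 joint
epochs. These sizes are the package's chosen study conditions: large
enough that every qualitative contrast (collapse vs. recovery,
consistency vs. baseline, performance preservation) is exercised at full
strength, and small enough to be a desk-scale experiment rather than a
cluster job.

## Known limitations

* The number of clusters J is an input; no model-selection machinery is
  provided (sweep J and inspect consistency instead).
* Mixing weights are fixed at 1/J and $\nu$ is never updated — by design,
  for fidelity to the training scheme, not because these could not be
  estimated.
* The scale clamp is heuristic; with very high-dimensional embeddings and
  few neurons the scale matrices overfit before the clamp helps.
* The miniature two-layer convolutional core is a stand-in architecture:
  any core exposing an H × W × K feature space satisfies the interface,
  and none of the conclusions here depend on core internals.
* Behavioral covariates are accepted by the data container as extra
  stimulus channels but no bundled experiment models them.
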