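# decembr

Joint training of per-neuron functional embeddings and a Student's
*t*-mixture clustering of those embeddings.

## What problem this solves, and for whom

Core–readout models of sensory neurons learn, for every neuron, a
K-dimensional readout weight vector — its *functional embedding*.
Clustering those embeddings is the standard route to functional cell
types, but clusterings computed post hoc (GMM, k-means) on independently
trained models agree poorly across random seeds. `decembr` is for
computational neuroscientists who want a clustering *bias inside
training*: an auxiliary loss that makes the embedding space organize into
clusters while the model is being fit, with the cluster parameters
refined by EM rather than gradient descent.

## The method

Soft assignments of embeddings $z_i$ to clusters come from a multivariate
Student's *t*-mixture with per-cluster diagonal scale matrices and shared
degrees of freedom $\nu = 2.1$:

$$q_{ij} = \frac{f_t(z_i;\,\mu_j, \Sigma_j, \nu)}{\sum_{j'} f_t(z_i;\,\mu_{j'}, \Sigma_{j'}, \nu)},\qquad
p_{ij} = \frac{q_{ij}^2/f_j}{\sum_{j'} q_{ij'}^2/f_{j'}},\quad f_j = \textstyle\sum_i q_{ij}.$$

Training minimizes $L = L_{model} + \beta \sum_{ij} p_{ij}\log(p_{ij}/q_{ij})$,
where $L_{model}$ is the predictive loss (MSE for linear neurons, Poisson
for spike counts) and the target P is a constant recomputed each batch.
Crucially, $\mu_j$ and $\Sigma_j$ are **not** gradient parameters: every
minibatch runs one E-step and one closed-form M-step of the *t*-mixture
(via its gamma–Gaussian shape-rate form) over all N embeddings. Learning
the scales is what prevents the center-collapse failure of fixed-scale
deep embedding clustering: with a unit-scale kernel on tightly scaled
data, all centers contract to the global weighted mean, assignments
become uniform, and the KL loss sits at a degenerate zero.

The package includes the linear-neuron toy benchmark that demonstrates
both behaviors, a miniature convolutional core with Gaussian readouts and
Poisson likelihood, planted-cluster synthetic populations, and the
consistency-evaluation stack (Adjusted Rand Index, cross-seed consistency,
GMM/k-means baselines, Hungarian-style confusion alignment, t-SNE).

## Worked example

The toy benchmark: 2500 linear neurons whose weight vectors form two
tight groups (2000 neurons at 1.0 per coordinate, 500 at 1.5, in 30
dimensions), responses $y_i = z_i^\top x$. Pretrain a linear regression
for 25 epochs, then optimize only the clustering loss with EM-updated
centers and scales:

```r
library(decembr)
toy <- runToyDemo("december", seed = 1)
toy$summary
#>   cluster size centerNorm minInterCenterDist
#> 1       1 2000   5.477239           2.738751
#> 2       2  500   8.215989           2.738751
```

All 2000 + 500 neurons are assigned to their generating group, and the
learned center norms match the true values $\sqrt{30} \approx 5.4772$ and
$\sqrt{30\cdot 1.5^2} \approx 8.2158$ to within 0.002%. The same data
under the fixed-unit-scale ablation collapse instead:

```r
dec <- runToyDemo("dec-unit-scale", seed = 1)
dec$summary$minInterCenterDist[1]
#> [1] 0
table(mapLabels(dec$result))
#>    1
#> 2500
```

— the two centers become one point and every neuron lands in a single
cluster, which is exactly the failure mode the adaptive scales remove.

Lower-level entry points: `eStep()`, `mStep()`, `targetDistribution()`,
`clusteringLoss()`, `emFit()` for standalone mixture fitting;
`pretrain()` + `decemberFit()` for the joint loop; `genToyLinear()`,
`genPoissonPopulation()`, `genTMMSamples()` for data;
`adjustedRandIndex()`, `consistencyAcrossSeeds()`, `gmmBaseline()` for
evaluation. A thin command-line front end with subcommands
`simulate | pretrain | fit | toy-demo | evaluate | tsne` is installed at
`inst/scripts/decembr`.

See the methods vignette (`vignettes/decembr-methods.Rmd`) for the model,
the design decisions and the known limitations.

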