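---
title: "Probabilistic ancestry mapping with generative topographic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic ancestry mapping with generative topographic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtmap)
```

## The problem

Principal-component plots are the workhorse for visualising population
structure in genotype data, but a scatter of points in two PCs offers no
probabilistic statement about an individual's ancestry, and projecting a
new cohort onto someone else's PCA plot gives positions, not memberships.
`gtmap` addresses this with a two-stage mapping. The genotype matrix
$G$ (individuals $\times$ minor-allele counts) is first reduced to its
first $F$ principal components $X'$, and a **generative topographic map**
(GTM) is then fitted to $X'$: a regular 2D grid of $K$ latent nodes
$x_k$, mapped through a radial-basis-function network
$y_k = W\,\phi(x_k)$ into PC space, where each node image $y_k$ is the
centre of an isotropic Gaussian

$$p(g \mid x_k, W, \beta) = \left(\frac{\beta}{2\pi}\right)^{F/2}
  \exp\!\left(-\frac{\beta}{2}\lVert y_k - g\rVert^2\right),$$

with a single shared inverse variance $\beta$. The data density is the
uniform mixture over nodes, and $W$ and $\beta$ are optimised by
expectation–maximisation. The posterior node membership
("responsibility")

$$R_{kn} = \frac{p(g_n \mid x_k) \, p(x_k)}
               {\sum_{k'} p(g_n \mid x_{k'}) \, p(x_{k'})}$$

is the quantity everything else is built on: mean map positions
$x(g_n) = \sum_k x_k R_{kn}$ for visualisation, and the Bayesian ancestry
layer for classification. Unlike t-SNE, a fitted map is a generative
model: new individuals are placed by a single E-step with frozen
$(W, \beta)$, which is what makes held-out-cohort projection and
classification possible.

## The Bayesian ancestry layer

Given training responsibilities and ancestry labels $a$ with $N_a$
members each, every node receives a per-class likelihood and, via Bayes'
rule, a posterior:

$$P(x_k \mid a) = \frac{\sum_{n \in a} R_{kn}}{N_a}, \qquad
  P(a \mid x_k) = \frac{P(x_k \mid a)\,P(a)}
                       {\sum_{a'} P(x_k \mid a')\,P(a')}.$$

An individual's ancestry profile is the responsibility-weighted average
of node posteriors, $P(a \mid g_i) = \sum_k P(a \mid x_k) R_{ki}$, and a
whole population's profile replaces $R_{ki}$ by the population-averaged
responsibility $R_{kp} = \sum_{i \in \mathrm{pop}} R_{ki} / N_{pop}$.
Because node posteriors are row-normalised and responsibilities
column-normalised, profiles always sum to one — the test suite asserts
this as a law, not an approximation.

Population profiles for cohorts that were *not* used to build the map
should be read as a similarity measure against the training ancestries,
not as an absolute admixture decomposition in the STRUCTURE/ADMIXTURE
sense: a population falling between two training clusters will split its
probability between them even if its true history is more complicated.

### Empty nodes

A node whose likelihood is zero for every class — no training individual
gives it any responsibility mass, which happens through floating-point
underflow once clusters are tight and far apart — is flagged *empty* and
assigned the uniform posterior $1/A$. Projected individuals landing on
empty territory therefore get a defined, maximally uncertain profile
rather than an error or an arbitrary class. This is the only
regularisation in the ancestry layer; likelihoods are otherwise used
exactly as estimated, with no smoothing constant.

### Priors and ties

The class prior $P(a)$ is the empirical frequency $N_a/N$ by default,
with a uniform option (`prior_mode = "uniform"`). The empirical default
is the Bayes-consistent choice on the training sample; the uniform mode
is useful when training class sizes are artefacts of study design rather
than of the cohort one cares about. Argmax ties in predicted classes and
node colourings are broken by class order and reported via a message, so
runs are deterministic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_pcs` (F) | 10 | principal components retained before the map; dimension of the data space |
| `k_side` | 16 | nodes per grid side, $K = 256$ latent nodes on $[-1,1]^2$ |
| `m_side` | 4 | RBF centres per side, $M = 16$ Gaussians + bias |
| `width_factor` | 0.3 | RBF width $\sigma$ as a multiple of the centre spacing |
| `lambda` | 0.1 | ridge weight on $W$ in the M-step |
| `tol` | 1e-5 | relative log-likelihood change declaring convergence |
| `max_iter` | 200 | EM iteration cap |

The map defaults (16×16 grid, 4×4 RBFs, width factor 0.3, regularisation
0.1) are the standard configuration for ancestry-scale cohorts; maps of a
few hundred to a few thousand individuals fit in seconds. One
convention deserves a note: with `m_side = 1` there is no centre-to-centre
spacing to multiply, so the spacing is defined as 2 (the full latent
extent). A lone centred RBF sees all nodes of a symmetric grid at equal
distance and thus cannot spread them apart — useful for hand-checkable
toy instances, not for real maps.

## Numerical choices

* **Initialisation is deterministic.** $W$ is chosen by regularised least
  squares so the node images tile the plane of the first two principal
  axes of $X'$, scaled by the square roots of the leading eigenvalues;
  $\beta^{-1}$ starts at the larger of the third eigenvalue of
  $\mathrm{cov}(X')$ (when $F > 2$) and the squared half-distance between
  adjacent node images. Fits are therefore seed-free: two runs on the same
  scores give bit-identical models. Data of rank < 2 cannot spread a 2D
  map and are rejected.
* **E-step in log space.** Responsibilities and the log-likelihood go
  through log-sum-exp, and squared distances through the expanded-norm
  identity, so projecting points arbitrarily far from the map still
  yields normalised columns.
* **M-step.** $W$ solves
  $(\Phi^\top G \Phi + (\lambda/\beta) I)\,W = \Phi^\top R X$ with
  $G = \mathrm{diag}(\mathrm{rowSums}\,R)$; $\beta$ is then re-estimated
  from the *new* node images. With $\lambda > 0$ EM ascends the
  penalised likelihood; the recorded trace is the plain data
  log-likelihood, whose monotonicity (within $10^{-8}$) is checked across
  50 seeded datasets in the test suite. $\beta$ is capped at $10^{12}$
  with a warning to guard collapse onto duplicated points.
* **PCA.** Columns are centred and unit-variance scaled by default (the
  standardisation convention genotype PCA tools assume); zero-variance
  columns get scale 1 and contribute nothing. The solver is exact SVD and
  each loading's largest-magnitude entry is made positive, so maps are
  reproducible across platforms. Scaling is a flag (`scale = FALSE`) for
  users who prefer raw covariance PCA.
* **Serialisation.** Models are saved as JSON with doubles rendered as
  `%.17g` strings, so a reloaded model reproduces projections
  bit-for-bit; plain JSON numbers would silently lose the last digits.

## Evaluation protocol

Classification quality is measured by 10×-repeated stratified 5-fold
cross-validation. Per repetition, held-out predictions are concatenated
over the whole dataset, per-class F1 ($2PR/(P+R)$) is computed once, and
the overall score is the class-size-weighted mean of per-class F1 within
the repetition, averaged over repetitions. Three protocol details are
choices of this package rather than forced by the procedure, and are
recorded in output metadata:

* folds are **stratified by class** — with many classes of moderate size,
  unstratified folds can starve a class entirely;
* the reported dispersion is $1.96\,\mathrm{SD}/\sqrt{J}$ across the $J$
  repetitions, labelled a 95% interval;
* a class with neither predicted nor actual positives scores F1 = 0
  (conservative).

Repetition $j$ derives its fold assignment from `base_seed + j`, so any
`cv_result` is reproducible from its base seed. All model fitting — PCA,
GTM, the node-class map, k-NN — happens inside the training folds; the
suite includes a spy classifier asserting that fold means differ from
full-data means.

The k-NN baseline deliberately lives on the **2D** PCA plot: it models
what a human reads off a scatter plot, which is the comparison of
interest, not a general k-NN. Its two tie rules (all equidistant points
at the k-th radius vote; vote ties go to the tied class with the closest
member) make predictions independent of training-row order. The number
of neighbours is selected by cross-validated grid search over
$k = 1..10$; the selection stage runs at 3 repetitions and the selected
model is then scored with the full 10 — a cost/precision trade-off, since
the grid multiplies the CV cost tenfold. A linear SVM hook
(`linear_svm_hook()`, grid $C = 2^{-5}..2^{10}$) delegates to e1071 when
present and raises a typed capability error when not; nothing else
depends on it.

The principal-component sweep (`pc_sweep()`) re-runs the whole
cross-validated GTM pipeline per PC count and reports the F1 curve with
cumulative variance explained, which is how one chooses $F$ in practice:
performance typically rises steeply over the first few components and
plateaus once the informative axes of variation are in.

## What the simulator emulates — and what it does not

The generator produces structured genotypes under the Balding–Nichols
model: ancestral frequencies $p_d$ uniform on (0.05, 0.5) — matching the
post-pruning minor-allele-frequency floor of typical real pipelines —
population frequencies
$q_d \sim \mathrm{Beta}(p_d(1-F_{ST})/F_{ST},\,(1-p_d)(1-F_{ST})/F_{ST})$
with mean $p_d$ and variance $F_{ST}\,p_d(1-p_d)$, and genotypes
$\mathrm{Binomial}(2, q_d)$. Admixed populations use a fixed global
mixture of source frequencies per variant. Two presets define the
validation studies:

* **preset A** — 5 populations × 100 individuals, $F_{ST} = 0.1$,
  D = 1000 variants: continental-scale differentiation;
* **preset B** — 4 groups × 3 populations × 50 individuals,
  between-group $F_{ST} = 0.1$, within-group 0.01, D = 2000:
  fine structure nested in broad clusters, the regime where a 2D plot
  stops being enough.

These sizes keep a full repeated-CV study of either preset in the
low-minutes range on a single core while leaving the contrasts of
interest (broad recovery near-perfect; fine structure separating GTM
from the 2D baseline) far from threshold. Everything is driven by one
seed through a pinned Mersenne-Twister stream, so datasets are
bit-reproducible across platforms.

The simulator deliberately omits linkage disequilibrium (real pipelines
prune it away upstream anyway), local-ancestry tracts (admixture is
global, matching a genome-wide-ancestry focus), genotyping error and
missingness (a separate corruption helper adds missingness for I/O
tests), and coalescent-realistic site-frequency spectra. Passing the
recovery studies therefore demonstrates that the machinery — reduction,
map, Bayes layer, evaluation — behaves correctly on cleanly structured
data; it does not certify performance on any particular real cohort,
where cluster shapes are less Gaussian and differentiation less uniform
across populations.

## Degenerate inputs and edge behaviour

Constant genotype matrices are rejected by PCA (zero total variance), as
are rank-deficient score matrices by the GTM initialiser. All-missing
variants are an error unless training column means are supplied to
`impute_missing()` — the intended path for imputing a test cohort with
training statistics. Genotype values outside {0, 1, 2, NA} fail fast
with the offending sample and variant named. Classes smaller than the
fold count are a stratification error rather than a silent degenerate
split.

## Known limitations

* The EM fixed point depends on the deterministic initialisation; other
  GTM implementations with different (sometimes random) initialisations
  will reach slightly different maps on the same data.
* Responsibility matrices are dense $K \times N$; at $K = 256$ this is
  comfortable into the tens of thousands of individuals but not designed
  for biobank scale.
* The ancestry layer inherits the map's resolution: populations whose
  clusters genuinely overlap in the first $F$ PCs cannot be separated by
  any node colouring, a data limit rather than a model one.
* Population-profile probabilities are map-relative similarity scores;
  they should not be reported as admixture fractions.
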