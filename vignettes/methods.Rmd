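---
title: "Models and algorithms in spotdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and algorithms in spotdecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdecon)
```

spotdecon resolves multi-cell spatial transcriptomics (ST) spots to
single-cell resolution using an annotated single-cell reference. This
vignette is the package's own account of the models, the tunable parameters,
the numerical choices, and what the synthetic benchmarks do and do not show.

## The observation model for cell typing

A spot $i$ with $M_i$ segmented cells (the count comes from external image
segmentation and is supplied as data) and UMI total $N_i$ is modelled per
gene $g$ as

$$y_{i,g} \mid \lambda_{i,g} \sim \mathrm{Poisson}(N_i\,\lambda_{i,g}),
\qquad
\log \lambda_{i,g} = \alpha_i +
\log\!\Big(\tfrac{1}{M_i}\textstyle\sum_{m=1}^{M_i}\mu_{k_{i,m},g}\Big)
+ \gamma_g + \varepsilon_{i,g},$$

where $\mu_{k,g}$ is the relative expression of gene $g$ in type $k$
(reference cells are normalised to sum one before averaging, so
$\lambda$ is a composition and $\alpha_i$ absorbs depth), $\gamma_g \sim
N(0,\sigma_\gamma^2)$ is a gene-level platform effect between the
single-cell and ST technologies, $\alpha_i$ a spot-level effect and
$\varepsilon_{i,g} \sim N(0,\sigma_\varepsilon^2)$ residual noise.
`spot_log_likelihood()` marginalises $\varepsilon$ with 16-node
Gauss–Hermite quadrature (the $\sigma_\varepsilon = 0$ closed form is used
below $10^{-10}$, and the two paths agree to $10^{-6}$ at
$\sigma_\varepsilon = 10^{-8}$). Rates are floored at $10^{-12}$ so a gene
observed in a spot but absent from every candidate type keeps the
likelihood finite (a warning reports it).

Platform effects are estimated by a pseudo-bulk strategy
(`estimate_platform_effects()`): all spots are summed into one bulk vector,
overall type weights come from nonnegative least squares of the bulk
composition on the profile rows, and $\hat\gamma_g$ is the log-ratio of
observed to fitted bulk counts shrunk by
$\sigma_\gamma^2 / (\sigma_\gamma^2 + 1/\mathrm{fitted}_g)$ — the Poisson
sampling variance of a log count is approximately the reciprocal fitted
count. $\sigma_\gamma$ itself is a method-of-moments estimate from the raw
log-ratios, $\hat\alpha_i$ is the per-spot maximum-likelihood intercept and
$\hat\sigma_\varepsilon$ matches the excess variance of spot-level log
residuals beyond Poisson noise. The exact estimation procedure for
$\alpha_i$ and $\sigma_\varepsilon$ is a design decision of this package;
only the bulk approximation of $\gamma$ is prescribed by the model. On
simulations with $\gamma \sim N(0, 0.5^2)$, $G = 200$ genes and $I = 500$
spots the estimator recovers $\gamma$ with Pearson correlation above 0.9.

## Potts prior and pairwise iterated conditional modes

Labels get a Potts prior on the cell-level neighbour graph: energy
$U(\mathbf K) = \sum_{\text{neighbour pairs}} \nu\,[1 - \mathbb{1}(k = k')]$,
with pairs counted once. The graph (`build_neighbor_graph()`) connects all
cells within a spot, all cells of same-slice spots within `radius` of each
other, and optionally the nearest spot of each adjacent slice
(`z_link = TRUE`; slice alignment is assumed done upstream). The default
$\nu = 10$; larger values give smoother label fields, $\nu = 0$ removes the
spatial coupling entirely.

`icm_map_labels()` maximises the posterior by iterated conditional modes
with *pairwise* updates: spots are visited in seed-shuffled order and every
unordered within-spot label pair is jointly re-optimised over the $K^2$
candidates (single-label updates where $M_i = 1$). Initialisation is
independent per-spot maximum likelihood; restarts perturb it by
re-randomising 10% of cells, and the best-energy local optimum wins.
Descent is monotone by construction (each accepted move lowers the
objective; the per-sweep trace is returned). On instances small enough to
enumerate exhaustively, 5-restart ICM attains the global MAP in roughly
19/20 cases and is always pairwise-locally optimal. The per-candidate spot
intercept is refit in closed form by default (`refit_alpha = TRUE`), so
typing responds to a spot's composition rather than its depth.

For high-resolution platforms without images, `classify_spot_multiplicity()`
compares the best one-type spot likelihood with the best two-type
likelihood (at most two cell types per spot) and declares a doublet only
when the log-likelihood gain exceeds a threshold (default 2, about a
7:1 likelihood ratio); ties — including a duplicated profile — stay
singlets.

## Conditional score model

Expression of a type-$k$ cell is modelled in centered log space,
$x = \log(\text{count} + 1) - \mu_k$, with $\mu_k$ the per-type mean of
$\log1p$ counts. `train_score_model()` learns the multi-level denoising
score $s_\theta(x, \sigma_l, \mu_k) \approx \nabla_x \log p_{\sigma_l}(x
\mid k)$ over a geometric noise ladder $\sigma_1 < \dots < \sigma_L$ with
weights $\lambda_l = \sigma_l^2$, by minimising
$\sum_l \lambda_l\,E\|s_\theta(x + \sigma_l z, \sigma_l, \mu_k) + z/\sigma_l\|^2$.
The type enters as the full vector $\mu_k$, the same dimension as $x$, so
the conditioning cannot be ignored by the network.

Architecture (the contract is the score function; the backend is
swappable):

* a **$\sigma$-gated linear skip** $x \odot c(\sigma)$ whose gate is linear
  in rational features $\sigma_{0j}^2 / (\sigma_{0j}^2 + \sigma^2)$ over a
  fixed ladder $\sigma_{0j}$. These features plateau as $\sigma \to 0$ and
  decay as $\sigma^{-2}$, the exact asymptotics of Gaussian-convolution
  scores, so behaviour at the smallest levels is pinned by levels that
  carry training signal. For Gaussian data the skip alone is exact.
* a two-hidden-layer tanh perceptron on $[x, \mu_k, \text{features}]$
  (width `max(64, 4G)`) for non-Gaussian structure.

Training uses the noise-prediction parametrisation (the network output is
$\sigma s$ and the loss $\|\sigma s + z\|^2$ — the identical objective,
with equally-scaled gradients at every level), Adam with cosine
learning-rate decay, an exponential moving average of the weights
(decay 0.999, the standard stabilisation for score models), and a small L2
penalty ($10^{-4}$) on the perceptron weights only — the linear gate is
never penalised — which damps spurious wiggle outside the data range. The
penalty enters the gradient directly, so its effective strength grows with
the optimizer step count; with much larger references, grow the batch size
alongside the data (keeping steps per epoch roughly constant) rather than
the step count. Everything is
deterministic given `seed`. Desk-scale defaults are $L = 50$, $T = 5$,
2000 epochs; the full-scale preset is $L = 232$, $T = 5$ and 7500 epochs
(recommended range 5000–10000). $\sigma_{\max}$ defaults to the maximum
pairwise distance in a 500-cell subsample; $\sigma_{\min} = 0.01$.

On a 1-D Gaussian reference ($x \sim N(0, 0.5^2)$, 8192 cells) the learned
score matches the analytic convolution score $-x/(0.25 + \sigma_l^2)$ with
relative L2 error well under 0.1 on the probe grid $\{-2, \dots, 2\}$ at
the three smallest levels — the package's main check that the training
machinery is correct. `analytic_gaussian_score()` provides the exact
perturbed score of any Gaussian as an oracle backend.

## Annealed Langevin posterior sampling

Decomposition treats the corrected spot vector as a noisy sum of its cells:
$y_i \mid X_i \sim N(f(X_i), \sigma_y^2 I)$ with
$f = \sum_m (\exp(x_m + \mu_{k_m}) - 1)$, and samples
$p(X_i \mid y_i, \mathbf k_i)$ by annealed Langevin dynamics: from level
$L$ down to 1, $T$ steps of
$X \leftarrow X + \eta(\nabla \log p(y \mid X) + s_\theta) + \sqrt{2\eta}\,\epsilon$
with $\eta = \eta_0 \sigma_l^2 / \sigma_1^2$ and warm starts between
levels; the final states of $R$ independent runs (default 10) are averaged
into the posterior mean. Chains start at $X = 0$. Before sampling, the raw
spot counts are corrected in two steps (`correct_spot_expression()`):
divide gene $g$ by $\exp(\hat\gamma_g)$, then rescale the total to the
reference mean per-cell total times $M_i$.

Numerical choices, each of which mattered in validation:

* **Step size.** $\eta_0$ defaults to $\sigma_1^2$, i.e. the level-$l$ step
  is $\sigma_l^2$. On Gaussian oracles this yields means indistinguishable
  from the closed form and variances within a few percent
  (Kolmogorov–Smirnov p > 0.01 in 9/10 seeded runs at $n = 2000$,
  $L = 50$, $T = 5$); much smaller steps leave the chain frozen at the low
  levels and inflate variances substantially.
* **Drift clipping.** The deterministic move per step is clamped
  elementwise to $\pm 5\sigma_l$. The exponential link makes the
  likelihood gradient proportional to $\exp(x + \mu)$, which overshoots
  catastrophically at the large-step high-noise levels without a trust
  region. The cap is far beyond typical moves, and the linear-mode
  closed-form checks are unchanged by it.
* **Observation-noise schedules.** The per-level default is
  $\sigma_{yl} = \sqrt{\sigma_l}$. For validation against conjugate
  closed forms the package provides `sigma_y = "conjugate"`,
  $\sigma_{yl}^2 = \sigma_y^2 + M\sigma_l^2$, which for the linear test
  link ($f = \sum_m x_m$) makes every level's target *exactly* the
  Gaussian posterior of the perturbed variables — a fixed
  $\sigma_y$ at every level is only stable with much smaller steps.
* **Count view.** $\exp(\bar x + \mu) - 1$ is clipped below at 0 and
  $x + \mu$ above at 30 (with a warning) to keep the view finite.

With the linear link and Gaussian oracle scores the sampler reproduces the
conjugate posterior means (e.g. two unit-prior cells, $\sigma_y^2 = 1$,
$y = 2$ gives per-cell mean $2/3$) and the conditional-Gaussian imputation
mean $\rho v$ — the primary correctness gate for the whole engine.

`impute_cell()` uses the same chain with the masked likelihood
$y \mid x \sim N(I_{\text{mask}}(\exp(x + \mu_k) - 1), \sigma_\varepsilon^2 I)$:
an empty mask is prior sampling, a full mask denoising. The measurement
noise is inflated by the current perturbation
($\sigma_\varepsilon^2 + \sigma_l^2$, exact for the linear link) by
default.

`correct_dropout()` reuses decomposition on singlet/doublet-classified
spots. Its observation noise defaults to a **capture model**: gene $g$ is
detected with efficiency $\exp(\gamma_g)$, so after dividing by
$\exp(\hat\gamma_g)$ the corrected count carries binomial-thinning variance
of roughly $1 + f_g(\exp(-\hat\gamma_g) - 1)$, where $f_g$ is the
prior-mean reconstruction. Heavily dropped genes therefore get a weak
likelihood — the learned expression distribution fills them in — while
well-measured genes stay anchored to the data. With the per-level
$\sqrt{\sigma_l}$ noise instead, the sampler reproduces the thinned
observation and no restoration happens; this choice is the package's own
(the observation noise of the dropout-correction step is not prescribed by
the model).

## The synthetic-data generator

`simulate_reference()` draws a parametric stand-in for an annotated
scRNA-seq reference: negative-binomial counts per gene and type
(default dispersion 2, a realistic overdispersion for droplet data), a
Poisson mode as the dispersion-free limit, and a `gaussian_log` mode
(log1p-scale Gaussian, sd 0.3) that exists so the analytic Gaussian oracle
is the *true* prior of the generated data. Default type means put an
exclusive 10% marker block per type at 5-fold elevation over log-normal
baselines.

`simulate_spots()` mirrors benchmarking by gridding and aggregation: a
spatially coherent type field is drawn by 50 Gibbs sweeps of a Potts model
on the spot grid (4-neighbourhood, unit spacing; all cells of a spot share
its type), each spot draws 1–20 cells without replacement from the
reference pool of its type, per-spot counts are exact sums of the drawn
cells, and gene effects $\exp(\gamma_g)$ ($\gamma \sim N(0,
\texttt{gamma\_sd}^2)$) plus a log-normal per-spot depth factor
(sd 0.3 by default where enabled) are applied afterwards with rounding.
`downsample_counts()` adds binomial UMI thinning to emulate capture rates.

What the generator does *not* emulate: hexagonal spot geometry (adjacency
is configurable by radius but synthetic grids are square), gene–gene
correlation within a type beyond what the marker structure induces,
ambient RNA, segmentation errors in $M_i$, and mixed-type spots (the
shared-label-per-spot choice matches the smoothness assumption the typing
stage exploits). Passing benchmarks on these data therefore shows the
machinery is correct under the stated model, not that real tissues meet
the model.

## Benchmark design and problem sizes

The packaged checks (test suite and `scripts/acceptance.R`) use desk-scale
problem sizes chosen as the smallest sizes at which each quantity is a
stable measurement: the 1-D score fixture uses 8192 cells at batch size
512 (the learned score approaches the *empirical* score of the sample;
smaller references leave the sample-vs-population gap comparable to the
tolerance of the check);
end-to-end decomposition uses $K = 4$ types, $G = 64$ genes, 6×6 spots of
2 cells at about 500 UMI per spot, 600 training epochs, capture rates
{0.25, 0.5, 1}; the dropout study uses a 10×10 grid (coherence 1.0) so the
thinned marker's own type occupies enough spots for a meaningful spatial
correlation — on a 6×6 grid a coherent Potts draw can leave it 2 spots and
the correlation is noise; platform-effect recovery uses $G = 200$,
$I = 500$. The decomposition baseline is assigning every cell its type's
mean reference profile — the discretised-deconvolution strategy — computed
with the same estimated labels, so the comparison isolates the value of
the generative prior.

## Known limitations

* MAP labels only; no marginal posterior over labels, and $\nu$ is not
  estimated from data.
* Weakly identified directions (low-count genes, within-spot differences
  of same-type cells) keep inflated per-run spread because the annealed
  chain relaxes slowly where the step is small; posterior *means* over
  $R$ runs are the supported summary.
* The pseudo-bulk $\gamma$ estimator assumes the reference types span the
  tissue composition; a missing major type biases $\gamma$.
* Training at full scale (thousands of genes, $L = 232$, 7500 epochs) is
  CPU-feasible but slow in this implementation; the desk-scale defaults
  are tuned for laptop-class validation.
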