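# spotdecon

Sequencing-based spatial transcriptomics (Visium, Slide-seq) measures gene
expression in capture spots that each aggregate transcripts from several
cells, so cell-level biology — who expresses what, next to whom — is hidden
inside spot-level sums. spotdecon resolves spots to single-cell resolution
by integrating an annotated scRNA-seq reference, for analysts who have (1) a
spot × gene count matrix with coordinates, (2) per-spot cell counts from
nucleus segmentation, and (3) a labelled reference of the same tissue type.

The method has three statistical parts:

1. **Cell typing.** Spot counts follow a Poisson model
   `y_ig ~ Poisson(N_i λ_ig)`,
   `log λ_ig = α_i + log(mean_m μ_{k_im,g}) + γ_g + ε_ig`, where `μ_k` are
   reference type profiles and `γ_g`, `α_i` are gene- and spot-level
   platform effects estimated from a pseudo-bulk fit. A Potts prior
   `U(K) = Σ ν·[labels differ]` over the cell neighbour graph encourages
   spatially smooth labels; the MAP field is found by pairwise iterated
   conditional modes (`icm_map_labels()`, default `ν = 10`).
2. **Conditional score-based generative prior.** The distribution of
   per-type expression in centered log space (`log1p(count) − μ_k`) is
   learned by multi-level denoising score matching
   (`train_score_model()`): a network `s(x, σ_l, μ_k)` estimates the score
   of the σ_l-perturbed density across a geometric noise ladder, with the
   type conditioning supplied as the full mean vector `μ_k`.
3. **Posterior sampling.** Spot expression is decomposed into per-cell
   profiles by annealed Langevin dynamics on
   `p(X | y, k) ∝ N(y; Σ_m(exp(x_m+μ_km)−1), σ_y²I) Π_m p(x_m|k_m)`
   (`decompose_spots()`), averaged over R runs. The same sampler corrects
   dropouts in sparse data (`correct_dropout()`) and imputes unmeasured
   genes in imaging-based ST (`impute_cell()`).

A synthetic-data generator (`simulate_reference()`, `simulate_spots()`,
`downsample_counts()`) reproduces the benchmarking scheme of gridding and
aggregating annotated cells into spots with known platform effects and
capture rates, and `analytic_gaussian_score()` provides exact Gaussian
oracles so both samplers are validated against conjugate closed forms.

## Worked example

```r
library(spotdecon)

spec <- sim_spec(n_types = 3, n_genes = 60, cells_per_type = 300,
                 grid_shape = c(8, 8), cells_per_spot = c(1, 3),
                 label_coherence = 1.5, gamma_sd = 0.3, depth_sd = 0.2,
                 seed = 7)
ref <- simulate_reference(spec)
sim <- simulate_spots(ref, spec)

profile <- estimate_type_profiles(ref$counts, ref$labels)
effects <- estimate_platform_effects(sim$spots, profile)
cor(effects$gamma, sim$truth$gamma)
#> [1] 0.9483353

graph <- build_neighbor_graph(sim$spots, radius = 1.01)
field <- icm_map_labels(sim$spots, graph, profile, effects,
                        nu = 10, n_restarts = 2, seed = 1)
mean(field$labels != sim$truth$cell_type)   # single-cell typing error
#> [1] 0.03053435
```

The estimated gene-level platform effects track the simulated truth
(r = 0.95), and with the spatial prior the per-cell typing error is 3.1%
on this instance (10.7% with `nu = 0` — the smoothing is doing real work).
Decomposition then splits each spot among its labelled cells:

```r
cen <- center_log_expression(ref$counts, ref$labels, log_mean = profile$log_mean)
schedule <- make_noise_schedule(0.01, default_sigma_max(cen$x), L = 50, T = 5)
prior <- train_score_model(cen$x, cen$type_ids, cen$log_mean, schedule,
                           epochs = 600, seed = 1)
yc <- correct_spot_expression(sim$spots$counts, effects,
                              target_depth = profile$mean_total * sim$spots$cell_counts)
dec <- decompose_spots(yc, split(field$labels, field$nodes$spot),
                       prior, schedule, R = 10, seed = 2)
dim(dec$counts)    # one expression profile per cell
```

`dec$counts` holds count-scale per-cell profiles whose per-spot sums
reconstruct the corrected spot expression; on the packaged end-to-end
benchmark (K = 4, G = 64, 2 cells/spot, ~500 UMI) their mean cosine
similarity to the true held-out cells is about 0.83 versus 0.77 for
assigning type-mean profiles, improving monotonely with capture rate.

## Scope

Nucleus segmentation (cell counts per spot are an input table), slice
alignment, and downstream biology (ligand–receptor analysis, differential
expression) are out of scope. The vignette in `vignettes/methods.Rmd`
documents the models, parameter defaults, numerical safeguards and known
limitations.
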