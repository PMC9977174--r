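# spotlayer

Layer-aware cell-type deconvolution for spatial transcriptomics.

Sequencing-based spatial transcriptomics (ST) reports gene counts per
barcoded spot, each spot covering tens of cells of mixed types.
Expression differences between spots mix three causes — cell number,
cell composition, and genuinely spatial (layer-driven) expression
change — and analyses that ignore the first two misattribute them to
the third. `spotlayer` is for analysts with (i) a spot-level ST count
matrix with per-spot layer annotations (from pathology or an upstream
spatial clustering) and (ii) a single-cell reference with cell-type
labels. It estimates each spot's cell-type composition while
simultaneously estimating a per-layer expression shift for every gene,
then tests those shifts to call layer-wise differentially expressed
(LDE) genes that are not explained by composition.

## Model

Counts are negative binomial (NB) with size–probability
parameterisation, mean `r p/(1-p)`. The reference model for cell `c`,
gene `g` is

    X_cg ~ NB[ S_c * softplus(theta[g, z_c]),  P_g ],   P_g = sigmoid(o_g)

with library size `S_c` and cell type `z_c`; `(theta, o)` are fitted by
maximum likelihood (`fit_reference()`). Because NB variables sharing
`P_g` add their sizes, a spot `s` in layer `L_s` containing `n_sz`
cells of type `z` has

    X_sg ~ NB[ sum_z beta_g * softplus(theta[g,z] + T[L_s,g]) * n_sz,  P_g ]

where `T` is the layers-by-genes shift matrix (prior `N(0,1)`) and
`beta_g` a gene-wise platform factor. `fit_spatial()` estimates
`(n, T, beta)` by MAP with `(theta, P)` held fixed; proportions are
`v_sz = n_sz / sum_z n_sz`. The between-layer fold change of a gene is
the per-type ratio of `softplus(theta + T)` for the layer against the
mean of the other layers, maximised over types; significance comes
from a layer-label permutation test on `T` with Bonferroni correction
and an `|log2 FC| > 1` gate (`run_lde()`).

A simulator (`simulate_dataset()`) reproduces the package's reference
study conditions — 100 genes, 6 cell types, ~500 cells/type, two
layers (30% of cells in layer 2), 50 + 150 pseudo-spots of 10–16 cells
drawn with replacement — with full ground truth for validation.

## Worked example

```r
library(spotlayer)

cfg <- sim_config(seed = 1L)          # the default study conditions
sim <- simulate_dataset(cfg)

ref_model <- fit_reference(sim$reference)
fit <- fit_spatial(sim$spatial, ref_model)
v <- proportions(fit)

# deconvolution accuracy vs the known composition
rmse(v, sim$truth$v_star[rownames(v), colnames(v)])
#> [1] 0.06097144
sqrt(mean((1/6 - sim$truth$v_star)^2))   # uniform-proportion baseline
#> [1] 0.1078652

# layer-wise fold-change recovery
l2_hat  <- log2(fold_change(fit$theta, fit$T))["layer1", ]
l2_true <- true_log2fc(sim)[names(l2_hat)]
log2fc_correlation(l2_hat, l2_true)
#> [1] 0.9900921

# LDE calls (N reduced from the 10,000 default for the example)
res <- run_lde(sim$spatial, ref_model,
               lde_config(n_permutations = 200L, seed = 2L),
               fit = fit, control = fit_control(factr = 1e9))
res
#> lde_result: 100 genes x 2 layers; 10 LDE calls at alpha = 0.05 / 100 and |log2FC| > 1
```

The RMSE of 0.061 against the known spot compositions (uniform
baseline 0.108) says the fitted proportions recover roughly half the
baseline error; the correlation of 0.99 says the fitted layer shifts
reproduce the true per-gene log2 fold changes almost exactly. At
N = 200 permutations the Bonferroni threshold 0.05/100 is only
reachable by p-values of exactly 0, so just the strongest 10 shifts
are called; the default N = 10,000 resolves smaller p-values and calls
correspondingly more of the truly shifted genes.

Everything is also drivable from the shell via the installed launcher
(`simulate`, `fit-ref`, `deconvolve`, `lde`, `evaluate` subcommands):

```sh
SPOTLAYER=$(Rscript -e 'cat(system.file("scripts", "spotlayer.R", package = "spotlayer"))')
Rscript "$SPOTLAYER" simulate --seed 1 --out sim_out
Rscript "$SPOTLAYER" fit-ref --counts sim_out/reference.mtx \
    --cell-types sim_out/cell_types.csv --out ref_out
Rscript "$SPOTLAYER" deconvolve --counts sim_out/spatial.mtx \
    --layers sim_out/layers.csv --ref-model ref_out/ref_model.json --out dec_out
Rscript "$SPOTLAYER" evaluate --proportions dec_out/proportions.csv \
    --truth sim_out/truth_composition.csv --out eval_out
```

Each run writes a JSON manifest with the configuration, seed and file
digests.

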