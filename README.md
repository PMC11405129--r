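# mfdl — multimodal functional deep learning for multiomics phenotype prediction

`mfdl` predicts disease phenotypes from several omics modalities at once —
for example a genotyped region plus gene-expression levels — for
biostatisticians working at cohort scale (hundreds of samples, hundreds of
markers). Plain deep networks overfit badly in this regime, and linear
models miss interactions between omics layers. This package implements a
multimodal *functional* neural network that addresses both problems.

## The model

Each genotyped region is represented as an **omics variant function**, a
Dirac comb over marker positions rescaled to the unit interval:

    G_i(t) = Σ_j g_ij δ(t − t_j),   t_j ∈ [0, 1].

Every modality is modelled by its own functional subnet whose layers map
functions to functions through bivariate weight surfaces expanded in
predetermined B-spline bases,

    Z(1)(t) = σ( X α + ∫ G(s) β(1)(t, s) ds ),
    Z(d)(t) = σ( α0(t) + ∫ Z(d−1)(s) β(d)(t, s) ds ),

followed by a linear function-to-vector output layer. The subnet embeddings
are concatenated into a shared representation `Z_wide = [Z1 Z2 …]` and a
dense head maps it to the phenotype. Because the Dirac comb turns every
integral against a smooth function into an exact marker sum, genotypes are
never interpolated; the smoothness assumption lives entirely in the effect
functions, which is what makes the model robust to high-dimensional,
LD-structured inputs. Scalar modalities (single-gene expression,
biomarkers) take a degenerate dense path, and an all-dense model reduces
exactly to a standard feedforward network.

Training minimizes `J̃ = (1/n) Σ ‖y_i − ŷ_i‖² + (λ/2)‖W‖²` (biases
unpenalized) by full-batch ADADELTA with exact gradients of the
discretized objective; λ is chosen from {0.1, 0.3, 1, 3, 10} by
validation. Baselines with the identical loss stack: the closed-form
functional linear model (FLM), a plain dense network on concatenated raw
inputs (NN), and a single functional network on one concatenated
pseudo-axis (FNN-3HL). Metrics: MSE, MAE and the Robert–Escoufier RV
coefficient. A seeded simulation suite generates LD-structured genotypes
with a rare-skewed MAF spectrum, expression data, and phenotypes under
linear, interaction and nonlinear transformations.

## Worked example

Simulate the two-genotype interaction scenario (n = 200, noise variance
0.3), split 160/40, and compare the multimodal model with the functional
linear baseline:

```r
library(mfdl)

spec <- scenario_spec("interaction", "G-G", phenotype_dim = 1, noise_var = 0.3)
ds <- make_dataset(spec, seed = 2)
#> Simulated dataset: interaction relationship, G-G, n = 200, phenotype dim 1,
#> noise var 0.3 (seed 2)

idx   <- sort(sample.int(200, 160))         # training rows
train <- lapply(ds$modalities, subset_modality, idx = idx)
test  <- lapply(ds$modalities, subset_modality, idx = -idx)
y_tr  <- ds$y[idx, , drop = FALSE]; y_te <- ds$y[-idx, , drop = FALSE]

model <- build_mfdl(
  list(subnet_config("functional", n_hidden = 0, embedding_width = 8),
       subnet_config("functional", n_hidden = 0, embedding_width = 8)),
  head_config(hidden_widths = 16, output_dim = 1), seed = 1)
model
#> Multimodal functional DL model: 2 modalities (functional q=8, functional q=8),
#> shared width 16
#>   head: 16 -> 1; 515 trainable parameters

fit <- fit_mfdl(model, train, y_tr, lambda = 0.1,
                schedule = fit_schedule(max_epochs = 1000),
                normalize_inputs = TRUE, standardize_response = TRUE)
flm <- fit_flm(train, y_tr, lambda = 0.1)

rbind(MFDL = c(mse = mse(y_te, predict(fit$model, test)),
               rv  = rv_coefficient(y_te, predict(fit$model, test))),
      FLM  = c(mse = mse(y_te, predict(flm, test)),
               rv  = rv_coefficient(y_te, predict(flm, test))))
#>            mse        rv
#> MFDL  2.795649 0.9466272
#> FLM  10.138609 0.7178244
```

The phenotype here contains an inner-product interaction between the two
genotype effects. The FLM, which is additive by construction, cannot
represent it: its test MSE (10.1) is dominated by the unexplained
interaction variance. The multimodal network captures most of it
(MSE 2.8, RV 0.95 — RV is the multivariate generalization of squared
Pearson correlation, 1 = perfect).

Full studies — replicated scenarios with per-replicate λ selection,
median/IQR summaries and tidy CSV output — run through `run_study()`, or
from a shell via the thin CLI:

```sh
exec/mfdl study --outdir results/ --seed 1          # desk scale, 20 replicates
exec/mfdl simulate --relationship interaction --omics G-G --outdir simdata/
```

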