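# palnn — potentially associated loci from neural networks

`palnn` detects candidate trait-associated loci (**PAL**, potentially
associated loci) for binary phenotypes by training feedforward neural
networks on genome-wide SNP genotypes and reading loci off the trained
models with post hoc attribution. Where per-SNP logistic regression is
blind to non-additive genetics, a network sees the whole genotype vector
at once, so dominance, recessiveness and epistatic interactions can
contribute to detection. The package is aimed at statistical geneticists
who want a nonlinear companion to a conventional GWAS on case/control
array data, plus a simulation harness to benchmark it.

## The method in brief

Genotypes are coded symmetrically, `-1/0/1` for AA/AB/BB. A classifier

```
input-mask dropout -> affine(L -> h1) -> dropout -> ReLU
                   -> affine(h1 -> h2) -> dropout -> GELU
                   -> affine(h2 -> 1) -> sigmoid
```

is trained with binary cross-entropy and Adam (weight decay 1e-3), case
duplication + control halving for class balance, and fresh `N(0, 0.1²)`
noise on inputs and labels each batch. For each of `m` seeds, attribution
scores on case samples — saliency `SM_j = |∂f/∂x_j|`, integrated
gradients `IG_j = (x_j − x'_j)∫₀¹ ∂f(x'+α(x−x'))/∂x_j dα` (zero
baseline), or permutation importance `PM_j = |f(x) − f(x^(j))|` — are
L1-normalised per sample and averaged into a **mean attribution score**
(MAS) vector. With `A` the `m × L` MAS matrix:

- `μ_j = mean_a A_aj`, threshold `θ` = 99.99 (strict) or 99.95 (relaxed)
  percentile of `μ`;
- weights `w_j = (1/m) Σ_a 1(A_aj > θ)`;
- `AMAS_j = w_j · μ_j` for `μ_j > θ`;
- `PAL_AMAS = {j : AMAS_j > θ}`, `PAL_Common = {j : A_aj > θ ∀a}`;
- detections across seeds with `|r| > 0.5` are merged into common signals.

P-values come from a global null: MAS from permuted-label models are
pooled, a half-normal scale `σ̂ = sqrt(mean(x²))` is fitted (candidate
tail families compared by AIC/BIC), and null AMAS values are simulated by
rank-matching half-normal draws to the observed MAS rows — repeated 100
times — so each observed AMAS is ranked against `100 × L` nulls.

## Worked example

A zero-noise simulation with 20 causal SNPs among 1000, three model
seeds (runs in ~20 s on one CPU):

```r
library(palnn)

g  <- generate_genotypes(n_individuals = 1200, n_positions = 1000, seed = 21)
e  <- assign_effects(g, n_causal = 20, seed = 22)     # 5:5:4:6 effect classes
ps <- simulate_phenotypes(g, e, k = 0, seed = 23)     # k = noise scale
cfg <- mlp_config(input_size = 1000, epochs = 150, learning_rate = 3e-4,
                  n_val_cases = 30, n_val_controls = 30)
models <- train_ensemble(g, ps$y_binary, cfg, seeds = c(31, 32, 33))
mas    <- ensemble_mas(models, g, ps$y_binary, method = "ig", n_steps = 20)
report <- aggregate_mas(mas_matrix(mas), q = 99)
report
#> pal_report [IG]: L = 1000, m = 3 models, theta = 0.00211 (99.00 pct of mu)
#>   PAL_AMAS: 3 positions; PAL_Common: 3 positions

evaluate_detections(report$pal_amas, e, g)$metrics
#> $precision 0.667   $recall 0.1   $tp 2   $fp 1   $fn 18
```

Two of the three detected loci sit within ±100 kb of a planted causal
SNP (`tp = 2`), one does not (`fp = 1`); recall is low by design — the
strict-threshold regime trades recall for precision. P-values for the
detected positions:

```r
nulls <- train_ensemble(g, ps$y_binary, cfg, seeds = c(41, 42),
                        permute_labels = TRUE, permutation_seed = 5)
nullm <- fit_halfnormal(pool_null_mas(
  ensemble_mas(nulls, g, ps$y_binary, method = "ig", n_steps = 20)))
nullm
#> null_model: half-normal sigma = 0.001171 (pooled n = 2000)
pv <- estimate_pvalues(mas_matrix(mas), report, nullm, n_reps = 100, seed = 6)
pv
#> pvalue_set: 3 position(s), 100 reps, floor = 1e-05
#>   min p = 0.00241
```

The floor `1/(n_reps × L)` is the smallest attainable P-value; values at
the floor are reported as upper bounds. A per-SNP logistic-regression
baseline with PCA covariates is available via `logistic_gwas()`, and
`run_stage("all", config)` drives the whole pipeline from a JSON config
(presets for the six simulation scenarios ship in `inst/extdata/`).

Note on small panels: the percentile convention leaves
`floor(L × (1 − q/100))` candidates above θ, so the genome-wide strict
threshold (99.99) only produces non-empty PAL sets for `L ≥ 10⁴`; pick
`q` to match the candidate count you want at smaller `L` (as with
`q = 99` above). See the methods vignette for details.

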