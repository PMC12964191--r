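---
title: "Detecting potentially associated loci from neural-network attributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting potentially associated loci from neural-network attributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional GWAS tests one SNP at a time with a linear (logistic) model,
which is blind by construction to non-additive genetics: dominance,
recessiveness and epistatic interactions between loci. `palnn` implements
an alternative detection route: train a fully connected neural network to
classify case/control status from the whole genotype vector, then read
candidate loci off the trained model with post hoc attribution methods.
Because single networks are stochastic (initialisation, dropout, batch
order), detection is stabilised across an ensemble of seeds, and
significance is calibrated against networks trained on permuted labels.

## Model and pipeline

**Genotypes.** An individuals-by-positions matrix with entries in
\{-1, 0, 1\} (AA / AB / BB). The symmetric coding gives both alleles equal
magnitude under symmetric weight initialisation; it is the usual 0/1/2
alt-dosage minus one.

**Phenotype simulator.** For individual $i$,
$$Y_i = \sum_{j \in D} f^D_j(X_{ij}) + \sum_{j \in R} f^R_j(X_{ij})
  + \sum_{(j,k)} \beta_{jk} X_{ij} X_{ik}
  + \sum_{(j,k,l)} \beta_{jkl} X_{ij} X_{ik} X_{il} + \varepsilon_i,$$
where $f^D_j(x) = \beta_j x$ unless $x = -1$ (then 0), $f^R_j(x) = \beta_j x$
only when $x = 1$, all $\beta \sim N(0,1)$, and
$\varepsilon_i \sim N(0, k\sigma^2)$ with $\sigma^2$ the empirical
(population) variance of the genetic sum and $k$ a noise scaling factor.
Causal positions are drawn uniformly genome-wide and split 5:5:4:6 into
dominant, recessive, two-way and three-way members — e.g. (25, 25, 20, 30)
at 100 causal SNPs — so additive-ish and interactive classes are equally
sized. The continuous trait is binarised at the order statistic that yields
the target case count (default case fraction 0.1985, i.e. ~1814 cases per
9139 individuals).

**Classifier.** Input-masking dropout (probability `input_mask_p`) →
affine($L \to h_1$) → dropout → ReLU → affine($h_1 \to h_2$) → dropout →
GELU → affine($h_2 \to 1$) → sigmoid. Two named presets are shipped:
genome-wide $290522 \to 290 \to 29 \to 1$ (mask 0.99; 84,260,139
parameters) and small $20714 \to 82 \to 8 \to 1$ (mask 0.50). For other
input sizes the rule is $h_1 = \max(8, L/1000)$, $h_2 = \max(4, h_1/10)$.
Training uses binary cross-entropy and Adam with weight decay $10^{-3}$;
classes are balanced by duplicating cases and halving controls; fresh
$N(0, 0.1^2)$ noise is added to inputs and labels every batch (labels are
clipped back to $[0,1]$); the epoch count is fixed, with no early stopping
or best-epoch selection. The training loop is compiled (RcppArmadillo)
with its own seeded RNG stream, so a run is bit-reproducible from one
integer seed.

**Attribution.** Scores are computed on case samples with dropout off:
saliency $SM_j = |\partial f/\partial x_j|$; integrated gradients
$IG_j = (x_j - x'_j)\int_0^1 \partial f(x' + \alpha(x - x'))/\partial x_j\,
d\alpha$ (midpoint Riemann sum, default 50 steps, zero baseline — an
all-heterozygous genome under this coding); permutation importance
$PM_j = |f(x) - f(x^{(j)})|$, with the replacement value taken either from
another sample's coordinate $j$ (`permute-samples`, the default, which
preserves the feature's marginal) or from the same sample's value at a
random other position (`random-feature`, the literal reading of
"replaced by a random feature" — both are provided because the phrase is
ambiguous). Absolute scores are L1-normalised per sample and averaged over
case samples into the **mean attribution score (MAS)**; every MAS vector
sums to 1.

**Aggregation.** With $A$ the $m \times L$ MAS matrix over $m$ seeds,
$\mu_j = \frac1m\sum_a A_{aj}$, a single threshold $\theta$ is the
strict (99.99) or relaxed (99.95) percentile of $\mu$,
$w_j = \frac1m\sum_a \mathbf 1(A_{aj} > \theta)$,
$\mathrm{AMAS}_j = w_j\mu_j$ for $\mu_j > \theta$, and
$\mathrm{PAL}_{\mathrm{AMAS}} = \{j : \mathrm{AMAS}_j > \theta\}$,
$\mathrm{PAL}_{\mathrm{Common}} = \{j: \forall a\, A_{aj} > \theta\}$.
$\theta$ is taken from $\mu$ (not the pooled per-model values) because
that convention yields the reference counts of 29 / 145 candidate
SNPs at $L = 290522$;
the pooled alternative is available via `theta_from = "pooled"`. Positions
detected by different seeds are merged into common signals when their
absolute Pearson $r$ exceeds 0.5, using connected components —
transitive closure is the natural graph reading of an "in LD with"
relation when chains occur. Distance clumping (>100 kb gaps) turns
detections into blocks for evaluation.

**Significance.** MAS from permuted-label ensembles pool into a null whose
tail is compared across half-normal, generalized Pareto, gamma,
exponential, Weibull and lognormal families by AIC/BIC. The comparison
uses truncated likelihoods $f(x)/(1 - F(u))$ on the tail subset — without
the truncation adjustment, whole-axis families could not compete fairly
with the threshold-anchored GPD, and the generating family would not win
even on its own data. The half-normal scale is the MLE
$\hat\sigma = \sqrt{\overline{x^2}}$ on the full pool. P-values follow the
rank-matched resampling scheme: per repetition, draw $m$ half-normal
vectors, reorder each to match the rank order of the corresponding
observed MAS row (transferring LD- and architecture-induced dependence
onto the null), average, recompute $\theta$, weights and null AMAS at all
$L$ positions (zero where gated), pool all `n_reps` × $L$ values and count
exceedances. The denominator includes zeros: that is the only reading
under which the attainable floor reaches genome-wide-significance
territory ($\approx 3.4\times10^{-8}$ at $100 \times 290522$ pooled
values); the exact
floor $1/(n_\mathrm{reps} L)$ is reported, and floor-level values are
flagged as upper bounds.

**Baseline.** Per-SNP logistic regression (dosage + intercept + top-3
PCA covariates), Wald P-values, Bonferroni threshold $\alpha/L$ with all
attempted tests in the denominator; separation and non-convergence are
flagged per SNP rather than silently reported as zero.

## The synthetic-genotype generator

Real case/control SNP-array cohorts are access-restricted as a rule;
`palnn` therefore ships a generator so that every stage runs without a
download. Positions are grouped into blocks of
`block_size` SNPs; per block, a pool of founder haplotypes is drawn with
per-site allele frequencies uniform on `maf_range`, each individual
samples two founders per block with a 1% per-site mutation rate, and the
two haplotypes sum to the genotype. This produces a realistic MAF
spectrum, strong within-block LD and independent blocks — the features
the clumping and TP logic actually exercise. Defaults (5 kb spacing, so
±100 kb ≈ ±20 SNPs, matching array density; blocks of 10; pools of 8)
are fixed once and documented here.

What the generator does **not** emulate: population structure and
admixture, relatedness, genotyping error and batch effects, realistic
recombination-rate variation and LD decay beyond the hard block boundary.
A green end-to-end test therefore establishes that the machinery detects
planted nonlinear signals under idealised LD, not that it reproduces
biobank-scale behaviour.

## Numerical and design choices

* **σ² of the genetic effects** is the population (ddof = 0) variance over
  the cohort ("variance of the total genetic effects" does not pin the
  denominator; the population variance is the convention adopted).
* **Binarisation ties**: τ is the (n_cases + 1)-th largest value; exact
  ties at τ reduce the case count with a warning (measure-zero for
  continuous traits).
* **Percentile convention**: θ is the value ranked
  $\lfloor N(1 - q/100)\rfloor + 1$ from the top, leaving exactly
  $\lfloor N(1-q/100)\rfloor$ values strictly above — the convention that
  yields 29 (strict) and 145 (relaxed) at $N = 290522$. Consequence: for
  $L \le 10^4$ the strict threshold is the maximum of μ and
  $\mathrm{PAL}_{\mathrm{AMAS}}$ is empty *by construction* (no value is
  strictly above the maximum). The desk-scale acceptance study at
  $L = 5000$ is run faithfully under this convention and its strict-θ
  criterion is expected to fail; the relaxed threshold (2 candidate
  positions at $L = 5000$) is the smallest desk-scale setting where the
  full PAL → P-value chain is exercised end to end.
* **Learning rate**: the named presets keep lr = 1e-5 (tuned for 84M
  parameters and ~28k optimizer steps). The generic default is 1e-4,
  chosen during bring-up because desk-scale nets (8 ReLU units) trained at
  1e-3 frequently collapse into attribution-dead states — every case
  sample's gradient path dead — while 1e-4 left all scanned seeds alive.
* **Dead attribution rows**: a case sample whose first-layer
  pre-activations are negative along the whole IG path has identically
  zero attributions and cannot be L1-normalised. `compute_mas()` errors by
  default; the pipeline drops such samples with a warning
  (`on_zero = "drop"`). This is a small-width pathology that 290-unit
  networks do not exhibit.
* **Label noise** is clipped to [0, 1] after addition so cross-entropy
  stays defined.
* **Null models at desk scale**: 3 permuted-label models per study (vs 10
  at full scale) — the half-normal scale is a 1-parameter MLE on
  m_null × L pooled values, and 15,000 values estimate it to well under a
  percent; the reduction keeps the test suite inside its time budget.
* **Per-model label permutations** are independent by default;
  `shared_permutation = TRUE` shares one permutation across the ensemble.
* **MAS averaging** uses all case samples (not only training cases), the
  default reading of attribution "for the case samples".

## Known limitations

* The global half-normal null tests *relative extremity* of a position's
  AMAS against all positions, not each SNP against its own null; small
  but real effects below the global tail are undetectable by design.
* Rank-matched resampling transfers the observed dependence structure
  onto the null but cannot manufacture dependence the half-normal pool
  lacks; calibration is exact only under exchangeability (see the
  property test with template-correlated observations).
* Desk-scale networks are far narrower than the preset architectures, so
  quantitative precision/recall does not transfer to biobank scale; only
  the qualitative FP-control behaviour is mirrored.
* The logistic baseline omits Firth correction and mixed-model components;
  separation-flagged SNPs simply carry no P-value.
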