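---
title: "Models and methods in gpdeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gpdeep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gpdeep` compares linear multi-component genomic prediction against
nonlinear deep-learning regressors for a moderately heritable quantitative
trait (the motivating application is feed efficiency in purebred boar
lines), and estimates how much nonadditive genetic variance a black-box
predictor has captured. This vignette documents the models, the defaults,
the numerical choices, and what the simulation-based tests can and cannot
show.

## The data-generating model

The synthetic-data generator (`sim_config()`, `simulate_genotypes()`,
`simulate_phenotypes()`) emulates a boar testing population: SNP dosages
coded 0/1/2, a trait with narrow-sense heritability around 0.25, a small
dominance fraction and essentially no additive-by-additive epistasis, plus
pen, litter and birth-month/herd-year/parity/compartment environmental
structure and birth-year cohorts whose youngest animals form the prediction
holdout.

Genotypes come from a first-order Markov haplotype model: each haplotype
allele is copied from the adjacent previous marker with probability
`ld_decay` (default 0.5), otherwise drawn fresh at a frequency uniform on
`maf_range` (default 0.05–0.5). A single scalar controls linkage
disequilibrium; this is deliberately simpler than a recombination map but
suffices for relationship-matrix and network training behaviour. With
`ld_decay = 0` markers are independent and genotype classes are in
Hardy–Weinberg proportions.

The phenotype is a sum of components:

* additive: dosage × per-marker effects, effects i.i.d. normal — the
  equal-variance convention that matches the VanRaden method-1 additive
  relationship matrix;
* dominance: heterozygosity indicator × per-marker effects, with effect
  variance proportional to $1/(2p_k^2q_k^2)$. This standardized-effect
  convention makes the simulated dominance covariance exactly proportional
  to the sample dominance relationship matrix, so dominance-variance
  recovery by REML is well-posed even under linkage disequilibrium;
* epistasis: products of centered dosages over random marker pairs,
  matching the additive-by-additive construction of the epistatic kinship;
* pen and litter random effects, four small fixed factors, and a residual.

Components are empirically centered, sequentially orthogonalized and
rescaled, so the realized variance fractions equal the targets exactly and
component variances sum to the phenotypic variance. The orthogonalization
perturbs each component by an $O(n^{-1/2})$ projection; group effects stay
group-constant up to that same order. What this generator does **not**
emulate: realistic recombination maps and MAF spectra, genotyping error or
missingness, selection-induced allele-frequency change, and pedigree
structure. Tests passing on these simulations therefore demonstrate
correctness of the estimators under their own assumptions, not performance
on any real population.

## Quality control and pre-correction

`apply_qc()` retains markers with minor allele frequency strictly above
0.05, exact Hardy–Weinberg p-value at or above $10^{-25}$, and autosomal
location. The keep/drop directions are stated explicitly because threshold
prose is often ambiguous; both thresholds are arguments. The HWE test
(`hwe_exact_p()`) is a two-sided exact test on the heterozygote count given
the allele counts, summing the probabilities of all configurations no more
likely than the observed one; it is evaluated in log space because QC uses
thresholds as extreme as $10^{-25}$.

`precorrect()` fits, by REML (via lme4), fixed birth-month, herd-year,
parity and compartment effects with random pen and litter effects, and
returns the conditional residuals — phenotype minus fixed-effect fit minus
pen and litter BLUPs — as the pre-corrected phenotype, which `znormalize()`
then scales to mean 0, sample SD 1 (the $n-1$ denominator; stated because
conventions differ). Mixed-model normal equations make these residuals
exactly orthogonal to every fixed-effect column.

## Relationship matrices

`build_G()` implements VanRaden method 1 verbatim: centered-dosage
cross-products with the single global denominator $\sum_k 2p_kq_k$;
frequencies default to the analyzed sample, with an argument for external
(e.g. training-only) frequencies. `build_Eaa()` is the Hadamard square of G
divided by $v = \mathrm{tr}(G\odot G)/n$, so its trace is exactly $n$.

`build_D()` implements the heterozygosity-coded dominance matrix with
per-marker denominator $2p_k^2q_k^2$ and a $1/m$ average. A caveat matters
here: that formula's expected diagonal is $(1-2p_kq_k)/(p_kq_k)$ per
marker — about 2 at $p=0.5$ and much larger at low MAF — so variance
components fitted against the raw matrix are not on the phenotypic-variance
scale. `build_D(..., normalize = TRUE)` divides by trace$/n$, a scalar
reparameterization that leaves likelihoods and predictions unchanged while
making $\hat\sigma^2_d$ directly interpretable; the fitting pipeline uses
the normalized form, while the raw form is what the formula-level tests
check.

## Multi-component REML

`fit_reml()` estimates variance components for the A, AD, AE and ADE models
(additive, +dominance, +epistasis, +both) with an intercept as the only
fixed effect, since phenotypes are pre-corrected. Each iteration evaluates
the average-information update and an expectation-maximization update and,
for components the AI step pushes out of the feasible region, a
floor-clamped variant; the candidate with the highest restricted likelihood
is taken, with step-halving as a final numerical guard. This hybrid keeps
AI's quadratic convergence in the interior while handling boundary
estimates (a fitted component of essentially zero) in a single jump — the
behaviour one sees in standard GREML tools that report `0.000` with a
finite standard error. Components are floored at $10^{-6}\times$ var(y);
convergence is declared when the restricted log-likelihood changes by less
than $10^{-6}$ (at most 100 iterations); standard errors come from the
inverse AI matrix and ratio standard errors from the delta method.
`reml_loglik()` provides an independent dense evaluation of the restricted
likelihood used by the tests to confirm the optimum.

`predict_genetic_values()` computes BLUPs of each genetic component for
test animals from a training-only fit; the additive component is the EBV.
The tests verify it against a Henderson mixed-model-equation solve.

## Deep models

`build_model()`/`train_model()` implement the two architectures on the
package's own dense/convolutional training engine (plain R matrix algebra;
gradients are verified against finite differences in the test suite):

* MLP: dense stack over the m-length 0/1/2 input (default 96:64:32:16);
* CNN: one 1-D valid convolution over the marker axis (kernel 5),
  non-overlapping max pooling (window 3), flatten, then a 64:32:16 dense
  stack.

Hidden activations are leaky-ReLU (negative slope 0.3, configurable),
output linear, He-normal initialization, Adam (default learning rate
$10^{-5}$, batch 32), MSE loss with L1/L2 kernel penalties on all dense and
convolution kernels. The `"sire"`/`"dam"` presets bundle the two tuned
regularization columns (MLP 0.01/0.1 and 0.007/0.15; CNN with 16 or 8
filters and 0.005/0.1, 0.003/0.15). Where the architecture description is
silent the defaults are explicit config, not claims: max pooling rather
than average, penalties applied to kernels, epoch budget 500 with early
stopping patience 20 monitoring validation MSE and restoring the
best-validation weights. Genotypes enter raw, without standardization.
Training is bit-reproducible under a fixed seed in a single-threaded
session; with threaded BLAS the reproducibility is statistical rather than
bitwise.

## Validation design

`make_splits()` holds out the youngest birth-year cohorts as the test set
and partitions the remaining pool either by 10-fold cross-validation
repeated 5 times (50 splits; each pool animal validates exactly 5 times) or
by repeated 20% validation draws. Both modes exist because a repeated-k-fold
description and an 80/20 train/validation size table cannot both be literal;
reports name the mode used. `splits_average()` is the mean (and sample SD)
of per-split Pearson correlations with the test phenotypes;
`averaged_predictions()` first averages each test animal's predictions over
splits — a bagging-style ensemble — and computes one correlation.
Undefined per-split correlations (zero-variance predictions) are excluded
with a warning and counted. `se_of_r()` is
$\sqrt{(1-r^2)/(n_{test}-2)}$.

## VAE augmentation

`train_vae()` fits a Gaussian-latent variational autoencoder to the
training genotypes: a dense encoder to 16 latent means and log-variances,
reparameterized sampling, a mirrored decoder, and a loss of reconstruction
term plus a weighted KL divergence to the standard normal. Training
phenotypes are split into 10 equal-frequency bins (`bin_phenotypes()`;
quantile bins guarantee nonempty bins, and tied quantiles merge with a
warning). `generate_synthetic()` fits a diagonal Gaussian to each bin's
encoded means, samples 100 latent vectors per bin, decodes, and assigns
each synthetic animal its bin's edge-midpoint as phenotype; `augment()`
appends the synthetic rows to the training set only — validation and test
sets are never touched.

One design choice deviates from the obvious default. Mapping decoder
regression outputs to genotypes by rounding and clipping quantizes each
marker toward its modal class: in our checks the synthetic-vs-training
allele-frequency correlation plateaued around 0.77 no matter how long the
VAE trained. The package therefore defaults to a per-marker 3-class softmax
head trained by cross-entropy, with synthetic genotypes *sampled* from the
class probabilities, which preserves genotype frequencies (correlation
above 0.9 in the same checks); `output_map = "round"` remains available.
A single VAE is trained on all training genotypes with per-bin latent
sampling, rather than one VAE per bin — cheaper, and the binning mechanism
is ambiguous in the source description either way.

## Linearizing a black-box predictor

`build_probe()` constructs the $(m+1)\times m$ probe: a zero row stacked on
the identity. Feeding it to any trained predictor gives
$a_k = f(e_k) - f(\mathbf{0})$ — the per-marker additive effect measured as
the 0-to-1 (heterozygote) step, since probe codes are 0 and 1 by
construction. Interactions are invisible at single-marker probes, which is
the point: EBV $= Xa$ is the model's own linear approximation, EGV $= f(X)$
its full prediction, and

$$n^2 = 1 - \mathrm{corr}(\mathrm{EGV}, \mathrm{EBV})^2, \qquad
\sigma^2_{NA} = n^2 \,\hat\sigma^2_u,$$

with $\hat\sigma^2_u$ the sample variance (n−1 denominator) of the test-set
EGVs, quantify the fraction and amount of predicted genetic variance not
explained by that linear approximation. Across splits,
`pooled_summary()` averages EBV and EGV per test animal before recomputing
$n^2$ (per-animal averaging matches the reported avg-EBV/avg-EGV
correlations; concatenation is available by flag, since the pooling rule
is ambiguous). Note that $n^2$ from a finitely trained network mixes true
nonadditivity with training noise; averaging across splits suppresses the
noise part, which is why the package's contrast tests compare *pooled*
$n^2$ between traits with and without simulated nonadditive variance.

## Problem sizes and runtime choices

The default test and acceptance runs use desk-scale problems chosen to
preserve the phenomena while staying fast: REML recovery at n = 1000
animals and m = 2000 markers across 10 seeds (standard errors scale with
the design, so 2-SE recovery bands remain meaningful), deep-model contrasts
at n = 1000 and m = 200 with six-split pooling, and a smoke-scale
end-to-end study at n = 500, m = 300 with six splits for the determinism
check. Matrices are dense 64-bit; n up to ~10^4 fits workstation memory.
The learning rate used in the fast tests (2×10⁻³) is larger than the tuned
production default (10⁻⁵), which is appropriate for the much smaller
networks and sample sizes involved.

## Known limitations

* The LD model is first-order Markov; long-range LD and realistic MAF
  spectra are not simulated, so absolute predictive abilities here do not
  transfer to real data.
* The epistatic relationship matrix is second-order additive-by-additive
  only; dominance-by-dominance and higher orders are out of scope.
* $n^2$ cannot be decomposed into dominance versus epistasis components.
* The REML solver is dense; cluster-scale cohorts (say n > 2×10^4) would
  need out-of-core or sparse methods that are deliberately not included.
* Missing genotypes are rejected rather than imputed; upstream imputation
  is assumed throughout.
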