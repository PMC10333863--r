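---
title: "Transcriptional decomposition and co-activity analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional decomposition and co-activity analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactivity)
```

This vignette explains the statistical machinery in `coactivity`: the
decomposition model and how it is fitted, the rules for calling domains, the
QTL and variance-partitioning layers, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where more
than one reasonable option existed.

## The decomposition model

Binned RNA-seq counts carry two kinds of signal: a *positional* part shared
with the genomic neighborhood (broad chromatin environment, shared
enhancers, co-regulation — "co-activity"), and a gene-specific part
independent of position. For one individual and one chromosome segment of
$N$ bins, the observation model is

$$ y_i \sim \mathrm{NB}\!\left(\mu_i = s\, e^{\alpha + PD_i + PI_i},\ \theta\right), $$

with $s$ the library size in millions of reads (so $e^{\alpha+PD_i+PI_i}$
reads as reads-per-million per bin), $\theta$ the negative binomial
overdispersion, $PD$ a first-order random walk
($PD_i - PD_{i-1} \sim N(0, 1/\tau_{PD})$) and $PI_i \sim N(0, 1/\tau_{PI})$
iid. The random walk makes $PD$ smooth along the chromosome; $PI$ absorbs
bin-specific departures. Both precisions are **fixed**, not estimated: the
decomposition is only comparable across individuals if every fit uses the
same smoothness trade-off, and the split between $PD$ and $PI$ is governed
by the ratio $\tau_{PD}/\tau_{PI}$ rather than by the data alone.

### Parameterization of the precisions

The default values are quoted as $-5$ for the random walk and $-1$ for the
iid field. A precision cannot be negative, so these are interpreted as
**log-precisions**, $\tau_{PD} = e^{-5}$, $\tau_{PI} = e^{-1}$ — the
internal scale on which Gaussian Markov random field software parameterizes
precisions. `model_hyperparams(tau_scale = "raw")` supports the alternative
reading should anyone prefer to pass precisions directly.

### Identifiability

Adding a constant to $PD$ and subtracting it from $\alpha$ leaves the
likelihood unchanged, so a level constraint is needed. A telescoping
constraint on increments, $\sum_i (PD_i - PD_{i-1}) = 0$, collapses to
$PD_N = PD_1$ and does not fix the level; the package therefore uses the
standard sum-to-zero constraint $\sum_i PD_i = 0$ per segment, enforced
exactly at every Newton step through a KKT system. All tests assert
$|\overline{PD}| \le 10\,\mathrm{tol}$ per segment.

### Fitting: MAP with a Laplace approximation

Given fixed precisions and $\theta$, the log-posterior is strictly concave
on the constrained subspace (the NB log-likelihood is concave in the linear
predictor, and the penalties are quadratic), so the posterior mode is found
by Newton iterations with step-halving on the sparse Hessian — tridiagonal
for the $PD$ block, diagonal for $PI$, one dense row for $\alpha$. Posterior
variances are the diagonal of the constrained inverse Hessian at the mode
(Laplace approximation); `laplace_samples > 0` replaces the analytic
diagonal by the empirical variance of Gaussian draws at the mode, which is
useful as a cross-check. This is a deliberate simplification of a fully
Bayesian treatment: with all hyperparameters fixed the posterior is
log-concave and unimodal, and the Gaussian approximation at the mode is
accurate; the package's contract is the suite of recovery tests (latent
field correlation, oracle-optimizer equivalence, autocorrelation separation)
rather than agreement with any particular sampler.

$\theta$ is fixed by default (`theta_mode = "fixed"`). With weak latent
priors the latent fields can absorb bin-level noise, leaving $\theta$
essentially unidentified against the fitted means; `theta_mode =
"estimated"` therefore profiles $\theta$ by maximum likelihood against a
fixed-bandwidth (11-bin) moving-average mean, which tracks the smooth field
but averages out count noise. This recovers the scale of the simulated
overdispersion, and deliberately attributes iid positional variation to the
dispersion rather than to $PI$.

### Segmentation, QC and masked regions

Libraries whose number of empty bins lies more than two standard deviations
from the mean are excluded — two-sided, since "away from the mean" includes
suspiciously few empty bins (e.g. contamination). Bins overlapping
immunoglobulin heavy/kappa/lambda gene segments are masked: VDJ
recombination makes read mapping there unreliable; masked bins propagate as
missing values and are never imputed. Per chromosome, the two longest runs
of zero-coverage bins are removed and the remainder split into segments of
at most 7,500 bins, preferring a split at a zero-coverage bin within the
last 10% of a piece so segment boundaries fall in silent regions. Fits are
independent per individual and segment, so no batching of individuals is
needed; `summary()` reports the mean pairwise correlation of scores across
individuals as the comparability QC.

Degenerate inputs: an all-zero segment would push $\alpha \to -\infty$, so
the intercept is floored at $-30$ (on the log scale, $e^{-30}$ RPM is
indistinguishable from zero) with flat latents and a `degenerate` flag;
constant counts collapse exactly to $PD = PI = 0$ with $\alpha$ absorbing
the level.

## Domain calling

A bin is *marked* when the fraction of individuals with a strictly positive
co-activity score is at least `frac_individuals` (default 0.15). The
"15% of individuals positive for 10 consecutive bins" rule admits a second
reading — 15% of individuals each carrying a 10-bin positive run — but the
per-bin-fraction reading is the one consistent with reporting bin counts as
a function of the positivity cutoff, and it is what the package implements.
Maximal runs of ≥ `min_run_bins` marked bins are kept, runs gapped by
≤ 100 kb merged, and merged regions retained only if they contain at least
two genes expressed at ≥ 0.1 TPM. A gene is *contained* when its TSS lies in
the half-open interval — unambiguous for genes spanning boundaries.

Variable domains repeat the procedure inside co-activity domains with the
per-bin between-individual SD and a **strict** threshold (SD > 0.6; a bin at
exactly 0.6 is not marked), truncating runs at domain boundaries. The SD is
computed per bin, not on domain-averaged scores: the bin-level rule is what
lets sub-regions of a larger domain qualify. Background regions are maximal
runs outside co-activity domains with negative median score — the median
across individuals being the robust reading of "regions with negative
co-activity scores".

Matched non-variable domains: candidates are co-activity domains with
< 10% of their length overlapped by variable domains; each variable domain
is matched greedily, without replacement, to the candidate nearest in
Euclidean distance on z-standardized (mean score, log length, number of
expressed genes), ties broken by genomic order. Greedy nearest-neighbor was
chosen over optimal matching because it is reproducible, auditable, and
adequate when the candidate pool is several times the variable set — the
matched-set tests verify feature agreement within 10% on a rich pool.

## The QTL layer

Associations are ordinary least squares of the target (gene log expression,
or domain mean co-activity) on the SNP dosage plus covariates: by default
3 genotype PCs and 15 phenotype PCs computed internally on the centered
matrices. Only non-missing SNPs with MAF > 0.1 enter. The proportion of
variance explained is recovered from the t statistic,
$R^2 = \left(t/\sqrt{\mathrm{df} + t^2}\right)^2$ with
$\mathrm{df} = n - (\#\text{covariates} + 2)$ — the partial $R^2$ of the
dosage given the covariates, verified in the tests against explicit
reduced/full model refits to $10^{-10}$. Testing is cis-only with a 1-Mb
window around the TSS (genes) or midpoint (domains): the panel sizes this
package targets have no power in trans, and cis-windowed testing is the
field convention. eGenes are called at BH q < 0.05 within target kind (the
threshold is configurable; no single published convention exists).

Two structural caps protect small analyses: phenotype PCs never exceed a
quarter of the number of domain targets (PCs of a handful of domain scores
would absorb the signal itself), and p values are floored at the smallest
positive double rather than reported as zero.

LD pruning is greedy by significance: keep the most significant QTL, drop
all others with dosage correlation $|r| > 0.8$ to it, recurse on the
remainder. The quoted procedure alternates between "> 0.8" for removal and
"< 0.8" for the stopping state; strict remove-if-greater is implemented, and
the result is verified against a brute-force reference. Pruning is applied
within each domain because the QSS consumes per-domain QTL sets.

The **QSS** polarizes each QTL so its risk allele increases co-activity
(genotype $g' = 2 - g$ when $\beta < 0$, weight $|\beta|$) and averages
polarized genotypes weighted by effect size. It is a bounded [0, 2]
per-individual summary — 2 means homozygous for every risk allele.

## TF selection and variance partitioning

Per variable domain, a random-forest regression (package `ranger`, 500
trees, default mtry, impurity importance, single-threaded for determinism)
of the domain's per-individual mean co-activity on all TF expressions is run
under 5-fold cross-validation; importances are averaged over folds and the
top 10 taken; after 3 repeats the 10 most frequently occurring TFs are
selected (ties by mean importance). Frequency aggregation damps sensitivity
to RF hyperparameters, which is why tree count and depth are left at
package defaults and merely recorded. `top1` mode ranks each repeat's
candidates by univariate OLS $R^2$ and selects the most frequently
top-ranked TF.

The partition then fits one OLS model per domain with the selected TF
expressions as a single multi-column group, the QSS, and the domain's total
enhancer-interaction (ABC) count; optional groups are domain-mean histone
marks and a laboratory batch factor. Each group's **type-II sum of
squares** is the rise in residual sum of squares when the whole group is
dropped with all others retained — equal, as the tests verify, to the
quadratic form $\hat\beta_g^\top V_g^{-1} \hat\beta_g$ on the full-model
coefficients. Fractions are type-II SS over the total (corrected) SS of the
response, so they read as proportions of co-activity variance. For
correlated predictors type-II sums of squares do not add up to the explained
SS, so the reported residual fraction is defined as one minus the sum of the
group fractions — it absorbs the overlap between predictors, and reduces
exactly to RSS/TSS in the orthogonal case. Held-one-out significance is the
F test of the model without the group against the full model; for a single
predictor this is identically the overall F test, a nesting identity the
tests assert.

Domain mean co-activity is averaged over **all** bins of the (variable)
domain, not only its most variable bins — the variable-calling step has
already restricted the interval, and averaging everything inside it is the
simpler, less tunable choice.

## What the generator emulates — and what it does not

`simulate_dataset()` plants, with known ground truth: non-overlapping
domains (margin and inter-domain gap kept above the 100-kb merge distance);
a per-individual co-activity field built from random-walk increments plus a
constant activity shift inside every domain; individual-specific shifts in
*variable* domains driven by TF expression (trans) and local SNPs (cis);
iid positional effects; NB counts with log-uniform library sizes (the
offset term gets exercised); Hardy–Weinberg genotypes with optional
allele-copying LD inside domains; per-gene expression coupled to the
co-activity at the TSS, so genes in one variable domain share eQTLs;
histone signal positively coupled to co-activity inside domains; ABC
interaction counts elevated and individual-coupled in variable domains; and
annotation tracks (OCRs denser in domains, TF binding sites enriched in
variable domains proportionally to the TF's expression variability, TAD
boundaries near domain edges, chromatin modules covering variable domains,
non-overlapping compartment classes).

TF effects are additive on the log scale — linear in TF log-expression —
matching the linear models used downstream, which makes variance-partition
recovery analytically interpretable. Each regulating TF contributes exactly
`tf_trans_effect_sd` of co-activity SD with a random sign (the coefficient
is scaled by the TF's own expression SD). A Gaussian draw of the
coefficients was rejected: it makes the planted trans variance
chi-square-distributed, so a fraction of nominally "variable" domains would
carry almost no TF signal and the dataset would not represent the
TF-dominated regime it is meant to define.

Default conditions (50 individuals, 2 chromosomes × 1,000 bins of 10 kb, 16
domains half of them variable, 12 TFs with 3 regulators per variable
domain, 8 cis SNPs per domain with MAF in [0.1, 0.5] and allele-copying
r = 0.6, domain activity shift +3, `tau_pd_sim` $= 10^4$,
`tau_pi_sim` $= 16$, $\theta = 50$, library sizes 5–50 million) were chosen
once so that: domains are unambiguous against the random-walk wiggle;
non-variable domains stay clearly below the 0.6 SD threshold while variable
ones (planted SD $\approx \sqrt{3} \times 0.8 \approx 1.4$) clearly exceed
it; TF trans variance dominates cis variance about eight-fold, the regime
the variance-partition analysis is designed to detect; and counts are deep
enough (tens to thousands per bin) that the decomposition operates away
from the zero-inflated limit. The effect magnitudes are illustrative — no
published values exist for the TF-to-co-activity coupling.

What the generator does **not** emulate: raw reads, splicing and
allele-specific expression; population structure or relatedness beyond what
PC covariates would absorb; realistic LD beyond within-domain blocks; Hi-C
contact matrices; the empirical size and GC biases of real coverage; or the
scale of a real panel (hundreds of individuals, 300,000 bins). Passing
recovery tests on this testbed therefore demonstrates correctness of the
algorithms under the stated generative assumptions — not that real data
satisfy those assumptions. In particular, at 50 individuals the co-activity
QTL scan is underpowered (as it would be in a real panel of this size), so
runs at the default scale typically report few or no significant
co-activity QTLs; the QSS and partition layers handle empty QTL sets.

## Numerical choices and problem sizes

* Newton convergence: max-norm of the projected gradient below `tol`
  ($10^{-8}$); step-halving up to 30 times; non-convergence flags the fit
  and warns, never returns silently.
* The dense inverse needed for Laplace variances costs $O(N^3)$; for long
  segments `variances = "none"` skips it when only posterior means are
  needed (domain calling and all downstream stages use means only).
* Randomness: every stage derives its seed from the global one through
  integer-safe modular arithmetic, so stages are independently reproducible
  and a pipeline rerun is byte-identical; the random forest is run
  single-threaded with an explicit seed.
* Ties: LD pruning orders by p, then |t|, then SNP id; matching and TF
  selection break ties by genomic order and mean importance respectively.
* Test problem sizes: the recovery suite runs the full study-scale
  configuration (50 × 2,000 bins, about forty seconds of fitting); unit
  tests use 20 × 400-bin fixtures; the pipeline's default configuration is
  30 individuals × 500 bins so end-to-end determinism can be checked by
  running it twice. These sizes were chosen as the smallest at which every
  planted structure is comfortably detectable.

## Known limitations

* The Laplace variances are approximations; no claim of exactness relative
  to a full posterior is made, and hyperparameter uncertainty is ignored by
  design (fixed precisions).
* $\theta$ profiling is heuristic (moving-average reference); when the
  dispersion matters scientifically it should be fixed from external
  knowledge.
* Type-II fractions of correlated predictor groups are not a unique
  decomposition of variance; the residual-as-complement convention makes
  the parts sum to one but the overlap is not attributed.
* The sample odds ratio is reported with explicit conventions
  ($\infty$ on a zero denominator, optional Haldane correction); for tables
  with tiny cells the conditional MLE would differ.
* Interval semantics are 0-based half-open throughout; VCF and GTF
  coordinates are converted at the format boundary only.
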