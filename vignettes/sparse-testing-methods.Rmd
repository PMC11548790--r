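---
title: "Sparse testing in multi-environment trials: models, designs and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse testing in multi-environment trials: models, designs and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemet)
```

## The problem

A breeding program wants to rank candidate lines for a target population of
environments (TPE), but evaluating every line in every environment is
expensive. Under *sparse testing* each line is planted in only a subset of
the environments, and marker-based relationships between lines propagate
information across the gaps. This vignette documents the models and
algorithms the package uses, the choices made where several reasonable
options exist, and what the synthetic-data experiments do and do not
demonstrate.

## The phenotypic model

The response is the adjusted phenotype (BLUE) of line $j$ in environment
$i$:

$$y_{ij} = \mu + L_i + g_j + gL_{ij} + \epsilon_{ij}$$

* $L = (L_1,\dots,L_I)^\top \sim N(0, \sigma^2_E\,\Omega_E)$ — environment
  effects with an $I \times I$ covariance $\Omega_E$;
* $g = (g_1,\dots,g_J)^\top \sim N(0, \sigma^2_g\,G)$ — additive line
  effects with the genomic relationship matrix $G$ (the posterior means of
  $g_j$ are the GEBVs);
* $gL \sim N\!\big(0, \sigma^2_{gL}\,(Z_g G Z_g^\top) \circ
  (Z_E \Omega_E Z_E^\top)\big)$ — G×E effects under the Hadamard-product
  kernel ($\circ$ elementwise);
* $\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)$ i.i.d.

We index environments by $i$ and lines by $j$ throughout.
The model assumes one BLUE per line-environment cell (no within-trial plot
structure — computing BLUEs from raw plots is upstream of this package),
Gaussian residuals with homogeneous variance, and additivity of the marker
effects summarised by $G$.

### Sampling scheme

`fit_gblup()` runs a Gibbs sampler. Over the full $J \times I$ grid in
environment-major order the three kernels factor as Kronecker products
($Z_g G Z_g^\top = \mathbf{1}\mathbf{1}^\top \otimes G$, and the interaction
kernel is exactly $\Omega_E \otimes G$), so all effects are sampled in the
eigenbases of $G$ and $\Omega_E$: one eigendecomposition each, then $O(J^2 I
+ J I^2)$ work per iteration with fully independent coefficient updates.
Cells not present in the training data are *missing-data nodes*: each
iteration imputes them from the current model, which is a standard data
augmentation and leaves the posterior over parameters identical to the
observed-data posterior. A useful by-product is that the posterior mean of
$\mu + L_i + g_j + gL_{ij}$ at a held-out cell — the model's prediction — is
accumulated directly during sampling (`predict_cells()`).

Eigenvalues below $10^{-8}$ of the largest are dropped from each basis;
this removes numerically null directions (e.g. after PSD repair of
$\Omega_E$) without affecting the fit.

### Priors

All four variance components have scaled-inverse-chi-square priors with
`prior_df = 5` degrees of freedom. The prior scales partition the observed
phenotypic variance: a fraction `prior_scale_fraction` (default 0.5) is
split equally among the three non-residual terms and the remainder assigned
to the residual, with scales chosen so the prior mode sits at the assigned
share. This is a weakly-informative default in the style of common Bayesian
GBLUP software; with hundreds of cells the likelihood dominates. The grand
mean has a flat prior.

The first-stage multi-response model (`fit_multitrait_unstructured()`) puts
inverse-Wishart priors with 5 degrees of freedom and identity scale on both
the unstructured genetic covariance $\Omega$ (line structure $G$) and the
residual covariance $R$ (line structure $I_J$). Its update for the line
values uses a double diagonalisation of $(\Omega, R)$, so the per-iteration
cost is a pair of $I \times I$ eigendecompositions plus dense matrix
products — no per-line loop. Posterior means (not last samples) of
$\Omega$ and $R$ are returned.

### The six methods

`build_omega()` turns the first-stage output into the $\Omega_E$ of each
method: identity (GBLUP, GBLUP_TRN), the genetic covariance (GBLUP_CE), its
elementwise absolute value (GBLUP_CE_Abs), the average of genetic and
residual covariances (GBLUP_CE_mean), or the residual covariance
(GBLUP_CE_Res). The absolute value and the average are not guaranteed
positive semi-definite, so negative eigenvalues are clipped at zero, a
$10^{-8}$ jitter is added, and the clipped mass is recorded on the returned
matrix.

GBLUP_TRN deliberately does **not** predict held-out cells. It fits the same
model on the observed (training) cells and scores every held-out cell of
line $j$ with the across-TPE estimate $\hat\mu + \hat g_j$, constant across
environments. This is the only reading under which test-set correlations
are computable for a method described as "no prediction methodology";
rankings under this score equal GEBV rankings, which is the quantity a
breeder selects on.

Two-stage protocol: within every cross-validation partition the first stage
is refitted with that partition's test cells masked, so no information leaks
from test to training. Masks are regenerated per partition with fresh
derived seeds (`seed + i`); the alternative of one fixed mask reused across
partitions would measure the same quantity with more between-partition
correlation.

## Marker processing

QC removes markers in a fixed order: missing fraction strictly above 50%
first, then minor allele frequency strictly below 5% (computed on
non-missing genotypes). Both thresholds are configurable; strict
inequalities mean a marker at exactly the threshold survives. Missing
genotypes are imputed from the marginal distribution at each marker.
Because the data are diploid dosages, the default draws Binomial$(2, \hat
p_j)$, preserving the 0/1/2 coding; a literal Bernoulli$(\hat p_j)$ option
(`impute_model = "bernoulli"`) serves 0/1-coded presence/absence data.
The relationship matrix is VanRaden's
$G = WW^\top / (2\sum_j \hat p_j(1-\hat p_j))$ with column-centred dosages.
$G$ must be PSD up to numerical noise: eigenvalues in $(-10^{-8}, 0)$
trigger a $10^{-8}$ diagonal jitter, anything more negative is an error
rather than silently repaired.

## Allocation designs

Notation: $J$ lines (treatments), $I$ environments (blocks) of size $k$,
$r$ replicates per line, $N = Jr = Ik$ observations, concurrence
$\lambda_{jj'}$ = number of blocks where lines $j$ and $j'$ co-occur.

**Incomplete-block search.** `find_incomplete_block()` minimises the
pairwise-concurrence variance $\sum_{j<j'} (\lambda_{jj'} - \bar\lambda)^2$
by seeded swap descent: start from a random equireplicate fill, then
repeatedly exchange a pair of lines between two blocks when the exchange
reduces the objective (the change is computed in closed form from the
concurrence matrix, so each scan is vectorised). Balanced-design objectives
are full of flat local optima, so when no strictly improving swap exists the
search takes a random objective-*neutral* swap — a plateau walk — up to a
patience limit, and restarts from fresh random fills until either a design
attaining the integer lower bound of the objective is found or the restart
budget is exhausted. The objective is therefore monotone non-increasing
within a start, and the search reliably recovers classical balanced designs
(e.g. all pairwise concurrences equal to 1 for 7 lines in 7 blocks of 3)
while returning the best partially balanced design otherwise. Equireplication
requires $Ik \equiv 0 \pmod J$; other requests are rejected with advice to
adjust $k$.

**Constrained-random allocation.** `random_allocation()` fills blocks of
$k = \lceil Jr/I \rceil$ sequentially, sampling uniformly from lines
currently below $r$ replicates. When fewer than $k$ candidates remain, the
shortfall is taken from the least-replicated lines (ties by index), allowing
at most $r + 1$; the number of lines exceeding $r$ is recorded on the
design. This fallback is needed because the sequential scheme can paint
itself into a corner even when an exact design exists.

**Cross-validation partitions.** `cv_partitions()` splits the full grid so
that the training cells of each partition form a sparse allocation with
$k = \mathrm{round}(f J)$ training lines per environment at training
fraction $f$ (half rounded up, so an odd line count at $f = 0.5$ still
covers every line with two environments). Per-line training counts take the
two integers bracketing $fI$, balanced so all column sums stay equal; with
$I = 4$ and $f = 0.5$ every line trains in exactly two environments and is
tested in the other two. The IBD variant runs the swap-descent search with
those per-line quotas; the Random variant fills blocks randomly under the
same quotas (lines whose remaining quota equals the number of remaining
environments are forced in, which keeps the fill feasible). Every line is
guaranteed at least one training environment, or the request is rejected.

## Evaluation metrics

Per partition, COR and NRMSE are computed over test cells and PM_10/PM_20 at
line level, where a line's observed score is the mean of its test-cell
BLUEs and its predicted score the mean of its predicted test-cell values.
Choices the methodology leaves open, fixed here:

* **NRMSE normaliser** — the mean of the observed values (options: sd,
  range). Mean-normalisation is the standard convention for strictly
  positive yield traits.
* **Top set** — $\lceil f J\rceil$ lines, ties broken by input order, so the
  metric is deterministic.
* **PM reference ranking** — computed from test cells only, so the "true"
  ranking never sees training data.
* **Relative efficiency** — ratio of method means (not mean of ratios):
  $100\,\bar m_{TRN}/\bar m_{other}$ for COR and PM, inverted for NRMSE so
  that RE > 100 always reads "GBLUP_TRN better". The additive gain
  (RE − 100) is reported alongside.

Aggregation reports per-method/per-allocation means and standard deviations
across partitions (a single partition yields sd 0 with a degeneracy flag)
and unweighted across-dataset averages of dataset-level means.

## The synthetic generator

`simulate_markers()` draws independent markers in Hardy–Weinberg
proportions with allele frequencies uniform on a configurable range, plus
uniform missingness. `simulate_met()` draws one trial exactly from the
phenotypic model above — including the G×E term from the full-grid Kronecker
kernel via the eigendecompositions of $G$ and $\Omega_E$, exact rather than
approximate — and stores every latent truth (effects, variance components,
implied cell heritability $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_{gL} +
\sigma^2_\epsilon)$).

Defaults mirror a single-season wheat TPE dataset in shape: $J = 166$
lines, $I = 4$ environments, 2000 markers (enough for a well-conditioned
$G$ at this $J$; the fidelity of $G$ saturates long before the ~18k markers
of a full GBS panel), grand mean 6 (a typical grain yield, t/ha), variances
$\sigma^2_E = \sigma^2_g = 1$, $\sigma^2_{gL} = \sigma^2_\epsilon = 0.5$
($h^2 = 0.5$), and compound-symmetric environment correlation 0.5.

What the generator does *not* emulate: linkage disequilibrium and marker
redundancy, population structure and family stratification, selection over
breeding cycles, non-Gaussian residuals, and heterogeneous per-environment
error variances. Passing recovery tests on these data therefore shows the
machinery is correct and well calibrated *under the model's own
assumptions*; it does not certify performance on structured real
populations, where $G$ is informative in ways (and misspecified in ways)
the simulation cannot represent.

## Problem sizes and runtime choices

The test-suite experiments use desk-scale sizes chosen so the full suite
runs in minutes while keeping estimation honest: oracle comparisons at
$J = 50$, $I = 3$ with 5000 iterations; variance-component recovery on ten
replicates at $J = 200$, $I = 4$ with 1500 iterations; genetic-correlation
recovery at $J = 300$, two environments, 4000 iterations; and the full
six-method × two-allocation comparison at the default scenario with two
partitions and 3000 iterations. Production analyses should use the default
`mcmc_config()` (20000 iterations, 10000 burn-in) and 10 partitions.

## Known limitations

* Single trait, Gaussian likelihood; no marker-effect (Bayes A/B/Cπ)
  alternatives.
* Homogeneous residual variance across environments in the second stage
  (the first stage does estimate an unstructured residual covariance).
* The incomplete-block search is a heuristic: for parameter sets where a
  balanced design exists but is combinatorially rare, it may return a
  partially balanced design; the achieved concurrence variance is always
  reported.
* Years/datasets are modelled independently; there is no borrowing of
  strength across seasons.
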