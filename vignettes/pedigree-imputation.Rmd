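---
title: "Pedigree-based mixed-model genotype imputation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based mixed-model genotype imputation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmimpute)
```

## The problem

Genotyping platforms for plant breeding panels leave missing calls, and the
way those gaps are filled changes every downstream analysis: genomic
relationship matrices, heritability estimates, and genome-wide prediction.
`mmimpute` implements a pedigree-based imputer for structured populations —
nested association mapping (NAM) panels of recombinant inbred lines (RILs)
in particular — together with the non-parametric baselines and the
evaluation machinery needed to compare imputation methods on equal footing.

The central idea: if marker alleles are transmitted in Mendelian fashion,
the 0/1/2 *gene content* of a marker behaves like a perfectly heritable
quantitative trait whose covariance among individuals is the additive
numerator relationship matrix $A$. Missing calls can then be predicted as
empirical-Bayes (BLUP) estimates from a mixed model, and the pedigree
heritability of a marker's gene content doubles as a quality filter:
markers whose transmission stops following the pedigree are likely
miscall-ridden.

## The multivariate mixed model

For a focal marker $j$ with flanking markers $i$ and $k$ on the map, the
imputer fits the trivariate response block
$\mathbf{Y} = \{\mathbf{y}_i, \mathbf{y}_j, \mathbf{y}_k\}$ (gene content
on a continuous scale) to

$$\mathbf{Y} = \mathbf{1}\boldsymbol{\mu} + \mathbf{Z}\boldsymbol{\gamma}
  + \boldsymbol{\varepsilon}, \qquad
  \operatorname{Var}(\mathbf{Y}) = \mathbf{A}\otimes\Sigma_\gamma
  + \mathbf{I}\otimes\Sigma_\varepsilon,$$

where $\Sigma_\gamma$ is the full $3\times 3$ genetic covariance of the
window (its off-diagonals carry the linkage disequilibrium between the
focal marker and its flanks) and $\Sigma_\varepsilon$ is *diagonal* — no
residual covariance between markers. The diagonal residual block is a
deliberate model commitment, kept even though same-individual residuals of
adjacent markers could plausibly correlate: all cross-marker information is
routed through the genetic part, where the kernel can distribute it along
the pedigree. Variance components are estimated per window by restricted
maximum likelihood (REML), missing entries of $\mathbf{y}_j$ are replaced
by $\hat\mu_j + \hat\gamma_j$, and the window slides one position.

Choices the model description leaves open, fixed here:

* **Edge markers** use a bivariate window with their single neighbour; a
  single-marker chromosome falls back to the univariate pedigree model.
* **Windows never consume imputed values.** Every window is fitted on the
  original observed calls, which prevents imputation errors from
  propagating along a chromosome.
* **Missing responses are omitted records**, not data-augmented: the exact
  restricted likelihood of the observed pattern is maximised, and the
  missing individuals' effects are still predicted through $A$.
* **Rounding**: dosages are clipped to $[0,2]$ and binned at 0.5 and 1.5,
  boundaries going to the heterozygote side; the continuous dosage is kept
  alongside the ordinal call for downstream kernels.
* **Fallbacks**: a window whose REML fit fails produces family-mean
  imputation for that marker (recorded in the diagnostics); a window with
  no usable variation returns the observed column mean.

## REML: EM warm-up, average-information steps, boundaries

Both engines (the multitrait window engine and the univariate multi-kernel
engine used for heritability) maximise the restricted likelihood through
Henderson's mixed-model equations: a few expectation-maximisation
iterations (guaranteed ascent) followed by average-information (AI) Newton
steps with exact analytic scores, falling back to EM — after trying half
and quarter AI steps — whenever a proposal would lower the likelihood or
leave the parameter space. $\Sigma_\gamma$ is projected onto the positive
semidefinite cone when an update leaves it; residual variances are floored
at a tiny positive multiple of the trait variance. Convergence is declared
when the relative norm of the parameter change drops below `tol`
(default `1e-8` for sliding windows; `1e-11` where strict
variance-component estimates are the goal, as in heritability
estimation).

Inbred panels routinely push window fits onto the boundary of the
parameter space: two flanking RIL markers a few centimorgan apart are
almost perfectly correlated, so the REML optimum has a singular
$\Sigma_\gamma$. On the boundary EM crawls along a likelihood ridge where
the parameters still drift but predictions no longer change; the engines
therefore also stop once the likelihood has been stationary (relative
change below `100 * tol`) for three consecutive iterations, and the window
imputer caps iterations at 30 by default. Measured on simulated panels,
imputation accuracy is unchanged between caps of 15 and 100.

A kernel equal to the identity makes $\sigma^2_\gamma$ and
$\sigma^2_\varepsilon$ jointly unidentifiable (the fit is flagged, not
errored). Fits that touch a boundary carry `boundary = TRUE`.

## Marker quality control

`minor_allele_frequency()` uses complete cases only. `marker_heritability()`
fits the univariate pedigree model to each marker's gene content and
returns $\sigma^2_\gamma / (\sigma^2_\gamma + \sigma^2_\varepsilon)$;
`filter_markers()` removes non-segregating markers, markers below the MAF
threshold (default 0.05) and markers below the gene-content heritability
threshold (default 0.99), reporting each removal with its reason. The
filter keeps high-heritability markers: reliable gene content follows the
pedigree, so a low value signals genotyping error.

One honest caveat for *selfed* panels at desk scale. The $A$-matrix
convention treats founders as non-inbred members of a base population,
while NAM founders are fully homozygous lines. Under that mismatch the
realised single-locus covariances deviate slightly from $A$ (e.g. RIL sibs
0.50 against the implied 0.516), and — more importantly — the variance
split between $\sigma^2_\gamma$ and $\sigma^2_\varepsilon$ is informed
only by covariances, so a single marker's estimated heritability at a few
hundred individuals has substantial sampling spread. Error-free markers
sit at the boundary $\hat h^2 = 1$ in the median but individual markers
can fall well below; the 0.99 default is calibrated to panels of thousands
of lines, and on small simulated panels a softer threshold separates
miscall-ridden from clean markers just as clearly. The package's tests
verify the $\hat h^2 \to 1$ behaviour on a non-inbred Mendelian
gene-dropping process, for which the $A$ model is exact.

## Baseline imputers

* **kNN** (`impute_knn()`, default $k = 10$): per-marker z-scored calls,
  pairwise-complete root-mean-square distance between individuals (the
  scaling by shared-marker count keeps distances comparable under
  missingness), inverse-distance-weighted mean of the $k$ nearest donors
  observed at the marker, with a `1e-6` floor so duplicate individuals do
  not divide by zero.
* **SVD** (`impute_svd()`): per chromosome, mean-initialised iterative
  truncated-SVD completion ($M = UDV^\top$), replacing only missing cells
  each pass until the largest change is below `1e-8`. `rank = "auto"`
  selects the rank by Owen–Perry bi-cross-validation with deterministic
  interleaved $2\times 2$ blocks, choosing the smallest rank within
  numerical reach of the minimal held-out error.
* **Mode** (`impute_mode()`): the degenerate baseline; column or
  family-segment modal call, ties to the lower call.
* **External tools** (`impute_external()`): an adapter that writes the
  panel, substitutes `{input}`/`{output}` into a command template, and
  parses the result. Hidden-Markov-model imputers and random-forest
  imputation are deliberately not reimplemented — they are reachable only
  through this adapter, and an absent executable yields a skip status
  rather than a failure.

## Evaluation framework

`imputation_accuracy()` is the share of masked cells whose rounded call is
identical to the standard. `vanraden_g()` builds the genomic relationship
$WW^\top / 2\sum p(1-p)$ with columns centred by $2\hat p$, allele
frequencies taken from each imputed panel itself (that is how a completed
panel would be used in practice). `estimate_heritability()` fits
$y = \mu + \text{environment} + (\text{controls}) + \text{additive} +
\varepsilon$ with the additive effect structured by $A$ or $G$ and reports
the intra-class correlation
$h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_E + \sigma^2_C +
\sigma^2_\varepsilon)$, the narrow-sense heritability used as the measure
of genetic variation a panel captures; the controls term is included only
when a `control` column is present. `prediction_accuracy_cv()` implements
five-fold ridge-type GBLUP: fold assignment is seeded; the held-out
individuals' genetic values are predicted through the kernel; observed
phenotypes are adjusted by subtracting the training model's environment
effects and averaging per individual; accuracy is the correlation divided
by $\sqrt{\hat h^2}$ from the training fit, guarded below $\hat h^2 =
0.01$. One shrinkage model is enough here because whole-genome regression
variants behave nearly identically for this purpose; richer Bayesian
alphabets are out of scope. `compare_methods()` wires everything into a
tidy method-by-rate quality report with an `autoplot()` method.

## The NAM simulator

`simulate_nam()` generates the study conditions every other module is
tested under: one common parent crossed to `n_families` founders, one F1
per cross, RILs advanced by single-seed descent for `selfing_generations`
rounds (default 4, so F5 lines with expected inbreeding
$1 - (1/2)^4 = 93.75\%$), equally spaced markers on a genetic map with
Poisson crossovers and no interference (Haldane model), an additive trait
from a marker-QTL subset with noise solved so the single-record
heritability hits its target (default 0.4; environment share 0.2 over 4
environments), and optional MCAR masking (`inject_missing()`, exact cell
counts, seeded) and uniform miscall injection
(`inject_genotyping_errors()`).

The pedigree records one F1 per cross and each RIL as a selfing chain off
that shared F1, which reproduces the textbook F5 diagonal
$1 + F = 1.9375$ while keeping pedigree files small; selfing chains are
expanded into virtual per-generation individuals internally so the tabular
method applies unchanged.

Two founder regimes matter. The default `founder_poly_rate = 1` makes
every marker segregate in every cross — the idealisation under which the
expected panel-wide heterozygosity of F5 lines is exactly $(1/2)^4 =
6.25\%$ — but it also makes all founders carry identical genotypes, so
between-family gene-content signal vanishes and marker-heritability QC has
nothing to work with. At `founder_poly_rate = 0.5` founders are drawn
independently, between-family variance appears, and the gene-content
filter behaves as intended, while panel-wide heterozygosity drops to
$6.25\% \times$ (segregation rate). Real panels sit between the two: the
simulator does not emulate markers segregating in a *correlated* subset of
families, ascertainment of chip markers, residual-heterozygosity hotspots,
crossover interference, or selection during inbreeding — passing tests on
these synthetic panels shows the machinery is correct under the stated
genetic model, not that real-data accuracies will match.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use desk-scale versions
of the study conditions, chosen as the package's own benchmark sizes: the
heterozygosity check runs the full 20 families $\times$ 30 RILs $\times$
300 markers panel; heritability recovery uses 600 lines in 4 environments
(50 replicates, true $h^2 = 0.4$); imputer comparisons use 10 families
$\times$ 10 RILs with 60 markers over two 120 cM chromosomes, 20% MCAR
masking, repeated over seeds. Dense Cholesky factorisations of the
mixed-model coefficient matrix dominate the cost; panels into the low
thousands of individuals are practical, and the sparse-inverse machinery
of dedicated animal-breeding software is intentionally out of scope.

Known limitations: no imputation of entirely ungenotyped individuals, no
phasing or multi-allelic sites, dominance/epistatic kernels and
single-step blended matrices are out of scope, and the ANOVA-style
hypothesis testing of method differences is deliberately left to the
user's statistics environment.
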