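# mmimpute

Pedigree-based multivariate mixed-model imputation of missing SNP
genotypes, with the baseline imputers and the evaluation framework needed
to compare imputation methods in structured plant populations.

## What problem this solves

Breeding panels — here, nested association mapping (NAM) populations of
recombinant inbred lines (RILs) sharing a common parent — are genotyped
with platforms that leave missing calls, and the imputation method chosen
to fill those gaps changes the genomic relationship matrix, the
heritability a SNP panel captures, and genome-wide prediction downstream.
This package is for quantitative geneticists and breeders who want a
pedigree-aware imputer and a level playing field on which to compare it
with standard alternatives.

The core method treats the 0/1/2 gene content of a marker as a
quantitative trait. For each focal marker `y_j` with flanking markers
`y_i`, `y_k` in map order, it fits the trivariate mixed model

    Y = 1 mu + Z gamma + e,
    Var(Y) = A (x) Sigma_g  +  I (x) Sigma_e      (Sigma_e diagonal)

where `A` is the additive numerator relationship matrix from the pedigree,
`Sigma_g` is the full 3x3 genetic covariance of the window (its
off-diagonals carry linkage disequilibrium with the flanks), and the
residual block is diagonal. Variance components are estimated by REML
(EM warm-up + average-information steps); missing entries of `y_j` are
replaced by their empirical-Bayes (BLUP) estimates `mu_j + gamma_j`,
which borrow strength from relatives through `A` and from flanking
markers through the genetic covariances; then the window slides one
position.

Around the core: k-nearest-neighbour, iterative truncated-SVD (with
Owen–Perry bi-cross-validation rank choice), and modal imputation;
an adapter for external tools (HMM imputers, random forest); gene-content
marker-heritability and MAF quality filters; post-imputation quality
metrics (identity accuracy against a standard, heterozygosity,
repeated-marker counts); intra-class-correlation heritability
`h2 = sigma2_A / (sigma2_A + sigma2_E + sigma2_C + sigma2_e)` and
five-fold GBLUP prediction accuracy; and a NAM population simulator that
provides error-free truth panels (F5 lines: expected inbreeding 93.75%,
expected heterozygosity 6.25%) so every claim is testable.

## Worked example

```r
library(mmimpute)

# simulate a small NAM panel: 10 families x 10 F5 RILs, 60 markers
tb <- simulate_nam(sim_config(n_families = 10, ril_per_family = 10,
                              n_chromosomes = 2,
                              markers_per_chromosome = 30, seed = 42))
heterozygosity_proportion(tb$geno)
#> [1] 0.0615

# mask 20% of calls, then impute with the pedigree mixed model
masked <- inject_missing(tb$geno, rate = 0.2, seed = 1)
A <- a_matrix(tb$pedigree)
res <- impute_mmm(masked$geno, A, families = tb$families)
imputation_accuracy(res, tb$geno, masked$mask)
#> [1] 0.8141667

# against the baselines on the same mask
imputation_accuracy(impute_knn(masked$geno), tb$geno, masked$mask)
#> [1] 0.5458333
imputation_accuracy(impute_mode(masked$geno), tb$geno, masked$mask)
#> [1] 0.46

# how much genetic variation does each completed panel capture?
fit <- estimate_heritability(tb$phenotypes,
                             vanraden_g(res$geno) + diag(1e-6, 100),
                             tol = 1e-8)
glance(fit)[, c("h2", "sigma2_A", "sigma2_E", "converged")]
#> # A tibble: 1 × 4
#>      h2 sigma2_A sigma2_E converged
#>   <dbl>    <dbl>    <dbl> <lgl>
#> 1 0.330     21.8     17.8 TRUE
```

The accuracy line reads: 81.4% of the masked calls were restored
identically to the truth panel by the pedigree model, against 54.6% for
kNN and 46.0% for column-mode filling — the pedigree and the flanking-LD
covariances carry most of the signal at this masking rate. The
heritability block shows the intra-class correlation computed from a
genomic kernel built on the imputed dosages.

A thin command-line front end covers the same pipeline
(`inst/cli/mmimpute simulate|qc|impute|evaluate ...`), and
`compare_methods()` assembles the full method-by-rate quality report with
an `autoplot()` method.

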