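# eccdeconv

Cell-composition deconvolution of bulk acute myeloid leukemia (AML)
transcriptomes against a healthy bone-marrow single-cell reference.

An AML sample's bulk RNA-seq profile is a mixture of cell-level
transcriptomes, and the stage at which the leukemic blasts are arrested
(HSC-like, GMP-like, monocytic, ...) is recoverable from that mixture.
`eccdeconv` estimates, per sample, the **estimated cell composition
(ECC)** — the vector of cell-type proportions $p$ whose weighted
signature sum best explains the bulk profile — and assigns each sample
its most abundant type as a maturation **phenotype**. Downstream, the
package predicts ex-vivo drug resistance from ECCs (leave-one-out
random-forest regression, Spearman ρ), runs univariate/multivariate
association ledgers with Benjamini–Hochberg correction, scores gene
signatures on cpm, removes additive batch effects, and compares survival
between ECC-defined groups (Kaplan–Meier / log-rank). It is written for
computational hematologists who have bulk AML cohorts and an annotated
single-cell reference (or want a fully synthetic benchmark).

## The model in brief

From an annotated multi-subject single-cell matrix the package builds a
reference atlas: per type *k*, the cross-subject mean relative
expression θ<sub>gk</sub> (columns sum to 1), the cross-subject variance
σ²<sub>gk</sub> of those per-donor profiles, and the average per-cell
library size S<sub>k</sub>. A bulk sample *y* (non-log counts, converted
to relative expression) is then decomposed by iteratively re-weighted
non-negative least squares with design D<sub>gk</sub> = θ<sub>gk</sub>
S<sub>k</sub> and per-gene weights

    w_g = 1 / (nu + r_g^2 + sum_k c_k^2 S_k^2 sigma2_gk)

(residual plus cross-subject variance of the fit, floored at ν = 1e-4);
coefficients are divided by S<sub>k</sub> and normalized to give
cell-count proportions. The inner solver is an exact Lawson–Hanson
active-set NNLS. Defaults: tolerance 0.01 on proportions, ≤ 1000
iterations, no design normalization. See the methods vignette
(`vignettes/ecc-deconvolution-methods.Rmd`) for the full account.

## Worked example

Simulate a benchmark atlas (8 types, 3 donors, 400 genes, 10 markers per
type), build the reference, create an 80%-type_03 pseudobulk of 1000
cells and deconvolute it:

```r
library(eccdeconv)

cells <- generate_synthetic_atlas(atlas_sim_config(seed = 7))
atlas <- build_reference(cells)
atlas
#> reference_atlas: 400 genes x 8 cell types (3 subjects)
#>   types: type_01, type_02, type_03, type_04, type_05, type_06, type_07, type_08

pb   <- simulate_overabundant_pseudobulk(cells, "type_03",
                                         n_cells = 1000, frac = 0.8,
                                         seed = 11)
ecc  <- deconvolute(cbind(pb1 = pb$bulk_counts), atlas)
#> [eccdeconv] 400 genes shared between bulk and atlas
round(ecc$proportions, 3)
#>     type_01 type_02 type_03 type_04 type_05 type_06 type_07 type_08
#> pb1   0.026   0.029   0.808   0.031    0.03   0.025   0.028   0.024
assign_phenotype(ecc)
#>   sample_id phenotype dominance   tie
#> 1       pb1   type_03 0.8078152 FALSE
```

The true composition was 80% type_03 with the remaining 200 cells spread
over the other seven types (inverse to their availability, here ~2.9%
each); the estimate lands within a percentage point of the truth and the
phenotype call is the designed dominant type. A survival comparison
between a monocytic-phenotype group and the rest looks like:

```r
surv <- generate_survival(rep(c("monocytic", "other"), each = 30),
                          c(monocytic = 2, other = 0.7), seed = 2)
km_logrank(surv)[c("chisq", "df", "p_value")]
#> $chisq   21.3
#> $df      1
#> $p_value 4.02e-06
```

i.e. the higher-hazard monocytic group separates clearly (χ² = 21.3 on
1 df). A command-line front end over the same functions is installed at
`inst/scripts/eccdeconv.R` (subcommands `simulate-atlas`, `build-ref`,
`simulate-pseudobulk`, `deconvolute`, `predict-drugs`, `associate`,
`survival`; global `--seed`, `--config`, `--log-level`).

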