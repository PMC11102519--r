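---
title: "Methods: estimating cell compositions of bulk AML transcriptomes"
author: "eccdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating cell compositions of bulk AML transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute myeloid leukemia (AML) blasts are blocked at some stage of normal
hematopoietic differentiation, and that stage (an HSC-like, GMP-like or
monocytic phenotype, for example) carries diagnostic and therapeutic
information. A bulk RNA-seq profile of an AML sample is a mixture of the
transcriptomes of its constituent cells, so the maturation stage can be
read off computationally: estimate, for each sample, the proportions of
healthy bone-marrow cell types whose weighted signature sum best explains
the bulk profile. We call the resulting per-sample proportion vector the
*estimated cell composition* (ECC), and the most abundant estimated type
the sample's *phenotype*. A healthy reference is used deliberately:
malignant single-cell references fragment into patient-specific clusters
rather than reusable signatures, and a healthy-type readout ("dominated
by CD14+ monocytes") is directly interpretable in the clinic.

## The model

### Reference atlas

From an annotated multi-subject single-cell count matrix (genes x cells,
non-log scale, with a cell-type and a donor label per cell) we build, per
cell type $k$:

* $\theta_{gk}$ — the cross-subject mean *relative expression* of gene
  $g$. For each donor $s$, the mean count over that donor's type-$k$
  cells is normalized to sum 1; $\theta_{\cdot k}$ is the average of
  these per-donor profiles, so each column sums to 1.
* $\sigma^2_{gk}$ — the cross-subject variance (unbiased, denominator
  $S-1$) of the same per-donor relative profiles; zero when a single
  donor contributes. This is the gene-stability information the weighted
  fit exploits: genes whose relative expression varies between donors
  are down-weighted.
* $S_k$ — the average total counts per type-$k$ cell ("cell size",
  average mRNA content), which converts expression-scale coefficients
  into cell-count proportions.

Donor-level profiles (not pooled cells) define $\theta$ so that
$\sigma^2$ measures between-donor biology rather than within-donor
sampling noise; a pooled mode exists behind a flag for comparison.
Types with fewer than `min_cells_per_type` (default 10) cells are
dropped — below that the variance estimate over 2–3 donors is dominated
by sampling noise. Genes with zero counts everywhere carry no design
information and are removed.

### Deconvolution

For a bulk sample $y$ restricted to the genes shared with the atlas
(case-sensitive symbol intersection — with targeted reference panels of a
few hundred genes this intersection is the dominant practical failure
mode, so its size is logged), we convert to relative expression and scale
to a percent-like range ($y \leftarrow 100\, y / \sum_g y_g$), set the
design $D_{gk} = \theta_{gk} S_k$, and solve iteratively re-weighted
non-negative least squares:

1. initial coefficients $c = \arg\min_{c \ge 0} \lVert y - Dc \rVert^2$;
2. per-gene weights
   $w_g = \bigl(\nu + r_g^2 + \sum_k c_k^2 S_k^2 \sigma^2_{gk}\bigr)^{-1}$,
   where $r = y - Dc$ — the inverse of the residual plus the
   cross-subject variance of the fitted value, floored at $\nu$;
3. re-solve with weights; repeat until the maximum absolute change of the
   *proportions* drops below `convergence_tol` or `max_iter` is reached;
4. proportions $p_k \propto c_k / S_k$, normalized to sum 1.

The defaults pin the documented behavior of the established
cross-subject weighted-NNLS deconvolution design: $\nu = 10^{-4}$,
tolerance $0.01$, at most 1000 iterations, and *no* normalization of the
design (bulk inputs are non-log counts; only the relative-expression
conversion is applied). The percent scaling of $y$ keeps squared
residuals commensurate with the $\nu$ floor; without it the floor would
dominate every weight and the iteration would degenerate to the
unweighted fit. Because of the relative-expression conversion, scaling a
sample's library (sequencing depth) provably cannot change its ECC.

The inner solver is a Lawson–Hanson active-set NNLS written for exactness
and determinism: it terminates at a KKT-satisfying point, has no step
size or initialization, and is invariant to rescaling all weights.
`max_iter = 0` exposes the plain unweighted NNLS limit for
cross-checking. Samples that hit the iteration cap return the last
iterate flagged `converged = FALSE` rather than erroring — a cohort run
should report every sample.

### Phenotype assignment

The per-sample phenotype is the argmax of the ECC row; an exact tie takes
the first type in atlas order and raises a tie flag, keeping assignment
deterministic.

## Bulk preprocessing

Cohort count matrices are cleaned the standard way before deconvolution:
ERCC spike-ins and mitochondrial genes are removed (by metadata flags
when supplied, otherwise by the conventional `ERCC-`/`MT-` prefixes,
case-insensitively), identifiers are mapped to symbols via a
user-supplied table (annotation releases differ, so the mapping is an
explicit input), and among rows sharing a symbol only the row with the
largest standard deviation across samples is kept — duplicated
low-variance rows carry less information. The deduplication SD is the
population SD (denominator $n$) on raw counts; the scale is configurable
(`sd_scale = "cpm"`) since reasonable pipelines disagree here. The whole
step is idempotent. Counts-per-million normalization is exact
(`cpm_gs = counts_gs / colsum_s \times 10^6`), and signature scores (e.g.
a stemness score) are computed as $\sum_g w_g \log_2(\mathrm{cpm}_{gs}+1)$
over the signature genes present — the weights are a required input, and
the $\log_2(\mathrm{cpm}+1)$ transform is our declared default since raw
cpm scoring is also in circulation (`log_transform = FALSE`).

## Synthetic data: what it emulates and what it does not

The generator produces the ground truth every downstream stage is
validated against. Defaults describe the benchmark used throughout the
package's tests: $K = 8$ cell types, $S = 3$ donors, $G = 400$ genes
(the scale of a targeted single-cell panel), 10 dedicated marker genes
per type up-regulated $2^3 = 8$-fold, 40 cells per type per donor,
negative-binomial counts with dispersion 0.2, a log-normal donor effect
(sd 0.3 on the log scale) shared across types, and log-normal per-cell
library sizes (mean 2000 counts, sd 0.3) — values typical of UMI-based
bone-marrow data. Baseline gene means are log-normal (meanlog 0,
sdlog 1).

Pseudobulks follow two schemes. The *overabundant* scheme draws 1000
cells, 80% (configurable) from one target type, with the remainder
allocated across the other types proportionally to the *inverse* of each
type's available cell count — rare types are deliberately over-sampled so
every signature is exercised — using largest-remainder rounding so the
total is exact; sampling is with replacement, and the drawn cells' counts
are summed. The *individual* scheme simply sums one donor's cells.
Log-scale integrated matrices are exponentiated first; the log base of
integrated values is a genuine ambiguity across toolchains, so natural
`expm1` is the default and the base is an argument.

What the simulation does *not* contain: malignant cells, clonal
substructure, continuous differentiation trajectories, batch effects, or
transcriptionally near-identical type pairs (the EMP/HSC/early-erythroid
ambiguity of real marrow). Passing the recovery benchmarks therefore
shows the estimator is correct and well calibrated on well-separated
mixtures — not that real AML cohorts deconvolute to 0.4% error.

Drug AUCs are simulated as a linear readout of the ECC
($\mathrm{auc} = \beta^\top p + \varepsilon$), and survival times as
per-group exponentials with administrative censoring; both record their
generative parameters.

## Downstream analyses

* **Drug resistance** (`loocv_predict`): per drug, min-max-normalized AUC
  is predicted from the $K$ ECC features by a random-forest regressor
  under leave-one-out cross-validation; performance is the Spearman
  $\rho$ (mid-rank Pearson; two-sided $p$ from the $t$ approximation,
  exact permutation behind a flag) between held-out predictions and
  observations. Forest settings mirror the classical defaults (500
  trees, $\lfloor K/3 \rfloor$ candidate features per split, no depth
  limit). Each fold re-seeds deterministically from the global seed and
  the held-out sample *identifier*, and training rows are ordered by
  identifier, so results are independent of sample order. Held-out
  predictions are reported relative to their fold's training baseline
  (plus the constant grand mean): leave-one-out training means are
  anti-correlated with the held-out value, which otherwise drags
  no-signal predictions towards spurious negative correlation; the
  correction is a per-fold constant shift, so genuine signal is
  untouched. Even so, a residual negative bias from the forest's
  response-adaptive splits survives in permutation nulls — an intrinsic
  property of cross-validated permutation testing worth remembering when
  interpreting small null correlations.
* **Associations**: univariate and multivariate linear models of
  attributes against a min-max-normalized response, slope $t$-test
  $p$-values, Benjamini–Hochberg correction across attributes (and
  across all cell-type x drug pairs in `ecc_drug_association`).
  Categorical attributes are one-hot encoded against their first level —
  the encoding convention is ours to declare. Exclusions (e.g. dropping
  FAB class and all ECCs except CD14+ monocytes when asking whether
  monocytic composition is independently predictive) are recorded in the
  result.
* **Batch correction**: per feature, each batch's deviation from the
  grand mean is subtracted, preserving the per-feature grand mean —
  appropriate for log-scale abundance matrices before association
  analyses.
* **Survival**: Kaplan–Meier product-limit curves per group and the
  unstratified log-rank test ($\chi^2$ on groups$-1$ df), delegated to
  the survival package; groups come from phenotype labels or a median
  split of a score (ties at the median go to "low", deterministically).
  Subgroup selection (e.g. one treatment arm) is a metadata filter
  upstream, not baked into the test.

## Numerical choices and edge cases

* Active-set NNLS tolerance is relative to the problem scale
  ($10^{-10} \max |A^\top y|$); backtracking removes variables that a
  least-squares pass drives non-positive, so the returned point satisfies
  the KKT conditions exactly up to that tolerance.
* An all-zero coefficient vector (a bulk sample orthogonal to every
  signature) returns the uniform composition rather than 0/0.
* Tabular output is TSV with 6 significant digits; reading back
  reproduces the written values exactly, and the ECC reader accepts the
  ~1e-6 row-sum slack that rounding introduces.
* The canonical cell-type order is sorted; every result is invariant to
  the order of input cells and genes, and equivariant in sample order.
* Gene-subset consistency of the atlas (subset-then-build equals
  build-then-subset after renormalizing columns) is exact for
  single-donor or pooled references; with several donors the per-donor
  renormalization makes it approximate, which the tests state
  explicitly.

## Benchmark sizes

The validation suite deconvolutes 1200 pseudobulks (50 per type at
overabundance fractions 0.2/0.5/0.8 over 8 types), runs a 100-sample
LOOCV with 20 permutation refits, 100 log-rank replicates at hazard
ratio 4 (200 per arm), and a 200-drug null calibration of the
association ledger — sizes chosen so the whole suite completes in a few
minutes on one core while keeping Monte-Carlo error well below the
tolerances being asserted. Measured results on this benchmark: per-type
proportion MAE ~0.004, dominant-type assignment 100%, LOOCV Spearman
$\rho \approx 0.99$, log-rank power 100%, association type-I rate
~0.055 — reproducible via `scripts/acceptance.R`.
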