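# cnaimpact

Quantifying the direct and indirect impact of gene copy number alterations
(CNAs) on gene expression and patient survival through a sparse
transcriptional regulatory network.

## The problem

Most somatic CNAs in a tumor are rare — seen in a handful of patients or
only one — so frequency-based driver detection cannot assess them. If,
however, a regulatory network is available, the effect of *any* CNA can be
propagated along regulatory paths to genes whose expression is prognostic,
yielding a patient-specific, mechanistically interpretable survival impact
score. This package implements that pipeline end to end for statisticians
and computational biologists working with paired expression/copy-number
cohorts, together with a synthetic-cohort generator that makes every stage
testable without external data.

## The model

For each target gene *i* and sample *d*, expression is modeled as

    e_id = a_ii * c_id + sum_{j != i} a_ji * e_jd

where `c_id` is the gene's copy-number log-ratio (cis effect `a_ii`) and
`a_ji` are trans effects of regulator expression, estimated by the lasso
with the penalty chosen by repeated ten-fold cross-validation. Active
predictors are tested with the covariance test for the lasso at their
first entry into the solution path, kept only when significant at
5×10⁻⁵ in all repeated fit instances, and pruned of local chromosomal
predictors (±50 gene ranks). On a cohort, per-gene explained variances
`R²_i = r_i²` (0 for genes with `r_i ≤ 0`) are split among each target's
predictors in proportion to their average absolute contribution, giving a
flow matrix `F` with `f_ji = p_ji R²_i` and column sums < 1. The impact
matrix

    F* = sum_{k >= 1} F^k = (I - F)^{-1} - I

accumulates all direct and indirect regulatory paths; standardized
columns (summing to 100) express impacts as percent of a target's total
incoming impact. Survival signature genes come from repeated
random-forest survival fits (selection frequencies, bias-corrected by
permuted-survival forests, profiled by successive permutation of
top-ranked genes); each gene carries a ±1 survival-association sign.
A patient's score averages, over their called CNAs (|log-ratio| ≥ 0.75),
the signed impact on each signature gene times the gene's sign; positive
scores predict longer survival, and the two score classes are compared by
Kaplan–Meier curves with a permutation test.

## Worked example

```r
library(cnaimpact)
cfg <- sim_config(n_genes = 40, n_samples = 120, cis_fraction = 1,
                  cna_rate_frequent = 0.2, cna_rate_rare = 0.02,
                  noise_sd = 0.4, survival_effect = 1, survival_noise_sd = 0.2,
                  seed = 3)
study <- simulate_study(cfg)
fit <- infer_network(study$expression, study$copy_number, study$annotation,
                     n_instances = 3, cv_repeats = 2, seed = 1)
print(fit)
#> Sparse transcriptional network (40 genes)
#>   consensus trans edges: 62 (54 activating, 8 repressing)
#>   genes with cis copy-number effect: 18
#>   instances: 3  significance threshold: 5e-05

pred <- predict_expression(fit, study$expression, study$copy_number)
prof <- predictability(pred, study$expression)
impact <- propagate(build_flow_matrix(fit, study$expression,
                                      study$copy_number, prof))
print(impact)
#> Impact matrix: 40 genes, unsigned (series, 16 iterations)

calls <- call_cnas(study$copy_number)
sig <- survival_signature(study$expression, study$clinical,
                          n_splits = 10, ntree = 100, repeats = 3,
                          steps = 1:40, direction_assign = "gene", seed = 1)
print(sig)
#> Survival signature: 7 gene(s) at cutoff 0.1
#>   4 positively and 3 negatively survival-associated
#>   genes: g0008, g0005, g0031, g0018, g0024, g0030, g0003

scores <- score_patients(fit, study$expression, study$copy_number, prof,
                         sig$signature, calls, method = "closed")
km_stratify(scores, study$clinical, seed = 1)
#> Kaplan-Meier stratification by survival impact score
#>   negative: 60  positive: 60  unclassifiable: 0
#>   restricted-mean-survival difference (positive - negative): 445.9
#>   permutation p-value: 0.000999 (1000 permutations)
```

The network print shows the consensus edge counts by sign (activating
dominates, as planted); the impact matrix line reports how many series
iterations the path sum needed; the signature print lists the selected
genes with their survival-association split; and the stratification
report gives the per-class patient counts, the signed
restricted-mean-survival difference in days between the positive- and
negative-score classes, and its permutation p-value.

A thin command-line wrapper (`exec/cnaimpact`) exposes the same stages as
`simulate | infer | impact | signature | score` subcommands with
`--config <json> --seed <int> --out <dir>`.

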