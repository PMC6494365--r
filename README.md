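# phenoclust

Unsupervised phenotype discovery for clinical cohorts with mixed-type
features, built for the septic bloodstream-infection (BSI) setting:
hundreds to thousands of patients described by ~25 continuous, binary and
categorical variables (demographics, comorbidities, acuity scores,
infection characteristics), with mortality and discharge disposition as
outcomes. Classifying such patients by a single a-priori axis (organism,
infection source) ignores how these characteristics interact;
`phenoclust` instead discovers groupings from the data and then audits
them for stability and clinical meaning.

## The method

The pipeline chains the field's standard pieces into one reproducible,
tested procedure:

1. **Gower dissimilarity** for mixed data with missing-pair weighting:
   `d(a,b) = Σ w_f δ_f s_f / Σ w_f δ_f`, with range-normalized absolute
   differences for continuous features and symmetric match/mismatch for
   binary and categorical features. Skewed duration variables are
   `log1p`-transformed first (declared per schema).
2. **PAM (k-medoids)**, classical BUILD + best-improvement SWAP over the
   precomputed dissimilarity matrix, fully deterministic (lowest-index
   tie-breaks), implemented in C++.
3. **Consensus clustering**: 1000 repetitions (default) of PAM on 80%
   patient subsamples; the consensus matrix M records, per pair, the
   fraction of co-sampled runs in which the two patients co-clustered.
   Final labels come from PAM on `1 - M`.
4. **PAC model selection**: the proportion of ambiguous clustering,
   `PAC = F(0.9) - F(0.1)` over off-diagonal consensus values, computed
   for k = 2..9; the smallest PAC selects k. Structureless cohorts and
   boundary minima raise explicit warnings.
5. **Validity and purification**: item consensus per patient; members
   more than 2 SDs below their cluster's mean consensus are outliers and
   are removed ("purified"), never reassigned; per-cluster phenotype
   summaries (content validity) and cluster x outcome chi-square tests
   (predictive validity), before and after purification.
6. **Feature reduction**: features weakly associated with the clustering
   (Cramér's V / rank epsilon-squared below 0.1) are dropped in batches,
   accepted only when the re-clustered partition agrees with the old one
   (ARI >= 0.9).

Because the EMR cohorts this procedure targets cannot be shipped, the
package includes a first-class synthetic cohort generator
(`cohort_spec()` / `generate_cohort()`) and a reference 4-phenotype
septic-BSI specification (`bsi_phenotype_spec()`) with planted signature
prevalences, a skewed pre-infection hospitalization duration, nuisance
features, and a 19.2%-44.6% mortality gradient across phenotypes. Every
stage of the pipeline is validated against this generator and against
independent oracles (scalar Gower, exhaustive k-medoid enumeration,
hand-recounted consensus ratios).

## Worked example

```r
library(phenoclust)

co  <- generate_cohort(bsi_phenotype_spec(400, seed = 1))
tab <- apply_transforms(co$table)
D   <- gower_matrix(tab)

sw  <- consensus_sweep(D, k_min = 2, k_max = 9, n_reps = 100, seed = 1)
pr  <- select_k(sw)
pr$selected_k
#> [1] 4

run <- sw$runs$k4
adjusted_rand_index(run$final_labels, co$true_labels)
#> [1] 0.9025768

ic  <- item_consensus(run)
out <- detect_outliers(ic)
round(out$by_cluster$fraction, 4)    # per-cluster outlier fractions
#> [1] 0.0310 0.0274 0.0380 0.0336
purified <- purify(run$final_labels, out)

outcome_comparison(co$outcomes, run$final_labels, purified)
#> [ raw ] mortality: X2 = 40.057 , df = 3 , p = 1.0365e-08
#> [ raw ] disposition: X2 = 45.441 , df = 6 , p = 3.8246e-08
#> [ purified ] mortality: X2 = 36.081 , df = 3 , p = 7.1986e-08
#> [ purified ] disposition: X2 = 44.544 , df = 6 , p = 5.7648e-08
```

On this run the sweep's PAC profile bottoms out at k = 4 with
PAC = 0.037 (the planted number of phenotypes), the recovered partition
matches the ground truth at ARI 0.90, per-cluster mean item consensus is
0.97–0.98 with 3.25% of patients flagged as outliers, and the recovered
clusters separate mortality from 17% to 54% (chi-square p ≈ 1e-8) —
i.e. the pipeline finds the planted structure and its outcome gradient.

For a one-call run that writes a full artifact directory (manifest,
consensus matrix TSV, PAC profile JSON, labels, validity report,
reduction trace, and all diagnostic plots):

```r
cfg <- run_config(sim_spec = bsi_phenotype_spec(400, seed = 1),
                  n_reps = 100, seed = 1, out_dir = "run1")
res <- run_pipeline(cfg)
```

A thin command-line front end is at `inst/cli/phenoclust.R`
(`simulate` and `all` subcommands).

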