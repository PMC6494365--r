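---
title: "Consensus-clustering phenotype discovery: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-clustering phenotype discovery: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclust)
```

## The problem

Septic patients with bloodstream infections (BSI) are clinically
heterogeneous: a priori groupings by organism, infection source or host
category ignore the interactions among patient characteristics, acuity of
illness and infection characteristics. `phenoclust` implements an
unsupervised phenotyping pipeline for such cohorts: mixed-type clinical
feature tables are clustered with partitioning around medoids (PAM) over
Gower dissimilarities, under repeated subsampling, and the resulting
phenotypes are audited for stability (item consensus, outlier
purification), parsimony (feature reduction) and clinical meaning (content
and predictive validity against mortality and discharge disposition).

## The model and its stages

### Gower dissimilarity

For patients $a, b$ and features $f$ with weights $w_f$,

$$d(a,b) = \frac{\sum_f w_f\,\delta_{abf}\,s_{abf}}{\sum_f w_f\,\delta_{abf}},$$

where $\delta_{abf}=1$ iff $f$ is observed in both records, and the score
$s_{abf}$ is $|x_{af}-x_{bf}|/R_f$ for continuous features (range $R_f$
over observed values; a constant feature contributes similarity, not 0/0)
and a 0/1 mismatch indicator for binary and categorical features. Binary
features are **symmetric** by default: joint absence counts as agreement,
which is the right reading for clinical flags such as septic shock (two
patients without shock genuinely resemble each other). A Jaccard-style
asymmetric mode is available per schema for rare "presence-only" markers.

Missingness is handled inside the coefficient (pairs average only their
jointly observed features); nothing is imputed. A pair with no jointly
observed feature aborts the run with the offending ids — at the sub-5%
missingness typical of curated EMR extracts this cannot occur.

Ranges are computed once on the full cohort and reused inside every
subsample. This makes pairwise dissimilarities subsample-invariant, so the
full matrix is computed once and sliced — the consensus loop then costs
only the PAM fits.

Continuous features flagged in the schema are transformed with
$\ln(1+x)$ *before* distances are computed. `log1p` rather than `log`
because duration variables (days hospitalized before the index BSI) are
legitimately zero; transforming before Gower is the coherent order, since
the transform exists precisely to stop a long right tail from dominating
the range normalization. Which variables are flagged is schema metadata,
not a hard-coded list: the normality judgment belongs to the dataset, and
the reference synthetic schema flags its duration feature.

### PAM

k-medoids over the precomputed dissimilarity matrix, classical BUILD
(first medoid minimizes total dissimilarity; each further medoid maximizes
the cost decrease) followed by best-improvement SWAP until no single
medoid exchange strictly lowers the cost. Every tie — equal BUILD gains,
equal swap deltas, equidistant assignment — is broken toward the lowest
index, so a PAM fit is a pure function of its inputs and all randomness in
the pipeline enters through subsampling alone. The classical
$O(k(n-k)^2)$ SWAP is deliberate: cohorts at this scale (hundreds to a few
thousand patients, subsampled) stay tractable, and the simple formulation
is the one an exhaustive-enumeration oracle can verify. Being a
single-start local search, PAM can land in a local optimum; on random
8-point problems it attains the exhaustive optimum in roughly 90% of
instances, matching the reference implementation in the `cluster` package
on identical inputs.

### Consensus clustering

For each candidate $k$, `n_reps` subsamples of 80% of patients (drawn
without replacement) are each clustered with PAM; for every pair the
pipeline tracks how often the two patients were sampled together and how
often they were then clustered together. The consensus matrix is the
ratio — normalized by the pairwise co-sampling count, not the repetition
count, so entries estimate the conditional co-clustering probability. The
diagonal is fixed at 1 by convention and excluded from all statistics.

Final labels are obtained by clustering $1 - M$ with PAM, keeping the
declared base algorithm in charge of its own summary; average-linkage
hierarchical clustering is available as a switch for parity with common
consensus-clustering tooling. $1 - M$ is not a metric; PAM never needs
metricity.

Reproducibility: one master seed; each $(k, \text{rep})$ pair derives its
own counter-based substream, so per-$k$ results are independent of sweep
order and identical configurations reproduce byte-identical artifacts.

### Choosing k: PAC

The proportion of ambiguous clustering is the fraction of off-diagonal
consensus values falling in an intermediate band,
$\mathrm{PAC} = F(u_2) - F(u_1)$ with the right-continuous empirical CDF
$F$ and the convention that a value $v$ is ambiguous iff $u_1 < v \le u_2$.
The default interval $(0.1, 0.9)$ follows the PAC literature. The sweep
runs $k = 2$ to $9$ by default — enough to cover clinically interpretable
phenotype counts without manufacturing micro-clusters — and the smallest
PAC selects $k$, ties toward fewer clusters.

Two diagnostics accompany the profile:

* **Boundary flag** — the argmin sits at the edge of the swept range,
  so the true minimum may lie outside it.
* **No-structure warning** — no $k$ achieves $\mathrm{PAC} < 0.25$.
  Resampled clustering happily slices structureless data into groups; the
  tell is that *no* candidate $k$ ever resolves the cohort crisply. The
  0.25 default comes from the separation we observe between regimes on
  the reference generator: with planted structure the best $k$ reaches
  PAC $\approx 0.04$–$0.15$, while null cohorts never drop below
  $\approx 0.28$. Note that raw PAC *declines mechanically with $k$* even
  on null data (random co-clustering at rate $1/k$ slides below
  $u_1 = 0.1$ once $k$ is large), so a global "PAC is smallest at
  $k=9$" on a null cohort is a boundary artifact, not structure — which
  is exactly why the warning keys on the absolute level rather than on
  the location of the minimum.

### Cluster validity and purification

A patient's **item consensus** is its mean consensus with the other
members of its assigned cluster (1 for singletons by convention). Within
each cluster, members whose item consensus falls more than 2 SDs
(sample SD, $n-1$ denominator; clusters under 3 members yield no
outliers) below the cluster mean are flagged as outliers and, on
purification, marked unassigned — never reassigned to a second-best
cluster. Content validity is reported as per-cluster feature summaries
(proportions for binary/categorical; median+IQR and mean+SD for
continuous, back on the untransformed scale so tables read clinically);
predictive validity as cluster-by-mortality and cluster-by-disposition
contingency tables with uncorrected Pearson chi-square (Yates optional
for 2×2; tables with expected cells below 1 are annotated, not
suppressed), repeated after purification.

### Feature reduction

"Equally distributed among the clusters" is operationalized as low
feature–cluster association on a common $[0,1]$ scale: Cramér's V for
binary/categorical features and rank-based epsilon-squared
($H/(n-1)$ from the Kruskal–Wallis statistic — rank-based because
clinical variables are skewed) for continuous ones. Features scoring
below `assoc_threshold` (default 0.1, a small effect by the usual V
convention) are dropped *as a batch*; the cohort is re-clustered at the
selected $k$ and the drop is accepted only if the adjusted Rand index
between old and new final labels reaches `ari_threshold` (default 0.9 —
ARI rather than raw agreement because cluster ids are arbitrary). On
rejection the most-associated half of the batch is restored and the rest
retried; at least 3 features are always kept. Batch-drop-with-backtracking
is a tractability choice over leave-one-out; the trace records every
attempt either way.

One sizing note: a null binary feature's Cramér's V concentrates around
$\sqrt{df/n}$, so at the default 0.1 threshold the screen only has power
once cohorts reach roughly $n \gtrsim 1200$; the validation studies below
run reduction at $n = 1500$ for exactly that reason.

## The synthetic cohort generator

The study data this pipeline targets are EMR extracts that cannot be
redistributed, so the package ships a generator that plants the structure
the method assumes: $K$ latent phenotypes mixed in fixed proportions;
cluster-specific Bernoulli prevalences, normal means, zero-truncated
shifted-lognormal durations and categorical level profiles; nuisance
features identically distributed everywhere; and cluster-graded outcomes.
`bsi_phenotype_spec()` encodes the reference 4-phenotype septic BSI
cohort: mixing proportions (0.215, 0.279, 0.287, 0.219); signature
prevalences 0.908 (outside-hospital transfer, phenotype 1), 0.778 (prior
intravenous antibiotics, phenotype 2), 0.646 (female, phenotype 3) and
0.71 (lung source, phenotype 4); mortality (0.268, 0.192, 0.21, 0.446),
i.e. a 19.2%–44.6% gradient with interior values interpolated inside the
printed endpoints; and a days-hospitalized duration with medians 2/7/0/2
across phenotypes.

Everything else — background prevalences of signature features in the
other clusters (0.02–0.30), the supporting-feature contrasts (surgical
profile for phenotype 1, immunosuppression/malignancy for phenotype 2,
urinary/skin and nursing-home admixture for phenotype 3, shock /
ventilation / acuity for phenotype 4), and all dispersions — is a free
parameter of the generator, fixed once as documented constants. They were
chosen so that the planted structure is *strongly* separable (pairwise
phenotype contrasts spread over 8–12 features), because that is the
regime the method claims to address — stable blocks, low PAC at the true
$k$, few outliers — and because recovery tests are only meaningful when
the generator's own signal is unambiguous. `separation` scales every
cluster-specific parameter toward the mixture average; `separation = 0`
is the structureless negative control. Labels are i.i.d. draws from the
mixing proportions (a quota mode fixes exact sizes for tests that need
them).

What the generator does **not** emulate: within-cluster feature
correlation beyond what shared cluster membership induces, informative
missingness, longitudinal structure, or measurement error. Passing
recovery tests on these cohorts therefore demonstrates the pipeline's
correctness and its behavior under the stated assumptions — not that any
particular real EMR cohort contains four phenotypes.

## Validation sizes and numerical choices

The shipped validation suite runs, per seed: recovery and purification
studies on $n = 400$ cohorts with 100 repetitions per $k$ over
$k = 2..9$ (20 seeds); the same sweep on null cohorts; reduction studies
at $n = 1500$ with 30 repetitions and 6 planted noise features
(20 seeds); and outcome-gradient checks at $n = 4000$ on true labels
(20 seeds). These sizes are the package's own validation design: large
enough that binomial noise sits well inside the tested tolerances, small
enough to re-run routinely. Production defaults remain the reference
settings (1000 repetitions, full cohort).

Numerical conventions collected in one place: all ties in PAM break
toward the lowest index; swap improvements must exceed $10^{-12}$ to
count, so floating-point noise cannot cycle; consensus denominators are
pairwise co-sampling counts and a never-co-sampled pair is a hard error
asking for more repetitions; the CDF is right-continuous and its area is
the exact step integral (equivalently $1 - \bar v$); PAC ties select the
smaller $k$; outlier SDs use $n-1$; chi-square is uncorrected unless the
2×2 Yates flag is set; the manifest echoes every parameter and rerunning
it reproduces matrices, labels and reports byte-for-byte.

## Known limitations

* PAM is a single-start local search; a small fraction of fits end in a
  local optimum. Consensus over 100–1000 subsamples absorbs most of the
  effect on the final partition.
* Raw PAC cannot be compared across very different $k$ on weakly
  structured data (the $1/k$ artifact above); the no-structure warning
  and boundary flag are the guardrails, not a formal test.
* The outlier rule is a within-cluster z-score heuristic; with very tight
  clusters (SD near 0) it flags nothing even for visibly atypical
  members, and it assumes item-consensus values are roughly unimodal
  within a cluster.
* Association screening treats features marginally; a feature that is
  null marginally but informative jointly would be dropped (the ARI
  stability check is the safety net).
* Chi-square predictive validity is a global independence test; it makes
  no multiplicity adjustment across outcomes and is not a causal claim.
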