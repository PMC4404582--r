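---
title: "Methods: signature screening, permutation QC and chemoresponse prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature screening, permutation QC and chemoresponse prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscreen)
```

# The screening model

`sigscreen` evaluates gene-expression signatures as prognostic markers by
a fully unsupervised stratify-then-test loop, applied uniformly over a
grid of signatures and survival-annotated expression datasets.

**Stratification.** For signature $S$ on dataset $D$, the similarity of
two samples is the Spearman rank correlation of their expression profiles
over the mapped signature genes; samples are clustered by average-linkage
agglomerative clustering on the distance $1 - \rho$, and the tree is cut
at its first bifurcation (`cutree(k = 2)`, which is exactly the root split
of an agglomerative tree) into two groups. No survival information enters
the split. Rank correlation makes the split invariant to any strictly
monotone per-sample transform of expression, which absorbs monotone
platform and normalization effects.

**Failure as data.** A stratification is recorded as N/A — a *failed
prediction*, not missing data — when the downstream log-rank test would be
meaningless: signature coverage below 50% of its genes; a minority group
smaller than $\max(5,\ 0.05\,n)$ samples; or a sample whose profile over
the mapped genes is constant (Spearman undefined — a "dead array"). These
three thresholds are exposed as arguments of `stratify_two_groups()`. N/A
cells stay in every denominator.

**Survival testing.** Each successful split is scored by the two-sample
log-rank $\chi^2$ (1 df, two-sided), the univariate Cox hazard ratio for
the high- vs low-risk group (partial likelihood, Efron tie handling, Wald
95% CI and P), optionally a multivariate Cox model with dummy-coded
clinical covariates (complete-case, rank checked), and Harrell's
concordance index. The c-index counts a pair as comparable when the
smaller observed time belongs to a subject with an event; tied risk scores
contribute 1/2. With a binary grouping, within-group comparable pairs are
tied on risk, so even a perfect two-group separation yields $c < 1$; this
is the standard behavior of Harrell's estimator, worth remembering when
reading two-group c-indices near 0.6.

**Risk labels.** The split itself is unsupervised, so which group is
"high risk" requires a rule; published screens rarely state one. Two modes
are implemented and always recorded: `by_direction` (default, prospective)
calls high-risk the group with the higher mean expression over the
signature's up-annotated genes (all mapped genes if no directions);
`by_outcome` (retrospective, evaluation only) uses the higher Nelson–Aalen
cumulative hazard at median follow-up. Exact ties break toward group1 and
are flagged; a tie with no direction information is unresolved and becomes
N/A.

# Screen summaries and permutation control

The screen aggregates per-signature over datasets and per-dataset over
signatures:

* **Significant rate** of a signature: the percentage of datasets with
  log-rank $P < \alpha$ ($\alpha = 0.05$); N/A cells count in the
  denominator. Candidates must exceed 50% *strictly* ("more than half").
  Reported percentages round half-up to integers; comparisons always use
  unrounded values.
* **N/A rate** of a dataset: the fraction of signatures that failed to
  stratify it. Above 5% (strict) the dataset is rejected.
* **Differential index (DI)** of a dataset: the mean percent-significant
  of the candidate signatures minus the mean percent-significant of
  length-matched random signatures, in percentage points. Datasets with
  DI below 9 are rejected (DI exactly 9 passes); the N/A filter applies
  first, and both reasons are recorded. DI is computed per dataset from
  that dataset's own cells.
* **Adjusted P** of a candidate cell: the fraction of $n$ random
  signatures of identical length, drawn from the same dataset's gene
  universe, achieving a *strictly smaller* log-rank P. The raw count is
  divided by $n$ with no add-one smoothing, because that is the estimator
  the screening procedure defines; the smoothed $(k+1)/(n+1)$ variant is
  available behind a flag. Ties (equal P) count as non-smaller, and null
  failures count as non-smaller and non-significant — both conservative.
  Candidates are ranked by adjusted median P over validated datasets.

Random signatures are drawn uniformly without replacement from the
dataset's own gene universe (coverage is therefore always 1), and nulls
are cached per (dataset, length, seed, $n$), so equal-length queries share
the identical null vector. $n = 1{,}000$ by default; desk-scale tests and
the analysis drivers use 50–200 with correspondingly wider tolerances.

A consequence of clustering-based stratification worth flagging: many
random signatures on the same dataset lock onto the same dominant
co-expression structure and thus produce the *same* two-group split, so
null cells within a dataset are positively correlated. Calibration
statements (e.g. "random signatures are significant in about 5% of
cells") are therefore reliable only when pooled across many independent
datasets, which is how both the test suite and `scripts/acceptance.R`
measure them.

# Chemoresponse prediction

Two predictors of neoadjuvant chemotherapy response are provided:

* **Centroid (prospective).** Cell lines with $\log(\mathrm{IC}_{50}) <
  -1$ (strict) for at least one of the named drugs ("and/or"), restricted
  to HER2-negative lines when status is recorded, define the sensitive
  panel; the centroid is the per-gene mean expression of the signature
  genes over those lines. A patient is predicted treatment-sensitive when
  the Spearman correlation between their profile and the centroid is
  strictly greater than 0.35; rank correlation again absorbs monotone
  platform differences between cell lines and tumors, so no cross-platform
  normalization is applied (a per-gene z-score option exists, off by
  default). Both the IC50 cutoff and the 0.35 threshold are configuration
  values treated as fixed inputs.
* **Clustering (retrospective).** The screening stratification reused on
  the cohort, with high-risk mapped to predicted-insensitive.

Predictions are scored against pCR/RD, RCB class (0/I responder vs II/III)
and DRFS dichotomized at 3 years: events within the horizon are
early events, patients followed past it are survivors, and patients
censored before it without an event are *indeterminate* — excluded from
the 3-year metrics with their count always reported, since no unbiased
assignment exists for them. PPV is the probability of the adverse outcome
among predicted-insensitive patients; NPV its complement among
predicted-sensitive. "RD, distant relapse, or death" is operationalized as
an early event on the DRFS clock in DRFS mode; RD status is used only in
the pCR/RD and RCB modes.

# The synthetic cohorts

The generators produce the statistical structure the screen assumes, with
known ground truth, so every stage is testable without downloads.

**Expression.** A latent *hazard program* of `program_size` genes (default
50) is planted in an `n_genes` universe (default 2,000; discrimination
studies in the tests use 4,000 to keep chance overlap with random
signatures realistically small). A TP53-like binary mutation
(`mutation_rate = 0.3`, the mutation frequency typical of breast tumors)
shifts each program gene by `mutation_effect` (default 2, in units of the
noise SD): 75% of program genes up, 25% down, mirroring the
mixed-direction composition of real TP53-associated signatures, and the
shift is centered on the cohort mean (wild-type at $-e/2$, mutant at
$+e/2$ per signed gene). Both choices are essential, not cosmetic: a
uniform (all-genes-equal) shift adds a constant to each sample's profile
and is exactly invisible to Spearman sample–sample correlation, and
without centering the wild-type samples form no coherent cluster, so the
first bifurcation cannot recover the mutation split under either
simplification. Ten decoy co-expression modules — gene blocks driven by
independent binary factors with the same effect size but no link to
mutation or survival — emulate the outcome-unrelated structure (subtype,
proliferation, stroma) of real tumors; they are what keeps a random
signature that grazes the program from clustering on the mutation split.

**Survival.** The program score is the unweighted mean expression over
program genes (directionless, matching how the screen treats signatures
as sets). Event times are exponential with rate
$h_0 \exp(\beta \cdot \mathrm{score})$, censoring uniform on
$(0, \mathrm{horizon})$. Defaults: $\beta = 1$ (cluster-level hazard
ratios near $e$, the size reported for strong prognostic signatures),
$h_0 = 0.15$/year and a 10-year horizon, giving an observed event
fraction around 40–45% — typical of relapse-endpoint breast cancer
cohorts with decade-long follow-up. Null datasets set $\beta = 0$;
dead-array datasets zero out a fraction of sample profiles to force N/A.
A registry shares one planted program across datasets (per-dataset
sub-seeds `seed + index`), which is the situation a multi-dataset screen
assumes.

**Cell lines and neoadjuvant cohorts.** Sensitive lines (a configurable
fraction; 13 of 20 at the defaults) draw $\log(\mathrm{IC}_{50})$ from
$U(-3, -1.01)$ for one or both drugs and carry the mutant-like program
shift; resistant lines draw from $U(-0.99, 2)$. Neoadjuvant cohorts give
each patient $P(\mathrm{pCR}) = \mathrm{logistic}(-0.8 + 2.5 \cdot
\mathrm{score})$ — about a 26% cohort pCR rate, matching real
taxane-anthracycline cohorts, concentrated in program-high tumors — with
RCB 0/I for responders and II/III otherwise, and DRFS hazard
$h_0\exp(\beta\,\mathrm{score})$ times a protective factor 0.5 for pCR
patients, sized to give a 5-year DRFS gap near 20 percentage points
between predicted groups. Evaluation-scale cohorts use $n = 508$ and
$h_0 = 0.12$/year, reproducing a 79% 3-year DRFS.

**What the generator does not emulate — and what passing therefore does
not show.** No platform-specific noise, batch effects, probe-level
artifacts, or gene–gene correlation beyond the planted program and the
block-structured decoys; gene symbols match exactly (case-insensitively),
so the probe-mapping ambiguity of real platforms is absorbed entirely by
the coverage-based N/A rule. Passing tests demonstrate that the
*machinery* — stratification, bookkeeping, permutation control,
classification — behaves as specified under proportional-hazards truth;
they say nothing about whether any real signature is prognostic. One
deliberate sign difference from real cohorts: with $\beta = 1$ the
program's prognostic harm dominates the pCR benefit, so the synthetic
predicted-sensitive (program-high) group has the *worse* DRFS, whereas
real taxane-anthracycline cohorts report the opposite direction; the
Kaplan–Meier separation checks are two-sided and unaffected, but the
DRFS3y PPV/NPV of the synthetic benchmark should not be read as estimates
of what real cohorts yield. Under the same sign regime the retrospective
clustering rule (high-risk $\mapsto$ insensitive) is anti-aligned with
response, so its pCR/RD metrics in the demo sit below the centroid's —
visible in `analysis/05_chemo_response.R`'s output.

# Numerical and design choices

* Duplicate gene rows collapse by per-gene **maximum** at read time
  (preserves dynamic range for rank-based similarity); duplicate symbols
  within a signature collapse to the first occurrence with a warning.
* Symbol matching is exact and case-insensitive; no identifier
  translation (out of scope, keeps the artifact download-free). Survival
  times are converted to years at read time via the manifest's
  `time_unit`.
* Spearman ties use the average-rank convention (`stats::cor`).
* Efron tie handling and two-sided Wald P for Cox models: conventional and
  stable at these sample sizes. Monotone-likelihood fits are flagged
  non-converged and surface as NA cells rather than errors.
* Rate ties in the candidate ranking break by ascending median log-rank P,
  then lexicographic id; adjusted-P ties by descending adjusted
  significant-rate, then id.
* Subset screens (e.g. ER-negative) apply a clinical predicate to the
  samples before stratification and keep the parent dataset id, so QC
  bookkeeping stays attached to the dataset; subsets that fall below 10
  samples become N/A cells rather than errors.
* All generators are pure functions of (configuration, seed); seeded
  helpers restore the caller's RNG state. The full pipeline writes every
  artifact as TSV/YAML and is bitwise reproducible from (inputs, config),
  which the test suite asserts.
* Analysis problem sizes (10–16 datasets of 120–200 samples, 50–200
  random signatures per null, 4,000-gene universes for discrimination
  studies) were chosen as the smallest sizes at which the planted effects
  are comfortably detectable; the same code runs unchanged at the
  real-study scale (351 signatures × 31 datasets, 1,000 permutations).

# Known limitations

* The first-bifurcation split can be hijacked by whatever expression
  structure dominates the signature's genes; this is intrinsic to the
  method (and is precisely what the differential index detects), not a
  defect of the implementation.
* Log-rank cells computed on one dataset against many signatures are
  correlated; none of the rankings model this, again matching the
  screening procedure itself.
* The c-index for binary groupings is attenuated toward 0.5 by
  within-group risk ties (see above).
* Proportional-hazards diagnostics, time-dependent covariates, competing
  risks and FDR summaries are out of scope.
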