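---
title: "Selecting and validating few-asset economic clustering models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating few-asset economic clustering models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Asset-based wealth indices summarize a household's economic position from
its ownership of goods and its housing characteristics.  The standard
PCA-based index needs answers to twenty or more questions, which is
impractical in time-constrained settings such as trauma registries.
`econclust` instead searches for a *small* set of categorical asset
questions — `n_assets` of them, five by default, always including the
rural/urban setting — whose survey-weighted k-medoids clustering splits the
population into maximally distinct groups.

The objects being clustered are **asset-answer profiles**: households
answering all model questions identically are interchangeable, so they are
collapsed into one profile whose weight is the sum of the member
households' survey weights.  Since both the PAM objective and the weighted
silhouette treat weights as replicate counts, clustering profiles is
*exactly* equivalent to clustering households (a property the test suite
asserts against household-level computation), while keeping every instance
small enough for the exhaustive search over asset subsets.

Dissimilarity is Gower's coefficient, which for all-nominal variables
reduces to simple matching: the fraction of model variables on which two
profiles differ.  All variables — including binary ownership and the
setting — are treated as nominal; no ordinal scoring of levels and no
per-variable weights are applied.

# Model search and selection

For each candidate subset (every `n_assets`-subset of the eligible
variables containing the forced variables) and each cluster count $k$ in
`k_min..k_max`, the pipeline is: aggregate profiles, Gower matrix, weighted
PAM, weighted average silhouette width (ASW).  Two selection rules are
offered:

* `max_asw`: the global ASW argmax over all (subset, $k$) candidates.
* `threshold` (default): the smallest $k$ whose best candidate reaches
  `asw_threshold` (default 0.70, the Kaufman–Rousseeuw level for a
  "strong" clustering structure), then the subset with the highest ASW at
  that $k$.  If no $k$ qualifies, the rule falls back to `max_asw` with a
  warning.

Ties on ASW resolve to the lexicographically first asset subset, then the
smaller $k$, so selection is reproducible from the score table alone.

**Choosing `k_min`.**  With well-separated groups the best-candidate ASW is
high at *every* coarse $k$: merging one pair of distinct groups leaves all
other profiles with silhouette near 1, so even an under-clustered solution
typically scores above 0.70.  The threshold rule therefore tends to select
$k =$ `k_min`, and `k_min` should be set to the smallest number of economic
strata the analyst considers interpretable — it is a substantive choice,
not a tuning constant.  In the packaged synthetic study (four planted
groups) the search runs over $k \in 4..10$ on the same reasoning that a
DHS-scale analysis searching $5..20$ reads its lower bound as "at least
five strata".

**Prevalence filter.**  Binary ownership variables whose survey-weighted
positive prevalence is below `min_prevalence` (default 10%) are excluded:
groups defined by rare assets would cover tiny population shares.  The
*positive* level of a two-level variable is by convention the **second
declared level** (declare `c("no", "yes")`); multi-level variables (fuel,
water source, floor material, …) always qualify.  Both the filter and the
convention can be overridden in the config.

# Weighted PAM: exactness and determinism

`weighted_pam()` minimizes $\sum_i w_i\, d(i, \mathrm{medoid}(i))$.
Instances with $\binom{n}{k} \le$ `exact_limit` (default 5000) are solved
by exhaustive enumeration of medoid subsets, so the result is the certified
global optimum; the lexicographically first optimal subset is returned on
ties.  Larger instances use the classic deterministic BUILD+SWAP local
search (greedy seeding; repeated best single exchange under strict cost
decrease, with a $10^{-12}$ tolerance so floating-point noise cannot cycle).
Local search can terminate in a solution from which no *single* swap
improves even though a cheaper medoid set exists; certifying the affordable
instances removes that failure mode exactly where the profile aggregation
makes instances small.  Nearest-medoid ties are broken toward the
lowest-indexed medoid and each medoid is labeled to its own cluster, making
labels deterministic and permutation-equivariant.

# Weighted silhouette

Weights are replicate counts.  For case $i$ in cluster $C$ with cluster
weight $W_C$:

$$a_i = \frac{\sum_{j \in C} w_j d(i,j)}{W_C - 1}, \qquad
  b_i = \min_{C' \ne C} \frac{\sum_{j \in C'} w_j d(i,j)}{W_{C'}}, \qquad
  s_i = \frac{b_i - a_i}{\max(a_i, b_i)},$$

with $s_i = 0$ when $\max(a_i,b_i) = 0$ or $W_C \le 1$ (an effective
singleton), and $\mathrm{ASW} = \sum w_i s_i / \sum w_i$.  For integer
weights this equals the textbook unweighted silhouette of the
replicate-expanded matrix, and for unit weights the textbook silhouette
itself — both asserted in the tests against independent implementations.
A consequence of the $W_C - 1$ denominator worth knowing: the ASW is *not*
exactly invariant under rescaling all weights by a constant (the medoids,
labels and relative costs are); it converges to the $W_C$-denominator value
as weights grow.  DHS-style weights are selection probabilities on a fixed
scale, so this has no practical effect, but it is the reason the package
never normalizes weights silently.

# Assignment of new participants

A participant answering the model's questions is compared with each
medoid; agreements are counted over the participant's *non-missing*
answers.  A unique best medoid assigns its cluster.  On a tie, the
participant is compared with every reference household (equivalently,
every reference profile — members share its answers exactly): if all
maximally-agreeing households sit in one cluster, the participant joins
it; otherwise the result is `UNASSIGNED`, an explicit outcome that is
preserved in all outputs.  There is no random tie-breaking anywhere.
Counting agreement only over observed answers is the minimal reading of
"most similar" under missingness; a participant with no observed answers
is `UNASSIGNED`.  The stage-2 similarity is the same agreement count as
stage 1 (not Gower over a wider variable set), and reference households
are *not* weighted in the unanimity check — the rule is unanimity, not
weighted majority.

# Outcome summaries and design-based statistics

Three outcomes validate a grouping as a wealth scale: mean child
height-for-age Z-score (HAZ), mean women's literacy (0 = cannot read, 1 =
reads parts, 2 = reads whole sentences), and the mean proportion of a
woman's children who are deceased, computed per woman as
`(sons_died + daughters_died) / children_ever_born` with childless women
excluded.  Individual-level weights are used throughout (child-level
weights for HAZ).

Estimation is design-based: the Hajek ratio mean with Taylor-linearized
variance under the with-replacement PSU approximation, stratified when
stratum/PSU columns are supplied.  When they are not, every observation is
its own PSU, which with equal weights reduces exactly to the classical
$s/\sqrt{n}$ — a closed-form reduction the tests assert.  Group means are
estimated on each group's own subsample and treated as independent
(diagonal covariance); this ignores covariance induced by PSUs spanning
groups, a deliberate simplification noted under limitations.  The one-way
ANOVA is a Wald test on the $G-1$ mean contrasts; eta squared is the
weighted between-group sum of squares over the weighted total sum of
squares, which is invariant to affine rescaling of the outcome and hits 0
(equal means) and 1 (within-group constancy) exactly.  Adjacent-group
tests are unequal-variance t tests on the design-based means and SEs with
Satterthwaite degrees of freedom, reported with significance tiers at
0.05 / 0.01 / 0.005.

# Condensing clusters into broad wealth groups

Models with many clusters (twenty, say) are hard to act on.  Clusters with
*different kinds* of assets but *similar outcomes* can share a wealth
bracket, so condensation clusters the clusters: within each setting
stratum, the three per-cluster outcome means are standardized across that
stratum's clusters (mean 0, sd 1 per outcome — unweighted, because the
objects are the cluster means themselves), a Euclidean distance matrix is
computed, and agglomerative hierarchical clustering is run.  Complete
linkage is the default (average and Ward are options): with at most a few
dozen points in three dimensions, complete linkage's compact,
conservatively merged groups match the use case; the choice is exposed
because it is genuinely open.  Rural and urban populations are condensed
separately, consistent with the practice of building separate rural and
urban wealth scales.

The dendrograms are cut at a common height, chosen as the largest height
whose total group count across strata falls in `target_groups` (default
5–10); if no common height lands in the interval, the finest cut not
exceeding the upper bound is used, with a warning.  Substantive overrides
are explicit: `keep_separate` lists clusters that must never share a group
(e.g. keeping LPG-cooking clusters apart from mixed-fuel ones on
subject-matter grounds); the cut of the offending stratum is refined until
the constraint holds.  Nothing is merged or kept apart automatically on
subject-matter grounds.

**Ordinal ranking** uses mean literacy as the primary key (ascending;
rank 1 = poorest) because literacy is consistently the most discriminating
of the three indicators.  For every adjacent pair the ranking records
whether HAZ (ascending) and child mortality (descending) agree; conflicts
are *reported*, never silently resolved, and literacy ties break by HAZ
then mortality, flagged.

# The synthetic survey generator

`ec_sim_spec()` plants the structure the method assumes: latent economic
groups with characteristic asset signatures.  The defaults describe a
four-group population with a realistic wealth gradient — shares
0.35/0.30/0.20/0.15 from poorest to wealthiest, the two poorer groups
rural; five informative assets (three binary: phone, electricity,
computer; two three-level: cooking fuel, water source) whose signatures
grade from wood/surface-water to LPG/piped; five independent binary noise
assets at 50% prevalence; log-normal survey weights with mean 1 and
$\sigma = 0.4$ (moderate DHS-like variation); 2% per-variable signature
corruption.  Outcomes are group-graded and monotone: HAZ means
$-1.8, -1.2, -0.6, 0.1$ (sd 1), literacy distributions shifting from
mostly-0 to mostly-2, per-child death probabilities
$0.12, 0.09, 0.06, 0.03$, children ever born Poisson(3), measured children
per household Poisson(2).  Every draw flows from the single seed, and the
generator restores the caller's RNG state.

What the fixture does *not* emulate: household-level confounding (outcome
effects attach to the group, the construct the method assumes), informative
missingness, multi-stage sampling with intra-PSU correlation (stratum/PSU
columns are exchangeable labels), and real surveys' much larger asset
pools.  Passing tests on this fixture therefore demonstrate algorithmic
correctness — recovery of a planted partition under mild noise — not
performance on any real population.

The package's reproducibility script (`scripts/acceptance.R`) runs this
study end to end at $n = 5000$ households with the search over
$k \in 4..10$: sizes at which the full exhaustive search completes in well
under a minute while leaving profile tables large enough to exercise both
the exact and heuristic PAM paths.

# Degenerate inputs and numerical conventions

* Candidates with fewer distinct profiles than $k$ are recorded as
  infeasible and skipped, never fatal.
* A stratum with a single cluster passes through condensation uncut; an
  outcome with zero variance across a stratum's clusters is dropped from
  scaling with a warning.
* Clusters with no linked individuals for an outcome get an undefined mean
  plus a warning; condensation requires all three means.
* Equal-cost PAM swaps are rejected (strict decrease, tolerance
  $10^{-12}$); all remaining ties resolve lexicographically.
* Model files are versioned JSON; a fingerprint of the reference table
  (row count + order-invariant hash of household ids) travels with the
  model, and assignment against a mismatched reference warns.
* Asset levels are case-sensitive strings declared in the config; nothing
  is recoded silently, and missingness is a marker, never a level.

# Known limitations

* The threshold selection rule is only as meaningful as `k_min`; with
  strongly separated groups it will select `k_min` itself (see above).
* Adjacent-group t tests and the Wald ANOVA treat group means as
  independent; PSUs spanning groups would induce covariance the diagonal
  approximation ignores.
* The condensation inherits hierarchical clustering's greediness; with
  near-ties in the outcome space, linkage choice can change the grouping,
  which is why the linkage and `keep_separate` are explicit arguments.
* Assignment quality degrades gracefully but silently with missing
  participant answers (fewer observed variables, more ties); the
  `match_count` and `method` columns should be inspected when missingness
  is common.
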