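# econclust

Measuring economic status in low-resource settings usually means a
PCA-based asset wealth index built from twenty or more survey questions —
too many for a trauma registry intake form or a rapid field survey.
`econclust` implements the alternative: find the **few** categorical asset
questions (five by default, always including rural/urban setting) whose
answers partition a population into the most distinct economic groups, so
that new participants can be placed on the population's economic scale by
asking only those questions.

The package is aimed at health-disparities and epidemiology researchers
working with DHS-style household surveys (the user converts recode files to
CSV; the package never parses proprietary formats) and at anyone who needs
a short, population-specific wealth module validated against health
outcomes.

## Method

For every candidate subset *A* of `n_assets` eligible asset variables
(binary ownership variables must have survey-weighted prevalence ≥ 10% by
default) and every cluster count *k* in a range:

1. Households are collapsed into distinct **asset-answer profiles**; a
   profile's weight is the sum of its members' survey weights
   (inverse-probability-of-selection weights, so clustering profiles is
   identical to clustering households).
2. The Gower dissimilarity between profiles — for all-nominal variables the
   simple-matching form *d(i,j) = #mismatches / |A|* — gives a dissimilarity
   matrix.
3. **Weighted k-medoids (PAM)** minimizes Σᵢ wᵢ·d(i, medoid(i)).  Small
   instances are solved exactly by enumeration; larger ones use the
   deterministic BUILD+SWAP search.
4. The clustering is scored by the **weighted average silhouette width**
   ASW = Σ wᵢsᵢ / Σ wᵢ with sᵢ = (bᵢ−aᵢ)/max(aᵢ,bᵢ), weights acting as
   replicate counts.

Model selection is either the global ASW maximum or the *threshold rule*:
the smallest *k* whose best candidate reaches ASW ≥ 0.70 (the
Kaufman–Rousseeuw "strong clustering" level), then the asset subset with
the highest ASW at that *k*.

Around the fitted model the package provides:

* **Assignment** of new participants by medoid matching with the two-stage
  tie-break (tie between medoids → compare against all reference
  households; non-unanimous → explicitly `UNASSIGNED`).
* **Validation**: survey-weighted group means and design-based standard
  errors of child height-for-age Z-score (HAZ), women's literacy (0–2) and
  the proportion of a woman's children who are deceased; weighted one-way
  ANOVA, eta squared, adjacent-group t tests.
* **Condensation** of many clusters into 5–10 interpretable wealth groups:
  agglomerative hierarchical clustering (complete linkage by default) of
  the standardized per-cluster outcome means, separately for rural and
  urban strata, with ordinal ranking by literacy and explicit reporting of
  any disagreement between the three outcome gradients.
* A **synthetic survey generator** with planted economic groups, so the
  whole pipeline is testable without access to restricted microdata.

## Worked example

```r
library(econclust)

# a synthetic DHS-like survey: 2,000 households, 4 planted wealth groups,
# 5 informative + 5 noise assets, 2% answer corruption
sim <- simulate_survey(ec_sim_spec(n_households = 2000, seed = 42))

cfg <- ec_config(n_assets = 5, k_min = 4, k_max = 8, mode = "threshold",
                 asw_threshold = 0.70, min_prevalence = 0.10)
res <- ec_search(sim$households, cfg)
res$model
#> Economic clustering model: k = 4 clusters, ASW = 0.9237
#>   variables: setting, phone, computer, fuel, water
#>   fitted on 2000 households (30 distinct profiles)
res$model$medoids
#>    setting phone computer     fuel   water
#> 1    rural    no       no     wood surface
#> 9    rural   yes       no     wood    well
#> 20   urban   yes       no charcoal    well
#> 30   urban   yes      yes      LPG   piped
```

The threshold rule stopped at the smallest *k* (4) with a strong model
(ASW 0.92 ≥ 0.70) and picked only informative variables — the noise assets
were rejected.  The four medoids read as an interpretable wealth gradient,
from rural households cooking with wood and drinking surface water to urban
households with computers, LPG and piped water.  Recovery of the planted
groups: `recovery_metrics(sim$labels, res$model)$ari` → **0.971**.

Validating the clusters against women's literacy:

```r
women <- sim$women
v <- validation_stats(res$model$assignment[match(women$household_id,
                                                 names(res$model$assignment))],
                      as.numeric(women$literacy), women$weight)
v
#> Weighted one-way ANOVA: F(3, 1994) = 321.680, p = 2.5e-170
#> Eta squared: 0.2785
#>  group      mean         se   n
#>      1 0.4132664 0.02619203 738
#>      2 0.7144766 0.03707800 567
#>      3 1.1898202 0.04457013 399
#>      4 1.7057814 0.03428299 296
#> Adjacent-group t tests:
#>  group_low group_high      diff        t        df            p    tier
#>          1          2 0.3012102 6.635164 1067.6447 5.143681e-11 p<0.005
#>          2          3 0.4753436 8.198900  852.4188 8.876479e-16 p<0.005
#>          3          4 0.5159613 9.175897  684.8431 5.195946e-19 p<0.005
```

Eta squared says the four-group model accounts for 28% of the variance in
literacy; every adjacently ranked pair differs significantly.  The same
interface (`outcome_summary()`, `condense_clusters()`, `rank_groups()`)
condenses larger models into 5–10 ordinally ranked wealth groups, and
`assign_participants()` places registry patients into the groups from their
answers to the five questions alone.

A command-line wrapper with `simulate`, `search`, `assign`, `condense`,
`rank` and `validate` subcommands is installed at
`system.file("cli", "econclust", package = "econclust")`; every run writes
a JSON manifest with the resolved options and input fingerprints.

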