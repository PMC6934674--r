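# socioscan

Social network analysis of behavioural scan data for wild animal groups that
split their time between a natural context and an anthropogenic one.

## The problem

When a habituated group of wild animals — here, the motivating system is a
macaque group whose home range is bisected by a road where passing motorists
provision them — spends part of its time near humans, two questions arise:

1. **Who goes near the humans?** Do life-history stage (age, sex) and a
   member's position in the group's *ordinary* social network predict how
   much of its time an individual spends in the risky, food-rewarding
   context?
2. **What does human proximity do to the group?** Do association networks
   built from behaviour near humans differ systematically (density,
   centrality, community structure) from networks built from behaviour in
   the natural context?

Both questions must be answered from instantaneous **scan samples** — repeated
group surveys recording each visible individual's location context
(road/forest), behavioural state, and all conspecifics within 1 m — plus
directed affiliative interaction records. Observation effort is unequal
across individuals and contexts, which the analysis has to correct for.

## The method

**Association indices.** Every dyad's edge weight is the half-weight
association index computed within one context and data type:

    HWI(A, B) = 2 N / (n_A + n_B)

where `N` is the number of scans in which the dyad was jointly sighted
(within 1 m, or with a directed interaction; reciprocal sightings within one
scan count once) and `n_A`, `n_B` are the individuals' total sightings in
that context. Proximity networks are undirected; affiliative networks keep
the directed joint count over the undirected denominator and so need not be
reciprocal. Six networks are built: road / comprehensive-forest /
estimated-forest, each for proximity and affiliative data.

**Sampling-effort correction.** The *estimated* forest network averages
dyadic HWI over 100 random samples of forest scans, each matched to the road
data's per-month scan counts, so road and forest networks rest on equal
effort with the same seasonal profile. Spearman rank correlations validate
estimated against comprehensive forest metrics.

**Who goes near the road** is modelled by a permutation-based linear
regression of each individual's percentage of records along the road on age
(adult/non-adult), sex, eigenvector and betweenness centrality, and the top
associate's eigenvector and betweenness centrality (all from the
comprehensive forest proximity network). The response is permuted against
fixed predictors; each term's two-tailed p is its coefficient's exceedance
rate, with sequential stopping per term (max 5,000 permutations).

**Context comparisons** subtract each individual's estimated-forest metric
from its road metric (weighted degree, betweenness, closeness, eigenvector;
both data types — eight comparisons) and test the mean difference against a
sign-flip randomization null with 10,000 resamples. Community structure is
assessed with walktrap clustering and weighted modularity Q.

Because field datasets of this kind are rarely public, the package includes
a first-class synthetic generator (`generate_scan_data()`) that plants known
ground truth — a logistic road-presence model with a sex effect, a
block-structured affinity matrix, monthly road patterns — for power and
calibration studies, and `truth_check()` to score recovery.

## Worked example

```r
library(socioscan)

sim <- generate_scan_data(sim_config(seed = 42))   # 35 individuals, 1,219 scans
bundle <- run_pipeline(sim$scans, sim$interactions, sim$roster,
                       pipeline_config(seed = 1))
bundle
#> <result_bundle>
#>   networks: road_proximity, road_affiliative, forest_proximity,
#>             forest_affiliative, estimated_forest_proximity,
#>             estimated_forest_affiliative
#>   32 individuals, 1219 scans, 1920 interaction records
#>   8 randomization comparisons; regression adjusted R^2 = 0.838

bundle$regression
#> <perm_reg_result>
#>               term coefficient iterations      p
#>        (Intercept)  8.17858175         50 0.7060
#>                age -1.75356495         50 0.7450
#>                sex  6.48343826       5000 0.0002
#>        eigenvector  3.41061021         50 0.7250
#>        betweenness  0.13026791        502 0.1670
#>  assoc_eigenvector  2.67177516         50 0.8630
#>  assoc_betweenness -0.02126363         50 0.8630
#>   adjusted R^2 = 0.838; omnibus p = 2e-04
```

The sex coefficient (+6.5 percentage points, p = 0.0002 at the permutation
floor after the full 5,000 iterations) recovers the generator's planted
male bias in road presence; null terms stop after ~50 permutations, which is
the sequential rule doing its job. The comparison table contrasts road and
estimated-forest networks per metric:

```r
bundle$comparisons[, c("data_type", "metric", "direction", "p")]
#>     data_type      metric          direction          p
#> 1   proximity      degree  greater in forest 0.00009999
#> 2   proximity betweenness greater along road 0.58934107
#> 3   proximity   closeness  greater in forest 0.00009999
#> 4   proximity eigenvector  greater in forest 0.00069993
#> 5 affiliative      degree  greater in forest 0.00009999
#> 6 affiliative betweenness greater along road 0.07369263
#> 7 affiliative   closeness greater along road 0.00009999
#> 8 affiliative eigenvector  greater in forest 0.03179682
```

Road networks are sparser than forest ones (road proximity density 0.933 vs
forest 1.0 in this run), the signature of reduced cohesion near humans.
`write_bundle(bundle, "out/")` exports every network (edge list + GraphML),
metric table, the validation, regression, comparison and class-summary
tables, and a JSON run manifest. A thin command-line wrapper lives at
`inst/scripts/socioscan.R` (`simulate` and `run` subcommands).

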