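---
title: "Methods: association networks, permutation inference and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association networks, permutation inference and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioscan)
```

This vignette is the package's own account of its statistical machinery: the
models and procedures, the assumptions they rest on, the tunable parameters
and their defaults, the numerical choices, and what the synthetic generator
does and does not emulate.

## Data model

The unit of observation is one individual's record within one instantaneous
scan of the group: a context (`road` or `forest`), one of eleven behavioural
states, and the set of conspecifics within 1 m. Directed affiliative events
are separate records (actor, recipient, context); A→B and B→A are distinct.
Record-level context is authoritative for sighting tallies and road
proportions. A *scan* is classed road at the group level if it contains at
least one road record, forest otherwise; this scan-level classification
defines the subsampling pool. Infants and individuals not present for the
full study are excluded before analysis; where an excluded individual
appears only in a neighbour set it is pruned from the set rather than
dropping the focal record, because the HWI denominator needs the focal
individual's full sighting count. An individual observed with no neighbours
still counts as one sighting for the same reason.

## Half-weight association indices

For a dyad (A, B) within one context and data type,

$$\mathrm{HWI}(A,B) = \frac{2N}{n_A + n_B},$$

with $N$ the number of scans containing a joint sighting (proximity: A lists
B or B lists A, counted once per scan; affiliative: at least one A→B event,
direction preserved, repeats within a scan counted once) and $n_A$, $n_B$
the individuals' total sightings in that context. An always-together dyad
scores 1; dyads never co-observed score 0 rather than missing, so downstream
matrices are complete. The affiliative index pairs a *directed* numerator
with the undirected denominator — the only reading under which affiliative
indices can be non-reciprocal while proximity indices are — so affiliative
matrices are directed and need not be symmetric. Dyads are never self-paired
(zero diagonal) and indices cannot exceed 1 while the joint-count invariant
$N \le \min(n_A, n_B)$ holds; a violation (possible only with inconsistent
input) triggers a warning, not silent clamping.

The `top associate` of an individual is the arg-max of its row in the
comprehensive forest proximity matrix; ties break to the lexicographically
smallest id for determinism, and an all-zero row is an error, because no
associate is definable for a fully isolated individual.

## Six networks and the sampling-effort correction

Networks carry one edge per nonzero HWI (zero dyads are absent edges).
Because the group spends far more time in the forest than at the road, the
road and comprehensive forest networks rest on very different effort. The
*estimated* forest network corrects this: per-month road scan counts define
quotas; each of `n_subsamples` (default 100) random samples draws that many
forest scans per month without replacement; HWI is recomputed within each
sample and averaged dyad-wise. Draws are seeded and invariant to input row
order (pools are sorted before sampling). When the quotas equal the full
forest availability every sample is the whole pool and the estimated network
equals the comprehensive one exactly — a structural identity the tests
exercise. Spearman rank correlations (average ranks on ties; exact
permutation p for n ≤ 9 without ties, t-approximation otherwise) compare
estimated against comprehensive metrics; by default the road comparisons use
the estimated network, with a switch to the comprehensive one.

## Network metrics

HWI is a similarity, so geodesic computations use distance $= 1/w$, the
standard convention in the network software family used for this kind of
analysis. Density ignores weights (edge presence over possible edges).
Weighted degree is the sum of incident weights (in + out when directed).
Betweenness is standard weighted shortest-path-count betweenness; a
"sum of edge weights along geodesics" variant sometimes described in
methods tables is nonstandard and is not what the cited software computes,
so the standard quantity is implemented and the discrepancy documented here.
Closeness is $1/\sum d$ over *reachable* nodes (isolates score 0); both
weighted and binarised modes are available, weighted being the default.

Eigenvector centrality is computed by deterministic power iteration on
$W + sI$ with a uniform start, tolerance $10^{-10}$ on the iterate, and a
10,000-iteration cap; the small shift $s = 0.05\max_i\sum_j w_{ij}$ breaks
the period-2 oscillation that plain power iteration exhibits on bipartite
spectra (a star graph is the canonical failure) without changing the
eigenvectors. Directed graphs use the right dominant eigenvector of $W$,
falling back to the symmetrised matrix if iteration fails to converge.
Scores are max-normalised; the returned vector satisfies
$Wx = \lambda x$ to $10^{-8}$, which the tests assert, and the undirected
case is cross-checked against an independent library implementation.

Community structure uses walktrap agglomeration (4-step walks) on the
weighted graph — directed graphs are first collapsed by summing reciprocal
weights — cut at the maximum-modularity partition. If no partition beats the
trivial single community, one community with $Q = 0$ is returned; an
edgeless graph yields one singleton cluster per node. Labels are renumbered
in order of first appearance along sorted vertex ids so runs are comparable.

## Permutation regression

The response is each individual's percentage of records along the road
(percent scale, matching coefficient magnitudes of a few points). Predictors:
age (1 = adult, with subadults coded adult), sex (1 = male), own and top
associate's eigenvector and betweenness centrality from the comprehensive
forest proximity network. The intercept therefore represents non-adult
females. Interaction terms are excluded by default; degree centrality is not
a predictor because it is nearly collinear with eigenvector centrality on
dense similarity networks (the suite checks Spearman ρ > 0.8 on generated
data), and closeness is omitted to keep the model comparable with related
analyses. Dominance rank is intentionally absent.

Reported coefficients are plain OLS estimates on the unpermuted data. The
test permutes the raw response against fixed predictors (a Freedman–Lane
residual-permutation option is provided); after each refit, term $j$'s
count of $|b^*_j| \ge |b_j|$ updates and its two-tailed
$p = (1 + \text{count})/(1 + \text{iterations})$ — the add-one correction
keeps $p > 0$. A term stops once at least 50 permutations are in and the
binomial standard error of $\hat p$ falls below $0.1\,\hat p$, or at
`max_iter` (default 5,000). This is the sequential convention of the
permutation-regression software family this design follows; clearly null
terms stop after ~50 iterations while significant terms run to the cap,
which is why reported iteration counts are informative in themselves. The
exact constant used by any particular historical software run is not
asserted — ours is documented here. Exceedance comparisons use a relative
$10^{-12}$ tolerance so floating-point ties count as ties. An exhaustive
mode enumerates all $n!$ permutations (n ≤ 8) with exact
$p = \text{count}/n!$; `exact_perm_lm()` provides the same enumeration
through an independent fitting route as a test oracle. Permutation p-values
are invariant to affine rescaling of the response for slope terms, which the
suite asserts.

## Randomization comparisons

For each metric and data type, per-individual differences
$d_i = \text{road}_i - \text{estimated forest}_i$ are formed (positive =
greater along the road; the direction label in every output makes the sign
convention explicit). The default null is the standard paired randomization
test: each resample flips the sign of every $d_i$ independently, and
$p = (1 + \#\{|\bar d^*| \ge |\bar d|\})/(1 + B)$ with $B$ = 10,000. A
literal "resample the observed differences and compare to the observed
mean" reading of this procedure yields a null centred on the observed mean
and cannot produce small p-values; it is retained as the
`centered_bootstrap` mode (resampling with replacement from mean-centred
differences) for audit, but sign-flipping is the default because it is the
standard test consistent with reporting significant context effects. An
exhaustive sign-flip mode enumerates all $2^n$ assignments (n ≤ 20) for
exact p. All-zero difference vectors return p = 1 with a warning.

Class-level summaries group the same differences by age-sex class
(mean ± sd; single-member classes report sd = 0 with an explicit flag), and
the risk-perception analysis compares per-record neighbour counts across
contexts within class by Mann-Whitney U (midranks; exact p by labeling
enumeration when the pooled sample is ≤ 12 without ties, otherwise the
normal approximation with tie and continuity corrections). Records are
treated as independent observations, replicating the field procedure; the
pseudo-replication caveat is documented rather than "fixed".

## The synthetic generator

`sim_config()` defaults encode the study conditions the pipeline targets:
35 individuals (9 adult males, 11 adult females, 2 subadult males, 6
juvenile males, 5 juvenile females, 2 infants; one adult male present for
only the first three months), 1,219 scans over 2016-08 – 2017-01 (~203 per
month), and monthly road probabilities averaging 19.8%. Remaining defaults
are generator choices, set once to values a field ecologist would call
realistic and not revisited: detectability 0.9 on the road (open habitat)
vs 0.6 in forest; block-structured affinities (juveniles vs
adults/subadults, mirroring the age-assorted clustering such groups show)
of 0.12 within and 0.05 between blocks with lognormal dyadic spread
σ = 0.4; a directed affiliative event rate of 0.05 × affinity per
co-present scan, which yields forest affiliative densities near 0.5–0.7 and
much sparser road affiliative networks; and a logit road-presence model
$\operatorname{logit} p_i = -0.5 + 0.95\,[\text{male}] + 0.3\,z(\text{betweenness})$,
whose sex contrast implies a ≈ +6 percentage-point male–female gap in road
proportion under the default detectabilities — the planted effect the
power analysis targets. During a road-context scan each individual is on
the road with probability $p_i$ and is recorded only there; forest-side
detections during road scans are not generated, which makes record-level
and scan-level forest coincide. Co-occurrence within 1 m is a per-scan
Bernoulli per dyad with probability equal to the dyadic affinity,
symmetrised into both members' neighbour sets. `truth.json` (and the
in-memory `truth` object, which additionally carries the realized affinity
matrix) records every planted parameter.

What the generator does **not** emulate: spatial structure and movement
(neighbour sets are exchangeable given affinity, with no spatial
autocorrelation), behavioural-state dynamics (states are i.i.d. draws, and
affiliative events are independent of the proximity draw rather than
entailed by it), observer effects beyond flat per-context detectability,
demographic change beyond one part-time male, and temporal dependence
between consecutive scans. Passing tests therefore show that the estimators
and tests behave correctly under the assumed sampling model — unbiased
tallies, calibrated nulls, power against planted effects — not that real
field data meet those assumptions.

## Problem sizes, tolerances and degenerate inputs

The test suite runs most property checks on three-month, 240-scan
simulations and reserves the full six-month default for the end-to-end
checks; calibration uses 500 null replicates (size within two binomial
standard errors of 0.05 for both the permutation regression and the
randomization test) and power uses 200 replicates of the full design
(planted sex effect detected in ≥ 80%; observed near 100%). Exhaustive
enumerations back every sampled p-value: all 720 permutations at n = 6, all
4,096 sign assignments at n = 12, all 20 labelings for the classic
Mann-Whitney example, all 120 rank permutations for the n = 5 Spearman p.
Closed-form centrality values (path betweenness 1, star eigenvector ratio
$\sqrt 3$, uniform-graph $Q = 0$) are reproduced to $10^{-8}$.

Degenerate inputs are defined, not crashed on: empty graphs warn and return
zero metrics; isolated nodes get closeness 0; constant vectors flag
undefined Spearman ρ; all-zero difference vectors give p = 1; an empty
analysis roster, an infeasible monthly quota (named month), and a
rank-deficient design (named columns) are errors.

## Known limitations

Closeness on directed graphs uses outgoing geodesics over the reachable
set; other conventions exist. The betweenness wording discrepancy noted
above means numerical equality with analyses that truly summed edge weights
along geodesics is not expected. The regression treats a proportion as a
linear response, replicating the analysis design it mirrors rather than a
GLM alternative. Monthly matching equalises scan counts, not individual
sighting counts; HWI absorbs the remainder. The sequential stop rule makes
per-term iteration counts seed-dependent near the threshold, and p-values
just above/below 0.05 should be read with that in mind.
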