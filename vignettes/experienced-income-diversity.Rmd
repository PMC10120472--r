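---
title: "Measuring the income diversity of urban encounters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the income diversity of urban encounters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbandiv)
library(data.table)
```

## The problem

Residential segregation statistics describe where people *live*; they say
little about whom people actually *meet*. When mobile-phone mobility data
record which venues individuals visit and for how long, one can ask a more
behavioural question: how evenly is the time spent at a place shared
between income groups, and how exposed is each individual to income groups
other than their own? `urbandiv` implements this measurement chain —
experienced income diversity at places, for individuals, and aggregated
over census geographies — together with the machinery needed to explain a
*change* in diversity: counterfactual downsampling that isolates
behavioural factors, estimation of exploration behaviour, area-level
regression, and a policy-stringency trade-off analysis. Because real
device-level mobility panels are license-restricted, the package ships a
generative model of a synthetic city so that every stage can be validated
against known ground truth.

## Exposure vectors and diversity

Users are assigned to `Q` income quantiles (default `Q = 4`) by the median
household income of their home census block group (CBG), split into
equal-count groups per city; ties at a boundary income share a quantile.
For each place $\alpha$ and each two-month analysis window, the exposure
vector is the share of (weighted) dwell time contributed by each quantile:

$$\tau_{q\alpha} \;=\; \frac{\sum_{i \in q} w_i\, d_{i\alpha}}
{\sum_i w_i\, d_{i\alpha}},$$

where $d_{i\alpha}$ is individual $i$'s dwell at $\alpha$ and $w_i$ an
optional post-stratification weight (consumed, never estimated here). The
evenness diversity of an exposure vector is

$$D_\alpha \;=\; 1 - \frac{Q}{2(Q-1)} \sum_q
\left|\tau_{q\alpha} - \tfrac{1}{Q}\right|,$$

which at `Q = 4` is the familiar $1 - \tfrac{2}{3}\sum_q |\tau_q -
\tfrac14|$: exactly 1 when every quantile contributes a quarter of the
time, exactly 0 when a single quantile contributes everything. The
general-`Q` normalisation $Q/(2(Q-1))$ is chosen so those endpoints are
reached for every `Q`. A normalised-entropy variant
($-\sum_q \tau_q \ln \tau_q / \ln Q$) is provided; the two are strongly
rank-correlated, which the test suite checks on random Dirichlet draws.

An individual's exposure is the time-share mixture of the places they
visited, $\tau_{iq} = \sum_\alpha \tau_{i\alpha}\, \tau_{q\alpha}$, with
$\tau_{i\alpha}$ their dwell share at $\alpha$ within the same window, and
$D_i$ applies the same evenness formula. CBG-level diversity is the
unweighted mean of $D_i$ over a CBG's observed residents. Changes are
reported as percentages against the same calendar month of the baseline
year, $\Delta D(t) = 100\,(\bar D(t) - \bar D(2019, m(t)))/\bar D(2019,
m(t))$, the same month-matched ratio convention used by
`deseasonalize()`.

```{r diversity}
evenness_diversity(c(0.25, 0.25, 0.25, 0.25))
evenness_diversity(c(1, 0, 0, 0))
entropy_diversity(c(0.5, 0.5, 0, 0))
```

### Preprocessing contract

`filter_stays()` keeps stays strictly between 10 and 240 minutes. The
boundaries are deliberately exclusive: the source wording ("longer
than… shorter than") supports the strict reading, and the synthetic
generator emits dwell inside `[10, 240]` so only exact boundary values are
affected either way. `attribute_pois()` assigns each stay to the nearest
POI by great-circle (haversine) distance within 100 m — at that scale the
choice of geodesic is immaterial — breaking exact ties towards the
smallest POI id so attribution is reproducible. The observation filter
(more than 300 min observed per day) is provider-side in real data; it is
exposed with a `strict` mode requiring a ping log and a `lenient` mode for
fully-observed synthetic panels. Analysis windows span exactly two
calendar months, labelled by the *last* month (window `"2020-04"` covers
March–April 2020), and consecutive windows overlap by one month; a stay in
the overlap belongs to both.

Places enter the reported mean diversity only with at least 2 distinct
visitors and 30 dwell-minutes in the window (configurable); the source
material only requires "a sufficient number of visits", so these minima
are package choices.

## The synthetic city and the Social-EPR generator

`generate_world()` builds a circular city: CBG centroids uniform in a
disk (default radius 25 km), lognormal CBG median incomes, POIs jittered
0.4 km around a CBG centroid with a category/subcategory vocabulary, and
users with home CBGs. Each POI inherits a *dominant income quantile* from
its CBG — the generator-side ground truth for "majority income quantile
group". PUMA-like fixed-effect geographies are angular sectors of the
disk.

`simulate_period()` generates one month of visits per user from a social
exploration and preferential return (Social-EPR) process. Visit occasions
arrive as a homogeneous Poisson process (default 2 occasions/day per
quantile). At an occasion where the user has already visited $S$ distinct
places, they *explore* with probability $\min(1, \rho S^{-\gamma})$
(forced at $S = 0$; defaults $\rho = 0.6$, $\gamma = 0.21$), otherwise
*return* to a known place with probability proportional to its past visit
count. An exploration is *social* with probability $\sigma_s$ (default
0.4): the new place is drawn from POIs whose dominant quantile differs
from the user's own, otherwise from same-quantile POIs, in both cases
excluding already-visited places and weighting candidates by a
distance-decaying kernel and by any subcategory preference multipliers.

Three numerical choices deserve note:

* **Distance kernel.** Candidate weight is $(d/s + d_0)^{-\beta}$ with
  $d$ the home-to-POI distance, offset $d_0 = 0.25$ km, default $\beta =
  1.5$, and $s$ the scenario's `distance_shrink_factor`. A pure power law
  is scale-free — rescaling all distances would not change normalised
  weights at all — so the shrink factor acts through the offset:
  $s < 1$ inflates effective distances and concentrates trips near home.
* **Activity reduction is thinning.** A scenario's per-quantile activity
  multiplier is applied as binomial thinning of the *realised* occasion
  sequence rather than by lowering the Poisson rate before the dynamics.
  The marginal process is still Poisson at the multiplied rate, but the
  underlying preference dynamics are untouched — which is precisely what
  the counterfactual decomposition means by "activity reduction": under
  an activity-only scenario the residual behavioural factor is zero by
  construction, and under a shared seed the reduced month is an exact
  subset of its baseline month.
* **Dwell times** are truncated-lognormal on $[10, 240]$ minutes drawn by
  inverse-CDF transformation (one uniform per visit), so every synthetic
  stay passes the ingest filter and per-user random streams stay aligned
  across scenarios. One global seed expands into per-user substreams
  derived from the user id, making trajectories reproducible regardless
  of user ordering or parallel grouping.

An optional sinusoidal monthly modulation of activity (peaking in July)
exists solely to exercise deseasonalization round-trips.

What the generator does *not* emulate: day-of-week schedules, road
networks, household structure, panel attrition and ping gaps, home-CBG
estimation error, or calibration to any real device panel. Passing tests
therefore demonstrate that the estimators recover the behaviour of this
model class — not that real mobility data satisfy the model.

```{r world}
w <- generate_world(world_config(n_users = 300, n_pois = 200, n_cbgs = 40,
                                 seed = 7))
st <- simulate_period(w, epr_params(), scenario_config("2019-04"),
                      n_days = 14, seed = 7)
profiles <- w$user_table[, .(user_id, home_cbg, income_quantile, weight)]
head(st, 3)
mean(diversity_panel(st, profiles, "individual")$D)
```

## Counterfactual decomposition

To attribute a diversity drop between a baseline month and an observed
month to behavioural factors, visits are removed at random from the
baseline panel until its dwell matches the observed month's, under three
nested stratifications: a single stratum (scenario *total*), income
quantile × seven travel-distance bins ([0,1), [1,3), [3,5), [5,10),
[10,20), [20,40), [40,∞) km from home-CBG centroid to POI)
(*quantile_distance*), and additionally by major place category. Within a
stratum, removal proceeds in uniformly random order and stops at the
first crossing at or below the target, so the match error is at most one
visit's dwell (≤ 240 min); the counterfactual is always a strict subset
of the baseline and visits are never added — a stratum whose target
exceeds its source keeps everything and warns. Matching is on dwell
minutes, not visit counts, and on stratum marginals rather than per-user
totals (per-user matching is not part of the documented interface).

The decomposition telescopes exactly:
contribution (i) $= \bar D_{2019} - \bar D_{cf(i)}$,
(ii) $= \bar D_{cf(i)} - \bar D_{cf(ii)}$,
(iii) $= \bar D_{cf(ii)} - \bar D_{actual}$, with shares dividing by the
total gap. Replicates (default 10, seeds `seed + r`) give a mean and
standard error. When judging whether a counterfactual *matches* the
observed panel, the right yardstick is two standard errors of the
*difference*, $2\,\mathrm{SD}_{rep}\sqrt{1 + 1/n_{reps}}$: the observed
panel is itself a single realisation of the same removal process, so
comparing it to the replicate mean using the standard error of the mean
alone would reject a true null about half the time.

## Behavioural estimation

`label_explorations()` flags each first visit to a place within the
estimation window ("new place" is defined within the window's history —
panel history before the window is unavailable, so measured exploration
is an upper bound on true exploration). `fit_exploration_law()` fits
$p(S) = \rho S^{-\gamma}$ to the empirical exploration fraction per
distinct-place count by count-weighted least squares on the log–log
scale, excluding $S = 0$ (forced exploration carries no information about
$\rho, \gamma$); a binomial maximum-likelihood fit is available behind
`method = "mle"`.

Social exploration is estimated directly:
$\hat\sigma_s$ is the fraction of explorations landing at places whose
majority income quantile differs from the explorer's, with an exact
binomial confidence interval. Majority labels are computed once on a
baseline window and held fixed across periods — $\sigma_s$ should
reflect choice behaviour, not pandemic-era re-labelling — with ties
broken towards the lowest quantile, flagged, and excluded from the
denominator by default. Label error is assessed separately against the
generator's dominant quantiles; among high-traffic places the agreement
is high, while thinly-visited places in mixed neighbourhoods can
genuinely attract a non-dominant majority.

`subcategory_popularity()` reports $f_r$: the share of individuals whose
top-$r$ most-visited places (ties by larger dwell, then smaller POI id)
include a given subcategory, and `popularity_change()` ranks shifts
against a baseline period.

## Area-level heterogeneity and the stringency trade-off

`fit_fe_ols()` regresses CBG-level diversity (or its percentage change)
on standardized covariates with absorbed geographic fixed effects:
within-group demeaning followed by OLS, numerically identical to dummy
variables, with classical standard errors on the dummy-model degrees of
freedom $n - k - G$ (HC1 available behind a flag, matching the "simple
linear regression" framing). Collinear columns are dropped left-to-right
by rank test with a VIF report. The place-visit feature block
`build_place_vector()` binarises, per individual, subcategories holding
more than 0.3% of their dwell (among subcategories with at least 100
venues) and aggregates to the CBG as the share of residents exceeding the
rule — the resident-mean reading of an ambiguous aggregation, chosen so
the feature stays in $[0,1]$ and uses all residents.

`stringency_tradeoff()` correlates the monthly diversity change per metro
area with a policy stringency index (0–100), reporting Pearson $\rho$
with a two-sided p-value, a companion OLS slope with CI, and a lag-1
autocorrelation diagnostic of the diversity series (time-series models
for the autocorrelated residual are out of scope).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle at
small scale (triple-loop exposure mixtures, all-pairs attribution
distances, enumerated removal orders, dummy-variable OLS, per-user sort
oracles) and the estimation chain end-to-end at moderate scale:
parameter-recovery studies run 50 seeds of roughly $10^5$-event panels
(1,000 users × 50 days), counterfactual attribution uses 2,000-user
months, and the stringency check simulates 24 months at 1,200 users.
These sizes were chosen as the smallest at which the sampling error of
the relevant statistics is comfortably below the effects being tested.

## Known limitations

* Exposure vectors ignore co-presence timing within a window: two
  quantiles visiting the same place at disjoint hours still count as
  mixing, exactly as in the dwell-share definition.
* The direct $\hat\sigma_s$ estimator conditions on majority labels;
  label noise at low-support places propagates into a small attenuation
  that the generator cross-check quantifies but the estimator does not
  correct.
* The WLS exploration-law fit uses event-count weights rather than the
  binomial variance profile; at the panel sizes validated the difference
  is well inside the confidence intervals, and the MLE flag exists for
  users who want the likelihood-exact fit.
* Deseasonalization is month-matched ratio normalisation only; no
  seasonal curve is fitted.
* The counterfactual framework only removes visits: scenarios requiring
  added or re-timed visits are out of scope by design.
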