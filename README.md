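# urbandiv

Experienced income diversity of urban encounters: who actually shares
time at the places of a city, and why that mixing changes when mobility
is disrupted.

`urbandiv` is for researchers working with stay/visit panels (device id,
start time, dwell, venue) joined to venue and census tables. Residential
segregation indices describe where people live; this package measures
the *behavioural* counterpart on co-location data and provides the full
analysis chain around it:

* **Diversity metrics.** For each place α and two-month moving window,
  the exposure vector τ_qα is the share of dwell time contributed by
  each of Q income quantiles (quantiles assigned from home-CBG median
  household income, equal-count per city). Evenness diversity is

      D_α = 1 − Q/(2(Q−1)) · Σ_q |τ_qα − 1/Q|

  (at Q = 4 the familiar `1 − (2/3) Σ|τ_q − 1/4|`): exactly 1 when every
  quantile contributes equal time, exactly 0 when a single quantile
  contributes all of it. Individual exposure is the time-share mixture
  τ_iq = Σ_α τ_iα τ_qα, with the same evenness statistic; CBG diversity
  is the resident mean. An entropy variant is included. Changes are
  reported as ΔD(t) = 100·(D̄(t) − D̄(2019, month))/D̄(2019, month).
* **Ingest.** Strict (10, 240)-minute stay filter, nearest-POI
  attribution within 100 m (haversine, smallest-id tie break), per-city
  income-quantile assignment, 2-month moving windows, per-day
  observation filter.
* **Counterfactual decomposition.** Stratified random removal of
  baseline visits to match an observed month's dwell — one stratum, or
  income quantile × 7 distance bins (× place category) — splits a
  diversity drop into activity (i), distance-shift (ii) and residual
  behavioural (iii) factors that telescope exactly.
* **Behavioural estimation.** Exploration events, the exploration law
  p(S) = ρS^−γ, the social exploration probability σ_s (explorations
  landing where the visitor's income group is not the place's majority),
  and top-r subcategory popularity f_r.
* **Heterogeneity.** Fixed-effects OLS of CBG diversity on standardized
  covariates with absorbed PUMA dummies, and the Pearson trade-off
  between monthly diversity change and a 0–100 policy stringency index.
* **Synthetic city.** A Social-EPR (social exploration and preferential
  return) generator with configurable pandemic-style behaviour changes —
  per-quantile activity cuts, distance preference shifts, lowered σ_s,
  subcategory preference shifts — so every stage is testable with known
  ground truth; real panels of this kind are license-restricted.

## Worked example

Simulate a baseline month and a "pandemic" month in the same synthetic
city (activity cut per quantile, social exploration lowered from 0.40 to
0.25), then measure the drop and decompose it:

```r
library(urbandiv); library(data.table)

w <- generate_world(world_config(n_users = 1000, n_pois = 500,
                                 n_cbgs = 100, seed = 3))
profiles <- w$user_table[, .(user_id, home_cbg, income_quantile, weight)]
ep <- epr_params(rho = 0.6, gamma = 0.21, sigma_s = 0.4,
                 event_rate_per_quantile = 2)

baseline <- simulate_period(w, ep, scenario_config("2019-04"),
                            n_days = 30, seed = 11)
pandemic <- simulate_period(
  w, ep,
  scenario_config("2020-04",
                  activity_multiplier_per_quantile = c(0.85, 0.7, 0.55, 0.45),
                  sigma_s_override = 0.25),
  n_days = 30, seed = 11)
baseline[, window := "2019-04"]; pandemic[, window := "2020-04"]

ip_base <- diversity_panel(baseline, profiles, "individual")
ip_pand <- diversity_panel(pandemic, profiles, "individual")
delta_percent(ip_pand, ip_base)
#>     window baseline         D D_baseline delta_pct
#> 1: 2020-04  2019-04 0.4950558  0.6832447 -27.54341
```

Mean individual diversity fell 27.5% against the same-month baseline.
The behavioural estimators recover the planted σ_s from the pandemic
panel:

```r
ev <- label_explorations(pandemic)
labs <- w$poi_table[, .(poi_id, majority_quantile = dominant_quantile,
                        tie_flag = FALSE)]
estimate_social_exploration(ev, labs, profiles)
#> sigma_s = 0.253  (95% CI 0.246-0.259, n = 17428)
```

Counterfactual downsampling of the baseline month to the pandemic
month's dwell (quantile × distance strata, 10 replicates) shows how much
of the drop activity and distance changes explain on their own:

```r
enr <- function(v) visit_distances(v, profiles, w$cbg_table, w$poi_table)
cf_i  <- run_counterfactual(enr(baseline), enr(pandemic), profiles,
                            "total", n_reps = 10, seed = 21)
cf_ii <- run_counterfactual(enr(baseline), enr(pandemic), profiles,
                            "quantile_distance", n_reps = 10, seed = 21)
decompose_change(cf_ii$baseline[["individual"]],
                 cf_i$summary[entity == "individual", D_mean],
                 cf_ii$summary[entity == "individual", D_mean],
                 cf_ii$actual[["individual"]])
#>    factor contribution      share
#> 1:      i  0.007896708 0.04196161
#> 2:     ii  0.031699795 0.16844669
#> 3:    iii  0.148592386 0.78959171
```

Activity and distance shifts account for about 21% of the drop; the
residual factor (iii) — here the planted change in social exploration —
carries about 79%. The vignette
(`vignettes/experienced-income-diversity.Rmd`) documents the model, the
estimators and every numerical choice.

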