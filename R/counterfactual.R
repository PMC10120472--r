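# Counterfactual stratified downsampling of baseline visits, and the
# decomposition of a diversity decrease into behavioural factors.

cf_scenarios <- c("total", "quantile_distance", "quantile_distance_category")

# stratum key per visit row for a given scenario
add_stratum <- function(visits, scenario, profiles = NULL) {
  visits <- ensure_window(as_dt(visits))
  if (scenario == "total") {
    visits[, stratum := "all"]
    return(visits)
  }
  if (!"income_quantile" %in% names(visits)) {
    if (is.null(profiles)) {
      stop("visits lack income_quantile; supply profiles", call. = FALSE)
    }
    profiles <- as_dt(profiles)
    # match() rather than merge() so row order is preserved: removal order
    # within a stratum must not depend on how strata were attached
    visits[, income_quantile :=
             profiles$income_quantile[match(user_id, profiles$user_id)]]
    if (anyNA(visits$income_quantile)) {
      stop("some visits belong to users missing from profiles", call. = FALSE)
    }
  }
  assert_cols(visits, "distance_km",
              "visits (run visit_distances() before stratified scenarios)")
  visits[, stratum := paste(income_quantile, distance_bin(distance_km),
                            sep = "|")]
  if (scenario == "quantile_distance_category") {
    assert_cols(visits, "category", "visits (category needed for this scenario)")
    visits[, stratum := paste(stratum, category, sep = "|")]
  }
  visits
}

#' Per-stratum dwell targets from an observed month
#'
#' Totals the dwell minutes of the observed (pandemic-period) visits per
#' stratum: a single stratum for the `"total"` scenario, income quantile
#' by seven-bin travel distance for `"quantile_distance"`, additionally by
#' major place category for `"quantile_distance_category"`. These totals
#' are what the counterfactual dataset must match.
#'
#' @param visits_ym observed visits for the target month, carrying the
#'   columns the scenario needs (`income_quantile` or `profiles`,
#'   `distance_km`, `category`).
#' @param scenario one of `"total"`, `"quantile_distance"`,
#'   `"quantile_distance_category"`.
#' @param profiles optional profile table used to attach quantiles.
#' @return data.table (`stratum`, `dwell_target`).
#' @export
dwell_targets <- function(visits_ym, scenario = cf_scenarios,
                          profiles = NULL) {
  scenario <- match.arg(scenario)
  v <- add_stratum(as_dt(visits_ym), scenario, profiles)
  v[, .(dwell_target = sum(dwell_min)), by = stratum]
}

#' Downsample baseline visits to per-stratum dwell targets
#'
#' Within each stratum, visits are removed in a uniformly random order
#' until the remaining dwell first drops to or below the target, so the
#' match error is at most one visit's dwell (<= 240 min under the ingest
#' filter). The output is always a subset of the source: a stratum whose
#' target exceeds its source dwell keeps all its visits and a shortfall
#' warning is raised (visits are never added); a source stratum absent
#' from the targets is removed entirely. Deterministic given `seed`.
#'
#' @param source_visits baseline (2019 same-month) visits, stratified like
#'   the targets.
#' @param targets output of [dwell_targets()].
#' @param scenario scenario used to form strata.
#' @param profiles optional profile table used to attach quantiles.
#' @param seed integer seed.
#' @return the counterfactual visit table (subset of `source_visits`).
#' @export
downsample_visits <- function(source_visits, targets,
                              scenario = cf_scenarios, profiles = NULL,
                              seed = 1L) {
  scenario <- match.arg(scenario)
  targets <- as_dt(targets)
  assert_cols(targets, c("stratum", "dwell_target"), "targets")
  v <- add_stratum(as_dt(source_visits), scenario, profiles)
  v[, `:=`(.row_id = .I)]
  tgt <- setNames(targets$dwell_target, targets$stratum)

  set.seed(seed)
  keep_rows <- integer(0)
  shortfall <- character(0)
  for (s in sort(unique(v$stratum))) {
    rows <- v[stratum == s, .row_id]
    total <- sum(v$dwell_min[rows])
    g <- tgt[s]
    if (is.na(g)) g <- 0  # stratum absent from the observed month
    if (g >= total) {
      if (g > total) shortfall <- c(shortfall, s)
      keep_rows <- c(keep_rows, rows)
      next
    }
    ord <- sample(rows)
    csum <- cumsum(v$dwell_min[ord])
    k <- which(total - csum <= g)[1]
    keep_rows <- c(keep_rows, ord[-seq_len(k)])
  }
  miss <- setdiff(names(tgt)[tgt > 0], unique(v$stratum))
  shortfall <- c(shortfall, miss)
  if (length(shortfall)) {
    warning(sprintf("dwell shortfall in %d stratum/strata (cannot add visits): %s",
                    length(shortfall),
                    paste(utils::head(shortfall, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- v[.row_id %in% keep_rows]
  out[, .row_id := NULL]
  out[]
}

#' Run a counterfactual simulation
#'
#' For each of `n_reps` replicates, downsamples the baseline month's
#' visits to the observed month's per-stratum dwell targets and computes
#' the mean place and individual diversity of the counterfactual panel;
#' also computes both means on the baseline and observed panels
#' themselves. Per-replicate seeds are `seed + replicate`.
#'
#' @param visits_2019m baseline-month visits (enriched with the columns
#'   the scenario needs).
#' @param visits_ym observed-month visits, same enrichment.
#' @param profiles profile table.
#' @param scenario counterfactual scenario.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param metric diversity metric.
#' @param min_users,min_dwell place support thresholds.
#' @return object of class `counterfactual_result`: list with
#'   `replicates` (per-replicate means), `summary` (mean and SE over
#'   replicates), `baseline` and `actual` means, and the call settings.
#' @export
run_counterfactual <- function(visits_2019m, visits_ym, profiles,
                               scenario = cf_scenarios, n_reps = 10L,
                               seed = 1L, metric = "evenness",
                               min_users = 2L, min_dwell = 30) {
  scenario <- match.arg(scenario)
  mean_both <- function(v) {
    pp <- diversity_panel(v, profiles, entity = "place", metric = metric,
                          min_users = min_users, min_dwell = min_dwell)
    ip <- diversity_panel(v, profiles, entity = "individual", metric = metric,
                          min_users = min_users, min_dwell = min_dwell)
    c(place = mean(pp[qualified == TRUE, D]), individual = mean(ip$D))
  }
  targets <- dwell_targets(visits_ym, scenario, profiles)
  reps <- lapply(seq_len(n_reps), function(r) {
    cf <- downsample_visits(visits_2019m, targets, scenario, profiles,
                            seed = seed + r)
    m <- mean_both(cf)
    data.table(replicate = r, D_place = m["place"],
               D_individual = m["individual"])
  })
  reps <- rbindlist(reps)
  summ <- data.table(
    entity = c("place", "individual"),
    D_mean = c(mean(reps$D_place), mean(reps$D_individual)),
    D_se = c(sd(reps$D_place), sd(reps$D_individual)) / sqrt(n_reps),
    D_sd = c(sd(reps$D_place), sd(reps$D_individual))
  )
  structure(list(replicates = reps, summary = summ,
                 baseline = mean_both(visits_2019m),
                 actual = mean_both(visits_ym),
                 scenario = scenario, n_reps = n_reps, seed = seed,
                 metric = metric),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat(sprintf("<counterfactual_result> scenario '%s', %d replicates\n",
              x$scenario, x$n_reps))
  cat(sprintf("  baseline D: place %.4f, individual %.4f\n",
              x$baseline["place"], x$baseline["individual"]))
  cat(sprintf("  actual   D: place %.4f, individual %.4f\n",
              x$actual["place"], x$actual["individual"]))
  print(x$summary)
  invisible(x)
}

#' Decompose a diversity decrease into behavioural factors
#'
#' Telescoping decomposition of the gap between a baseline mean diversity
#' and the observed mean: factor (i), activity reduction, is
#' `D_2019 - D_cf_i`; factor (ii), distance-shift by quantile, is
#' `D_cf_i - D_cf_ii`; factor (iii), residual microscopic preference and
#' exploration changes, is `D_cf_ii - D_actual`. Contributions sum to the
#' total gap exactly by construction; shares divide by the gap and are
#' `NA` when the gap is zero.
#'
#' @param d_2019 baseline mean diversity.
#' @param d_cf_i mean diversity of the total-activity counterfactual.
#' @param d_cf_ii mean diversity of the quantile-by-distance
#'   counterfactual.
#' @param d_actual observed mean diversity.
#' @return data.table (`factor`, `contribution`, `share`).
#' @export
decompose_change <- function(d_2019, d_cf_i, d_cf_ii, d_actual) {
  contr <- c(i = d_2019 - d_cf_i, ii = d_cf_i - d_cf_ii,
             iii = d_cf_ii - d_actual)
  total <- d_2019 - d_actual
  share <- if (total == 0) rep(NA_real_, 3) else unname(contr) / total
  if (total == 0) {
    message("zero total decrease: shares undefined, returning contributions only")
  }
  data.table(factor = names(contr), contribution = unname(contr),
             share = share)
}
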