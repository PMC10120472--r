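# Exposure vectors and experienced income diversity.

ensure_window <- function(visits) {
  if (!"window" %in% names(visits)) visits[, window := "all"]
  visits
}

tau_cols <- function(Q) paste0("tau_", seq_len(Q))

#' Place exposure vectors
#'
#' For each place and window, the share of total (post-stratification
#' weighted) dwell time contributed by each income quantile:
#' `tau_q = sum_{i in q} w_i dwell_i / sum_i w_i dwell_i`. Places with at
#' least `min_users` distinct visitors and `min_dwell` unweighted
#' dwell-minutes in the window are flagged `qualified`; places with zero
#' dwell are absent.
#'
#' @param visits attributed visit table (`user_id`, `poi_id`, `dwell_min`,
#'   optionally `window`).
#' @param profiles profile table (`user_id`, `income_quantile`, `weight`).
#' @param Q number of quantiles (default: maximum in `profiles`).
#' @param min_users,min_dwell minimum support for the `qualified` flag.
#' @return data.table (`window`, `poi_id`, `tau_1..tau_Q`, `support_dwell`,
#'   `support_users`, `qualified`).
#' @export
place_exposure <- function(visits, profiles, Q = NULL,
                           min_users = 2L, min_dwell = 30) {
  visits <- ensure_window(as_dt(visits))
  profiles <- as_dt(profiles)
  assert_cols(visits, c("user_id", "poi_id", "dwell_min"), "visits")
  assert_cols(profiles, c("user_id", "income_quantile"), "profiles")
  if (!"weight" %in% names(profiles)) profiles[, weight := 1]
  Q <- as.integer(Q %||% max(profiles$income_quantile))

  pre <- intersect(c("income_quantile", "weight"), names(visits))
  if (length(pre)) visits <- visits[, setdiff(names(visits), pre), with = FALSE]
  v <- merge(visits, profiles[, .(user_id, income_quantile, weight)],
             by = "user_id")
  byq <- v[, .(w_dwell = sum(weight * dwell_min)),
           by = .(window, poi_id, income_quantile)]
  supp <- v[, .(support_dwell = sum(dwell_min),
                support_users = uniqueN(user_id)),
            by = .(window, poi_id)]
  wide <- dcast(byq, window + poi_id ~ income_quantile, value.var = "w_dwell",
                fill = 0)
  present_q <- setdiff(names(wide), c("window", "poi_id"))
  for (qq in setdiff(as.character(seq_len(Q)), present_q)) wide[, (qq) := 0]
  setnames(wide, as.character(seq_len(Q)), tau_cols(Q))
  tot <- rowSums(wide[, tau_cols(Q), with = FALSE])
  for (cc in tau_cols(Q)) set(wide, j = cc, value = wide[[cc]] / tot)
  out <- merge(wide, supp, by = c("window", "poi_id"))
  out[, qualified := support_users >= min_users & support_dwell >= min_dwell]
  setattr(out, "Q", Q)
  out[]
}

check_tau <- function(tau) {
  if (is.vector(tau)) tau <- matrix(tau, nrow = 1)
  tau <- as.matrix(tau)
  if (any(tau < -1e-9)) stop("exposure shares must be nonnegative", call. = FALSE)
  s <- rowSums(tau)
  if (any(abs(s - 1) > 1e-6)) {
    stop("exposure vector(s) do not sum to 1", call. = FALSE)
  }
  tau
}

#' Evenness income diversity
#'
#' The evenness of an exposure vector over `Q` income quantiles:
#' `D = 1 - Q / (2 (Q - 1)) * sum_q |tau_q - 1/Q|`, which is the printed
#' `1 - (2/3) sum_q |tau_q - 1/4|` at `Q = 4`. `D = 1` for a uniform
#' vector (equal time from every quantile) and `D = 0` for a point mass
#' (a single quantile); the normalisation maps those extremes to exactly
#' `{1, 0}` for every `Q`. Clipped to \[0, 1\] against float error.
#'
#' @param tau exposure vector, or a matrix / data.frame with one vector
#'   per row.
#' @param Q number of quantiles (default `length`/`ncol` of `tau`).
#' @return numeric vector of diversities in \[0, 1\].
#' @export
evenness_diversity <- function(tau, Q = NULL) {
  tau <- check_tau(tau)
  Q <- Q %||% ncol(tau)
  d <- 1 - Q / (2 * (Q - 1)) * rowSums(abs(tau - 1 / Q))
  pmin(pmax(d, 0), 1)
}

#' Entropy income diversity
#'
#' Normalised Shannon entropy of an exposure vector:
#' `D = -sum_q tau_q ln tau_q / ln Q`, with `0 ln 0 = 0`. Shares the
#' \[0, 1\] range and endpoints of [evenness_diversity()].
#'
#' @inheritParams evenness_diversity
#' @return numeric vector of diversities in \[0, 1\].
#' @export
entropy_diversity <- function(tau, Q = NULL) {
  tau <- check_tau(tau)
  Q <- Q %||% ncol(tau)
  lt <- ifelse(tau > 0, log(tau), 0)
  d <- -rowSums(tau * lt) / log(Q)
  pmin(pmax(d, 0), 1)
}

#' Individual time-share table
#'
#' The share of an individual's dwell time spent at each place within a
#' window (`tau_ia`), over attributed visits; shares sum to 1 per
#' individual per window.
#'
#' @param visits attributed visit table.
#' @return data.table (`window`, `user_id`, `poi_id`, `tau_ia`).
#' @export
time_share_table <- function(visits) {
  visits <- ensure_window(as_dt(visits))
  assert_cols(visits, c("user_id", "poi_id", "dwell_min"), "visits")
  ts <- visits[, .(w_dwell = sum(dwell_min)), by = .(window, user_id, poi_id)]
  ts[, tau_ia := w_dwell / sum(w_dwell), by = .(window, user_id)]
  ts[, w_dwell := NULL]
  ts[]
}

#' Individual exposure vectors
#'
#' An individual's relative exposure to income quantile `q` is the
#' time-share-weighted mixture of the exposure vectors of the places they
#' visited: `tau_iq = sum_a tau_ia tau_qa`. Individuals with no visit at a
#' place carrying an exposure vector are omitted.
#'
#' @param visits attributed visit table on the same windows as
#'   `place_exposures`.
#' @param place_exposures output of [place_exposure()].
#' @return data.table (`window`, `user_id`, `tau_1..tau_Q`,
#'   `support_visits`).
#' @export
individual_exposure <- function(visits, place_exposures) {
  place_exposures <- as_dt(place_exposures)
  Q <- attr(place_exposures, "Q") %||%
    sum(grepl("^tau_\\d+$", names(place_exposures)))
  ts <- time_share_table(visits)
  nv <- as_dt(ensure_window(as_dt(visits)))[, .(support_visits = .N),
                                            by = .(window, user_id)]
  m <- merge(ts, place_exposures[, c("window", "poi_id", tau_cols(Q)),
                                 with = FALSE],
             by = c("window", "poi_id"))
  # renormalise shares over the places that carry an exposure vector
  m[, tau_ia := tau_ia / sum(tau_ia), by = .(window, user_id)]
  out <- m[, lapply(.SD, function(x) sum(tau_ia * x)),
           by = .(window, user_id), .SDcols = tau_cols(Q)]
  out <- merge(out, nv, by = c("window", "user_id"))
  setattr(out, "Q", Q)
  out[]
}

#' Diversity panel for places or individuals
#'
#' End-to-end convenience: computes exposure vectors and a diversity value
#' per entity per window, in the long panel format shared by all
#' aggregation and comparison helpers.
#'
#' @param visits attributed, windowed visit table.
#' @param profiles profile table.
#' @param entity `"place"` or `"individual"`.
#' @param metric `"evenness"` or `"entropy"`.
#' @param Q number of quantiles.
#' @param min_users,min_dwell place support thresholds (see
#'   [place_exposure()]).
#' @return data.table (`entity_kind`, `entity_id`, `window`, `D`, `metric`,
#'   `Q`, `support`, `qualified`).
#' @export
diversity_panel <- function(visits, profiles,
                            entity = c("place", "individual"),
                            metric = c("evenness", "entropy"), Q = NULL,
                            min_users = 2L, min_dwell = 30) {
  entity <- match.arg(entity)
  metric <- match.arg(metric)
  fn <- if (metric == "evenness") evenness_diversity else entropy_diversity
  pe <- place_exposure(visits, profiles, Q = Q,
                       min_users = min_users, min_dwell = min_dwell)
  Q <- attr(pe, "Q")
  if (entity == "place") {
    D <- fn(pe[, tau_cols(Q), with = FALSE], Q)
    out <- data.table(entity_kind = "place", entity_id = pe$poi_id,
                      window = pe$window, D = D, metric = metric, Q = Q,
                      support = pe$support_users, qualified = pe$qualified)
  } else {
    ie <- individual_exposure(visits, pe)
    D <- fn(ie[, tau_cols(Q), with = FALSE], Q)
    out <- data.table(entity_kind = "individual", entity_id = ie$user_id,
                      window = ie$window, D = D, metric = metric, Q = Q,
                      support = ie$support_visits, qualified = TRUE)
  }
  out[]
}

#' Aggregate individual diversity to census block groups
#'
#' The unweighted mean of individual diversities over the observed
#' residents of each CBG; CBGs with fewer than `min_residents` observed
#' residents are flagged unqualified, and CBGs with none are absent.
#'
#' @param ind_panel individual [diversity_panel()].
#' @param profiles profile table with `user_id` and `home_cbg`.
#' @param min_residents support threshold for the `qualified` flag.
#' @return CBG-level panel in the same long format.
#' @export
aggregate_cbg <- function(ind_panel, profiles, min_residents = 1L) {
  ind_panel <- as_dt(ind_panel)
  profiles <- as_dt(profiles)
  assert_cols(profiles, c("user_id", "home_cbg"), "profiles")
  m <- merge(ind_panel, profiles[, .(entity_id = user_id, home_cbg)],
             by = "entity_id")
  out <- m[, .(entity_kind = "cbg", D = mean(D), metric = metric[1],
               Q = Q[1], support = .N),
           by = .(entity_id = home_cbg, window)]
  out[, qualified := support >= min_residents]
  setcolorder(out, c("entity_kind", "entity_id", "window", "D", "metric",
                     "Q", "support", "qualified"))
  out[]
}

panel_means <- function(panel, qualified_only = TRUE) {
  panel <- as_dt(panel)
  if (qualified_only && "qualified" %in% names(panel)) {
    panel <- panel[qualified == TRUE]
  }
  panel[, .(D = mean(D), n = .N), by = window]
}

#' Mean diversity per window
#'
#' Unweighted mean of `D` over qualifying entities, per window.
#'
#' @param panel a diversity panel.
#' @param qualified_only restrict to entities passing support thresholds.
#' @return data.table (`window`, `D`, `n`).
#' @export
mean_diversity <- function(panel, qualified_only = TRUE) {
  panel_means(panel, qualified_only)
}

#' Percentage change in diversity against a same-month baseline
#'
#' `Delta D(t) = 100 * (Dbar(t) - Dbar(2019, month(t))) / Dbar(2019,
#' month(t))`, where the baseline is the mean diversity across entities in
#' the same calendar month of the baseline panel. With
#' `by_entity = TRUE` the change is computed entity by entity (the
#' `Delta D_CBG` / `Delta D_CBSA` convention) rather than on panel means.
#'
#' @param panel diversity panel for the periods of interest.
#' @param baseline_panel diversity panel for the baseline year; its window
#'   labels must cover each calendar month used, once.
#' @param by_entity match baseline per entity instead of on panel means.
#' @param qualified_only restrict both panels to qualifying entities.
#' @return data.table with `window`, baseline label, means and
#'   `delta_pct`.
#' @export
delta_percent <- function(panel, baseline_panel, by_entity = FALSE,
                          qualified_only = TRUE) {
  panel <- as_dt(panel)
  baseline_panel <- as_dt(baseline_panel)
  base_labels <- unique(baseline_panel$window)
  base_month <- vapply(base_labels, month_of, 1L)
  if (anyDuplicated(base_month)) {
    stop("baseline panel has more than one window for some calendar month",
         call. = FALSE)
  }
  lookup <- setNames(base_labels, base_month)

  if (!by_entity) {
    mt <- panel_means(panel, qualified_only)
    mb <- panel_means(baseline_panel, qualified_only)
    mt[, baseline := lookup[as.character(month_of(window))], by = window]
    if (anyNA(mt$baseline)) stop("missing baseline month", call. = FALSE)
    out <- merge(mt, mb[, .(baseline = window, D_baseline = D)],
                 by = "baseline")
    if (any(out$D_baseline == 0)) stop("zero baseline mean", call. = FALSE)
    out[, delta_pct := 100 * (D - D_baseline) / D_baseline]
    return(out[order(window),
               .(window, baseline, D, D_baseline, delta_pct)])
  }

  pt <- if (qualified_only && "qualified" %in% names(panel)) {
    panel[qualified == TRUE]
  } else panel
  pb <- if (qualified_only && "qualified" %in% names(baseline_panel)) {
    baseline_panel[qualified == TRUE]
  } else baseline_panel
  pt <- copy(pt)[, baseline := lookup[as.character(month_of(window))], by = window]
  if (anyNA(pt$baseline)) stop("missing baseline month", call. = FALSE)
  out <- merge(pt, pb[, .(entity_id, baseline = window, D_baseline = D)],
               by = c("entity_id", "baseline"))
  if (any(out$D_baseline == 0)) stop("zero baseline mean", call. = FALSE)
  out[, delta_pct := 100 * (D - D_baseline) / D_baseline]
  out[order(window, entity_id),
      .(entity_kind, entity_id, window, baseline, D, D_baseline, delta_pct)]
}

#' Deseasonalize a monthly series with a baseline-year trend
#'
#' Month-matched ratio normalisation: each value is divided by the
#' baseline value of the same calendar month, the multiplicative
#' convention consistent with [delta_percent()].
#'
#' @param series data.table (`window`, `value`).
#' @param baseline data.table (`window`, `value`) with exactly one row per
#'   calendar month.
#' @return `series` with a `deseasonalized` column.
#' @export
deseasonalize <- function(series, baseline) {
  series <- as_dt(series)
  baseline <- as_dt(baseline)
  assert_cols(series, c("window", "value"), "series")
  assert_cols(baseline, c("window", "value"), "baseline")
  bm <- vapply(baseline$window, month_of, 1L)
  if (anyDuplicated(bm)) {
    stop("baseline has more than one value for some calendar month",
         call. = FALSE)
  }
  ref <- setNames(baseline$value, bm)
  key <- as.character(vapply(series$window, month_of, 1L))
  if (!all(key %in% names(ref))) stop("missing baseline month", call. = FALSE)
  out <- copy(series)
  out[, deseasonalized := value / ref[key]]
  out[]
}
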