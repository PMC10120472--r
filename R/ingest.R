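#' Filter stays to the analysis dwell range
#'
#' Keeps stays strictly longer than 10 minutes and strictly shorter than
#' 4 hours (240 minutes); the number of dropped records is reported as a
#' message.
#'
#' @param stays data.table with a `dwell_min` column.
#' @param min_min,max_min dwell bounds in minutes (exclusive).
#' @return the filtered stays (a new data.table; possibly zero rows).
#' @export
filter_stays <- function(stays, min_min = 10, max_min = 240) {
  stays <- as_dt(stays)
  assert_cols(stays, "dwell_min", "stays")
  keep <- stays$dwell_min > min_min & stays$dwell_min < max_min
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("filter_stays: dropped %d of %d stays outside (%g, %g) min",
                    dropped, nrow(stays), min_min, max_min))
  }
  stays[keep]
}

#' User-day observation filter
#'
#' Retains user-days observed for more than `min_daily_min` minutes,
#' mirroring a provider-side panel-quality filter. Synthetic fixtures have
#' no ping gaps, so with `ping_log = NULL` the lenient mode passes every
#' user-day through (with a warning); strict mode requires a ping log.
#'
#' @param stays stay table with `user_id` and `t_start`.
#' @param ping_log optional data.table (`user_id`, `date`, `observed_min`).
#' @param min_daily_min threshold in minutes (exclusive).
#' @param mode `"strict"` (error without a ping log) or `"lenient"`.
#' @return data.table (`user_id`, `date`) of qualifying user-days.
#' @export
filter_user_days <- function(stays, ping_log = NULL, min_daily_min = 300,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stays <- as_dt(stays)
  assert_cols(stays, c("user_id", "t_start"), "stays")
  if (is.null(ping_log)) {
    if (mode == "strict") {
      stop("no ping log supplied in strict mode; pass mode = 'lenient' for fully observed synthetic panels",
           call. = FALSE)
    }
    warning("no ping log: treating every user-day as fully observed",
            call. = FALSE)
    return(unique(stays[, .(user_id, date = as.Date(t_start))]))
  }
  ping_log <- as_dt(ping_log)
  assert_cols(ping_log, c("user_id", "date", "observed_min"), "ping_log")
  ping_log[observed_min > min_daily_min, .(user_id, date)]
}

#' Apply a user-day keep set to a stay table
#'
#' @param stays stay table.
#' @param keep_days output of [filter_user_days()].
#' @return stays restricted to qualifying user-days.
#' @export
apply_user_days <- function(stays, keep_days) {
  stays <- as_dt(stays)
  keep_days <- as_dt(keep_days)
  stays[, date := as.Date(t_start)]
  out <- stays[keep_days, on = c("user_id", "date"), nomatch = NULL]
  out[, date := NULL]
  out[]
}

#' Attribute stays to the nearest POI within a radius
#'
#' Each stay is attributed to the closest POI by great-circle distance,
#' provided it lies within `radius_m` metres; ties are broken towards the
#' smallest `poi_id`. Stays with no POI in range are flagged `matched =
#' FALSE` (retained for total-dwell accounting but excluded from diversity
#' computations downstream).
#'
#' A coarse latitude/longitude grid prunes candidate POIs so the pairwise
#' distance work stays proportional to the number of local pairs.
#'
#' @param stays stay table with `lon`, `lat`.
#' @param poi_table POI table with `poi_id`, `lon`, `lat`.
#' @param radius_m attribution radius in metres.
#' @return stays with columns `poi_id`, `attribution_m` (distance to the
#'   attributed POI) and `matched`.
#' @export
attribute_pois <- function(stays, poi_table, radius_m = 100) {
  stays <- as_dt(stays)
  poi_table <- as_dt(poi_table)
  assert_cols(stays, c("lon", "lat"), "stays")
  assert_cols(poi_table, c("poi_id", "lon", "lat"), "poi_table")
  if (nrow(poi_table) == 0) stop("empty POI table", call. = FALSE)

  # grid cells a bit larger than the radius; search the 3x3 neighbourhood
  cell_deg <- max(radius_m / 1000 / 110.574 * 2, 1e-4)
  key_of <- function(lon, lat) {
    paste(floor(lon / cell_deg), floor(lat / cell_deg))
  }
  poi_cells <- split(seq_len(nrow(poi_table)),
                     key_of(poi_table$lon, poi_table$lat))

  n <- nrow(stays)
  out_idx <- rep(NA_integer_, n)
  out_dist <- rep(NA_real_, n)
  cx <- floor(stays$lon / cell_deg)
  cy <- floor(stays$lat / cell_deg)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      cand <- c(cand, poi_cells[[k]])
    }
    if (!length(cand)) next
    d <- haversine_km(stays$lon[i], stays$lat[i],
                      poi_table$lon[cand], poi_table$lat[cand]) * 1000
    ok <- which(d <= radius_m)
    if (!length(ok)) next
    # nearest; ties towards smallest poi_id
    dmin <- min(d[ok])
    best <- ok[d[ok] <= dmin + 1e-9]
    ids <- poi_table$poi_id[cand[best]]
    sel <- best[order(ids)][1]
    out_idx[i] <- cand[sel]
    out_dist[i] <- d[sel]
  }
  stays[, `:=`(poi_id = poi_table$poi_id[out_idx],
               attribution_m = out_dist,
               matched = !is.na(out_idx))]
  stays[]
}

#' Assign income quantiles from home-CBG median income
#'
#' Users are ranked by the median household income of their home CBG and
#' split into `Q` equal-count groups (quantile 1 = lowest income). Ties at
#' a boundary income share a quantile, so group sizes are equal only up to
#' the tied mass. When `by` is given (e.g. `"cbsa_id"`), thresholds are
#' formed within each city separately. Users whose home CBG has no income
#' are excluded with a warning.
#'
#' @param user_table data.table with `user_id`, `home_cbg` and optionally
#'   `weight`.
#' @param cbg_income_table data.table with `cbg_id`, `median_income` and
#'   optionally the `by` column.
#' @param Q number of quantiles.
#' @param by optional city column in `cbg_income_table` used to form
#'   thresholds per city.
#' @return profile data.table (`user_id`, `home_cbg`, `income_quantile`,
#'   `weight`).
#' @export
assign_quantiles <- function(user_table, cbg_income_table, Q = 4L, by = NULL) {
  user_table <- as_dt(user_table)
  cbg_income_table <- as_dt(cbg_income_table)
  assert_cols(user_table, c("user_id", "home_cbg"), "user_table")
  assert_cols(cbg_income_table, c("cbg_id", "median_income"), "cbg_income_table")
  Q <- as.integer(Q)
  if (Q < 2L) stop("Q must be >= 2", call. = FALSE)

  cols <- c("cbg_id", "median_income", by)
  prof <- merge(user_table, cbg_income_table[, cols, with = FALSE],
                by.x = "home_cbg", by.y = "cbg_id", all.x = TRUE)
  n_missing <- sum(is.na(prof$median_income))
  if (n_missing > 0) {
    warning(sprintf("excluding %d user(s) whose home CBG has no income",
                    n_missing), call. = FALSE)
    prof <- prof[!is.na(median_income)]
  }
  if (is.null(by)) {
    prof[, income_quantile := rank_quantiles(median_income, Q)]
  } else {
    prof[, income_quantile := rank_quantiles(median_income, Q), by = by]
  }
  if (!"weight" %in% names(prof)) prof[, weight := 1]
  prof[, .(user_id, home_cbg, income_quantile, weight)]
}

#' Build two-month moving analysis windows
#'
#' Each window is labelled by its last month and spans exactly the two
#' calendar months ending there: window `"2020-04"` covers
#' 2020-03-01 00:00 to 2020-04-30 24:00 UTC. Consecutive windows overlap by
#' one month.
#'
#' @param labels character vector of `"YYYY-MM"` window labels.
#' @return data.table (`window`, `start`, `end`), end exclusive.
#' @export
make_windows <- function(labels) {
  stopifnot(all(grepl("^\\d{4}-\\d{2}$", labels)))
  if (anyDuplicated(labels)) stop("window labels must be unique", call. = FALSE)
  data.table(
    window = labels,
    start = as.POSIXct(vapply(labels, function(l) {
      as.character(month_start(month_prev(l)))
    }, ""), tz = "UTC"),
    end = as.POSIXct(vapply(labels, function(l) {
      as.character(month_start(month_next(l)))
    }, ""), tz = "UTC")
  )
}

#' Assign stays to analysis windows
#'
#' A stay is keyed into every window whose span contains its start time; a
#' stay inside the overlap of two moving windows appears twice, once per
#' window. Stays outside all windows are dropped.
#'
#' @param stays stay table with `t_start`.
#' @param windows output of [make_windows()].
#' @return stays replicated per containing window, with a `window` column.
#' @export
assign_windows <- function(stays, windows) {
  stays <- as_dt(stays)
  windows <- as_dt(windows)
  assert_cols(stays, "t_start", "stays")
  assert_cols(windows, c("window", "start", "end"), "windows")
  out <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- stays[t_start >= windows$start[i] & t_start < windows$end[i]]
    if (nrow(sel)) sel[, window := windows$window[i]]
    else sel[, window := character(0)]
    sel
  })
  rbindlist(out)
}

#' Home-to-POI travel distance per visit
#'
#' Adds `distance_km`, the great-circle distance from the visitor's home
#' CBG centroid to the visited POI — the travel-distance convention used
#' for distance-binned counterfactual strata and mobility covariates.
#'
#' @param visits attributed visit table with `user_id`, `poi_id`.
#' @param profiles profile table with `user_id`, `home_cbg`.
#' @param cbg_table CBG table with `cbg_id`, `centroid_lon`, `centroid_lat`.
#' @param poi_table POI table with `poi_id`, `lon`, `lat`.
#' @return visits with a `distance_km` column.
#' @export
visit_distances <- function(visits, profiles, cbg_table, poi_table) {
  visits <- as_dt(visits)
  profiles <- as_dt(profiles)
  cbg_table <- as_dt(cbg_table)
  poi_table <- as_dt(poi_table)
  v <- merge(visits, profiles[, .(user_id, home_cbg)], by = "user_id")
  v <- merge(v, cbg_table[, .(home_cbg = cbg_id, centroid_lon, centroid_lat)],
             by = "home_cbg")
  v <- merge(v, poi_table[, .(poi_id, poi_lon = lon, poi_lat = lat)],
             by = "poi_id")
  v[, distance_km := haversine_km(centroid_lon, centroid_lat, poi_lon, poi_lat)]
  v[, c("home_cbg", "centroid_lon", "centroid_lat", "poi_lon", "poi_lat") := NULL]
  v[]
}

#' Distance-range bin of a travel distance
#'
#' Fixed seven-bin ladder (km, left-closed right-open):
#' \[0,1), \[1,3), \[3,5), \[5,10), \[10,20), \[20,40), \[40,Inf).
#'
#' @param d_km numeric distances in km.
#' @return integer bin indices 0..6.
#' @export
distance_bin <- function(d_km) {
  breaks <- c(0, 1, 3, 5, 10, 20, 40, Inf)
  as.integer(cut(d_km, breaks = breaks, right = FALSE, labels = FALSE)) - 1L
}
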