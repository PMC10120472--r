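#' Per-user mobility metrics
#'
#' The aggregate mobility panel per user and window: daily number of
#' visits, daily dwell minutes at POIs, mean dwell per visit, number of
#' distinct POIs visited, the visit-weighted radius of gyration (root mean
#' squared great-circle distance of visit locations from their
#' visit-weighted centroid), and — when a `distance_km` column is present
#' (see [visit_distances()]) — the mean home-to-place distance. Daily
#' rates divide by the user's number of active days in the window.
#'
#' @param visits attributed visit table with `user_id`, `t_start`,
#'   `dwell_min`, `lon`, `lat` and optionally `window`, `distance_km`.
#' @return data.table, one row per user per window.
#' @export
mobility_metrics <- function(visits) {
  visits <- ensure_window(as_dt(visits))
  assert_cols(visits, c("user_id", "t_start", "dwell_min", "lon", "lat"),
              "visits")
  has_dist <- "distance_km" %in% names(visits)
  visits[, event_day := as.Date(t_start)]
  out <- visits[, {
    n_days_active <- uniqueN(event_day)
    clon <- mean(lon)
    clat <- mean(lat)
    rg <- sqrt(mean(haversine_km(lon, lat, clon, clat)^2))
    res <- list(
      visits_per_day = .N / n_days_active,
      dwell_min_per_day = sum(dwell_min) / n_days_active,
      mean_dwell_per_visit = mean(dwell_min),
      n_unique_pois = uniqueN(poi_id),
      radius_gyration_km = rg
    )
    if (has_dist) res$mean_home_distance_km <- mean(distance_km)
    res
  }, by = .(window, user_id)]
  visits[, event_day := NULL]
  out[]
}
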