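library(data.table)

# Small synthetic city reused across tests; built once per test run.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_world(world_config(
        n_users = 800, n_pois = 400, n_cbgs = 80, seed = 42
      ))
    }
    cache
  }
})

world_profiles <- function(world) {
  world$user_table[, .(user_id, home_cbg, income_quantile, weight)]
}

ground_truth_labels <- function(world) {
  world$poi_table[, .(poi_id, majority_quantile = dominant_quantile,
                      tie_flag = FALSE)]
}

# Hand-built visit table: one row per (user, poi, dwell); quantile profile
# alongside. Times are spaced a minute apart in the given order.
tiny_visits <- function(user, poi, dwell, t0 = "2019-04-01") {
  data.table(
    user_id = user,
    poi_id = poi,
    dwell_min = dwell,
    t_start = as.POSIXct(t0, tz = "UTC") + seq_along(user) * 60
  )
}

tiny_profiles <- function(user_ids, quantiles, weights = 1) {
  data.table(user_id = user_ids, income_quantile = as.integer(quantiles),
             weight = weights, home_cbg = paste0("C", quantiles))
}

enrich_visits <- function(st, world, profiles) {
  v <- visit_distances(st, profiles, world$cbg_table, world$poi_table)
  merge(v, world$poi_table[, .(poi_id, category, subcategory)], by = "poi_id")
}
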