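#' World configuration for the synthetic city
#'
#' Describes a synthetic metropolitan area: census block groups (CBGs) with
#' lognormal median household incomes, points of interest (POIs) attached to
#' CBGs, and a resident panel of users assigned to income quantiles from
#' their home-CBG income. The configuration is consumed by
#' [generate_world()].
#'
#' @param n_users number of panel users.
#' @param n_pois number of POIs.
#' @param n_cbgs number of census block groups.
#' @param city_radius_km radius of the circular city, km.
#' @param income_lognormal `c(meanlog, sdlog)` of CBG median household
#'   income (dollars). Default centres around exp(11) ~ 60k with wide spread.
#' @param quantile_count number of income quantiles Q (>= 2).
#' @param dwell_lognormal `c(meanlog, sdlog)` of visit dwell time in
#'   minutes, truncated to the 10--240 min analysis range at simulation time.
#' @param center_lon,center_lat city centre coordinates, degrees.
#' @param n_pumas number of fixed-effect geographies (angular sectors).
#' @param seed integer seed controlling world generation.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_users = 2000L, n_pois = 600L, n_cbgs = 150L,
                         city_radius_km = 25, income_lognormal = c(11.0, 0.45),
                         quantile_count = 4L, dwell_lognormal = c(log(45), 0.8),
                         center_lon = -71.06, center_lat = 42.36,
                         n_pumas = NULL, seed = 1L) {
  stopifnot(n_users >= 1, n_pois >= 1, n_cbgs >= 1, city_radius_km > 0,
            length(income_lognormal) == 2, income_lognormal[2] >= 0,
            length(dwell_lognormal) == 2, dwell_lognormal[2] >= 0)
  quantile_count <- as.integer(quantile_count)
  if (quantile_count < 2L) stop("quantile_count must be >= 2", call. = FALSE)
  n_pumas <- as.integer(n_pumas %||% max(2L, ceiling(n_cbgs / 25)))
  structure(list(
    n_users = as.integer(n_users), n_pois = as.integer(n_pois),
    n_cbgs = as.integer(n_cbgs), city_radius_km = city_radius_km,
    income_lognormal = income_lognormal, quantile_count = quantile_count,
    dwell_lognormal = dwell_lognormal, center_lon = center_lon,
    center_lat = center_lat, n_pumas = n_pumas, seed = as.integer(seed)
  ), class = "world_config")
}

#' Social-EPR behavioural parameters
#'
#' Parameters of the social exploration and preferential return model that
#' drives the synthetic visit generator. At each visit occasion a user with
#' `S` distinct places in their history explores a new place with
#' probability `min(1, rho * S^-gamma)` (forced exploration at `S = 0`),
#' otherwise returns to a known place with probability proportional to its
#' past visit count. An exploration is *social* with probability `sigma_s`:
#' the new place is drawn from POIs whose dominant income quantile differs
#' from the user's own; otherwise from same-quantile POIs. Candidate places
#' are weighted by a decaying function of home-to-place distance with
#' exponent `beta`.
#'
#' @param rho exploration scale in (0, 1].
#' @param gamma exploration exponent >= 0.
#' @param sigma_s social exploration probability in \[0, 1\].
#' @param event_rate_per_quantile expected visit occasions per user per day,
#'   either a scalar or one value per income quantile.
#' @param beta distance-decay exponent >= 0 of the exploration kernel.
#' @return an object of class `epr_params`.
#' @export
epr_params <- function(rho = 0.6, gamma = 0.21, sigma_s = 0.4,
                       event_rate_per_quantile = 2, beta = 1.5) {
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (sigma_s < 0 || sigma_s > 1) stop("sigma_s must be in [0, 1]", call. = FALSE)
  if (any(event_rate_per_quantile <= 0)) stop("event rates must be positive", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(rho = rho, gamma = gamma, sigma_s = sigma_s,
                 event_rate_per_quantile = event_rate_per_quantile,
                 beta = beta), class = "epr_params")
}

#' Scenario configuration for one simulated period
#'
#' Describes the behavioural state of the population in one calendar month:
#' per-quantile activity reduction, a shift of trips towards closer places,
#' an optional override of the social exploration probability, and
#' multiplicative preference shifts for POI subcategories. A baseline period
#' uses the defaults (no change).
#'
#' @param period_label calendar month label `"YYYY-MM"`.
#' @param activity_multiplier_per_quantile factors in (0, 1\], scalar or one
#'   per quantile; realised visit occasions are thinned to this fraction.
#' @param distance_shrink_factor factor in (0, 1\]; values below 1 inflate
#'   effective distances in the exploration kernel so trips concentrate
#'   closer to home.
#' @param sigma_s_override optional social exploration probability replacing
#'   the baseline `sigma_s` for this period.
#' @param subcategory_preference_shift named numeric vector of
#'   multiplicative weights applied to exploration candidates by POI
#'   subcategory.
#' @param seasonal_amplitude amplitude in \[0, 1) of an optional sinusoidal
#'   modulation of activity by calendar month (peak in July), used to test
#'   deseasonalization.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(period_label,
                            activity_multiplier_per_quantile = 1,
                            distance_shrink_factor = 1,
                            sigma_s_override = NULL,
                            subcategory_preference_shift = NULL,
                            seasonal_amplitude = 0) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", period_label))
  if (any(activity_multiplier_per_quantile <= 0) ||
      any(activity_multiplier_per_quantile > 1)) {
    stop("activity multipliers must be in (0, 1]", call. = FALSE)
  }
  if (distance_shrink_factor <= 0 || distance_shrink_factor > 1) {
    stop("distance_shrink_factor must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(sigma_s_override) &&
      (sigma_s_override < 0 || sigma_s_override > 1)) {
    stop("sigma_s_override must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(subcategory_preference_shift)) {
    if (is.null(names(subcategory_preference_shift)) ||
        any(subcategory_preference_shift < 0)) {
      stop("subcategory_preference_shift must be a named nonnegative vector",
           call. = FALSE)
    }
  }
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("seasonal_amplitude must be in [0, 1)", call. = FALSE)
  }
  structure(list(period_label = period_label,
                 activity_multiplier_per_quantile = activity_multiplier_per_quantile,
                 distance_shrink_factor = distance_shrink_factor,
                 sigma_s_override = sigma_s_override,
                 subcategory_preference_shift = subcategory_preference_shift,
                 seasonal_amplitude = seasonal_amplitude),
            class = "scenario_config")
}

# Equal-count quantile assignment by ranked value; ties share a quantile so
# group sizes are equal only up to the mass tied at a boundary.
rank_quantiles <- function(x, Q) {
  rk <- rank(x, ties.method = "average")
  q <- ceiling(Q * rk / length(x))
  as.integer(pmin(pmax(q, 1L), Q))
}

# Major category -> subcategory vocabulary of the synthetic city.
poi_vocabulary <- function() {
  list(
    Grocery        = c("Grocery Store", "Supermarket", "Convenience Store"),
    Museums        = c("Art Museum", "History Museum", "Science Museum"),
    Leisure        = c("Gym / Fitness", "Park", "Movie Theater", "Bar"),
    Transportation = c("Metro Station", "Bus Station", "Airport Terminal"),
    Coffee         = c("Coffee Shop", "Cafe", "Donut Shop"),
    Restaurants    = c("Fast Food", "Pizza Place", "Sushi Restaurant"),
    Shopping       = c("Big Box Store", "Clothing Store", "Bookstore"),
    Services       = c("Bank", "Post Office", "Salon / Barbershop")
  )
}

#' Generate a synthetic city
#'
#' Builds the three static tables of the synthetic world: CBGs with
#' centroids, median incomes, income quantiles and parent PUMA/CBSA; POIs
#' with coordinates, category/subcategory and a dominant income quantile
#' inherited from their CBG; and users with home CBGs, income quantiles
#' (equal-count split of home-CBG income) and unit post-stratification
#' weights. Deterministic given `config$seed`.
#'
#' @param config a [world_config()].
#' @return an object of class `urban_world`: a list with elements
#'   `cbg_table`, `poi_table`, `user_table` (all data.tables) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  Q <- config$quantile_count
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(config$center_lat * pi / 180)

  # CBG centroids uniform in the city disk
  r <- config$city_radius_km * sqrt(runif(config$n_cbgs))
  th <- runif(config$n_cbgs, 0, 2 * pi)
  cbg <- data.table(
    cbg_id = sprintf("C%04d", seq_len(config$n_cbgs)),
    centroid_lon = config$center_lon + r * cos(th) / km_per_deg_lon,
    centroid_lat = config$center_lat + r * sin(th) / km_per_deg_lat,
    median_income = rlnorm(config$n_cbgs, config$income_lognormal[1],
                           config$income_lognormal[2])
  )
  if (length(unique(cbg$median_income)) < Q) {
    stop("cannot form Q nonempty quantiles: fewer than Q distinct CBG incomes",
         call. = FALSE)
  }
  cbg[, puma_id := sprintf("P%02d", 1 + (floor(th / (2 * pi) * config$n_pumas) %% config$n_pumas))]
  cbg[, cbsa_id := "CBSA1"]
  cbg[, income_quantile := rank_quantiles(median_income, Q)]

  # POIs: pick a CBG, jitter around its centroid; inherit its quantile
  vocab <- poi_vocabulary()
  cats <- names(vocab)
  poi_cbg_idx <- sample.int(config$n_cbgs, config$n_pois, replace = TRUE)
  jit_km <- 0.4
  poi_cat <- sample(cats, config$n_pois, replace = TRUE)
  poi <- data.table(
    poi_id = sprintf("V%05d", seq_len(config$n_pois)),
    lon = cbg$centroid_lon[poi_cbg_idx] +
      stats::rnorm(config$n_pois, 0, jit_km / km_per_deg_lon),
    lat = cbg$centroid_lat[poi_cbg_idx] +
      stats::rnorm(config$n_pois, 0, jit_km / km_per_deg_lat),
    category = poi_cat,
    subcategory = vapply(poi_cat, function(cc) sample(vocab[[cc]], 1L), ""),
    cbg_id = cbg$cbg_id[poi_cbg_idx],
    dominant_quantile = cbg$income_quantile[poi_cbg_idx]
  )

  # Users: home CBG uniform; equal-count income quantiles over users
  home_idx <- sample.int(config$n_cbgs, config$n_users, replace = TRUE)
  usr <- data.table(
    user_id = sprintf("U%06d", seq_len(config$n_users)),
    home_cbg = cbg$cbg_id[home_idx],
    home_income = cbg$median_income[home_idx]
  )
  usr[, income_quantile := rank_quantiles(home_income, Q)]
  usr[, weight := 1]

  structure(list(cbg_table = cbg, poi_table = poi, user_table = usr,
                 config = config), class = "urban_world")
}

#' @export
print.urban_world <- function(x, ...) {
  cat(sprintf("<urban_world> %d users, %d POIs, %d CBGs, Q = %d, seed = %d\n",
              nrow(x$user_table), nrow(x$poi_table), nrow(x$cbg_table),
              x$config$quantile_count, x$config$seed))
  invisible(x)
}
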