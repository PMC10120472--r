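#' Simulate one period of visits from the Social-EPR model
#'
#' Generates a stay table for one calendar month (or a span of `n_days`
#' starting at the first of the month) under the behavioural state described
#' by `scenario`. Visit occasions arrive as a homogeneous Poisson process
#' per user; the sequential exploration / preferential-return dynamics are
#' driven by `epr` (see [epr_params()]). Activity reduction is applied as
#' binomial thinning of the realised occasion sequence, so a pure activity
#' cut changes *which* visits happen but not the underlying preference
#' dynamics — the ground truth that stratified-removal counterfactuals are
#' designed to recover. Dwell times are truncated-lognormal on \[10, 240\]
#' minutes via inverse-CDF sampling, so every synthetic stay passes the
#' ingest dwell filter unchanged.
#'
#' One global `seed` expands into per-user substreams derived from the user
#' id, so trajectories are reproducible independently of user ordering.
#'
#' @param world an `urban_world` from [generate_world()].
#' @param epr an [epr_params()] object.
#' @param scenario a [scenario_config()] object.
#' @param n_days days simulated from the first of the scenario month.
#' @param seed integer seed for this period.
#' @return a data.table with columns `user_id`, `t_start` (POSIXct UTC),
#'   `dwell_min`, `poi_id`, `lon`, `lat`, sorted by user and time. The
#'   number of pool-exhaustion fallbacks is attached as attribute
#'   `n_fallback` (also raised as a warning when positive).
#' @export
simulate_period <- function(world, epr, scenario, n_days = 28L, seed = 1L) {
  stopifnot(inherits(world, "urban_world"), inherits(epr, "epr_params"),
            inherits(scenario, "scenario_config"), n_days >= 1)
  Q <- world$config$quantile_count
  poi <- world$poi_table
  cbg <- world$cbg_table
  usr <- world$user_table

  rates <- rep_len(epr$event_rate_per_quantile, Q)
  mult <- rep_len(scenario$activity_multiplier_per_quantile, Q)
  sigma_s <- scenario$sigma_s_override %||% epr$sigma_s
  shrink <- scenario$distance_shrink_factor

  m <- month_of(scenario$period_label)
  seasonal <- 1 + scenario$seasonal_amplitude * sin(2 * pi * (m - 4) / 12)

  # subcategory preference multipliers per POI
  shift <- rep(1, nrow(poi))
  if (!is.null(scenario$subcategory_preference_shift)) {
    s <- scenario$subcategory_preference_shift
    hit <- match(poi$subcategory, names(s))
    shift[!is.na(hit)] <- s[hit[!is.na(hit)]]
  }

  # distance kernel weights per home CBG: w = (d / shrink + d0)^(-beta).
  # A pure power law is scale-free, so the shrink factor acts through the
  # 0.25 km offset: inflating effective distances concentrates mass closer
  # to home.
  d0 <- 0.25
  home_cbgs <- unique(usr$home_cbg)
  cbg_idx <- match(home_cbgs, cbg$cbg_id)
  kernel_by_cbg <- lapply(cbg_idx, function(ci) {
    d <- haversine_km(cbg$centroid_lon[ci], cbg$centroid_lat[ci],
                      poi$lon, poi$lat)
    (d / shrink + d0)^(-epr$beta) * shift
  })
  names(kernel_by_cbg) <- home_cbgs

  # candidate pools per (home CBG, user quantile), built lazily
  pool_cache <- new.env(parent = emptyenv())
  get_pool <- function(hc, q) {
    key <- paste0(hc, "|", q)
    p <- pool_cache[[key]]
    if (is.null(p)) {
      w <- kernel_by_cbg[[hc]]
      same <- which(poi$dominant_quantile == q)
      other <- which(poi$dominant_quantile != q)
      p <- list(
        idx_same = as.integer(same), cum_same = cumsum(w[same]),
        idx_other = as.integer(other), cum_other = cumsum(w[other]),
        w_all = w,
        set_of_poi = ifelse(poi$dominant_quantile == q, 1L, 2L)
      )
      pool_cache[[key]] <- p
    }
    p
  }

  t0 <- month_start(scenario$period_label)
  mu <- world$config$dwell_lognormal[1]
  sdl <- world$config$dwell_lognormal[2]
  f_lo <- plnorm(10, mu, sdl)
  f_hi <- plnorm(240, mu, sdl)

  user_index <- match(usr$user_id, sort(unique(usr$user_id)))
  n_fallback_total <- 0L
  out <- vector("list", nrow(usr))

  for (i in seq_len(nrow(usr))) {
    q <- usr$income_quantile[i]
    set.seed(derive_seed(seed, user_index[i]))
    n_ev <- rpois(1, rates[q] * n_days * seasonal)
    if (n_ev == 0L) next
    p <- get_pool(usr$home_cbg[i], q)
    sim <- simulate_user_seq(n_ev, p$cum_same, p$idx_same,
                             p$cum_other, p$idx_other,
                             p$w_all, p$set_of_poi,
                             epr$rho, epr$gamma, sigma_s)
    n_fallback_total <- n_fallback_total + sim$n_fallback
    times <- sort(runif(n_ev, 0, n_days * 86400))
    dwell <- qlnorm(f_lo + runif(n_ev) * (f_hi - f_lo), mu, sdl)
    # thinning consumes the RNG stream last, so under a shared seed a
    # thinned period is an exact subset of its unthinned counterpart
    keep <- if (mult[q] < 1) rbinom(n_ev, 1L, mult[q]) == 1L else rep(TRUE, n_ev)
    if (!any(keep)) next
    pidx <- sim$poi[keep]
    out[[i]] <- data.table(
      user_id = usr$user_id[i],
      t_start = t0 + times[keep],
      dwell_min = dwell[keep],
      poi_id = poi$poi_id[pidx],
      lon = poi$lon[pidx],
      lat = poi$lat[pidx]
    )
  }

  stays <- rbindlist(out)
  if (nrow(stays)) setkey(stays, user_id, t_start)
  if (n_fallback_total > 0) {
    warning(sprintf("%d exploration draw(s) fell back to the complementary candidate pool",
                    n_fallback_total), call. = FALSE)
  }
  setattr(stays, "n_fallback", n_fallback_total)
  setattr(stays, "period_label", scenario$period_label)
  stays[]
}
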