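# Estimation of Social-EPR behavioural parameters and subcategory
# popularity from visit panels.

#' Label exploration events
#'
#' Flags, per user in time order, every first visit to a place not seen
#' before within the estimation window (`is_exploration`), and records the
#' number of distinct places already visited before the event
#' (`S_before`). History starts empty at the beginning of the window, so
#' the measured exploration rate is an upper bound on true exploration
#' for users with prior unobserved history.
#'
#' @param visits attributed visit table (`user_id`, `t_start`, `poi_id`).
#' @return data.table (`user_id`, `t_start`, `poi_id`, `S_before`,
#'   `is_exploration`).
#' @export
label_explorations <- function(visits) {
  v <- as_dt(visits)
  assert_cols(v, c("user_id", "t_start", "poi_id"), "visits")
  setorder(v, user_id, t_start)
  v[, is_exploration := !duplicated(poi_id), by = user_id]
  v[, S_before := cumsum(is_exploration) - is_exploration, by = user_id]
  v[, .(user_id, t_start, poi_id, S_before, is_exploration)]
}

#' Fit the exploration law p(S) = rho * S^-gamma
#'
#' Estimates the exploration-probability decay from labelled events: the
#' empirical exploration fraction at each distinct-place count `S >= 1`
#' (S = 0 is forced exploration and excluded) is regressed on `S` on the
#' log--log scale, weighted by the number of events at each `S`.
#' A binomial maximum-likelihood fit is available with `method = "mle"`.
#'
#' @param events output of [label_explorations()].
#' @param method `"wls"` (default) or `"mle"`.
#' @return list with `rho`, `gamma`, 95% confidence intervals
#'   (`rho_ci`, `gamma_ci`), and the per-S fraction table `by_S`.
#' @export
fit_exploration_law <- function(events, method = c("wls", "mle")) {
  method <- match.arg(method)
  ev <- as_dt(events)
  assert_cols(ev, c("S_before", "is_exploration"), "events")
  ev <- ev[S_before >= 1]
  if (nrow(ev) == 0) stop("no informative states", call. = FALSE)
  by_S <- ev[, .(n = .N, k = sum(is_exploration)), by = .(S = S_before)]
  by_S[, p := k / n]
  setorder(by_S, S)
  if (nrow(by_S) < 2) stop("no informative states", call. = FALSE)

  if (method == "wls") {
    fitd <- by_S[p > 0]
    if (nrow(fitd) < 2) stop("no informative states", call. = FALSE)
    fit <- lm(log(p) ~ log(S), data = fitd, weights = fitd$n)
    rho <- unname(exp(coef(fit)[1]))
    gamma <- unname(-coef(fit)[2])
    ci <- tryCatch(suppressMessages(confint(fit)),
                   error = function(e) matrix(NA_real_, 2, 2))
    rho_ci <- exp(unname(ci[1, ]))
    gamma_ci <- sort(-unname(ci[2, ]))
  } else {
    nll <- function(par) {
      r <- exp(par[1])
      g <- par[2]
      pp <- pmin(pmax(r * by_S$S^(-g), 1e-12), 1 - 1e-12)
      -sum(by_S$k * log(pp) + (by_S$n - by_S$k) * log(1 - pp))
    }
    opt <- stats::optim(c(log(0.5), 0.1), nll, hessian = TRUE,
                        method = "BFGS")
    rho <- exp(opt$par[1])
    gamma <- opt$par[2]
    se <- sqrt(diag(solve(opt$hessian)))
    rho_ci <- exp(opt$par[1] + c(-1.96, 1.96) * se[1])
    gamma_ci <- opt$par[2] + c(-1.96, 1.96) * se[2]
  }
  list(rho = rho, gamma = gamma, rho_ci = rho_ci, gamma_ci = gamma_ci,
       by_S = by_S[], method = method)
}

#' Majority income quantile per place
#'
#' The income quantile contributing the largest exposure share at each
#' place, from baseline-window exposures; ties are broken towards the
#' lowest quantile and flagged. Held fixed across periods so that social
#' exploration reflects choice behaviour rather than period-specific
#' re-labelling.
#'
#' @param place_exposures output of [place_exposure()] on the baseline
#'   window.
#' @return data.table (`poi_id`, `majority_quantile`, `tie_flag`), one row
#'   per place per window present.
#' @export
majority_labels <- function(place_exposures) {
  pe <- as_dt(place_exposures)
  Q <- attr(place_exposures, "Q") %||% sum(grepl("^tau_\\d+$", names(pe)))
  tm <- as.matrix(pe[, tau_cols(Q), with = FALSE])
  maj <- max.col(tm, ties.method = "first")
  mx <- tm[cbind(seq_len(nrow(tm)), maj)]
  tie <- rowSums(abs(tm - mx) < 1e-12) > 1
  out <- data.table(poi_id = pe$poi_id, majority_quantile = as.integer(maj),
                    tie_flag = tie)
  if ("window" %in% names(pe)) out[, window := pe$window]
  out[]
}

#' Estimate the social exploration probability
#'
#' The empirical probability that an exploration (first visit to a new
#' place) lands where the explorer's income quantile is not the place's
#' majority quantile:
#' `sigma_hat = #(explorations with majority != own quantile) /
#' #(labelled explorations)`, with an exact binomial 95% confidence
#' interval. Tie-flagged places are excluded from the denominator by
#' default.
#'
#' @param events output of [label_explorations()] for the period.
#' @param labels majority labels ([majority_labels()] on the baseline, or
#'   generator ground truth as `poi_id` + `majority_quantile`).
#' @param profiles profile table with `user_id`, `income_quantile`.
#' @param include_ties keep tie-flagged places (labelled by the lowest-q
#'   rule).
#' @return list with `sigma_s`, `ci`, `n_explorations`.
#' @export
estimate_social_exploration <- function(events, labels, profiles,
                                        include_ties = FALSE) {
  ev <- as_dt(events)[is_exploration == TRUE]
  labels <- as_dt(labels)
  assert_cols(labels, c("poi_id", "majority_quantile"), "labels")
  if (!include_ties && "tie_flag" %in% names(labels)) {
    labels <- labels[tie_flag == FALSE]
  }
  m <- merge(ev, unique(labels[, .(poi_id, majority_quantile)]),
             by = "poi_id")
  m <- merge(m, as_dt(profiles)[, .(user_id, income_quantile)],
             by = "user_id")
  n <- nrow(m)
  if (n == 0) stop("no labelled explorations: sigma_s undefined", call. = FALSE)
  k <- sum(m$majority_quantile != m$income_quantile)
  ci <- as.numeric(binom.test(k, n)$conf.int)
  list(sigma_s = k / n, ci = ci, n_explorations = n)
}

#' Subcategory popularity
#'
#' The share of individuals whose top-`r` most frequently visited places
#' include at least one POI of each subcategory. Per-user top-`r` sets
#' rank POIs by visit count, breaking ties by larger total dwell and then
#' smaller `poi_id`; when a user has fewer than `r` distinct POIs the set
#' is all of them.
#'
#' @param visits attributed visit table (optionally windowed).
#' @param poi_table POI table with `poi_id`, `subcategory`.
#' @param r size of the per-user top set (>= 1).
#' @return data.table (`window`, `subcategory`, `f_r`, `n_users`).
#' @export
subcategory_popularity <- function(visits, poi_table, r = 5L) {
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  v <- ensure_window(as_dt(visits))
  poi_table <- as_dt(poi_table)
  assert_cols(poi_table, c("poi_id", "subcategory"), "poi_table")
  agg <- v[, .(n_visits = .N, total_dwell = sum(dwell_min)),
           by = .(window, user_id, poi_id)]
  setorder(agg, window, user_id, -n_visits, -total_dwell, poi_id)
  agg[, visit_rank := seq_len(.N), by = .(window, user_id)]
  top <- agg[visit_rank <= r]
  top <- merge(top, poi_table[, .(poi_id, subcategory)], by = "poi_id")
  n_users <- v[, .(n_user = uniqueN(user_id)), by = window]
  out <- top[, .(n_with = uniqueN(user_id)), by = .(window, subcategory)]
  out <- merge(out, n_users, by = "window")
  out[, f_r := n_with / n_user]
  out[, .(window, subcategory, f_r, n_users = n_user)][order(window, -f_r)]
}

#' Change in subcategory popularity against a baseline
#'
#' @param current,baseline two [subcategory_popularity()] tables.
#' @return merged table with `delta_f_r = f_r - f_r_baseline`, sorted by
#'   decreasing change; subcategories absent from one side count as 0.
#' @export
popularity_change <- function(current, baseline) {
  cur <- as_dt(current)[, .(subcategory, f_r)]
  bas <- as_dt(baseline)[, .(subcategory, f_r_baseline = f_r)]
  m <- merge(cur, bas, by = "subcategory", all = TRUE)
  m[is.na(f_r), f_r := 0]
  m[is.na(f_r_baseline), f_r_baseline := 0]
  m[, delta_f_r := f_r - f_r_baseline]
  m[order(-delta_f_r)]
}
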