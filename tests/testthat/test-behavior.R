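test_that("exploration labelling flags first visits with correct S", {
  v <- tiny_visits(rep("u1", 4), c("A", "B", "A", "C"), 30)
  ev <- label_explorations(v)
  expect_equal(ev$is_exploration, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(ev$S_before, c(0L, 1L, 2L, 2L))
  one <- label_explorations(tiny_visits("u9", "Z", 20))
  expect_equal(one$is_exploration, TRUE)
  expect_equal(one$S_before, 0L)
})

test_that("exploration flags match a brute-force seen-set oracle", {
  set.seed(91)
  n <- 10000
  v <- tiny_visits(sample(paste0("u", 1:100), n, TRUE),
                   sample(paste0("a", 1:50), n, TRUE), 30)
  ev <- label_explorations(v)
  setorder(v, user_id, t_start)
  seen <- new.env(parent = emptyenv())
  want_flag <- logical(n)
  want_S <- integer(n)
  for (i in seq_len(n)) {
    key <- v$user_id[i]
    s <- if (is.null(seen[[key]])) character(0) else seen[[key]]
    want_S[i] <- length(s)
    want_flag[i] <- !(v$poi_id[i] %in% s)
    if (want_flag[i]) seen[[key]] <- c(s, v$poi_id[i])
  }
  expect_equal(ev$is_exploration, want_flag)
  expect_equal(ev$S_before, want_S)
  # total explorations = total distinct POIs over users
  expect_equal(sum(ev$is_exploration),
               v[, uniqueN(poi_id), by = user_id][, sum(V1)])
})

test_that("the exploration-law fit recovers a noiseless power law", {
  # exact fractions p(S) = 0.6 * S^-0.21 at S = 1..20, 1000 events each
  S <- rep(1:20, each = 1000)
  p <- 0.6 * (1:20)^(-0.21)
  flag <- unlist(lapply(1:20, function(s) {
    k <- round(1000 * p[s])
    c(rep(TRUE, k), rep(FALSE, 1000 - k))
  }))
  # rounding to integer counts perturbs p by < 5e-4
  ev <- data.table(user_id = "u", S_before = S, is_exploration = flag)
  fit <- fit_exploration_law(ev)
  expect_equal(fit$rho, 0.6, tolerance = 2e-3)
  expect_equal(fit$gamma, 0.21, tolerance = 5e-3)
  # a flat law has gamma ~ 0
  ev0 <- data.table(user_id = "u", S_before = S,
                    is_exploration = rep(c(TRUE, FALSE), length(S) / 2))
  fit0 <- fit_exploration_law(ev0)
  expect_lt(abs(fit0$gamma), 1e-10)
  expect_equal(fit0$rho, 0.5, tolerance = 1e-10)
  # S = 0 only -> no informative states
  expect_error(fit_exploration_law(
    data.table(user_id = "u", S_before = 0L, is_exploration = TRUE)),
    "no informative states")
  # MLE route agrees on clean data
  fitm <- fit_exploration_law(ev, method = "mle")
  expect_equal(fitm$rho, 0.6, tolerance = 5e-3)
  expect_equal(fitm$gamma, 0.21, tolerance = 2e-2)
})

test_that("majority labels take the argmax with low-quantile tie rule", {
  pe <- data.table(window = "w", poi_id = c("a", "b"),
                   tau_1 = c(0.6, 0.5), tau_2 = c(0.2, 0.5),
                   tau_3 = c(0.2, 0), tau_4 = c(0, 0))
  lab <- majority_labels(pe)
  expect_equal(lab$majority_quantile, c(1L, 1L))
  expect_equal(lab$tie_flag, c(FALSE, TRUE))
})

test_that("majority labels recover generator dominant quantiles", {
  w <- small_world()
  st <- simulate_period(w, epr_params(event_rate_per_quantile = 3),
                        scenario_config("2019-04"), n_days = 30, seed = 15)
  pe <- place_exposure(st, world_profiles(w))
  # restrict to high-support places: low-traffic POIs in thin
  # neighbourhoods can genuinely attract a non-dominant majority
  lab <- majority_labels(pe[support_users >= 60])
  m <- merge(lab, w$poi_table[, .(poi_id, dominant_quantile)], by = "poi_id")
  m <- m[tie_flag == FALSE]
  expect_gt(mean(m$majority_quantile == m$dominant_quantile), 0.95)
})

test_that("sigma_s estimator hits its boundaries and flags degenerate input", {
  labs <- data.table(poi_id = c("a", "b"), majority_quantile = c(1L, 2L),
                     tie_flag = FALSE)
  prof <- tiny_profiles("u1", 1)
  own <- data.table(user_id = "u1", t_start = Sys.time(), poi_id = "a",
                    S_before = 1L, is_exploration = TRUE)
  other <- copy(own)[, poi_id := "b"]
  expect_equal(estimate_social_exploration(own, labs, prof)$sigma_s, 0)
  expect_equal(estimate_social_exploration(other, labs, prof)$sigma_s, 1)
  expect_error(estimate_social_exploration(own[0], labs, prof),
               "no labelled explorations")
  # tie-flagged places are excluded from the denominator by default
  labs_tie <- copy(labs)[poi_id == "b", tie_flag := TRUE]
  expect_error(estimate_social_exploration(other, labs_tie, prof),
               "no labelled explorations")
  expect_equal(estimate_social_exploration(other, labs_tie, prof,
                                           include_ties = TRUE)$sigma_s, 1)
})

test_that("sigma_s is invariant to relabelling and within-POI order", {
  w <- small_world()
  st <- simulate_period(w, epr_params(sigma_s = 0.35),
                        scenario_config("2019-04"), n_days = 10, seed = 19)
  prof <- world_profiles(w)
  labs <- ground_truth_labels(w)
  s1 <- estimate_social_exploration(label_explorations(st), labs, prof)
  # shuffle row order; first-visit structure is unchanged
  s2 <- estimate_social_exploration(
    label_explorations(st[sample(.N)]), labs, prof)
  expect_equal(s1$sigma_s, s2$sigma_s)
  expect_equal(s1$n_explorations, s2$n_explorations)
})

test_that("subcategory popularity matches a per-user sort oracle", {
  poi <- data.table(poi_id = paste0("a", 1:12),
                    subcategory = rep(c("Grocery Store", "Cafe", "Gym"), 4))
  set.seed(97)
  n <- 3000
  v <- tiny_visits(sample(paste0("u", 1:200), n, TRUE),
                   sample(poi$poi_id, n, TRUE), runif(n, 10, 60))
  r <- 5
  tab <- subcategory_popularity(v, poi, r = r)
  # oracle: per user, sort POIs by count, dwell, id; collect top-r subcats
  agg <- v[, .(n_visits = .N, dwell = sum(dwell_min)),
           by = .(user_id, poi_id)]
  users <- unique(v$user_id)
  hit <- sapply(sort(unique(poi$subcategory)), function(sc) {
    mean(sapply(users, function(u) {
      du <- agg[user_id == u][order(-n_visits, -dwell, poi_id)]
      top <- head(du$poi_id, r)
      any(poi[poi_id %in% top, subcategory] == sc)
    }))
  })
  got <- setNames(tab$f_r, tab$subcategory)[names(hit)]
  expect_equal(unname(got), unname(hit))
  # f_r is monotone non-decreasing in r
  f3 <- subcategory_popularity(v, poi, r = 3)
  m <- merge(f3[, .(subcategory, f3 = f_r)], tab[, .(subcategory, f5 = f_r)],
             by = "subcategory", all = TRUE)
  m[is.na(f3), f3 := 0]
  expect_true(all(m$f5 >= m$f3 - 1e-12))
  expect_error(subcategory_popularity(v, poi, r = 0), "r must be")
})

test_that("single-POI users and r overflow behave as documented", {
  poi <- data.table(poi_id = c("g", "c"), subcategory = c("Grocery", "Cafe"))
  v <- tiny_visits(c("u1", "u1"), c("g", "g"), c(30, 40))
  tab <- subcategory_popularity(v, poi, r = 1)
  expect_equal(tab[subcategory == "Grocery", f_r], 1)
  # r beyond the user's distinct POIs takes all of them
  v2 <- tiny_visits(c("u1", "u1"), c("g", "c"), c(30, 40))
  tab2 <- subcategory_popularity(v2, poi, r = 10)
  expect_equal(sort(tab2$f_r), c(1, 1))
})

test_that("popularity change ranks shifted subcategories", {
  a <- data.table(window = "2020-04", subcategory = c("Grocery", "Gym"),
                  f_r = c(0.8, 0.1), n_users = 10L)
  b <- data.table(window = "2019-04", subcategory = c("Grocery", "Gym"),
                  f_r = c(0.6, 0.5), n_users = 10L)
  ch <- popularity_change(a, b)
  expect_equal(ch$subcategory, c("Grocery", "Gym"))
  expect_equal(ch$delta_f_r, c(0.2, -0.4))
})
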