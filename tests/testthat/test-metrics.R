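test_that("place exposure vectors are dwell shares by quantile", {
  v <- tiny_visits(paste0("u", 1:4), "a", c(30, 30, 30, 30))
  p <- tiny_profiles(paste0("u", 1:4), 1:4)
  pe <- place_exposure(v, p)
  expect_equal(unlist(pe[, paste0("tau_", 1:4), with = FALSE]),
               rep(0.25, 4), ignore_attr = TRUE)

  v2 <- tiny_visits(paste0("u", 1:3), "a", c(60, 20, 20))
  p2 <- tiny_profiles(paste0("u", 1:3), c(1, 2, 3))
  pe2 <- place_exposure(v2, p2, Q = 4)
  expect_equal(unlist(pe2[, paste0("tau_", 1:4), with = FALSE]),
               c(0.6, 0.2, 0.2, 0), ignore_attr = TRUE)

  # all dwell from one quantile
  pe3 <- place_exposure(tiny_visits("u1", "a", 50), tiny_profiles("u1", 2),
                        Q = 4)
  expect_equal(unlist(pe3[, paste0("tau_", 1:4), with = FALSE]),
               c(0, 1, 0, 0), ignore_attr = TRUE)

  # brute-force per-visit accumulation oracle on a random fixture
  set.seed(17)
  n <- 500
  v4 <- tiny_visits(sample(paste0("u", 1:40), n, TRUE),
                    sample(paste0("a", 1:15), n, TRUE),
                    runif(n, 10, 240))
  p4 <- tiny_profiles(paste0("u", 1:40), sample(1:4, 40, TRUE),
                      weights = runif(40, 0.5, 2))
  pe4 <- place_exposure(v4, p4)
  vv <- merge(v4, p4, by = "user_id")
  for (a in unique(v4$poi_id)) {
    sub <- vv[poi_id == a]
    want <- sapply(1:4, function(q)
      sum(sub[income_quantile == q, weight * dwell_min])) /
      sum(sub$weight * sub$dwell_min)
    got <- unlist(pe4[poi_id == a, paste0("tau_", 1:4), with = FALSE])
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("evenness diversity has the printed boundary behaviour", {
  expect_identical(evenness_diversity(c(0.25, 0.25, 0.25, 0.25)), 1)
  expect_identical(evenness_diversity(c(1, 0, 0, 0)), 0)
  expect_equal(evenness_diversity(c(0.5, 0.5, 0, 0)), 1 / 3)
  # generalized normalization at Q = 2
  expect_equal(evenness_diversity(c(1, 0)), 0)
  expect_equal(evenness_diversity(c(0.5, 0.5)), 1)
  expect_error(evenness_diversity(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(evenness_diversity(c(1.2, -0.2, 0, 0)), "nonnegative")
})

test_that("entropy diversity matches its closed form", {
  expect_equal(entropy_diversity(rep(0.25, 4)), 1)
  expect_equal(entropy_diversity(c(0, 1, 0, 0)), 0)
  expect_equal(entropy_diversity(c(0.5, 0.5, 0, 0)), 0.5)  # ln2 / ln4
})

test_that("diversity metrics stay in [0,1] and agree in rank on Dirichlet draws", {
  set.seed(23)
  g <- matrix(rgamma(4e4, shape = 0.7), ncol = 4)
  tau <- g / rowSums(g)
  de <- evenness_diversity(tau)
  dh <- entropy_diversity(tau)
  expect_true(all(de >= 0 & de <= 1))
  expect_true(all(dh >= 0 & dh <= 1))
  expect_gt(cor(de, dh, method = "spearman"), 0.9)
})

test_that("individual exposure is the time-share mixture of place exposures", {
  # one-place individual inherits that place's vector exactly
  v <- tiny_visits(c("u1", "u2", "u3"), c("a", "a", "a"), c(30, 60, 30))
  p <- tiny_profiles(paste0("u", 1:3), c(1, 2, 4))
  pe <- place_exposure(v, p, Q = 4)
  ie <- individual_exposure(v, pe)
  for (u in paste0("u", 1:3)) {
    expect_equal(unlist(ie[user_id == u, paste0("tau_", 1:4), with = FALSE]),
                 unlist(pe[, paste0("tau_", 1:4), with = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("tau_iq matches a triple-loop brute force to 1e-12", {
  set.seed(29)
  n <- 600
  v <- tiny_visits(sample(paste0("u", 1:50), n, TRUE),
                   sample(paste0("a", 1:20), n, TRUE),
                   runif(n, 10, 240))
  p <- tiny_profiles(paste0("u", 1:50), sample(1:4, 50, TRUE))
  pe <- place_exposure(v, p)
  ie <- individual_exposure(v, pe)
  # brute force: tau_iq = sum_a tau_ia * tau_qa
  tau_qa <- as.matrix(pe[, paste0("tau_", 1:4), with = FALSE])
  rownames(tau_qa) <- pe$poi_id
  dwell <- v[, .(d = sum(dwell_min)), by = .(user_id, poi_id)]
  for (u in unique(v$user_id)) {
    du <- dwell[user_id == u]
    tau_ia <- du$d / sum(du$d)
    want <- rep(0, 4)
    for (j in seq_len(nrow(du))) {
      for (q in 1:4) {
        want[q] <- want[q] + tau_ia[j] * tau_qa[du$poi_id[j], q]
      }
    }
    got <- unlist(ie[user_id == u, paste0("tau_", 1:4), with = FALSE])
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
  }
  # conservation
  expect_equal(rowSums(as.matrix(ie[, paste0("tau_", 1:4), with = FALSE])),
               rep(1, nrow(ie)), tolerance = 1e-9)
})

test_that("merging two places with identical exposure leaves tau unchanged", {
  v <- tiny_visits(c("u1", "u2", "u1", "u2"), c("a", "a", "b", "b"),
                   c(40, 40, 20, 20))
  p <- tiny_profiles(c("u1", "u2"), c(1, 3))
  pe <- place_exposure(v, p, Q = 4)
  merged <- copy(v)[, poi_id := "ab"]
  pem <- place_exposure(merged, p, Q = 4)
  expect_equal(unlist(pem[, paste0("tau_", 1:4), with = FALSE]),
               unlist(pe[poi_id == "a", paste0("tau_", 1:4), with = FALSE]),
               ignore_attr = TRUE)
})

test_that("unit weights equal the unweighted computation exactly", {
  set.seed(41)
  n <- 200
  v <- tiny_visits(sample(paste0("u", 1:20), n, TRUE),
                   sample(paste0("a", 1:8), n, TRUE), runif(n, 10, 240))
  p1 <- tiny_profiles(paste0("u", 1:20), sample(1:4, 20, TRUE), weights = 1)
  p2 <- copy(p1)[, weight := NULL]
  expect_identical(place_exposure(v, p1), place_exposure(v, p2))
})

test_that("CBG aggregation is the unweighted resident mean", {
  panel <- data.table(entity_kind = "individual",
                      entity_id = c("u1", "u2", "u3"),
                      window = "2019-04", D = c(0.4, 0.6, 0.9),
                      metric = "evenness", Q = 4L, support = 5L,
                      qualified = TRUE)
  prof <- data.table(user_id = c("u1", "u2", "u3"),
                     home_cbg = c("c1", "c1", "c2"))
  agg <- aggregate_cbg(panel, prof)
  expect_equal(agg[entity_id == "c1", D], 0.5)
  expect_equal(agg[entity_id == "c2", D], 0.9)  # single resident
  # permutation invariance
  agg2 <- aggregate_cbg(panel[c(3, 1, 2)], prof)
  expect_equal(agg[order(entity_id)], agg2[order(entity_id)])
})

test_that("percentage change compares means to the same 2019 month", {
  mk <- function(window, d) data.table(entity_kind = "individual",
                                       entity_id = paste0("u", seq_along(d)),
                                       window = window, D = d,
                                       metric = "evenness", Q = 4L,
                                       support = 1L, qualified = TRUE)
  panel <- mk("2020-04", c(0.40, 0.50))
  base <- mk("2019-04", c(0.45, 0.55))
  dd <- delta_percent(panel, base)
  expect_equal(dd$delta_pct, -10)
  # identical panels -> 0% everywhere
  same <- rbind(mk("2020-03", c(0.3, 0.5)), mk("2020-04", c(0.2, 0.6)))
  base2 <- rbind(mk("2019-03", c(0.3, 0.5)), mk("2019-04", c(0.2, 0.6)))
  expect_equal(delta_percent(same, base2)$delta_pct, c(0, 0))
  expect_error(delta_percent(mk("2020-05", 0.4), base), "baseline")
  expect_error(delta_percent(panel, mk("2019-04", c(0, 0))), "zero baseline")
})

test_that("deseasonalization divides by the same-month baseline", {
  base <- data.table(window = sprintf("2019-%02d", 1:12),
                     value = 1 + 0.2 * sin(2 * pi * (1:12) / 12))
  s <- data.table(window = sprintf("2020-%02d", 1:12), value = base$value)
  expect_equal(deseasonalize(s, base)$deseasonalized, rep(1, 12))
  s2 <- copy(s)[, value := value * 2]
  expect_equal(deseasonalize(s2, base)$deseasonalized, rep(2, 12))
  expect_error(deseasonalize(data.table(window = "2020-01", value = 1),
                             base[2:12]), "missing baseline")
  expect_error(deseasonalize(s, rbind(base, base[1])), "more than one")
})

test_that("generator seasonality is removed by 2019-trend normalization", {
  w <- small_world()
  amp <- 0.3
  monthly_visits <- function(year, seed0) {
    sapply(1:6, function(m) {
      sc <- scenario_config(sprintf("%d-%02d", year, m),
                            seasonal_amplitude = amp)
      nrow(simulate_period(w, epr_params(event_rate_per_quantile = 1),
                           sc, n_days = 10, seed = seed0 + m))
    })
  }
  v19 <- monthly_visits(2019, 300)
  v20 <- monthly_visits(2020, 400)
  raw_spread <- diff(range(v20 / mean(v20)))
  des <- deseasonalize(
    data.table(window = sprintf("2020-%02d", 1:6), value = as.numeric(v20)),
    data.table(window = sprintf("2019-%02d", 1:6), value = as.numeric(v19)))
  des_spread <- diff(range(des$deseasonalized))
  expect_lt(des_spread, raw_spread)
  expect_true(all(abs(des$deseasonalized - 1) < 0.1))
})

test_that("mobility metrics match their definitions and a brute-force r_g", {
  # all visits at one POI -> zero radius of gyration
  v1 <- tiny_visits(rep("u1", 3), "a", c(20, 30, 40))
  v1[, `:=`(lon = 1.0, lat = 2.0)]
  m1 <- mobility_metrics(v1)
  expect_equal(m1$radius_gyration_km, 0)
  expect_equal(m1$n_unique_pois, 1L)

  # 6 visits across 3 active days -> 2 visits/day
  v2 <- data.table(user_id = "u1",
                   poi_id = rep(c("a", "b"), 3),
                   dwell_min = 30,
                   t_start = as.POSIXct("2019-04-01", tz = "UTC") +
                     rep(c(0, 1, 2), each = 2) * 86400 + c(0, 3600),
                   lon = rnorm(6, 0, 0.01), lat = rnorm(6, 0, 0.01))
  m2 <- mobility_metrics(v2)
  expect_equal(m2$visits_per_day, 2)
  expect_equal(m2$dwell_min_per_day, 60)

  # brute-force two-pass oracle for the radius of gyration
  set.seed(47)
  v3 <- data.table(user_id = "u1", poi_id = sample(letters, 100, TRUE),
                   dwell_min = 30,
                   t_start = as.POSIXct("2019-04-01", tz = "UTC") +
                     seq_len(100) * 600,
                   lon = rnorm(100, -71, 0.05), lat = rnorm(100, 42, 0.05))
  m3 <- mobility_metrics(v3)
  clon <- mean(v3$lon); clat <- mean(v3$lat)
  rg <- sqrt(mean(haversine_km(v3$lon, v3$lat, clon, clat)^2))
  expect_equal(m3$radius_gyration_km, rg, tolerance = 1e-9)
})
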