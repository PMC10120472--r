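# Area-level heterogeneity: place-visit feature blocks, fixed-effects
# OLS with absorbed geography dummies, and the stringency trade-off.

#' Build the CBG place-visit feature block
#'
#' From baseline-year visits: a subcategory qualifies if it has at least
#' `min_venues` venues in the POI table; an individual's indicator for a
#' qualifying subcategory is 1 when more than `share_threshold` of their
#' dwell time is spent there; the CBG feature is the mean indicator over
#' the CBG's observed residents (the share of residents exceeding the
#' rule).
#'
#' @param visits_2019 attributed baseline visits.
#' @param poi_table POI table with `poi_id`, `subcategory`.
#' @param profiles profile table with `user_id`, `home_cbg`.
#' @param min_venues minimum venue count for a subcategory to qualify.
#' @param share_threshold dwell-share threshold for the individual
#'   indicator.
#' @return data.table keyed by `cbg_id` with one `P_`-prefixed column per
#'   qualifying subcategory; zero feature columns (with a warning) when
#'   none qualify.
#' @export
build_place_vector <- function(visits_2019, poi_table, profiles,
                               min_venues = 100L, share_threshold = 0.003) {
  v <- as_dt(visits_2019)
  poi_table <- as_dt(poi_table)
  profiles <- as_dt(profiles)
  counts <- poi_table[, .N, by = subcategory]
  qualifying <- counts[N >= min_venues, subcategory]
  homes <- profiles[, .(user_id, home_cbg)]
  if (!length(qualifying)) {
    warning("no subcategory qualifies; returning an empty feature block",
            call. = FALSE)
    return(unique(merge(v[, .(user_id)], homes,
                        by = "user_id"))[, .(cbg_id = unique(home_cbg))])
  }
  v <- merge(v, poi_table[, .(poi_id, subcategory)], by = "poi_id")
  shares <- v[, .(sub_dwell = sum(dwell_min)),
              by = .(user_id, subcategory)]
  shares[, share := sub_dwell / sum(sub_dwell), by = user_id]
  ind <- shares[subcategory %in% qualifying & share > share_threshold]
  users <- unique(v$user_id)
  wide <- dcast(ind, user_id ~ subcategory, fun.aggregate = length,
                value.var = "share")
  # users with no qualifying indicator still count in the resident mean
  missing_users <- setdiff(users, wide$user_id)
  if (length(missing_users)) {
    wide <- rbind(wide, data.table(user_id = missing_users), fill = TRUE)
  }
  for (cc in setdiff(qualifying, names(wide))) wide[, (cc) := 0L]
  for (cc in qualifying) set(wide, which(is.na(wide[[cc]])), cc, 0L)
  wide <- merge(wide, homes, by = "user_id")
  out <- wide[, lapply(.SD, mean), by = .(cbg_id = home_cbg),
              .SDcols = qualifying]
  setnames(out, qualifying, paste0("P_", gsub("[^A-Za-z0-9]+", "_", qualifying)))
  out[]
}

#' Standardize covariate columns
#'
#' Centres and scales each column to zero mean and unit variance within
#' the supplied sample; constant columns are dropped with a warning.
#'
#' @param dt data.table.
#' @param cols columns to standardize.
#' @return a copy of `dt` with standardized columns (constants removed).
#' @export
standardize_covariates <- function(dt, cols) {
  out <- as_dt(dt)
  drop <- character(0)
  for (cc in cols) {
    s <- sd(out[[cc]])
    if (!is.finite(s) || s == 0) {
      drop <- c(drop, cc)
      next
    }
    set(out, j = cc, value = (out[[cc]] - mean(out[[cc]])) / s)
  }
  if (length(drop)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    out[, (drop) := NULL]
  }
  out[]
}

#' Fixed-effects OLS with absorbed group dummies
#'
#' Within-group demeaning of the outcome and covariates followed by
#' ordinary least squares, numerically identical to including one dummy
#' per group. Classical standard errors use the dummy-model degrees of
#' freedom `n - k - G`; heteroskedasticity-robust (HC1) errors are
#' available behind `robust`. Adjusted R-squared accounts for the
#' absorbed fixed effects. Collinear covariate columns are dropped by
#' pivoted QR with a warning, and a variance-inflation-factor report is
#' attached.
#'
#' @param data data.table holding outcome, covariates and the group
#'   column.
#' @param y outcome column name.
#' @param covariates character vector of covariate column names
#'   (standardized; see [standardize_covariates()]).
#' @param fe_group fixed-effect group column name (e.g. a PUMA id).
#' @param robust use HC1 standard errors.
#' @return object of class `fe_ols`: coefficient table with 95% CIs and
#'   two-sided p-values, `r2`, `adj_r2`, `n`, `n_groups`, `df`,
#'   `dropped`, `vif`.
#' @export
fit_fe_ols <- function(data, y, covariates, fe_group, robust = FALSE) {
  data <- as_dt(data)
  model_cols <- c(y, covariates, fe_group)
  assert_cols(data, model_cols, "data")
  keep <- stats::complete.cases(as.data.frame(data)[, model_cols])
  data <- data[keep]
  g <- as.factor(data[[fe_group]])
  G <- nlevels(g)
  if (G < 2) stop("need at least 2 fixed-effect groups", call. = FALSE)
  yv <- data[[y]]
  X <- as.matrix(data[, covariates, with = FALSE])
  n <- length(yv)

  demean <- function(v) v - ave(v, g)
  yd <- demean(yv)
  Xd <- apply(X, 2, demean)

  # drop collinear columns left to right, keeping the earliest of any
  # linearly dependent set
  keep_cols <- integer(0)
  for (j in seq_len(ncol(Xd))) {
    cand <- Xd[, c(keep_cols, j), drop = FALSE]
    if (qr(cand)$rank == length(keep_cols) + 1L) keep_cols <- c(keep_cols, j)
  }
  dropped <- covariates[setdiff(seq_along(covariates), keep_cols)]
  if (length(dropped)) {
    warning(sprintf("dropping collinear covariate(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  kept <- covariates[keep_cols]
  Xd <- Xd[, keep_cols, drop = FALSE]
  k <- ncol(Xd)
  df <- n - k - G
  if (df <= 0) stop("not enough observations for the model", call. = FALSE)

  XtX <- crossprod(Xd)
  beta <- solve(XtX, crossprod(Xd, yd))
  res <- yd - Xd %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / df
  if (robust) {
    meat <- crossprod(Xd * as.numeric(res))
    bread <- solve(XtX)
    vcov_b <- bread %*% meat %*% bread * n / df
  } else {
    vcov_b <- sigma2 * solve(XtX)
  }
  se <- sqrt(diag(vcov_b))
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(0.975, df)

  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df

  vif <- rep(NA_real_, k)
  if (k > 1) {
    cx <- stats::cor(Xd)
    inv <- tryCatch(solve(cx), error = function(e) NULL)
    if (!is.null(inv)) vif <- diag(inv)
  }

  structure(list(
    coefficients = data.table(term = kept, estimate = as.numeric(beta),
                              se = se, t = tval, p = pval,
                              ci_lo = as.numeric(beta) - crit * se,
                              ci_hi = as.numeric(beta) + crit * se),
    r2 = r2, adj_r2 = adj_r2, n = n, n_groups = G, df = df,
    dropped = dropped, vif = data.table(term = kept, vif = vif),
    robust = robust
  ), class = "fe_ols")
}

#' @export
print.fe_ols <- function(x, ...) {
  cat(sprintf("<fe_ols> n = %d, groups = %d, R2 = %.4f, adj R2 = %.4f%s\n",
              x$n, x$n_groups, x$r2, x$adj_r2,
              if (x$robust) " (HC1 SEs)" else ""))
  print(x$coefficients)
  if (length(x$dropped)) {
    cat("dropped collinear:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stringency--diversity trade-off
#'
#' Per metro area (CBSA), the Pearson correlation between the monthly
#' change in experienced income diversity and the policy stringency
#' index, with a two-sided p-value, a companion OLS slope with its 95%
#' CI, and a lag-1 autocorrelation diagnostic of the diversity-change
#' series.
#'
#' @param delta_series data.table (`cbsa_id`, `window`, `delta_pct`).
#' @param si_series data.table (`cbsa_id`, `window`, `SI`) with
#'   `SI` in \[0, 100\].
#' @return data.table, one row per CBSA: `rho`, `p_value`, `slope`,
#'   `slope_lo`, `slope_hi`, `n_months`, `lag1_autocorr`.
#' @export
stringency_tradeoff <- function(delta_series, si_series) {
  d <- as_dt(delta_series)
  s <- as_dt(si_series)
  assert_cols(d, c("cbsa_id", "window", "delta_pct"), "delta_series")
  assert_cols(s, c("cbsa_id", "window", "SI"), "si_series")
  if (any(s$SI < 0 | s$SI > 100)) {
    stop("SI must lie in [0, 100]", call. = FALSE)
  }
  m <- merge(d, s, by = c("cbsa_id", "window"))
  setorder(m, cbsa_id, window)
  m[, {
    if (.N < 3) stop("fewer than 3 aligned months for CBSA ", cbsa_id[1],
                     call. = FALSE)
    if (sd(SI) == 0) stop("constant stringency index for CBSA ", cbsa_id[1],
                          ": correlation undefined", call. = FALSE)
    ct <- cor.test(SI, delta_pct, method = "pearson")
    fit <- lm(delta_pct ~ SI)
    ci <- suppressWarnings(confint(fit)["SI", ])  # silent on perfect fits
    x <- delta_pct
    l1 <- if (.N >= 3 && sd(x) > 0) {
      stats::cor(x[-1], x[-length(x)])
    } else NA_real_
    .(rho = unname(ct$estimate), p_value = ct$p.value,
      slope = unname(coef(fit)["SI"]), slope_lo = ci[1], slope_hi = ci[2],
      n_months = .N, lag1_autocorr = l1)
  }, by = cbsa_id]
}
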