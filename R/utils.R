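# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance in kilometres
#'
#' Haversine distance on the WGS84 mean Earth radius. Used for POI
#' attribution, home-to-place distances and the radius of gyration, where
#' the sub-kilometre scale makes the projection choice immaterial.
#'
#' @param lon1,lat1,lon2,lat2 coordinate vectors in decimal degrees.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Deterministic 31-bit substream seed derived from a global seed and an
# index (user id rank, replicate number, ...). Splitting the seed this way
# keeps per-user trajectories reproducible independently of user ordering.
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  # two rounds of a Lehmer-style mix; doubles are exact below 2^53
  x <- (x * 48271) %% m
  x <- (x + (as.numeric(index) %% m) * 16807) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

# "YYYY-MM" helpers -----------------------------------------------------

month_start <- function(label) {
  as.POSIXct(paste0(label, "-01 00:00:00"), tz = "UTC")
}

month_next <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  m <- as.integer(substr(label, 6, 7))
  m <- m + 1L
  if (m == 13L) {
    y <- y + 1L
    m <- 1L
  }
  sprintf("%04d-%02d", y, m)
}

month_prev <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  m <- as.integer(substr(label, 6, 7))
  m <- m - 1L
  if (m == 0L) {
    y <- y - 1L
    m <- 12L
  }
  sprintf("%04d-%02d", y, m)
}

month_of <- function(label) as.integer(substr(label, 6, 7))

year_of <- function(label) as.integer(substr(label, 1, 4))

assert_cols <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

as_dt <- function(x) {
  if (!data.table::is.data.table(x)) data.table::as.data.table(x) else data.table::copy(x)
}
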