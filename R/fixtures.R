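# Fixture serialization: CSV (always), Parquet (if arrow is available),
# GeoJSON for POI and CBG-centroid geometries, YAML echo of the world
# configuration for provenance.

geojson_points <- function(dt, lon_col, lat_col, prop_cols) {
  feats <- lapply(seq_len(nrow(dt)), function(i) {
    props <- as.list(dt[i, prop_cols, with = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(dt[[lon_col]][i], dt[[lat_col]][i])),
         properties = props)
  })
  list(type = "FeatureCollection", features = feats)
}

#' Write synthetic-world fixtures to disk
#'
#' Serialises the world tables and one or more stay tables: CSVs always,
#' Parquet alongside when the arrow package is installed, GeoJSON point
#' features for POIs and CBG centroids, and a YAML echo of the generating
#' configuration. Timestamps are written as ISO-8601 UTC.
#'
#' @param world an `urban_world`.
#' @param stays a stay table, or a named list of stay tables keyed by
#'   period label.
#' @param out_dir output directory (created if needed).
#' @param parquet also write Parquet stay tables (requires arrow).
#' @return invisibly, the character vector of files written.
#' @export
write_fixtures <- function(world, stays, out_dir, parquet = FALSE) {
  stopifnot(inherits(world, "urban_world"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
    }
  }
  if (is.data.frame(stays)) {
    lbl <- attr(stays, "period_label") %||% "period"
    stays <- setNames(list(stays), lbl)
  }
  files <- character(0)
  wr <- function(dt, name) {
    f <- file.path(out_dir, name)
    data.table::fwrite(dt, f, dateTimeAs = "ISO")
    files <<- c(files, f)
    f
  }
  wr(world$cbg_table, "cbgs.csv")
  wr(world$poi_table, "pois.csv")
  wr(world$user_table, "users.csv")
  for (lbl in names(stays)) {
    st <- stays[[lbl]]
    wr(st, sprintf("stays_%s.csv", lbl))
    if (parquet) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        warning("arrow not installed; skipping Parquet output", call. = FALSE)
      } else {
        f <- file.path(out_dir, sprintf("stays_%s.parquet", lbl))
        arrow::write_parquet(st, f)
        files <- c(files, f)
      }
    }
  }

  gj_poi <- geojson_points(world$poi_table, "lon", "lat",
                           c("poi_id", "category", "subcategory", "cbg_id",
                             "dominant_quantile"))
  gj_cbg <- geojson_points(world$cbg_table, "centroid_lon", "centroid_lat",
                           c("cbg_id", "median_income", "puma_id", "cbsa_id",
                             "income_quantile"))
  f <- file.path(out_dir, "pois.geojson")
  jsonlite::write_json(gj_poi, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(out_dir, "cbg_centroids.geojson")
  jsonlite::write_json(gj_cbg, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  cfg <- world$config
  f <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), f)
  files <- c(files, f)
  invisible(files)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir fixture directory.
#' @return a list with `cbg_table`, `poi_table`, `user_table`, `config`,
#'   and `stays` (a named list of stay tables keyed by period label, with
#'   `t_start` parsed back to POSIXct UTC).
#' @export
read_fixtures <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory '%s'", dir), call. = FALSE)
  rd <- function(name) data.table::fread(file.path(dir, name))
  out <- list(cbg_table = rd("cbgs.csv"), poi_table = rd("pois.csv"),
              user_table = rd("users.csv"),
              config = yaml::read_yaml(file.path(dir, "config.yaml")))
  stay_files <- list.files(dir, pattern = "^stays_.*\\.csv$")
  stays <- lapply(stay_files, function(fn) {
    st <- rd(fn)
    st[, t_start := as.POSIXct(t_start, tz = "UTC")]
    st
  })
  names(stays) <- sub("^stays_(.*)\\.csv$", "\\1", stay_files)
  out$stays <- stays
  out
}
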