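# Gridded data travel as long-format CSV (year, lat, lon, value; empty value
# = invalid cell), tabular summaries as plain CSV, configuration and run
# manifests as JSON.

#' Write / read a density series as long-format CSV
#'
#' Columns \code{year, lat, lon, density} (t C/ha); invalid cells are
#' written as empty fields and read back as invalid. The grid is
#' reconstructed from the unique coordinates, so a write/read round trip is
#' lossless for finite values.
#'
#' @param ds a \code{\link{density_series}}.
#' @param grid the \code{\link{grid_spec}} the series lives on.
#' @param path file path.
#' @param units unit string recorded in the header comment; densities in
#'   \code{kg C m-2} are converted to t C/ha (x10) on read.
#' @return \code{write_density_csv}: the path, invisibly.
#' @export
write_density_csv <- function(ds, grid, path, units = "t C ha-1") {
  co <- cell_coords(grid)
  ny <- length(ds$years)
  v <- ds$values
  v[!ds$valid] <- NA_real_
  df <- data.frame(year = rep(ds$years, each = grid$n_cell),
                   lat = rep(co[, "lat"], ny),
                   lon = rep(co[, "lon"], ny),
                   density = as.vector(t(v)))
  con <- file(path, "w")
  writeLines(sprintf("# woody biomass carbon density; units: %s", units), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  invisible(path)
}

#' @rdname write_density_csv
#' @return \code{read_density_csv}: a list with \code{densities} (a
#'   \code{\link{density_series}}) and \code{grid}.
#' @export
read_density_csv <- function(path) {
  header <- readLines(path, n = 1)
  units <- sub(".*units:\\s*", "", header)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year", "lat", "lon", "density")
  if (!all(need %in% names(df)))
    stop("read_density_csv: file must have columns year, lat, lon, density")
  scale <- if (grepl("kg\\s*C?\\s*m-2", units)) 10 else 1
  lat <- sort(unique(df$lat), decreasing = TRUE)
  lon <- sort(unique(df$lon))
  grid <- grid_spec(lat, lon)
  years <- sort(unique(df$year))
  vals <- matrix(NA_real_, length(years), grid$n_cell)
  i_lat <- match(df$lat, lat)
  i_lon <- match(df$lon, lon)
  idx <- cbind(match(df$year, years), cell_index(i_lat, i_lon, grid))
  vals[idx] <- df$density * scale
  list(densities = density_series(years, vals), grid = grid)
}

#' Write the annual decomposition series as CSV
#'
#' @param decomp a \code{bkm_decomposition}.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(decomp, path) {
  utils::write.csv(decomp$series, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Conservative (area-weighted) regridding
#'
#' Remaps a field between regular latitude-longitude grids by exact
#' interval-overlap area weighting on the sphere: each target cell takes the
#' overlap-area-weighted average of the source cells it intersects, which
#' preserves the global area-weighted integral.
#'
#' @param field vector (length source n_cell) or matrix \code{n_lat x
#'   n_lon} on the source grid.
#' @param src,tgt \code{\link{grid_spec}}s; the grids must overlap.
#' @return The field on the target grid (same shape convention as input).
#' @export
conservative_remap <- function(field, src, tgt) {
  was_matrix <- is.matrix(field)
  x <- matrix(as.vector(field), src$n_lat, src$n_lon)
  # interval overlap helpers on cell bounds
  bounds <- function(centres, d) cbind(centres - d / 2, centres + d / 2)
  olap <- function(b1, b2) {
    lo <- outer(b1[, 1], b2[, 1], pmax)
    hi <- outer(b1[, 2], b2[, 2], pmin)
    pmax(hi - lo, 0)
  }
  # latitudinal overlap weighted by sphere area (difference of sines)
  slat <- bounds(src$lat, src$dlat); tlat <- bounds(tgt$lat, tgt$dlat)
  lo <- outer(slat[, 1], tlat[, 1], pmax)
  hi <- outer(slat[, 2], tlat[, 2], pmin)
  wlat <- ifelse(hi > lo,
                 sin(pmin(hi, 90) * pi / 180) - sin(pmax(lo, -90) * pi / 180),
                 0)                                   # [src_lat, tgt_lat]
  wlon <- olap(bounds(src$lon, src$dlon), bounds(tgt$lon, tgt$dlon))
  if (all(wlat == 0) || all(wlon == 0))
    stop("conservative_remap: grids do not overlap")
  num <- t(wlat) %*% x %*% wlon                       # [tgt_lat, tgt_lon]
  den <- t(wlat) %*% matrix(1, src$n_lat, src$n_lon) %*% wlon
  if (any(den == 0))
    stop("conservative_remap: a target cell has no source coverage")
  out <- num / den
  if (was_matrix) out else as.vector(out)
}

#' Read and validate a pipeline configuration file (JSON)
#'
#' The configuration names the input paths and run parameters for the
#' command-line pipeline. Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return A validated named list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("density_csv", "out_dir", "start_year", "end_year", "seed",
             "tau_decay_clearing", "tau_decay_harvest", "tau_regrow",
             "harvest_intensity", "threshold_limit", "threshold_percentile",
             "grid_n_lat", "grid_n_lon", "env_trend", "clearing_rate",
             "harvest_rate", "abandon_rate", "missing_frac", "noise_sd",
             "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("read_pipeline_config: unknown keys: ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a machine-readable run manifest (JSON)
#'
#' @param path output path.
#' @param params named list of parameters to record; package version and
#'   timestamp are added.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, params = list()) {
  params$package <- "woodbkm"
  params$version <- as.character(utils::packageVersion("woodbkm"))
  params$r_version <- R.version.string
  params$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
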