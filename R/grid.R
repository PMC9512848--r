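#' Regular latitude-longitude grid specification
#'
#' Describes the regular grid all gridded inputs and pool states live on.
#' Cell areas are computed from the cell bounds on a sphere, so they are
#' reproducible bit-exactly from the coordinates: for a cell spanning
#' longitudes \eqn{[\lambda_0, \lambda_1]} (degrees) and latitudes
#' \eqn{[\phi_0, \phi_1]},
#' \deqn{A = R^2 (\lambda_1 - \lambda_0) \frac{\pi}{180}
#'       (\sin\phi_1 - \sin\phi_0)}
#' with \eqn{R} the Earth radius. Areas are in hectares.
#'
#' @param lat numeric vector of cell-centre latitudes in degrees, regularly
#'   spaced (stored as given; conventionally descending).
#' @param lon numeric vector of cell-centre longitudes in degrees, regularly
#'   spaced.
#' @param radius_m Earth radius in metres used for the spherical area formula.
#' @return An object of class \code{grid_spec}: a list with \code{n_lat},
#'   \code{n_lon}, \code{lat}, \code{lon}, \code{cell_area} (ha, a matrix
#'   \code{n_lat x n_lon} flattened cell-major in \code{area_vec}), and the
#'   number of cells \code{n_cell = n_lat * n_lon}.
#' @details Cells are indexed cell-major as \code{cell = (i_lon - 1) * n_lat
#'   + i_lat}, i.e. latitude varies fastest. Helper \code{\link{cell_index}}
#'   maps (lat, lon) indices to the flat cell index.
#' @examples
#' g <- grid_spec(lat = c(0.5, -0.5), lon = c(0.5, 1.5))
#' sum(g$area_vec) # area of the 2x2 degree patch in ha
#' @export
grid_spec <- function(lat, lon, radius_m = 6371000) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) < 1 || length(lon) < 1)
    stop("grid_spec: need at least one latitude and one longitude")
  if (length(lat) > 1) {
    dl <- diff(lat)
    if (max(abs(dl - dl[1])) > 1e-8 * max(abs(dl[1]), 1))
      stop("grid_spec: latitudes must be regularly spaced")
  }
  if (length(lon) > 1) {
    dn <- diff(lon)
    if (max(abs(dn - dn[1])) > 1e-8 * max(abs(dn[1]), 1))
      stop("grid_spec: longitudes must be regularly spaced")
  }
  dlat <- if (length(lat) > 1) abs(lat[2] - lat[1]) else 1
  dlon <- if (length(lon) > 1) abs(lon[2] - lon[1]) else 1
  a_lat <- cell_band_area(lat, dlat, dlon, radius_m) # ha, one per latitude
  area <- matrix(rep(a_lat, length(lon)), nrow = length(lat))
  if (any(area <= 0)) stop("grid_spec: nonpositive cell area")
  g <- list(
    n_lat = length(lat), n_lon = length(lon),
    n_cell = length(lat) * length(lon),
    lat = lat, lon = lon,
    dlat = dlat, dlon = dlon,
    cell_area = area,
    area_vec = as.vector(area),
    radius_m = radius_m
  )
  class(g) <- "grid_spec"
  g
}

# spherical quadrilateral area per latitude band, in hectares
cell_band_area <- function(lat, dlat, dlon, radius_m) {
  phi1 <- pmin(lat + dlat / 2, 90) * pi / 180
  phi0 <- pmax(lat - dlat / 2, -90) * pi / 180
  a_m2 <- radius_m^2 * (dlon * pi / 180) * (sin(phi1) - sin(phi0))
  a_m2 / 1e4
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%.4g deg x %.4g deg), area %.4g ha\n",
              x$n_lat, x$n_lon, x$dlat, x$dlon, sum(x$area_vec)))
  invisible(x)
}

#' Flat cell index from latitude/longitude indices
#'
#' @param i_lat,i_lon integer indices into \code{grid$lat} / \code{grid$lon}.
#' @param grid a \code{\link{grid_spec}}.
#' @return Integer cell index (latitude varies fastest).
#' @export
cell_index <- function(i_lat, i_lon, grid) {
  (i_lon - 1L) * grid$n_lat + i_lat
}

# cell-centre coordinates as an (n_cell x 2) matrix (lon, lat)
cell_coords <- function(grid) {
  cbind(lon = rep(grid$lon, each = grid$n_lat),
        lat = rep(grid$lat, times = grid$n_lon))
}
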