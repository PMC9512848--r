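#' Annual observed woody biomass carbon density series
#'
#' @param years integer vector of contiguous years.
#' @param values matrix \code{[n_year, n_cell]} of densities in t C per
#'   hectare; \code{NA} marks invalid cells.
#' @param valid optional logical mask \code{[n_year, n_cell]}; defaults to
#'   \code{!is.na(values)}.
#' @return Object of class \code{density_series}.
#' @export
density_series <- function(years, values, valid = NULL) {
  years <- as.integer(years)
  values <- as.matrix(values)
  if (length(years) != nrow(values))
    stop("density_series: one row of values per year")
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("density_series: years must be contiguous")
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.matrix(valid)
  if (!identical(dim(valid), dim(values)))
    stop("density_series: valid mask must match values")
  if (any(values[valid] < 0, na.rm = TRUE))
    stop("density_series: negative density where valid")
  ds <- list(years = years, values = values, valid = valid)
  class(ds) <- "density_series"
  ds
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf(
    "density_series: years %d-%d, %d cells, %.1f%% valid, mean %.3g tC/ha\n",
    min(x$years), max(x$years), ncol(x$values), 100 * mean(x$valid),
    mean(x$values[x$valid])))
  invisible(x)
}

# single-year density vector
density_year <- function(ds, year) {
  i <- match(year, ds$years)
  if (is.na(i)) stop(sprintf("no density field for year %d", year))
  list(rho = ds$values[i, ], valid = ds$valid[i, ])
}

#' Woody biomass fractions per cover type and PFT
#'
#' The fraction of a cell's total woody biomass carbon held in each woody
#' cover type (primary, secondary) and PFT,
#' \eqn{f_{B,j,l} = C_{B,j,l} / C_B}, computed from the model's living stock.
#' Cells with zero woody stock fall back to the static cover-by-PFT
#' area-fraction weights.
#'
#' @param state a \code{\link{pool_state}}.
#' @return Array \code{[n_cell, 2, n_pft]} (covers v, s) with nonnegative
#'   entries summing to 1 on every cell that has woody area or stock.
#' @export
compute_biomass_fractions <- function(state) {
  n <- state$grid$n_cell
  liv <- living_cp(state)[, WOODY_COVERS, , drop = FALSE]
  tot <- rowSums(matrix(liv, nrow = n))
  if (any(tot < -1e-9 * max(1, max(abs(liv)))))
    stop("compute_biomass_fractions: negative woody stock")
  f <- array(0, dim = c(n, 2L, state$n_pft),
             dimnames = list(NULL, WOODY_COVERS, NULL))
  pos <- tot > 0
  if (any(pos))
    f[pos, , ] <- liv[pos, , , drop = FALSE] / tot[pos]
  if (any(!pos)) {
    f0 <- static_woody_weights(state)
    f[!pos, , ] <- f0[!pos, , , drop = FALSE]
  }
  f
}

# static cover x PFT area-fraction weights over the woody covers
static_woody_weights <- function(state) {
  n <- state$grid$n_cell
  w <- array(0, dim = c(n, 2L, state$n_pft),
             dimnames = list(NULL, WOODY_COVERS, NULL))
  for (j in seq_along(WOODY_COVERS))
    w[, j, ] <- state$cover_frac[, WOODY_COVERS[j]] * state$pft_frac
  tot <- rowSums(matrix(w, nrow = n))
  pos <- tot > 0
  w[pos, , ] <- w[pos, , , drop = FALSE] / tot[pos]
  # cells without any woody area: uniform over slots (degenerate fallback)
  if (any(!pos)) w[!pos, , ] <- 1 / (2 * state$n_pft)
  w
}

#' Distribute an observed cell density into cover/PFT stocks
#'
#' Assimilated stock per cover type and PFT:
#' \eqn{C_{B,as,j,l} = \rho_{Ba} \, A \, f_{B,j,l}}. The sum over (j, l)
#' returns exactly \eqn{\rho_{Ba} A}.
#'
#' @param rho observed density per cell (t C/ha), vector of length n_cell.
#' @param area cell areas in ha.
#' @param f fractions from \code{\link{compute_biomass_fractions}}.
#' @param valid optional logical mask; invalid cells get \code{NA} stocks.
#' @return Array \code{[n_cell, 2, n_pft]} of stocks in t C.
#' @export
distribute_density <- function(rho, area, f, valid = NULL) {
  if (any(rho < 0, na.rm = TRUE))
    stop("distribute_density: negative density")
  tot <- rho * area
  out <- f * as.vector(tot)          # recycles over the cell axis
  if (!is.null(valid) && any(!valid)) out[!valid, , ] <- NA_real_
  out
}

#' Per cover/PFT densities from stocks
#'
#' Inverse of the distribution step: density = stock / (area x area
#' fraction). Zero-area slots must carry zero stock.
#'
#' @param stocks array \code{[n_cell, n_cover, n_pft]} in t C.
#' @param frac cover-PFT area fractions of the same shape (product of cover
#'   fraction and PFT fraction).
#' @param area cell areas in ha.
#' @return Densities in t C/ha, zero on zero-area slots.
#' @export
derive_cell_densities <- function(stocks, frac, area) {
  slot_area <- frac * as.vector(area)
  zero <- slot_area <= 0
  if (any(abs(stocks[zero]) > 1e-9))
    stop("derive_cell_densities: stock on a zero-area slot")
  dens <- array(0, dim = dim(stocks))
  dens[!zero] <- stocks[!zero] / slot_area[!zero]
  dens
}

#' Threshold policy for excluding inconsistent densities
#'
#' Two screening rules for assimilated per-(PFT, cover) densities: a uniform
#' upper limit (default 375 t C/ha, the ceiling of the source dataset), and a
#' percentile rule that additionally masks values above a chosen percentile
#' (default the 99th) of the values already below the uniform limit. Both
#' rules are applied per PFT and woody cover type over the whole time series.
#'
#' @param mode \code{"uniform"} or \code{"percentile"}.
#' @param limit uniform upper limit in t C/ha.
#' @param percentile percentile level in (0, 100].
#' @return Object of class \code{threshold_policy}.
#' @export
threshold_policy <- function(mode = c("uniform", "percentile"),
                             limit = 375, percentile = 99) {
  mode <- match.arg(mode)
  if (!(percentile > 0 && percentile <= 100))
    stop("threshold_policy: percentile must be in (0, 100]")
  if (limit <= 0) stop("threshold_policy: limit must be positive")
  p <- list(mode = mode, limit = limit, percentile = percentile)
  class(p) <- "threshold_policy"
  p
}

#' Apply a threshold policy to a per-(cover, PFT) density series
#'
#' Uniform mode masks values at or above the limit. Percentile mode
#' additionally masks, within the values below the uniform limit, those above
#' the stated percentile cutoff, computed per (cover, PFT) layer over all
#' years; percentile-mode exclusions are therefore a superset of uniform-mode
#' exclusions.
#'
#' @param series array \code{[n_year, n_cell, n_cover, n_pft]} of densities
#'   (t C/ha); \code{NA} entries are carried through as already-invalid.
#' @param policy a \code{\link{threshold_policy}}.
#' @return List with \code{mask} (logical array, TRUE = excluded),
#'   \code{cutoffs} (matrix \code{n_cover x n_pft} of applied upper limits)
#'   and \code{report}: data frame of excluded entries (year index, cell,
#'   cover, pft, value, rule).
#' @export
apply_thresholds <- function(series, policy) {
  series <- as.array(series)
  if (length(dim(series)) != 4L)
    stop("apply_thresholds: series must be [year, cell, cover, pft]")
  if (length(series) == 0 || all(is.na(series)))
    stop("apply_thresholds: empty series")
  nc <- dim(series)[3]; np <- dim(series)[4]
  mask <- array(FALSE, dim = dim(series))
  cutoffs <- matrix(policy$limit, nc, np)
  for (j in seq_len(nc)) for (l in seq_len(np)) {
    v <- series[, , j, l]
    m <- !is.na(v) & v >= policy$limit
    if (policy$mode == "percentile") {
      below <- v[!is.na(v) & v < policy$limit]
      if (length(below) > 0) {
        cut <- as.numeric(stats::quantile(below, policy$percentile / 100,
                                          type = 7, names = FALSE))
        cutoffs[j, l] <- min(cut, policy$limit)
        m <- m | (!is.na(v) & v < policy$limit & v > cut)
      }
    }
    mask[, , j, l] <- m
  }
  idx <- which(mask, arr.ind = TRUE)
  report <- data.frame(year_index = idx[, 1], cell = idx[, 2],
                       cover = idx[, 3], pft = idx[, 4],
                       value = series[mask],
                       rule = rep(policy$mode, nrow(idx)))
  list(mask = mask, cutoffs = cutoffs, report = report)
}

#' Fill masked cells of a single-year field by barycentric interpolation
#'
#' Masked (NA) cells are filled by linear barycentric interpolation on the
#' cell-centre coordinates: each gap takes the plane through the vertices of
#' a triangle of nearby valid cells that contains it (searched among the
#' nearest valid neighbours), which reproduces linear fields exactly. Gaps
#' inside the convex hull of the valid cells for which no clean containing
#' triangle is found fall back to a least-squares plane through the nearest
#' valid neighbours (also exact for linear fields); gaps outside the hull
#' take the nearest valid value. Valid cells are never changed.
#'
#' @param field numeric vector of length n_cell (or matrix n_lat x n_lon)
#'   with \code{NA} for masked cells.
#' @param grid a \code{\link{grid_spec}}.
#' @param k number of nearest valid neighbours considered per gap.
#' @return The completed field, same shape as the input.
#' @export
interpolate_missing <- function(field, grid, k = 12) {
  was_matrix <- is.matrix(field)
  x <- as.vector(field)
  if (length(x) != grid$n_cell)
    stop("interpolate_missing: field length must match grid")
  miss <- is.na(x)
  if (!any(miss)) return(field)
  ok <- which(!miss)
  if (length(ok) < 3)
    stop("interpolate_missing: need at least 3 valid cells")
  co <- cell_coords(grid)
  vx <- co[ok, 1]; vy <- co[ok, 2]; vz <- x[ok]
  if (max(vx) == min(vx) || max(vy) == min(vy))
    stop("interpolate_missing: valid cells are collinear")
  hull <- grDevices::chull(vx, vy)
  for (i in which(miss)) {
    px <- co[i, 1]; py <- co[i, 2]
    d2 <- (vx - px)^2 + (vy - py)^2
    nb <- order(d2)[seq_len(min(k, length(ok)))]
    inside <- point_in_poly(px, py, vx[hull], vy[hull])
    val <- NA_real_
    if (inside) {
      val <- bary_value(px, py, vx[nb], vy[nb], vz[nb])
      if (is.na(val)) val <- plane_value(px, py, vx[nb], vy[nb], vz[nb])
    }
    if (is.na(val)) val <- vz[which.min(d2)]   # outside hull: nearest valid
    x[i] <- val
  }
  if (was_matrix) matrix(x, nrow = grid$n_lat) else x
}

# barycentric interpolation from the first containing triangle among the
# candidate points (ordered by distance); NA if none contains (px, py)
bary_value <- function(px, py, cx, cy, cz) {
  m <- length(cx)
  if (m < 3) return(NA_real_)
  combs <- utils::combn(seq_len(m), 3)
  for (ci in seq_len(ncol(combs))) {
    tri <- combs[, ci]
    x1 <- cx[tri[1]]; y1 <- cy[tri[1]]
    x2 <- cx[tri[2]]; y2 <- cy[tri[2]]
    x3 <- cx[tri[3]]; y3 <- cy[tri[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-12) next
    w1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    w2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    w3 <- 1 - w1 - w2
    if (w1 >= -1e-9 && w2 >= -1e-9 && w3 >= -1e-9)
      return(w1 * cz[tri[1]] + w2 * cz[tri[2]] + w3 * cz[tri[3]])
  }
  NA_real_
}

# least-squares plane z ~ 1 + x + y through the candidate points
plane_value <- function(px, py, cx, cy, cz) {
  X <- cbind(1, cx - px, cy - py)
  fit <- tryCatch(stats::lm.fit(X, cz), error = function(e) NULL)
  if (is.null(fit) || is.na(fit$coefficients[1])) return(mean(cz))
  unname(fit$coefficients[1])
}

# even-odd ray casting point-in-polygon (hull vertices in order)
point_in_poly <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    on_edge <- abs((hx[j] - hx[i]) * (py - hy[i]) -
                     (hy[j] - hy[i]) * (px - hx[i])) < 1e-9 &&
      px >= min(hx[i], hx[j]) - 1e-9 && px <= max(hx[i], hx[j]) + 1e-9 &&
      py >= min(hy[i], hy[j]) - 1e-9 && py <= max(hy[i], hy[j]) + 1e-9
    if (on_edge) return(TRUE)
    if ((hy[i] > py) != (hy[j] > py)) {
      xint <- (hx[j] - hx[i]) * (py - hy[i]) / (hy[j] - hy[i]) + hx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Re-initialize woody pools from assimilated stocks (transient setup)
#'
#' Folds the current main excess into the post-T0 legacy trackers and
#' overwrites the woody equilibrium pools so that the living stock per
#' (cover, PFT) equals the assimilated stock exactly. The equilibrium
#' overwrite difference is returned as the external assimilation injection
#' for the run's mass ledger.
#'
#' @param state a \code{\link{pool_state}} (pools already relaxed this year).
#' @param C_as assimilated stocks \code{[n_cell, 2, n_pft]} (covers v, s) in
#'   t C, from \code{\link{distribute_density}}.
#' @param mode must be \code{"transient"}; calling in fixed mode is an error.
#' @return List with \code{state} and \code{injection}, the net carbon added
#'   to the tracked pools by the overwrite (t C, global scalar).
#' @export
reinitialize_pools <- function(state, C_as, mode = "transient") {
  if (!identical(mode, "transient"))
    stop("reinitialize_pools: only the transient setup re-initializes pools")
  n <- state$grid$n_cell
  if (any(is.na(C_as))) stop("reinitialize_pools: NA in assimilated stocks")
  before <- pool_total(state)
  state <- fold_excess(state)
  woody <- match(WOODY_COVERS, COVER_TYPES)
  tracker_reg <- (sum_regrow_cp(state$leg_pre) +
                    sum_regrow_cp(state$leg_post))[, woody, , drop = FALSE]
  tracker_reg <- array(tracker_reg, dim = c(n, 2L, state$n_pft))
  # eq := assimilated - tracked deficits, so that living == assimilated
  state$eq[, WOODY_COVERS, ] <- array(C_as, dim = c(n, 2L, state$n_pft)) -
    tracker_reg
  after <- pool_total(state)
  list(state = state, injection = after - before)
}
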