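# Index conventions shared across the package:
#   cover types  j: v (primary/"virgin"), s (secondary), c (cropland), p (pasture)
#   history      k: l (clearing), h (harvest), a (abandonment), g (other)
#   PFT          l: 1..8 woody plant functional types
#   role          : decay (detached material, positive excess) vs regrow
#                   (stand deficit, negative excess). The role axis keeps
#                   harvested-material decay and the stand-regrowth deficit —
#                   both booked under history "h" — in separate slots with
#                   separate time constants.

#' @export
COVER_TYPES <- c("v", "s", "c", "p")
#' @export
HISTORY_TYPES <- c("l", "h", "a", "g")
#' @export
EXCESS_ROLES <- c("decay", "regrow")
#' @export
WOODY_COVERS <- c("v", "s")
N_PFT <- 8L

# zero excess array [cell, cover, history, pft, role]
zero_excess <- function(n_cell, n_pft = N_PFT) {
  array(0, dim = c(n_cell, 4L, 4L, n_pft, 2L),
        dimnames = list(NULL, COVER_TYPES, HISTORY_TYPES, NULL, EXCESS_ROLES))
}

# zero equilibrium array [cell, cover, pft]; equilibrium pools carry no
# history or role axis (they do not relax)
zero_eq <- function(n_cell, n_pft = N_PFT) {
  array(0, dim = c(n_cell, 4L, n_pft),
        dimnames = list(NULL, COVER_TYPES, NULL))
}

#' Pool state of the bookkeeping model
#'
#' Carbon is partitioned per (cell, cover type, history type, PFT) between
#' equilibrium pools (the stock the stand relaxes toward) and signed excess
#' pools that decay exponentially: positive excess is detached material
#' committed to the atmosphere (clearing slash, harvested wood), negative
#' excess is a regrowth deficit that fills in as uptake. Two extra excess-pool
#' sets track legacy fluxes: \code{leg_pre} holds excess carbon from land-use
#' transitions before the assimilation start year T0, \code{leg_post} holds
#' excess folded out of the main pools at each annual re-initialization in the
#' transient setup. Legacy pools are pure flux trackers: their stock
#' counterpart is carried by the assimilated observations.
#'
#' Living (stand) woody carbon per cell is \code{eq + exc[, , , , "regrow"]};
#' detached decay pools and legacy pools are not living biomass.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param cover_frac matrix \code{n_cell x 4} of cover area fractions (v, s,
#'   c, p), rows summing to at most 1.
#' @param pft_frac matrix \code{n_cell x n_pft} of temporally constant PFT
#'   area fractions (rows summing to 1 where any woody cover exists).
#' @param year integer year stamp.
#' @param n_pft number of woody PFTs (default 8).
#' @return An object of class \code{pool_state}.
#' @export
pool_state <- function(grid, cover_frac, pft_frac, year = 0L, n_pft = N_PFT) {
  stopifnot(inherits(grid, "grid_spec"))
  cover_frac <- as.matrix(cover_frac)
  pft_frac <- as.matrix(pft_frac)
  if (nrow(cover_frac) != grid$n_cell || ncol(cover_frac) != 4L)
    stop("pool_state: cover_frac must be n_cell x 4")
  if (nrow(pft_frac) != grid$n_cell || ncol(pft_frac) != n_pft)
    stop("pool_state: pft_frac must be n_cell x n_pft")
  if (any(cover_frac < -1e-12) || any(rowSums(cover_frac) > 1 + 1e-9))
    stop("pool_state: cover fractions must be in [0,1] and sum to <= 1")
  if (any(pft_frac < -1e-12))
    stop("pool_state: PFT fractions must be nonnegative")
  colnames(cover_frac) <- COVER_TYPES
  st <- list(
    grid = grid, n_pft = as.integer(n_pft), year = as.integer(year),
    cover_frac = cover_frac, pft_frac = pft_frac,
    eq = zero_eq(grid$n_cell, n_pft),
    exc = zero_excess(grid$n_cell, n_pft),
    leg_pre = zero_excess(grid$n_cell, n_pft),
    leg_post = zero_excess(grid$n_cell, n_pft)
  )
  class(st) <- "pool_state"
  st
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf(
    "pool_state (year %d): %d cells, %d PFTs\n  eq %.6g tC | exc %.6g | leg<T0 %.6g | leg>=T0 %.6g tC\n",
    x$year, x$grid$n_cell, x$n_pft,
    sum(x$eq), sum(x$exc), sum(x$leg_pre), sum(x$leg_post)))
  invisible(x)
}

#' Total tracked carbon in a pool state
#'
#' Sum of equilibrium, excess and both legacy excess pool sets, per cell or
#' globally. Used by the mass-closure ledger.
#'
#' @param state a \code{\link{pool_state}}.
#' @param per_cell if TRUE return a vector per cell, else the global scalar.
#' @return Carbon in t C.
#' @export
pool_total <- function(state, per_cell = FALSE) {
  if (!per_cell)
    return(sum(state$eq) + sum(state$exc) + sum(state$leg_pre) +
             sum(state$leg_post))
  n <- state$grid$n_cell
  rowSums(matrix(state$eq, nrow = n)) +
    rowSums(matrix(state$exc, nrow = n)) +
    rowSums(matrix(state$leg_pre, nrow = n)) +
    rowSums(matrix(state$leg_post, nrow = n))
}

#' Living (stand) woody carbon stock
#'
#' Living carbon is the equilibrium stock plus all stand-attached regrowth
#' deficits, i.e. the regrow-role excess of the main pools and of both legacy
#' pool sets (negative amounts that fill in as the stand regrows). Detached
#' decay-role pools (cleared slash, harvested wood) are not living biomass.
#' This is the quantity the observed woody-biomass density measures, and the
#' stock the decomposition differences.
#'
#' @param state a \code{\link{pool_state}}.
#' @param by one of \code{"cell"} (vector per cell), \code{"cover_pft"}
#'   (array \code{n_cell x 4 x n_pft}) or \code{"total"}.
#' @return Living carbon in t C at the requested aggregation.
#' @export
living_stock <- function(state, by = c("cell", "cover_pft", "total")) {
  by <- match.arg(by)
  n <- state$grid$n_cell
  cp <- living_cp(state)
  switch(by,
         cell = rowSums(matrix(cp, nrow = n)),
         cover_pft = cp,
         total = sum(cp))
}

#' Relaxation time-constant table
#'
#' One time constant per (cover, history, PFT, role), in years. Defaults
#' follow the package's simplified response curves: detached material from
#' clearing decays with tau = 1 yr, harvested material with tau = 2 yr,
#' "other" detached material with tau = 1 yr; all regrowth deficits fill in
#' with tau = 15 yr. These are configurable placeholders for the
#' literature-calibrated constants of full bookkeeping models.
#'
#' @param decay named numeric vector of decay-role time constants per history
#'   type (years).
#' @param regrow regrowth-role time constant in years (scalar or named per
#'   history type).
#' @param n_pft number of PFTs.
#' @return Object of class \code{tau_table}: array \code{[4 cover, 4 history,
#'   n_pft, 2 role]} of strictly positive time constants.
#' @export
tau_table <- function(decay = c(l = 1, h = 2, a = 1, g = 1),
                      regrow = 15, n_pft = N_PFT) {
  decay <- decay[HISTORY_TYPES]
  if (anyNA(decay)) stop("tau_table: decay must name all history types")
  if (length(regrow) == 1) {
    regrow <- stats::setNames(rep(regrow, 4), HISTORY_TYPES)
  } else {
    regrow <- regrow[HISTORY_TYPES]
    if (anyNA(regrow)) stop("tau_table: regrow must name all history types")
  }
  tau <- array(NA_real_, dim = c(4L, 4L, n_pft, 2L),
               dimnames = list(COVER_TYPES, HISTORY_TYPES, NULL, EXCESS_ROLES))
  for (k in HISTORY_TYPES) {
    tau[, k, , "decay"] <- decay[[k]]
    tau[, k, , "regrow"] <- regrow[[k]]
  }
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("tau_table: all time constants must be finite and > 0")
  class(tau) <- c("tau_table", class(tau))
  tau
}

# per-pool survival factor e^{-1/tau}, broadcast to an excess array shape
tau_alpha <- function(tau, n_cell) {
  if (any(tau <= 0)) stop("relaxation requires tau > 0")
  a <- exp(-1 / unclass(tau))
  # excess arrays are [cell, cover, history, pft, role]
  aperm(array(rep(a, n_cell), dim = c(dim(a), n_cell)), c(5, 1, 2, 3, 4))
}

# fast reductions over excess-shaped arrays [cell, cover, history, pft, role]

# sum over history and role, keep [cell, cover, pft]
sum_cp <- function(a) {
  d <- dim(a)
  b <- aperm(a, c(1, 2, 4, 3, 5))
  dim(b) <- c(d[1] * d[2] * d[4], d[3] * d[5])
  array(rowSums(b), d[c(1, 2, 4)])
}

# regrow-role slice summed over history -> [cell, cover, pft]
sum_regrow_cp <- function(a) {
  d <- dim(a)
  b <- array(a[, , , , 2L], dim = d[1:4])
  b <- aperm(b, c(1, 2, 4, 3))
  dim(b) <- c(d[1] * d[2] * d[4], d[3])
  array(rowSums(b), d[c(1, 2, 4)])
}

# sum over cover, pft and role, keep [cell, history]
sum_hist <- function(a) {
  d <- dim(a)
  b <- aperm(a, c(1, 3, 2, 4, 5))
  dim(b) <- c(d[1] * d[3], d[2] * d[4] * d[5])
  matrix(rowSums(b), d[1], d[3])
}

# regrow-role slice summed over cover and pft, keep [cell, history]
sum_hist_regrow <- function(a) {
  d <- dim(a)
  b <- array(a[, , , , 2L], dim = d[1:4])
  b <- aperm(b, c(1, 3, 2, 4))
  dim(b) <- c(d[1] * d[3], d[2] * d[4])
  matrix(rowSums(b), d[1], d[3])
}

#' Initialize equilibrium pools from a carbon-stock field
#'
#' Places the supplied stocks (t C, per cell, cover type and PFT) entirely in
#' the equilibrium pools; all excess and legacy pools are zero — the model
#' assumes biomass carbon is in equilibrium at initialization.
#'
#' @param stocks array \code{n_cell x 4 x n_pft} (covers in order v, s, c, p)
#'   or \code{n_cell x 2 x n_pft} for the woody covers (v, s) only, in t C.
#' @param grid a \code{\link{grid_spec}}.
#' @param cover_frac,pft_frac area-fraction fields, see
#'   \code{\link{pool_state}}.
#' @param year year stamp for the state.
#' @return A \code{\link{pool_state}} with the stock in \code{eq} and every
#'   excess pool zero.
#' @export
initialize_equilibrium <- function(stocks, grid, cover_frac, pft_frac,
                                   year = 0L) {
  stocks <- as.array(stocks)
  if (length(dim(stocks)) != 3L)
    stop("initialize_equilibrium: stocks must be [cell, cover, pft]")
  if (any(stocks < 0)) stop("initialize_equilibrium: negative stock")
  n_pft <- dim(stocks)[3]
  st <- pool_state(grid, cover_frac, pft_frac, year = year, n_pft = n_pft)
  if (dim(stocks)[2] == 2L) {
    st$eq[, WOODY_COVERS, ] <- stocks
  } else if (dim(stocks)[2] == 4L) {
    st$eq[] <- stocks
  } else stop("initialize_equilibrium: cover axis must have length 2 or 4")
  st
}
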