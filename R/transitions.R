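#' Annual land-use transition forcing
#'
#' Fractional-area land-use transitions per year and grid cell, in the four
#' categories the bookkeeping model distinguishes: clearing (primary or
#' secondary land to cropland or pasture), wood harvest on secondary land
#' (source and target cover identical), abandonment (cropland or pasture to
#' secondary land) and "other" (primary to secondary, e.g. degradation). All
#' fractions are of the whole grid-cell area.
#'
#' @param years integer vector of forcing years (contiguous).
#' @param clearing array \code{[n_year, n_cell, 2, 2]}: source (v, s) by
#'   target (c, p) clearing fractions. Missing trailing dims are allowed for
#'   zero forcing.
#' @param harvest matrix \code{[n_year, n_cell]}: harvested fraction of the
#'   cell area (on secondary land).
#' @param abandonment array \code{[n_year, n_cell, 2]}: source (c, p)
#'   fractions moving to secondary land.
#' @param other matrix \code{[n_year, n_cell]}: primary-to-secondary
#'   transition fraction.
#' @param n_cell number of grid cells (used to build zero defaults).
#' @return Object of class \code{transition_forcing}.
#' @export
transition_forcing <- function(years, n_cell,
                               clearing = NULL, harvest = NULL,
                               abandonment = NULL, other = NULL) {
  years <- as.integer(years)
  ny <- length(years)
  if (ny > 1 && any(diff(years) != 1L))
    stop("transition_forcing: years must be contiguous")
  if (is.null(clearing))
    clearing <- array(0, dim = c(ny, n_cell, 2, 2))
  if (is.null(harvest)) harvest <- matrix(0, ny, n_cell)
  if (is.null(abandonment)) abandonment <- array(0, dim = c(ny, n_cell, 2))
  if (is.null(other)) other <- matrix(0, ny, n_cell)
  clearing <- as.array(clearing); abandonment <- as.array(abandonment)
  if (!identical(dim(clearing), as.integer(c(ny, n_cell, 2, 2))))
    stop("transition_forcing: clearing must be [n_year, n_cell, 2, 2]")
  if (!identical(dim(abandonment), as.integer(c(ny, n_cell, 2))))
    stop("transition_forcing: abandonment must be [n_year, n_cell, 2]")
  if (!identical(dim(harvest), as.integer(c(ny, n_cell))) ||
      !identical(dim(other), as.integer(c(ny, n_cell))))
    stop("transition_forcing: harvest/other must be [n_year, n_cell]")
  if (any(clearing < 0) || any(harvest < 0) || any(abandonment < 0) ||
      any(other < 0))
    stop("transition_forcing: fractions must be nonnegative")
  dimnames(clearing) <- list(NULL, NULL, c("v", "s"), c("c", "p"))
  dimnames(abandonment) <- list(NULL, NULL, c("c", "p"))
  fo <- list(years = years, n_cell = as.integer(n_cell),
             clearing = clearing, harvest = harvest,
             abandonment = abandonment, other = other)
  class(fo) <- "transition_forcing"
  fo
}

#' @export
print.transition_forcing <- function(x, ...) {
  cat(sprintf(
    "transition_forcing: years %d-%d, %d cells; mean annual fractions: clearing %.4g, harvest %.4g, abandonment %.4g, other %.4g\n",
    min(x$years), max(x$years), x$n_cell,
    mean(apply(x$clearing, 1:2, sum)), mean(x$harvest),
    mean(apply(x$abandonment, 1:2, sum)), mean(x$other)))
  invisible(x)
}

# extract the single-year slice of a forcing as plain arrays
forcing_year <- function(forcing, year) {
  i <- match(year, forcing$years)
  if (is.na(i)) stop(sprintf("no forcing for year %d", year))
  list(clearing = forcing$clearing[i, , , , drop = TRUE],
       harvest = forcing$harvest[i, ],
       abandonment = forcing$abandonment[i, , , drop = TRUE],
       other = forcing$other[i, ])
}

# reshape a possibly-dropped slice back to the canonical per-year shapes
canon_year_slice <- function(fy, n_cell) {
  cl <- array(fy$clearing, dim = c(n_cell, 2, 2),
              dimnames = list(NULL, c("v", "s"), c("c", "p")))
  ab <- array(fy$abandonment, dim = c(n_cell, 2),
              dimnames = list(NULL, c("c", "p")))
  list(clearing = cl, harvest = as.numeric(fy$harvest), abandonment = ab,
       other = as.numeric(fy$other))
}

#' Equilibrium carbon densities implied by a pool state
#'
#' Per (cell, cover, PFT) equilibrium density in t C per hectare:
#' equilibrium stock divided by the cover-PFT area. Zero-area slots report
#' zero density (or the supplied fallback).
#'
#' @param state a \code{\link{pool_state}}.
#' @param fallback array \code{[n_cell, 4, n_pft]} (or scalar) of densities
#'   used where the cover-PFT area is zero.
#' @return Array \code{[n_cell, 4, n_pft]} of densities (t C / ha).
#' @export
eq_density <- function(state, fallback = 0) {
  slot_area <- slot_areas(state)          # [cell, cover, pft], ha
  dens <- array(fallback, dim = dim(state$eq),
                dimnames = list(NULL, COVER_TYPES, NULL))
  pos <- slot_area > 0
  dens[pos] <- state$eq[pos] / slot_area[pos]
  dens
}

# cover-PFT areas in ha: A * cover_frac_j * pft_frac_l
slot_areas <- function(state) {
  n <- state$grid$n_cell
  a <- state$grid$area_vec
  out <- array(0, dim = c(n, 4L, state$n_pft))
  for (j in seq_len(4L))
    out[, j, ] <- (a * state$cover_frac[, j]) * state$pft_frac
  out
}

# living stock per (cell, cover, pft): eq + all regrow-role excess (main and
# legacy tracker sets). Regrow pools are stand-attached deficits.
living_cp <- function(state) {
  state$eq + sum_regrow_cp(state$exc) + sum_regrow_cp(state$leg_pre) +
    sum_regrow_cp(state$leg_post)
}

#' Apply one year of land-use transitions to a pool state
#'
#' Carbon transfers for each transition category on an area \eqn{a} (ha):
#' clearing moves the living stock of the affected area off the stand; the
#' target cover is booked at its equilibrium density and the difference
#' \eqn{(\rho_{src} - \rho_{tgt,eq})\,a} becomes a positive decaying excess
#' with history "l". Harvest removes \eqn{h\,\rho_{src}\,a} into a positive
#' decaying excess with history "h" and books the equal-magnitude negative
#' regrowth deficit on the stand. Abandonment books the target (secondary)
#' cover at its equilibrium and creates the negative regrowth excess
#' \eqn{(\rho_{src} - \rho_{tgt,eq})\,a} with history "a". No carbon is
#' created or destroyed: the total over all pools is unchanged (fluxes to the
#' atmosphere are realized later by relaxation).
#'
#' Area-changing transitions also trim the area share of stand-attached
#' regrow-role pools (including legacy trackers): the deficit of cleared land
#' will never regrow, so its tracker is cancelled against the detached
#' material.
#'
#' @param state a \code{\link{pool_state}}.
#' @param fy single-year forcing: list with \code{clearing} \code{[cell,2,2]},
#'   \code{harvest} \code{[cell]}, \code{abandonment} \code{[cell,2]},
#'   \code{other} \code{[cell]} (see \code{\link{transition_forcing}});
#'   alternatively a \code{transition_forcing} plus \code{year}.
#' @param target_eq target-equilibrium density field \code{[n_cell, 4,
#'   n_pft]} (t C/ha) used to book cleared/abandoned target covers. Defaults
#'   to the densities implied by the current equilibrium pools
#'   (\code{\link{eq_density}}).
#' @param harvest_intensity fraction of stand biomass removed per harvested
#'   area (default 1).
#' @param year if \code{fy} is a full \code{transition_forcing}, the year to
#'   apply.
#' @return List with elements \code{state} (updated pools) and \code{created}
#'   (excess created this year, same shape as the excess array).
#' @export
apply_transitions <- function(state, fy, target_eq = NULL,
                              harvest_intensity = 1, year = NULL) {
  if (inherits(fy, "transition_forcing")) {
    if (is.null(year)) stop("apply_transitions: year required with a full forcing")
    fy <- forcing_year(fy, year)
  }
  n <- state$grid$n_cell
  fy <- canon_year_slice(fy, n)
  if (any(fy$clearing < 0) || any(fy$harvest < 0) ||
      any(fy$abandonment < 0) || any(fy$other < 0))
    stop("apply_transitions: negative transition fraction")
  if (is.null(target_eq)) target_eq <- eq_density(state)
  if (any(target_eq < 0)) stop("apply_transitions: negative target density")
  A <- state$grid$area_vec
  tol <- 1e-10

  # outgoing-fraction validity per source cover
  out_v <- fy$clearing[, "v", "c"] + fy$clearing[, "v", "p"] + fy$other
  out_s <- fy$clearing[, "s", "c"] + fy$clearing[, "s", "p"]
  out_c <- fy$abandonment[, "c"]
  out_p <- fy$abandonment[, "p"]
  if (any(out_v > state$cover_frac[, "v"] + tol) ||
      any(out_s > state$cover_frac[, "s"] + tol) ||
      any(out_c > state$cover_frac[, "c"] + tol) ||
      any(out_p > state$cover_frac[, "p"] + tol))
    stop("apply_transitions: transition area exceeds available cover fraction")
  if (any(fy$harvest > state$cover_frac[, "s"] + tol))
    stop("apply_transitions: harvest area exceeds secondary cover fraction")

  created <- zero_excess(n, state$n_pft)

  # shares are evaluated against the cover fractions at the start of the
  # year; all area-changing moves are then applied at once
  base_frac <- state$cover_frac

  transfer <- function(state, created, src, tgt, a, hist, role) {
    if (all(a <= 0)) return(list(state = state, created = created))
    src_frac <- base_frac[, src]
    bad <- a > 0 & src_frac <= 0
    if (any(bad))
      stop("apply_transitions: transition from cover with zero area")
    share <- ifelse(src_frac > 0, pmin(a / src_frac, 1), 0)
    # removed living: equilibrium share plus regrow-role shares of all sets
    rem_eq <- state$eq[, src, , drop = FALSE] * share        # [cell,1,pft]
    rem_eq <- array(rem_eq, dim = c(n, state$n_pft))
    take_reg <- function(arr) {
      sl <- arr[, src, , , "regrow", drop = FALSE]           # [cell,1,4,pft,1]
      sl <- array(sl, dim = c(n, 4L, state$n_pft))
      sl * share                                              # recycle on cells
    }
    t_exc <- take_reg(state$exc)
    t_pre <- take_reg(state$leg_pre)
    t_post <- take_reg(state$leg_post)
    tt <- aperm(t_exc + t_pre + t_post, c(1, 3, 2))
    dim(tt) <- c(n * state$n_pft, 4L)
    removed <- rem_eq + matrix(rowSums(tt), n, state$n_pft)
    state$eq[, src, ] <- array(state$eq[, src, , drop = FALSE],
                               dim = c(n, state$n_pft)) - rem_eq
    sub_reg <- function(arr, tk) {
      cur <- array(arr[, src, , , "regrow", drop = FALSE],
                   dim = c(n, 4L, state$n_pft))
      arr[, src, , , "regrow"] <- cur - tk
      arr
    }
    state$exc <- sub_reg(state$exc, t_exc)
    state$leg_pre <- sub_reg(state$leg_pre, t_pre)
    state$leg_post <- sub_reg(state$leg_post, t_post)
    # book target at its equilibrium density on the transferred area
    eq_add <- (target_eq[, tgt, , drop = FALSE])
    eq_add <- array(eq_add, dim = c(n, state$n_pft)) *
      (a * A) * state$pft_frac
    state$eq[, tgt, ] <- array(state$eq[, tgt, , drop = FALSE],
                               dim = c(n, state$n_pft)) + eq_add
    delta <- removed - eq_add
    cur <- array(state$exc[, tgt, hist, , role],
                 dim = c(n, state$n_pft))
    state$exc[, tgt, hist, , role] <- cur + delta
    curc <- array(created[, tgt, hist, , role], dim = c(n, state$n_pft))
    created[, tgt, hist, , role] <- curc + delta
    state$cover_frac[, src] <- state$cover_frac[, src] - a
    state$cover_frac[, tgt] <- state$cover_frac[, tgt] + a
    list(state = state, created = created)
  }

  # clearing: v/s -> c/p, history "l", detached material decays
  for (src in c("v", "s")) for (tgt in c("c", "p")) {
    r <- transfer(state, created, src, tgt, fy$clearing[, src, tgt],
                  hist = "l", role = "decay")
    state <- r$state; created <- r$created
  }
  # other: v -> s, history "g", treated like a clearing-type transfer
  r <- transfer(state, created, "v", "s", fy$other, hist = "g", role = "decay")
  state <- r$state; created <- r$created
  # abandonment: c/p -> s, history "a", regrowth deficit toward secondary
  for (src in c("c", "p")) {
    r <- transfer(state, created, src, "s", fy$abandonment[, src],
                  hist = "a", role = "regrow")
    state <- r$state; created <- r$created
  }
  # harvest on secondary land: j = j', no area change; removes
  # h * rho_living * a into decay, books -same as stand regrowth deficit
  a <- fy$harvest
  if (any(a > 0)) {
    s_frac <- base_frac[, "s"]
    if (any(a > 0 & s_frac <= 0))
      stop("apply_transitions: harvest on cell without secondary land")
    share <- ifelse(s_frac > 0, pmin(a / s_frac, 1), 0)
    liv <- living_cp(state)
    liv_s <- array(liv[, "s", , drop = FALSE], dim = c(n, state$n_pft))
    H <- harvest_intensity * liv_s * share
    if (any(H < -tol * max(1, max(abs(H)))))
      stop("apply_transitions: negative harvested stock")
    cur_d <- array(state$exc[, "s", "h", , "decay"], dim = c(n, state$n_pft))
    cur_r <- array(state$exc[, "s", "h", , "regrow"], dim = c(n, state$n_pft))
    state$exc[, "s", "h", , "decay"] <- cur_d + H
    state$exc[, "s", "h", , "regrow"] <- cur_r - H
    created[, "s", "h", , "decay"] <-
      array(created[, "s", "h", , "decay"], dim = c(n, state$n_pft)) + H
    created[, "s", "h", , "regrow"] <-
      array(created[, "s", "h", , "regrow"], dim = c(n, state$n_pft)) - H
  }
  list(state = state, created = created)
}
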