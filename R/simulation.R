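#' Configuration of a single bookkeeping simulation
#'
#' @param mode \code{"transient"} (observed densities assimilated every year)
#'   or \code{"fixed"} (densities assimilated only in the start year; stocks
#'   subsequently altered by land-use change alone).
#' @param start_year first simulated year T0 (assimilation start).
#' @param end_year last simulated year.
#' @param tau a \code{\link{tau_table}} of relaxation time constants.
#' @param harvest_intensity fraction of stand biomass removed per harvested
#'   area (default 1).
#' @param seed integer seed recorded with the run (the simulation itself is
#'   deterministic).
#' @return Object of class \code{run_config}. The sign convention is fixed:
#'   carbon release to the atmosphere is positive, uptake negative.
#' @export
run_config <- function(mode = c("transient", "fixed"),
                       start_year, end_year,
                       tau = tau_table(), harvest_intensity = 1,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (end_year < start_year) stop("run_config: end_year before start_year")
  if (harvest_intensity < 0 || harvest_intensity > 1)
    stop("run_config: harvest_intensity must be in [0, 1]")
  cfg <- list(mode = mode, start_year = as.integer(start_year),
              end_year = as.integer(end_year), tau = tau,
              harvest_intensity = harvest_intensity, seed = seed,
              release_positive = TRUE)
  class(cfg) <- "run_config"
  cfg
}

# target-equilibrium densities for transition booking: woody covers regrow
# toward the current (assimilated) living density, crop/pasture toward the
# density implied by their equilibrium pools (zero unless configured)
target_eq_field <- function(state) {
  dens <- eq_density(state)
  slot_area <- slot_areas(state)
  liv <- living_cp(state)
  for (j in match(WOODY_COVERS, COVER_TYPES)) {
    sa <- matrix(slot_area[, j, ], nrow = dim(slot_area)[1])
    d <- matrix(0, nrow(sa), ncol(sa))
    pos <- sa > 0
    lv <- matrix(liv[, j, ], nrow = nrow(sa))
    d[pos] <- lv[pos] / sa[pos]
    dens[, j, ] <- d
  }
  dens
}

#' Run one bookkeeping simulation
#'
#' Yearly order of operations: (1) relaxation fluxes from the previous
#' year's pools are realized (instantaneous, pre-T0 legacy and post-T0
#' legacy terms); (2) in the transient setup the main excess is folded into
#' the post-T0 legacy trackers and the woody pools are re-initialized from
#' the year's observed densities (in the fixed setup this happens only in
#' the start year); (3) the year's land-use transitions are applied. The
#' reported stock for year X is the end-of-year-X living woody carbon.
#'
#' @param config a \code{\link{run_config}}.
#' @param forcing a \code{\link{transition_forcing}} covering all simulated
#'   years.
#' @param densities a complete (all-valid) \code{\link{density_series}};
#'   the transient mode needs every simulated year, the fixed mode only T0.
#' @param init a \code{\link{pool_state}} at T0 carrying cover/PFT area
#'   fractions and any pre-T0 legacy excess (\code{leg_pre}).
#' @return Object of class \code{bkm_run}: living-stock series, carried
#'   (pre-assimilation) stocks, observed stocks, the flux ledger by category
#'   and term, assimilation injections, and the final pool state.
#' @export
run_simulation <- function(config, forcing, densities, init) {
  stopifnot(inherits(config, "run_config"),
            inherits(forcing, "transition_forcing"),
            inherits(densities, "density_series"),
            inherits(init, "pool_state"))
  years <- config$start_year:config$end_year
  ny <- length(years)
  if (!all(years %in% forcing$years))
    stop("run_simulation: forcing does not cover the simulated years")
  need <- if (config$mode == "transient") years else years[1]
  if (!all(need %in% densities$years))
    stop("run_simulation: density series does not cover the simulated years")
  iy <- match(need, densities$years)
  if (!all(densities$valid[iy, ]))
    stop("run_simulation: density series has invalid cells; screen it first")
  n <- init$grid$n_cell
  A <- init$grid$area_vec
  st <- init

  stocks <- carried <- obs_stock <- matrix(NA_real_, ny, n)
  f_inst <- f_pre <- f_post <- f_upt <-
    array(0, dim = c(ny, n, 4L), dimnames = list(NULL, NULL, HISTORY_TYPES))
  injections <- numeric(ny)
  initial_total <- pool_total(st)
  alpha <- tau_alpha(config$tau, n)

  for (i in seq_len(ny)) {
    t <- years[i]
    rel <- relax_step(st, config$tau, .alpha = alpha)
    st <- rel$state
    f_inst[i, , ] <- rel$flux$inst
    f_pre[i, , ] <- rel$flux$leg_pre
    f_post[i, , ] <- rel$flux$leg_post
    f_upt[i, , ] <- rel$flux$uptake
    carried[i, ] <- living_stock(st, "cell")
    assimilate <- config$mode == "transient" || i == 1L
    if (assimilate) {
      dy <- density_year(densities, t)
      obs_stock[i, ] <- dy$rho * A
      f <- compute_biomass_fractions(st)
      C_as <- distribute_density(dy$rho, A, f)
      ri <- reinitialize_pools(st, C_as, mode = "transient")
      st <- ri$state
      injections[i] <- ri$injection
    }
    tr <- apply_transitions(st, forcing, target_eq = target_eq_field(st),
                            harvest_intensity = config$harvest_intensity,
                            year = t)
    st <- tr$state
    st$year <- t
    stocks[i, ] <- living_stock(st, "cell")
  }

  run <- list(config = config, years = years,
              stocks = stocks, carried = carried, obs_stock = obs_stock,
              flux = list(inst = f_inst, leg_pre = f_pre, leg_post = f_post,
                          uptake = f_upt),
              injections = injections,
              initial_total = initial_total,
              final_state = st)
  class(run) <- "bkm_run"
  run
}

#' @export
print.bkm_run <- function(x, ...) {
  cat(sprintf(
    "bkm_run (%s): %d-%d, %d cells\n  mean living stock %.4g PgC; mean annual net flux %.4g PgC/yr\n",
    x$config$mode, min(x$years), max(x$years), ncol(x$stocks),
    mean(rowSums(x$stocks)) * 1e-9,
    mean(apply(flux_total(x), 1, sum)) * 1e-9))
  invisible(x)
}

#' Total flux of a run per year, cell and category
#'
#' Sum of the instantaneous, pre-T0 legacy and post-T0 legacy terms of the
#' run's flux ledger (release-positive, t C).
#'
#' @param run a \code{bkm_run}.
#' @return Array \code{[n_year, n_cell, 4]} by history category.
#' @export
flux_total <- function(run) {
  total_flux(run$flux$inst, run$flux$leg_pre, run$flux$leg_post)
}

#' Mass-closure residual of a run
#'
#' Checks that cumulative fluxes plus the final pool total equal the initial
#' pool total plus all external assimilation injections.
#'
#' @param run a \code{bkm_run}.
#' @return List with the absolute residual (t C) and the residual relative
#'   to the initial pool total.
#' @export
mass_closure <- function(run) {
  lhs <- sum(flux_total(run)) + pool_total(run$final_state)
  rhs <- run$initial_total + sum(run$injections)
  res <- lhs - rhs
  list(residual = res,
       relative = abs(res) / max(abs(rhs), 1))
}

#' Screen and complete an observed density series
#'
#' Derives per-(cover, PFT) density layers from the observed cell densities
#' using the static cover-by-PFT area weights of the initial state, applies
#' the threshold policy per layer over the whole series, masks the excluded
#' entries (and any already-missing observations), interpolates every masked
#' layer field by \code{\link{interpolate_missing}}, and recombines the
#' layers into a complete cell-density series.
#'
#' @param densities a \code{\link{density_series}} (may contain invalid
#'   cells).
#' @param init a \code{\link{pool_state}} providing grid and area fractions.
#' @param policy a \code{\link{threshold_policy}}.
#' @return List with \code{densities} (a complete \code{density_series}),
#'   \code{report} (excluded entries), \code{excluded_fraction} and the
#'   layer \code{mask}.
#' @export
screen_density_series <- function(densities, init, policy = threshold_policy()) {
  grid <- init$grid
  n <- grid$n_cell
  ny <- length(densities$years)
  f0 <- static_woody_weights(init)                 # [cell, 2, npft]
  frac <- array(0, dim = dim(f0))
  for (j in seq_along(WOODY_COVERS))
    frac[, j, ] <- init$cover_frac[, WOODY_COVERS[j]] * init$pft_frac
  series <- array(NA_real_, dim = c(ny, n, 2L, init$n_pft))
  ratio <- array(0, dim = dim(f0))
  pos <- frac > 0
  ratio[pos] <- f0[pos] / frac[pos]
  for (i in seq_len(ny)) {
    rho <- densities$values[i, ]
    rho[!densities$valid[i, ]] <- NA_real_
    lay <- ratio * rho                              # recycle over cells
    lay[!pos] <- NA_real_
    series[i, , , ] <- lay
  }
  thr <- apply_thresholds(series, policy)
  mask <- thr$mask | is.na(series)
  filled <- series
  filled[mask] <- NA_real_
  for (i in seq_len(ny)) for (j in 1:2) for (l in seq_len(init$n_pft)) {
    fld <- filled[i, , j, l]
    if (anyNA(fld)) filled[i, , j, l] <- interpolate_missing(fld, grid)
  }
  out <- matrix(0, ny, n)
  for (i in seq_len(ny))
    out[i, ] <- rowSums(matrix(filled[i, , , ] * frac, nrow = n))
  out <- pmax(out, 0)
  list(densities = density_series(densities$years, out),
       report = thr$report,
       excluded_fraction = mean(thr$mask[!is.na(series)]),
       mask = mask)
}
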