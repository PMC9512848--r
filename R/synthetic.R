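#' Configuration of a synthetic test world
#'
#' Describes a self-contained world with the statistical structure the
#' analysis assumes: per-PFT equilibrium woody carbon densities, a secular
#' environmental trend (emulating CO2 fertilization), temperature-coupled
#' interannual variability, constant-rate land-use transitions (clearing of
#' primary land to cropland, wood harvest on secondary land, abandonment of
#' cropland), observation noise and a missing-data mask. The defaults are
#' the package's stated desk-scale world: a 20 x 20 grid over 20 years with
#' 8 woody PFTs.
#'
#' @param n_lat,n_lon grid size (1-degree cells).
#' @param years simulated years (default 2000-2019).
#' @param seed integer seed; the same seed reproduces the world bit-exactly.
#' @param pft_eq_density equilibrium woody carbon density per PFT (t C/ha).
#' @param env_trend fractional secular growth of equilibrium densities per
#'   year (default 0.005).
#' @param temp_coupling fractional density response per degree of
#'   temperature anomaly (default 0.02).
#' @param temp_sd standard deviation of annual temperature anomalies (K).
#' @param clearing_rate annual cleared fraction of cell area (primary to
#'   cropland).
#' @param harvest_rate annual harvested fraction of cell area (secondary
#'   land).
#' @param abandon_rate annual abandoned fraction of cell area (cropland to
#'   secondary).
#' @param other_rate annual primary-to-secondary transition fraction.
#' @param missing_frac fraction of cell-years masked as invalid in the
#'   degraded observations.
#' @param noise_sd observation noise standard deviation (t C/ha).
#' @param harvest_intensity fraction of stand biomass removed per harvested
#'   area.
#' @param cover_frac initial cover fractions (v, s, c, p).
#' @param tau a \code{\link{tau_table}} used by the world's own carbon
#'   transfers.
#' @return Object of class \code{synthetic_world_config}.
#' @export
synthetic_world_config <- function(n_lat = 20, n_lon = 20,
                                   years = 2000:2019, seed = 1,
                                   pft_eq_density = seq(20, 180,
                                                        length.out = 8),
                                   env_trend = 0.005,
                                   temp_coupling = 0.02, temp_sd = 0.7,
                                   clearing_rate = 0.005,
                                   harvest_rate = 0.01,
                                   abandon_rate = 0.002,
                                   other_rate = 0,
                                   missing_frac = 0.05, noise_sd = 1,
                                   harvest_intensity = 1,
                                   cover_frac = c(v = 0.4, s = 0.3,
                                                  c = 0.2, p = 0.1),
                                   tau = tau_table(n_pft =
                                                     length(pft_eq_density))) {
  rates <- c(clearing_rate, harvest_rate, abandon_rate, other_rate,
             missing_frac, noise_sd, env_trend + 1, temp_sd)
  if (any(rates < 0)) stop("synthetic_world_config: negative rate")
  if (missing_frac >= 1)
    stop("synthetic_world_config: missing_frac must be < 1")
  ny <- length(years)
  v_end <- cover_frac[["v"]] - ny * (clearing_rate + other_rate)
  c_min <- cover_frac[["c"]] - ny * abandon_rate
  if (v_end < -1e-9 || c_min + ny * clearing_rate < -1e-9)
    stop("synthetic_world_config: transition rates exhaust a cover type")
  cfg <- list(n_lat = n_lat, n_lon = n_lon, years = as.integer(years),
              seed = as.integer(seed), pft_eq_density = pft_eq_density,
              n_pft = length(pft_eq_density),
              env_trend = env_trend, temp_coupling = temp_coupling,
              temp_sd = temp_sd, clearing_rate = clearing_rate,
              harvest_rate = harvest_rate, abandon_rate = abandon_rate,
              other_rate = other_rate, missing_frac = missing_frac,
              noise_sd = noise_sd, harvest_intensity = harvest_intensity,
              cover_frac = cover_frac, tau = tau)
  class(cfg) <- "synthetic_world_config"
  cfg
}

#' Generate a synthetic world with an exact ground-truth ledger
#'
#' Evolves a true woody-carbon world with the same transition and
#' relaxation rules as the bookkeeping kernel: equilibrium pools are scaled
#' by the environmental multiplier path (trend plus temperature-coupled
#' anomalies), land-use transitions remove living carbon into decaying
#' detached pools and create regrowth deficits, and deficits fill in
#' exponentially. The observed density for year t is the beginning-of-year
#' living density (after relaxation and the environmental increment, before
#' the year's transitions), which is what the assimilation consumes. Every
#' component of the annual stock change is recorded exactly in the ledger.
#'
#' @param config a \code{\link{synthetic_world_config}}.
#' @return Object of class \code{synthetic_world}: \code{densities}
#'   (degraded observations), \code{truth_densities} (noise-free),
#'   \code{forcing}, \code{climate} (temperature/precipitation anomaly
#'   matrices), \code{ledger} (annual global data frame, t C:
#'   \code{env_change}, \code{created_decay}, \code{regrowth_uptake},
#'   \code{lulcc_change}, \code{stock} end-of-year, satisfying
#'   \code{stock(t) = stock(t-1) + env_change + lulcc_change} exactly),
#'   \code{events} (created excess by year/cover/history/role, the analytic
#'   flux oracle input), \code{init_state} and \code{grid}.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  set.seed(config$seed)
  ny <- length(config$years)
  grid <- grid_spec(lat = seq(55, by = -1, length.out = config$n_lat),
                    lon = seq(0, by = 1, length.out = config$n_lon))
  n <- grid$n_cell
  np <- config$n_pft

  # static PFT mix and mild spatial heterogeneity of equilibrium density
  pft_frac <- matrix(stats::rgamma(n * np, shape = 2), n, np)
  pft_frac <- pft_frac / rowSums(pft_frac)
  cell_factor <- stats::runif(n, 0.8, 1.2)
  cover0 <- matrix(rep(config$cover_frac, each = n), n, 4,
                   dimnames = list(NULL, COVER_TYPES))

  stocks0 <- array(0, dim = c(n, 2L, np))
  for (j in seq_along(WOODY_COVERS)) for (l in seq_len(np))
    stocks0[, j, l] <- config$pft_eq_density[l] * cell_factor *
      grid$area_vec * cover0[, WOODY_COVERS[j]] * pft_frac[, l]
  init <- initialize_equilibrium(stocks0, grid, cover0, pft_frac,
                                 year = config$years[1] - 1L)

  # climate anomaly fields and the environmental multiplier path
  temp <- matrix(stats::rnorm(ny * n, 0, config$temp_sd), ny, n)
  precip <- matrix(stats::rnorm(ny * n, 0, 100), ny, n)
  tfac <- 1 + config$temp_coupling * temp
  if (any(tfac <= 0))
    stop("generate_world: environmental multiplier drives densities negative")

  fo <- constant_forcing(config, n)

  st <- init
  rho_true <- matrix(NA_real_, ny, n)
  stock_end <- numeric(ny)
  env_change <- created_decay <- regrowth_uptake <- numeric(ny)
  events <- array(0, dim = c(ny, 4L, 4L, 2L),
                  dimnames = list(NULL, COVER_TYPES, HISTORY_TYPES,
                                  EXCESS_ROLES))
  for (i in seq_len(ny)) {
    if (i > 1L) {
      rel <- relax_step(st, config$tau)
      st <- rel$state
      regrowth_uptake[i] <- sum(rel$flux$uptake)
    }
    g <- if (i == 1L) tfac[1, ] else
      (1 + config$env_trend) * tfac[i, ] / tfac[i - 1L, ]
    eq_before <- sum(st$eq)
    st$eq <- st$eq * as.vector(g)          # recycles over the cell axis
    env_change[i] <- sum(st$eq) - eq_before
    rho_true[i, ] <- living_stock(st, "cell") / grid$area_vec
    tr <- apply_transitions(st, fo, target_eq = target_eq_field(st),
                            harvest_intensity = config$harvest_intensity,
                            year = config$years[i])
    st <- tr$state
    events[i, , , ] <- apply(tr$created, c(2, 3, 5), sum)
    created_decay[i] <- sum(tr$created[, , , , "decay"])
    stock_end[i] <- living_stock(st, "total")
  }
  if (any(rho_true < -1e-9))
    stop("generate_world: rates drive a density negative")
  rho_true <- pmax(rho_true, 0)

  ledger <- data.frame(
    year = config$years,
    env_change = env_change,
    created_decay = created_decay,
    regrowth_uptake = regrowth_uptake,
    lulcc_change = -created_decay - regrowth_uptake,
    stock = stock_end)

  truth <- density_series(config$years, rho_true)
  obs <- degrade_observations(truth, config$noise_sd, config$missing_frac,
                              seed = config$seed + 1L)
  w <- list(config = config, grid = grid, init_state = init,
            forcing = fo, densities = obs, truth_densities = truth,
            climate = list(temperature = temp, precipitation = precip),
            ledger = ledger, events = events, tau = config$tau)
  class(w) <- "synthetic_world"
  w
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %dx%d cells, %d-%d, seed %d\n  initial stock %.4g PgC; trend %.2g/yr; clearing %.2g, harvest %.2g, abandonment %.2g /yr\n",
    x$config$n_lat, x$config$n_lon, min(x$config$years),
    max(x$config$years), x$config$seed,
    living_stock(x$init_state, "total") * 1e-9, x$config$env_trend,
    x$config$clearing_rate, x$config$harvest_rate, x$config$abandon_rate))
  invisible(x)
}

# constant-rate forcing on every cell and year
constant_forcing <- function(config, n_cell) {
  ny <- length(config$years)
  cl <- array(0, dim = c(ny, n_cell, 2, 2))
  cl[, , 1, 1] <- config$clearing_rate          # v -> c
  ab <- array(0, dim = c(ny, n_cell, 2))
  ab[, , 1] <- config$abandon_rate              # c -> s
  transition_forcing(config$years, n_cell, clearing = cl,
                     harvest = matrix(config$harvest_rate, ny, n_cell),
                     abandonment = ab,
                     other = matrix(config$other_rate, ny, n_cell))
}

#' Degrade a clean density series into noisy, gappy observations
#'
#' Adds zero-mean Gaussian observation noise truncated at zero and masks a
#' random fraction of cell-years as invalid. Reproducible by seed.
#'
#' @param densities a \code{\link{density_series}}.
#' @param noise_sd noise standard deviation (t C/ha).
#' @param missing_frac fraction of cell-years masked, in [0, 1).
#' @param seed integer seed.
#' @return A new \code{\link{density_series}}.
#' @export
degrade_observations <- function(densities, noise_sd, missing_frac, seed) {
  if (noise_sd < 0) stop("degrade_observations: negative noise sd")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("degrade_observations: missing_frac must be in [0, 1)")
  set.seed(seed)
  v <- densities$values
  if (noise_sd > 0)
    v <- pmax(v + matrix(stats::rnorm(length(v), 0, noise_sd),
                         nrow(v), ncol(v)), 0)
  valid <- densities$valid &
    matrix(stats::runif(length(v)) >= missing_frac, nrow(v), ncol(v))
  v[!valid] <- NA_real_
  density_series(densities$years, v, valid)
}
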