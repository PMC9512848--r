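# Shared fixture builders. Everything is generated in code; no stored data.

# a single-cell state with given cover fractions and one or more PFTs
one_cell_state <- function(cover = c(v = 0.4, s = 0.3, c = 0.2, p = 0.1),
                           n_pft = 1, pft_frac = NULL, year = 2000) {
  g <- grid_spec(lat = 0.5, lon = 0.5)
  if (is.null(pft_frac)) pft_frac <- matrix(1 / n_pft, 1, n_pft)
  pool_state(g, matrix(cover, 1, 4), pft_frac, year = year, n_pft = n_pft)
}

# small deterministic world configs used across tests
quiet_world_config <- function(..., seed = 42) {
  synthetic_world_config(n_lat = 4, n_lon = 4, years = 2000:2007, seed = seed,
                         missing_frac = 0, noise_sd = 0, ...)
}

no_env_config <- function(...) {
  quiet_world_config(env_trend = 0, temp_coupling = 0, temp_sd = 0, ...)
}

no_lulcc_config <- function(...) {
  quiet_world_config(clearing_rate = 0, harvest_rate = 0, abandon_rate = 0,
                     other_rate = 0, ...)
}

# independent per-event exponential cohort ledger. An event of size `amount`
# created during year `year` first relaxes at the start of year year+1.
# cohort_pool: pooled legacy stock after the start-of-year-t update;
# cohort_flux: flux realized at the start of year t.
cohort_pool <- function(events, t) {
  sum(vapply(seq_len(nrow(events)), function(i) {
    if (events$year[i] >= t) return(0)
    events$amount[i] * events$alpha[i]^(t - events$year[i])
  }, numeric(1)))
}

cohort_flux <- function(events, t) {
  sum(vapply(seq_len(nrow(events)), function(i) {
    if (events$year[i] >= t) return(0)
    events$amount[i] * events$alpha[i]^(t - events$year[i] - 1) *
      (1 - events$alpha[i])
  }, numeric(1)))
}

# analytic flux schedule for a generated world's event ledger (fixed run)
analytic_flux_schedule <- function(world) {
  ny <- length(world$config$years)
  tau <- unclass(world$tau)[, , 1, ]          # pft-invariant defaults
  alpha <- exp(-1 / tau)
  sched <- numeric(ny)
  for (te in seq_len(ny)) for (j in 1:4) for (k in 1:4) for (r in 1:2) {
    amt <- world$events[te, j, k, r]
    if (amt == 0) next
    a <- alpha[j, k, r]
    t_later <- seq_len(ny)[seq_len(ny) > te]
    if (length(t_later))
      sched[t_later] <- sched[t_later] + amt * a^(t_later - te - 1) * (1 - a)
  }
  sched
}
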