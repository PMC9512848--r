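#' Interannual variability of an annual series
#'
#' Coefficient of variation: sample standard deviation (n-1 denominator)
#' divided by the mean, reported as an absolute value. Undefined for a zero
#' mean.
#'
#' @param series numeric vector of at least two annual values.
#' @return Nonnegative scalar.
#' @examples
#' iav(c(1, 2, 3)) # 0.5
#' @export
iav <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2) stop("iav: need at least two values")
  m <- mean(series)
  if (m == 0) stop("iav: undefined for zero mean")
  abs(stats::sd(series) / m)
}

#' Biomass assimilation bias
#'
#' Time-mean difference between the model's carried (pre-assimilation) woody
#' carbon stocks and the observed stocks, per cell, plus the global
#' aggregate with its interannual standard deviation. A large bias flags
#' cells where the land-use forcing or the cover/PFT distribution is
#' inconsistent with the observed carbon dynamics.
#'
#' @param assimilated matrix \code{[n_year, n_cell]} of model stocks (t C),
#'   e.g. the \code{carried} component of a transient \code{bkm_run}.
#' @param observed matrix of observed stocks on the same years/cells (t C).
#' @return List with \code{bias_field} (t C per cell, time mean),
#'   \code{global_mean} and \code{global_sd} (Pg C).
#' @export
assimilation_bias <- function(assimilated, observed) {
  assimilated <- as.matrix(assimilated); observed <- as.matrix(observed)
  if (!identical(dim(assimilated), dim(observed)))
    stop("assimilation_bias: misaligned series")
  d <- assimilated - observed
  annual <- rowSums(d) * 1e-9
  list(bias_field = colMeans(d),
       global_mean = mean(annual),
       global_sd = stats::sd(annual))
}

#' Temporal trend agreement between two annual series
#'
#' The number of years in which both series change in the same direction
#' relative to the previous year, divided by the total number of
#' year-to-year changes. A zero change agrees only with a zero change.
#'
#' @param series_a,series_b numeric vectors of equal length >= 2.
#' @return Fraction in [0, 1].
#' @export
temporal_agreement <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("temporal_agreement: lengths differ")
  if (length(series_a) < 2)
    stop("temporal_agreement: need at least two values")
  mean(sign(diff(series_a)) == sign(diff(series_b)))
}

#' Mean annual cleared-plus-harvested area fraction
#'
#' The time-mean fraction of each grid cell's area affected by clearing or
#' wood harvest, as a percentage. Abandonment and other transitions are
#' excluded.
#'
#' @param forcing a \code{\link{transition_forcing}}.
#' @return Numeric vector per cell, in percent per year.
#' @export
lulcc_intensity <- function(forcing) {
  cl <- apply(forcing$clearing, 1:2, sum)
  100 * colMeans(cl + forcing$harvest)
}

#' Linear detrending of an annual series
#'
#' Residuals from an ordinary least-squares fit against year. Residuals sum
#' to zero; a perfectly linear (or constant) series detrends to zeros.
#'
#' @param series numeric vector of at least three values.
#' @param years optional abscissa (defaults to the index).
#' @return Anomaly series of the same length.
#' @export
detrend <- function(series, years = seq_along(series)) {
  series <- as.numeric(series)
  if (length(series) < 3) stop("detrend: need at least three points")
  as.numeric(stats::residuals(stats::lm(series ~ years)))
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average-rank tie handling. For tie-free series of length <= 9 the
#' p-value comes from the exact permutation null distribution (cached per
#' n); otherwise from the large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with \code{rho} and \code{p}.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("spearman_test: lengths differ")
  if (n < 4) stop("spearman_test: need at least four pairs")
  if (max(x) == min(x) || max(y) == min(y))
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (!ties && n <= 9) {
    null_rho <- spearman_null(n)
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p = p)
}

# exact permutation null of Spearman's rho for tie-free samples of size n
spearman_null_cache <- new.env(parent = emptyenv())
spearman_null <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_null_cache[[key]])) return(spearman_null_cache[[key]])
  perms <- all_permutations(n)                 # n! x n matrix
  r <- seq_len(n)
  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) for tie-free ranks
  d2 <- rowSums((perms - matrix(r, nrow(perms), n, byrow = TRUE))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  spearman_null_cache[[key]] <- rho
  rho
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, -pos] <- sub
  }
  out
}

#' Gridded detrended Spearman correlation maps
#'
#' Detrends the carbon and climate series per cell (ordinary least squares)
#' and computes the Spearman rank correlation and its two-sided p-value per
#' cell, with a significance mask at the chosen level. Cells whose series
#' are constant are masked.
#'
#' @param carbon matrix \code{[n_year, n_cell]} of annual carbon values.
#' @param climate matrix of the climate variable on the same layout.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction).
#' @param detrend_first detrend both variables before correlating (default
#'   TRUE).
#' @return List with vectors \code{rho}, \code{p} and logical
#'   \code{significant} per cell.
#' @export
spearman_map <- function(carbon, climate, alpha = 0.05,
                         detrend_first = TRUE) {
  carbon <- as.matrix(carbon); climate <- as.matrix(climate)
  if (!identical(dim(carbon), dim(climate)))
    stop("spearman_map: misaligned inputs")
  if (nrow(carbon) < 4)
    stop("spearman_map: need at least four paired years")
  n_cell <- ncol(carbon)
  rho <- p <- rep(NA_real_, n_cell)
  for (i in seq_len(n_cell)) {
    a <- carbon[, i]; b <- climate[, i]
    if (max(a) == min(a) || max(b) == min(b)) next
    if (detrend_first) {
      a <- detrend(a)
      b <- detrend(b)
    }
    st <- spearman_test(a, b)
    rho[i] <- st$rho; p[i] <- st$p
  }
  list(rho = rho, p = p, significant = !is.na(p) & p < alpha)
}

#' Area-weighted regional aggregation
#'
#' Sums a per-cell annual series over integer-labelled regions. Values are
#' either already extensive (t C per cell; \code{areas = NULL}) or densities
#' to be multiplied by cell areas first. Regions partition the global total.
#'
#' @param field matrix \code{[n_year, n_cell]}.
#' @param mask integer region label per cell.
#' @param areas optional cell areas (ha) for density input.
#' @return Matrix \code{[n_year, n_region]} with region labels as columns.
#' @export
regional_aggregate <- function(field, mask, areas = NULL) {
  field <- as.matrix(field)
  if (length(mask) != ncol(field))
    stop("regional_aggregate: mask does not cover the grid")
  if (!is.null(areas))
    field <- sweep(field, 2, areas, `*`)
  labs <- sort(unique(mask))
  out <- sapply(labs, function(r)
    rowSums(field[, mask == r, drop = FALSE]))
  out <- matrix(out, nrow = nrow(field))
  colnames(out) <- as.character(labs)
  out
}

#' Symmetric relative uncertainty bounds
#'
#' Scales an aggregated stock or flux by a relative error fraction (default
#' 0.5\%, the source dataset's global error on woody carbon) to symmetric
#' bounds.
#'
#' @param value numeric value(s).
#' @param fraction relative error, >= 0 (default 0.005).
#' @return List with \code{lower}, \code{upper} and \code{half_width}.
#' @export
scale_uncertainty <- function(value, fraction = 0.005) {
  if (any(fraction < 0)) stop("scale_uncertainty: fraction must be >= 0")
  hw <- abs(value) * fraction
  list(lower = value - hw, upper = value + hw, half_width = hw)
}

#' Diagnostics report for a decomposition
#'
#' Convenience wrapper assembling the package's evaluation metrics for a
#' fitted decomposition: IAV of the flux series, assimilation bias,
#' temporal agreement of global observed vs. carried stocks, land-use
#' intensity, optional detrended Spearman climate correlation maps and
#' regional series, and the scaled uncertainty of the mean stocks.
#'
#' @param decomp a \code{bkm_decomposition}.
#' @param forcing the \code{\link{transition_forcing}} used.
#' @param climate optional list with matrices \code{temperature} and/or
#'   \code{precipitation} (\code{[n_year, n_cell]} anomalies or raw values).
#' @param region_mask optional integer region labels per cell.
#' @param error_fraction relative observational error (default 0.005).
#' @return Object of class \code{bkm_diagnostics} (a list of metric
#'   results).
#' @export
bkm_diagnostics <- function(decomp, forcing, climate = NULL,
                            region_mask = NULL, error_fraction = 0.005) {
  stopifnot(inherits(decomp, "bkm_decomposition"))
  run_t <- decomp$runs$transient
  s <- decomp$series
  obs <- run_t$obs_stock
  bias <- assimilation_bias(run_t$carried, obs)
  agree <- temporal_agreement(rowSums(obs), rowSums(run_t$carried))
  out <- list(
    iav = list(
      eluc_transient = iav(s$eluc_transient),
      eluc_fixed = iav(s$eluc_fixed),
      sland = tryCatch(iav(s$sland[-1]), error = function(e) NA_real_),
      net_transient = tryCatch(iav(s$eluc_transient + s$sland),
                               error = function(e) NA_real_)),
    assimilation_bias = bias,
    temporal_agreement = agree,
    lulcc_intensity = lulcc_intensity(forcing),
    stock_uncertainty = list(
      transient = scale_uncertainty(mean(s$stock_transient), error_fraction),
      fixed = scale_uncertainty(mean(s$stock_fixed), error_fraction))
  )
  if (!is.null(climate)) {
    out$correlations <- lapply(climate, function(cl)
      spearman_map(run_t$stocks, cl))
  }
  if (!is.null(region_mask)) {
    out$regional_stocks <- regional_aggregate(run_t$stocks, region_mask)
  }
  class(out) <- "bkm_diagnostics"
  out
}

#' @export
print.bkm_diagnostics <- function(x, ...) {
  cat("bkm_diagnostics\n")
  cat(sprintf("  IAV: E_LUC transient %.3g | fixed %.3g | S_LAND,B %.3g\n",
              x$iav$eluc_transient, x$iav$eluc_fixed, x$iav$sland))
  cat(sprintf("  assimilation bias: %.4g +- %.2g PgC\n",
              x$assimilation_bias$global_mean, x$assimilation_bias$global_sd))
  cat(sprintf("  temporal agreement (global stocks): %.1f%%\n",
              100 * x$temporal_agreement))
  cat(sprintf("  mean land-use intensity: %.3g%% of cell area per yr\n",
              mean(x$lulcc_intensity)))
  if (!is.null(x$correlations))
    for (nm in names(x$correlations))
      cat(sprintf("  Spearman vs %s: median rho %.2f, %.0f%% significant\n",
                  nm, stats::median(x$correlations[[nm]]$rho, na.rm = TRUE),
                  100 * mean(x$correlations[[nm]]$significant)))
  invisible(x)
}
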