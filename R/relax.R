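#' One-year exponential relaxation of all excess pools
#'
#' Every excess pool is relaxed as \eqn{\delta(t) = \delta(t-1)\,e^{-1/\tau}}
#' and the difference is booked as a carbon flux
#' \eqn{\theta(t) = \delta(t-1)\,(1 - e^{-1/\tau})} with the pool's sign:
#' positive (detached material) excess releases carbon to the atmosphere,
#' negative (regrowth deficit) excess takes carbon up. Fluxes are reported
#' separately for the main excess pools ("instantaneous", driven by the
#' previous year's transitions), the pre-T0 legacy pools and the post-T0
#' legacy pools, each split by history category (clearing, harvest,
#' abandonment, other).
#'
#' @param state a \code{\link{pool_state}}.
#' @param tau a \code{\link{tau_table}}.
#' @param .alpha optional precomputed survival-factor array (internal, for
#'   reuse across years of a run).
#' @return List with \code{state} (relaxed pools) and \code{flux}: a list of
#'   matrices \code{inst}, \code{leg_pre}, \code{leg_post}, \code{total}
#'   (\code{n_cell x 4} history categories, t C, release-positive) plus
#'   \code{uptake}, the regrow-role (negative) part of the total.
#' @export
relax_step <- function(state, tau, .alpha = NULL) {
  al <- if (is.null(.alpha)) tau_alpha(tau, state$grid$n_cell) else .alpha
  one_set <- function(arr) {
    th <- arr * (1 - al)
    list(pool = arr * al, theta = th)
  }
  e <- one_set(state$exc)
  p <- one_set(state$leg_pre)
  q <- one_set(state$leg_post)
  state$exc <- e$pool
  state$leg_pre <- p$pool
  state$leg_post <- q$pool
  flux <- list(inst = sum_hist(e$theta),
               leg_pre = sum_hist(p$theta),
               leg_post = sum_hist(q$theta))
  flux$total <- flux$inst + flux$leg_pre + flux$leg_post
  flux$uptake <- sum_hist_regrow(e$theta) + sum_hist_regrow(p$theta) +
    sum_hist_regrow(q$theta)
  colnames(flux$inst) <- colnames(flux$leg_pre) <-
    colnames(flux$leg_post) <- colnames(flux$total) <-
    colnames(flux$uptake) <- HISTORY_TYPES
  list(state = state, flux = flux)
}

#' Update the post-T0 legacy pools
#'
#' At the beginning of each simulated year the post-T0 legacy pools release
#' their relaxation flux \eqn{\theta_{leg\ge T0}(t) = \delta_{leg\ge
#' T0}(t-1)(1 - e^{-1/\tau})} and absorb the previous year's main excess.
#' The injected excess is added after its own first-year relaxation (booked
#' as the instantaneous flux), i.e.
#' \deqn{\delta_{leg\ge T0}(t) = \delta_{leg\ge T0}(t-1)\,e^{-1/\tau}
#'       + \delta_B(t-1)\,e^{-1/\tau},}
#' which makes the pooled accounting exactly equal to an independent
#' per-event cohort ledger and closes the carbon budget (adding the
#' injection undecayed while also booking its first-year flux would create
#' carbon from nothing).
#'
#' @param state a \code{\link{pool_state}} whose \code{leg_post} holds
#'   \eqn{\delta_{leg\ge T0}(t-1)}.
#' @param prior_excess the previous year's main excess array
#'   \eqn{\delta_B(t-1)} (same shape as \code{state$exc}).
#' @param tau a \code{\link{tau_table}}.
#' @return List with \code{state} (updated \code{leg_post}, main excess
#'   zeroed) and \code{theta}: the legacy flux matrix \code{n_cell x 4}
#'   history categories (t C, release-positive).
#' @export
update_legacy_pools <- function(state, prior_excess, tau) {
  if (!identical(dim(prior_excess), dim(state$leg_post)))
    stop("update_legacy_pools: mismatched index shapes")
  al <- tau_alpha(tau, state$grid$n_cell)
  theta_arr <- state$leg_post * (1 - al)
  state$leg_post <- state$leg_post * al + prior_excess * al
  state$exc[] <- 0
  theta <- apply(theta_arr, c(1, 3), sum)
  colnames(theta) <- HISTORY_TYPES
  list(state = state, theta = theta)
}

# fold the (already relaxed) main excess into the post-T0 legacy trackers;
# used by the transient run after relax_step has booked this year's fluxes
fold_excess <- function(state) {
  state$leg_post <- state$leg_post + state$exc
  state$exc[] <- 0
  state
}

#' Total carbon flux from its three components
#'
#' Elementwise sum of the instantaneous flux, the pre-T0 legacy flux and the
#' post-T0 legacy flux; any category split is preserved.
#'
#' @param theta_inst,theta_leg_pre,theta_leg_post conforming numeric arrays
#'   (t C, release-positive).
#' @return Their elementwise sum.
#' @export
total_flux <- function(theta_inst, theta_leg_pre, theta_leg_post) {
  if (!identical(dim(theta_inst), dim(theta_leg_pre)) ||
      !identical(dim(theta_inst), dim(theta_leg_post)) ||
      length(theta_inst) != length(theta_leg_pre) ||
      length(theta_inst) != length(theta_leg_post))
    stop("total_flux: mismatched shapes")
  theta_inst + theta_leg_pre + theta_leg_post
}
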