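## Mesoscale surrogate tree: couples the averaged outlet flow of the feeding
## artery to the capillary inlets through a symmetric Murray-law bifurcation
## tree. Only the algebraic radius/flow relations are modelled; the
## intermediate geometry (lengths, angles) never enters.

#' Time-averaged flow over one period
#'
#' Trapezoidal time-weighted mean (1/T) * integral of Q over one beat.
#'
#' @param t times (s), strictly increasing, spanning one period.
#' @param Q flow samples (cm^3/s) at \code{t}.
#' @param T_period beat period in seconds; \code{t} must cover it to within
#'   one sample spacing.
#' @return scalar mean flow Q0 (cm^3/s).
#' @export
average_period_flow <- function(t, Q, T_period) {
  stopifnot(length(t) == length(Q), length(t) >= 2, T_period > 0)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  span <- t[length(t)] - t[1]
  if (span < T_period - 1.5 * max(diff(t))) {
    stop("flow series does not cover one full period")
  }
  sum(diff(t) * (head(Q, -1) + Q[-1]) / 2) / span
}

#' Number of bifurcation levels of a symmetric Murray tree
#'
#' Inverts the level-radius relation r0 = 2^(n/gamma) * rn, giving
#' n = gamma * log2(r0/rn). n is generally non-integer and is not rounded:
#' only the radius-ratio power law is used downstream.
#'
#' @param r0 root radius (cm).
#' @param rn leaf radius (cm), 0 < rn <= r0.
#' @param gamma Murray exponent in [2, 3.5].
#' @return number of levels (real, >= 0).
#' @export
tree_levels <- function(r0, rn, gamma = 3) {
  stopifnot(r0 > 0, rn > 0, gamma >= 2, gamma <= 3.5)
  if (any(rn > r0)) stop("leaf radius exceeds root radius")
  gamma * log2(r0 / rn)
}

#' Capillary inlet flow from the surrogate tree
#'
#' Flow delivered to a leaf of radius \code{r_c} when the root (the feeding
#' artery, reference radius \code{r0}) carries \code{Q0}:
#' Q = Q0 * (r_c/r0)^gamma.
#'
#' @param Q0 root flow (cm^3/s).
#' @param r_c leaf (capillary inlet) radius (cm); vectorised.
#' @param r0 root radius (cm).
#' @param gamma Murray exponent.
#' @return inlet flow(s) (cm^3/s).
#' @export
leaf_inflow <- function(Q0, r_c, r0, gamma = 3) {
  stopifnot(Q0 >= 0, all(r_c > 0), r0 > 0)
  Q0 * (r_c / r0)^gamma
}

#' Distribute a total flow over outlets by cross-section area
#'
#' @param Q_total total flow to distribute (cm^3/s).
#' @param areas outlet cross-section areas (any common unit).
#' @return per-outlet flows summing exactly to \code{Q_total}.
#' @export
distribute_outflow <- function(Q_total, areas) {
  if (length(areas) == 0) stop("empty outlet set")
  stopifnot(all(areas > 0))
  Q_total * areas / sum(areas)
}

#' Mean velocity in a circular vessel
#'
#' @param Q flow (cm^3/s).
#' @param r radius (cm).
#' @return velocity Q/(pi r^2) (cm/s).
#' @export
inlet_velocity <- function(Q, r) {
  stopifnot(all(r > 0))
  Q / (pi * r^2)
}

#' Mesoscale coupling record
#'
#' Convenience wrapper producing the per-inlet coupling quantities from an
#' averaged root flow and the chosen capillary inlet radii.
#'
#' @param Q0 averaged root flow (cm^3/s).
#' @param inlet_radii_cm capillary inlet radii (cm), largest first.
#' @param r0 root (feeding artery) reference radius (cm).
#' @param gamma Murray exponent, default 3.
#' @return list with \code{Q0}, \code{gamma} and a data.frame \code{inlets}
#'   (radius_cm, Q_cm3s, v_cms).
#' @export
mesotree_couple <- function(Q0, inlet_radii_cm, r0, gamma = 3) {
  Qs <- leaf_inflow(Q0, inlet_radii_cm, r0, gamma)
  list(Q0 = Q0, gamma = gamma,
       inlets = data.frame(radius_cm = inlet_radii_cm,
                           Q_cm3s = Qs,
                           v_cms = inlet_velocity(Qs, inlet_radii_cm)))
}
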