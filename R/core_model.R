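#' Specific surface of bone available for remodelling
#'
#' Square-root surface law relating bone volume fraction to the bone--marrow
#' interface area per unit tissue volume:
#' `Sv = a * sqrt(1 - fBM) * (1 - b * (1 - fBM))`.
#' The surface vanishes at `fBM = 1` (fully dense bone has no internal
#' surface on which remodelling can act).
#'
#' @param fBM bone volume fraction, in \[0, 1\] (vectorized).
#' @param params a [bone_params()] object.
#' @return Specific surface (1/mm).
#' @examples
#' specific_surface(0.9, bone_params())
#' @export
specific_surface <- function(fBM, params = bone_params()) {
  if (any(!is.finite(fBM)) || any(fBM < 0) || any(fBM > 1)) {
    stop("fBM must lie in [0, 1]")
  }
  params$a * sqrt(1 - fBM) * (1 - params$b * (1 - fBM))
}

#' Tissue stiffness as a function of bone volume fraction and strain rate
#'
#' `E = E0 * strain_rate^gammaE * fBM^3`: stiffness rises with mineralized
#' volume (cubically) and weakly with loading rate.
#'
#' @param fBM bone volume fraction in (0, 1\] (vectorized).
#' @param strain_rate strain rate (1/s), strictly positive.
#' @inheritParams specific_surface
#' @return Stiffness (MPa).
#' @examples
#' tissue_stiffness(0.9, 0.36, bone_params())  # reference stiffness 1714.1
#' @export
tissue_stiffness <- function(fBM, strain_rate, params = bone_params()) {
  if (any(!is.finite(strain_rate)) || any(strain_rate <= 0)) {
    stop("strain_rate must be positive")
  }
  if (any(!is.finite(fBM)) || any(fBM <= 0) || any(fBM > 1)) {
    stop("fBM must lie in (0, 1]")
  }
  params$E0 * strain_rate^params$gammaE * fBM^3
}

#' Strain energy density under uniaxial compression
#'
#' `psi = sigma^2 / (2 E)`, the mechanical signal sensed by osteocytes.
#'
#' @param sigma joint contact pressure (MPa, compression positive).
#' @param E tissue stiffness (MPa), strictly positive.
#' @return Strain energy density (MPa).
#' @export
strain_energy_density <- function(sigma, E) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  if (any(sigma < 0)) stop("sigma must be non-negative (compression positive)")
  sigma^2 / (2 * E)
}

# increasing Hill term psi^g / (d^g + psi^g), with the convention 0^g/d^g = 0
.hill_up <- function(psi, delta, gamma) {
  h <- ifelse(psi <= 0, 0, psi^gamma / (delta^gamma + psi^gamma))
  h
}

#' Osteoblast formation activity
#'
#' Increasing Hill function of strain energy density:
#' `AOBL = AOBL_min + (AOBL_max - AOBL_min) * psi^gammaB / (deltaB^gammaB + psi^gammaB)`.
#' Bounded by the activity limits and monotone non-decreasing in `psi`.
#'
#' @param psi strain energy density (MPa), non-negative (vectorized).
#' @inheritParams specific_surface
#' @return Formation activity (mm/day).
#' @export
formation_activity <- function(psi, params = bone_params()) {
  if (any(psi < 0)) stop("psi must be non-negative")
  params$AOBL_min + (params$AOBL_max - params$AOBL_min) *
    .hill_up(psi, params$deltaB, params$gammaB)
}

#' Osteoclast resorption activity
#'
#' Decreasing Hill function of strain energy density:
#' `AOCL = AOCL_min + (AOCL_max - AOCL_min) * deltaC^gammaC / (deltaC^gammaC + psi^gammaC)`.
#' Intense loading inhibits resorption; at rest the activity approaches
#' `AOCL_max`.
#'
#' @inheritParams formation_activity
#' @return Resorption activity (mm/day).
#' @export
resorption_activity <- function(psi, params = bone_params()) {
  if (any(psi < 0)) stop("psi must be non-negative")
  params$AOCL_min + (params$AOCL_max - params$AOCL_min) *
    (1 - .hill_up(psi, params$deltaC, params$gammaC))
}

#' Stiffness-adjusted fatigue life
#'
#' Power-law fatigue life of subchondral bone adjusted by the ratio of the
#' current stiffness to the reference stiffness of the fatigue experiments:
#' `Nf* = 10^(-(sigma - sigma0)/sigma1) * E / Enom`.
#' Strictly decreasing in stress and increasing in stiffness.
#'
#' @inheritParams strain_energy_density
#' @inheritParams specific_surface
#' @return Adjusted fatigue life (cycles).
#' @export
fatigue_life <- function(sigma, E, params = bone_params()) {
  if (any(sigma < 0)) stop("sigma must be non-negative (compression positive)")
  10^(-(sigma - params$sigma0) / params$sigma1) * E / params$Enom
}

#' Damage incurred per loading cycle
#'
#' The reciprocal of the adjusted fatigue life: `vD = 1 / Nf*`. The identity
#' `damage_per_cycle * fatigue_life == 1` holds to machine precision.
#'
#' @inheritParams fatigue_life
#' @return Damage life-fraction per cycle.
#' @export
damage_per_cycle <- function(sigma, E, params = bone_params()) {
  1 / fatigue_life(sigma, E, params)
}

#' Daily damage formation rate
#'
#' `Df = vD * vn`: per-cycle damage times cycles per day.
#'
#' @param vD damage per cycle.
#' @param vn cycles per day (1/day).
#' @return Damage formation rate (1/day).
#' @export
damage_formation_rate <- function(vD, vn) {
  if (any(vD < 0) || any(vn < 0)) stop("vD and vn must be non-negative")
  vD * vn
}

#' Daily damage repair rate
#'
#' Repair through remodelling: formation dilutes microcracks over new bone
#' volume, and resorption removes cracks preferentially when osteoclasts
#' target them (specificity factor `Fs`; `Fs = 1` is untargeted resorption,
#' which repairs nothing beyond the formation term):
#' `Dr = (AOBL + (Fs - 1) * AOCL) * alpha * Sv * D / fBM`.
#' Exactly linear in the current damage `D`.
#'
#' @param AOBL formation activity (mm/day).
#' @param AOCL resorption activity (mm/day).
#' @param Sv specific surface (1/mm).
#' @param fBM bone volume fraction, strictly positive.
#' @param D damage life fraction.
#' @inheritParams specific_surface
#' @return Damage repair rate (1/day).
#' @export
damage_repair_rate <- function(AOBL, AOCL, Sv, fBM, D, params = bone_params()) {
  if (any(fBM <= 0)) stop("fBM must be positive")
  (AOBL + (params$Fs - 1) * AOCL) * params$alpha * Sv * D / fBM
}

#' All algebraic intermediates and state derivatives at one state
#'
#' Composes the full model: surface, stiffness, strain energy density, both
#' activities, adjusted fatigue life, per-cycle damage, damage formation and
#' repair rates, and the two state derivatives
#' `dfBM/dt = (AOBL - AOCL) * alpha * Sv` and `dD/dt = Df - Dr`.
#' Every intermediate is returned so downstream stages (traces, damage
#' attribution, tests) never re-derive the physics. Vectorized over `fBM`
#' and `D` of equal length.
#'
#' @param fBM bone volume fraction (vectorized).
#' @param D damage life fraction (vectorized, recycled against `fBM`).
#' @param loading a [loading_condition()].
#' @inheritParams specific_surface
#' @return A list of class `rate_bundle` with elements `Sv`, `E`, `psi`,
#'   `AOBL`, `AOCL`, `Nf_adj`, `vD`, `Df`, `Dr`, `dfBM_dt`, `dD_dt`.
#' @export
rate_bundle <- function(fBM, D, loading, params = bone_params()) {
  Sv   <- specific_surface(fBM, params)
  E    <- tissue_stiffness(fBM, loading$strain_rate, params)
  psi  <- strain_energy_density(loading$sigma, E)
  AOBL <- formation_activity(psi, params)
  AOCL <- resorption_activity(psi, params)
  Nf   <- fatigue_life(loading$sigma, E, params)
  vD   <- 1 / Nf
  Df   <- damage_formation_rate(vD, loading$vn)
  Dr   <- damage_repair_rate(AOBL, AOCL, Sv, fBM, D, params)
  structure(list(
    Sv = Sv, E = E, psi = psi, AOBL = AOBL, AOCL = AOCL,
    Nf_adj = Nf, vD = vD, Df = Df, Dr = Dr,
    dfBM_dt = (AOBL - AOCL) * params$alpha * Sv,
    dD_dt = Df - Dr
  ), class = "rate_bundle")
}

#' Right-hand side of the coupled adaptation--damage ODE
#'
#' Thin wrapper over [rate_bundle()] in the `(t, state, ...)` signature used
#' by integrators. Time does not enter the autonomous right-hand side; it is
#' accepted for interface compatibility.
#'
#' @param t time (days); unused (autonomous system).
#' @param state named numeric vector or [bone_state()] with `fBM` and `D`.
#' @param loading a [loading_condition()].
#' @inheritParams specific_surface
#' @return A `rate_bundle` list (see [rate_bundle()]).
#' @export
model_rhs <- function(t, state, loading, params = bone_params()) {
  rate_bundle(unname(state[["fBM"]]), unname(state[["D"]]), loading, params)
}
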