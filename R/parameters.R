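#' Model parameter sets for the subchondral bone adaptation model
#'
#' Constructs the full set of constants governing the coupled bone volume
#' fraction / microdamage model: the surface law (`a`, `b`, `alpha`), the
#' stiffness law (`E0`, `gammaE`), the Hill mechanoregulation of osteoblast
#' formation (`AOBL_min`, `AOBL_max`, `deltaB`, `gammaB`) and osteoclast
#' resorption (`AOCL_min`, `AOCL_max`, `deltaC`, `gammaC`), the fatigue-life
#' power law (`sigma0`, `sigma1`, `Enom`) and the damage-repair specificity
#' factor `Fs`.
#'
#' Two presets are available. `"table2-fitted"` (the default) carries the
#' values after calibration to bone volume fraction and fracture-time data
#' (`AOBL_max = 0.00603`, `AOCL_max = 0.00358`, `sigma0 = 139.0`).
#' `"table2-initial"` carries the pre-calibration literature values
#' (`AOBL_max = 0.0127`, `AOCL_max = 0.011`, `sigma0 = 134.2`); the
#' "four-fold higher resorption at rest" tuning of the resorption Hill
#' function refers to this preset.
#'
#' @param preset character; `"table2-fitted"` or `"table2-initial"`.
#' @param ... named overrides of individual parameters, e.g. `sigma0 = 140`.
#'   Unknown names are an error.
#' @return An object of class `bone_params`: a named list of 17 numeric
#'   constants.
#' @examples
#' p <- bone_params()
#' p$sigma0
#' p_pre <- bone_params("table2-initial")
#' p_pre$AOCL_max
#' @export
bone_params <- function(preset = c("table2-fitted", "table2-initial"), ...) {
  preset <- match.arg(preset)
  p <- list(
    a         = 11.42,     # surface-law coefficient (mm^-1)
    b         = -0.02,     # surface-law coefficient (-)
    alpha     = 0.19,      # fraction of specific surface available (-)
    E0        = 2500,      # maximum bone stiffness (MPa)
    gammaE    = 0.06,      # strain-rate exponent (-)
    AOBL_min  = 0.001094,  # min formation activity (mm/day)
    AOBL_max  = 0.00603,   # max formation activity (mm/day), fitted
    deltaB    = 7,         # formation half-saturation (MPa)
    gammaB    = 1,         # formation sigmoidicity (-)
    AOCL_min  = 0.001,     # min resorption activity (mm/day)
    AOCL_max  = 0.00358,   # max resorption activity (mm/day), fitted
    deltaC    = 1,         # resorption half-saturation (MPa)
    gammaC    = 2,         # resorption sigmoidicity (-)
    sigma0    = 139.0,     # fatigue-life offset stress (MPa), fitted
    sigma1    = 14.1,      # fatigue-life decade stress (MPa)
    Enom      = 1714.1,    # reference stiffness of the fatigue tests (MPa)
    Fs        = 5          # damage repair specificity factor (-)
  )
  if (preset == "table2-initial") {
    p$AOBL_max <- 0.0127
    p$AOCL_max <- 0.011
    p$sigma0   <- 134.2
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
  }
  p <- lapply(p, as.numeric)
  class(p) <- "bone_params"
  validate_bone_params(p)
  p
}

#' Validate a bone_params object
#'
#' Checks positivity of stiffnesses, rates and half-saturations, the ordering
#' of the activity bounds, `Fs >= 1` and `alpha` in (0, 1].
#'
#' @param p a `bone_params` object (or plain named list with the same fields).
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_bone_params <- function(p) {
  need <- c("a", "b", "alpha", "E0", "gammaE", "AOBL_min", "AOBL_max",
            "deltaB", "gammaB", "AOCL_min", "AOCL_max", "deltaC", "gammaC",
            "sigma0", "sigma1", "Enom", "Fs")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  stopifnot(
    "E0 must be positive" = p$E0 > 0,
    "Enom must be positive" = p$Enom > 0,
    "sigma0 must be positive" = p$sigma0 > 0,
    "sigma1 must be positive" = p$sigma1 > 0,
    "deltaB must be positive" = p$deltaB > 0,
    "deltaC must be positive" = p$deltaC > 0,
    "a must be positive" = p$a > 0,
    "activity bounds must satisfy 0 <= min <= max" =
      p$AOBL_min >= 0 && p$AOBL_max >= p$AOBL_min &&
      p$AOCL_min >= 0 && p$AOCL_max >= p$AOCL_min,
    "Fs must be >= 1" = p$Fs >= 1,
    "alpha must be in (0, 1]" = p$alpha > 0 && p$alpha <= 1
  )
  invisible(p)
}

#' @export
print.bone_params <- function(x, ...) {
  cat("<bone_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Loading condition: joint contact pressure, strain rate, daily cycles
#'
#' @param sigma joint contact pressure (MPa, compression positive). Negative
#'   (tensile) values are outside the fatigue law's domain and are rejected.
#' @param strain_rate strain rate (1/s), strictly positive.
#' @param vn loading cycles (strides) per day (1/day), non-negative.
#' @return An object of class `loading_condition`.
#' @examples
#' training_loading()
#' rest_loading()
#' @export
loading_condition <- function(sigma, strain_rate, vn) {
  stopifnot(
    "sigma must be a non-negative scalar (compression positive)" =
      is.numeric(sigma) && length(sigma) == 1 && is.finite(sigma) && sigma >= 0,
    "strain_rate must be a positive scalar" =
      is.numeric(strain_rate) && length(strain_rate) == 1 &&
      is.finite(strain_rate) && strain_rate > 0,
    "vn must be a non-negative scalar" =
      is.numeric(vn) && length(vn) == 1 && is.finite(vn) && vn >= 0
  )
  structure(list(sigma = as.numeric(sigma),
                 strain_rate = as.numeric(strain_rate),
                 vn = as.numeric(vn)),
            class = "loading_condition")
}

#' @export
print.loading_condition <- function(x, ...) {
  cat(sprintf("<loading_condition> sigma = %g MPa, strain_rate = %g /s, vn = %g /day\n",
              x$sigma, x$strain_rate, x$vn))
  invisible(x)
}

#' Reference loading conditions
#'
#' `rest_loading()` is the proxy for a horse at rest: 30 MPa joint pressure
#' and no damage-relevant cycles. The rest strain rate is back-calculated so
#' that the strain energy density equals 0.31 MPa in race-adapted bone
#' (`fBM = 0.9`), the value used to tune the resorption Hill function; with
#' the default stiffness law this gives approximately 0.0225 1/s.
#' `training_loading()` is the surveyed routine training condition
#' (81.1 MPa, 0.2974 1/s, 43.7 cycles/day), and `race_loading()` the
#' race-fit/racing proxy at 90 MPa with the same strain rate and cycles.
#'
#' @param params a `bone_params` object supplying the stiffness law.
#' @param sigma joint contact pressure (MPa).
#' @param psi_ref strain energy density (MPa) that the rest condition should
#'   produce at `fBM_ref`.
#' @param fBM_ref reference bone volume fraction for the back-calculation.
#' @param vn cycles per day.
#' @return A `loading_condition`.
#' @export
rest_loading <- function(params = bone_params(), sigma = 30,
                         psi_ref = 0.31, fBM_ref = 0.9, vn = 0) {
  E_target <- sigma^2 / (2 * psi_ref)
  sr <- (E_target / (params$E0 * fBM_ref^3))^(1 / params$gammaE)
  loading_condition(sigma = sigma, strain_rate = sr, vn = vn)
}

#' @rdname rest_loading
#' @export
training_loading <- function(sigma = 81.1, vn = 43.7) {
  loading_condition(sigma = sigma, strain_rate = 0.2974, vn = vn)
}

#' @rdname rest_loading
#' @export
race_loading <- function(sigma = 90, vn = 43.7) {
  loading_condition(sigma = sigma, strain_rate = 0.2974, vn = vn)
}

#' Bone state constructor
#'
#' The state advanced by the ODE: bone volume fraction `fBM` in (0, 1] and
#' accumulated damage life-fraction `D` in \[0, 1\] (`D = 1` is failure of the
#' bone pocket).
#'
#' @param fBM bone volume fraction.
#' @param D damage life fraction.
#' @return A named numeric vector `c(fBM, D)` of class `bone_state`.
#' @export
bone_state <- function(fBM, D = 0) {
  stopifnot(
    "fBM must be in (0, 1]" = is.numeric(fBM) && length(fBM) == 1 &&
      is.finite(fBM) && fBM > 0 && fBM <= 1,
    "D must be in [0, 1]" = is.numeric(D) && length(D) == 1 &&
      is.finite(D) && D >= 0 && D <= 1
  )
  structure(c(fBM = as.numeric(fBM), D = as.numeric(D)), class = "bone_state")
}

# parameter vector in the order the compiled right-hand side expects
.parms_vector <- function(params, loading) {
  c(loading$sigma, loading$strain_rate, loading$vn,
    params$a, params$b, params$alpha, params$E0, params$gammaE,
    params$AOBL_min, params$AOBL_max, params$deltaB, params$gammaB,
    params$AOCL_min, params$AOCL_max, params$deltaC, params$gammaC,
    params$sigma0, params$sigma1, params$Enom, params$Fs)
}
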