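#' Specification of a synthetic calibration dataset
#'
#' Describes a dataset with the statistical structure of the calibration
#' data: cross-sectional bone volume fraction observations (one per limb)
#' against days in training or at rest, and a small right-skewed set of
#' times in training until fracture. Defaults mirror the calibration data's
#' shape: 213 training limbs, 24 resting limbs, 16 fracture horses,
#' Gaussian observation noise with sd 0.05 on the bone volume fraction.
#'
#' @param n_training,n_rest,n_fracture sample sizes.
#' @param noise_sd standard deviation of the Gaussian observation noise on
#'   fBM (observations truncated to (0, 1)).
#' @param training_window,rest_window observation-day windows (days); days
#'   are drawn uniformly within them.
#' @param dispersion log-scale standard deviation of the fracture-time
#'   distribution (log-normal, rescaled so the sample median matches the
#'   model's time to failure).
#' @param params generating [bone_params()].
#' @param training_initial,rest_initial arm initial bone volume fractions.
#' @param training_loading,rest_loading,fracture_loading arm loading
#'   conditions (see [calibration_dataset()]).
#' @param fracture_initial initial state for the high-workload fracture
#'   simulation.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_training = 213, n_rest = 24, n_fracture = 16,
                           noise_sd = 0.05,
                           training_window = c(0, 150),
                           rest_window = c(0, 120),
                           dispersion = 0.3,
                           params = bone_params(),
                           training_initial = 0.85, rest_initial = 0.93,
                           training_loading = equibone::training_loading(),
                           rest_loading = equibone::rest_loading(),
                           fracture_loading = race_loading(),
                           fracture_initial = bone_state(0.9, 0),
                           seed = 1) {
  stopifnot(
    "counts must be positive" = n_training > 0 && n_rest > 0 && n_fracture > 0,
    "noise_sd must be non-negative" = noise_sd >= 0,
    "dispersion must be non-negative" = dispersion >= 0,
    "windows must be increasing" =
      diff(training_window) > 0 && diff(rest_window) > 0
  )
  structure(list(n_training = n_training, n_rest = n_rest,
                 n_fracture = n_fracture, noise_sd = noise_sd,
                 training_window = training_window, rest_window = rest_window,
                 dispersion = dispersion, params = params,
                 training_initial = training_initial,
                 rest_initial = rest_initial,
                 training_loading = training_loading,
                 rest_loading = rest_loading,
                 fracture_loading = fracture_loading,
                 fracture_initial = fracture_initial,
                 seed = seed),
            class = "synthetic_spec")
}

# truncated-normal draw by rejection into (lo, hi)
.rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(pmin(pmax(mean, lo + 1e-12), hi - 1e-12))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate one cross-sectional arm of a synthetic dataset
#'
#' Draws observation days uniformly on the arm's window, simulates the
#' model trajectory for the arm from its initial condition and loading, and
#' adds Gaussian observation noise truncated to (0, 1). One observation per
#' synthetic limb.
#'
#' @param spec a [synthetic_spec()].
#' @param arm `"training"` or `"rest"`.
#' @param seed optional seed override (default: the spec's).
#' @return data.frame with columns `day`, `fBM`.
#' @export
generate_cross_sectional <- function(spec, arm = c("training", "rest"),
                                     seed = spec$seed) {
  arm <- match.arg(arm)
  n <- if (arm == "training") spec$n_training else spec$n_rest
  win <- if (arm == "training") spec$training_window else spec$rest_window
  init <- if (arm == "training") spec$training_initial else spec$rest_initial
  loading <- if (arm == "training") spec$training_loading else spec$rest_loading

  set.seed(seed + if (arm == "rest") 1L else 0L)
  days <- stats::runif(n, win[1], win[2])
  sim <- simulate_bone(constant_schedule(loading, win[2]),
                       bone_state(init, 0), spec$params, output_step = 0.5)
  mu <- stats::approx(sim$times, sim$fBM, xout = days, rule = 2)$y
  data.frame(day = days, fBM = .rnorm_trunc(n, mu, spec$noise_sd))
}

#' Generate synthetic fracture times
#'
#' Log-normal times with log-sd `dispersion`, rescaled multiplicatively so
#' the sample median equals the model's noise-free time to failure under
#' the spec's high-workload condition (by construction, the median carries
#' the model signal; the dispersion carries the between-horse spread).
#'
#' @inheritParams generate_cross_sectional
#' @return Numeric vector of days (length `n_fracture`).
#' @export
generate_fracture_times <- function(spec, seed = spec$seed) {
  ttf <- time_to_failure(spec$fracture_loading,
                         bone_state(spec$fracture_initial[["fBM"]],
                                    spec$fracture_initial[["D"]]),
                         spec$params)
  if (ttf$status != "failed") {
    stop("the spec's high-workload condition does not produce failure; ",
         "no fracture-time target exists")
  }
  set.seed(seed + 2L)
  raw <- stats::rlnorm(spec$n_fracture, meanlog = 0, sdlog = spec$dispersion)
  raw * ttf$days / stats::median(raw)
}

#' Generate a complete synthetic calibration dataset
#'
#' Both cross-sectional arms plus fracture times, assembled into a
#' [calibration_dataset()] carrying the spec's arm conventions.
#'
#' @inheritParams generate_cross_sectional
#' @return A [calibration_dataset()].
#' @export
generate_calibration_dataset <- function(spec, seed = spec$seed) {
  calibration_dataset(
    training = generate_cross_sectional(spec, "training", seed),
    rest = generate_cross_sectional(spec, "rest", seed),
    fracture_times = generate_fracture_times(spec, seed),
    training_initial = spec$training_initial,
    rest_initial = spec$rest_initial,
    training_loading = spec$training_loading,
    rest_loading = spec$rest_loading,
    fracture_loading = spec$fracture_loading,
    fracture_initial = spec$fracture_initial
  )
}
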