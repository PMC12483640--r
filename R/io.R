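#' Read model parameters from a flat config file
#'
#' Accepts a YAML or JSON file of `key: value` pairs whose keys are
#' [bone_params()] field names; values override the chosen preset. Unknown
#' keys are an error (typos must not silently become defaults). A `preset`
#' key selects the base preset.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return A [bone_params()] object.
#' @export
read_params_config <- function(path) {
  cfg <- .read_config(path)
  preset <- cfg$preset %||% "table2-fitted"
  cfg$preset <- NULL
  do.call(bone_params, c(list(preset = preset), cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read a training programme from a config file
#'
#' Layout: a top-level `phases` list; each phase has `kind`,
#' `duration_days` and optionally `workouts`, each workout a mapping with
#' `speed_m_s`, `distance_m` and `per` (`day` or `week`). Unknown keys are
#' an error.
#'
#' @param path YAML or JSON file path.
#' @return A list of [training_phase()] objects.
#' @export
read_programme_config <- function(path) {
  cfg <- .read_config(path)
  extra <- setdiff(names(cfg), c("phases", "description"))
  if (length(extra)) stop("unknown top-level key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$phases)) stop("programme config needs a 'phases' list")
  lapply(cfg$phases, function(ph) {
    extra <- setdiff(names(ph), c("kind", "duration_days", "workouts"))
    if (length(extra)) stop("unknown phase key(s): ", paste(extra, collapse = ", "))
    wk <- lapply(ph$workouts, function(w) {
      extra <- setdiff(names(w), c("speed_m_s", "distance_m", "per"))
      if (length(extra)) stop("unknown workout key(s): ",
                              paste(extra, collapse = ", "))
      workout(w$speed_m_s, w$distance_m, w$per %||% "day")
    })
    training_phase(ph$kind, ph$duration_days, wk)
  })
}

#' Write a simulation trajectory as tidy CSV
#'
#' One row per output time with the state, loading and the full rate bundle
#' (columns `day`, `fBM`, `D`, `Sv`, `E`, `psi`, `AOBL`, `AOCL`, `Df`,
#' `Dr`, ...). Numbers are written with 10 significant digits so re-runs
#' are byte-comparable.
#'
#' @param sim a [simulate_bone()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  df <- sim$trace
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the fully resolved inputs of a run: parameters, seed, solver
#' settings, units conventions (days, m/s, MPa) and any extra fields, so a
#' result file can be traced to its configuration.
#'
#' @param path JSON path.
#' @param params a [bone_params()] object.
#' @param seed integer seed (or `NULL`).
#' @param solver named list of solver settings.
#' @param ... further named fields stored verbatim.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params = bone_params(), seed = NULL,
                           solver = list(method = "lsodar", rtol = 1e-8,
                                         atol = 1e-10), ...) {
  manifest <- list(
    package = "equibone",
    version = as.character(utils::packageVersion("equibone")),
    units = list(time = "day", speed = "m/s", stress = "MPa",
                 strain_rate = "1/s"),
    parameters = unclass(params),
    seed = seed,
    solver = solver,
    ...
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
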