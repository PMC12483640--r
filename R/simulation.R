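#' Piecewise-constant loading schedule
#'
#' A loading schedule is an ordered set of contiguous segments, each holding
#' one [loading_condition()] constant. Segments must start at day 0, be
#' contiguous and non-overlapping.
#'
#' @param segments a data.frame with columns `start_day`, `end_day`, `sigma`,
#'   `strain_rate`, `vn` (one row per segment).
#' @return An object of class `loading_schedule` with elements `segments`
#'   and `total_duration` (days).
#' @seealso [constant_schedule()] for the single-segment case.
#' @export
loading_schedule <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("start_day", "end_day", "sigma", "strain_rate", "vn")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  segments <- segments[order(segments$start_day), need, drop = FALSE]
  n <- nrow(segments)
  if (n > 0) {
    if (abs(segments$start_day[1]) > 1e-12) stop("schedule must start at day 0")
    if (any(segments$end_day <= segments$start_day)) {
      stop("each segment must satisfy end_day > start_day")
    }
    if (n > 1 && any(abs(segments$start_day[-1] - segments$end_day[-n]) > 1e-9)) {
      stop("segments must be contiguous and non-overlapping")
    }
    for (i in seq_len(n)) {  # validates each condition
      loading_condition(segments$sigma[i], segments$strain_rate[i], segments$vn[i])
    }
  }
  structure(list(segments = segments,
                 total_duration = if (n) segments$end_day[n] else 0),
            class = "loading_schedule")
}

#' @rdname loading_schedule
#' @param loading a [loading_condition()].
#' @param duration segment length (days).
#' @export
constant_schedule <- function(loading, duration) {
  if (duration == 0) {
    return(structure(list(segments = data.frame(start_day = numeric(0),
                                                end_day = numeric(0),
                                                sigma = numeric(0),
                                                strain_rate = numeric(0),
                                                vn = numeric(0)),
                          total_duration = 0),
                     class = "loading_schedule"))
  }
  loading_schedule(data.frame(start_day = 0, end_day = duration,
                              sigma = loading$sigma,
                              strain_rate = loading$strain_rate,
                              vn = loading$vn))
}

#' @export
print.loading_schedule <- function(x, ...) {
  cat(sprintf("<loading_schedule> %d segment(s), %g days\n",
              nrow(x$segments), x$total_duration))
  invisible(x)
}

# R-language right-hand side, mirroring src/bone_model.c
.rhs_r <- function(loading, params) {
  function(t, y, parms) {
    fBM <- min(max(y[1], 1e-9), 1 - 1e-9)
    D <- y[2]
    Sv <- params$a * sqrt(1 - fBM) * (1 - params$b * (1 - fBM))
    E <- params$E0 * loading$strain_rate^params$gammaE * fBM^3
    psi <- loading$sigma^2 / (2 * E)
    hb <- if (psi <= 0) 0 else psi^params$gammaB /
      (params$deltaB^params$gammaB + psi^params$gammaB)
    AOBL <- params$AOBL_min + (params$AOBL_max - params$AOBL_min) * hb
    hc <- params$deltaC^params$gammaC /
      (params$deltaC^params$gammaC + psi^params$gammaC)
    AOCL <- params$AOCL_min + (params$AOCL_max - params$AOCL_min) * hc
    vD <- 10^((loading$sigma - params$sigma0) / params$sigma1) * params$Enom / E
    Dr <- (AOBL + (params$Fs - 1) * AOCL) * params$alpha * Sv * D / fBM
    list(c((AOBL - AOCL) * params$alpha * Sv, vD * loading$vn - Dr))
  }
}

# integrate one constant-loading segment; stops at the D = 1 root
.integrate_segment <- function(y0, t0, t1, loading, params, output_step,
                               engine, rtol, atol) {
  times <- unique(c(seq(t0, t1, by = output_step), t1))
  if (length(times) < 2) times <- c(t0, t1)
  if (engine == "compiled") {
    out <- deSolve::ode(y = y0, times = times, func = "bone_derivs",
                        parms = .parms_vector(params, loading),
                        dllname = "equibone", initfunc = "bone_init",
                        rootfunc = "bone_root", nroot = 1,
                        method = "lsodar", rtol = rtol, atol = atol)
  } else {
    root_r <- function(t, y, parms) y[2] - 1
    out <- deSolve::ode(y = y0, times = times, func = .rhs_r(loading, params),
                        parms = NULL, rootfunc = root_r,
                        method = "lsodar", rtol = rtol, atol = atol)
  }
  troot <- attributes(out)$troot
  list(times = out[, 1], states = unname(out[, 2:3, drop = FALSE]),
       troot = if (length(troot)) troot[1] else NA_real_)
}

#' Simulate the coupled adaptation--damage ODE under a loading schedule
#'
#' Integrates segment by segment with a stiff-capable adaptive solver
#' (`lsodar`), restarting at every segment boundary so discontinuous loading
#' never crosses a solver step. Integration terminates at the first time the
#' damage `D` reaches 1 (failure of the bone pocket), located by the solver's
#' root finder. The bone volume fraction is kept inside (0, 1) by clipping at
#' `1 - 1e-9` (the surface law is undefined above 1); any clipping is
#' recorded in the result.
#'
#' @param schedule a [loading_schedule()].
#' @param initial a [bone_state()] (or named vector with `fBM`, `D`).
#' @param params a [bone_params()] object.
#' @param output_step spacing of the output grid (days).
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return An object of class `bone_simulation`: list with `times`, `fBM`,
#'   `D`, `trace` (a data.frame with the full rate bundle and loading at each
#'   output time), `failure_day` (`NA` if `D` never reached 1),
#'   `terminated_early`, `clipped`, plus the inputs.
#' @examples
#' sim <- simulate_bone(constant_schedule(training_loading(), 30),
#'                      bone_state(0.9, 0), bone_params())
#' tail(sim$trace, 2)
#' @export
simulate_bone <- function(schedule, initial, params = bone_params(),
                          output_step = 1, engine = c("compiled", "R"),
                          rtol = 1e-8, atol = 1e-10) {
  engine <- match.arg(engine)
  validate_bone_params(params)
  y <- c(fBM = unname(initial[["fBM"]]), D = unname(initial[["D"]]))
  stopifnot("initial fBM must be in (0, 1]" = y[1] > 0 && y[1] <= 1,
            "initial D must be in [0, 1]" = y[2] >= 0 && y[2] <= 1)

  segs <- schedule$segments
  if (nrow(segs) == 0 || y[2] >= 1) {
    times <- 0
    states <- matrix(y, nrow = 1)
    failure_day <- if (y[2] >= 1) 0 else NA_real_
    loading_rows <- if (nrow(segs)) 1L else integer(0)
  } else {
    times <- numeric(0)
    states <- NULL
    seg_of <- integer(0)
    failure_day <- NA_real_
    for (i in seq_len(nrow(segs))) {
      loading <- loading_condition(segs$sigma[i], segs$strain_rate[i], segs$vn[i])
      res <- .integrate_segment(y, segs$start_day[i], segs$end_day[i], loading,
                                params, output_step, engine, rtol, atol)
      keep <- if (length(times)) res$times > times[length(times)] else
        rep(TRUE, length(res$times))
      times <- c(times, res$times[keep])
      states <- rbind(states, res$states[keep, , drop = FALSE])
      seg_of <- c(seg_of, rep(i, sum(keep)))
      y <- c(fBM = res$states[nrow(res$states), 1],
             D = res$states[nrow(res$states), 2])
      if (!is.na(res$troot)) {
        failure_day <- res$troot
        break
      }
    }
  }

  clipped <- any(states[, 1] > 1 - 1e-9 + 1e-12)
  states[, 1] <- pmin(states[, 1], 1 - 1e-9)

  # per-time rate bundle, segment-wise so each row uses its own loading
  if (nrow(segs)) {
    seg_idx <- pmin(findInterval(times, segs$start_day,
                                 rightmost.closed = TRUE), nrow(segs))
    seg_idx[1] <- max(seg_idx[1], 1L)
    trace <- do.call(rbind, lapply(split(seq_along(times), seg_idx), function(ii) {
      i <- seg_idx[ii[1]]
      ld <- loading_condition(segs$sigma[i], segs$strain_rate[i], segs$vn[i])
      rb <- rate_bundle(states[ii, 1], states[ii, 2], ld, params)
      data.frame(day = times[ii], fBM = states[ii, 1], D = states[ii, 2],
                 sigma = ld$sigma, strain_rate = ld$strain_rate, vn = ld$vn,
                 Sv = rb$Sv, E = rb$E, psi = rb$psi, AOBL = rb$AOBL,
                 AOCL = rb$AOCL, Nf_adj = rb$Nf_adj, vD = rb$vD,
                 Df = rb$Df, Dr = rb$Dr,
                 dfBM_dt = rb$dfBM_dt, dD_dt = rb$dD_dt)
    }))
    trace <- trace[order(trace$day), ]
    rownames(trace) <- NULL
  } else {
    trace <- data.frame(day = times, fBM = states[, 1], D = states[, 2])
  }

  structure(list(times = times, fBM = states[, 1], D = states[, 2],
                 trace = trace, failure_day = failure_day,
                 terminated_early = !is.na(failure_day),
                 clipped = clipped, schedule = schedule, params = params,
                 initial = c(fBM = unname(initial[["fBM"]]),
                             D = unname(initial[["D"]])),
                 solver = list(engine = engine, rtol = rtol, atol = atol,
                               output_step = output_step)),
            class = "bone_simulation")
}

#' @export
print.bone_simulation <- function(x, ...) {
  cat(sprintf("<bone_simulation> %g days, fBM %0.4f -> %0.4f, D %0.4f -> %0.4f%s\n",
              max(x$times), x$fBM[1], x$fBM[length(x$fBM)],
              x$D[1], x$D[length(x$D)],
              if (x$terminated_early)
                sprintf(" (failed at day %0.2f)", x$failure_day) else ""))
  invisible(x)
}

#' Locate the steady state of bone volume fraction under constant loading
#'
#' Integrates the adaptation equation over a long horizon until the declared
#' steady-state criterion is met: `|dfBM/dt| < rate_tol` sustained for
#' `sustain_days` consecutive days. The reported `time_to_steady` is the
#' first time the rate enters (and stays in) that band. Damage does not feed
#' back on adaptation, so the search integrates the bone volume fraction with
#' damage accumulation switched off and reports the quasi-steady damage
#' (where formation balances repair, `Df = Dr`) analytically at the located
#' state. Steady states at the `fBM -> 1` boundary (no interior balance of
#' formation and resorption) are flagged `type = "boundary"`; there the
#' remodelling surface vanishes, repair is lost, and no finite quasi-steady
#' damage exists (`D_quasi = Inf` when cycles are applied).
#'
#' @param loading a [loading_condition()].
#' @param params a [bone_params()] object.
#' @param fBM_guess starting bone volume fraction for the search.
#' @param horizon maximum integration time (days).
#' @param rate_tol steady-state rate criterion (1/day).
#' @param sustain_days days the criterion must hold.
#' @param output_step trace resolution (days).
#' @return A list with `fBM`, `D_quasi`, `time_to_steady` (days, `NA` if the
#'   criterion was not met within the horizon), `type`
#'   (`"interior"`, `"boundary"` or `"degenerate"`), and `converged`.
#' @export
steady_state <- function(loading, params = bone_params(), fBM_guess = 0.5,
                         horizon = 4000, rate_tol = 1e-7, sustain_days = 50,
                         output_step = 0.5) {
  probe <- vapply(c(0.2, 0.5, 0.8), function(f) {
    rate_bundle(f, 0, loading, params)$dfBM_dt
  }, numeric(1))
  if (all(abs(probe) < rate_tol)) {
    warning("formation and resorption balance at every probed fBM; ",
            "any bone volume fraction is stationary")
    return(list(fBM = fBM_guess, D_quasi = NA_real_, time_to_steady = 0,
                type = "degenerate", converged = TRUE))
  }
  quiet <- loading_condition(loading$sigma, loading$strain_rate, vn = 0)
  sim <- simulate_bone(constant_schedule(quiet, horizon),
                       bone_state(fBM_guess, 0), params,
                       output_step = output_step)
  rate <- sim$trace$dfBM_dt
  inside <- abs(rate) < rate_tol
  # first index from which the criterion holds for sustain_days
  n_sustain <- ceiling(sustain_days / output_step)
  run_end <- rev(cumsum(rev(!inside)))  # zero iff inside from here to end
  ok <- which(inside & run_end == 0)
  t_star <- NA_real_
  if (length(ok)) {
    first <- ok[1]
    if (sim$times[length(sim$times)] - sim$times[first] >= sustain_days) {
      t_star <- sim$times[first]
    }
  }
  converged <- !is.na(t_star)
  if (!converged) {
    warning("steady-state criterion not met within horizon; ",
            "returning the last state")
  }
  fBM_end <- sim$fBM[length(sim$fBM)]
  type <- if (fBM_end > 1 - 1e-6) "boundary" else "interior"
  rb <- rate_bundle(fBM_end, 0, loading, params)
  repair_coef <- (rb$AOBL + (params$Fs - 1) * rb$AOCL) *
    params$alpha * rb$Sv / fBM_end
  D_quasi <- if (loading$vn == 0) 0
             else if (repair_coef <= 0) Inf else rb$Df / repair_coef
  list(fBM = fBM_end, D_quasi = D_quasi, time_to_steady = t_star,
       type = type, converged = converged)
}

#' Time until accumulated damage reaches failure under constant loading
#'
#' Simulates the coupled model and reports the first day `D` reaches 1.
#' If instead the damage rate falls and stays below `plateau_tol` while
#' `D < 1` (repair balancing formation), the result is a plateau: the bone
#' does not fail under this loading. Plateau and horizon exhaustion are
#' distinguished in the returned status.
#'
#' @param loading a [loading_condition()].
#' @param initial a [bone_state()].
#' @param params a [bone_params()] object.
#' @param horizon maximum simulated time (days).
#' @param plateau_tol damage-rate threshold (1/day) below which damage is
#'   declared to have plateaued (checked sustained over `sustain_days`).
#' @param sustain_days window over which the plateau criterion must hold.
#' @param output_step trace resolution (days).
#' @return A list with `days` (failure day, or `NA`), `status` (`"failed"`,
#'   `"plateau"` or `"horizon"`), `D_final`, `fBM_final`.
#' @export
time_to_failure <- function(loading, initial = bone_state(0.9, 0),
                            params = bone_params(), horizon = 2000,
                            plateau_tol = 1e-3, sustain_days = 20,
                            output_step = 0.5) {
  stopifnot("horizon must be positive" = horizon > 0)
  if (initial[["D"]] >= 1) {
    return(list(days = 0, status = "failed",
                D_final = initial[["D"]], fBM_final = initial[["fBM"]]))
  }
  chunk <- min(horizon, 100)
  y <- bone_state(initial[["fBM"]], initial[["D"]])
  t0 <- 0
  while (t0 < horizon) {
    t1 <- min(t0 + chunk, horizon)
    sim <- simulate_bone(constant_schedule(loading, t1 - t0), y, params,
                         output_step = output_step)
    if (!is.na(sim$failure_day)) {
      return(list(days = t0 + sim$failure_day, status = "failed",
                  D_final = 1, fBM_final = sim$fBM[length(sim$fBM)]))
    }
    n <- length(sim$times)
    tail_idx <- which(sim$times >= sim$times[n] - sustain_days)
    if (max(sim$trace$dD_dt[tail_idx]) < plateau_tol) {
      return(list(days = NA_real_, status = "plateau",
                  D_final = sim$D[n], fBM_final = sim$fBM[n]))
    }
    y <- bone_state(min(sim$fBM[n], 1 - 1e-9), sim$D[n])
    t0 <- t1
  }
  list(days = NA_real_, status = "horizon",
       D_final = y[["D"]], fBM_final = y[["fBM"]])
}
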