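#' Workouts and training phases
#'
#' A workout is a speed (m/s) and a distance (m) performed either every day
#' (`per = "day"`) or spread over each week (`per = "week"`); slower
#' long-distance work is typically daily while fast gallops happen on set
#' days of the week. A training phase bundles workouts with a duration and a
#' kind (`rest`, `pre-training`, `progressive`, `race-fit`).
#'
#' @param speed speed (m/s), positive.
#' @param distance distance (m), non-negative.
#' @param per `"day"` or `"week"`: whether `distance` is covered per day or
#'   per week.
#' @return `workout()`: a list of class `workout`.
#' @export
workout <- function(speed, distance, per = c("day", "week")) {
  per <- match.arg(per)
  stopifnot("speed must be positive" = is.numeric(speed) && speed > 0,
            "distance must be non-negative" = is.numeric(distance) && distance >= 0)
  structure(list(speed = as.numeric(speed), distance = as.numeric(distance),
                 per = per), class = "workout")
}

#' @rdname workout
#' @param kind phase kind: `rest`, `pre-training`, `progressive`, `race-fit`.
#' @param duration phase duration (days), positive.
#' @param workouts list of [workout()] objects (empty for rest).
#' @param fast_speed speed (m/s) above which a workout counts as fast work;
#'   rest phases must not contain fast workouts.
#' @return `training_phase()`: a list of class `training_phase`.
#' @export
training_phase <- function(kind = c("rest", "pre-training", "progressive", "race-fit"),
                           duration, workouts = list(), fast_speed = 7.5) {
  kind <- match.arg(kind)
  stopifnot("duration must be positive" = is.numeric(duration) && duration > 0)
  if (length(workouts) && inherits(workouts, "workout")) workouts <- list(workouts)
  for (w in workouts) stopifnot(inherits(w, "workout"))
  if (kind == "rest" &&
      any(vapply(workouts, function(w) w$speed >= fast_speed, logical(1)))) {
    stop("rest phases must not contain fast workouts")
  }
  structure(list(kind = kind, duration = as.numeric(duration),
                 workouts = workouts), class = "training_phase")
}

#' Map training speed to joint loading
#'
#' Translates gait speed into the loading felt by the subchondral bone:
#' joint contact pressure `sigma` (MPa), strain rate (1/s) and stride length
#' (m). The default anchor table interpolates linearly between the printed
#' calibration points: the rest/walk proxy at 30 MPa, routine training at
#' 14.0 m/s mapping to 81.1 MPa and strain rate 0.2974 1/s, and the
#' race-fit/racing proxy at 90 MPa (taken at 16.0 m/s); the strain-rate and
#' pressure columns at other speeds continue those line segments. Stride
#' length is proportional to speed through the anchor 6.103 m at 14.0 m/s
#' (which makes 8000 m per 30 days at 14.0 m/s produce 43.7 cycles per day).
#' Speeds outside the anchor range are an error rather than extrapolated;
#' every entry can be overridden.
#'
#' @param anchors data.frame with columns `speed`, `sigma`, `strain_rate`.
#' @param stride_ref_speed,stride_ref_length the stride-length anchor.
#' @return An object of class `speed_load_map`.
#' @export
speed_load_map <- function(anchors = NULL,
                           stride_ref_speed = 14.0, stride_ref_length = 6.103) {
  if (is.null(anchors)) {
    # strain rate at 1.7 m/s is the rest back-calculation (psi = 0.31 at
    # fBM = 0.9); 16.0 m/s continues the 1.7 -> 14.0 line segment
    sr_rest <- rest_loading()$strain_rate
    sr16 <- 0.2974 + (0.2974 - sr_rest) / (14.0 - 1.7) * 2.0
    anchors <- data.frame(
      speed = c(1.7, 14.0, 16.0),
      sigma = c(30, 81.1, 90),
      strain_rate = c(sr_rest, 0.2974, sr16)
    )
  }
  anchors <- as.data.frame(anchors)[order(anchors$speed), ]
  stopifnot(
    "anchors need columns speed, sigma, strain_rate" =
      all(c("speed", "sigma", "strain_rate") %in% names(anchors)),
    "need at least two anchors" = nrow(anchors) >= 2,
    "sigma must be non-decreasing in speed" = !is.unsorted(anchors$sigma),
    "stride reference must be positive" =
      stride_ref_speed > 0 && stride_ref_length > 0
  )
  structure(list(anchors = anchors,
                 stride_ref_speed = stride_ref_speed,
                 stride_ref_length = stride_ref_length),
            class = "speed_load_map")
}

#' @rdname speed_load_map
#' @param map a `speed_load_map`.
#' @param speed speed (m/s), inside the anchor range (vectorized).
#' @return `map_speed()`: data.frame with `sigma` and `strain_rate`;
#'   `stride_length()`: stride length (m).
#' @export
map_speed <- function(map, speed) {
  rng <- range(map$anchors$speed)
  if (any(speed < rng[1] - 1e-9) || any(speed > rng[2] + 1e-9)) {
    stop(sprintf("speed outside the map's anchor range [%g, %g]; no extrapolation",
                 rng[1], rng[2]))
  }
  data.frame(
    sigma = stats::approx(map$anchors$speed, map$anchors$sigma, xout = speed,
                          rule = 2)$y,
    strain_rate = stats::approx(map$anchors$speed, map$anchors$strain_rate,
                                xout = speed, rule = 2)$y
  )
}

#' @rdname speed_load_map
#' @export
stride_length <- function(map, speed) {
  len <- map$stride_ref_length * speed / map$stride_ref_speed
  if (any(len <= 0)) stop("stride length must be positive; check the map")
  len
}

#' Loading cycles per day implied by a daily distance
#'
#' `cycles = distance_per_day / stride_length(speed)`: one stride is one
#' loading cycle on the joint.
#'
#' @param distance_per_day distance covered per day (m).
#' @param speed speed (m/s).
#' @param map a [speed_load_map()].
#' @return Cycles per day (1/day).
#' @examples
#' cycles_per_day(8000 / 30, 14.0)  # the printed 43.7 cycles/day anchor
#' @export
cycles_per_day <- function(distance_per_day, speed, map = speed_load_map()) {
  stopifnot("inputs must be non-negative" =
              all(distance_per_day >= 0) && all(speed > 0))
  distance_per_day / stride_length(map, speed)
}

# expand phases into one row per day per workout; a day carrying weekly
# (fast-work) workouts replaces that day's routine daily work rather than
# adding to it -- fast-work days and routine days alternate
.day_workouts <- function(phases, week_days = 3L) {
  day0 <- 0
  rows <- list()
  for (ph in phases) {
    nd <- ph$duration
    for (d in seq_len(nd)) {
      day <- day0 + d - 1  # day index, starting at 0
      wd <- ((d - 1) %% 7) + 1
      weekly_today <- wd %in% week_days &&
        any(vapply(ph$workouts, function(w)
          w$per == "week" && w$distance > 0, logical(1)))
      for (w in ph$workouts) {
        if (w$per == "day") {
          if (weekly_today) next
          dist <- w$distance
        } else {
          if (!weekly_today) next
          # weekly distance split equally across the scheduled weekdays
          dist <- w$distance / length(week_days)
        }
        if (dist <= 0) next
        rows[[length(rows) + 1]] <-
          data.frame(day = day, speed = w$speed, distance = dist,
                     kind = ph$kind)
      }
    }
    day0 <- day0 + nd
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(day = numeric(0), speed = numeric(0), distance = numeric(0),
               kind = character(0))
}

#' Build a loading schedule from a phased training programme
#'
#' Each simulated day receives one loading condition: its joint pressure and
#' strain rate come from the day's highest-speed (dominant) workout, while
#' the cycle count aggregates strides across all of the day's workouts.
#' Days without workouts (rest) use the rest loading condition. Weekly
#' workouts are spread equally over `week_days` (days of the week, 1--7),
#' and on those days they replace the phase's routine daily work: fast-work
#' days and routine days alternate rather than stack, so routine strides are
#' never billed at the fast workout's joint pressure.
#' Consecutive identical days are merged into single schedule segments.
#'
#' @param phases list of [training_phase()] objects, simulated in order.
#' @param map a [speed_load_map()].
#' @param params a [bone_params()] object (sets the rest strain rate).
#' @param week_days integer day(s) of the week on which weekly workouts run.
#' @return A list with `schedule` (a [loading_schedule()]) and
#'   `day_workouts` (data.frame: `day`, `speed`, `distance`, `kind`),
#'   the per-day workout log that damage attribution consumes.
#' @export
schedule_from_programme <- function(phases, map = speed_load_map(),
                                    params = bone_params(), week_days = 3L) {
  if (inherits(phases, "training_phase")) phases <- list(phases)
  for (ph in phases) stopifnot(inherits(ph, "training_phase"))
  dw <- .day_workouts(phases, week_days)
  total <- sum(vapply(phases, `[[`, numeric(1), "duration"))
  rest <- rest_loading(params)

  days <- data.frame(day = seq_len(total) - 1,
                     sigma = rest$sigma, strain_rate = rest$strain_rate,
                     vn = 0)
  if (nrow(dw)) {
    for (d in unique(dw$day)) {
      sub <- dw[dw$day == d, ]
      dom <- sub[which.max(sub$speed), ]
      ld <- map_speed(map, dom$speed)
      days$sigma[days$day == d] <- ld$sigma
      days$strain_rate[days$day == d] <- ld$strain_rate
      days$vn[days$day == d] <-
        sum(cycles_per_day(sub$distance, sub$speed, map))
    }
  }
  # merge runs of identical days into segments
  key <- paste(days$sigma, days$strain_rate, days$vn)
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  segs <- do.call(rbind, lapply(split(days, run), function(g) {
    data.frame(start_day = g$day[1], end_day = g$day[nrow(g)] + 1,
               sigma = g$sigma[1], strain_rate = g$strain_rate[1],
               vn = g$vn[1])
  }))
  rownames(segs) <- NULL
  list(schedule = loading_schedule(segs), day_workouts = dw)
}

#' Attribute simulated damage and distance to speed bins
#'
#' For each day of a simulated programme, the damage formed by each workout
#' is `vD(sigma_workout, E(t)) * cycles_workout`, evaluated with the
#' stiffness trace of the simulation (so adaptation during the programme
#' feeds into the per-cycle damage) and each workout's own joint pressure.
#' Damage and distance are summed into bins keyed by workout speed, with
#' daily and cumulative series.
#'
#' @param result a [simulate_bone()] result for the programme's schedule.
#' @param day_workouts the `day_workouts` data.frame from
#'   [schedule_from_programme()].
#' @param map the [speed_load_map()] used to build the schedule.
#' @param params the [bone_params()] used in the simulation.
#' @return A list of class `damage_attribution` with `daily` (long-format
#'   data.frame: `day`, `speed`, `distance`, `damage`, `cum_distance`,
#'   `cum_damage`) and `totals` (per-speed totals).
#' @export
attribute_damage <- function(result, day_workouts, map = speed_load_map(),
                             params = bone_params()) {
  stopifnot(inherits(result, "bone_simulation"))
  dw <- day_workouts
  if (nrow(dw) && max(dw$day) >= result$schedule$total_duration) {
    stop("day_workouts extends beyond the simulated schedule")
  }
  if (result$terminated_early && nrow(dw)) {
    # attribute only up to failure; the day of failure still counts
    dw <- dw[dw$day <= result$failure_day, , drop = FALSE]
  }
  if (!nrow(dw)) {
    return(structure(list(daily = data.frame(), totals = data.frame()),
                     class = "damage_attribution"))
  }
  # stiffness at each workout day from the simulation trace (fBM at day start)
  fBM_at <- stats::approx(result$times, result$fBM, xout = dw$day, rule = 2)$y
  ld <- map_speed(map, dw$speed)
  E <- tissue_stiffness(fBM_at, ld$strain_rate, params)
  cycles <- cycles_per_day(dw$distance, dw$speed, map)
  dw$damage <- damage_per_cycle(ld$sigma, E, params) * cycles

  daily <- stats::aggregate(cbind(distance, damage) ~ day + speed, data = dw, sum)
  daily <- daily[order(daily$speed, daily$day), ]
  daily$cum_distance <- stats::ave(daily$distance, daily$speed, FUN = cumsum)
  daily$cum_damage <- stats::ave(daily$damage, daily$speed, FUN = cumsum)
  rownames(daily) <- NULL
  totals <- stats::aggregate(cbind(distance, damage) ~ speed, data = dw, sum)
  structure(list(daily = daily, totals = totals), class = "damage_attribution")
}

#' Default demonstration training programme
#'
#' A reconstruction of a four-preparation Australian-style campaign: each
#' preparation is rest, then pre-training (trot), progressive training
#' (daily canter plus weekly gallops of increasing speed) and race-fit
#' training (daily canter plus weekly fast gallop/racing work). Durations
#' (44 + 28 + 61 + 61 days per preparation) make four preparations span 776
#' days with the final progressive/race-fit block at days 654--776. The
#' speeds and distances are plausible surveyed values, not a published
#' table; treat this as a demonstration fixture (it is also shipped as
#' `inst/extdata/default_programme.yaml`).
#'
#' @param n_preparations number of preparations to chain.
#' @return A list of [training_phase()] objects.
#' @export
default_programme <- function(n_preparations = 4) {
  one <- list(
    training_phase("rest", 44),
    training_phase("pre-training", 28, list(workout(4.0, 1500, "day"))),
    training_phase("progressive", 61, list(
      workout(7.5, 2000, "day"),
      workout(11.8, 500, "week"),
      workout(13.8, 500, "week")
    )),
    training_phase("race-fit", 61, list(
      workout(7.5, 2000, "day"),
      workout(13.8, 500, "week"),
      workout(16.0, 500, "week")
    ))
  )
  rep(one, n_preparations)
}
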