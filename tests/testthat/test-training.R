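p <- bone_params()
map <- speed_load_map()

test_that("the speed map reproduces the printed loading anchors exactly", {
  at14 <- map_speed(map, 14.0)
  expect_equal(at14$sigma, 81.1)
  expect_equal(at14$strain_rate, 0.2974)
  expect_equal(map_speed(map, 16.0)$sigma, 90)
  expect_equal(map_speed(map, 1.7)$sigma, 30)
  expect_error(map_speed(map, 20), "anchor range")
  expect_error(map_speed(map, 0.5), "anchor range")
  # sigma is non-decreasing in speed across the anchor range
  sp <- seq(1.7, 16, length.out = 40)
  expect_true(all(diff(map_speed(map, sp)$sigma) >= 0))
})

test_that("cycles per day reproduce the printed workload anchors", {
  # 8000 m per 30 days at 14 m/s -> 43.7 strides per day
  expect_equal(cycles_per_day(8000 / 30, 14.0, map), 43.7, tolerance = 1e-3)
  expect_equal(cycles_per_day(0, 14.0, map), 0)
  # a typical 1800 m/week gallop volume gives approximately 40 cycles per day
  approx40 <- cycles_per_day(1800 / 7, 13.8, map)
  expect_true(abs(approx40 - 40) / 40 < 0.15)
})

test_that("a rest phase maps to a single rest segment", {
  out <- schedule_from_programme(list(training_phase("rest", 10)), map, p)
  segs <- out$schedule$segments
  expect_equal(nrow(segs), 1)
  expect_equal(segs$end_day, 10)
  expect_equal(segs$sigma, 30)
  expect_equal(segs$vn, 0)
  expect_equal(nrow(out$day_workouts), 0)
})

test_that("a daily workout at the surveyed anchor yields the printed condition", {
  ph <- training_phase("race-fit", 15,
                       list(workout(14.0, 8000 / 30, "day")))
  out <- schedule_from_programme(list(ph), map, p)
  segs <- out$schedule$segments
  expect_equal(nrow(segs), 1)
  expect_equal(segs$sigma, 81.1)
  expect_equal(segs$strain_rate, 0.2974)
  expect_equal(segs$vn, 43.7, tolerance = 1e-3)
})

test_that("consecutive identical phases merge into one doubled phase", {
  ph <- training_phase("progressive", 12, list(workout(7.5, 2000, "day")))
  one <- schedule_from_programme(list(training_phase("progressive", 24,
                                                     list(workout(7.5, 2000, "day")))),
                                 map, p)
  two <- schedule_from_programme(list(ph, ph), map, p)
  expect_equal(one$schedule$segments, two$schedule$segments)
})

test_that("weekly workouts are spread onto the configured weekdays", {
  ph <- training_phase("race-fit", 14, list(workout(16.0, 1400, "week")))
  out <- schedule_from_programme(list(ph), map, p, week_days = c(2, 5))
  dw <- out$day_workouts
  expect_equal(nrow(dw), 4)            # 2 days/week x 2 weeks
  expect_equal(unique(dw$distance), 700)  # weekly distance split across days
  expect_equal(sum(dw$distance), 2 * 1400)
})

test_that("rest phases reject fast work and workouts validate domains", {
  expect_error(training_phase("rest", 10, list(workout(14, 1000))), "fast")
  expect_error(workout(-1, 100), "positive")
  expect_error(workout(10, -5), "non-negative")
})

test_that("damage attribution puts all damage in the only active speed bin", {
  ph <- training_phase("progressive", 20, list(workout(14.0, 300, "day")))
  out <- schedule_from_programme(list(ph), map, p)
  sim <- simulate_bone(out$schedule, bone_state(0.85, 0), p)
  att <- attribute_damage(sim, out$day_workouts, map, p)
  expect_equal(nrow(att$totals), 1)
  expect_equal(att$totals$speed, 14.0)
  expect_equal(att$totals$distance, 20 * 300)
  # cumulative series are non-decreasing and end at the totals
  expect_true(all(diff(att$daily$cum_damage) >= 0))
  expect_equal(max(att$daily$cum_damage), att$totals$damage)
})

test_that("attributed damage conserves the integrated formation rate", {
  ph <- training_phase("progressive", 30, list(workout(14.0, 400, "day")))
  out <- schedule_from_programme(list(ph), map, p)
  sim <- simulate_bone(out$schedule, bone_state(0.85, 0), p, output_step = 0.25)
  att <- attribute_damage(sim, out$day_workouts, map, p)
  tr <- sim$trace
  integral_Df <- sum(diff(tr$day) * (head(tr$Df, -1) + tail(tr$Df, -1)) / 2)
  expect_equal(sum(att$totals$damage), integral_Df, tolerance = 0.01)
})

test_that("per-cycle damage ratio between two speeds follows the fatigue law", {
  # two workouts on one day, at stresses 90 and 60 MPa, with the stiffness
  # pinned at the reference value via the initial bone volume fraction;
  # expected bin ratio is 10 * 10^((90-139)/14.1) : 100 * 10^((60-139)/14.1)
  # = 13.417 (frozen direct evaluation of the per-cycle law)
  sr <- 0.2974
  m2 <- speed_load_map(anchors = data.frame(
    speed = c(10, 12), sigma = c(60, 90), strain_rate = c(sr, sr)))
  fBM0 <- (p$Enom / (p$E0 * sr^p$gammaE))^(1 / 3)
  d10 <- 100 * stride_length(m2, 10)  # 100 cycles at 60 MPa
  d12 <- 10 * stride_length(m2, 12)   # 10 cycles at 90 MPa
  ph <- training_phase("race-fit", 1, list(workout(10, d10, "day"),
                                           workout(12, d12, "day")))
  out <- schedule_from_programme(list(ph), m2, p)
  sim <- simulate_bone(out$schedule, bone_state(fBM0, 0), p, output_step = 0.5)
  att <- attribute_damage(sim, out$day_workouts, m2, p)
  ratio <- att$totals$damage[att$totals$speed == 12] /
    att$totals$damage[att$totals$speed == 10]
  expect_equal(ratio, 13.417, tolerance = 1e-3)
})

test_that("removing fast work strictly reduces cumulative damage", {
  with_fast <- list(training_phase("race-fit", 28, list(
    workout(7.5, 2000, "day"), workout(16.0, 1800, "week"))))
  without_fast <- list(training_phase("progressive", 28, list(
    workout(7.5, 2000, "day"))))
  run <- function(phases) {
    out <- schedule_from_programme(phases, map, p)
    sim <- simulate_bone(out$schedule, bone_state(0.85, 0), p)
    sum(attribute_damage(sim, out$day_workouts, map, p)$totals$damage)
  }
  expect_gt(run(with_fast), run(without_fast))
})

test_that("the default programme builds a four-preparation schedule", {
  prog <- default_programme()
  expect_length(prog, 16)  # 4 phases x 4 preparations
  out <- schedule_from_programme(prog, map, p)
  expect_equal(out$schedule$total_duration, 776)
  # the final progressive block starts at day 654 (fourth preparation)
  expect_equal(3 * 194 + 44 + 28, 654)
})

test_that("programme configs load from YAML with unknown keys rejected", {
  path <- system.file("extdata", "default_programme.yaml", package = "equibone")
  prog <- read_programme_config(path)
  expect_length(prog, 4)
  expect_equal(prog[[1]]$kind, "rest")
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("phases:", "- kind: rest", "  duration_days: 10",
               "  surprise: 1"), bad)
  expect_error(read_programme_config(bad), "unknown phase key")
})
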