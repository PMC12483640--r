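p <- bone_params()

test_that("schedule construction validates contiguity and domains", {
  expect_error(loading_schedule(data.frame(start_day = 1, end_day = 5,
                                           sigma = 80, strain_rate = 0.3,
                                           vn = 40)),
               "start at day 0")
  expect_error(loading_schedule(data.frame(start_day = c(0, 6), end_day = c(5, 10),
                                           sigma = 80, strain_rate = 0.3,
                                           vn = 40)),
               "contiguous")
  expect_error(loading_schedule(data.frame(start_day = 0, end_day = 0,
                                           sigma = 80, strain_rate = 0.3,
                                           vn = 40)),
               "end_day > start_day")
  sch <- constant_schedule(training_loading(), 30)
  expect_equal(sch$total_duration, 30)
})

test_that("a zero-duration schedule returns the initial state", {
  sim <- simulate_bone(constant_schedule(training_loading(), 0),
                       bone_state(0.83, 0.21), p)
  expect_equal(length(sim$times), 1)
  expect_equal(unname(sim$fBM), 0.83)
  expect_equal(unname(sim$D), 0.21)
  expect_false(sim$terminated_early)
})

test_that("bone volume is constant at a formation/resorption fixed point", {
  sig_star <- balance_sigma(0.7, 0.15, p)
  ld <- loading_condition(sig_star, 0.15, 0)
  sim <- simulate_bone(constant_schedule(ld, 100), bone_state(0.7, 0), p)
  expect_true(all(abs(sim$fBM - 0.7) < 1e-6))
})

test_that("the adaptive solver matches a fine fixed-step Euler oracle", {
  ld <- loading_condition(90, 0.2974, 43.7)
  sim <- simulate_bone(constant_schedule(ld, 30), bone_state(0.9, 0), p)
  n <- length(sim$times)
  eo <- euler_oracle(ld, 0.9, 0, p, 30)
  expect_equal(unname(sim$fBM[n]), unname(eo[["fBM"]]), tolerance = 1e-4)
  expect_equal(unname(sim$D[n]), unname(eo[["D"]]), tolerance = 1e-4)
})

test_that("compiled and R right-hand sides produce the same trajectory", {
  ld <- loading_condition(85, 0.25, 50)
  s1 <- simulate_bone(constant_schedule(ld, 40), bone_state(0.8, 0.1), p)
  s2 <- simulate_bone(constant_schedule(ld, 40), bone_state(0.8, 0.1), p,
                      engine = "R")
  expect_equal(s1$fBM, s2$fBM, tolerance = 1e-8)
  expect_equal(s1$D, s2$D, tolerance = 1e-8)
})

test_that("inserting a break point inside a constant segment changes nothing", {
  ld <- training_loading()
  one <- simulate_bone(constant_schedule(ld, 30), bone_state(0.9, 0), p)
  two <- simulate_bone(loading_schedule(data.frame(
    start_day = c(0, 13.7), end_day = c(13.7, 30),
    sigma = ld$sigma, strain_rate = ld$strain_rate, vn = ld$vn)),
    bone_state(0.9, 0), p)
  n1 <- length(one$times); n2 <- length(two$times)
  expect_equal(one$fBM[n1], two$fBM[n2], tolerance = 1e-7)
  expect_equal(one$D[n1], two$D[n2], tolerance = 1e-7)
})

test_that("failure at D = 1 terminates the run and is sharply located", {
  sim <- simulate_bone(constant_schedule(race_loading(), 400),
                       bone_state(0.9, 0), p)
  expect_true(sim$terminated_early)
  expect_false(is.na(sim$failure_day))
  expect_equal(max(sim$D), 1, tolerance = 1e-6)
  expect_lt(sim$failure_day, 400)
  # the event time is consistent with the damage trace bracketing D = 1
  below <- sim$times[sim$D < 1]
  expect_lt(sim$failure_day - max(below), 1 + 0.1)
  # damage is non-decreasing on the way to failure (no repair exceeds formation)
  expect_true(all(diff(sim$D) > -1e-10))
})

test_that("without repair, damage is non-decreasing under any loading", {
  p_norep <- bone_params(Fs = 1, AOBL_min = 0, AOBL_max = 0)
  set.seed(21)
  for (i in 1:5) {
    d <- random_draw()
    sim <- simulate_bone(constant_schedule(d$loading, 25),
                         bone_state(0.8, 0.3), p_norep)
    expect_true(all(diff(sim$D) >= -1e-12))
  }
})

test_that("rest loading has an interior steady state near the balance root", {
  rl <- rest_loading(p)
  # independent oracle: root of (AOBL - AOCL) in fBM
  g <- function(f) rate_bundle(f, 0, rl, p)$dfBM_dt
  root <- uniroot(g, c(0.3, 0.9), tol = 1e-10)$root
  expect_equal(root, 0.549, tolerance = 0.005)  # frozen from root bracketing
  ss <- steady_state(rl, p, fBM_guess = 0.93, horizon = 2000)
  expect_true(ss$converged)
  expect_equal(ss$type, "interior")
  expect_equal(ss$fBM, root, tolerance = 0.01)
  expect_equal(ss$D_quasi, 0)  # no loading cycles at rest
})

test_that("race loading drives bone volume to the boundary, flagged as such", {
  ss <- steady_state(race_loading(), p, fBM_guess = 0.9, horizon = 3000)
  expect_equal(ss$type, "boundary")
  expect_gt(ss$fBM, 1 - 1e-6)
  # with the surface gone, repair cannot balance formation at any finite D
  expect_gt(ss$D_quasi, 1)
})

test_that("degenerate mechanoregulation is reported, not silently iterated", {
  p_deg <- bone_params(AOBL_min = 0.002, AOBL_max = 0.002,
                       AOCL_min = 0.002, AOCL_max = 0.002)
  expect_warning(ss <- steady_state(training_loading(), p_deg),
                 "stationary")
  expect_equal(ss$type, "degenerate")
})

test_that("time to failure distinguishes failure, plateau and no-damage cases", {
  # no cycles: no damage ever forms
  quiet <- loading_condition(90, 0.2974, 0)
  r0 <- time_to_failure(quiet, bone_state(0.9, 0), p, horizon = 200)
  expect_equal(r0$status, "plateau")
  expect_equal(r0$D_final, 0, tolerance = 1e-9)
  # already failed
  r1 <- time_to_failure(race_loading(), c(fBM = 0.9, D = 1), p)
  expect_equal(r1$days, 0)
  # race loading fails in finite time
  r2 <- time_to_failure(race_loading(), bone_state(0.9, 0), p)
  expect_equal(r2$status, "failed")
  expect_true(r2$days > 50 && r2$days < 200)
  # routine training: repair holds damage below failure
  r3 <- time_to_failure(training_loading(), bone_state(0.9, 0), p)
  expect_equal(r3$status, "plateau")
  expect_lt(r3$D_final, 1)
})
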