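p_fit <- bone_params()
p_pre <- bone_params("table2-initial")

test_that("specific surface follows the square-root law and vanishes at full density", {
  expect_equal(specific_surface(1, p_fit), 0)
  # frozen direct evaluations of a*sqrt(1-f)*(1-b*(1-f))
  expect_equal(specific_surface(0.9, p_fit), 3.618544, tolerance = 1e-6)
  expect_equal(specific_surface(0.5, p_fit), 8.155911, tolerance = 1e-6)
  expect_error(specific_surface(-0.1, p_fit), "0, 1")
  expect_error(specific_surface(1.2, p_fit), "0, 1")
  # positive on the open interval for the default a, b
  f <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(specific_surface(f, p_fit) > 0))
})

test_that("tissue stiffness reproduces the reference stiffness and is monotone", {
  # E0 * 0.9^3 * 0.36^0.06, the nominal stiffness of the fatigue experiments
  expect_equal(tissue_stiffness(0.9, 0.36, p_fit), 1714.1, tolerance = 1e-4)
  expect_equal(tissue_stiffness(1, 1, p_fit), p_fit$E0)
  expect_equal(tissue_stiffness(0.9, 0.2974, p_fit), 1694.603, tolerance = 1e-6)
  expect_error(tissue_stiffness(0.9, 0, p_fit), "positive")
  f <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(tissue_stiffness(f, 0.3, p_fit)) > 0))
  sr <- seq(0.05, 0.46, by = 0.05)
  expect_true(all(diff(tissue_stiffness(0.8, sr, p_fit)) > 0))
})

test_that("strain energy density matches the printed rest and race anchors", {
  expect_equal(strain_energy_density(90, 1714.138), 2.36, tolerance = 2e-3)
  expect_equal(strain_energy_density(0, 1500), 0)
  # E back-calculated so the rest anchor 0.31 is reproduced at 30 MPa
  expect_equal(strain_energy_density(30, 1451.613), 0.31, tolerance = 1e-6)
  expect_error(strain_energy_density(90, -1), "positive")
})

test_that("Hill activities respect bounds, half-saturation and monotonicity", {
  expect_equal(formation_activity(0, p_fit), p_fit$AOBL_min)
  expect_equal(formation_activity(p_fit$deltaB, p_fit),
               (p_fit$AOBL_min + p_fit$AOBL_max) / 2)
  expect_equal(formation_activity(2.36, p_fit), 0.0023385, tolerance = 1e-4)
  expect_equal(resorption_activity(0, p_fit), p_fit$AOCL_max)
  expect_equal(resorption_activity(p_fit$deltaC, p_fit),
               (p_fit$AOCL_min + p_fit$AOCL_max) / 2)

  psi <- c(0, 10^seq(-3, 2, length.out = 60))
  ab <- formation_activity(psi, p_fit)
  ac <- resorption_activity(psi, p_fit)
  expect_true(all(diff(ab) >= 0))
  expect_true(all(diff(ac) <= 0))
  expect_true(all(ab >= p_fit$AOBL_min & ab <= p_fit$AOBL_max))
  expect_true(all(ac >= p_fit$AOCL_min & ac <= p_fit$AOCL_max))
  # fractional sigmoidicity stays finite at psi = 0
  p_frac <- bone_params(gammaB = 0.5)
  expect_equal(formation_activity(0, p_frac), p_frac$AOBL_min)
})

test_that("resting bone resorbs about four times faster than training bone (pre-fit tuning)", {
  ratio <- resorption_activity(0.31, p_pre) / resorption_activity(2.36, p_pre)
  expect_equal(ratio, 4.01372, tolerance = 1e-5)
})

test_that("fatigue life follows the stiffness-adjusted power law", {
  expect_equal(fatigue_life(p_fit$sigma0, p_fit$Enom, p_fit), 1)
  expect_equal(fatigue_life(p_fit$sigma0 - p_fit$sigma1, p_fit$Enom, p_fit), 10)
  expect_equal(fatigue_life(90, 1694.6, p_fit), 2952.6, tolerance = 1e-4)
  sig <- seq(30, 100, by = 5)
  expect_true(all(diff(fatigue_life(sig, 1700, p_fit)) < 0))
})

test_that("damage per cycle is the exact reciprocal of fatigue life", {
  expect_equal(damage_per_cycle(p_fit$sigma0, p_fit$Enom, p_fit), 1)
  expect_equal(damage_per_cycle(90, 1694.6, p_fit), 3.387e-4, tolerance = 1e-3)
  set.seed(11)
  for (i in 1:50) {
    s <- runif(1, 0, 110)
    E <- runif(1, 500, 3000)
    expect_equal(damage_per_cycle(s, E, p_fit) * fatigue_life(s, E, p_fit), 1)
  }
})

test_that("damage formation rate is the per-cycle damage times daily cycles", {
  expect_equal(damage_formation_rate(3.387e-4, 0), 0)
  expect_equal(damage_formation_rate(3.387e-4, 43.7), 0.014801, tolerance = 1e-4)
  expect_equal(damage_formation_rate(1, 1), 1)
  expect_error(damage_formation_rate(-1, 1), "non-negative")
})

test_that("damage repair is remodelling-coupled, targeted, and linear in damage", {
  expect_equal(damage_repair_rate(0.002, 0.001, 3.6, 0.9, 0, p_fit), 0)
  # untargeted resorption with no formation repairs nothing
  p1 <- bone_params(Fs = 1)
  expect_equal(damage_repair_rate(0, 0.005, 3.6, 0.9, 0.7, p1), 0)
  expect_equal(damage_repair_rate(0.002350, 0.001384, 3.6185, 0.9, 0.5, p_fit),
               0.0030121, tolerance = 1e-4)
  expect_error(damage_repair_rate(0.002, 0.001, 3.6, 0, 0.5, p_fit), "positive")
  # exact linearity in D
  set.seed(12)
  for (i in 1:20) {
    ab <- runif(1, 0, 0.01); ac <- runif(1, 0, 0.01)
    Sv <- runif(1, 0.5, 8); f <- runif(1, 0.3, 0.99); D <- runif(1, 0, 1)
    base <- damage_repair_rate(ab, ac, Sv, f, D, p_fit)
    expect_equal(damage_repair_rate(ab, ac, Sv, f, 3 * D, p_fit), 3 * base)
  }
})

test_that("the full right-hand side composes the laws and reports intermediates", {
  ld <- loading_condition(90, 0.2974, 43.7)
  rb <- model_rhs(0, bone_state(0.9, 0), ld, p_fit)
  expect_equal(rb$dD_dt, 0.014800, tolerance = 1e-4)
  expect_equal(rb$dfBM_dt, 6.641e-4, tolerance = 1e-4)
  expect_equal(rb$E, 1694.603, tolerance = 1e-6)
  expect_equal(rb$Dr, 0)  # no damage yet
  expect_named(rb, c("Sv", "E", "psi", "AOBL", "AOCL", "Nf_adj", "vD",
                     "Df", "Dr", "dfBM_dt", "dD_dt"))
  # intermediates are mutually consistent
  expect_equal(rb$vD * rb$Nf_adj, 1)
  expect_equal(rb$Df, rb$vD * ld$vn)
  expect_equal(rb$dD_dt, rb$Df - rb$Dr)

  # fully dense bone: no surface, no remodelling, no repair
  rb1 <- model_rhs(0, c(fBM = 1, D = 0.5), ld, p_fit)
  expect_equal(rb1$Sv, 0)
  expect_equal(rb1$dfBM_dt, 0)
  expect_equal(rb1$Dr, 0)

  # at the formation/resorption balance point the bone volume is stationary
  sig_star <- balance_sigma(0.7, 0.15, p_fit)
  rb2 <- model_rhs(0, bone_state(0.7, 0),
                   loading_condition(sig_star, 0.15, 0), p_fit)
  expect_equal(rb2$dfBM_dt, 0, tolerance = 1e-12)
})
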