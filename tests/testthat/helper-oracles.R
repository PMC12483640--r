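# Independent oracles used across the suite. The Euler integrator writes the
# model algebra out inline (it shares no code with the package's right-hand
# sides), so trajectory comparisons are a genuine dual-route check.

euler_oracle <- function(loading, fBM0, D0, p, days, step = 1e-3) {
  f <- fBM0
  D <- D0
  srf <- p$E0 * loading$strain_rate^p$gammaE
  for (i in seq_len(round(days / step))) {
    fc <- min(max(f, 1e-9), 1 - 1e-9)
    Sv <- p$a * sqrt(1 - fc) * (1 - p$b * (1 - fc))
    E <- srf * fc^3
    psi <- loading$sigma^2 / (2 * E)
    AOBL <- p$AOBL_min + (p$AOBL_max - p$AOBL_min) *
      psi^p$gammaB / (p$deltaB^p$gammaB + psi^p$gammaB)
    AOCL <- p$AOCL_min + (p$AOCL_max - p$AOCL_min) *
      p$deltaC^p$gammaC / (p$deltaC^p$gammaC + psi^p$gammaC)
    vD <- 10^((loading$sigma - p$sigma0) / p$sigma1) * p$Enom / E
    Dr <- (AOBL + (p$Fs - 1) * AOCL) * p$alpha * Sv * D / fc
    f <- f + step * (AOBL - AOCL) * p$alpha * Sv
    D <- D + step * (vD * loading$vn - Dr)
  }
  c(fBM = f, D = D)
}

# random but physiologically sensible parameter/loading draws
random_draw <- function() {
  p <- bone_params(
    AOBL_max = runif(1, 0.004, 0.009),
    AOCL_max = runif(1, 0.002, 0.0054),
    sigma0 = runif(1, 130, 150),
    Fs = runif(1, 1, 10),
    alpha = runif(1, 0.1, 0.28)
  )
  ld <- loading_condition(sigma = runif(1, 40, 95),
                          strain_rate = runif(1, 0.05, 0.46),
                          vn = runif(1, 0, 60))
  list(params = p, loading = ld)
}

# sigma at which formation balances resorption for a given state (fixed point)
balance_sigma <- function(fBM, strain_rate, p) {
  g <- function(sigma) {
    ld <- loading_condition(sigma, strain_rate, 0)
    rate_bundle(fBM, 0, ld, p)$dfBM_dt
  }
  uniroot(g, c(20, 110), tol = 1e-12)$root
}
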