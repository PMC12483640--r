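#' Sensitivity-analysis ranges for all model parameters
#'
#' The sampling ranges for the 20 model and loading parameters, plus a
#' `dummy` parameter with no effect on the model, included to flag spurious
#' correlations. The loading variables (`sigma`, `strain_rate`, `vn`) are
#' sampled exactly like the intrinsic parameters.
#'
#' @param dummy include the inert dummy parameter.
#' @return A data.frame with columns `parameter`, `low`, `high`.
#' @export
param_ranges <- function(dummy = TRUE) {
  r <- data.frame(
    parameter = c("sigma", "strain_rate", "vn", "alpha", "a", "b", "E0",
                  "gammaE", "AOBL_min", "AOBL_max", "deltaB", "gammaB",
                  "AOCL_min", "AOCL_max", "deltaC", "gammaC", "sigma0",
                  "sigma1", "Enom", "Fs"),
    low  = c(30.0, 0.05, 25.0, 0.095, 5.71, -0.2, 1250.0, 0.03, 0.0,
             0.00301, 3.5, 1.0, 0.0, 0.0018, 0.5, 1.0, 125.1, 12.69,
             857.0, 1.0),
    high = c(102.0, 0.46, 120.0, 0.285, 17.13, 0.2, 3750.0, 0.09, 0.00301,
             0.00904, 10.5, 5.0, 0.0018, 0.0054, 1.5, 5.0, 152.9, 15.51,
             2571.2, 10.0)
  )
  if (dummy) r <- rbind(r, data.frame(parameter = "dummy", low = 0, high = 1))
  r
}

#' Latin hypercube sample over parameter ranges
#'
#' Stratified uniform sampling: each of the `n` rows occupies one
#' equal-probability stratum per dimension, then the unit hypercube is
#' rescaled to the ranges. Reproducible by seed.
#'
#' @param ranges data.frame as from [param_ranges()].
#' @param n number of samples (recommended at least 10 per dimension).
#' @param seed integer seed.
#' @return An `n x d` numeric matrix with parameter names as columns.
#' @export
lhs_sample <- function(ranges, n, seed = 1) {
  stopifnot("ranges must have low < high" = all(ranges$low < ranges$high),
            n >= 1)
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  m <- sweep(sweep(u, 2, ranges$high - ranges$low, `*`), 2, ranges$low, `+`)
  colnames(m) <- ranges$parameter
  m
}

# build params + loading from one sample row (dummy ignored)
.row_to_inputs <- function(row) {
  nm <- names(row)
  model_nm <- setdiff(nm, c("sigma", "strain_rate", "vn", "dummy"))
  params <- bone_params()
  params[model_nm] <- as.list(unname(row[model_nm]))
  # sampled bounds may invert the preset ordering of min/max; keep the wider
  if (params$AOBL_max < params$AOBL_min) params$AOBL_max <- params$AOBL_min
  if (params$AOCL_max < params$AOCL_min) params$AOCL_max <- params$AOCL_min
  list(params = params,
       loading = loading_condition(row[["sigma"]], row[["strain_rate"]],
                                   row[["vn"]]))
}

#' Evaluate the model at a batch of sampled parameter sets
#'
#' Simulates the coupled model for each row under constant loading built
#' from the row's `sigma`, `strain_rate` and `vn`, from a common initial
#' state, and records bone volume fraction and damage at the evaluation
#' time. Rows whose simulation fails (damage reaches 1 early) report
#' `D = 1` and the bone volume fraction at the stopping time; rows whose
#' solver errors are flagged and carry `NA`.
#'
#' @param samples matrix from [lhs_sample()] (columns named).
#' @param evaluation_time days at which outputs are read (default 70 days,
#'   i.e. 10 weeks).
#' @param initial initial [bone_state()]; the sensitivity analyses use
#'   unadapted bone `fBM = 0.7`, `D = 0`.
#' @param output_step trace resolution passed to the simulator.
#' @return data.frame with columns `fBM`, `D`, `failed`, `error`.
#' @export
evaluate_batch <- function(samples, evaluation_time = 70,
                           initial = bone_state(0.7, 0), output_step = 70) {
  stopifnot("evaluation_time must be positive" = evaluation_time > 0)
  out <- data.frame(fBM = rep(NA_real_, nrow(samples)), D = NA_real_,
                    failed = FALSE, error = FALSE)
  for (i in seq_len(nrow(samples))) {
    inp <- .row_to_inputs(samples[i, ])
    sim <- tryCatch(
      simulate_bone(constant_schedule(inp$loading, evaluation_time),
                    bone_state(initial[["fBM"]], initial[["D"]]),
                    inp$params, output_step = output_step),
      error = function(e) NULL)
    if (is.null(sim)) {
      out$error[i] <- TRUE
      next
    }
    n <- length(sim$times)
    out$fBM[i] <- sim$fBM[n]
    out$D[i] <- if (sim$terminated_early) 1 else sim$D[n]
    out$failed[i] <- sim$terminated_early
  }
  out
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every column (ties get average ranks), then computes for
#' each parameter the correlation between the residuals of its ranks and of
#' the output ranks after linearly regressing both on the ranks of all other
#' parameters (the linear-residual partial correlation on ranks).
#'
#' @param samples matrix of sampled parameters (columns named).
#' @param output numeric vector of model outputs (one per row).
#' @return data.frame with columns `parameter` and `prcc`, in column order
#'   of `samples`.
#' @export
prcc <- function(samples, output) {
  stopifnot(nrow(samples) == length(output))
  if (any(apply(samples, 2, function(x) length(unique(x))) < 2)) {
    stop("constant parameter column: PRCC undefined")
  }
  if (length(unique(output)) < 2) stop("constant output: PRCC undefined")
  R <- apply(samples, 2, rank)
  ry <- rank(output)
  d <- ncol(R)
  est <- vapply(seq_len(d), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, R[, j])$residuals
    rr <- stats::lm.fit(Z, ry)$residuals
    if (stats::sd(rx) == 0 || stats::sd(rr) == 0) return(0)
    stats::cor(rx, rr)
  }, numeric(1))
  data.frame(parameter = colnames(samples), prcc = est)
}

#' PRCC sensitivity analysis of the bone model
#'
#' Latin-hypercube sampling over [param_ranges()] followed by [prcc()] of
#' both outputs (bone volume fraction and damage at the evaluation time).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param evaluation_time days (default 70 = 10 weeks).
#' @param initial initial state (default unadapted bone, `fBM = 0.7`).
#' @param ranges sampling ranges.
#' @return A list of class `prcc_result`: `estimates` (data.frame:
#'   `parameter`, `output`, `prcc`), `outputs`, `samples`, `n`, `seed`,
#'   `evaluation_time`.
#' @export
prcc_analysis <- function(n = 1000, seed = 1, evaluation_time = 70,
                          initial = bone_state(0.7, 0),
                          ranges = param_ranges()) {
  samples <- lhs_sample(ranges, n, seed)
  outs <- evaluate_batch(samples, evaluation_time, initial)
  keep <- !outs$error
  est <- rbind(
    cbind(prcc(samples[keep, , drop = FALSE], outs$fBM[keep]), output = "fBM"),
    cbind(prcc(samples[keep, , drop = FALSE], outs$D[keep]), output = "D")
  )
  structure(list(estimates = est[, c("parameter", "output", "prcc")],
                 outputs = outs, samples = samples, n = n, seed = seed,
                 evaluation_time = evaluation_time),
            class = "prcc_result")
}

#' Sobol variance-based sensitivity indices (Saltelli sampling)
#'
#' First-order, pairwise second-order and total-order Sobol indices by the
#' Saltelli scheme: two base matrices `A` and `B` (Latin-hypercube sampled),
#' plus cross matrices `AB_i` (`A` with column `i` from `B`) and `BA_i`,
#' giving `n_base * (2d + 2)` model evaluations. Estimators: first order
#' `mean(B * (AB_i - A)) / V`; total order `mean((A - AB_i)^2) / (2 V)`;
#' closed second order `mean(BA_i * AB_j) - mean(A) * mean(B)` divided by
#' `V`, minus the two first-order indices. Percentile bootstrap confidence
#' intervals resample base rows jointly across all matrices. Small negative
#' estimates are estimator noise and are reported as-is.
#'
#' @param fun vectorized-by-row evaluator: takes a sample matrix, returns a
#'   numeric vector of outputs. Defaults to the model's damage at
#'   `evaluation_time`.
#' @param ranges sampling ranges (default [param_ranges()]).
#' @param n_base base sample size (at least 128 recommended).
#' @param seed integer seed.
#' @param n_boot bootstrap replicates for confidence intervals.
#' @param conf confidence level.
#' @param evaluation_time,initial passed to the default evaluator.
#' @param output which model output the default evaluator returns.
#' @return A list of class `sobol_result`: `first` and `total` (data.frames
#'   with estimate and CI), `second` (pairwise data.frame), `variance`,
#'   `n_base`, `seed`.
#' @export
sobol_indices <- function(fun = NULL, ranges = param_ranges(), n_base = 512,
                          seed = 1, n_boot = 200, conf = 0.95,
                          evaluation_time = 70, initial = bone_state(0.7, 0),
                          output = c("D", "fBM")) {
  output <- match.arg(output)
  if (is.null(fun)) {
    fun <- function(m) evaluate_batch(m, evaluation_time, initial)[[output]]
  }
  d <- nrow(ranges)
  set.seed(seed)
  A <- lhs_sample(ranges, n_base, seed = seed)
  B <- lhs_sample(ranges, n_base, seed = seed + 1000003L)
  yA <- fun(A)
  yB <- fun(B)
  yAB <- matrix(NA_real_, n_base, d)
  yBA <- matrix(NA_real_, n_base, d)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    BAi <- B; BAi[, i] <- A[, i]
    yAB[, i] <- fun(ABi)
    yBA[, i] <- fun(BAi)
  }

  est_all <- function(idx) {
    a <- yA[idx]; b <- yB[idx]
    V <- stats::var(c(a, b))
    S1 <- colMeans(b * (yAB[idx, , drop = FALSE] - a)) / V
    ST <- colMeans((a - yAB[idx, , drop = FALSE])^2) / (2 * V)
    pairs <- utils::combn(d, 2)
    S2 <- apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      Vij <- mean(yBA[idx, i] * yAB[idx, j]) - mean(a) * mean(b)
      Vij / V - S1[i] - S1[j]
    })
    list(S1 = S1, ST = ST, S2 = S2, V = V, pairs = pairs)
  }

  pt <- est_all(seq_len(n_base))
  boot_S1 <- matrix(NA_real_, n_boot, d)
  boot_ST <- matrix(NA_real_, n_boot, d)
  boot_S2 <- matrix(NA_real_, n_boot, ncol(pt$pairs))
  for (bi in seq_len(n_boot)) {
    idx <- sample.int(n_base, n_base, replace = TRUE)
    e <- est_all(idx)
    boot_S1[bi, ] <- e$S1
    boot_ST[bi, ] <- e$ST
    boot_S2[bi, ] <- e$S2
  }
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- function(m) t(apply(m, 2, stats::quantile, probs = qs, na.rm = TRUE))
  ci1 <- ci(boot_S1); cit <- ci(boot_ST); ci2 <- ci(boot_S2)

  pnames <- ranges$parameter
  first <- data.frame(parameter = pnames, estimate = unname(pt$S1),
                      ci_low = ci1[, 1], ci_high = ci1[, 2])
  total <- data.frame(parameter = pnames, estimate = unname(pt$ST),
                      ci_low = cit[, 1], ci_high = cit[, 2])
  second <- data.frame(parameter_i = pnames[pt$pairs[1, ]],
                       parameter_j = pnames[pt$pairs[2, ]],
                       estimate = unname(pt$S2),
                       ci_low = ci2[, 1], ci_high = ci2[, 2])
  rownames(first) <- rownames(total) <- rownames(second) <- NULL
  structure(list(first = first, total = total, second = second,
                 variance = pt$V, n_base = n_base, seed = seed,
                 n_evaluations = n_base * (2 * d + 2)),
            class = "sobol_result")
}
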