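noiseless_set <- function(...) {
  simulate_traces(trace_sim_spec(n_rois = 1, noise_sd = 0, seed = 1, ...))
}

test_that("ratio computation subtracts background and masks bad points", {
  ts <- noiseless_set(bleach_rate = 0, treatment_effect = 0,
                      ph_coupling = 0)
  rr <- compute_ratio(ts)
  expect_equal(rr$ratio, rep(1, nrow(rr)), tolerance = 1e-12)

  # equal channels after subtraction give ratio one
  d <- ts$data
  d$f488 <- d$f405 - 50 + 60  # signal equal in both channels
  rr2 <- compute_ratio(as_ratio_trace_set(d, ts$events))
  expect_equal(rr2$ratio, rep(1, nrow(rr2)), tolerance = 1e-12)

  # denominator at background level: masked with a warning
  d3 <- ts$data
  bad <- !d3$is_background & d3$time_s < 10
  d3$f405[bad] <- 50
  expect_warning(rr3 <- compute_ratio(as_ratio_trace_set(d3, ts$events)),
                 "masked")
  expect_true(all(is.na(rr3$ratio[rr3$time_s < 10])))
  d4 <- ts$data
  d4$f405[!d4$is_background] <- 50
  expect_error(compute_ratio(as_ratio_trace_set(d4, ts$events)),
               "background")
})

test_that("noiseless generator ratio is recovered exactly end to end", {
  ts <- simulate_traces(trace_sim_spec(n_rois = 1, noise_sd = 0,
                                       bleach_rate = 1e-3,
                                       treatment_effect = -0.15,
                                       ph_coupling = 0.4, seed = 2))
  truth <- attr(ts, "truth")
  rr <- compute_ratio(ts)
  expected <- (1 + truth$deflect + 0.4 * truth$pulse) * truth$envelope
  expect_equal(rr$ratio, expected, tolerance = 1e-12)
})

test_that("baseline normalization recovers the premix exponential", {
  t <- seq(0, 600, by = 2)
  r <- 2 * exp(-0.001 * t)
  tr <- normalize_to_baseline(data.frame(time_s = t, ratio = r),
                              premix_end = 120)
  expect_equal(tr$baseline_fit$k, 0.001, tolerance = 1e-6)
  expect_equal(tr$baseline_fit$A, 2, tolerance = 1e-6)
  expect_equal(tr$data$ratio, rep(1, length(t)), tolerance = 1e-9)

  # constant premix: divide by the constant
  trc <- normalize_to_baseline(data.frame(time_s = t, ratio = rep(3, length(t))),
                               premix_end = 120)
  expect_equal(trc$data$ratio, rep(1, length(t)), tolerance = 1e-12)
  expect_equal(trc$premix_mean, 1, tolerance = 1e-9)

  # idempotence
  tr2 <- normalize_to_baseline(tr$data, premix_end = 120)
  expect_equal(tr2$data$ratio, tr$data$ratio, tolerance = 1e-9)
  expect_error(normalize_to_baseline(
    data.frame(time_s = 1:3, ratio = rep(1, 3)), premix_end = 120),
    "premix")
})

test_that("pH calibration recovers the coupling slope", {
  ts <- noiseless_set(bleach_rate = 0, treatment_effect = 0,
                      ph_coupling = 0.5)
  rr <- compute_ratio(ts)
  tr <- normalize_to_baseline(rr, premix_end = 120)
  cal <- calibrate_ph(tr, c(600, 720))
  expect_equal(cal$slope, 0.5, tolerance = 1e-9)
  expect_gt(cal$r_squared, 1 - 1e-9)

  # flat pHrodo: zero-variance guard
  flat <- tr
  flat$data$phrodo <- 1
  expect_error(calibrate_ph(flat, c(600, 720)), "zero variance")

  # noisy case: pooled slope within 10% over 50 ROIs
  tsn <- simulate_traces(trace_sim_spec(n_rois = 50, noise_sd = 0.01,
                                        bleach_rate = 0,
                                        treatment_effect = 0,
                                        ph_coupling = 0.5, seed = 3))
  rrn <- compute_ratio(tsn)
  norm <- lapply(split(rrn, rrn$roi), normalize_to_baseline,
                 premix_end = 120)
  caln <- calibrate_ph(norm, c(600, 720), scope = "pooled")
  expect_equal(caln$slope, 0.5, tolerance = 0.1)
})

test_that("pH correction flattens a pure pH artifact", {
  ts <- noiseless_set(bleach_rate = 0, treatment_effect = 0,
                      ph_coupling = 0.5)
  rr <- compute_ratio(ts)
  tr <- normalize_to_baseline(rr, premix_end = 120)
  cal <- calibrate_ph(tr, c(600, 720))
  corr <- ph_correct(tr, cal)
  expect_equal(corr$data$ratio, rep(1, nrow(corr$data)), tolerance = 1e-9)

  # zero slope is the identity
  cal0 <- cal; cal0$slope <- 0
  expect_equal(ph_correct(tr, cal0)$data$ratio, tr$data$ratio)

  # noisy case: NH4Cl-window RMS deviation drops by >= 90%
  tsn <- simulate_traces(trace_sim_spec(n_rois = 20, noise_sd = 0.005,
                                        bleach_rate = 0,
                                        treatment_effect = 0,
                                        ph_coupling = 0.5, seed = 4))
  rrn <- compute_ratio(tsn)
  rms <- vapply(split(rrn, rrn$roi), function(sub) {
    tr <- normalize_to_baseline(sub, premix_end = 120)
    cal <- calibrate_ph(tr, c(600, 720))
    corr <- ph_correct(tr, cal)
    win <- sub$time_s >= 600 & sub$time_s <= 720
    c(before = sqrt(mean((tr$data$ratio[win] - 1)^2)),
      after = sqrt(mean((corr$data$ratio[win] - 1)^2)))
  }, numeric(2))
  expect_gt(1 - mean(rms["after", ]) / mean(rms["before", ]), 0.90)
})

test_that("counterfactual baseline extrapolates level and trend", {
  # flat noiseless baseline: prediction 1, band essentially zero width
  t <- seq(0, 480, by = 2)
  tr <- normalize_to_baseline(data.frame(time_s = t, ratio = rep(1, length(t))),
                              premix_end = 120)
  bl <- counterfactual_baseline(tr, 120)
  expect_equal(bl$fit, rep(1, nrow(bl)), tolerance = 1e-6)
  expect_lt(max(bl$upr - bl$lwr), 1e-4)

  # OLS mode continues a linear drift exactly
  drift <- 1 + 0.0005 * t
  trd <- structure(list(data = data.frame(time_s = t, ratio = drift,
                                          phrodo = 1),
                        baseline_fit = list(A = 1, k = 0,
                                            constant_fallback = FALSE),
                        premix_end = 120, premix_mean = 1,
                        ph_corrected = FALSE),
                   class = "corrected_trace")
  bld <- counterfactual_baseline(trd, 120, method = "ols")
  expect_equal(bld$fit, drift[t >= 120], tolerance = 1e-9)
  expect_error(counterfactual_baseline(
    structure(list(data = data.frame(time_s = 1:5, ratio = rep(1, 5),
                                     phrodo = 1)),
              class = "corrected_trace"), 120), "pre-treatment")
})

test_that("the 95% counterfactual band covers a no-effect future", {
  cover <- withr::with_seed(5, replicate(100, {
    t <- seq(0, 360, by = 3)
    y <- 1 + cumsum(rnorm(length(t), 0, 1e-4)) + rnorm(length(t), 0, 0.01)
    tr <- structure(list(data = data.frame(time_s = t, ratio = y,
                                           phrodo = 1),
                         baseline_fit = list(A = 1, k = 0,
                                             constant_fallback = FALSE),
                         premix_end = 180, premix_mean = 1,
                         ph_corrected = FALSE),
                    class = "corrected_trace")
    bl <- counterfactual_baseline(tr, 180)
    post <- tr$data[tr$data$time_s >= 180, ]
    mean(post$ratio >= bl$lwr & post$ratio <= bl$upr)
  }))
  expect_gte(mean(cover), 0.90)
})

test_that("integrated change matches analytic and quadrature oracles", {
  t <- seq(0, 480, by = 0.01)
  flat_baseline <- data.frame(time_s = t[t >= 120], fit = 1, lwr = 1,
                              upr = 1)
  mk_trace <- function(y) {
    structure(list(data = data.frame(time_s = t, ratio = y, phrodo = 1),
                   baseline_fit = list(A = 1, k = 0,
                                       constant_fallback = FALSE),
                   premix_end = 120, premix_mean = 1,
                   ph_corrected = TRUE),
              class = "corrected_trace")
  }
  # trace equal to baseline: zero
  ic0 <- integrated_change(mk_trace(rep(1, length(t))), flat_baseline,
                           120, 480)
  expect_equal(ic0$value, 0, tolerance = 1e-12)

  # step deflection of -0.2 across the whole window
  step <- ifelse(t >= 120 & t <= 480, 0.8, 1)
  ic1 <- integrated_change(mk_trace(step), flat_baseline, 120, 480)
  expect_equal(ic1$value, -0.2, tolerance = 1e-6)

  # smooth deflection against dense numerical integration
  w <- 2 * pi / 360
  y <- 1 + 0.1 * sin(w * (t - 120)) * (t >= 120)
  ic2 <- integrated_change(mk_trace(y), flat_baseline, 120, 480)
  oracle <- stats::integrate(function(x) 0.1 * sin(w * (x - 120)),
                             120, 480, rel.tol = 1e-12)$value / 360
  expect_equal(ic2$value, oracle, tolerance = 1e-6)
  expect_error(integrated_change(mk_trace(y), flat_baseline, 480, 120),
               "washout")
})

test_that("known treatment effects are recovered with artifacts active", {
  ts <- simulate_traces(trace_sim_spec(n_rois = 50, noise_sd = 0,
                                       bleach_rate = 5e-4,
                                       treatment_effect = -0.2,
                                       ph_coupling = 0.5, seed = 6))
  res <- process_trace_set(ts)
  expect_equal(nrow(res), 50)
  expect_true(all(abs(res$integrated_change - (-0.2)) / 0.2 < 0.10))
})

test_that("artifact-free traces give integrated change near zero", {
  ts <- simulate_traces(trace_sim_spec(n_rois = 20, noise_sd = 0.005,
                                       bleach_rate = 0,
                                       treatment_effect = 0,
                                       ph_coupling = 0.5, seed = 7))
  res <- process_trace_set(ts)
  se <- sd(res$integrated_change) / sqrt(nrow(res))
  expect_lt(abs(mean(res$integrated_change)), 3 * se + 0.003)
})

test_that("corrected traces are invariant to intensity rescaling", {
  ts <- simulate_traces(trace_sim_spec(n_rois = 3, noise_sd = 0.005,
                                       bleach_rate = 5e-4,
                                       treatment_effect = -0.1,
                                       ph_coupling = 0.5, seed = 8))
  res1 <- process_trace_set(ts)
  scaled <- ts
  scaled$data$f405 <- ts$data$f405 * 7.3
  scaled$data$f488 <- ts$data$f488 * 7.3
  res2 <- process_trace_set(scaled)
  # the corrected ratio itself is scale-free ...
  r1 <- compute_ratio(ts); r2 <- compute_ratio(scaled)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-9)
  # ... and the summary statistic follows, up to state-space optimizer
  # float noise in the counterfactual step
  expect_equal(res2$integrated_change, res1$integrated_change,
               tolerance = 1e-6)
})

test_that("group comparison matches a brute-force Mann-Whitney count", {
  x <- c(1.2, 3.1, 0.4, 2.2, 5.0)
  y <- c(0.9, 2.8, 1.1, 0.2, 4.1)
  res <- compare_groups(c(x, y), rep(c("a", "b"), each = 5))
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(res$tests$U, u_brute)

  # identical samples: U = n^2/2, p ~ 1
  z <- c(x, x)
  res2 <- compare_groups(z, rep(c("a", "b"), each = 5))
  expect_equal(res2$tests$U, 12.5)
  expect_gt(res2$tests$p, 0.9)
  expect_error(compare_groups(1:4, c("a", "a", "b", "b")), "at least 3")

  # power: 1 SD shift at n = 60/group detected in almost all replicates
  rej <- withr::with_seed(9, replicate(60, {
    v <- c(rnorm(60), rnorm(60, 1))
    compare_groups(v, rep(c("a", "b"), each = 60))$tests$p < 0.05
  }))
  expect_gte(mean(rej), 0.95)

  # median CIs bracket the medians
  expect_true(all(res$summary$ci_lower <= res$summary$median &
                    res$summary$median <= res$summary$ci_upper))
})
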