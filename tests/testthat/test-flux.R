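test_that("phase labelling follows the injection sequence", {
  raw <- data.frame(well = rep(c("w1", "w2"), each = 12),
                    batch = "b1", genotype = "g", medium = "full",
                    time_min = rep(seq(6, 72, by = 6), 2))
  raw$ocr <- 100; raw$ecar <- 20

  # no injections: everything is baseline
  a0 <- label_phases(raw)
  expect_true(all(a0$phase == "baseline"))

  # three injections, three cycles each
  inj <- c(post_oligo = 21, post_fccp = 39, post_rotAA = 57)
  a1 <- label_phases(raw, inj)
  expect_equal(as.vector(table(a1$phase[a1$well == "w1"])),
               c(3, 3, 3, 3))
  expect_equal(levels(a1$phase),
               c("baseline", "post_oligo", "post_fccp", "post_rotAA"))

  # first post-injection cycle droppable as a mixing artifact
  a2 <- label_phases(raw, inj, drop_first_cycle = TRUE)
  expect_equal(sum(a2$phase == "post_oligo"), 4)
  expect_equal(sum(a2$phase == "baseline"), 6)
  expect_error(label_phases(transform(raw, time_min = time_min - 10)),
               "before the first")

  # round-trip with the generator's own phase labels
  fx <- two_genotype_flux(seed = 1)
  raw2 <- as.data.frame(fx)[, c("well", "batch", "genotype", "medium",
                                "time_min", "ocr", "ecar")]
  m <- 3
  inj2 <- setNames((seq_len(4) * m) * 6 + 3,
                   levels(fx$phase)[-1])
  relab <- label_phases(raw2, inj2)
  expect_equal(as.character(relab$phase), as.character(fx$phase))
})

test_that("LMM fixed effects collapse to OLS when variance is absent", {
  fx <- two_genotype_flux(seed = 2, sigma_well = 0, sigma_batch = 0,
                          sigma_resid = 1)
  fit <- fit_flux_lmm(fx, "ecar", "phase * genotype",
                      phases = c("baseline", "post_rotAA"))
  d <- fit$data
  ols <- lm(ecar ~ phase * genotype, data = d)
  expect_equal(unname(fit$fixef), unname(coef(ols)), tolerance = 1e-6)
  expect_true(fit$boundary)
})

test_that("REML variance components match closed-form ANOVA on balanced data", {
  # one random factor (well), balanced: expected-mean-squares estimators
  withr::with_seed(3, {
    n_well <- 12; m <- 20
    well <- rep(sprintf("w%02d", 1:n_well), each = m)
    y <- 5 + rep(rnorm(n_well, 0, 2), each = m) + rnorm(n_well * m, 0, 1)
    d <- data.frame(well = well, batch = "b1", genotype = "g",
                    medium = "full", phase = "baseline",
                    time_min = 1, ocr = NA_real_, ecar = y)
    fx <- as_flux_assay(d)
    fit <- suppressWarnings(fit_flux_lmm(fx, "ecar", "1"))
    agg <- tapply(y, well, mean)
    mse <- sum((y - rep(agg, each = m))^2) / (n_well * (m - 1))
    msa <- m * sum((agg - mean(y))^2) / (n_well - 1)
    expect_equal(unname(fit$varcomp["well"]), (msa - mse) / m,
                 tolerance = 1e-6)
    expect_equal(unname(fit$varcomp["residual"]), mse, tolerance = 1e-6)
  })
})

test_that("REML criterion at the optimum beats the zero-variance corner", {
  fx <- two_genotype_flux(seed = 4, sigma_well = 2, sigma_batch = 1,
                          sigma_resid = 1)
  d <- as.data.frame(fx)[is.finite(fx$ecar), ]
  devfun <- suppressMessages(lme4::lmer(
    ecar ~ phase * genotype + (1 | well) + (1 | batch), data = d,
    devFunOnly = TRUE))
  fit <- suppressMessages(lme4::lmer(
    ecar ~ phase * genotype + (1 | well) + (1 | batch), data = d))
  expect_lte(devfun(fit@theta), devfun(c(0, 0)) + 1e-8)
})

test_that("variance components are recovered in simulation", {
  # 24 wells across 8 batches so every component has usable df
  est <- withr::with_seed(5, replicate(100, {
    fx <- simulate_flux_plate(do.call(flux_sim_spec, c(
      default_flux_means(),
      list(sigma_well = 2, sigma_batch = 1, sigma_resid = 1,
           n_wells_per_genotype = 12, n_batches = 8,
           measurements_per_phase = 5,
           seed = sample.int(1e6, 1)))))
    fit <- fit_flux_lmm(fx, "ecar", "phase * genotype")
    c(fit$varcomp["well"], fit$varcomp["batch"], fit$varcomp["residual"])
  }))
  med <- apply(est, 1, median)
  expect_equal(unname(med[1]), 4, tolerance = 0.3)
  expect_equal(unname(med[2]), 1, tolerance = 0.3)
  expect_equal(unname(med[3]), 1, tolerance = 0.3)
})

test_that("glycolytic reserve and its genotype contrast are recovered", {
  # design: control reserve 40-20 = 20, tau reserve 40-30 = 10
  fx <- two_genotype_flux(seed = 6, sigma_well = 0.5, sigma_batch = 0.5,
                          sigma_resid = 0.5, n_wells = 8)
  gr <- suppressWarnings(glycolytic_reserve(fx))
  est <- setNames(gr$per_genotype$estimate, gr$per_genotype$genotype)
  expect_equal(unname(est["control"]), 20, tolerance = 0.15)
  expect_equal(unname(est["tau"]), 10, tolerance = 0.3)
  ctr <- gr$contrast
  expect_equal(ctr$estimate, 10, tolerance = 3 * ctr$se)
  expect_lt(ctr$p, 0.01)
  # tau reserve below control: negative tau-minus-control contrast
  expect_lt(est["tau"] - est["control"], 0)
  expect_error(glycolytic_reserve(fx, maximal_phase = "nonexistent"),
               "missing phase")
})

test_that("reserve contrast p-values are calibrated under the null", {
  means <- default_flux_means()
  means$ecar_means["tau", ] <- means$ecar_means["control", ]
  pvals <- withr::with_seed(7, replicate(1000, {
    fx <- simulate_flux_plate(do.call(flux_sim_spec, c(
      means, list(sigma_well = 1, sigma_batch = 0.5, sigma_resid = 1,
                  n_wells_per_genotype = 4, n_batches = 2,
                  measurements_per_phase = 3,
                  seed = sample.int(1e6, 1)))))
    suppressWarnings(glycolytic_reserve(fx)$contrast$p)
  }))
  expect_lte(mean(pvals < 0.05), 0.075)
})

test_that("maximal ECAR model recovers the genotype means", {
  fx <- two_genotype_flux(seed = 8, sigma_well = 0.5, sigma_batch = 0.5,
                          sigma_resid = 0.5)
  me <- suppressWarnings(maximal_ecar(fx))
  expect_equal(me$per_genotype$estimate, c(40, 40), tolerance = 0.05)
  expect_gt(me$contrast$p, 0.05)

  # injected +15 shift shows up in the contrast
  means <- default_flux_means()
  means$ecar_means["tau", "post_rotAA"] <- 55
  fx2 <- simulate_flux_plate(do.call(flux_sim_spec, c(
    means, list(sigma_well = 0.5, sigma_batch = 0.5, sigma_resid = 0.5,
                seed = 9))))
  me2 <- suppressWarnings(maximal_ecar(fx2))
  expect_equal(me2$contrast$estimate, -15, tolerance = 0.2)
  expect_lt(me2$contrast$p, 1e-6)
})

test_that("post-2DG decline slopes and their contrast are recovered", {
  fx <- two_genotype_flux(seed = 10, sigma_well = 0.2, sigma_batch = 0.2,
                          sigma_resid = 0.2)
  # flat post-2DG phase: slopes near zero
  dg0 <- suppressWarnings(dg2_slope(fx))
  expect_true(all(abs(dg0$per_genotype$estimate) < 0.2))

  # inject genotype-specific declines of -2 and -1 per minute
  d <- as.data.frame(fx)
  sel <- as.character(d$phase) == "post_2dg"
  tc <- d$time_min - mean(d$time_min[sel])
  slope <- ifelse(d$genotype == "control", -2, -1)
  d$ecar[sel] <- d$ecar[sel] + slope[sel] * tc[sel]
  dg1 <- suppressWarnings(
    dg2_slope(as_flux_assay(d, phase_levels = levels(fx$phase))))
  est <- setNames(dg1$per_genotype$estimate, dg1$per_genotype$genotype)
  expect_equal(unname(est["control"]), -2, tolerance = 0.1)
  expect_equal(unname(est["tau"]), -1, tolerance = 0.2)
  expect_equal(dg1$contrast$estimate, -1, tolerance = 0.2)
  expect_lt(dg1$contrast$p, 1e-4)

  # no-random-effect limit: slope equals the average of per-well OLS slopes
  fx0 <- two_genotype_flux(seed = 11, sigma_well = 0, sigma_batch = 0,
                           sigma_resid = 0.5)
  d0 <- as.data.frame(fx0)
  sel0 <- as.character(d0$phase) == "post_2dg"
  d0$ecar[sel0] <- d0$ecar[sel0] -
    1.5 * (d0$time_min[sel0] - mean(d0$time_min[sel0]))
  dg2 <- suppressWarnings(
    dg2_slope(as_flux_assay(d0, phase_levels = levels(fx0$phase))))
  per_well <- vapply(split(d0[sel0, ], d0$well[sel0]), function(sub)
    unname(coef(lm(ecar ~ time_min, data = sub))[2]), numeric(1))
  expect_equal(mean(dg2$per_genotype$estimate), mean(per_well),
               tolerance = 0.02)
})

test_that("OCR metrics reproduce their designed differences", {
  # truth: ATP-linked 60 (both), reserve 50 vs 20, peak 140 vs 110
  fx <- two_genotype_flux(seed = 12, sigma_well = 0.5, sigma_batch = 0.5,
                          sigma_resid = 0.5, n_wells = 8)
  om <- ocr_metrics(fx)
  get <- function(metric, g) {
    pg <- om[[metric]]$per_genotype
    pg$estimate[pg$genotype == g]
  }
  se <- function(metric, g) {
    pg <- om[[metric]]$per_genotype
    pg$se[pg$genotype == g]
  }
  expect_lt(abs(get("atp_linked", "control") - 60),
            2 * se("atp_linked", "control") + 0.2)
  expect_lt(abs(get("respiratory_reserve", "control") - 50),
            2 * se("respiratory_reserve", "control") + 0.2)
  expect_lt(abs(get("respiratory_reserve", "tau") - 20),
            2 * se("respiratory_reserve", "tau") + 0.2)
  expect_lt(abs(get("peak_capacity", "control") - 140),
            2 * se("peak_capacity", "control") + 0.2)
  expect_lt(abs(get("peak_capacity", "tau") - 110),
            2 * se("peak_capacity", "tau") + 0.2)

  # constant offset to every measurement leaves all metrics unchanged
  fx2 <- fx; fx2$ocr <- fx2$ocr + 37
  om2 <- ocr_metrics(fx2)
  for (mt in names(om))
    expect_equal(om2[[mt]]$per_genotype$estimate,
                 om[[mt]]$per_genotype$estimate, tolerance = 1e-6)
})

test_that("single-level random factors are dropped with a warning", {
  fx <- simulate_flux_plate(do.call(flux_sim_spec, c(
    default_flux_means(), list(n_batches = 1, seed = 13))))
  expect_warning(fit <- fit_flux_lmm(fx, "ecar", "phase * genotype",
                                     phases = c("baseline", "post_rotAA")),
                 "single level")
  expect_false("batch" %in% names(fit$varcomp))
})

test_that("internal EMMs agree with the emmeans reference grid", {
  skip_if_not_installed("emmeans")
  fx <- two_genotype_flux(seed = 30)
  fit <- fit_flux_lmm(fx, "ecar", "phase * genotype",
                      phases = c("baseline", "post_rotAA"))
  em <- as.data.frame(emmeans::emmeans(fit$model, ~ phase * genotype,
                                       lmer.df = "asymptotic"))
  key <- paste(fit$emm$phase, fit$emm$genotype)
  ref <- setNames(em$emmean, paste(em$phase, em$genotype))
  expect_equal(fit$emm$emmean, unname(ref[key]), tolerance = 1e-8)
  refse <- setNames(em$SE, paste(em$phase, em$genotype))
  expect_equal(fit$emm$se, unname(refse[key]), tolerance = 1e-6)
})
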