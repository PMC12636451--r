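# ATP/ADP ratio trace processing: background subtraction, exponential
# baseline normalization (bleach + baseline in one step, on the ratio),
# empirical pH correction against the pHrodo proxy, counterfactual
# baseline extrapolation, and duration-adjusted integrated change.

#' Background-subtracted excitation ratio per ROI
#'
#' ratio = (F488 - background488) / (F405 - background405) per timepoint;
#' points where the denominator is <= 0 are masked (NA) with a warning.
#'
#' @param traces a `ratio_trace_set` (see [as_ratio_trace_set()]).
#' @return data.frame with columns roi, time_s, ratio, phrodo.
#' @export
compute_ratio <- function(traces) {
  stop_if(!inherits(traces, "ratio_trace_set"), "need a ratio_trace_set")
  d <- traces$data
  bg <- d[d$is_background, , drop = FALSE]
  stop_if(nrow(bg) == 0L, "background ROI series missing")
  bg <- bg[order(bg$time_s), ]
  out <- lapply(split(d[!d$is_background, ], d$roi[!d$is_background]),
                function(sub) {
    sub <- sub[order(sub$time_s), ]
    b405 <- approx(bg$time_s, bg$f405, xout = sub$time_s, rule = 2)$y
    b488 <- approx(bg$time_s, bg$f488, xout = sub$time_s, rule = 2)$y
    den <- sub$f405 - b405
    num <- sub$f488 - b488
    ratio <- ifelse(den > 0, num / den, NA_real_)
    if (all(is.na(ratio)))
      stop(sprintf("ROI '%s': denominator channel never exceeds background",
                   sub$roi[1]), call. = FALSE)
    if (anyNA(ratio))
      warning(sprintf("ROI '%s': %d timepoints masked (denominator <= 0)",
                      sub$roi[1], sum(is.na(ratio))), call. = FALSE)
    data.frame(roi = sub$roi, time_s = sub$time_s, ratio = ratio,
               phrodo = sub$phrodo)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# fit A * exp(-k t) to premix points; log-linear fit, refined by nls when
# possible; k is clamped at 0 (constant fit) if the slope runs uphill
fit_premix_exponential <- function(t, r) {
  ok <- is.finite(r) & r > 0
  flagged <- FALSE
  if (sum(ok) >= 5L) {
    ll <- lm(log(r[ok]) ~ t[ok])
    A <- exp(unname(coef(ll)[1])); k <- -unname(coef(ll)[2])
  } else {
    A <- mean(r, na.rm = TRUE); k <- 0; flagged <- TRUE
  }
  if (!is.finite(k) || k < 0) { k <- 0; A <- mean(r, na.rm = TRUE) }
  ref <- tryCatch({
    st <- list(A = A, k = k)
    nf <- suppressWarnings(
      nls(r ~ A * exp(-k * t), start = st,
          lower = c(A = 1e-12, k = 0), algorithm = "port",
          control = list(warnOnly = TRUE)))
    coef(nf)
  }, error = function(e) NULL)
  if (!is.null(ref) && all(is.finite(ref))) {
    A <- unname(ref["A"]); k <- max(unname(ref["k"]), 0)
  } else if (is.null(ref)) flagged <- TRUE
  list(A = A, k = k, constant_fallback = flagged)
}

#' Normalize a ratio trace to its premix exponential baseline
#'
#' Fits A * exp(-k t) (k >= 0; k = 0 is a constant baseline) to the ratio
#' over the premix window, divides the whole trace by the extrapolated
#' fit, and rescales so the premix mean is exactly 1. This single step
#' absorbs both photobleach decay and the baseline level.
#'
#' @param ratio data.frame for one ROI with columns time_s, ratio (and
#'   optionally phrodo, carried through).
#' @param premix_end end of the premix window in seconds (treatment time).
#' @return a `corrected_trace`: list with `data` (time_s, ratio, phrodo),
#'   `baseline_fit` (A, k, constant_fallback), `premix_end`,
#'   `premix_mean` (= 1 after normalization) and `ph_corrected = FALSE`.
#' @export
normalize_to_baseline <- function(ratio, premix_end) {
  stop_if(!all(c("time_s", "ratio") %in% names(ratio)),
          "need columns time_s and ratio")
  pre <- ratio$time_s < premix_end
  stop_if(sum(pre & is.finite(ratio$ratio)) < 5L,
          "at least 5 finite premix points required")
  bf <- fit_premix_exponential(ratio$time_s[pre], ratio$ratio[pre])
  env <- bf$A * exp(-bf$k * ratio$time_s)
  r <- ratio$ratio / env
  r <- r / mean(r[pre], na.rm = TRUE)  # pin premix mean at exactly 1
  structure(list(data = data.frame(time_s = ratio$time_s, ratio = r,
                                   phrodo = ratio$phrodo %||%
                                     rep(NA_real_, nrow(ratio))),
                 baseline_fit = bf, premix_end = premix_end,
                 premix_mean = mean(r[pre], na.rm = TRUE),
                 ph_corrected = FALSE),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("Corrected trace: %d points, premix < %gs (mean %.6f), bleach k = %.3g/s%s%s\n",
              nrow(x$data), x$premix_end, x$premix_mean, x$baseline_fit$k,
              if (x$baseline_fit$constant_fallback) ", constant fallback" else "",
              if (x$ph_corrected) ", pH-corrected" else ""))
  invisible(x)
}

#' Empirical pH calibration from the NH4Cl pulse
#'
#' During the NH4Cl window the ATP/ADP sensor deviation is driven purely
#' by cytosolic pH; its relationship to the pHrodo deviation is linear
#' and gives the correction slope. Deviations are measured from the means
#' over the `pre_window` seconds preceding NH4Cl onset.
#'
#' @param trace a `corrected_trace` (normalized, not yet pH-corrected),
#'   with a `phrodo` column, or a list of them (`scope = "pooled"`).
#' @param nh4cl_window `c(start, end)` seconds.
#' @param scope `"per_roi"` (fit this trace) or `"pooled"` (fit one line
#'   through the pooled deviation pairs of a list of traces).
#' @param pre_window seconds before NH4Cl onset defining the local
#'   baseline (default 30).
#' @return a `ph_calibration`: list with `slope`, `intercept`,
#'   `r_squared`, `scope`, `n_points`.
#' @export
calibrate_ph <- function(trace, nh4cl_window, scope = c("per_roi", "pooled"),
                         pre_window = 30) {
  scope <- match.arg(scope)
  traces <- if (scope == "pooled") trace else list(trace)
  devs <- lapply(traces, function(tr) {
    stop_if(!inherits(tr, "corrected_trace"), "need corrected_trace input")
    d <- tr$data
    win <- d$time_s >= nh4cl_window[1] & d$time_s <= nh4cl_window[2]
    stop_if(sum(win) < 5L, "NH4Cl window must contain at least 5 points")
    pre <- d$time_s >= nh4cl_window[1] - pre_window &
      d$time_s < nh4cl_window[1]
    stop_if(sum(pre) < 1L, "no points in the pre-NH4Cl baseline window")
    data.frame(dp = d$phrodo[win] - mean(d$phrodo[pre], na.rm = TRUE),
               dr = d$ratio[win] - mean(d$ratio[pre], na.rm = TRUE))
  })
  dd <- do.call(rbind, devs)
  dd <- dd[complete.cases(dd), ]
  stop_if(var(dd$dp) < 1e-20,
          "zero variance in pHrodo deviations; cannot calibrate")
  fit <- lm(dr ~ dp, data = dd)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 scope = scope, n_points = nrow(dd)),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("pH calibration (%s): slope %.4f, R^2 %.3f, %d points\n",
              x$scope, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Apply the empirical pH correction
#'
#' corrected ratio = normalized ratio - slope * (pHrodo deviation), with
#' the pHrodo deviation measured from its premix mean; the premix ratio
#' mean stays 1.
#'
#' @param trace a `corrected_trace`.
#' @param cal a `ph_calibration`.
#' @return the pH-corrected `corrected_trace`.
#' @export
ph_correct <- function(trace, cal) {
  stop_if(!inherits(trace, "corrected_trace"), "need a corrected_trace")
  stop_if(!inherits(cal, "ph_calibration"), "need a ph_calibration")
  d <- trace$data
  pre <- d$time_s < trace$premix_end
  dev <- d$phrodo - mean(d$phrodo[pre], na.rm = TRUE)
  trace$data$ratio <- d$ratio - cal$slope * dev
  trace$ph_corrected <- TRUE
  trace$ph_slope <- cal$slope
  trace
}

#' Counterfactual baseline by local-level-plus-trend extrapolation
#'
#' Fits a Gaussian local-level + trend state-space model
#' ([stats::StructTS()], variances by maximum likelihood) to the
#' pre-treatment points and projects it over the treatment window with a
#' pointwise 95% band whose width is nondecreasing with horizon. When the
#' state-space fit is degenerate or `method = "ols"`, a deterministic OLS
#' linear trend with its prediction band is used instead.
#'
#' @param trace a `corrected_trace`.
#' @param treatment_time start of the treatment window, seconds.
#' @param horizon_end end of the projection (default: end of trace).
#' @param method `"auto"`, `"structts"` or `"ols"`.
#' @return a `counterfactual_baseline`: data.frame time_s, fit, lwr, upr
#'   with attribute `method`.
#' @export
counterfactual_baseline <- function(trace, treatment_time,
                                    horizon_end = NULL,
                                    method = c("auto", "structts", "ols")) {
  method <- match.arg(method)
  stop_if(!inherits(trace, "corrected_trace"), "need a corrected_trace")
  d <- trace$data[is.finite(trace$data$ratio), ]
  horizon_end <- horizon_end %||% max(d$time_s)
  pre <- d[d$time_s < treatment_time, ]
  post_t <- d$time_s[d$time_s >= treatment_time & d$time_s <= horizon_end]
  stop_if(nrow(pre) < 10L, "at least 10 pre-treatment points required")
  stop_if(length(post_t) < 1L, "projection window is outside the record")

  used <- "ols"
  fitvals <- se <- NULL
  if (method != "ols") {
    res <- tryCatch({
      y <- ts(pre$ratio)
      sfit <- suppressWarnings(StructTS(y, type = "trend"))
      # forecast at the post indices (uniform sampling assumed)
      n_ahead <- length(post_t)
      fc <- predict(sfit, n.ahead = n_ahead)
      list(fit = as.numeric(fc$pred), se = as.numeric(fc$se))
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res$fit))) {
      fitvals <- res$fit
      se <- cummax(ifelse(is.finite(res$se), res$se, 0))
      used <- "structts"
    } else if (method == "structts") {
      stop("state-space fit failed; use method = 'ols'", call. = FALSE)
    }
  }
  if (used == "ols") {
    ols <- lm(ratio ~ time_s, data = pre)
    pr <- predict(ols, newdata = data.frame(time_s = post_t),
                  interval = "prediction", level = 0.95)
    fitvals <- pr[, "fit"]
    se <- (pr[, "upr"] - pr[, "fit"]) / qnorm(0.975)
    se <- cummax(se)
  }
  out <- data.frame(time_s = post_t, fit = fitvals,
                    lwr = fitvals - qnorm(0.975) * se,
                    upr = fitvals + qnorm(0.975) * se)
  attr(out, "method") <- used
  class(out) <- c("counterfactual_baseline", "data.frame")
  out
}

#' Duration-adjusted integrated change against the counterfactual
#'
#' Trapezoidal area under (trace - extrapolated baseline) from treatment
#' to washout, divided by the window duration: the average deflection of
#' the pH-corrected ATP/ADP ratio attributable to the treatment. The
#' counterfactual band propagates to a (lower, upper) interval.
#'
#' @param trace a `corrected_trace`.
#' @param baseline a `counterfactual_baseline`.
#' @param treatment_time,washout_time window in seconds
#'   (washout > treatment).
#' @return an `integrated_change`: list with `value` (dimensionless),
#'   `lower`, `upper`, `auc_trace`, `auc_baseline`, `duration`.
#' @export
integrated_change <- function(trace, baseline, treatment_time,
                              washout_time) {
  stop_if(washout_time <= treatment_time, "washout must follow treatment")
  d <- trace$data[is.finite(trace$data$ratio), ]
  win <- d$time_s >= treatment_time & d$time_s <= washout_time
  stop_if(sum(win) < 2L, "window lies outside the recorded trace")
  tt <- d$time_s[win]
  base <- approx(baseline$time_s, baseline$fit, xout = tt, rule = 2)$y
  blwr <- approx(baseline$time_s, baseline$lwr, xout = tt, rule = 2)$y
  bupr <- approx(baseline$time_s, baseline$upr, xout = tt, rule = 2)$y
  dur <- washout_time - treatment_time
  auc_tr <- trapezoid(tt, d$ratio[win])
  auc_bl <- trapezoid(tt, base)
  structure(list(value = (auc_tr - auc_bl) / dur,
                 lower = (auc_tr - trapezoid(tt, bupr)) / dur,
                 upper = (auc_tr - trapezoid(tt, blwr)) / dur,
                 auc_trace = auc_tr, auc_baseline = auc_bl,
                 duration = dur),
            class = "integrated_change")
}

#' @export
print.integrated_change <- function(x, ...) {
  cat(sprintf("Integrated change: %.4f [%.4f, %.4f] per unit time over %gs\n",
              x$value, x$lower, x$upper, x$duration))
  invisible(x)
}

#' Process a full trace set to per-ROI integrated changes
#'
#' Convenience chain: ratio -> baseline normalization -> per-ROI pH
#' calibration (pooled fallback when a ROI's NH4Cl response is
#' degenerate) -> pH correction -> counterfactual baseline -> integrated
#' change.
#'
#' @param traces a `ratio_trace_set`.
#' @param cf_method counterfactual method (see [counterfactual_baseline()]).
#' @return data.frame with one row per ROI: roi, integrated_change,
#'   lower, upper, ph_slope, bleach_k, cf_method.
#' @export
process_trace_set <- function(traces, cf_method = "auto") {
  ev <- traces$events
  rr <- compute_ratio(traces)
  by_roi <- split(rr, rr$roi)
  norm <- lapply(by_roi, normalize_to_baseline, premix_end = ev$treatment)
  win <- c(ev$nh4cl_start, ev$nh4cl_end)
  pooled <- tryCatch(calibrate_ph(norm, win, scope = "pooled"),
                     error = function(e) NULL)
  rows <- lapply(names(norm), function(id) {
    tr <- norm[[id]]
    cal <- tryCatch(calibrate_ph(tr, win, scope = "per_roi"),
                    error = function(e) pooled)
    if (!is.null(cal)) tr <- ph_correct(tr, cal)
    bl <- counterfactual_baseline(tr, ev$treatment,
                                  horizon_end = ev$washout,
                                  method = cf_method)
    ic <- integrated_change(tr, bl, ev$treatment, ev$washout)
    data.frame(roi = id, integrated_change = ic$value, lower = ic$lower,
               upper = ic$upper,
               ph_slope = if (is.null(cal)) NA_real_ else cal$slope,
               bleach_k = tr$baseline_fit$k,
               cf_method = attr(bl, "method"))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Compare per-ROI integrated changes between groups
#'
#' Group medians with binomial order-statistic 95% confidence intervals
#' and two-sided Mann-Whitney tests (exact where feasible, tie-corrected
#' normal approximation otherwise) for every pair of groups.
#'
#' @param values numeric vector of per-ROI integrated changes.
#' @param groups group labels (same length, >= 3 ROIs per group).
#' @return list with `summary` (group, n, median, ci_lower, ci_upper) and
#'   `tests` (group1, group2, U, p).
#' @export
compare_groups <- function(values, groups) {
  stop_if(length(values) != length(groups), "lengths differ")
  groups <- factor(groups)
  stop_if(any(table(groups) < 3L), "each group needs at least 3 values")
  med_ci <- function(x) {
    n <- length(x); xs <- sort(x)
    lo <- qbinom(0.025, n, 0.5); hi <- qbinom(0.975, n, 0.5) + 1L
    c(median = median(x), lower = xs[max(lo, 1L)], upper = xs[min(hi, n)])
  }
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    ci <- med_ci(values[groups == g])
    data.frame(group = g, n = sum(groups == g), median = ci["median"],
               ci_lower = ci["lower"], ci_upper = ci["upper"])
  }))
  rownames(summ) <- NULL
  pairs <- utils::combn(levels(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    x <- values[groups == pairs[1, i]]
    y <- values[groups == pairs[2, i]]
    wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               U = unname(wt$statistic), p = wt$p.value)
  }))
  list(summary = summ, tests = tests)
}
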