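# Gompertz mortality decomposition: h(t) = alpha * exp(beta * t).
# The right-censored log-likelihood, its gradient and observed information
# are written in terms of g(x) = (e^x - 1)/x and its derivatives so that
# the exponential submodel (beta -> 0) is reached continuously.

gfun <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 + xs / 2 + xs^2 / 6 + xs^3 / 24
  xl <- x[!small]
  out[!small] <- expm1(xl) / xl
  out
}

gfun1 <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 / 2 + xs / 3 + xs^2 / 8 + xs^3 / 30
  xl <- x[!small]
  out[!small] <- (exp(xl) * (xl - 1) + 1) / xl^2
  out
}

gfun2 <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 / 3 + xs / 4 + xs^2 / 10
  xl <- x[!small]
  out[!small] <- (exp(xl) * (xl^2 - 2 * xl + 2) - 2) / xl^3
  out
}

#' Gompertz right-censored log-likelihood
#'
#' ll = sum over deaths of (log(alpha) + beta * t) minus the cumulative
#' hazard (alpha/beta) * (exp(beta t) - 1) summed over all subjects;
#' evaluated continuously through beta = 0 (the exponential limit).
#'
#' @param alpha baseline hazard per day (> 0).
#' @param beta aging rate per day (>= 0).
#' @param time event/censoring times in days.
#' @param status 1 = death, 0 = censored.
#' @return log-likelihood in nats.
#' @export
gompertz_loglik <- function(alpha, beta, time, status) {
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0, allow_equal_lower = TRUE)
  H <- alpha * time * gfun(beta * time)
  sum(status * (log(alpha) + beta * time)) - sum(H)
}

gompertz_score <- function(alpha, beta, time, status) {
  D <- sum(status)
  c(dalpha = D / alpha - sum(time * gfun(beta * time)),
    dbeta = sum(status * time) - alpha * sum(time^2 * gfun1(beta * time)))
}

gompertz_obsinfo <- function(alpha, beta, time, status) {
  D <- sum(status)
  haa <- -D / alpha^2
  hab <- -sum(time^2 * gfun1(beta * time))
  hbb <- -alpha * sum(time^3 * gfun2(beta * time))
  -matrix(c(haa, hab, hab, hbb), 2, 2,
          dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
}

#' Fit the Gompertz mortality model by maximum likelihood
#'
#' Decomposes a lifespan cohort into baseline mortality `alpha` (hazard at
#' the start of adult life, t = 0 at eclosion) and aging rate `beta` (the
#' exponential increase in mortality risk with age). Optimization is
#' quasi-Newton (L-BFGS-B) on (log alpha, log beta) with the analytic
#' gradient, initialized from OLS on the kernel-smoothed log hazard when
#' enough deaths are available; Nelder-Mead is the fallback. Standard
#' errors come from the inverse observed information at the optimum.
#'
#' @param events an `event_times` object (see [impute_event_times()],
#'   [as_event_times()]), or a data.frame with `time` and `status`.
#' @return object of class `gompertz_fit` with components `alpha`, `beta`,
#'   `se_alpha`, `se_beta`, `cov` (2 x 2), `loglik`, `converged`,
#'   `n_events`, `n`.
#' @examples
#' ev <- as_event_times(rgompertz_time(500, 0.002, 0.1), rep(1, 500))
#' fit_gompertz(ev)
#' @export
fit_gompertz <- function(events) {
  stop_if(!is.data.frame(events) ||
            !all(c("time", "status") %in% names(events)),
          "need event times with columns time and status")
  tt <- events$time; ss <- events$status
  dtimes <- tt[ss == 1]
  stop_if(length(unique(dtimes)) < 2L,
          "at least 2 distinct death times required")
  D <- sum(ss)

  init <- tryCatch({
    ev <- structure(events, class = c("event_times", "data.frame"))
    lh <- loghazard_linearity(empirical_hazard(ev))
    c(log(max(exp(lh$intercept), 1e-10)), log(max(lh$slope, 1e-4)))
  }, error = function(e) {
    c(log(D / sum(tt)), log(max(1 / sd(dtimes), 1e-4)))
  })

  nll <- function(th) -gompertz_loglik(exp(th[1]), exp(th[2]), tt, ss)
  ngr <- function(th) {
    sc <- gompertz_score(exp(th[1]), exp(th[2]), tt, ss)
    -c(sc[1] * exp(th[1]), sc[2] * exp(th[2]))  # chain rule to log scale
  }
  opt <- tryCatch(
    optim(init, nll, ngr, method = "L-BFGS-B",
          lower = c(-30, -30), upper = c(5, 5),
          control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    opt2 <- optim(init, nll, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(opt) || opt2$value < opt$value) opt <- opt2
  }
  alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
  info <- gompertz_obsinfo(alpha, beta, tt, ss)
  cov <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = dimnames(info)))
  ses <- unname(suppressWarnings(sqrt(diag(cov))))
  grad_norm <- sqrt(sum(gompertz_score(alpha, beta, tt, ss)^2 *
                          c(alpha, beta)^2))
  # optimizer report, or a log-scale gradient at numerical noise level,
  # plus a usable observed information
  converged <- (opt$convergence == 0 || grad_norm < 1e-4 * max(1, D)) &&
    all(is.finite(ses)) && all(ses > 0)
  structure(list(alpha = alpha, beta = beta,
                 se_alpha = ses[1], se_beta = ses[2], cov = cov,
                 loglik = -opt$value, converged = converged,
                 grad_norm = grad_norm, n_events = D, n = length(tt)),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat("Gompertz mortality fit: h(t) = alpha * exp(beta * t)\n")
  cat(sprintf("  alpha (baseline mortality /day): %.*g (SE %.*g)\n",
              digits, x$alpha, digits, x$se_alpha))
  cat(sprintf("  beta  (aging rate /day):         %.*g (SE %.*g)\n",
              digits, x$beta, digits, x$se_beta))
  cat(sprintf("  log-likelihood %.4f on %d deaths / %d flies%s\n",
              x$loglik, x$n_events, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
vcov.gompertz_fit <- function(object, ...) object$cov

#' @export
logLik.gompertz_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  z <- c(object$alpha / object$se_alpha, object$beta / object$se_beta)
  tab <- data.frame(estimate = c(object$alpha, object$beta),
                    se = c(object$se_alpha, object$se_beta), z = z,
                    row.names = c("alpha", "beta"))
  structure(list(coefficients = tab, loglik = object$loglik,
                 converged = object$converged, n = object$n,
                 n_events = object$n_events, mrdt = log(2) / object$beta),
            class = "summary.gompertz_fit")
}

#' @export
print.summary.gompertz_fit <- function(x, ...) {
  cat("Gompertz mortality fit\n")
  print(x$coefficients)
  cat(sprintf("Mortality-rate doubling time: %.2f days; loglik %.3f (n = %d)\n",
              x$mrdt, x$loglik, x$n))
  invisible(x)
}

#' @export
confint.gompertz_fit <- function(object, parm = c("alpha", "beta"),
                                 level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  est <- coef(object)[parm]
  se <- c(alpha = object$se_alpha, beta = object$se_beta)[parm]
  zq <- qnorm(1 - (1 - level) / 2)
  cbind(lower = est - zq * se, upper = est + zq * se)
}

#' @export
predict.gompertz_fit <- function(object, times,
                                 type = c("hazard", "survival",
                                          "cumhaz"), ...) {
  type <- match.arg(type)
  a <- object$alpha; b <- object$beta
  switch(type,
         hazard = a * exp(b * times),
         cumhaz = a * times * gfun(b * times),
         survival = exp(-a * times * gfun(b * times)))
}

#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rgompertz_time(nsim, object$alpha, object$beta)
}

#' Pairwise Wald z-tests on Gompertz parameters
#'
#' For every pair of fits, z = (p1 - p2) / sqrt(SE1^2 + SE2^2) with a
#' two-sided standard-normal p-value; Holm adjustment is applied across
#' the whole family of pairwise comparisons of the chosen parameter.
#'
#' @param fits named list of `gompertz_fit` objects (all converged).
#' @param parameter `"alpha"` or `"beta"`.
#' @return a data.frame (class `param_comparison`) with columns group1,
#'   group2, parameter, estimate1, estimate2, z, p_raw, p_adj, method.
#' @export
compare_parameters <- function(fits, parameter = c("beta", "alpha")) {
  parameter <- match.arg(parameter)
  stop_if(length(fits) < 2L, "need at least two fits")
  stop_if(is.null(names(fits)) || any(!nzchar(names(fits))),
          "'fits' must be a named list")
  stop_if(!all(vapply(fits, inherits, logical(1), "gompertz_fit")),
          "all elements must be gompertz_fit objects")
  stop_if(!all(vapply(fits, `[[`, logical(1), "converged")),
          "all fits must have converged")
  est <- vapply(fits, `[[`, numeric(1), parameter)
  se <- vapply(fits, `[[`,
               numeric(1), paste0("se_", parameter))
  stop_if(any(se <= 0), "zero or negative standard errors")
  pairs <- utils::combn(names(fits), 2)
  z <- (est[pairs[1, ]] - est[pairs[2, ]]) /
    sqrt(se[pairs[1, ]]^2 + se[pairs[2, ]]^2)
  p_raw <- 2 * pnorm(-abs(z))
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    parameter = parameter,
                    estimate1 = unname(est[pairs[1, ]]),
                    estimate2 = unname(est[pairs[2, ]]),
                    z = unname(z), p_raw = unname(p_raw),
                    p_adj = holm_adjust(unname(p_raw)),
                    method = "holm", stringsAsFactors = FALSE)
  structure(res, class = c("param_comparison", "data.frame"))
}
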