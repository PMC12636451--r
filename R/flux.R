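# Seahorse-style flux metrics through random-intercept linear mixed
# models: y ~ fixed design + (1|well) + (1|batch), fitted with lme4.
# Estimated marginal means are equally-weighted cell-mean predictions
# computed from the fixed effects; contrasts use a Satterthwaite t
# reference by default (desk-scale designs carry few well-level degrees
# of freedom, and a plain z reference is anticonservative there), with
# z available as an option.

#' Assign injection phases to raw flux measurements
#'
#' Each measurement gets the phase of the most recent injection; the first
#' post-injection cycle can be dropped as a mixing artifact.
#'
#' @param raw data.frame with columns well, batch, genotype, medium,
#'   time_min, ocr, ecar.
#' @param injections named numeric vector of injection times (minutes);
#'   names become the post-injection phase labels, e.g.
#'   `c(post_rotAA = 18, post_2dg = 36)`. Measurements before the first
#'   injection are `"baseline"`.
#' @param drop_first_cycle drop the first measurement after each
#'   injection (default FALSE).
#' @return a `flux_assay` with phases in injection order.
#' @export
label_phases <- function(raw, injections = NULL, drop_first_cycle = FALSE) {
  stop_if(!all(c("well", "batch", "genotype", "medium", "time_min") %in%
                 names(raw)), "raw flux data missing required columns")
  stop_if(any(raw$time_min < 0), "measurement before the first timestamp")
  if (length(injections)) {
    stop_if(is.null(names(injections)) || is.unsorted(injections),
            "'injections' must be a named vector with ordered times")
  }
  bounds <- c(-Inf, unname(injections), Inf)
  labels <- c("baseline", names(injections))
  idx <- findInterval(raw$time_min, bounds[-1], left.open = FALSE) + 1L
  idx <- pmin(idx, length(labels))
  raw$phase <- labels[idx]
  if (drop_first_cycle && length(injections)) {
    keep <- rep(TRUE, nrow(raw))
    for (w in unique(raw$well)) {
      for (ph in names(injections)) {
        i <- which(raw$well == w & raw$phase == ph)
        if (length(i)) keep[i[which.min(raw$time_min[i])]] <- FALSE
      }
    }
    raw <- raw[keep, , drop = FALSE]
  }
  if (!"ocr" %in% names(raw)) raw$ocr <- NA_real_
  if (!"ecar" %in% names(raw)) raw$ecar <- NA_real_
  as_flux_assay(raw, phase_levels = labels)
}

# build the lme4 formula, auto-dropping single-level random factors
flux_formula <- function(response, fixed, data) {
  rand <- character(0)
  for (term in c("well", "batch")) {
    if (length(unique(data[[term]])) >= 2L) {
      rand <- c(rand, sprintf("(1 | %s)", term))
    } else {
      warning(sprintf("random factor '%s' has a single level; dropped",
                      term), call. = FALSE)
    }
  }
  stop_if(length(rand) == 0L, "no usable random factor (well, batch)")
  stats::as.formula(paste(response, "~", fixed, "+",
                          paste(rand, collapse = " + ")))
}

#' Fit a random-intercept linear mixed model to flux data
#'
#' Fits `response ~ fixed + (1|well) + (1|batch)` by REML (default)
#' through [lme4::lmer()]; single-level random factors are dropped with a
#' warning, and variance components sitting on the zero boundary are
#' flagged. Estimated marginal means per genotype-by-phase cell are
#' equally weighted fixed-effect predictions. Downstream contrasts use a
#' Satterthwaite t reference (falling back to normal z if the
#' degrees-of-freedom computation fails); the `df` column records which.
#'
#' @param assay a `flux_assay`.
#' @param response `"ecar"` or `"ocr"`.
#' @param fixed right-hand side of the fixed design, e.g.
#'   `"phase * genotype"` or `"time_c * genotype"`.
#' @param REML logical; `FALSE` for ML.
#' @param phases optional subset of phases to model.
#' @return an `lmm_fit`: list with `model` (the merMod), `fixef`, `vcov`,
#'   `varcomp` (well, batch, residual variances), `emm` (data.frame of
#'   genotype x phase cell means with SEs, when the design includes
#'   phase), `boundary` flag, `converged`, `method`.
#' @export
fit_flux_lmm <- function(assay, response = c("ecar", "ocr"),
                         fixed = "phase * genotype", REML = TRUE,
                         phases = NULL) {
  response <- match.arg(response)
  stop_if(!inherits(assay, "flux_assay"), "need a flux_assay")
  d <- as.data.frame(assay)
  if (!is.null(phases)) d <- d[as.character(d$phase) %in% phases, ]
  d <- d[is.finite(d[[response]]), ]
  stop_if(nrow(d) == 0L, "no finite measurements for this response")
  d$phase <- droplevels(factor(d$phase, levels = levels(assay$phase)))
  d$genotype <- factor(d$genotype)
  form <- flux_formula(response, fixed, d)
  fit <- suppressMessages(
    lmerTest::lmer(form, data = d, REML = REML,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  emm <- NULL
  if (grepl("phase", fixed)) {
    grid <- expand.grid(phase = levels(d$phase),
                        genotype = levels(d$genotype))
    emm <- cbind(grid, emm_predict(fit, grid, fixed))
  }
  structure(list(model = fit, fixef = lme4::fixef(fit),
                 vcov = as.matrix(vcov(fit)), varcomp = varcomp,
                 emm = emm,
                 boundary = any(varcomp[names(varcomp) != "residual"] <
                                  1e-10),
                 converged = length(fit@optinfo$conv$lme4) == 0L,
                 method = if (REML) "REML" else "ML",
                 data = d, fixed = fixed, response = response),
            class = "lmm_fit")
}

# fixed-effect predictions (and SEs) for a reference grid
emm_predict <- function(fit, grid, fixed) {
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed)),
                            data = grid,
                            xlev = lapply(grid, levels))
  beta <- lme4::fixef(fit)
  mm <- mm[, names(beta), drop = FALSE]
  V <- as.matrix(vcov(fit))
  est <- drop(mm %*% beta)
  se <- sqrt(rowSums((mm %*% V) * mm))
  data.frame(emmean = est, se = se)
}

# test on a linear combination L of the fixed effects; Satterthwaite t
# by default, normal z on request or when the t machinery fails
fixef_contrast <- function(fit, L, df_method = c("satterthwaite", "z")) {
  df_method <- match.arg(df_method)
  est <- drop(L %*% fit$fixef)
  se <- sqrt(drop(L %*% fit$vcov %*% L))
  stat <- est / se
  if (df_method == "satterthwaite" &&
      inherits(fit$model, "lmerModLmerTest")) {
    ct <- tryCatch(lmerTest::contest1D(fit$model, L,
                                       ddf = "Satterthwaite"),
                   error = function(e) NULL)
    if (!is.null(ct) && is.finite(ct[["Pr(>|t|)"]])) {
      return(data.frame(estimate = est, se = se, z = stat,
                        df = ct[["df"]], p = ct[["Pr(>|t|)"]]))
    }
  }
  data.frame(estimate = est, se = se, z = stat, df = Inf,
             p = 2 * pnorm(-abs(stat)))
}

# contrast row for EMM(genotype g, phase p1) - EMM(g, p0); differences of
# such rows give interaction contrasts
emm_row <- function(fit, genotype, phase) {
  grid <- data.frame(phase = factor(phase, levels = levels(fit$data$phase)),
                     genotype = factor(genotype,
                                       levels = levels(fit$data$genotype)))
  mm <- stats::model.matrix(stats::as.formula(paste("~", fit$fixed)),
                            data = grid, xlev = lapply(grid, levels))
  mm[, names(fit$fixef), drop = FALSE]
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s): %s ~ %s\n", x$method,
              x$response, x$fixed))
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(x$varcomp), x$varcomp),
            collapse = ", "),
      if (x$boundary) " [boundary]" else "", "\n")
  if (!is.null(x$emm)) {
    cat("  estimated marginal means:\n")
    print(x$emm, row.names = FALSE)
  }
  invisible(x)
}

# shared backbone for phase-difference metrics: per-genotype
# EMM(phase_hi) - EMM(phase_lo) plus the between-genotype interaction
# contrast from the phase x genotype model
phase_difference_metric <- function(assay, response, phase_lo, phase_hi,
                                    REML = TRUE) {
  present <- levels(droplevels(factor(assay$phase[
    is.finite(assay[[response]])])))
  miss <- setdiff(c(phase_lo, phase_hi), present)
  stop_if(length(miss) > 0,
          paste("missing phase(s):", paste(miss, collapse = ", ")))
  fit <- fit_flux_lmm(assay, response, fixed = "phase * genotype",
                      REML = REML, phases = c(phase_lo, phase_hi))
  genos <- levels(fit$data$genotype)
  rows <- lapply(genos, function(g) {
    L <- emm_row(fit, g, phase_hi) - emm_row(fit, g, phase_lo)
    cbind(data.frame(genotype = g), fixef_contrast(fit, drop(L)))
  })
  per_geno <- do.call(rbind, rows)
  contrasts <- NULL
  if (length(genos) >= 2L) {
    prs <- utils::combn(genos, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      L <- (emm_row(fit, prs[1, i], phase_hi) -
              emm_row(fit, prs[1, i], phase_lo)) -
        (emm_row(fit, prs[2, i], phase_hi) -
           emm_row(fit, prs[2, i], phase_lo))
      cbind(data.frame(group1 = prs[1, i], group2 = prs[2, i]),
            fixef_contrast(fit, drop(L)))
    }))
  }
  list(per_genotype = per_geno, contrast = contrasts, fit = fit)
}

#' Glycolytic reserve from the phase-coded ECAR model
#'
#' Reserve = EMM(post rotenone/antimycin ECAR) - EMM(baseline ECAR) per
#' genotype from `ECAR ~ phase * genotype + (1|well) + (1|batch)`; the
#' genotype difference is the interaction contrast.
#'
#' @param assay a `flux_assay` containing baseline and post_rotAA phases.
#' @param baseline_phase,maximal_phase phase labels (defaults `"baseline"`
#'   and `"post_rotAA"`).
#' @param REML logical.
#' @return list with `per_genotype` (genotype, estimate, se, z, p),
#'   `contrast` (between-genotype reserve differences) and `fit`.
#' @export
glycolytic_reserve <- function(assay, baseline_phase = "baseline",
                               maximal_phase = "post_rotAA", REML = TRUE) {
  phase_difference_metric(assay, "ecar", baseline_phase, maximal_phase,
                          REML = REML)
}

#' Maximal ECAR during OXPHOS inhibition
#'
#' Models ECAR within the rotenone + antimycin phase only, with genotype
#' as the fixed effect (`ECAR ~ genotype + (1|well) + (1|batch)`), and
#' tests genotype differences on the estimated marginal means.
#'
#' @param assay a `flux_assay`.
#' @param maximal_phase the post rotenone/antimycin phase label.
#' @param REML logical.
#' @return list with `per_genotype` EMMs, `contrast`, `fit`.
#' @export
maximal_ecar <- function(assay, maximal_phase = "post_rotAA", REML = TRUE) {
  fit <- fit_flux_lmm(assay, "ecar", fixed = "genotype", REML = REML,
                      phases = maximal_phase)
  genos <- levels(fit$data$genotype)
  mmrow <- function(g) {
    grid <- data.frame(genotype = factor(g, levels = genos))
    mm <- stats::model.matrix(~genotype, grid,
                              xlev = list(genotype = genos))
    mm[, names(fit$fixef), drop = FALSE]
  }
  per_geno <- do.call(rbind, lapply(genos, function(g)
    cbind(data.frame(genotype = g), fixef_contrast(fit, drop(mmrow(g))))))
  contrasts <- NULL
  if (length(genos) >= 2L) {
    prs <- utils::combn(genos, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      L <- mmrow(prs[1, i]) - mmrow(prs[2, i])
      cbind(data.frame(group1 = prs[1, i], group2 = prs[2, i]),
            fixef_contrast(fit, drop(L)))
    }))
  }
  list(per_genotype = per_geno, contrast = contrasts, fit = fit)
}

#' Post-2DG ECAR decline slope
#'
#' Genotype-specific marginal slopes of ECAR on centred time within the
#' post-2DG phase from `ECAR ~ time_c * genotype + (1|well) + (1|batch)`,
#' with the between-genotype slope difference tested via the interaction.
#'
#' @param assay a `flux_assay` with >= 3 post-2DG timepoints.
#' @param dg_phase post-2DG phase label.
#' @param REML logical.
#' @return list with `per_genotype` slopes (flux units per min),
#'   `contrast`, `fit`.
#' @export
dg2_slope <- function(assay, dg_phase = "post_2dg", REML = TRUE) {
  d <- as.data.frame(assay)
  d <- d[as.character(d$phase) == dg_phase & is.finite(d$ecar), ]
  stop_if(length(unique(d$time_min)) < 3L,
          "at least 3 post-2DG timepoints required")
  d$time_c <- d$time_min - mean(d$time_min)
  sub <- as_flux_assay(d, phase_levels = dg_phase)
  sub$time_c <- d$time_c
  fit <- fit_flux_lmm(sub, "ecar", fixed = "time_c * genotype", REML = REML)
  genos <- levels(fit$data$genotype)
  # slope for genotype g: d/dt of the fixed-effect prediction
  slope_row <- function(g) {
    grid0 <- data.frame(time_c = 0, genotype = factor(g, levels = genos))
    grid1 <- data.frame(time_c = 1, genotype = factor(g, levels = genos))
    mm <- function(gr) {
      m <- stats::model.matrix(~time_c * genotype, gr,
                               xlev = list(genotype = genos))
      m[, names(fit$fixef), drop = FALSE]
    }
    mm(grid1) - mm(grid0)
  }
  per_geno <- do.call(rbind, lapply(genos, function(g)
    cbind(data.frame(genotype = g),
          fixef_contrast(fit, drop(slope_row(g))))))
  contrasts <- NULL
  if (length(genos) >= 2L) {
    prs <- utils::combn(genos, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      L <- slope_row(prs[1, i]) - slope_row(prs[2, i])
      cbind(data.frame(group1 = prs[1, i], group2 = prs[2, i]),
            fixef_contrast(fit, drop(L)))
    }))
  }
  list(per_genotype = per_geno, contrast = contrasts, fit = fit)
}

#' OCR-derived respiration metrics
#'
#' From the phase-coded `OCR ~ phase * genotype + (1|well) + (1|batch)`
#' models: ATP-linked respiration = EMM(baseline) - EMM(post-oligomycin);
#' respiratory reserve = EMM(post-FCCP) - EMM(baseline); peak respiratory
#' capacity = EMM(post-FCCP) - EMM(post rotenone/antimycin). Each metric
#' is fitted on its own two phases, matching its phase coding.
#'
#' @param assay a `flux_assay` with baseline, post_oligo, post_fccp and
#'   post_rotAA phases.
#' @param REML logical.
#' @return named list (`atp_linked`, `respiratory_reserve`,
#'   `peak_capacity`), each with `per_genotype` and `contrast` tables.
#' @export
ocr_metrics <- function(assay, REML = TRUE) {
  flip <- function(m) {  # report baseline - post as a positive quantity
    m$per_genotype$estimate <- -m$per_genotype$estimate
    m$per_genotype$z <- -m$per_genotype$z
    if (!is.null(m$contrast)) {
      m$contrast$estimate <- -m$contrast$estimate
      m$contrast$z <- -m$contrast$z
    }
    m
  }
  list(
    atp_linked = flip(phase_difference_metric(
      assay, "ocr", "baseline", "post_oligo", REML = REML)),
    respiratory_reserve = phase_difference_metric(
      assay, "ocr", "baseline", "post_fccp", REML = REML),
    peak_capacity = phase_difference_metric(
      assay, "ocr", "post_rotAA", "post_fccp", REML = REML))
}
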