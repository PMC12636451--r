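#' Specify a Seahorse-style flux plate simulation
#'
#' Measurements follow the additive model assumed by the downstream mixed
#' models: value = genotype-by-phase mean + well intercept N(0, sigma_well)
#' + batch intercept N(0, sigma_batch) + residual N(0, sigma_resid). OCR
#' and ECAR are generated independently with their own phase means and
#' their own random intercepts.
#'
#' @param ocr_means,ecar_means genotype x phase matrices of phase means
#'   (rownames = genotype labels, colnames = phase labels in injection
#'   order; the standard phases are baseline, post_oligo, post_fccp,
#'   post_rotAA, post_2dg for OCR and baseline, post_rotAA, post_2dg for
#'   ECAR, but any ordered set is accepted).
#' @param sigma_well,sigma_batch,sigma_resid random-effect and residual
#'   SDs (flux units, >= 0).
#' @param n_wells_per_genotype wells per genotype.
#' @param n_batches number of experimental batches (wells are assigned
#'   round-robin across batches within genotype).
#' @param measurements_per_phase measurement cycles per injection phase.
#' @param cycle_min minutes between measurement cycles (default 6).
#' @param medium assay medium label (default "full").
#' @param seed integer RNG seed.
#' @return object of class `flux_sim_spec`.
#' @export
flux_sim_spec <- function(ocr_means, ecar_means,
                          sigma_well = 2, sigma_batch = 1, sigma_resid = 1,
                          n_wells_per_genotype = 6,
                          n_batches = 2,
                          measurements_per_phase = 3,
                          cycle_min = 6,
                          medium = "full",
                          seed = 1L) {
  stop_if(!is.matrix(ocr_means) || is.null(rownames(ocr_means)) ||
            is.null(colnames(ocr_means)),
          "'ocr_means' must be a genotype x phase matrix with dimnames")
  stop_if(!is.matrix(ecar_means) || is.null(rownames(ecar_means)) ||
            is.null(colnames(ecar_means)),
          "'ecar_means' must be a genotype x phase matrix with dimnames")
  stop_if(!identical(rownames(ocr_means), rownames(ecar_means)),
          "OCR and ECAR matrices must cover the same genotypes")
  for (s in c(sigma_well, sigma_batch, sigma_resid))
    check_number(s, "sigma", lower = 0, allow_equal_lower = TRUE)
  check_count(n_wells_per_genotype, "n_wells_per_genotype")
  check_count(n_batches, "n_batches")
  check_count(measurements_per_phase, "measurements_per_phase")
  structure(list(ocr_means = ocr_means, ecar_means = ecar_means,
                 sigma_well = sigma_well, sigma_batch = sigma_batch,
                 sigma_resid = sigma_resid,
                 n_wells_per_genotype = as.integer(n_wells_per_genotype),
                 n_batches = as.integer(n_batches),
                 measurements_per_phase = as.integer(measurements_per_phase),
                 cycle_min = cycle_min, medium = medium,
                 seed = as.integer(seed)),
            class = "flux_sim_spec")
}

#' Default phase-mean matrices for a two-genotype plate
#'
#' Convenience constructor giving a control/tau-like contrast: reduced
#' glycolytic reserve and reduced maximal OCR in the second genotype with
#' shared baselines, in typical instrument units.
#'
#' @param genotypes two genotype labels.
#' @return list with `ocr_means` and `ecar_means` matrices.
#' @export
default_flux_means <- function(genotypes = c("control", "tau")) {
  stop_if(length(genotypes) != 2L, "exactly two genotypes")
  ocr <- rbind(c(100, 40, 150, 10, 10),
               c(100, 40, 120, 10, 10))
  dimnames(ocr) <- list(genotypes,
                        c("baseline", "post_oligo", "post_fccp",
                          "post_rotAA", "post_2dg"))
  ecar <- rbind(c(20, 40, 15),
                c(30, 40, 20))
  dimnames(ecar) <- list(genotypes, c("baseline", "post_rotAA", "post_2dg"))
  list(ocr_means = ocr, ecar_means = ecar)
}

#' Simulate a flux assay plate
#'
#' @param spec a [flux_sim_spec()].
#' @return a `flux_assay`: data.frame with columns well, batch, genotype,
#'   medium, phase, time_min, ocr, ecar. Phase is an ordered factor in
#'   injection order; OCR phases absent from the ECAR design (or vice
#'   versa) carry NA for that response.
#' @export
simulate_flux_plate <- function(spec) {
  stop_if(!inherits(spec, "flux_sim_spec"), "need a flux_sim_spec")
  with_seed(spec$seed, {
    genos <- rownames(spec$ocr_means)
    phases <- union(colnames(spec$ocr_means), colnames(spec$ecar_means))
    wells <- data.frame(
      well = sprintf("w%02d", seq_len(spec$n_wells_per_genotype * length(genos))),
      genotype = rep(genos, each = spec$n_wells_per_genotype),
      stringsAsFactors = FALSE)
    wells$batch <- sprintf("b%d", rep_len(seq_len(spec$n_batches), nrow(wells)))
    batch_ids <- sprintf("b%d", seq_len(spec$n_batches))
    ub_ocr_all <- setNames(rnorm(spec$n_batches, 0, spec$sigma_batch), batch_ids)
    ub_ecar_all <- setNames(rnorm(spec$n_batches, 0, spec$sigma_batch), batch_ids)
    rows <- vector("list", nrow(wells))
    for (w in seq_len(nrow(wells))) {
      uw_ocr <- rnorm(1, 0, spec$sigma_well)
      uw_ecar <- rnorm(1, 0, spec$sigma_well)
      ub_ocr <- ub_ocr_all[wells$batch[w]]
      ub_ecar <- ub_ecar_all[wells$batch[w]]
      m <- spec$measurements_per_phase
      ph <- rep(phases, each = m)
      tm <- seq_along(ph) * spec$cycle_min
      ocr <- ecar <- rep(NA_real_, length(ph))
      for (i in seq_along(ph)) {
        g <- wells$genotype[w]
        if (ph[i] %in% colnames(spec$ocr_means))
          ocr[i] <- spec$ocr_means[g, ph[i]] + uw_ocr + ub_ocr +
            rnorm(1, 0, spec$sigma_resid)
        if (ph[i] %in% colnames(spec$ecar_means))
          ecar[i] <- spec$ecar_means[g, ph[i]] + uw_ecar + ub_ecar +
            rnorm(1, 0, spec$sigma_resid)
      }
      rows[[w]] <- data.frame(well = wells$well[w], batch = wells$batch[w],
                              genotype = wells$genotype[w],
                              medium = spec$medium, phase = ph,
                              time_min = tm, ocr = ocr, ecar = ecar,
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    as_flux_assay(res, phase_levels = phases)
  })
}

#' Construct/validate a flux assay table
#'
#' @param df data.frame with columns well, batch, genotype, medium, phase,
#'   time_min, ocr, ecar.
#' @param phase_levels phase labels in injection order (default: order of
#'   first appearance).
#' @return the data.frame with class `flux_assay`; `phase` becomes an
#'   ordered-level factor.
#' @export
as_flux_assay <- function(df, phase_levels = NULL) {
  need <- c("well", "batch", "genotype", "medium", "phase", "time_min",
            "ocr", "ecar")
  stop_if(!is.data.frame(df) || !all(need %in% names(df)),
          "flux assay needs columns well, batch, genotype, medium, phase, time_min, ocr, ecar")
  per_well <- tapply(paste(df$genotype, df$batch, df$medium), df$well,
                     function(x) length(unique(x)))
  stop_if(any(per_well != 1L),
          "each well must have exactly one genotype, batch and medium")
  stop_if(any(!is.finite(df$ocr) & !is.finite(df$ecar) &
                !(is.na(df$ocr) | is.na(df$ecar))),
          "OCR/ECAR must be finite where present")
  if (is.null(phase_levels)) phase_levels <- unique(as.character(df$phase))
  df$phase <- factor(as.character(df$phase), levels = phase_levels)
  structure(df, class = c("flux_assay", "data.frame"))
}

#' @export
print.flux_assay <- function(x, ...) {
  cat(sprintf("Flux assay: %d wells, %d batches, genotypes: %s; phases: %s\n",
              length(unique(x$well)), length(unique(x$batch)),
              paste(unique(x$genotype), collapse = ", "),
              paste(levels(x$phase), collapse = " -> ")))
  NextMethod()
}

#' Write / read flux assay CSV
#'
#' @param x a `flux_assay`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `flux_assay` (reader).
#' @export
write_flux_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) as_flux_assay(read.csv(path))
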