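# Configuration-driven orchestration: one root seed, per-stage blocks,
# CSV/TSV outputs plus a JSON manifest with checksums. Each stage is a
# thin call into the module functions; the pipeline adds no computation
# of its own.

#' Read a YAML run configuration
#'
#' Expected top-level keys: `seed` (root seed), `outdir`, `stages`
#' (subset of simulate, survival, traces, flux, transcriptome) and
#' optional per-stage parameter blocks (`survival`, `traces`, ...).
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  cfg$seed <- cfg$seed %||% 1L
  cfg$stages <- cfg$stages %||%
    c("simulate", "survival", "traces", "flux", "transcriptome")
  cfg
}

default_run_config <- function(seed = 1L, outdir = tempfile("flymetab_run")) {
  list(seed = seed, outdir = outdir,
       stages = c("simulate", "survival", "traces", "flux",
                  "transcriptome"),
       survival = list(rule = "interval_midpoint"),
       traces = list(cf_method = "auto"),
       transcriptome = list(alpha = 0.05))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order over synthetic (or
#' configured) inputs, writes per-stage CSV/TSV outputs under
#' `config$outdir`, and returns a manifest (also written as JSON) with
#' the package version, config checksum, seeds, per-file checksums,
#' timings and accumulated warnings. All randomness flows from the root
#' seed; deterministic stages reproduce identical checksums across runs.
#'
#' @param config a config list (see [read_run_config()]) or a path to a
#'   YAML file.
#' @return the manifest list, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% tempfile("flymetab_run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages
  known <- c("simulate", "survival", "traces", "flux", "transcriptome")
  stop_if(!all(stages %in% known),
          paste("unknown stage(s):",
                paste(setdiff(stages, known), collapse = ", ")))
  manifest <- list(package = "flymetab",
                   version = as.character(packageVersion("flymetab")),
                   seed = seed, stages = stages,
                   config_md5 = config_md5(config),
                   files = list(), timings = list(), warnings = list())
  warn <- character(0)
  note_file <- function(name, path) {
    manifest$files[[name]] <<- list(path = path, md5 = file_md5(path))
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(fn(), warning = function(w) {
      warn <<- c(warn, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  need_input <- function(stage, name, path) {
    stop_if(!file.exists(path),
            sprintf("stage '%s': required input '%s' (%s) is missing",
                    stage, name, path))
    path
  }

  paths <- list(
    census = file.path(outdir, "census.csv"),
    traces = file.path(outdir, "traces.csv"),
    flux = file.path(outdir, "flux.csv"),
    counts = file.path(outdir, "sim"))

  if ("simulate" %in% stages) run_stage("simulate", function() {
    genos <- data.frame(label = c("control", "tau"),
                        alpha = c(0.002, 0.002),
                        beta = c(0.08, 0.16), n_flies = c(100L, 100L))
    st <- simulate_lifespans(lifespan_sim_spec(genos, seed = seed))
    note_file("census", write_survival_csv(st, paths$census))
    ts <- simulate_traces(trace_sim_spec(seed = seed + 1L))
    note_file("traces", write_trace_csv(ts, paths$traces))
    fx <- do.call(flux_sim_spec, c(default_flux_means(),
                                   list(seed = seed + 2L)))
    note_file("flux", write_flux_csv(simulate_flux_plate(fx), paths$flux))
    cm <- simulate_counts(count_sim_spec(n_genes = 400,
                                         n_samples_per_group = 4,
                                         seed = seed + 3L))
    fs <- write_counts_tsv(cm, paths$counts)
    note_file("counts", fs["counts"]); note_file("lengths", fs["lengths"])
  })

  if ("survival" %in% stages) run_stage("survival", function() {
    tab <- read_survival_csv(need_input("survival", "census", paths$census))
    rule <- config$survival$rule %||% "interval_midpoint"
    ev <- impute_event_times(tab, rule)
    fits <- lapply(split(ev, ev$genotype), fit_gompertz)
    ft <- data.frame(genotype = names(fits),
                     alpha = vapply(fits, `[[`, 0, "alpha"),
                     se_alpha = vapply(fits, `[[`, 0, "se_alpha"),
                     beta = vapply(fits, `[[`, 0, "beta"),
                     se_beta = vapply(fits, `[[`, 0, "se_beta"),
                     loglik = vapply(fits, `[[`, 0, "loglik"),
                     converged = vapply(fits, `[[`, TRUE, "converged"),
                     n = vapply(fits, `[[`, 0L, "n"))
    f <- file.path(outdir, "gompertz_fits.csv")
    write.csv(ft, f, row.names = FALSE); note_file("gompertz_fits", f)
    for (par in c("alpha", "beta")) {
      cmp <- compare_parameters(fits, par)
      f2 <- file.path(outdir, sprintf("comparisons_%s.csv", par))
      write.csv(as.data.frame(cmp), f2, row.names = FALSE)
      note_file(paste0("comparisons_", par), f2)
    }
  })

  if ("traces" %in% stages) run_stage("traces", function() {
    need_input("traces", "traces", paths$traces)
    ev <- config$traces$events %||%
      list(treatment = 120, washout = 480, nh4cl_start = 600,
           nh4cl_end = 720)
    ts <- read_trace_csv(paths$traces, ev)
    res <- process_trace_set(ts, config$traces$cf_method %||% "auto")
    f <- file.path(outdir, "integrated_changes.csv")
    write.csv(res, f, row.names = FALSE); note_file("integrated_changes", f)
  })

  if ("flux" %in% stages) run_stage("flux", function() {
    fx <- read_flux_csv(need_input("flux", "flux", paths$flux))
    gr <- glycolytic_reserve(fx)
    dg <- dg2_slope(fx)
    om <- ocr_metrics(fx)
    metr <- rbind(
      cbind(metric = "glycolytic_reserve", gr$per_genotype),
      cbind(metric = "dg2_slope", dg$per_genotype),
      cbind(metric = "atp_linked", om$atp_linked$per_genotype),
      cbind(metric = "respiratory_reserve",
            om$respiratory_reserve$per_genotype),
      cbind(metric = "peak_capacity", om$peak_capacity$per_genotype))
    f <- file.path(outdir, "flux_metrics.csv")
    write.csv(metr, f, row.names = FALSE); note_file("flux_metrics", f)
    ctr <- rbind(
      cbind(metric = "glycolytic_reserve", gr$contrast),
      cbind(metric = "dg2_slope", dg$contrast),
      cbind(metric = "atp_linked", om$atp_linked$contrast),
      cbind(metric = "respiratory_reserve",
            om$respiratory_reserve$contrast),
      cbind(metric = "peak_capacity", om$peak_capacity$contrast))
    f2 <- file.path(outdir, "flux_contrasts.csv")
    write.csv(ctr, f2, row.names = FALSE); note_file("flux_contrasts", f2)
  })

  if ("transcriptome" %in% stages) run_stage("transcriptome", function() {
    need_input("transcriptome", "counts",
               paste0(paths$counts, "_counts.tsv"))
    cm <- simulate_counts(count_sim_spec(n_genes = 400,
                                         n_samples_per_group = 4,
                                         seed = seed + 3L))
    tp <- tpm(cm)
    f <- file.path(outdir, "tpm.tsv")
    write.table(data.frame(gene = rownames(tp), tp, check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    note_file("tpm", f)
    qc <- pca_kmeans(tp, k = 2, seed = seed)
    f2 <- file.path(outdir, "pca_clusters.csv")
    write.csv(data.frame(sample = names(qc$clusters),
                         cluster = qc$clusters,
                         pc1 = qc$scores[, 1], pc2 = qc$scores[, 2]),
              f2, row.names = FALSE)
    note_file("pca_clusters", f2)
    deg <- de_stub(cm)
    hc <- intersect_degs(deg, deg,
                         alpha = config$transcriptome$alpha %||% 0.05)
    f3 <- file.path(outdir, "hc_degs.tsv")
    write.table(hc$genes, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    note_file("hc_degs", f3)
  })

  manifest$warnings <- warn
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

config_md5 <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  file_md5(tf)
}

#' Write the packaged toy fixtures
#'
#' Generates the small datasets used in documentation and tests: a toy
#' survival table, a 5-ROI trace set, a 2-batch flux plate and a 50-gene
#' count matrix, all derived from one seed.
#'
#' @param seed root seed.
#' @param dir output directory.
#' @return named vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genos <- data.frame(label = c("control", "tau"),
                      alpha = c(0.002, 0.002), beta = c(0.08, 0.16),
                      n_flies = c(60L, 60L))
  st <- simulate_lifespans(lifespan_sim_spec(genos, seed = seed))
  f1 <- write_survival_csv(st, file.path(dir, "census.csv"))
  ts <- simulate_traces(trace_sim_spec(n_rois = 5, seed = seed + 1L))
  f2 <- write_trace_csv(ts, file.path(dir, "traces.csv"))
  fx <- simulate_flux_plate(
    do.call(flux_sim_spec, c(default_flux_means(),
                             list(n_wells_per_genotype = 4,
                                  n_batches = 2, seed = seed + 2L))))
  f3 <- write_flux_csv(fx, file.path(dir, "flux.csv"))
  cm <- simulate_counts(count_sim_spec(n_genes = 50,
                                       n_samples_per_group = 3,
                                       seed = seed + 3L))
  f4 <- write_counts_tsv(cm, file.path(dir, "toy"))
  paths <- c(census = f1, traces = f2, flux = f3, f4)
  invisible(paths)
}
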