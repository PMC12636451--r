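#' Specify a negative-binomial count-matrix simulation
#'
#' Two-group bulk RNA-seq style counts: per-gene baseline means drawn
#' log-normally, a fraction of genes differentially expressed with
#' log2 fold changes ~ N(0, lfc_sd) applied to the treatment group, and
#' NB sampling with a common dispersion. Gene lengths are uniform over
#' `length_range` (bp).
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group replicates per group (two groups).
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion*mu^2.
#' @param frac_deg fraction of genes with a true effect, in `[0, 1]`.
#' @param lfc_sd SD of true log2 fold changes (log2 units).
#' @param min_abs_lfc when > 0, DEG magnitudes are drawn as
#'   `min_abs_lfc + |N(0, lfc_sd)|` with random sign, bounding true
#'   effects away from zero (useful for recovery benchmarks); at the
#'   default 0, effects are plain `N(0, lfc_sd)`.
#' @param base_mean_min floor on per-gene baseline means (counts).
#' @param length_range gene-length range in bp, `c(min, max)`.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   per-gene baseline mean (defaults give a realistic spread of depths).
#' @param seed integer RNG seed.
#' @return object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000,
                           n_samples_per_group = 6,
                           dispersion = 0.05,
                           frac_deg = 0.2,
                           lfc_sd = 1,
                           min_abs_lfc = 0,
                           base_mean_min = 0,
                           length_range = c(500, 5000),
                           base_mean_meanlog = 4,
                           base_mean_sdlog = 1.5,
                           seed = 1L) {
  check_count(n_genes, "n_genes")
  check_count(n_samples_per_group, "n_samples_per_group")
  check_number(dispersion, "dispersion", lower = 0)
  check_number(frac_deg, "frac_deg", lower = 0, upper = 1,
               allow_equal_lower = TRUE)
  check_number(lfc_sd, "lfc_sd", lower = 0, allow_equal_lower = TRUE)
  check_number(min_abs_lfc, "min_abs_lfc", lower = 0, allow_equal_lower = TRUE)
  check_number(base_mean_min, "base_mean_min", lower = 0,
               allow_equal_lower = TRUE)
  stop_if(length(length_range) != 2L || any(length_range < 1),
          "'length_range' must be c(min, max) with min >= 1 bp")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 dispersion = dispersion, frac_deg = frac_deg,
                 lfc_sd = lfc_sd, min_abs_lfc = min_abs_lfc,
                 base_mean_min = base_mean_min,
                 length_range = length_range,
                 base_mean_meanlog = base_mean_meanlog,
                 base_mean_sdlog = base_mean_sdlog,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate an NB count matrix with ground-truth DEG labels
#'
#' @param spec a [count_sim_spec()].
#' @return a `count_matrix`: list with `counts` (gene x sample integer
#'   matrix), `lengths` (named bp vector), `groups` (sample -> group
#'   factor), and `truth` (data.frame gene, is_deg, true_lfc, direction).
#' @export
simulate_counts <- function(spec) {
  stop_if(!inherits(spec, "count_sim_spec"), "need a count_sim_spec")
  with_seed(spec$seed, {
    genes <- sprintf("g%05d", seq_len(spec$n_genes))
    lengths <- setNames(round(runif(spec$n_genes, spec$length_range[1],
                                    spec$length_range[2])), genes)
    base_mu <- pmax(rlnorm(spec$n_genes, spec$base_mean_meanlog,
                           spec$base_mean_sdlog), spec$base_mean_min)
    n_deg <- round(spec$frac_deg * spec$n_genes)
    is_deg <- c(rep(TRUE, n_deg), rep(FALSE, spec$n_genes - n_deg))
    raw_lfc <- rnorm(spec$n_genes, 0, spec$lfc_sd)
    if (spec$min_abs_lfc > 0)
      raw_lfc <- sign(raw_lfc + (raw_lfc == 0)) *
        (spec$min_abs_lfc + abs(raw_lfc))
    lfc <- ifelse(is_deg, raw_lfc, 0)
    ns <- spec$n_samples_per_group
    groups <- factor(rep(c("control", "treatment"), each = ns))
    samples <- paste0(rep(c("ctl", "trt"), each = ns), seq_len(ns))
    size <- 1 / spec$dispersion
    counts <- matrix(0L, spec$n_genes, 2L * ns,
                     dimnames = list(genes, samples))
    for (j in seq_len(2L * ns)) {
      mu <- if (groups[j] == "treatment") base_mu * 2^lfc else base_mu
      counts[, j] <- rnbinom(spec$n_genes, mu = mu, size = size)
    }
    truth <- data.frame(gene = genes, is_deg = is_deg, true_lfc = lfc,
                        direction = ifelse(!is_deg, "none",
                                           ifelse(lfc >= 0, "up", "down")),
                        stringsAsFactors = FALSE)
    structure(list(counts = counts, lengths = lengths,
                   groups = setNames(groups, samples), truth = truth),
              class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d samples (%s); %d true DEGs\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$groups), collapse = " vs "),
              sum(x$truth$is_deg)))
  invisible(x)
}

#' Write / read counts and gene lengths as TSV
#'
#' `write_counts_tsv` writes `<stem>_counts.tsv` (gene column + samples)
#' and `<stem>_lengths.tsv` (gene, length_bp). The reader restores a
#' `count_matrix` (without truth labels) given the sample -> group map.
#'
#' @param x a `count_matrix`.
#' @param stem file stem for the two TSVs.
#' @param groups named factor/character mapping sample names to groups
#'   (reader only).
#' @return file paths invisibly (writer); a `count_matrix` (reader).
#' @export
write_counts_tsv <- function(x, stem) {
  cf <- paste0(stem, "_counts.tsv")
  lf <- paste0(stem, "_lengths.tsv")
  write.table(data.frame(gene = rownames(x$counts), x$counts,
                         check.names = FALSE),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(x$lengths), length_bp = x$lengths),
              lf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cf, lengths = lf))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(stem, groups) {
  cts <- read.delim(paste0(stem, "_counts.tsv"), check.names = FALSE)
  lens <- read.delim(paste0(stem, "_lengths.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene
  structure(list(counts = m,
                 lengths = setNames(lens$length_bp, lens$gene),
                 groups = factor(groups[colnames(m)]),
                 truth = NULL),
            class = "count_matrix")
}
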