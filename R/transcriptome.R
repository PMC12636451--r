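# Transcriptome summary layer downstream of DE testing: TPM, PCA/k-means
# QC, dual-control DEG concordance, Fisher over-representation scoring,
# and 2^-ddCt qPCR summaries. DE testing itself (DESeq2-style NB fits) is
# out of scope; DEG tables are ingested, and de_stub() exists only so
# end-to-end synthetic runs are possible.

#' Transcripts per million
#'
#' RPK = count / (gene length in kb); TPM = (RPK / sum of RPK) * 1e6 per
#' sample, so each sample's TPM column sums to one million.
#'
#' @param counts gene x sample matrix of nonnegative counts, or a
#'   `count_matrix` (lengths taken from it).
#' @param lengths named per-gene lengths in bp (>= 1), required when
#'   `counts` is a bare matrix.
#' @return TPM matrix with the dimensions of `counts`.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  stop_if(is.null(lengths), "gene lengths required")
  lengths <- lengths[rownames(counts)]
  stop_if(anyNA(lengths), "lengths missing for some genes")
  stop_if(any(lengths < 1), "gene lengths must be >= 1 bp")
  stop_if(any(counts < 0), "counts must be nonnegative")
  rpk <- counts / (lengths / 1000)
  tot <- colSums(rpk)
  stop_if(any(tot <= 0), "a sample has zero total RPK")
  sweep(rpk, 2, tot, "/") * 1e6
}

#' PCA and k-means clustering QC of a TPM matrix
#'
#' Genes with zero expression across all samples are removed, each
#' remaining gene is z-scored across samples (constant genes are dropped
#' as zero-variance), samples are projected by PCA, and k-means (fixed
#' seed, multiple restarts, best inertia) labels the samples.
#'
#' @param tpm_mat gene x sample TPM (or otherwise normalized) matrix.
#' @param k number of clusters (default 2).
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts (default 50).
#' @return list with `scores` (sample x PC coordinates),
#'   `variance_fraction` (per PC, sums to 1), `clusters` (named integer
#'   labels), `n_genes_used`, `n_genes_dropped`.
#' @export
pca_kmeans <- function(tpm_mat, k = 2, seed = 1L, nstart = 50) {
  stop_if(ncol(tpm_mat) < 2L, "at least 2 samples required")
  stop_if(ncol(tpm_mat) < k, "fewer samples than clusters")
  nz <- rowSums(tpm_mat != 0) > 0
  m <- tpm_mat[nz, , drop = FALSE]
  sds <- apply(m, 1, sd)
  keep <- sds > 0
  z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
    sds[keep]
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  cl <- with_seed(seed, kmeans(t(z), centers = k, nstart = nstart))
  list(scores = pc$x, variance_fraction = vf,
       clusters = setNames(cl$cluster, colnames(tpm_mat)),
       n_genes_used = sum(keep), n_genes_dropped = nrow(tpm_mat) - sum(keep))
}

#' Validate a DEG table
#'
#' @param df data.frame with columns gene, log2fc, p, padj (BH-adjusted).
#' @param contrast optional contrast label attached as attribute.
#' @return the data.frame with class `deg_table`.
#' @export
as_deg_table <- function(df, contrast = NULL) {
  need <- c("gene", "log2fc", "p", "padj")
  stop_if(!is.data.frame(df) || !all(need %in% names(df)),
          "DEG table needs columns gene, log2fc, p, padj")
  stop_if(any(df$padj < 0 | df$padj > 1, na.rm = TRUE),
          "padj must lie in [0, 1]")
  stop_if(anyDuplicated(df$gene) > 0, "duplicate gene ids")
  attr(df, "contrast") <- contrast
  structure(df, class = c("deg_table", "data.frame"))
}

#' Dual-control DEG intersection with directional concordance
#'
#' Shared DEGs are genes significant (padj < alpha, strict) against both
#' controls; concordant genes have the same log2 fold-change sign in both
#' contrasts. Only concordant genes enter the high-confidence set, split
#' into up- and downregulated.
#'
#' @param table_a,table_b `deg_table`s over a shared gene universe.
#' @param alpha significance threshold on adjusted p (default 0.05,
#'   strict inequality).
#' @return a `hc_deg_set`: list with `genes` (data.frame gene, direction,
#'   log2fc_a, log2fc_b), `n_shared`, `n_concordant`, `n_discordant`,
#'   `n_up`, `n_down`, `concordance` (fraction of shared).
#' @export
intersect_degs <- function(table_a, table_b, alpha = 0.05) {
  stop_if(!inherits(table_a, "deg_table") || !inherits(table_b, "deg_table"),
          "inputs must be deg_table objects")
  stop_if(length(intersect(table_a$gene, table_b$gene)) == 0L,
          "gene universes are disjoint")
  sig_a <- table_a[!is.na(table_a$padj) & table_a$padj < alpha, ]
  sig_b <- table_b[!is.na(table_b$padj) & table_b$padj < alpha, ]
  shared <- intersect(sig_a$gene, sig_b$gene)
  la <- setNames(sig_a$log2fc, sig_a$gene)[shared]
  lb <- setNames(sig_b$log2fc, sig_b$gene)[shared]
  conc <- sign(la) == sign(lb) & sign(la) != 0
  genes <- data.frame(gene = shared[conc],
                      direction = ifelse(la[conc] > 0, "up", "down"),
                      log2fc_a = unname(la[conc]),
                      log2fc_b = unname(lb[conc]),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 n_shared = length(shared),
                 n_concordant = sum(conc),
                 n_discordant = sum(!conc),
                 n_up = sum(genes$direction == "up"),
                 n_down = sum(genes$direction == "down"),
                 concordance = if (length(shared))
                   sum(conc) / length(shared) else NA_real_,
                 alpha = alpha),
            class = "hc_deg_set")
}

#' @export
print.hc_deg_set <- function(x, ...) {
  cat(sprintf("High-confidence DEG set: %d shared, %d concordant (%.1f%%; %d up, %d down), %d discordant\n",
              x$n_shared, x$n_concordant, 100 * x$concordance, x$n_up,
              x$n_down, x$n_discordant))
  invisible(x)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Builds the 2x2 table over the universe (a = overlap, b = set only,
#' c = DEG only, d = neither), computes the two-sided Fisher exact p and
#' the sample (cross-product) odds ratio ad/bc. A Haldane correction of
#' 0.5 per cell is applied only when a zero cell occurs (flagged). Counts
#' may be given directly instead of gene vectors.
#'
#' @param deg_genes character vector of DEGs, or `a` when using counts.
#' @param set_genes character vector for the annotation set, or `NULL`.
#' @param universe character vector of all genes, or `NULL`.
#' @param counts optional named numeric `c(a=, b=, c=, d=)` to build the
#'   table from printed counts directly.
#' @return an `enrichment_result`: list with `table` (a, b, c, d),
#'   `odds_ratio`, `p`, `padj` (NA until [enrich_sets()] adjusts),
#'   `score` (NA until adjusted), `haldane`.
#' @export
enrich <- function(deg_genes, set_genes = NULL, universe = NULL,
                   counts = NULL) {
  if (is.null(counts)) {
    stop_if(length(universe) == 0L, "empty universe")
    stop_if(!all(deg_genes %in% universe) || !all(set_genes %in% universe),
            "both sets must be subsets of the universe")
    a <- length(intersect(deg_genes, set_genes))
    b <- length(setdiff(set_genes, deg_genes))
    cc <- length(setdiff(deg_genes, set_genes))
    d <- length(universe) - a - b - cc
  } else {
    stop_if(!all(c("a", "b", "c", "d") %in% names(counts)),
            "'counts' needs named entries a, b, c, d")
    a <- counts["a"]; b <- counts["b"]; cc <- counts["c"]; d <- counts["d"]
  }
  m <- matrix(c(a, b, cc, d), 2, 2)
  p <- fisher.test(m)$p.value
  haldane <- any(m == 0)
  if (haldane) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(table = c(a = unname(a), b = unname(b), c = unname(cc),
                           d = unname(d)),
                 odds_ratio = unname(or), p = unname(p), padj = NA_real_,
                 score = NA_real_, haldane = haldane),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: overlap %d | OR %.2f | p %.3g | padj %s | score %s%s\n",
              x$table["a"], x$odds_ratio, x$p,
              if (is.na(x$padj)) "-" else format(x$padj, digits = 3),
              if (is.na(x$score)) "-" else format(x$score, digits = 3),
              if (x$haldane) " [Haldane 0.5]" else ""))
  invisible(x)
}

#' Enrichment across a collection of gene sets with BH and scoring
#'
#' Runs [enrich()] for every set, BH-adjusts the Fisher p-values across
#' the collection, computes the enrichment score OR * -log10(padj), and
#' ranks by [rank_by_score()].
#'
#' @param deg_genes character vector of DEGs.
#' @param sets named list of gene-set character vectors.
#' @param universe gene universe (default: union of DEGs and all sets).
#' @return data.frame (ranked): set, a, b, c, d, odds_ratio, p, padj,
#'   score.
#' @export
enrich_sets <- function(deg_genes, sets, universe = NULL) {
  stop_if(length(sets) == 0L || is.null(names(sets)),
          "'sets' must be a named list")
  universe <- universe %||% unique(c(deg_genes, unlist(sets)))
  res <- lapply(sets, function(s)
    enrich(deg_genes, intersect(s, universe), universe))
  padj <- bh_adjust(vapply(res, `[[`, numeric(1), "p"))
  df <- data.frame(set = names(sets),
                   t(vapply(res, `[[`, numeric(4), "table")),
                   odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
                   p = vapply(res, `[[`, numeric(1), "p"),
                   padj = padj, stringsAsFactors = FALSE)
  df$score <- df$odds_ratio * -log10(pmax(df$padj, .Machine$double.xmin))
  df$score[df$padj >= 1] <- 0
  rank_by_score(df)
}

#' Rank enrichment results by score
#'
#' Descending enrichment score (OR * -log10 padj); ties broken by smaller
#' padj, then larger overlap.
#'
#' @param results data.frame with columns score, padj, a (overlap).
#' @return the reordered data.frame with a `rank` column.
#' @export
rank_by_score <- function(results) {
  stop_if(!all(c("score", "padj", "a") %in% names(results)),
          "need columns score, padj, a")
  ord <- order(-results$score, results$padj, -results$a)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged first; dCt = Ct(target) -
#' Ct(housekeeping) per sample; ddCt = dCt - mean dCt of the reference
#' group; relative expression = 2^-ddCt.
#'
#' @param ct data.frame with columns sample, group, gene, ct (one row per
#'   technical replicate).
#' @param housekeeping housekeeping gene name (e.g. "rp49").
#' @param reference_group reference group label.
#' @return data.frame: sample, group, gene, dct, ddct, rel_expr.
#' @export
ddct <- function(ct, housekeeping, reference_group) {
  need <- c("sample", "group", "gene", "ct")
  stop_if(!all(need %in% names(ct)), "need columns sample, group, gene, ct")
  stop_if(!housekeeping %in% ct$gene,
          sprintf("housekeeping gene '%s' not measured", housekeeping))
  stop_if(!reference_group %in% ct$group, "reference group not present")
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  hk <- agg[agg$gene == housekeeping, c("sample", "ct")]
  names(hk)[2] <- "ct_hk"
  tg <- agg[agg$gene != housekeeping, ]
  stop_if(!all(tg$sample %in% hk$sample),
          "housekeeping measurements missing for some samples")
  tg <- merge(tg, hk, by = "sample")
  tg$dct <- tg$ct - tg$ct_hk
  out <- do.call(rbind, lapply(split(tg, tg$gene), function(sub) {
    ref <- mean(sub$dct[sub$group == reference_group])
    sub$ddct <- sub$dct - ref
    sub$rel_expr <- 2^(-sub$ddct)
    sub
  }))
  rownames(out) <- NULL
  out[, c("sample", "group", "gene", "dct", "ddct", "rel_expr")]
}

#' Stub differential-expression step for synthetic end-to-end runs
#'
#' Two-sample Welch t-test on log2(TPM + 1) per gene with BH adjustment.
#' This is a deliberately simple placeholder so the DEG-intersection and
#' enrichment layers can be exercised on simulated counts; it is not a
#' negative-binomial DE method and should not be used on real data.
#'
#' @param cm a `count_matrix` (see [simulate_counts()]).
#' @return a `deg_table` (gene, log2fc, p, padj).
#' @export
de_stub <- function(cm) {
  stop_if(!inherits(cm, "count_matrix"), "need a count_matrix")
  x <- log2(tpm(cm) + 1)
  g <- cm$groups[colnames(x)]
  lv <- levels(g)
  stop_if(length(lv) != 2L, "exactly two groups required")
  a <- x[, g == lv[1], drop = FALSE]
  b <- x[, g == lv[2], drop = FALSE]
  lfc <- rowMeans(b) - rowMeans(a)
  p <- vapply(seq_len(nrow(x)), function(i) {
    if (sd(a[i, ]) == 0 && sd(b[i, ]) == 0) return(1)
    tryCatch(stats::t.test(b[i, ], a[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  as_deg_table(data.frame(gene = rownames(x), log2fc = lfc, p = p,
                          padj = bh_adjust(p)),
               contrast = paste(lv[2], "vs", lv[1]))
}

#' Read / write DEG tables as TSV
#'
#' @param path TSV with columns gene, log2fc, p, padj.
#' @param x a `deg_table` (writer).
#' @param contrast contrast label (reader).
#' @return a `deg_table` (reader); `path` invisibly (writer).
#' @export
read_deg_tsv <- function(path, contrast = NULL) {
  as_deg_table(read.delim(path), contrast = contrast)
}

#' @rdname read_deg_tsv
#' @export
write_deg_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stop_if(length(parts) < 3L, "malformed GMT line")
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Read an ortholog map with a confidence filter
#'
#' Two-column mapping (e.g. fly gene -> human gene) with a numeric
#' confidence column; rows below `min_confidence` are dropped.
#'
#' @param path TSV with columns from, to, confidence.
#' @param min_confidence keep rows with confidence >= this (default 0).
#' @return data.frame from, to, confidence.
#' @export
read_ortholog_map <- function(path, min_confidence = 0) {
  df <- read.delim(path)
  stop_if(!all(c("from", "to", "confidence") %in% names(df)),
          "ortholog map needs columns from, to, confidence")
  df[df$confidence >= min_confidence, , drop = FALSE]
}
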