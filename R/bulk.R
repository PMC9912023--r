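# Per-gene labeling rates, SD-based selection, sample comparison,
# consensus and PCA-input gene sets for bulk samples.

#' Per-gene labeling statistics for one bulk sample
#'
#' For each gene, counts quality-passing base calls at non-blacklisted
#' transcript-strand T positions (reference `T` for plus-strand genes,
#' reference `A` for minus-strand genes) and the subset showing the
#' conversion base (`C` / `G` respectively). The labeling rate is
#' `converted_observations / t_observations` in `observation` mode
#' (coverage-weighted, the standard nucleotide-conversion estimator) or
#' `converted_sites / t_sites` in `site` mode (fraction of covered T
#' positions showing at least one conversion). Genes with a zero
#' denominator get a missing rate and are excluded from mean/SD
#' computations downstream; reads overlapping multiple genes are excluded
#' from all of them.
#'
#' @param reads read table.
#' @param reference [Biostrings::DNAStringSet].
#' @param genes gene table (see [read_gene_models()]).
#' @param blacklist optional blacklist from [build_blacklist()].
#' @param min_quality minimum Phred base quality (default 20).
#' @param mode `"observation"` (default) or `"site"`.
#' @param discard_antisense drop antisense reads before counting.
#' @param sample_id label stored on the result.
#' @return `data.table` of class `gene_labeling_stats` with one row per
#'   gene: `gene_id`, `t_observations`, `converted_observations`,
#'   `t_sites`, `converted_sites`, `rate`, `read_count`.
#' @export
gene_labeling_stats <- function(reads, reference, genes, blacklist = NULL,
                                min_quality = 20L,
                                mode = c("observation", "site"),
                                discard_antisense = TRUE,
                                sample_id = "sample") {
  mode <- match.arg(mode)
  genes <- as.data.table(genes)
  assigned <- assign_reads_to_genes(reads, genes,
                                    discard_antisense = discard_antisense)
  pu <- build_pileup(assigned, reference, min_quality = min_quality)
  pu <- exclude_blacklisted(pu, blacklist)
  setkey(pu, contig, pos)
  read_counts <- assigned[, .(read_count = .N), by = gene_id]

  per_gene <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    tbase <- if (g$strand == "+") "T" else "A"
    cbase <- if (g$strand == "+") "C" else "G"
    sub <- pu[.(g$contig), nomatch = NULL][pos >= g$start & pos < g$end &
                                             ref == tbase]
    conv <- sub[[cbase]]
    per_gene[[i]] <- data.table(
      gene_id = g$gene_id,
      t_observations = sum(sub$coverage),
      converted_observations = sum(conv),
      t_sites = nrow(sub),
      converted_sites = sum(conv > 0L)
    )
  }
  out <- rbindlist(per_gene)
  out <- merge(out, read_counts, by = "gene_id", all.x = TRUE)
  out[is.na(read_count), read_count := 0L]
  if (mode == "observation") {
    out[, rate := ifelse(t_observations > 0L,
                         converted_observations / t_observations, NA_real_)]
  } else {
    out[, rate := ifelse(t_sites > 0L,
                         converted_sites / t_sites, NA_real_)]
  }
  setorder(out, gene_id)
  setattr(out, "mode", mode)
  setattr(out, "sample_id", sample_id)
  setattr(out, "discarded", attr(assigned, "discarded"))
  setattr(out, "class", c("gene_labeling_stats", class(out)))
  out[]
}

#' Select highly labeled genes by an SD threshold
#'
#' Computes mean and standard deviation (n-1 sample estimator) over all
#' non-missing gene rates and returns the genes whose rate strictly exceeds
#' `mean + k * sd`. With all rates identical the SD is 0 and no rate
#' strictly exceeds the mean, so the set is empty.
#'
#' @param stats table from [gene_labeling_stats()].
#' @param k SD multiplier (default 5, the selection used for
#'   dissociation-response gene calling; 1 for the PCA input filter).
#' @param sample_id label; defaults to the one stored on `stats`.
#' @return list of class `labeled_gene_set` with elements `sample_id`,
#'   `mean_rate`, `sd_rate`, `k`, `threshold`, `genes` (character vector),
#'   `n_scored`.
#' @export
select_labeled_genes <- function(stats, k = 5,
                                 sample_id = attr(stats, "sample_id")) {
  st <- as.data.table(stats)
  r <- st$rate[!is.na(st$rate)]
  if (length(r) < 2L)
    stop("need at least 2 genes with non-missing rates")
  m <- mean(r)
  s <- stats::sd(r)
  thr <- m + k * s
  genes <- st[!is.na(rate) & rate > thr, gene_id]
  structure(list(sample_id = sample_id %||% "sample", mean_rate = m,
                 sd_rate = s, k = k, threshold = thr,
                 genes = sort(genes), n_scored = length(r)),
            class = "labeled_gene_set")
}

#' @export
print.labeled_gene_set <- function(x, ...) {
  cat(sprintf(
    "<labeled_gene_set> sample=%s  %d/%d genes above mean+%g*SD (thr %.4g)\n",
    x$sample_id, length(x$genes), x$n_scored, x$k, x$threshold))
  invisible(x)
}

#' Classify genes between two bulk samples
#'
#' Each gene scored in both samples is classified by membership of the two
#' per-sample labeled gene sets (`high_in_A_only`, `high_in_B_only`,
#' `high_in_both`, `background`). Genes missing a rate in either sample are
#' reported with class `unscored`, never silently dropped.
#'
#' @param stats_a,stats_b per-sample tables from [gene_labeling_stats()],
#'   computed with the same mode.
#' @param k SD multiplier passed to [select_labeled_genes()] per sample.
#' @return list of class `sample_comparison` with the per-sample sets and a
#'   `classification` table (`gene_id`, `rate_a`, `rate_b`, `class`).
#' @export
compare_samples <- function(stats_a, stats_b, k = 5) {
  a <- as.data.table(stats_a)[, .(gene_id, rate_a = rate)]
  b <- as.data.table(stats_b)[, .(gene_id, rate_b = rate)]
  if (!length(intersect(a$gene_id, b$gene_id)))
    stop("samples share no genes")
  set_a <- select_labeled_genes(stats_a, k = k, sample_id = "A")
  set_b <- select_labeled_genes(stats_b, k = k, sample_id = "B")
  cl <- merge(a, b, by = "gene_id", all = TRUE)
  in_a <- cl$gene_id %in% set_a$genes
  in_b <- cl$gene_id %in% set_b$genes
  cl[, class := fifelse(is.na(rate_a) | is.na(rate_b), "unscored",
                fifelse(in_a & in_b, "high_in_both",
                fifelse(in_a, "high_in_A_only",
                fifelse(in_b, "high_in_B_only", "background"))))]
  setorder(cl, gene_id)
  structure(list(set_a = set_a, set_b = set_b, classification = cl[]),
            class = "sample_comparison")
}

#' Consensus of per-sample labeled gene sets
#'
#' Returns genes selected in at least `min_samples` of the supplied
#' per-sample sets — the notion behind a "core" dissociation-response set
#' shared across replicates.
#'
#' @param sets list of `labeled_gene_set` objects (or plain character
#'   vectors of gene ids).
#' @param min_samples minimum number of sets a gene must belong to.
#' @return sorted character vector of gene ids.
#' @export
consensus_genes <- function(sets, min_samples = 3L) {
  if (min_samples > length(sets))
    stop("min_samples exceeds the number of samples")
  ids <- lapply(sets, function(s) if (is.character(s)) s else s$genes)
  tab <- table(unlist(ids, use.names = FALSE))
  sort(names(tab)[tab >= min_samples])
}

#' Rate matrix for external PCA
#'
#' Builds the genes-by-samples labeling-rate matrix restricted to genes
#' with a non-missing rate in every sample and a rate strictly above
#' `mean + k * sd` in at least one sample (a noise filter). The PCA itself
#' is left to external tools.
#'
#' @param stats_list list of per-sample tables from
#'   [gene_labeling_stats()].
#' @param k SD multiplier for the per-sample filter (default 1).
#' @return numeric matrix (genes x samples); zero rows with a warning when
#'   no gene qualifies.
#' @export
pca_input_matrix <- function(stats_list, k = 1) {
  if (length(stats_list) < 2L) stop("need at least 2 samples")
  nm <- names(stats_list) %||% paste0("sample", seq_along(stats_list))
  if (is.null(names(stats_list))) names(stats_list) <- nm
  rates <- lapply(stats_list, function(st)
    as.data.table(st)[, .(gene_id, rate)])
  wide <- Reduce(function(x, y) merge(x, y, by = "gene_id", all = TRUE),
                 Map(function(r, n) setnames(r, "rate", n), rates, nm))
  mat <- as.matrix(wide[, -1L, with = FALSE])
  rownames(mat) <- wide$gene_id
  complete <- stats::complete.cases(mat)
  thr <- vapply(stats_list, function(st) {
    s <- select_labeled_genes(st, k = k)
    s$threshold
  }, numeric(1L))
  above <- sweep(mat, 2L, thr, ">")
  keep <- complete & rowSums(above, na.rm = TRUE) > 0L
  out <- mat[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("no gene passes the PCA input filter")
    return(out)
  }
  out[order(rownames(out)), , drop = FALSE]
}
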