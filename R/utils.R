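#' Numeric thresholds used across the pipeline
#'
#' Central container for every tunable threshold. Defaults follow the assay's
#' published filtering rules: base quality >= 20 (Q20, 99% call accuracy) for
#' any substitution used downstream; positions with non-reference fraction
#' strictly above 25% or coverage strictly below 10 blacklisted; bulk gene
#' selection at mean + 5 SD (PCA input at 1 SD); single-cell molecules
#' labeled at >= 2 distinct conversion events; the cell-type gene summary
#' requires >= 250 units with >= 10% labeled; the removal report lists genes
#' with >= 3 removed reads making up >= 5% of the gene's reads; consensus
#' genes must be selected in >= 3 samples.
#'
#' @param min_quality minimum Phred base quality for a base call to count.
#' @param max_alt_frac blacklist a position when non-reference fraction is
#'   strictly greater than this.
#' @param min_coverage blacklist a position when quality-passing coverage is
#'   strictly below this.
#' @param k_sd_select SD multiplier for labeled-gene selection.
#' @param k_sd_pca SD multiplier for the PCA input gene filter.
#' @param sc_min_conversions distinct conversion events needed to flag a UMI
#'   as labeled.
#' @param sc_min_units minimum units (UMIs or reads) per gene/cell type in
#'   the labeling summary.
#' @param sc_min_frac minimum labeled fraction per gene/cell type in the
#'   labeling summary.
#' @param report_min_removed minimum removed reads for a gene to appear in
#'   the removal report.
#' @param report_min_frac minimum removed read fraction for the removal
#'   report.
#' @param consensus_min_samples minimum number of samples a gene must be
#'   selected in to enter the consensus set.
#' @return A named list of class `threshold_config`.
#' @export
threshold_config <- function(min_quality = 20L,
                             max_alt_frac = 0.25,
                             min_coverage = 10L,
                             k_sd_select = 5,
                             k_sd_pca = 1,
                             sc_min_conversions = 2L,
                             sc_min_units = 250L,
                             sc_min_frac = 0.10,
                             report_min_removed = 3L,
                             report_min_frac = 0.05,
                             consensus_min_samples = 3L) {
  cfg <- list(
    min_quality = as.integer(min_quality),
    max_alt_frac = as.numeric(max_alt_frac),
    min_coverage = as.integer(min_coverage),
    k_sd_select = as.numeric(k_sd_select),
    k_sd_pca = as.numeric(k_sd_pca),
    sc_min_conversions = as.integer(sc_min_conversions),
    sc_min_units = as.integer(sc_min_units),
    sc_min_frac = as.numeric(sc_min_frac),
    report_min_removed = as.integer(report_min_removed),
    report_min_frac = as.numeric(report_min_frac),
    consensus_min_samples = as.integer(consensus_min_samples)
  )
  fracs <- c(cfg$max_alt_frac, cfg$sc_min_frac, cfg$report_min_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  ints <- c(cfg$min_quality, cfg$min_coverage, cfg$sc_min_conversions,
            cfg$sc_min_units, cfg$report_min_removed,
            cfg$consensus_min_samples)
  if (any(ints < 0L)) stop("integer thresholds must be >= 0")
  structure(cfg, class = "threshold_config")
}

# Phred string -> integer vector (offset 33)
phred_ints <- function(qual) utf8ToInt(qual) - 33L

BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

# deterministic RNG scope
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as a plain TSV, deterministically
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
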