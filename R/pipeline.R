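# End-to-end bulk and single-cell runs: resolve inputs, execute the stage
# chain, write every report plus a serialized config and a JSON summary of
# counts at each filter stage.

resolve_inputs <- function(alignments, reference, annotation) {
  reads <- if (is.character(alignments)) read_alignments(alignments)
           else as.data.table(alignments)
  ref <- if (is.character(reference)) read_fasta(reference) else reference
  # FASTA descriptions may carry extra words; keep the first token
  names(ref) <- sub("\\s.*$", "", names(ref))
  genes <- if (is.character(annotation)) read_gene_models(annotation)
           else as.data.table(annotation)
  list(reads = reads, reference = ref, genes = genes)
}

write_run_config <- function(out_dir, params) {
  params$dissoscan_version <- as.character(utils::packageVersion("dissoscan"))
  yaml::write_yaml(params, file.path(out_dir, "config.yaml"))
}

#' Run the full bulk pipeline
#'
#' Executes pileup, blacklist, conversion calling, substitution spectrum,
#' per-gene labeling rates and SD-based gene selection, writing all outputs
#' to `out_dir`: `rates.tsv` (per-gene statistics with a `selected` flag),
#' `spectrum.tsv`, `blacklist.bed` / `blacklist.tsv`, `summary.json`
#' (counts at every filter stage) and `config.yaml` (resolved parameters
#' and package version). Outputs are deterministic for fixed inputs.
#'
#' @param alignments SAM/BAM path or an in-memory read table.
#' @param reference FASTA path or [Biostrings::DNAStringSet].
#' @param annotation GTF path or gene table.
#' @param out_dir output directory (created).
#' @param config a [threshold_config()].
#' @param mode labeling-rate mode, `"observation"` or `"site"`.
#' @param sample_id sample label used in outputs.
#' @param max_missing_md_frac abort when more than this fraction of reads
#'   lacks an MD tag.
#' @return invisibly, a list with `stats`, `selected`, `blacklist`,
#'   `spectrum`, `summary`.
#' @export
run_bulk <- function(alignments, reference, annotation, out_dir,
                     config = threshold_config(),
                     mode = c("observation", "site"),
                     sample_id = "sample",
                     max_missing_md_frac = 0.2) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- resolve_inputs(alignments, reference, annotation)
  reads <- inp$reads
  n_reads <- nrow(reads)
  n_missing_md <- sum(is.na(reads$md) | reads$md == "")
  if (n_reads > 0L && n_missing_md / n_reads > max_missing_md_frac)
    stop(sprintf("%d/%d reads lack MD tags (limit %.0f%%)",
                 n_missing_md, n_reads, 100 * max_missing_md_frac))
  if (n_reads == 0L) warning("no mapped reads in input")

  pileup <- build_pileup(reads, inp$reference,
                         min_quality = config$min_quality)
  blacklist <- build_blacklist(pileup, max_alt_frac = config$max_alt_frac,
                               min_coverage = config$min_coverage)
  spectrum <- substitution_spectrum(reads, inp$reference,
                                    blacklist = blacklist,
                                    min_quality = config$min_quality,
                                    pileup = pileup)
  mm <- suppressWarnings(extract_mismatches(reads))
  n_events_prefilter <- nrow(mm)
  n_events_q <- nrow(mm[qual >= config$min_quality])
  stats <- gene_labeling_stats(reads, inp$reference, inp$genes,
                               blacklist = blacklist,
                               min_quality = config$min_quality,
                               mode = mode, sample_id = sample_id)
  scored <- sum(!is.na(stats$rate))
  sel <- NULL
  selected_ids <- character(0)
  if (scored >= 2L) {
    sel <- select_labeled_genes(stats, k = config$k_sd_select,
                                sample_id = sample_id)
    selected_ids <- sel$genes
  }
  out_stats <- copy(as.data.table(stats))
  out_stats[, selected := gene_id %in% selected_ids]
  write_tsv(out_stats, file.path(out_dir, "rates.tsv"))
  write_tsv(spectrum, file.path(out_dir, "spectrum.tsv"))
  write_tsv(blacklist, file.path(out_dir, "blacklist.tsv"))
  write_blacklist_bed(blacklist, file.path(out_dir, "blacklist.bed"))
  writeLines(selected_ids, file.path(out_dir, "selected_genes.txt"))

  discarded <- attr(stats, "discarded")
  summary <- list(
    sample_id = sample_id,
    n_reads = n_reads,
    n_missing_md = n_missing_md,
    n_reads_unassigned = unname(discarded["unassigned"]),
    n_reads_ambiguous = unname(discarded["ambiguous"]),
    n_reads_antisense = unname(discarded["antisense"]),
    n_events_prefilter = n_events_prefilter,
    n_events_quality = n_events_q,
    n_blacklisted_positions = nrow(blacklist),
    n_genes_scored = scored,
    n_genes_selected = length(selected_ids),
    selection_threshold = if (is.null(sel)) NA else sel$threshold
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_config(out_dir, list(sample_id = sample_id, mode = mode,
                                 thresholds = unclass(config)))
  invisible(list(stats = stats, selected = sel, blacklist = blacklist,
                 spectrum = spectrum, summary = summary))
}

#' Run the full single-cell pipeline
#'
#' Executes conversion calling, UMI grouping, labeled-molecule flagging and
#' count-matrix regeneration, writing 10x-layout `raw/` and `corrected/`
#' matrix triplets, `removed_umis.tsv` (audit of removed molecules),
#' `per_cell_labeling.tsv`, and — when a cell-type map is supplied —
#' `celltype_summary.tsv` and `removal_report.tsv`, plus `summary.json`
#' and `config.yaml`.
#'
#' @param alignments SAM/BAM path or read table; reads must carry CB/UB/GX
#'   tags on a nonzero fraction of records.
#' @param reference FASTA path or [Biostrings::DNAStringSet].
#' @param annotation GTF path or gene table.
#' @param out_dir output directory.
#' @param config a [threshold_config()].
#' @param celltype_map optional path to a two-column TSV (barcode,
#'   cell type) or an equivalent table.
#' @param use_blacklist also apply the SNP/coverage blacklist to
#'   single-cell conversions (off by default).
#' @return invisibly, a list with `umis`, `matrices`, `per_cell`,
#'   `summary` (and `celltype_summary`, `removal_report` when a map was
#'   given).
#' @export
run_sc <- function(alignments, reference, annotation, out_dir,
                   config = threshold_config(), celltype_map = NULL,
                   use_blacklist = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- resolve_inputs(alignments, reference, annotation)
  reads <- inp$reads
  n_tagged <- sum(!is.na(reads$cb) & !is.na(reads$ub) & !is.na(reads$gx))
  if (n_tagged == 0L)
    stop("no reads carry CB/UB/GX tags; is this single-cell data?")

  bl <- NULL
  if (use_blacklist) {
    pu <- build_pileup(reads, inp$reference,
                       min_quality = config$min_quality)
    bl <- build_blacklist(pu, max_alt_frac = config$max_alt_frac,
                          min_coverage = config$min_coverage)
  }
  umis <- group_umis(reads, inp$genes, min_quality = config$min_quality,
                     min_conversions = config$sc_min_conversions,
                     blacklist = bl)
  mats <- regenerate_count_matrix(umis)
  write_matrix_10x(mats$raw, file.path(out_dir, "raw"))
  write_matrix_10x(mats$corrected, file.path(out_dir, "corrected"))
  write_tsv(mats$removed_umis, file.path(out_dir, "removed_umis.tsv"))
  per_cell <- per_cell_labeled_gene_fraction(umis)
  write_tsv(per_cell, file.path(out_dir, "per_cell_labeling.tsv"))

  ct_summary <- rep_report <- NULL
  if (!is.null(celltype_map)) {
    if (is.character(celltype_map))
      celltype_map <- utils::read.table(celltype_map, sep = "\t",
                                        header = TRUE,
                                        stringsAsFactors = FALSE)
    ct_summary <- celltype_gene_labeling_summary(
      umis, celltype_map, min_units = config$sc_min_units,
      min_frac = config$sc_min_frac,
      min_conversions = config$sc_min_conversions)
    write_tsv(ct_summary, file.path(out_dir, "celltype_summary.tsv"))
    rep_report <- removal_report(
      umis, reads, inp$reference, inp$genes, celltype_map,
      min_removed = config$report_min_removed,
      min_frac = config$report_min_frac,
      min_quality = config$min_quality)
    write_tsv(rep_report$by_gene_celltype,
              file.path(out_dir, "removal_report.tsv"))
    write_tsv(rep_report$listed_genes,
              file.path(out_dir, "removal_listed_genes.tsv"))
  }

  summary <- list(
    n_reads = nrow(reads),
    n_tagged_reads = n_tagged,
    n_untagged_reads = attr(umis, "n_untagged"),
    n_multigene_umis = attr(umis, "n_multigene_umis"),
    n_umis = nrow(umis),
    n_labeled_umis = sum(umis$labeled),
    n_removed_umis = nrow(mats$removed_umis),
    total_raw = sum(mats$raw),
    total_corrected = sum(mats$corrected),
    n_genes = nrow(mats$raw),
    n_cells = ncol(mats$raw)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_config(out_dir, list(use_blacklist = use_blacklist,
                                 thresholds = unclass(config)))
  invisible(list(umis = umis, matrices = mats, per_cell = per_cell,
                 celltype_summary = ct_summary,
                 removal_report = rep_report, summary = summary))
}
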