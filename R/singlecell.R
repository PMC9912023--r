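# UMI grouping, labeled-molecule flagging, corrected count matrices and
# single-cell labeling reports.

#' Group tagged reads into UMIs and flag labeled molecules
#'
#' Builds one record per distinct (cell barcode, UMI, gene) combination from
#' reads carrying CB/UB/GX tags. A molecule's conversion events are the
#' union of quality-passing transcript-strand T-to-C positions over its
#' supporting reads (a UMI denotes one molecule, so conversions are
#' molecular properties); with `mode = "any_read"` the maximum per single
#' read is used instead. A molecule is `labeled` when its distinct
#' conversion count reaches `min_conversions`. Reads lacking any of the
#' three tags are counted and skipped; the same (cell, UMI) assigned to two
#' genes yields two records (matching upstream tag semantics) and is
#' counted in the diagnostics attribute.
#'
#' @param reads read table with `cb`, `ub`, `gx` columns.
#' @param genes gene table supplying gene strand for the T-to-C rule.
#' @param min_quality minimum Phred base quality for a conversion (default
#'   20).
#' @param min_conversions distinct conversions flagging a molecule as
#'   labeled (default 2).
#' @param blacklist optional blacklist; positions in it contribute no
#'   conversions (off by default, matching the published single-cell
#'   filtering which names only the quality rule).
#' @param mode `"union"` (default) or `"any_read"`.
#' @return `data.table` of class `umi_records`: `cell_barcode`, `umi`,
#'   `gene_id`, `read_count`, `conversion_positions` (list column of
#'   integer vectors), `conversion_count`, `labeled`. Attributes:
#'   `n_untagged` (skipped reads), `n_multigene_umis`.
#' @export
group_umis <- function(reads, genes, min_quality = 20L,
                       min_conversions = 2L, blacklist = NULL,
                       mode = c("union", "any_read")) {
  mode <- match.arg(mode)
  reads <- as.data.table(reads)
  genes <- as.data.table(genes)
  tagged <- reads[!is.na(cb) & !is.na(ub) & !is.na(gx)]
  n_untagged <- nrow(reads) - nrow(tagged)

  ev <- extract_mismatches(tagged)
  ev <- merge(ev, tagged[, .(read_id, gx, cb, ub)], by = "read_id")
  ev <- merge(ev, genes[, .(gene_id, gene_strand = strand)],
              by.x = "gx", by.y = "gene_id", all.x = TRUE)
  ev <- ev[!is.na(gene_strand)]
  ev <- call_conversions(ev[, .(read_id, contig, pos, ref, alt, qual, cb,
                                ub, gx, gene_strand)],
                         min_quality = min_quality)
  tc <- ev[is_tc == TRUE]
  tc <- exclude_blacklisted(tc, blacklist)

  umis <- tagged[, .(read_count = .N, read_ids = list(read_id)),
                 by = .(cell_barcode = cb, umi = ub, gene_id = gx)]
  if (mode == "union") {
    conv <- tc[, .(conversion_positions = list(sort(unique(pos)))),
               by = .(cell_barcode = cb, umi = ub, gene_id = gx)]
  } else {
    per_read <- tc[, .(n = uniqueN(pos),
                       p = list(sort(unique(pos)))),
                   by = .(cell_barcode = cb, umi = ub, gene_id = gx,
                          read_id)]
    conv <- per_read[, .(conversion_positions = p[which.max(n)]),
                     by = .(cell_barcode, umi, gene_id)]
  }
  umis <- merge(umis, conv, by = c("cell_barcode", "umi", "gene_id"),
                all.x = TRUE)
  umis[, conversion_count := vapply(conversion_positions,
                                    function(p) length(p %||% integer(0)),
                                    integer(1L))]
  umis[, labeled := conversion_count >= min_conversions]
  multi <- umis[, .(ngene = uniqueN(gene_id)), by = .(cell_barcode, umi)]
  setorder(umis, cell_barcode, umi, gene_id)
  setattr(umis, "n_untagged", n_untagged)
  setattr(umis, "n_multigene_umis", sum(multi$ngene > 1L))
  setattr(umis, "min_conversions", as.integer(min_conversions))
  setattr(umis, "class", c("umi_records", class(umis)))
  umis[]
}

#' Regenerate gene-by-cell count matrices, removing labeled molecules
#'
#' Counts every UMI record into the raw matrix, then regenerates a
#' corrected matrix omitting labeled records only — individual molecules
#' are removed, no gene is ever dropped wholesale. Entry-wise,
#' `raw = corrected + removed`.
#'
#' @param umis records from [group_umis()].
#' @param remove_labeled remove labeled molecules (default `TRUE`); with
#'   `FALSE` the corrected matrix equals the raw matrix.
#' @param gene_universe,cell_universe optional axis label vectors (defaults:
#'   those observed).
#' @return list of class `cell_count_matrices`: sparse `raw` and
#'   `corrected` matrices (genes x cells), and `removed_umis`, an audit
#'   table of the removed records.
#' @export
regenerate_count_matrix <- function(umis, remove_labeled = TRUE,
                                    gene_universe = NULL,
                                    cell_universe = NULL) {
  u <- as.data.table(umis)
  genes <- sort(unique(c(gene_universe, u$gene_id)))
  cells <- sort(unique(c(cell_universe, u$cell_barcode)))
  tally <- function(d) {
    if (!nrow(d)) {
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0),
                                  dims = c(length(genes), length(cells)),
                                  dimnames = list(genes, cells)))
    }
    cnt <- d[, .N, by = .(gene_id, cell_barcode)]
    m <- Matrix::sparseMatrix(i = match(cnt$gene_id, genes),
                              j = match(cnt$cell_barcode, cells),
                              x = cnt$N,
                              dims = c(length(genes), length(cells)),
                              dimnames = list(genes, cells))
    methods::as(m, "CsparseMatrix")
  }
  raw <- tally(u)
  removed <- if (remove_labeled) u[labeled == TRUE] else u[0L]
  corrected <- tally(if (remove_labeled) u[labeled == FALSE] else u)
  audit <- removed[, .(cell_barcode, umi, gene_id, read_count,
                       conversion_count)]
  structure(list(raw = raw, corrected = corrected, removed_umis = audit),
            class = "cell_count_matrices")
}

#' Per-cell percentage of genes with labeling events
#'
#' For each cell: the percentage of its detected genes (>= 1 UMI) that have
#' at least one UMI with `min_events` or more conversion events.
#'
#' @param umis records from [group_umis()].
#' @param min_events conversion events per UMI needed for a gene to count
#'   as labeled in that cell (default 1).
#' @return `data.table` with `cell_barcode`, `n_genes`, `n_labeled_genes`,
#'   `pct_labeled_genes`.
#' @export
per_cell_labeled_gene_fraction <- function(umis, min_events = 1L) {
  u <- as.data.table(umis)
  out <- u[, .(n_genes = uniqueN(gene_id),
               n_labeled_genes = uniqueN(gene_id[conversion_count >=
                                                   min_events])),
           by = cell_barcode]
  out <- out[n_genes > 0L]
  out[, pct_labeled_genes := 100 * n_labeled_genes / n_genes]
  setorder(out, cell_barcode)
  out[]
}

# barcode -> cell type lookup; unmapped barcodes become "unknown"
celltype_of <- function(barcodes, celltype_map) {
  m <- as.data.table(celltype_map)
  setnames(m, c("cell_barcode", "cell_type"))
  ct <- m$cell_type[match(barcodes, m$cell_barcode)]
  fifelse(is.na(ct), "unknown", ct)
}

#' Gene labeling summary per cell type
#'
#' For every (gene, cell type): total units (UMIs by default, reads
#' optionally), labeled units (conversion count >= `min_conversions`), and
#' their fraction. A gene `passes_filter` when, in at least one cell type,
#' it has `min_units` or more units of which `min_frac` or more are labeled
#' — the filter behind the cell-type dissociation-response heatmap.
#'
#' @param umis records from [group_umis()].
#' @param celltype_map two-column table (cell barcode, cell type); barcodes
#'   absent from it are assigned type `"unknown"`.
#' @param min_units minimum units per (gene, cell type) (default 250).
#' @param min_frac minimum labeled fraction (default 0.10).
#' @param min_conversions events flagging a unit as labeled (default 2).
#' @param unit `"umi"` (default) or `"read"` (units weighted by read
#'   support).
#' @return `data.table`: `gene_id`, `cell_type`, `units_total`,
#'   `units_labeled`, `fraction`, `passes_filter` (gene-level flag).
#' @export
celltype_gene_labeling_summary <- function(umis, celltype_map,
                                           min_units = 250L,
                                           min_frac = 0.10,
                                           min_conversions = 2L,
                                           unit = c("umi", "read")) {
  unit <- match.arg(unit)
  u <- copy(as.data.table(umis))
  u[, cell_type := celltype_of(cell_barcode, celltype_map)]
  u[, .w := if (unit == "umi") 1L else read_count]
  u[, .lab := conversion_count >= min_conversions]
  out <- u[, .(units_total = sum(.w), units_labeled = sum(.w[.lab])),
           by = .(gene_id, cell_type)]
  out[, fraction := units_labeled / units_total]
  gene_pass <- out[, .(passes_filter = any(units_total >= min_units &
                                             fraction >= min_frac)),
                   by = gene_id]
  out <- merge(out, gene_pass, by = "gene_id")
  setorder(out, gene_id, cell_type)
  out[]
}

#' Removal report per gene and cell type
#'
#' Summarises the effect of labeled-molecule removal: per (gene, cell type)
#' read totals, removed reads and removal fraction, plus a filtered gene
#' list (genes with at least `min_removed` removed reads making up at least
#' `min_frac` of their reads in some cell type) and, per listed gene, the
#' labeling rate within the removed reads (site-mode formula — fraction of
#' covered transcript-strand T positions showing a conversion — restricted
#' to reads of removed molecules).
#'
#' @param umis records from [group_umis()].
#' @param reads the read table the records were built from.
#' @param reference [Biostrings::DNAStringSet].
#' @param genes gene table.
#' @param celltype_map barcode-to-cell-type table.
#' @param min_removed minimum removed reads (default 3).
#' @param min_frac minimum removed fraction (default 0.05).
#' @param min_quality minimum Phred base quality (default 20).
#' @return list of class `removal_report`: `by_gene_celltype` table,
#'   `listed_genes` table with removed-read labeling rates.
#' @export
removal_report <- function(umis, reads, reference, genes, celltype_map,
                           min_removed = 3L, min_frac = 0.05,
                           min_quality = 20L) {
  u <- copy(as.data.table(umis))
  u[, cell_type := celltype_of(cell_barcode, celltype_map)]
  per <- u[, .(reads_total = sum(read_count),
               reads_removed = sum(read_count[labeled])),
           by = .(gene_id, cell_type)]
  per[, removal_fraction := reads_removed / reads_total]
  listed <- per[, .(listed = any(reads_removed >= min_removed &
                                   removal_fraction >= min_frac)),
                by = gene_id][listed == TRUE, gene_id]

  # labeling rate of removed reads, per listed gene (site mode)
  rm_ids <- unlist(u[labeled == TRUE & gene_id %in% listed, read_ids],
                   use.names = FALSE)
  rates <- data.table(gene_id = character(0), removed_reads = integer(0),
                      removed_labeling_rate = numeric(0))
  if (length(rm_ids)) {
    rreads <- as.data.table(reads)[read_id %in% rm_ids]
    st <- gene_labeling_stats(rreads, reference,
                              as.data.table(genes)[gene_id %in% listed],
                              min_quality = min_quality, mode = "site",
                              sample_id = "removed")
    rates <- as.data.table(st)[, .(gene_id, removed_reads = read_count,
                                   removed_labeling_rate = rate)]
  }
  listed_tab <- merge(
    per[gene_id %in% listed,
        .(reads_total = sum(reads_total),
          reads_removed = sum(reads_removed)), by = gene_id],
    rates, by = "gene_id", all.x = TRUE)
  setorder(per, gene_id, cell_type)
  structure(list(by_gene_celltype = per[], listed_genes = listed_tab),
            class = "removal_report")
}

#' Gradually remove random subsets of labeled molecules
#'
#' For each fraction `f`, removes a uniformly random subset comprising
#' `round-half-up(f * n_labeled)` of the labeled molecules. Subsets are
#' nested (drawn from one seeded permutation), so removal grows
#' monotonically with `f`; `f = 0` reproduces the raw matrix and `f = 1`
#' the fully corrected one. Deterministic per seed.
#'
#' @param umis records from [group_umis()].
#' @param fractions numeric vector of removal fractions in `[0, 1]`.
#' @param seed integer seed for the subset draw.
#' @return named list (one element per fraction) of
#'   `cell_count_matrices`-style lists (`raw`, `corrected`,
#'   `removed_umis`).
#' @export
gradual_removal <- function(umis, fractions, seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  u <- as.data.table(umis)
  lab_idx <- which(u$labeled)
  perm <- with_seed(seed, sample(lab_idx))
  out <- vector("list", length(fractions))
  names(out) <- as.character(fractions)
  for (i in seq_along(fractions)) {
    k <- floor(fractions[i] * length(lab_idx) + 0.5)  # half-up
    drop <- perm[seq_len(k)]
    u2 <- copy(u)
    u2[, labeled := FALSE]
    if (k > 0L) u2[drop, labeled := TRUE]
    out[[i]] <- regenerate_count_matrix(u2, remove_labeled = TRUE,
                                        gene_universe = unique(u$gene_id),
                                        cell_universe =
                                          unique(u$cell_barcode))
  }
  out
}

#' Write a count matrix in 10x-style MatrixMarket layout
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` into `dir` so the
#' corrected matrix drops into external single-cell frameworks.
#'
#' @param mat sparse genes-by-cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_10x <- function(mat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style MatrixMarket directory
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return sparse genes-by-cells matrix.
#' @export
read_matrix_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
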