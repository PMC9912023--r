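#' Read tagged alignments from SAM or BAM into a read table
#'
#' Loads alignment records (with the MD tag and, when present, CellRanger
#' style CB/UB/GX tags) into the flat read table used by all downstream
#' steps. Plain-text SAM files are converted to BAM on the fly with
#' [Rsamtools::asBam()]. Unmapped records are dropped.
#'
#' @param path path to a SAM or BAM file; SAM is detected by extension.
#' @return A `data.table` with one row per mapped record and columns
#'   `read_id`, `flag`, `contig`, `pos` (0-based leftmost aligned position),
#'   `strand` (`"+"`/`"-"` alignment strand), `cigar`, `seq`, `qual`
#'   (Phred+33 string), `md`, `cb`, `ub`, `gx` (missing tags are `NA`).
#' @export
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("MD", "CB", "UB", "GX"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  tagcol <- function(tag) {
    v <- x$tag[[tag]]
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  reads <- data.table(
    read_id = x$qname,
    flag = as.integer(x$flag),
    contig = as.character(x$rname),
    pos = as.integer(x$pos) - 1L,
    strand = ifelse(bitwAnd(as.integer(x$flag), 16L) > 0L, "-", "+"),
    cigar = as.character(x$cigar),
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    md = tagcol("MD"),
    cb = tagcol("CB"),
    ub = tagcol("UB"),
    gx = tagcol("GX")
  )
  reads[]
}

#' Write a read table as a coordinate-sorted SAM file
#'
#' Inverse of [read_alignments()] for simulator output: emits a valid SAM
#' with `@SQ` lines, the MD tag, and CB/UB/GX tags where present.
#'
#' @param reads read table as produced by the simulator or
#'   [read_alignments()].
#' @param reference a [Biostrings::DNAStringSet] providing contig names and
#'   lengths for the header.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  reads <- as.data.table(reads)
  setorder(reads, contig, pos, read_id)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  if (!nrow(reads)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  tags <- paste0("MD:Z:", reads$md)
  has_cb <- !is.na(reads$cb)
  if (any(has_cb)) {
    tags <- paste0(tags,
                   ifelse(has_cb, paste0("\tCB:Z:", reads$cb), ""),
                   ifelse(!is.na(reads$ub), paste0("\tUB:Z:", reads$ub), ""),
                   ifelse(!is.na(reads$gx), paste0("\tGX:Z:", reads$gx), ""))
  }
  body <- paste(reads$read_id, reads$flag, reads$contig, reads$pos + 1L,
                255L, reads$cigar, "*", 0L, 0L, reads$seq, reads$qual,
                tags, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports gene records (falling back to the union of exon records per gene
#' when no `gene` features are present) and returns the interval table used
#' for read-to-gene assignment and labeling statistics.
#'
#' @param path GTF file path.
#' @return `data.table` with columns `gene_id`, `contig`, `start` (0-based),
#'   `end` (exclusive), `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
  }
  dt <- data.table(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  # collapse multi-feature genes to their span
  dt <- dt[, .(contig = contig[1L], start = min(start), end = max(end),
               strand = strand[1L]), by = gene_id]
  if (any(!dt$strand %in% c("+", "-")))
    stop("gene models must have explicit +/- strand")
  dt[]
}

#' Write gene models as GTF
#'
#' @param genes gene table as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  genes <- as.data.table(genes)
  setorder(genes, contig, start)
  attr_str <- sprintf('gene_id "%s"; gene_name "%s";',
                      genes$gene_id, genes$gene_id)
  gene_ln <- paste(genes$contig, "dissoscan_sim", "gene", genes$start + 1L,
                   genes$end, ".", genes$strand, ".", attr_str, sep = "\t")
  exon_ln <- paste(genes$contig, "dissoscan_sim", "exon", genes$start + 1L,
                   genes$end, ".", genes$strand, ".",
                   sprintf('gene_id "%s"; transcript_id "%s.t1";',
                           genes$gene_id, genes$gene_id), sep = "\t")
  writeLines(as.vector(rbind(gene_ln, exon_ln)), path)
  invisible(path)
}

#' Write a reference as FASTA
#' @param reference [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path.
#' @return [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

# reference contig -> character vector, with existence check
contig_chars <- function(reference, contig) {
  if (!contig %in% names(reference))
    stop("contig absent from reference: ", contig)
  strsplit(as.character(reference[[contig]]), "", fixed = TRUE)[[1L]]
}
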