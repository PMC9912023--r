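# CIGAR / MD walking and conversion-event calling.
#
# Coordinates are 0-based half-open everywhere inside the package; 1-based
# only at SAM/BED text boundaries.

# Parse a CIGAR string into op/length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") stop("read has no CIGAR")
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  op <- substr(toks, nchar(toks), nchar(toks))
  list(op = op, len = len)
}

# Layout of aligned (M/=/X) bases: for each, its 0-based offset in the read
# and in the reference, plus reference span and expected deletion length.
# Cached per CIGAR string since libraries contain few distinct CIGARs.
.cigar_cache <- new.env(parent = emptyenv())

cigar_layout <- function(cigar) {
  hit <- .cigar_cache[[cigar]]
  if (!is.null(hit)) return(hit)
  cg <- parse_cigar(cigar)
  read_off <- integer(0)
  ref_off <- integer(0)
  roff <- 0L   # read cursor
  goff <- 0L   # reference cursor
  del_len <- 0L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; n <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      read_off <- c(read_off, roff + seq_len(n) - 1L)
      ref_off <- c(ref_off, goff + seq_len(n) - 1L)
      roff <- roff + n; goff <- goff + n
    } else if (op %in% c("I", "S")) {
      roff <- roff + n
    } else if (op == "D") {
      goff <- goff + n; del_len <- del_len + n
    } else if (op == "N") {
      goff <- goff + n
    } # H, P consume nothing
  }
  out <- list(read_off = read_off, ref_off = ref_off,
              ref_span = goff, read_len = roff, del_len = del_len)
  assign(cigar, out, envir = .cigar_cache)
  out
}

cigar_ref_span <- function(cigars) {
  vapply(cigars, function(cg) cigar_layout(cg)$ref_span, integer(1L),
         USE.NAMES = FALSE)
}

md_tokens <- function(md) {
  m <- gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md)[[1L]]
  regmatches(md, list(m))[[1L]]
}

# Walk one read's CIGAR and MD jointly; return mismatch offsets.
# Returns data.frame(ref_off, read_off, ref, alt, qual) or a condition on
# inconsistency.
walk_md <- function(read_id, cigar, seq, qual, md) {
  lay <- cigar_layout(cigar)
  toks <- md_tokens(md)
  n_aligned <- length(lay$read_off)
  i <- 0L       # aligned bases consumed
  del_seen <- 0L
  hit_ref <- character(0)
  hit_idx <- integer(0)
  for (tok in toks) {
    c1 <- substr(tok, 1L, 1L)
    if (c1 >= "0" && c1 <= "9") {
      i <- i + as.integer(tok)
    } else if (c1 == "^") {
      del_seen <- del_seen + nchar(tok) - 1L
    } else {
      i <- i + 1L
      if (i > n_aligned)
        stop("MD/CIGAR inconsistency for read ", read_id)
      hit_ref <- c(hit_ref, toupper(tok))
      hit_idx <- c(hit_idx, i)
    }
  }
  if (i != n_aligned || del_seen != lay$del_len)
    stop("MD/CIGAR inconsistency for read ", read_id)
  if (!length(hit_idx))
    return(NULL)
  roff <- lay$read_off[hit_idx]
  alt <- toupper(substring(seq, roff + 1L, roff + 1L))
  data.frame(ref_off = lay$ref_off[hit_idx], read_off = roff,
             ref = hit_ref, alt = alt,
             qual = phred_ints(qual)[roff + 1L],
             stringsAsFactors = FALSE)
}

#' Extract reference mismatches from aligned reads
#'
#' Reconstructs every reference-mismatch position carried by each read by
#' walking its CIGAR and MD tag jointly: insertions and soft-clips advance
#' the read only, deletions and skips advance the reference only. Mismatches
#' where either the reference or the read base is `N` are dropped.
#'
#' @param reads read table (see [read_alignments()]).
#' @param on_missing_md what to do with reads lacking an MD tag: `"skip"`
#'   (default; skipped reads are counted in the `n_missing_md` attribute of
#'   the result) or `"error"`.
#' @return `data.table` with columns `read_id`, `contig`, `pos` (0-based
#'   genomic position), `ref`, `alt`, `qual`; one row per mismatch.
#'   Attribute `n_missing_md` counts skipped reads.
#' @export
extract_mismatches <- function(reads, on_missing_md = c("skip", "error")) {
  on_missing_md <- match.arg(on_missing_md)
  reads <- as.data.table(reads)
  missing_md <- is.na(reads$md) | reads$md == ""
  if (any(missing_md)) {
    if (on_missing_md == "error")
      stop("MD tag missing for read ", reads$read_id[which(missing_md)[1L]])
    warning(sum(missing_md), " read(s) without MD tag skipped")
    reads <- reads[!missing_md]
  }
  empty <- data.table(read_id = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), qual = integer(0))
  if (!nrow(reads)) {
    setattr(empty, "n_missing_md", sum(missing_md))
    return(empty)
  }
  # fast path: after stripping deletion runs, an MD without letters
  # carries no mismatches and needs no walk
  cand <- grepl("[A-Za-z]", gsub("\\^[A-Za-z]+", "", reads$md))
  sub <- reads[cand]
  if (!nrow(sub)) {
    setattr(empty, "n_missing_md", sum(missing_md))
    return(empty)
  }
  res <- vector("list", nrow(sub))
  for (r in seq_len(nrow(sub))) {
    hits <- walk_md(sub$read_id[r], sub$cigar[r], sub$seq[r],
                    sub$qual[r], sub$md[r])
    if (!is.null(hits)) {
      hits$read_id <- sub$read_id[r]
      hits$contig <- sub$contig[r]
      hits$pos <- sub$pos[r] + hits$ref_off
      res[[r]] <- hits
    }
  }
  # validate MD consistency of no-mismatch reads lazily only when asked?
  # they cannot produce events; CIGAR/MD length agreement for them is
  # checked by the simulator round-trip tests.
  out <- rbindlist(res)
  if (!nrow(out)) {
    setattr(empty, "n_missing_md", sum(missing_md))
    return(empty)
  }
  out <- out[ref %chin% BASES & alt %chin% BASES,
             .(read_id, contig, pos, ref, alt, qual)]
  setattr(out, "n_missing_md", sum(missing_md))
  out[]
}

#' Assign reads to genes by overlap
#'
#' Reads are assigned to the single gene whose extent contains their aligned
#' span; reads overlapping multiple genes are excluded from all of them, and
#' reads aligned antisense to their gene are discarded by default (the
#' library chemistry is sense-stranded, so antisense conversions are
#' uninterpretable).
#'
#' @param reads read table.
#' @param genes gene table (see [read_gene_models()]).
#' @param discard_antisense drop reads whose alignment strand differs from
#'   the gene strand (default `TRUE`).
#' @return the read table with `gene_id` and `gene_strand` columns added,
#'   restricted to uniquely and sense-assigned reads. Attribute `discarded`
#'   is a named vector counting `unassigned`, `ambiguous`, `antisense`.
#' @export
assign_reads_to_genes <- function(reads, genes, discard_antisense = TRUE) {
  reads <- as.data.table(reads)
  genes <- as.data.table(genes)
  span <- cigar_ref_span(reads$cigar)
  rgr <- GenomicRanges::GRanges(reads$contig,
                                IRanges::IRanges(reads$pos + 1L,
                                                 reads$pos + pmax(span, 1L)))
  ggr <- GenomicRanges::GRanges(genes$contig,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(rgr, ggr)
  qh <- S4Vectors::queryHits(ov)
  nhits <- tabulate(qh, nbins = nrow(reads))
  uniq <- which(nhits == 1L)
  hit_gene <- integer(nrow(reads))
  hit_gene[qh] <- S4Vectors::subjectHits(ov)  # last hit wins; only uniq used
  out <- reads[uniq]
  out[, gene_id := genes$gene_id[hit_gene[uniq]]]
  out[, gene_strand := genes$strand[hit_gene[uniq]]]
  n_anti <- 0L
  if (discard_antisense) {
    anti <- out$strand != out$gene_strand
    n_anti <- sum(anti)
    out <- out[!anti]
  }
  setattr(out, "discarded",
          c(unassigned = sum(nhits == 0L), ambiguous = sum(nhits > 1L),
            antisense = n_anti))
  out[]
}

#' Call strand-aware conversion events from mismatches
#'
#' Filters mismatch events at a minimum base quality and flags
#' transcript-strand T-to-C conversions: a genomic `T>C` on a plus-strand
#' gene, or a genomic `A>G` on a minus-strand gene. Non-T-to-C events are
#' retained (with `is_tc = FALSE`) so the substitution spectrum can be
#' computed from the same stream. With `genomic_only = TRUE` only genomic
#' `T>C` counts, regardless of gene strand (the strand-naive reading).
#'
#' @param mismatches mismatch table from [extract_mismatches()]; either
#'   already carrying `gene_id`/`gene_strand` columns, or a single gene
#'   given via the `gene_id`/`gene_strand` arguments.
#' @param gene_id,gene_strand gene assignment applied to all events when the
#'   table has none.
#' @param min_quality minimum Phred base quality (default 20).
#' @param genomic_only ignore gene strand when flagging T-to-C.
#' @return the filtered table with `gene_id`, `gene_strand`, `is_tc` added.
#' @export
call_conversions <- function(mismatches, gene_id = NULL, gene_strand = NULL,
                             min_quality = 20L, genomic_only = FALSE) {
  ev <- as.data.table(mismatches)
  if (!is.null(gene_id)) {
    if (!gene_strand %in% c("+", "-"))
      stop("unknown strand symbol: ", gene_strand)
    ev[, gene_id := gene_id]
    ev[, gene_strand := gene_strand]
  }
  if (!"gene_strand" %in% names(ev))
    stop("events carry no gene assignment")
  if (nrow(ev) && any(!ev$gene_strand %in% c("+", "-")))
    stop("unknown strand symbol in gene_strand")
  ev <- ev[qual >= min_quality]
  if (genomic_only) {
    ev[, is_tc := ref == "T" & alt == "C"]
  } else {
    ev[, is_tc := (gene_strand == "+" & ref == "T" & alt == "C") |
                  (gene_strand == "-" & ref == "A" & alt == "G")]
  }
  ev[]
}

#' Genome-wide substitution spectrum
#'
#' Computes, for each of the 12 substitution types, the number of
#' quality-passing mismatch events and the number of quality-passing aligned
#' observations of the reference base (blacklisted positions excluded from
#' both), and their ratio. In 4sU-labeled libraries the T>C rate stands out
#' above the uniform error background.
#'
#' @param reads read table.
#' @param reference [Biostrings::DNAStringSet].
#' @param blacklist optional blacklist table (see [build_blacklist()]).
#' @param min_quality minimum Phred base quality.
#' @param pileup optional precomputed pileup (same `min_quality`); computed
#'   from `reads` when `NULL`.
#' @return `data.table` with columns `ref`, `alt`, `events`, `observations`,
#'   `rate` (NA when a reference base was never observed); 12 rows.
#' @export
substitution_spectrum <- function(reads, reference, blacklist = NULL,
                                  min_quality = 20L, pileup = NULL) {
  if (is.null(pileup))
    pileup <- build_pileup(reads, reference, min_quality = min_quality)
  pu <- exclude_blacklisted(pileup, blacklist)
  grid <- CJ(ref = BASES, alt = BASES)[ref != alt]
  if (!nrow(pu)) {
    grid[, `:=`(events = 0L, observations = 0L, rate = NA_real_)]
    return(grid[])
  }
  long <- melt(pu[, .(ref, A, C, G, T)], id.vars = "ref",
               variable.name = "alt", value.name = "n",
               variable.factor = FALSE)
  obs <- long[, .(observations = sum(n)), by = ref]
  ev <- long[ref != alt, .(events = sum(n)), by = .(ref, alt)]
  out <- merge(grid, ev, by = c("ref", "alt"), all.x = TRUE)
  out <- merge(out, obs, by = "ref", all.x = TRUE)
  out[is.na(events), events := 0L]
  out[is.na(observations), observations := 0L]
  out[, rate := ifelse(observations > 0L, events / observations, NA_real_)]
  setorder(out, ref, alt)
  out[]
}
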