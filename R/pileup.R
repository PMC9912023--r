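# Per-position pileup and SNP/low-coverage blacklisting.

#' Build a base-quality-aware pileup
#'
#' Tallies every aligned, quality-passing base call at its genomic position.
#' Deletions and reference skips contribute nothing; `N` base calls and `N`
#' reference positions are excluded from both counts and coverage. The same
#' quality filter is applied here as in conversion calling, so the blacklist
#' judges exactly the evidence the labeling rate uses.
#'
#' @param reads read table (see [read_alignments()]).
#' @param reference [Biostrings::DNAStringSet]; every read contig must be
#'   present.
#' @param min_quality minimum Phred base quality for a call to count.
#' @return `data.table` of class `position_pileup` with columns `contig`,
#'   `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `coverage`; one row per
#'   covered position. Positions whose reference base is `N` are omitted.
#' @export
build_pileup <- function(reads, reference, min_quality = 20L) {
  reads <- as.data.table(reads)
  if (!nrow(reads)) {
    out <- data.table(contig = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), coverage = integer(0))
    setattr(out, "class", c("position_pileup", class(out)))
    return(out)
  }
  miss <- setdiff(unique(reads$contig), names(reference))
  if (length(miss))
    stop("contig absent from reference: ", paste(miss, collapse = ", "))

  # expand every read into (contig, pos, base, qual) rows, grouped by CIGAR
  # so the per-CIGAR layout is computed once
  pieces <- vector("list", 0L)
  for (cg in unique(reads$cigar)) {
    lay <- cigar_layout(cg)
    idx <- which(reads$cigar == cg)
    n <- length(lay$read_off)
    if (n == 0L) next
    seqs <- reads$seq[idx]
    quals <- reads$qual[idx]
    if (lay$read_len == n && all(lay$read_off == seq_len(n) - 1L)) {
      # pure-match layout: whole read aligned in order
      bases <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
      qv <- unlist(lapply(quals, phred_ints), use.names = FALSE)
    } else {
      pick <- lay$read_off + 1L
      bases <- unlist(lapply(strsplit(seqs, "", fixed = TRUE),
                             `[`, pick), use.names = FALSE)
      qv <- unlist(lapply(quals, function(q) phred_ints(q)[pick]),
                   use.names = FALSE)
    }
    pieces[[length(pieces) + 1L]] <- data.table(
      contig = rep(reads$contig[idx], each = n),
      pos = rep(reads$pos[idx], each = n) + rep(lay$ref_off,
                                                times = length(idx)),
      base = bases, qual = qv)
  }
  calls <- rbindlist(pieces)
  calls <- calls[qual >= min_quality & base %chin% BASES]
  tab <- dcast(calls[, .N, by = .(contig, pos, base)],
               contig + pos ~ base, value.var = "N", fill = 0L)
  for (b in BASES) if (!b %in% names(tab)) tab[, (b) := 0L]
  # reference base lookup, one grouped pass per contig
  tab[, ref := {
    cs <- contig_chars(reference, .BY[[1L]])
    if (any(pos < 0L | pos >= length(cs)))
      stop("aligned position outside reference contig ", .BY[[1L]])
    cs[pos + 1L]
  }, by = contig]
  tab <- tab[ref %chin% BASES]
  tab[, coverage := A + C + G + T]
  setcolorder(tab, c("contig", "pos", "ref", "A", "C", "G", "T", "coverage"))
  setorder(tab, contig, pos)
  setattr(tab, "min_quality", as.integer(min_quality))
  setattr(tab, "class", c("position_pileup", class(tab)))
  tab[]
}

#' Blacklist SNP-like and low-coverage positions
#'
#' A position is blacklisted when its non-reference fraction is strictly
#' greater than `max_alt_frac` (likely SNP) or its quality-passing coverage
#' is strictly below `min_coverage` (too shallow to judge). Both rules use
#' strict inequalities: 3/12 alternative calls (exactly 25%) is kept,
#' coverage 10 is kept. With `tc_only = TRUE` the fraction rule considers
#' only the conversion-like alternative (C at reference-T positions, G at
#' reference-A positions), the strand-naive reading of removing frequent
#' T-to-C transitions; other positions are then subject only to the
#' coverage rule.
#'
#' @param pileup pileup from [build_pileup()].
#' @param max_alt_frac blacklist when alt fraction strictly exceeds this
#'   (default 0.25).
#' @param min_coverage blacklist when coverage is strictly below this
#'   (default 10).
#' @param tc_only restrict the fraction rule to conversion-like alternatives.
#' @return `data.table` with columns `contig`, `pos`, `coverage`,
#'   `alt_count`, `reason` (`"alt_fraction"`, `"low_coverage"`, or both
#'   comma-joined).
#' @export
build_blacklist <- function(pileup, max_alt_frac = 0.25, min_coverage = 10L,
                            tc_only = FALSE) {
  pu <- as.data.table(pileup)
  if (!nrow(pu)) {
    return(data.table(contig = character(0), pos = integer(0),
                      coverage = integer(0), alt_count = integer(0),
                      reason = character(0)))
  }
  cnt <- as.matrix(pu[, .(A, C, G, T)])
  ref_count <- cnt[cbind(seq_len(nrow(pu)), match(pu$ref, BASES))]
  if (tc_only) {
    alt_count <- integer(nrow(pu))
    alt_count[pu$ref == "T"] <- cnt[pu$ref == "T", "C"]
    alt_count[pu$ref == "A"] <- cnt[pu$ref == "A", "G"]
  } else {
    alt_count <- pu$coverage - ref_count
  }
  low <- pu$coverage < min_coverage
  snp <- pu$coverage > 0L & (alt_count / pmax(pu$coverage, 1L)) > max_alt_frac
  keep <- low | snp
  out <- pu[keep, .(contig, pos, coverage)]
  out[, alt_count := alt_count[keep]]
  out[, reason := paste0(ifelse(snp[keep], "alt_fraction", ""),
                         ifelse(snp[keep] & low[keep], ",", ""),
                         ifelse(low[keep], "low_coverage", ""))]
  setorder(out, contig, pos)
  out[]
}

# drop blacklisted positions from a pileup (or any contig/pos table)
exclude_blacklisted <- function(tab, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) return(as.data.table(tab))
  tab <- as.data.table(tab)
  bl <- as.data.table(blacklist)[, .(contig, pos)]
  tab[!bl, on = c("contig", "pos")]
}

#' Write a blacklist as BED (0-based half-open, one interval per position)
#'
#' @param blacklist table from [build_blacklist()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_blacklist_bed <- function(blacklist, path) {
  bl <- as.data.table(blacklist)
  lines <- paste(bl$contig, bl$pos, bl$pos + 1L, bl$reason, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
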