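# Test helpers: an independent brute-force mismatch oracle (its own CIGAR
# walk, diffing read bases against the reference slice base by base — it
# never looks at the MD tag) and small builders for crafted read tables.

library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mismatch finder: returns data.table(read_id, pos, ref, alt)
oracle_mismatches <- function(reads, reference) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    cg <- reads$cigar[i]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    ops <- sub("^\\d+", "", toks)
    cs <- strsplit(as.character(reference[[reads$contig[i]]]), "")[[1]]
    rb <- strsplit(reads$seq[i], "")[[1]]
    roff <- 0L; goff <- reads$pos[i]
    for (k in seq_along(ops)) {
      n <- lens[k]
      if (ops[k] %in% c("M", "=", "X")) {
        for (j in seq_len(n)) {
          rfb <- cs[goff + j]
          rdb <- rb[roff + j]
          if (rfb != rdb && rfb %in% c("A", "C", "G", "T") &&
              rdb %in% c("A", "C", "G", "T")) {
            out[[length(out) + 1L]] <- data.table(
              read_id = reads$read_id[i], pos = goff + j - 1L,
              ref = rfb, alt = rdb)
          }
        }
        roff <- roff + n; goff <- goff + n
      } else if (ops[k] %in% c("I", "S")) {
        roff <- roff + n
      } else if (ops[k] %in% c("D", "N")) {
        goff <- goff + n
      }
    }
  }
  if (!length(out)) {
    return(data.table(read_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  rbindlist(out)
}

# build one read-table row; qual defaults to Q37 everywhere
mk_read <- function(read_id = "r1", contig = "c1", pos = 0L, cigar, seq,
                    md, qual = NULL, strand = "+",
                    cb = NA_character_, ub = NA_character_,
                    gx = NA_character_) {
  if (is.null(qual)) qual <- paste(rep("F", nchar(seq)), collapse = "")
  data.table(read_id = read_id, flag = if (strand == "-") 16L else 0L,
             contig = contig, pos = as.integer(pos), strand = strand,
             cigar = cigar, seq = seq, qual = qual, md = md,
             cb = cb, ub = ub, gx = gx)
}

# a single-contig reference from a string
mk_ref <- function(seq, name = "c1") {
  r <- Biostrings::DNAStringSet(seq)
  names(r) <- name
  r
}

# n identical full-match reads over contig positions [pos, pos+len), with
# optional per-read substitutions: subs = list(read_index = c(pos = base))
mk_pile_reads <- function(refseq, n, pos = 0L, len = nchar(refseq) - pos,
                          subs = list(), qual_char = "F", contig = "c1",
                          gx = NA_character_, cb = NA_character_,
                          ub = NA_character_, strand = "+") {
  cs <- strsplit(refseq, "")[[1]]
  rows <- lapply(seq_len(n), function(i) {
    w <- cs[pos + seq_len(len)]
    s <- subs[[as.character(i)]]
    if (!is.null(s)) {
      for (p in as.integer(names(s))) w[p - pos + 1L] <- s[[as.character(p)]]
    }
    mism <- which(w != cs[pos + seq_len(len)])
    md <- if (!length(mism)) as.character(len) else {
      gaps <- diff(c(0L, mism)) - 1L
      paste0(paste0(gaps, cs[pos + mism], collapse = ""),
             len - mism[length(mism)])
    }
    mk_read(read_id = sprintf("pr%03d", i), contig = contig, pos = pos,
            cigar = paste0(len, "M"), seq = paste(w, collapse = ""),
            md = md, qual = paste(rep(qual_char, len), collapse = ""),
            strand = strand, cb = cb, ub = ub, gx = gx)
  })
  rbindlist(rows)
}

# fabricate a UMI-records table compatible with group_umis() output
mk_umis <- function(cell_barcode, umi, gene_id, conversion_count,
                    read_count = 1L, min_conversions = 2L) {
  dt <- data.table(cell_barcode = cell_barcode, umi = umi,
                   gene_id = gene_id, read_count = read_count,
                   read_ids = lapply(seq_along(cell_barcode),
                                     function(i) sprintf("rid%03d", i)),
                   conversion_positions = lapply(conversion_count,
                                                 function(k) seq_len(k)),
                   conversion_count = as.integer(conversion_count))
  dt[, labeled := conversion_count >= min_conversions]
  dt[]
}

hash_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) unname(tools::md5sum(f)), character(1))
}
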