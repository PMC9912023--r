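# Ground-truthed simulator: synthetic reference, gene models and tagged
# alignments emulating 4sU labeling chemistry (elevated T-to-C conversion in
# labeled units, uniform sequencing error across all 12 substitution types,
# SNP positions, two-point base qualities, multi-read UMIs in single-cell
# mode). Every planted event is recorded in truth tables.

#' Simulation configuration
#'
#' Defaults describe the data regime the pipeline targets: 90 nt
#' single-end sense-strand tag reads, half the genes on the minus strand,
#' a labeled read/molecule subpopulation converting each transcript-strand
#' T independently with probability `conversion_prob`, a uniform
#' per-base error rate spread evenly over the three alternative bases
#' (so the background rate of any single substitution type is
#' `error_rate / 3`), and a two-point quality mixture (Q37 / Q12) that
#' exercises the Q20 filter. Planted conversions carry high quality unless
#' `conversion_quality = "mixture"`.
#'
#' @param seed integer seed; fully determines all output.
#' @param n_genes number of genes (one single-exon gene per contig).
#' @param gene_length contig/gene length in bases.
#' @param strand_mix fraction of minus-strand genes (exact count by
#'   construction).
#' @param read_length read length in bases.
#' @param reads_per_gene bulk mode: reads simulated per gene.
#' @param n_cells,umis_per_cell,reads_per_umi single-cell mode geometry.
#' @param labeled_fraction probability a read (bulk) or molecule
#'   (single-cell) is labeled.
#' @param conversion_prob per-T conversion probability in labeled units.
#' @param error_rate per-base sequencing error probability.
#' @param snp_positions `data.frame(gene_id, offset, alt_fraction)` of
#'   planted SNPs (`offset` 0-based within the gene); the alternative base
#'   is drawn once per SNP.
#' @param quality_high,quality_low Phred values of the quality mixture.
#' @param low_quality_fraction fraction of bases drawn at `quality_low`.
#' @param conversion_quality `"high"` (default) or `"mixture"`.
#' @param spiked_genes `data.frame(gene_id, multiplier)` multiplying
#'   `labeled_fraction` for selected genes (capped at 1).
#' @param complex_frac fraction of bulk reads generated with mixed CIGARs
#'   (soft-clips, insertions, deletions) to exercise alignment walking;
#'   such reads carry errors but no conversions.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       gene_length = 300L,
                       strand_mix = 0.5,
                       read_length = 90L,
                       reads_per_gene = 200L,
                       n_cells = 500L,
                       umis_per_cell = 20L,
                       reads_per_umi = 2L,
                       labeled_fraction = 0.5,
                       conversion_prob = 0.04,
                       error_rate = 1e-3,
                       snp_positions = NULL,
                       quality_high = 37L,
                       quality_low = 12L,
                       low_quality_fraction = 0.10,
                       conversion_quality = c("high", "mixture"),
                       spiked_genes = NULL,
                       complex_frac = 0) {
  conversion_quality <- match.arg(conversion_quality)
  cfg <- as.list(environment())
  fr <- c(strand_mix, labeled_fraction, conversion_prob, error_rate,
          low_quality_fraction, complex_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (n_genes <= 0L || gene_length <= 0L) stop("n_genes, gene_length > 0")
  if (read_length > gene_length) stop("read_length exceeds gene_length")
  if (seed >= .Machine$integer.max) stop("seed too large")
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome and gene models
#'
#' One contig per gene (uniform base composition), with a single-exon gene
#' spanning it. Exactly `round(strand_mix * n_genes)` genes are placed on
#' the minus strand. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return list with `reference` ([Biostrings::DNAStringSet]) and `genes`
#'   (table as from [read_gene_models()]).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    ids <- sprintf("gene%04d", seq_len(config$n_genes))
    seqs <- vapply(ids, function(i)
      paste(sample(BASES, config$gene_length, replace = TRUE),
            collapse = ""), character(1L))
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- ids
    n_minus <- round(config$strand_mix * config$n_genes)
    minus <- sample(config$n_genes, n_minus)
    genes <- data.table(gene_id = ids, contig = ids, start = 0L,
                        end = config$gene_length,
                        strand = rep("+", config$n_genes))
    genes[minus, strand := "-"]
    list(reference = reference, genes = genes[])
  })
}

# run-length MD encoding for a pure-M alignment of length rl with
# mismatches at sorted 1-based offsets `off` whose reference bases are `rb`
md_encode <- function(off, rb, rl) {
  if (!length(off)) return(as.character(rl))
  gaps <- diff(c(0L, off)) - 1L
  paste0(paste0(gaps, rb, collapse = ""), rl - off[length(off)])
}

# Plant SNP draws and conversions into read/molecule windows of one gene.
# cs: contig chars; starts: 0-based window starts; labeled: logical;
# p_conv: scalar or per-unit vector. Returns the window matrices plus
# per-unit planted-position lists (0-based genomic).
plant_windows <- function(cs, starts, labeled, p_conv, strand, snps) {
  rl_n <- length(starts)
  rl <- attr(starts, "read_length")
  idx <- outer(seq_len(rl), starts, `+`)          # 1-based contig offsets
  Wref <- matrix(cs[idx], nrow = rl)
  W <- Wref
  snp_pos <- rep(list(integer(0)), rl_n)
  if (!is.null(snps) && nrow(snps)) {
    for (s in seq_len(nrow(snps))) {
      cells <- which(idx == snps$offset[s] + 1L)
      if (!length(cells)) next
      hit <- cells[runif(length(cells)) < snps$alt_fraction[s]]
      W[hit] <- snps$alt_base[s]
      cols <- ((hit - 1L) %/% rl) + 1L
      for (cl in unique(cols))
        snp_pos[[cl]] <- c(snp_pos[[cl]], snps$offset[s])
    }
  }
  tchar <- if (strand == "+") "T" else "A"
  cchar <- if (strand == "+") "C" else "G"
  eligible <- (W == tchar) & (Wref == tchar)
  p_conv <- rep_len(p_conv, rl_n)
  conv <- eligible &
    matrix(runif(rl * rl_n) < rep(p_conv, each = rl), nrow = rl) &
    matrix(rep(labeled, each = rl), nrow = rl)
  W[conv] <- cchar
  conv_pos <- lapply(seq_len(rl_n), function(j) {
    r <- which(conv[, j])
    as.integer(starts[j] + r - 1L)
  })
  list(W = W, Wref = Wref, conv = conv, conv_pos = conv_pos,
       snp_pos = snp_pos, idx = idx)
}

# Overlay sequencing errors (never on planted conversions) and assign
# qualities; build SEQ/QUAL/MD strings. Returns a data.table fragment.
finalize_reads <- function(pw, starts, cfg) {
  rl <- nrow(pw$W)
  n <- ncol(pw$W)
  W <- pw$W
  # errors overlay only bases that still match the reference: planted
  # conversions and SNP draws keep their identity, and every recorded
  # error is guaranteed to be visible as a mismatch
  err <- matrix(runif(rl * n) < cfg$error_rate, nrow = rl) &
    !pw$conv & (W == pw$Wref)
  if (any(err)) {
    cur <- W[err]
    pick <- ceiling(runif(length(cur)) * 3)
    W[err] <- vapply(seq_along(cur), function(i)
      BASES[BASES != cur[i]][pick[i]], character(1L))
    # an "error" that redraws the same base class cannot happen (3 distinct
    # alternatives), but one may coincide with the reference only when the
    # pre-error base already differed from it (SNP cells)
  }
  q <- matrix(ifelse(runif(rl * n) < cfg$low_quality_fraction,
                     cfg$quality_low, cfg$quality_high), nrow = rl)
  if (cfg$conversion_quality == "high") q[pw$conv] <- cfg$quality_high
  qc <- matrix(intToUtf8(as.vector(q) + 33L, multiple = TRUE), nrow = rl)
  seqs <- do.call(paste0, lapply(seq_len(rl), function(i) W[i, ]))
  quals <- do.call(paste0, lapply(seq_len(rl), function(i) qc[i, ]))
  mds <- character(n)
  err_pos <- rep(list(integer(0)), n)
  mism_any <- colSums(W != pw$Wref) > 0L
  for (j in seq_len(n)) {
    if (mism_any[j]) {
      off <- which(W[, j] != pw$Wref[, j])
      mds[j] <- md_encode(off, pw$Wref[off, j], rl)
    } else mds[j] <- as.character(rl)
    e <- which(err[, j])
    if (length(e)) err_pos[[j]] <- as.integer(starts[j] + e - 1L)
  }
  list(seq = seqs, qual = quals, md = mds, err_pos = err_pos)
}

# one read with a randomly structured CIGAR (soft-clips / insertion /
# deletion), errors on aligned bases, no conversions
complex_read <- function(cs, rl) {
  L <- length(cs)
  s1 <- if (runif(1) < 0.4) sample(1:5, 1L) else 0L
  s2 <- if (runif(1) < 0.4) sample(1:5, 1L) else 0L
  ilen <- if (runif(1) < 0.5) sample(1:3, 1L) else 0L
  dlen <- if (runif(1) < 0.5) sample(1:3, 1L) else 0L
  na <- rl - s1 - s2 - ilen
  if (na < 3L) { s1 <- 0L; s2 <- 0L; na <- rl - ilen }
  a <- sample(seq_len(na - 2L), 1L)
  b <- sample(seq_len(na - a - 1L), 1L)
  cc <- na - a - b
  span <- na + dlen
  start <- sample(0:(L - span), 1L)
  seg1 <- cs[start + seq_len(a)]
  seg2 <- cs[start + a + seq_len(b)]
  del <- if (dlen) cs[start + a + b + seq_len(dlen)] else character(0)
  seg3 <- cs[start + a + b + dlen + seq_len(cc)]
  aligned <- c(seg1, seg2, seg3)
  ref_aligned <- aligned
  err <- runif(length(aligned)) < 0.03
  if (any(err)) {
    for (i in which(err))
      aligned[i] <- sample(BASES[BASES != aligned[i]], 1L)
  }
  p1 <- aligned[seq_len(a)]
  p2 <- aligned[a + seq_len(b)]
  p3 <- aligned[a + b + seq_len(cc)]
  ins <- if (ilen) sample(BASES, ilen, replace = TRUE) else character(0)
  sc1 <- if (s1) sample(BASES, s1, replace = TRUE) else character(0)
  sc2 <- if (s2) sample(BASES, s2, replace = TRUE) else character(0)
  seqv <- c(sc1, p1, ins, p2, p3, sc2)
  cig <- paste0(c(if (s1) paste0(s1, "S"),
                  paste0(a, "M"),
                  if (ilen) paste0(ilen, "I"),
                  if (dlen) c(paste0(b, "M"), paste0(dlen, "D"),
                              paste0(cc, "M"))
                  else paste0(b + cc, "M"),
                  if (s2) paste0(s2, "S")), collapse = "")
  # MD: matches/mismatches over segments 1,2 then ^del then segment 3
  md12 <- which(c(p1, p2) != ref_aligned[seq_len(a + b)])
  md3 <- which(p3 != ref_aligned[a + b + seq_len(cc)])
  md_a <- md_encode(md12, ref_aligned[md12], a + b)
  md_c <- md_encode(md3, ref_aligned[a + b + md3], cc)
  md <- if (dlen) paste0(md_a, "^", paste(del, collapse = ""), md_c)
        else md_encode(c(md12, a + b + md3),
                       ref_aligned[c(md12, a + b + md3)], a + b + cc)
  list(start = start, cigar = cig, seq = paste(seqv, collapse = ""),
       qual = paste(rep("F", length(seqv)), collapse = ""), md = md)
}

#' Simulate a bulk labeling experiment
#'
#' Draws `reads_per_gene` reads per gene, marks each labeled with
#' probability `labeled_fraction` (times any per-gene spike multiplier),
#' converts transcript-strand Ts in labeled reads with `conversion_prob`
#' (written as genomic A>G on minus-strand genes), overlays uniform
#' sequencing errors on non-converted positions, emits SNP alternative
#' bases at planted positions, and computes MD tags from the final
#' sequences.
#'
#' @param config a [sim_config()].
#' @return list with `reads` (read table), `reference`, `genes`, and
#'   `truth` (list of `reads`, `snps`, `genes` tables recording every
#'   planted event).
#' @export
simulate_bulk <- function(config) {
  refs <- simulate_reference(config)
  genes <- refs$genes
  mult <- rep(1, nrow(genes))
  if (!is.null(config$spiked_genes)) {
    sg <- as.data.table(config$spiked_genes)
    mult[match(sg$gene_id, genes$gene_id)] <- sg$multiplier
  }
  snps <- NULL
  with_seed(config$seed + 1L, {
    if (!is.null(config$snp_positions)) {
      snps <- as.data.table(config$snp_positions)
      snps[, contig := genes$contig[match(gene_id, genes$gene_id)]]
      cs_ref <- vapply(seq_len(nrow(snps)), function(i) {
        contig_chars(refs$reference, snps$contig[i])[snps$offset[i] + 1L]
      }, character(1L))
      snps[, alt_base := vapply(cs_ref, function(b)
        sample(BASES[BASES != b], 1L), character(1L))]
      snps[, ref_base := cs_ref]
    }
    rl <- config$read_length
    read_rows <- vector("list", nrow(genes))
    truth_rows <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      cs <- contig_chars(refs$reference, genes$contig[g])
      n <- config$reads_per_gene
      n_cplx <- round(config$complex_frac * n)
      n_std <- n - n_cplx
      frag_r <- frag_t <- NULL
      if (n_std > 0L) {
        starts <- sample(0:(config$gene_length - rl), n_std, replace = TRUE)
        attr(starts, "read_length") <- rl
        labeled <- runif(n_std) < min(1, config$labeled_fraction * mult[g])
        pw <- plant_windows(cs, starts, labeled, config$conversion_prob,
                            genes$strand[g],
                            if (is.null(snps)) NULL else snps[gene_id == gid])
        fr <- finalize_reads(pw, starts, config)
        ids <- sprintf("%s_r%06d", gid, seq_len(n_std))
        frag_r <- data.table(
          read_id = ids,
          flag = if (genes$strand[g] == "-") 16L else 0L,
          contig = genes$contig[g], pos = as.integer(starts),
          strand = genes$strand[g],
          cigar = paste0(rl, "M"),
          seq = fr$seq, qual = fr$qual, md = fr$md,
          cb = NA_character_, ub = NA_character_, gx = NA_character_)
        frag_t <- data.table(
          read_id = ids, gene_id = gid, labeled = labeled,
          conversion_pos = vapply(pw$conv_pos, paste, character(1L),
                                  collapse = ","),
          error_pos = vapply(fr$err_pos, paste, character(1L),
                             collapse = ","),
          snp_pos = vapply(pw$snp_pos, function(p)
            paste(sort(unique(p)), collapse = ","), character(1L)))
      }
      if (n_cplx > 0L) {
        cx <- lapply(seq_len(n_cplx), function(i) complex_read(cs, rl))
        ids <- sprintf("%s_cx%05d", gid, seq_len(n_cplx))
        frag_r <- rbindlist(list(frag_r, data.table(
          read_id = ids,
          flag = if (genes$strand[g] == "-") 16L else 0L,
          contig = genes$contig[g],
          pos = vapply(cx, `[[`, integer(1L), "start"),
          strand = genes$strand[g],
          cigar = vapply(cx, `[[`, character(1L), "cigar"),
          seq = vapply(cx, `[[`, character(1L), "seq"),
          qual = vapply(cx, `[[`, character(1L), "qual"),
          md = vapply(cx, `[[`, character(1L), "md"),
          cb = NA_character_, ub = NA_character_, gx = NA_character_)))
        frag_t <- rbindlist(list(frag_t, data.table(
          read_id = ids, gene_id = gid, labeled = FALSE,
          conversion_pos = "", error_pos = "", snp_pos = "")))
      }
      read_rows[[g]] <- frag_r
      truth_rows[[g]] <- frag_t
    }
    reads <- rbindlist(read_rows)
    truth_reads <- rbindlist(truth_rows)
    truth_genes <- data.table(gene_id = genes$gene_id,
                              strand = genes$strand,
                              spike_multiplier = mult,
                              spiked = mult != 1)
    list(reads = reads[], reference = refs$reference, genes = genes,
         truth = list(reads = truth_reads[], snps = snps,
                      genes = truth_genes[]))
  })
}

# Generate reads for a prespecified molecule table (single-cell engine).
# mol: data.table(cell_barcode, umi, gene_id, labeled, p_conv)
sim_molecule_reads <- function(refs, mol, config) {
  genes <- refs$genes
  rl <- config$read_length
  read_rows <- list()
  mol <- copy(mol)
  mol[, mol_id := seq_len(.N)]
  mol[, conversion_pos := ""]
  mol[, n_planted := 0L]
  for (gid in unique(mol$gene_id)) {
    g <- genes[gene_id == gid]
    cs <- contig_chars(refs$reference, g$contig)
    sub <- mol[gene_id == gid]
    n <- nrow(sub)
    starts <- sample(0:(config$gene_length - rl), n, replace = TRUE)
    attr(starts, "read_length") <- rl
    pw <- plant_windows(cs, starts, sub$labeled, sub$p_conv, g$strand, NULL)
    mol[sub$mol_id, `:=`(
      conversion_pos = vapply(pw$conv_pos, paste, character(1L),
                              collapse = ","),
      n_planted = vapply(pw$conv_pos, length, integer(1L)))]
    for (r in seq_len(config$reads_per_umi)) {
      fr <- finalize_reads(pw, starts, config)
      read_rows[[length(read_rows) + 1L]] <- data.table(
        read_id = sprintf("%s_%s_%s_rep%d", sub$cell_barcode, sub$umi,
                          gid, r),
        flag = if (g$strand == "-") 16L else 0L,
        contig = g$contig, pos = as.integer(starts), strand = g$strand,
        cigar = paste0(rl, "M"), seq = fr$seq, qual = fr$qual, md = fr$md,
        cb = sub$cell_barcode, ub = sub$umi, gx = gid)
    }
  }
  list(reads = rbindlist(read_rows),
       molecules = mol[, .(cell_barcode, umi, gene_id, labeled,
                           n_planted, conversion_pos)])
}

#' Simulate a single-cell labeling experiment
#'
#' Generates `n_cells` cells with `umis_per_cell` molecules each (genes
#' drawn uniformly), every molecule labeled with probability
#' `labeled_fraction`. All reads of one UMI share the molecule's start,
#' labeled flag and planted conversion positions; sequencing errors and
#' base qualities are drawn independently per read. Reads carry CB/UB/GX
#' tags.
#'
#' @param config a [sim_config()].
#' @return list with `reads`, `reference`, `genes` and `truth` (list with
#'   `molecules` table: `cell_barcode`, `umi`, `gene_id`, `labeled`,
#'   `n_planted` distinct planted conversions, `conversion_pos`).
#' @export
simulate_sc <- function(config) {
  if (config$umis_per_cell <= 0L || config$n_cells <= 0L ||
      config$reads_per_umi <= 0L)
    stop("single-cell mode needs n_cells, umis_per_cell, reads_per_umi > 0")
  refs <- simulate_reference(config)
  with_seed(config$seed + 2L, {
    cells <- sprintf("CELL%04d", seq_len(config$n_cells))
    mol <- data.table(
      cell_barcode = rep(cells, each = config$umis_per_cell),
      umi = rep(sprintf("UMI%04d", seq_len(config$umis_per_cell)),
                times = config$n_cells))
    mol[, gene_id := sample(refs$genes$gene_id, .N, replace = TRUE)]
    mol[, labeled := runif(.N) < config$labeled_fraction]
    mol[, p_conv := config$conversion_prob]
    sim <- sim_molecule_reads(refs, mol, config)
    list(reads = sim$reads, reference = refs$reference, genes = refs$genes,
         truth = list(molecules = sim$molecules))
  })
}

#' Simulate a dissociation-activation scenario
#'
#' Two cell populations share an identical baseline transcriptome; the
#' "activated" subpopulation additionally carries labeled molecules on a
#' set of stress genes, modeling transcripts synthesised during
#' dissociation. Stress molecules are fully nascent, so they convert at a
#' high per-T rate (`stress_conversion_prob`) and nearly all carry two or
#' more conversions. Removing labeled molecules should therefore collapse
#' the difference between the populations.
#'
#' @param config a [sim_config()]; its `labeled_fraction` is the shared
#'   baseline labeling level.
#' @param n_stress_genes number of stress genes (first genes of the
#'   reference).
#' @param stress_umis_per_gene extra labeled molecules per stress gene in
#'   each activated cell.
#' @param stress_conversion_prob per-T conversion probability of stress
#'   molecules.
#' @param activated_fraction fraction of cells in the activated
#'   subpopulation.
#' @return as [simulate_sc()], plus `cell_groups` (`cell_barcode`,
#'   `group`) and `stress_genes` in `truth`.
#' @export
simulate_activation_scenario <- function(config,
                                         n_stress_genes = 20L,
                                         stress_umis_per_gene = 3L,
                                         stress_conversion_prob = 0.2,
                                         activated_fraction = 0.5) {
  refs <- simulate_reference(config)
  stress <- refs$genes$gene_id[seq_len(n_stress_genes)]
  with_seed(config$seed + 2L, {
    cells <- sprintf("CELL%04d", seq_len(config$n_cells))
    n_act <- round(activated_fraction * config$n_cells)
    group <- rep("parent", config$n_cells)
    group[sample(config$n_cells, n_act)] <- "activated"
    base <- data.table(
      cell_barcode = rep(cells, each = config$umis_per_cell),
      umi = rep(sprintf("UMI%04d", seq_len(config$umis_per_cell)),
                times = config$n_cells))
    base[, gene_id := sample(refs$genes$gene_id, .N, replace = TRUE)]
    base[, labeled := runif(.N) < config$labeled_fraction]
    base[, p_conv := config$conversion_prob]
    act_cells <- cells[group == "activated"]
    extra <- CJ(cell_barcode = act_cells, gene_id = stress,
                rep = seq_len(stress_umis_per_gene))
    extra[, umi := sprintf("UMIS%03d", seq_len(.N)), by = cell_barcode]
    extra[, `:=`(labeled = TRUE, p_conv = stress_conversion_prob,
                 rep = NULL)]
    mol <- rbindlist(list(base, extra), use.names = TRUE)
    sim <- sim_molecule_reads(refs, mol, config)
    list(reads = sim$reads, reference = refs$reference, genes = refs$genes,
         truth = list(molecules = sim$molecules,
                      cell_groups = data.table(cell_barcode = cells,
                                               group = group),
                      stress_genes = stress))
  })
}

#' Write a simulation to disk
#'
#' Emits `reference.fa`, `genes.gtf`, `alignments.sam` and truth TSVs
#' (`truth_reads.tsv` / `truth_molecules.tsv`, `truth_snps.tsv`,
#' `truth_genes.tsv` as applicable) into `dir`.
#'
#' @param sim result of [simulate_bulk()], [simulate_sc()] or
#'   [simulate_activation_scenario()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_gtf(sim$genes, file.path(dir, "genes.gtf"))
  write_sam(sim$reads, sim$reference, file.path(dir, "alignments.sam"))
  tr <- sim$truth
  if (!is.null(tr$reads))
    write_tsv(tr$reads, file.path(dir, "truth_reads.tsv"))
  if (!is.null(tr$molecules))
    write_tsv(tr$molecules, file.path(dir, "truth_molecules.tsv"))
  if (!is.null(tr$snps))
    write_tsv(tr$snps, file.path(dir, "truth_snps.tsv"))
  if (!is.null(tr$genes))
    write_tsv(tr$genes, file.path(dir, "truth_genes.tsv"))
  if (!is.null(tr$cell_groups))
    write_tsv(tr$cell_groups, file.path(dir, "truth_cell_groups.tsv"))
  invisible(dir)
}
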