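# UMI grouping, labeled-molecule removal, matrices and reports.

# tiny crafted single-cell dataset: one plus-strand gene over a poly-T
# contig; conversions are C substitutions at chosen 0-based positions
sc_reads <- function(spec) {
  # spec: list of list(cell, umi, read, conv = integer positions, qual)
  rows <- lapply(spec, function(s) {
    len <- 30L
    w <- rep("T", len)
    conv <- s$conv %||% integer(0)
    w[conv + 1L] <- "C"
    md <- if (!length(conv)) as.character(len) else {
      sorted <- sort(conv + 1L)
      gaps <- diff(c(0L, sorted)) - 1L
      paste0(paste0(gaps, "T", collapse = ""), len - sorted[length(sorted)])
    }
    qual <- s$qual %||% paste(rep("F", len), collapse = "")
    mk_read(read_id = s$read, contig = "c1", pos = 0L, cigar = "30M",
            seq = paste(w, collapse = ""), md = md, qual = qual,
            cb = s$cell, ub = s$umi, gx = "g1")
  })
  rbindlist(rows)
}

sc_genes <- data.table(gene_id = "g1", contig = "c1", start = 0L,
                       end = 30L, strand = "+")

test_that("UMI conversion events are the union over supporting reads", {
  reads <- sc_reads(list(
    list(cell = "c01", umi = "u1", read = "r1", conv = 5L),
    list(cell = "c01", umi = "u1", read = "r2", conv = c(5L, 9L)),
    list(cell = "c01", umi = "u1", read = "r3", conv = integer(0))))
  u <- group_umis(reads, sc_genes)
  expect_equal(nrow(u), 1L)
  expect_equal(u$read_count, 3L)
  expect_equal(u$conversion_count, 2L)
  expect_equal(u$conversion_positions[[1]], c(5L, 9L))
  expect_true(u$labeled)
})

test_that("the same position in every read counts once, below threshold", {
  reads <- sc_reads(lapply(1:3, function(i)
    list(cell = "c01", umi = "u1", read = paste0("r", i), conv = 7L)))
  u <- group_umis(reads, sc_genes)
  expect_equal(u$conversion_count, 1L)
  expect_false(u$labeled)
})

test_that("conversions below Q20 contribute nothing", {
  lowq <- paste0(strrep("F", 7), "4", strrep("F", 22))  # Q19 at offset 7
  reads <- sc_reads(list(
    list(cell = "c01", umi = "u1", read = "r1", conv = 7L, qual = lowq)))
  u <- group_umis(reads, sc_genes)
  expect_equal(u$conversion_count, 0L)
})

test_that("any_read mode takes the maximum over single reads", {
  reads <- sc_reads(list(
    list(cell = "c01", umi = "u1", read = "r1", conv = 5L),
    list(cell = "c01", umi = "u1", read = "r2", conv = 9L)))
  u_union <- group_umis(reads, sc_genes, mode = "union")
  u_any <- group_umis(reads, sc_genes, mode = "any_read")
  expect_equal(u_union$conversion_count, 2L)
  expect_equal(u_any$conversion_count, 1L)
})

test_that("untagged reads are skipped and counted", {
  tagged <- sc_reads(list(list(cell = "c01", umi = "u1", read = "r1")))
  untagged <- mk_read(read_id = "naked", contig = "c1", cigar = "30M",
                      seq = strrep("T", 30), md = "30")
  u <- group_umis(rbind(tagged, untagged), sc_genes)
  expect_equal(nrow(u), 1L)
  expect_equal(attr(u, "n_untagged"), 1L)
})

test_that("count matrices conserve molecules entry-wise", {
  u <- mk_umis(cell_barcode = rep("c01", 5), umi = paste0("u", 1:5),
               gene_id = "g1", conversion_count = c(0, 1, 2, 3, 0))
  m <- regenerate_count_matrix(u)
  expect_equal(as.numeric(m$raw["g1", "c01"]), 5)
  expect_equal(as.numeric(m$corrected["g1", "c01"]), 3)
  expect_equal(nrow(m$removed_umis), 2L)
  expect_equal(sum(m$raw), sum(m$corrected) + nrow(m$removed_umis))
  # a threshold no molecule reaches makes correction the identity
  u_hi <- mk_umis(cell_barcode = rep("c01", 5), umi = paste0("u", 1:5),
                  gene_id = "g1", conversion_count = c(0, 1, 2, 3, 0),
                  min_conversions = 100L)
  m_hi <- regenerate_count_matrix(u_hi)
  expect_equal(m_hi$raw, m_hi$corrected)
})

test_that("per-cell labeled-gene percentage follows its definition", {
  u <- mk_umis(cell_barcode = rep("c01", 10), umi = paste0("u", 1:10),
               gene_id = paste0("g", 1:10),
               conversion_count = c(1, 1, 1, rep(0, 7)))
  pc <- per_cell_labeled_gene_fraction(u, min_events = 1L)
  expect_equal(pc$pct_labeled_genes, 30)
  u0 <- mk_umis(cell_barcode = rep("c02", 4), umi = paste0("u", 1:4),
                gene_id = paste0("g", 1:4), conversion_count = rep(0, 4))
  pc0 <- per_cell_labeled_gene_fraction(u0)
  expect_equal(pc0$pct_labeled_genes, 0)
})

test_that("cell-type summary applies the 250-unit / 10% filter", {
  mk_ct_case <- function(n_units, n_labeled, gene, cell) {
    mk_umis(cell_barcode = rep(cell, n_units),
            umi = sprintf("u%04d", seq_len(n_units)),
            gene_id = gene,
            conversion_count = c(rep(2L, n_labeled),
                                 rep(0L, n_units - n_labeled)))
  }
  u <- rbind(mk_ct_case(300, 45, "gA", "c01"),   # 300 >= 250, 15% -> pass
             mk_ct_case(200, 40, "gB", "c02"),   # too few units
             mk_ct_case(1000, 50, "gC", "c03"))  # 5% < 10%
  ctmap <- data.table(cell_barcode = c("c01", "c02", "c03"),
                      cell_type = c("t1", "t2", "t3"))
  sm <- celltype_gene_labeling_summary(u, ctmap)
  expect_true(sm[gene_id == "gA", unique(passes_filter)])
  expect_false(sm[gene_id == "gB", unique(passes_filter)])
  expect_false(sm[gene_id == "gC", unique(passes_filter)])
  expect_equal(sm[gene_id == "gA", fraction], 0.15)
  # unmapped barcodes fall into an explicit "unknown" type
  sm2 <- celltype_gene_labeling_summary(u, ctmap[1:2])
  expect_true("unknown" %in% sm2$cell_type)
})

test_that("removal report lists genes by the 3-read / 5% rule", {
  reads <- sc_reads(c(
    lapply(1:7, function(i)                       # 7 labeled singles
      list(cell = "c01", umi = paste0("lab", i), read = paste0("L", i),
           conv = c(3L, 11L))),
    lapply(1:93, function(i)
      list(cell = "c01", umi = paste0("bg", i), read = paste0("B", i)))))
  ref <- mk_ref(strrep("T", 30))
  u <- group_umis(reads, sc_genes)
  ctmap <- data.table(cell_barcode = "c01", cell_type = "microglia")
  rep1 <- removal_report(u, reads, ref, sc_genes, ctmap)
  per <- rep1$by_gene_celltype
  expect_equal(per$reads_total, 100L)
  expect_equal(per$reads_removed, 7L)
  expect_equal(per$removal_fraction, 0.07)
  expect_equal(rep1$listed_genes$gene_id, "g1")
  expect_equal(rep1$listed_genes$removed_labeling_rate, 2 / 30)
  # 2 removed of 10 violates the minimum of 3
  reads2 <- sc_reads(c(
    lapply(1:2, function(i)
      list(cell = "c01", umi = paste0("lab", i), read = paste0("L", i),
           conv = c(3L, 11L))),
    lapply(1:8, function(i)
      list(cell = "c01", umi = paste0("bg", i), read = paste0("B", i)))))
  u2 <- group_umis(reads2, sc_genes)
  rep2 <- removal_report(u2, reads2, ref, sc_genes, ctmap)
  expect_equal(nrow(rep2$listed_genes), 0L)
})

test_that("gradual removal is exact, nested and seed-deterministic", {
  u <- mk_umis(cell_barcode = rep("c01", 200),
               umi = sprintf("u%03d", 1:200), gene_id = "g1",
               conversion_count = c(rep(2L, 100), rep(0L, 100)))
  full <- regenerate_count_matrix(u)
  gr <- gradual_removal(u, c(0, 0.25, 0.5, 1), seed = 99L)
  expect_equal(gr[["0"]]$corrected, full$raw)
  expect_equal(gr[["1"]]$corrected, full$corrected)
  expect_equal(nrow(gr[["0.25"]]$removed_umis), 25L)
  expect_equal(nrow(gr[["0.5"]]$removed_umis), 50L)
  # nested subsets
  expect_true(all(gr[["0.25"]]$removed_umis$umi %in%
                    gr[["0.5"]]$removed_umis$umi))
  gr2 <- gradual_removal(u, c(0.25), seed = 99L)
  expect_equal(gr2[["0.25"]]$removed_umis, gr[["0.25"]]$removed_umis)
})

test_that("lowering the conversion threshold removes at least as much", {
  cfg <- sim_config(seed = 41, n_genes = 10, n_cells = 40,
                    umis_per_cell = 10, reads_per_umi = 2,
                    labeled_fraction = 0.4)
  sim <- simulate_sc(cfg)
  totals <- sapply(c(1L, 2L, 3L), function(k) {
    u <- group_umis(sim$reads, sim$genes, min_conversions = k)
    sum(regenerate_count_matrix(u)$corrected)
  })
  expect_true(all(diff(totals) >= 0))
})

test_that("two populations with different labeling order as expected", {
  cfg_hi <- sim_config(seed = 42, n_genes = 10, n_cells = 30,
                       umis_per_cell = 15, reads_per_umi = 2,
                       labeled_fraction = 0.3, conversion_prob = 0.08)
  cfg_lo <- sim_config(seed = 43, n_genes = 10, n_cells = 30,
                       umis_per_cell = 15, reads_per_umi = 2,
                       labeled_fraction = 0.05, conversion_prob = 0.08)
  pc <- function(cfg) {
    sim <- simulate_sc(cfg)
    u <- group_umis(sim$reads, sim$genes)
    mean(per_cell_labeled_gene_fraction(u, min_events = 1L)$pct_labeled_genes)
  }
  expect_gt(pc(cfg_hi), pc(cfg_lo))
})
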