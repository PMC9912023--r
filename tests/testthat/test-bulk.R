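# Per-gene labeling rates, SD selection, comparison, consensus, PCA input.

gene_tbl <- function(n = 1L, len = 10L, strand = "+") {
  data.table(gene_id = sprintf("g%d", seq_len(n)),
             contig = sprintf("c%d", seq_len(n)),
             start = 0L, end = as.integer(len), strand = strand)
}

stats_tbl <- function(rates, ids = sprintf("g%d", seq_along(rates))) {
  data.table(gene_id = ids, t_observations = 1000L,
             converted_observations = as.integer(round(rates * 1000)),
             t_sites = 100L, converted_sites = 0L, rate = rates,
             read_count = 10L)
}

test_that("observation and site mode rates follow their definitions", {
  refseq <- strrep("T", 10)
  ref <- mk_ref(refseq)
  reads <- mk_pile_reads(refseq, 10, subs = list(`1` = c(`4` = "C")))
  g <- gene_tbl()
  st_obs <- gene_labeling_stats(reads, ref, g, mode = "observation")
  expect_equal(st_obs$t_observations, 100L)
  expect_equal(st_obs$converted_observations, 1L)
  expect_equal(st_obs$rate, 0.01)
  st_site <- gene_labeling_stats(reads, ref, g, mode = "site")
  expect_equal(st_site$t_sites, 10L)
  expect_equal(st_site$converted_sites, 1L)
  expect_equal(st_site$rate, 0.1)
})

test_that("blacklisted positions count for neither numerator nor denominator", {
  refseq <- strrep("T", 10)
  ref <- mk_ref(refseq)
  reads <- mk_pile_reads(refseq, 10, subs = list(`1` = c(`4` = "C")))
  bl <- data.table(contig = "c1", pos = 4L, reason = "alt_fraction")
  st <- gene_labeling_stats(reads, ref, gene_tbl(), blacklist = bl)
  expect_equal(st$t_observations, 90L)
  expect_equal(st$converted_observations, 0L)
  expect_equal(st$rate, 0)    # only conversion was blacklisted
})

test_that("genes without transcript-strand T coverage get a missing rate", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("G", 10),
                                    c2 = strrep("T", 10)))
  genes <- data.table(gene_id = c("g1", "g2"), contig = c("c1", "c2"),
                      start = 0L, end = 10L, strand = "+")
  reads <- rbind(mk_pile_reads(strrep("G", 10), 5, contig = "c1"),
                 mk_pile_reads(strrep("T", 10), 5, contig = "c2"))
  reads[, read_id := sprintf("r%02d", .I)]
  st <- gene_labeling_stats(reads, ref, genes)
  expect_true(is.na(st[gene_id == "g1", rate]))
  expect_equal(st[gene_id == "g2", rate], 0)
})

test_that("minus-strand genes count A>G as conversions", {
  refseq <- strrep("A", 10)
  ref <- mk_ref(refseq)
  reads <- mk_pile_reads(refseq, 10, strand = "-",
                         subs = list(`1` = c(`4` = "G")))
  st <- gene_labeling_stats(reads, ref, gene_tbl(strand = "-"))
  expect_equal(st$converted_observations, 1L)
  expect_equal(st$rate, 0.01)
})

test_that("antisense reads are discarded by default but kept on request", {
  refseq <- strrep("T", 10)
  ref <- mk_ref(refseq)
  reads <- mk_pile_reads(refseq, 10, strand = "-")  # gene is plus-strand
  st <- gene_labeling_stats(reads, ref, gene_tbl())
  expect_equal(st$read_count, 0L)
  st2 <- gene_labeling_stats(reads, ref, gene_tbl(),
                             discard_antisense = FALSE)
  expect_equal(st2$read_count, 10L)
})

test_that("SD selection uses n-1 SD and a strict threshold", {
  st <- stats_tbl(c(rep(0, 9), 1))
  sel <- select_labeled_genes(st, k = 1)
  expect_equal(sel$mean_rate, 0.1)
  expect_equal(sel$sd_rate, sd(c(rep(0, 9), 1)))
  expect_equal(sel$genes, "g10")
  # identical rates: SD 0, strict inequality -> empty set
  sel0 <- select_labeled_genes(stats_tbl(rep(0.01, 10)), k = 5)
  expect_equal(length(sel0$genes), 0L)
  # a gene exactly at the threshold is not selected
  r <- c(rep(0.01, 9), 0.02)
  thr <- mean(r) + 1 * sd(r)
  st2 <- stats_tbl(c(r, thr), ids = sprintf("g%d", 1:11))
  sel2 <- select_labeled_genes(st2, k = 1)
  expect_false("g11" %in% sel2$genes)
})

test_that("missing rates are excluded from mean/SD but reported", {
  st <- stats_tbl(c(0.01, 0.02, NA, 0.03))
  sel <- select_labeled_genes(st, k = 1)
  expect_equal(sel$n_scored, 3L)
  expect_equal(sel$mean_rate, mean(c(0.01, 0.02, 0.03)))
})

test_that("two identical samples classify only as high_in_both/background", {
  st <- stats_tbl(c(rep(0.01, 20), 0.5))
  cmp <- compare_samples(st, st, k = 1)
  expect_true(all(cmp$classification$class %in%
                    c("high_in_both", "background")))
  expect_equal(cmp$classification[class == "high_in_both", gene_id], "g21")
})

test_that("asymmetric spikes classify to the correct side", {
  a <- stats_tbl(c(rep(0.01, 20), 0.5, 0.6))
  b <- stats_tbl(c(rep(0.01, 20), 0.5, 0.01))
  cmp <- compare_samples(a, b, k = 1)
  cl <- cmp$classification
  expect_equal(cl[gene_id == "g21", class], "high_in_both")
  expect_equal(cl[gene_id == "g22", class], "high_in_A_only")
  # genes missing in one sample are reported, not dropped
  a2 <- stats_tbl(c(rep(0.01, 20), 0.5, NA))
  cmp2 <- compare_samples(a2, b, k = 1)
  expect_equal(cmp2$classification[gene_id == "g22", class], "unscored")
  # disjoint universes are an error
  b3 <- stats_tbl(rep(0.01, 3), ids = c("x1", "x2", "x3"))
  expect_error(compare_samples(a, b3), "share no genes")
})

test_that("consensus keeps genes present in >= min_samples sets", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d"), c("b"))
  expect_equal(consensus_genes(sets, 3), c("a", "b"))
  expect_equal(consensus_genes(sets, 2), c("a", "b"))
  expect_false("c" %in% consensus_genes(sets, 2))
  expect_error(consensus_genes(sets, 6), "exceeds")
})

test_that("PCA input keeps complete genes above threshold in >= 1 sample", {
  a <- stats_tbl(c(rep(0.01, 20), 0.5, NA))
  b <- stats_tbl(c(rep(0.01, 20), 0.5, 0.7))
  m <- pca_input_matrix(list(A = a, B = b), k = 1)
  expect_true("g21" %in% rownames(m))
  expect_false("g22" %in% rownames(m))  # missing in sample A
  expect_equal(ncol(m), 2L)
  # nothing above threshold anywhere -> empty with warning
  flat <- stats_tbl(rep(0.01, 10))
  expect_warning(m0 <- pca_input_matrix(list(A = flat, B = flat), k = 1))
  expect_equal(nrow(m0), 0L)
})

test_that("doubling coverage leaves observation-mode rates unchanged", {
  cfg <- sim_config(seed = 31, n_genes = 8, reads_per_gene = 40)
  sim <- simulate_bulk(cfg)
  dup <- copy(sim$reads)[, read_id := paste0(read_id, "_dup")]
  both <- rbind(sim$reads, dup)
  st1 <- gene_labeling_stats(sim$reads, sim$reference, sim$genes)
  st2 <- gene_labeling_stats(both, sim$reference, sim$genes)
  expect_equal(st1$rate, st2$rate)
  expect_equal(st2$t_observations, 2L * st1$t_observations)
})

test_that("spiked genes are recovered and a null run stays near-empty", {
  spikes <- data.frame(gene_id = sprintf("gene%04d", 1:5), multiplier = 20)
  cfg <- sim_config(seed = 32, n_genes = 250, reads_per_gene = 80,
                    labeled_fraction = 0.025, spiked_genes = spikes)
  sim <- simulate_bulk(cfg)
  pu <- build_pileup(sim$reads, sim$reference)
  bl <- build_blacklist(pu)
  st <- gene_labeling_stats(sim$reads, sim$reference, sim$genes,
                            blacklist = bl)
  sel <- select_labeled_genes(st, k = 5)
  expect_gte(sum(spikes$gene_id %in% sel$genes), 4L)
  cfg0 <- sim_config(seed = 32, n_genes = 250, reads_per_gene = 80,
                     labeled_fraction = 0.025, conversion_prob = 0,
                     spiked_genes = spikes)
  sim0 <- simulate_bulk(cfg0)
  st0 <- gene_labeling_stats(sim0$reads, sim0$reference, sim0$genes,
                             blacklist = build_blacklist(
                               build_pileup(sim0$reads, sim0$reference)))
  sel0 <- select_labeled_genes(st0, k = 5)
  expect_lte(length(sel0$genes), 3L)
  expect_lt(length(sel0$genes), length(sel$genes))
})
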