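one_gene_annotation <- function(tss = 10000, strand = "+",
                                type = "protein_coding", tsl = 1,
                                expr = 5, gene_id = "G1",
                                gene_name = "GeneOne",
                                transcript_id = "G1.t1", len = 2000) {
  data.frame(gene_id = gene_id, gene_name = gene_name,
             transcript_id = transcript_id, transcript_type = type,
             transcript_support_level = tsl, chrom = "chr1",
             strand = strand, tss = tss, length = len, expression = expr,
             stringsAsFactors = FALSE)
}

test_that("a peak at the TSS of a single gene is assigned to it", {
  ann <- one_gene_annotation()
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901, 10100))
  names(pk) <- "p1"
  ga <- assign_peaks_to_genes(pk, ann)
  expect_equal(ga$bound_genes$gene_id, "G1")
  expect_equal(ga$bound_genes$peak_id, "p1")
  expect_equal(ga$bound_genes$distance, 1)  # centre 10001 vs TSS 10000
  expect_false(ga$assigned_peaks$bidirectional)
})

test_that("the TSS window is strand-aware and the centre rule is strict", {
  ann <- one_gene_annotation()
  # + strand window covers [tss-2000, tss+999]; a peak just inside/outside
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 8100))
  outside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7800, 7999))
  expect_equal(nrow(assign_peaks_to_genes(inside, ann)$bound_genes), 1)
  expect_equal(nrow(assign_peaks_to_genes(outside, ann)$bound_genes), 0)
  # minus strand: window flips to [tss-999, tss+2000]
  ann_m <- one_gene_annotation(strand = "-")
  up_m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11900, 12000))
  expect_equal(nrow(assign_peaks_to_genes(up_m, ann_m)$bound_genes), 1)
  expect_equal(nrow(assign_peaks_to_genes(outside, ann_m)$bound_genes), 0)
  # window overlap alone is not enough: centre must be < 2 kb from TSS
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10900, 14000))
  expect_equal(nrow(assign_peaks_to_genes(wide, ann)$bound_genes), 0)
})

test_that("transcript choice follows the ranked criteria", {
  ann <- rbind(
    one_gene_annotation(tss = 10000, tsl = 3, transcript_id = "G1.t1"),
    one_gene_annotation(tss = 10800, tsl = 1, transcript_id = "G1.t2"))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901, 10100))
  ga <- assign_peaks_to_genes(pk, ann)
  expect_equal(ga$bound_genes$transcript_id, "G1.t2")  # best TSL wins
  # at equal TSL, smaller distance wins
  ann2 <- rbind(
    one_gene_annotation(tss = 10000, tsl = 1, transcript_id = "G1.t1"),
    one_gene_annotation(tss = 10800, tsl = 1, transcript_id = "G1.t2"))
  expect_equal(assign_peaks_to_genes(pk, ann2)$bound_genes$transcript_id,
               "G1.t1")
  # then higher expression
  ann3 <- rbind(
    one_gene_annotation(tss = 10000, tsl = 1, expr = 2,
                        transcript_id = "G1.t1"),
    one_gene_annotation(tss = 10000, tsl = 1, expr = 9,
                        transcript_id = "G1.t2"))
  expect_equal(assign_peaks_to_genes(pk, ann3)$bound_genes$transcript_id,
               "G1.t2")
  # then maximum length, then transcript id
  ann4 <- rbind(
    one_gene_annotation(tss = 10000, len = 900, transcript_id = "G1.t1"),
    one_gene_annotation(tss = 10000, len = 3000, transcript_id = "G1.t2"))
  expect_equal(assign_peaks_to_genes(pk, ann4)$bound_genes$transcript_id,
               "G1.t2")
})

test_that("type, support-level, and expression filters apply", {
  ann <- rbind(one_gene_annotation(type = "miRNA"),
               one_gene_annotation(gene_id = "G2", gene_name = "GeneTwo",
                                   transcript_id = "G2.t1", tsl = NA),
               one_gene_annotation(gene_id = "G3", gene_name = "GeneThree",
                                   transcript_id = "G3.t1", expr = 0))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901, 10100))
  ga <- assign_peaks_to_genes(pk, ann)
  expect_equal(nrow(ga$bound_genes), 0)
  bad <- one_gene_annotation(type = "not_a_type")
  expect_error(assign_peaks_to_genes(pk, bad), "not_a_type")
})

test_that("planted fixture assignment matches the expected tables exactly", {
  fix <- simulate_annotation(sim_config(seed = 1))
  ga <- assign_peaks_to_genes(fix$peaks, fix$annotation)
  norm <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(ga$bound_genes), norm(fix$expected$bound_genes))
  expect_equal(norm(ga$assigned_peaks), norm(fix$expected$assigned_peaks))
  expect_equal(norm(ga$discarded), norm(fix$expected$discarded))
  # no gene is both bound and discarded
  disc_genes <- unlist(strsplit(ga$discarded$gene_ids, ","))
  expect_length(intersect(ga$bound_genes$gene_id, disc_genes), 0)
  # determinism
  ga2 <- assign_peaks_to_genes(fix$peaks, fix$annotation)
  expect_identical(ga$bound_genes, ga2$bound_genes)
})

test_that("shrinking the TSS window never adds bound genes", {
  fix <- simulate_annotation(sim_config(seed = 1))
  full <- assign_peaks_to_genes(fix$peaks, fix$annotation)
  small <- assign_peaks_to_genes(fix$peaks, fix$annotation,
                                 upstream = 500L, downstream = 250L)
  expect_true(all(small$bound_genes$gene_id %in% full$bound_genes$gene_id))
  expect_lte(nrow(small$bound_genes), nrow(full$bound_genes))
})

test_that("conserved sites require support from every cell type", {
  g1 <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 500, 900),
                                                width = 50))
  only1 <- conserved_sites(list(d1 = g1), c(d1 = "ctA"))
  expect_length(only1, 3)
  g2 <- g1[1:2]
  both <- conserved_sites(list(d1 = g1, d2 = g2),
                          c(d1 = "ctA", d2 = "ctB"))
  expect_length(both, 2)   # region 3 present in only one cell type
  expect_error(conserved_sites(list(d1 = g1, d2 = g2), c(d1 = "ctA")),
               "without a cell type")
})

test_that("conserved sites match brute force and shrink with more types", {
  set.seed(47)
  genome <- c(chr1 = 30000)
  sets <- lapply(1:5, function(i) random_granges(30, genome))
  names(sets) <- paste0("d", 1:5)
  ct3 <- c(d1 = "a", d2 = "a", d3 = "b", d4 = "c", d5 = "c")
  got <- conserved_sites(sets, ct3)
  consensus <- merge_union(sets)
  want <- brute_conserved(consensus, sets, ct3)
  expect_identical(GenomicRanges::granges(got),
                   GenomicRanges::granges(want))
  # adding a cell type never adds conserved regions
  for (rep in 1:5) {
    extra <- random_granges(30, genome)
    sets2 <- c(sets, list(d6 = extra))
    ct4 <- c(ct3, d6 = paste0("new", rep))
    expect_lte(length(conserved_sites(sets2, ct4)), length(got))
  }
})
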