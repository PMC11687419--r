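# independent exhaustive-null oracle: shift 0-based intervals by every
# offset, split wraps, count overlaps by brute force
oracle_exhaustive_null <- function(regions, features, L) {
  s0 <- GenomicRanges::start(regions) - 1
  e0 <- GenomicRanges::end(regions)
  chrom <- as.character(GenomicRanges::seqnames(regions))[1]
  vapply(0:(L - 1), function(d) {
    ns <- (s0 + d) %% L
    ne <- ns + (e0 - s0)
    pieces_s <- c(); pieces_e <- c(); parent <- c()
    for (i in seq_along(ns)) {
      if (ne[i] <= L) {
        pieces_s <- c(pieces_s, ns[i]); pieces_e <- c(pieces_e, ne[i])
        parent <- c(parent, i)
      } else {
        pieces_s <- c(pieces_s, ns[i], 0)
        pieces_e <- c(pieces_e, L, ne[i] - L)
        parent <- c(parent, i, i)
      }
    }
    shifted <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(pieces_s + 1,
                                                       pieces_e))
    hit_parent <- unique(parent[vapply(seq_along(shifted), function(j)
      brute_count_overlapping(shifted[j], features) > 0, TRUE)])
    length(hit_parent)
  }, 0)
}

test_that("circular permutation shifts, wraps, and preserves coverage", {
  genome <- c(chr1 = 1000)
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(901, 950))
  ident <- circular_permute(r, genome, offsets = c(chr1 = 0))
  expect_equal(GenomicRanges::start(ident), 901)
  shifted <- circular_permute(r, genome, offsets = c(chr1 = 100))
  expect_equal(GenomicRanges::start(shifted), 1)
  expect_equal(GenomicRanges::end(shifted), 50)
  # wrap: [971, 990] shifted by 20 spans the origin and splits into
  # [991, 1000] + [1, 10]; covered length 20 preserved
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(971, 990))
  wrapped <- circular_permute(r2, genome, offsets = c(chr1 = 20))
  expect_length(wrapped, 2)
  expect_equal(GenomicRanges::start(wrapped), c(1, 991))
  expect_equal(GenomicRanges::end(wrapped), c(10, 1000))
  expect_equal(sum(GenomicRanges::width(wrapped)), 20)
  expect_equal(GenomicRanges::mcols(wrapped)$parent, c(1, 1))
  set.seed(13)
  many <- random_granges(80, c(chr1 = 5000, chr2 = 3000))
  for (i in 1:10) {
    perm <- circular_permute(many, c(chr1 = 5000, chr2 = 3000))
    for (chrom in c("chr1", "chr2")) {
      sel_o <- as.character(GenomicRanges::seqnames(many)) == chrom
      sel_p <- as.character(GenomicRanges::seqnames(perm)) == chrom
      expect_equal(sum(GenomicRanges::width(perm[sel_p])),
                   sum(GenomicRanges::width(many[sel_o])))
    }
  }
  expect_error(circular_permute(r, c(chrX = 100)), "absent")
  expect_error(circular_permute(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(990, 1010)),
    genome), "beyond")
})

test_that("exhaustive mode matches the brute-force exact null", {
  genome <- c(toy = 200)
  set.seed(51)
  regions <- GenomicRanges::GRanges(
    "toy", IRanges::IRanges(c(11, 61, 141), width = c(10, 15, 8)))
  features <- GenomicRanges::GRanges(
    "toy", IRanges::IRanges(c(1, 96, 171), width = c(20, 12, 10)))
  res <- permutation_enrichment(regions, features, genome,
                                exhaustive = TRUE)
  null <- oracle_exhaustive_null(regions, features, 200)
  expect_equal(res$null_mean, mean(null))
  expect_equal(res$p, mean(null >= res$observed))
  expect_equal(res$observed, brute_count_overlapping(regions, features))
  # Monte-Carlo null mean approaches the exact null mean
  mc <- permutation_enrichment(regions, features, genome, n_perm = 400,
                               seed = 5)
  se <- sd(null) / sqrt(400)
  expect_lt(abs(mc$null_mean - mean(null)), 3 * se + 1e-9)
})

test_that("planted enrichment is detected with the smallest possible p", {
  genome <- c(chr1 = 100000)
  set.seed(61)
  # irregular feature spacing so no circular shift stays in phase
  fstart <- cumsum(sample(1200:2800, 45))
  fstart <- fstart[fstart < 95000]
  features <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(fstart, width = 300))
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(fstart[seq_len(30)] + 50, width = 100))
  res <- permutation_enrichment(regions, features, genome, n_perm = 100,
                                seed = 3)
  expect_gt(res$z, 3)
  expect_equal(res$p, 1 / 101)
})

test_that("degenerate inputs give observed 0 and p 1 with a warning", {
  genome <- c(chr1 = 1000)
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_warning(res <- permutation_enrichment(
    r, GenomicRanges::GRanges(), genome, n_perm = 10, seed = 1),
    "degenerate")
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
})

test_that("p-values never reach zero and are roughly calibrated under null", {
  genome <- c(chr1 = 50000)
  set.seed(71)
  pvals <- vapply(1:60, function(i) {
    regions <- random_granges(20, genome, max_width = 120)
    features <- random_granges(20, genome, max_width = 120)
    permutation_enrichment(regions, features, genome, n_perm = 50,
                           seed = 1000 + i)$p
  }, 0)
  expect_true(all(pvals > 0))
  expect_gt(mean(pvals), 0.2)   # no wild anti-conservative behaviour
})

test_that("anchor enrichment table normalises by the reference mean", {
  genome <- c(chr1 = 50000)
  set.seed(81)
  anchors <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1000, 45000, by = 1500), width = 400))
  self_tab <- anchor_enrichment_table(
    anchors, list(self = anchors), reference_flags = TRUE, genome = genome,
    n_perm = 30, seed = 2)
  expect_equal(self_tab$anchor_fraction, 1)
  expect_equal(self_tab$relative_fold, 1)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(49900, 49950))
  two <- anchor_enrichment_table(
    anchors, list(self = anchors, far = far),
    reference_flags = c(TRUE, FALSE), genome = genome, n_perm = 30,
    seed = 2)
  expect_equal(two$anchor_fraction[2], 0)
  expect_error(anchor_enrichment_table(
    anchors, list(self = anchors), reference_flags = FALSE,
    genome = genome), "reference")
})

test_that("a peakset planted at anchors outranks random references", {
  genome <- c(chr1 = 80000)
  set.seed(91)
  # irregular anchor spacing so circular shifts cannot stay in phase
  anchor_start <- cumsum(sample(1500:3500, 25))
  anchor_start <- anchor_start[anchor_start < 75000]
  anchors <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(anchor_start, width = 500))
  planted <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(anchor_start + 100, width = 200))
  refs <- lapply(1:10, function(i) random_granges(25, genome,
                                                  max_width = 200))
  sets <- c(list(planted = planted), setNames(refs, paste0("r", 1:10)))
  tab <- anchor_enrichment_table(
    anchors, sets, reference_flags = c(FALSE, rep(TRUE, 10)),
    genome = genome, n_perm = 50, seed = 7)
  expect_gt(tab$relative_fold[1],
            max(tab$relative_fold[tab$is_reference]))
})
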