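make_random_pwm <- function(w, seed, pseudocount = 0.8) {
  set.seed(seed)
  mat <- matrix(rgamma(4 * w, shape = 0.6), 4, w)
  pwm(sweep(mat, 2, colSums(mat), "/"), id = paste0("rand", seed),
      pseudocount = pseudocount)
}

test_that("log-odds scoring matches closed forms", {
  # width-1 PWM, P(A)=1, uniform background, no pseudocount: score log2(4)=2
  p1 <- pwm(matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(score_matrix(p1)["A", 1]), 2)
  hits <- scan_pwm(c(s = "AACA"), p1, p_threshold = 0.25)
  # every A on the forward strand and every T (A on reverse) qualifies
  expect_true(all(GenomicRanges::mcols(hits)$score == 2))
  # consensus scores the matrix maximum
  pw <- make_random_pwm(6, seed = 2)
  consensus <- paste(rownames(pw$mat)[apply(pw$mat, 2, which.max)],
                     collapse = "")
  S <- score_matrix(pw)
  expect_equal(
    sum(S[cbind(apply(pw$mat, 2, which.max), 1:6)]),
    sum(apply(S, 2, max)))
  hit <- scan_pwm(c(s = consensus), pw, p_threshold = 1)
  expect_equal(max(GenomicRanges::mcols(hit)$score),
               sum(apply(S, 2, max)), tolerance = 1e-9)
})

test_that("degenerate uniform PWM behaves at the p boundaries", {
  u <- pwm(matrix(0.25, 4, 2), pseudocount = 0)
  thr1 <- score_threshold_from_p(u, 1)
  expect_equal(thr1$threshold, 0)
  hits_all <- scan_pwm(c(s = "ACGTACGT"), u, p_threshold = 1)
  expect_length(hits_all, 2 * (8 - 2 + 1))
  hits_none <- scan_pwm(c(s = "ACGTACGT"), u, p_threshold = 0.5)
  expect_length(hits_none, 0)
})

test_that("DP threshold and tails match exhaustive word enumeration", {
  # the DP reports the smallest grid score whose tail is <= p; enumeration
  # reports the smallest achievable word score with that property — both
  # must select the same word set and the same exact tail probability
  for (w in c(3, 4, 6, 8)) {
    pw <- make_random_pwm(w, seed = w * 11)
    ws <- enum_word_scores(pw)
    # independently re-derive each word's grid score from the score matrix
    S <- crosspeak::score_matrix(pw)
    Kg <- round(S / 1e-3)
    words <- expand.grid(rep(list(1:4), w))
    grid_sum <- apply(words, 1, function(idx)
      sum(Kg[cbind(as.integer(idx), seq_len(w))]))
    for (p in c(1, 0.1, 0.01, 1e-3)) {
      dp <- score_threshold_from_p(pw, p)
      en <- enum_threshold(pw, p, ws)
      # DP tail equals the enumerated tail on the grid domain, exactly
      expect_equal(dp$tail, sum(ws$prob[grid_sum >= dp$grid_threshold]),
                   tolerance = 1e-12)
      expect_lte(dp$tail, p)
      # the DP-selected and enumeration-selected word sets may disagree
      # only on words whose exact score lies within one grid step of the
      # enumerated threshold (the documented discretisation resolution)
      set_dp <- which(grid_sum >= dp$grid_threshold)
      set_en <- which(ws$score >= en - 1e-9)
      off_boundary <- c(setdiff(set_dp, set_en), setdiff(set_en, set_dp))
      if (length(off_boundary))
        expect_lt(max(abs(ws$score[off_boundary] - en)), w * 1e-3)
      tail_enum <- sum(ws$prob[set_en])
      if (tail_enum == 0) expect_equal(dp$tail, 0)
    }
  }
})

test_that("scan equals exhaustive per-window enumeration", {
  set.seed(19)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")
  for (w in c(4, 6, 8)) {
    pw <- make_random_pwm(w, seed = w)
    p <- 0.01
    got <- scan_pwm(setNames(c(seq_chr), "chr1"), pw, p_threshold = p)
    want <- naive_scan(seq_chr, pw, enum_threshold(pw, p))
    key <- function(st, strand) paste(st, strand)
    expect_setequal(key(GenomicRanges::start(got),
                        as.character(GenomicRanges::strand(got))),
                    key(want$start, want$strand))
    got_sc <- GenomicRanges::mcols(got)$score[
      order(GenomicRanges::start(got), as.character(
        GenomicRanges::strand(got)))]
    want_sc <- want$score[order(want$start, want$strand)]
    expect_equal(got_sc, want_sc, tolerance = 1e-9)
  }
})

test_that("windows containing N are skipped", {
  pw <- make_random_pwm(4, seed = 5)
  hits <- scan_pwm(c(s = "NNNNNNNN"), pw, p_threshold = 1)
  expect_length(hits, 0)
})

test_that("scan is strand-symmetric and monotone in p", {
  set.seed(29)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
  pw <- make_random_pwm(7, seed = 3)
  fwd <- scan_pwm(c(chr = seq_chr), pw, p_threshold = 0.02)
  rc_seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  rc <- scan_pwm(c(chr = rc_seq), pw, p_threshold = 0.02)
  # mirrored coordinates: start' = L - end + 1, strands flipped
  L <- nchar(seq_chr)
  expect_setequal(paste(L - GenomicRanges::end(rc) + 1,
                        c("+" = "-", "-" = "+")[
                          as.character(GenomicRanges::strand(rc))]),
                  paste(GenomicRanges::start(fwd),
                        as.character(GenomicRanges::strand(fwd))))
  for (p_pair in list(c(0.05, 0.01), c(0.01, 1e-3))) {
    n_loose <- length(scan_pwm(c(chr = seq_chr), pw, p_pair[1]))
    n_tight <- length(scan_pwm(c(chr = seq_chr), pw, p_pair[2]))
    expect_gte(n_loose, n_tight)
  }
})

test_that("JASPAR reader parses bracketed and bare formats", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 testmotif",
               "A [ 10  2  0 ]",
               "C [  0  8  1 ]",
               "G [  0  0  9 ]",
               "T [  0  0  0 ]",
               ">plain second",
               "1 2", "3 4", "5 6", "7 8"), f)
  pwms <- read_jaspar(f)
  expect_named(pwms, c("MA0001.1", "plain"))
  expect_equal(pwms[["MA0001.1"]]$width, 3)
  expect_equal(colSums(pwms[["MA0001.1"]]$mat), rep(1, 3), tolerance = 1e-9)
})

test_that("motif fraction in peaks reflects the planting rate", {
  set.seed(37)
  n <- 500
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, by = 500, length.out = n), width = 200))
  planted <- rbinom(n, 1, 0.8) == 1
  hits <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(peaks)[planted] + 90,
                             width = 12))
  frac <- motif_fraction_in_peaks(peaks, hits)
  expect_equal(frac, mean(planted))
  expect_lt(abs(frac - 0.8), 0.06)
  expect_equal(motif_fraction_in_peaks(peaks, peaks), 1)
  expect_equal(motif_fraction_in_peaks(
    peaks, GenomicRanges::GRanges("chr1", IRanges::IRanges(900000, 900010))),
    0)
  expect_error(motif_fraction_in_peaks(GenomicRanges::GRanges(), hits),
               "empty")
})

test_that("pair spacing reports gaps, modes, and repeat overlap", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 110))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(148, 157))
  sp <- pair_spacing(a, b)
  expect_equal(sp$table$distance, 37)
  ov <- pair_spacing(a, GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(105, 120)))
  expect_equal(ov$table$distance, 0)
  # planted: 60% of A hits at gap 37 inside repeats, rest at random gaps
  set.seed(41)
  n <- 100
  a_start <- seq(1000, by = 2000, length.out = n)
  at37 <- seq_len(60)
  gaps <- c(rep(37, 60), sample(c(5, 12, 61, 90, 140), 40, replace = TRUE))
  a_hits <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(a_start, width = 10))
  b_hits <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(a_start + 10 + gaps, width = 10))
  repeats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(a_start[at37] - 5, width = 80))
  res <- pair_spacing(a_hits, b_hits, repeat_annotation = repeats)
  expect_equal(res$modal_distance, 37)
  expect_equal(res$modal_frequency, 0.6)
  expect_equal(res$modal_repeat_fraction, 1)
})
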