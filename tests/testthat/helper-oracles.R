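# Independent brute-force oracles used to check the interval algebra, the
# PWM machinery, and the permutation machinery. These never call the code
# paths they verify.

# random GRanges on a small genome
random_granges <- function(n, genome, max_width = 200L) {
  chroms <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(genome[[chroms[i]]] - w[i] + 1L, 1L), 1L)
  GenomicRanges::GRanges(chroms, IRanges::IRanges(start, width = w))
}

# O(n*m) all-pairs overlap count (1-based closed logic on GRanges fields)
brute_count_overlapping <- function(query, subject) {
  qc <- as.character(GenomicRanges::seqnames(query))
  sc <- as.character(GenomicRanges::seqnames(subject))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  n <- 0L
  for (i in seq_along(query)) {
    hit <- FALSE
    for (j in seq_along(subject)) {
      if (qc[i] == sc[j] && qs[i] <= se[j] && ss[j] <= qe[i]) {
        hit <- TRUE; break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

# per-base bitmap union length
brute_union_length <- function(gr, genome) {
  total <- 0
  for (chrom in names(genome)) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == chrom
    if (!any(sel)) next
    cover <- logical(genome[[chrom]])
    s <- GenomicRanges::start(gr)[sel]; e <- GenomicRanges::end(gr)[sel]
    for (i in seq_along(s)) cover[s[i]:e[i]] <- TRUE
    total <- total + sum(cover)
  }
  total
}

# membership scan for reproducible peaks (rule = at_least_k incl. all)
brute_reproducible <- function(sets, k) {
  first <- sets[[1]]
  keep <- vapply(seq_along(first), function(i) {
    support <- 1L
    for (other in sets[-1])
      if (brute_count_overlapping(first[i], other) > 0L)
        support <- support + 1L
    support >= k
  }, TRUE)
  first[keep]
}

# per-region cell-type membership scan for conserved sites
brute_conserved <- function(consensus, peaksets, cell_type_of) {
  all_types <- unique(cell_type_of[names(peaksets)])
  keep <- vapply(seq_along(consensus), function(i) {
    seen <- character(0)
    for (ds in names(peaksets))
      if (brute_count_overlapping(consensus[i], peaksets[[ds]]) > 0L)
        seen <- union(seen, cell_type_of[[ds]])
    setequal(seen, all_types)
  }, TRUE)
  consensus[keep]
}

# exhaustive enumeration of all 4^w words: exact score distribution,
# tail-derived threshold, and per-window naive scores
enum_word_scores <- function(pwm_obj) {
  S <- crosspeak::score_matrix(pwm_obj)
  bg <- pwm_obj$background
  w <- pwm_obj$width
  words <- expand.grid(rep(list(1:4), w))
  score <- numeric(nrow(words)); prob <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    idx <- as.integer(words[r, ])
    score[r] <- sum(S[cbind(idx, seq_len(w))])
    prob[r] <- prod(bg[idx])
  }
  list(score = score, prob = prob)
}

enum_threshold <- function(pwm_obj, p, ws = enum_word_scores(pwm_obj)) {
  o <- order(ws$score, decreasing = TRUE)
  tail_p <- cumsum(ws$prob[o])
  sc <- ws$score[o]
  ok <- which(tail_p <= p + 1e-12)
  if (length(ok) == 0L) return(max(sc) + 1)
  min(sc[ok])
}

# naive per-window scan on one sequence string, both strands
naive_scan <- function(seq_chr, pwm_obj, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_chr, "")[[1]]
  S <- crosspeak::score_matrix(pwm_obj)
  w <- pwm_obj$width
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (pos in seq_len(length(chars) - w + 1L)) {
    win <- chars[pos:(pos + w - 1L)]
    if (any(!win %in% bases)) next
    fwd <- sum(S[cbind(match(win, bases), seq_len(w))])
    rcw <- rev(unname(comp[win]))
    rev_sc <- sum(S[cbind(match(rcw, bases), seq_len(w))])
    if (fwd >= threshold)
      out[[length(out) + 1L]] <- data.frame(start = pos, strand = "+",
                                            score = fwd)
    if (rev_sc >= threshold)
      out[[length(out) + 1L]] <- data.frame(start = pos, strand = "-",
                                            score = rev_sc)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# direct formula evaluation for median-of-ratios factors
brute_size_factors <- function(counts) {
  pos <- apply(counts > 0, 1, all)
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  apply(counts[pos, , drop = FALSE], 2, function(col) median(col / ref))
}

# groupby-sum oracle for pseudobulk
brute_pseudobulk <- function(mat, labels) {
  out <- sapply(unique(labels), function(cl)
    apply(mat[, labels == cl, drop = FALSE], 1, sum))
  matrix(out, nrow = nrow(mat),
         dimnames = list(rownames(mat), unique(labels)))
}
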