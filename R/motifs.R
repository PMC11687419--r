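# PWM scanning of genomic sequence with exact (dynamic-programming) score
# thresholds, and motif-pair spacing analysis.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Accepts a 4 x w matrix of per-position counts or probabilities over
#' (A, C, G, T). A pseudocount is distributed according to the background and
#' columns renormalised to sum to 1, so zero probabilities never meet a
#' nonzero background in the log-odds.
#'
#' @param mat 4 x w numeric matrix; rows in A, C, G, T order (row names, if
#'   present, are checked).
#' @param id Motif identifier.
#' @param background Background frequencies over (A, C, G, T); must sum to 1.
#' @param pseudocount Pseudocount mass added per column, split by background
#'   (default 0.8, a common motif-matching convention).
#' @return List of class \code{pwm}: id, mat (normalised probabilities),
#'   background, pseudocount, width.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.8) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, all(mat >= 0), length(background) == 4)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (!is.null(rownames(mat)) && !identical(rownames(mat), BASES))
    mat <- mat[BASES, , drop = FALSE]
  if (pseudocount <= 0 && any(mat > 0 & background == 0))
    stop("zero background frequency with nonzero matrix probability; ",
         "use pseudocount > 0")
  colsums <- colSums(mat)
  if (pseudocount > 0)
    mat <- sweep(mat + outer(background, colsums) * pseudocount /
                   ifelse(colsums > 0, colsums, 1),
                 2, colsums + pseudocount * (colsums > 0), "/")
  else
    mat <- sweep(mat, 2, ifelse(colsums > 0, colsums, 1), "/")
  mat[, colsums == 0] <- background  # all-zero column: background
  dimnames(mat) <- list(BASES, NULL)
  structure(list(id = id, mat = mat, background = setNames(background, BASES),
                 pseudocount = pseudocount, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "- width", x$width, "\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Per-position log2-odds score matrix of a PWM
#' @param x A \code{pwm}.
#' @return 4 x w matrix of log2(p/background).
#' @export
score_matrix <- function(x) log2(x$mat / x$background)

#' Reverse complement of a PWM
#' @param x A \code{pwm}.
#' @return A \code{pwm} scoring the reverse strand.
#' @export
reverse_complement_pwm <- function(x) {
  m <- x$mat[4:1, rev(seq_len(x$width)), drop = FALSE]
  dimnames(m) <- list(BASES, NULL)
  x$mat <- m
  x$background <- setNames(x$background[4:1], BASES)
  x
}

#' Read JASPAR-style PFM/PWM files
#'
#' Parses the JASPAR text format: a \code{>id name} header followed by four
#' rows (\code{A [ 1 2 ... ]} or bare numbers, in A, C, G, T order).
#'
#' @param path File path.
#' @param background,pseudocount Passed to \code{\link{pwm}}.
#' @return A named list of \code{pwm} objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) { heads <- 0L; ids <- "motif1" } else
    ids <- sub("^>\\s*(\\S+).*", "\\1", lines[heads])
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    rows <- lines[from:to][seq_len(4)]
    nums <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(nums))) != 1L)
      stop("ragged matrix for motif ", ids[i], " in ", path)
    out[[ids[i]]] <- pwm(do.call(rbind, nums), id = ids[i],
                         background = background, pseudocount = pseudocount)
  }
  out
}

#' Built-in example motifs for the two synthetic factors
#'
#' Strong 12-bp motifs (dominant base probability 0.85) used by the
#' synthetic-data generators: factor A is the target (SBS-like role), factor
#' B the off-target (CTCF-like role).
#'
#' @param factor \code{"A"} or \code{"B"}.
#' @param pseudocount Passed to \code{\link{pwm}}.
#' @return A \code{pwm}.
#' @export
example_pwm <- function(factor = c("A", "B"), pseudocount = 0.8) {
  factor <- match.arg(factor)
  consensus <- if (factor == "A") "TTCCCAGAATGC" else "CCACCAGGGGGC"
  letters <- strsplit(consensus, "")[[1]]
  mat <- matrix(0.05, 4, length(letters), dimnames = list(BASES, NULL))
  for (j in seq_along(letters)) mat[letters[j], j] <- 0.85
  pwm(mat, id = paste0("factor_", factor), pseudocount = pseudocount)
}

# Column scores rounded onto the DP grid (integer units of `granularity`).
# Zero-probability cells score -Inf and are marked NA: windows containing
# them can never be hits, and their null mass is dropped from the DP (the
# finite-score tail is unaffected).
pwm_grid_scores <- function(x, granularity) {
  K <- round(score_matrix(x) / granularity)
  K[!is.finite(K)] <- NA
  K
}

#' Score threshold for a PWM at a null tail probability
#'
#' Exact dynamic programming over discretised column scores: the full null
#' distribution of the window score under i.i.d. background is computed, and
#' the threshold is the smallest (grid) score whose upper tail probability is
#' at most \code{p_threshold}. If no achievable score qualifies, the
#' threshold lies just above the maximum achievable score (no hits).
#'
#' @param x A \code{pwm}.
#' @param p_threshold Null tail probability, in (0, 1].
#' @param granularity Score discretisation step (default 1e-3).
#' @return List: \code{threshold} (score units), \code{grid_threshold}
#'   (integer grid units), \code{tail} (achieved tail probability).
#' @export
score_threshold_from_p <- function(x, p_threshold, granularity = 1e-3) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  K <- pwm_grid_scores(x, granularity)
  bg <- x$background
  # convolve the per-column score distributions, column by column
  dist <- 1
  offset <- 0
  for (j in seq_len(ncol(K))) {
    kj <- K[, j]
    finite <- which(!is.na(kj))
    if (length(finite) == 0L) stop("PWM column with no scorable base")
    new_lo <- offset + min(kj[finite])
    new <- rep(0, (offset + max(kj[finite]) + length(dist) - 1L) -
                 new_lo + 1L)
    for (b in finite) {
      sh <- offset + kj[b] - new_lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    offset <- new_lo
  }
  # dist[i] = P(grid score == offset + i - 1)
  tail_from <- rev(cumsum(rev(dist)))
  qualifying <- which(tail_from <= p_threshold)
  if (length(qualifying) == 0L) {
    grid_thr <- offset + length(dist)      # above max achievable
    tail <- 0
  } else {
    grid_thr <- offset + qualifying[1] - 1L
    tail <- tail_from[qualifying[1]]
  }
  list(threshold = grid_thr * granularity, grid_threshold = grid_thr,
       tail = tail)
}

scan_one_strand <- function(codes, K, grid_thr) {
  w <- ncol(K)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer(0))
  acc <- rep(0L, n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    sc <- K[cbind(cj, j)]          # NA for N bases or forbidden cells
    bad <- is.na(sc)
    ok <- ok & !bad
    sc[bad] <- 0L
    acc <- acc + sc
  }
  which(ok & acc >= grid_thr)
}

#' Scan sequences for PWM hits
#'
#' Scores every window on both strands with the log2-odds score
#' \eqn{\sum_j \log_2(p_j(x_j)/bg(x_j))} and reports windows at or above the
#' threshold whose null tail probability is at most \code{p_threshold}
#' (threshold from \code{\link{score_threshold_from_p}}). Windows containing
#' N are skipped. Scoring is performed on the same discretised grid as the
#' threshold, so scan and threshold are mutually consistent.
#'
#' @param sequences Named DNAStringSet (or named character vector).
#' @param x A \code{pwm}.
#' @param p_threshold Null tail probability (default 5e-5).
#' @param granularity Score grid step (default 1e-3).
#' @return GRanges of hits (width = motif width) with strand and
#'   \code{mcols()$score} (exact log2-odds).
#' @export
scan_pwm <- function(sequences, x, p_threshold = 5e-5, granularity = 1e-3) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  thr <- score_threshold_from_p(x, p_threshold, granularity)
  K_f <- pwm_grid_scores(x, granularity)
  rc <- reverse_complement_pwm(x)
  K_r <- pwm_grid_scores(rc, granularity)
  S_f <- score_matrix(x); S_r <- score_matrix(rc)
  w <- x$width
  hit_chrom <- character(0); hit_pos <- integer(0)
  hit_strand <- character(0); hit_score <- numeric(0)
  for (chrom in names(sequences)) {
    chars <- strsplit(as.character(sequences[[chrom]]), "")[[1]]
    codes <- match(chars, BASES)   # N -> NA
    for (strand in c("+", "-")) {
      K <- if (strand == "+") K_f else K_r
      S <- if (strand == "+") S_f else S_r
      pos <- scan_one_strand(codes, K, thr$grid_threshold)
      if (length(pos) == 0L) next
      sc <- vapply(pos, function(p) {
        sum(S[cbind(codes[p:(p + w - 1L)], seq_len(w))])
      }, 0)
      hit_chrom <- c(hit_chrom, rep(chrom, length(pos)))
      hit_pos <- c(hit_pos, pos)
      hit_strand <- c(hit_strand, rep(strand, length(pos)))
      hit_score <- c(hit_score, sc)
    }
  }
  gr <- GenomicRanges::GRanges(hit_chrom,
                               IRanges::IRanges(hit_pos, width = w),
                               strand = hit_strand)
  GenomicRanges::mcols(gr)$score <- hit_score
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Fraction of peaks containing at least one motif hit
#'
#' @param peaks Nonempty GRanges.
#' @param hits GRanges of motif hits, or a list of such (hits from several
#'   motifs are combined; a peak counts if it contains any).
#' @return Real in [0, 1].
#' @export
motif_fraction_in_peaks <- function(peaks, hits) {
  if (length(peaks) == 0L) stop("empty peak set")
  if (is.list(hits))
    hits <- do.call(c, lapply(hits, function(g) {
      GenomicRanges::mcols(g) <- NULL; names(g) <- NULL; g
    }))
  mean(IRanges::overlapsAny(peaks, hits, ignore.strand = TRUE))
}

#' Spacing between two motifs' hits
#'
#' For each A hit, the distance to the nearest B hit — edge-to-edge gap by
#' default (0 when overlapping or touching), or centre-to-centre with
#' \code{measure = "center"}. Reports the modal distance, its frequency, and
#' (when a repeat annotation is supplied) the fraction of modal-distance
#' pairs whose span overlaps a repeat.
#'
#' @param hits_a,hits_b Nonempty GRanges of motif hits.
#' @param repeat_annotation Optional GRanges of repeat elements.
#' @param measure \code{"gap"} or \code{"center"}.
#' @return List: \code{table} (per-A-hit distances and B partner index),
#'   \code{modal_distance}, \code{modal_frequency},
#'   \code{modal_repeat_fraction} (NA without annotation).
#' @export
pair_spacing <- function(hits_a, hits_b, repeat_annotation = NULL,
                         measure = c("gap", "center")) {
  measure <- match.arg(measure)
  if (length(hits_a) == 0L || length(hits_b) == 0L)
    stop("both hit lists must be nonempty")
  near <- GenomicRanges::distanceToNearest(hits_a, hits_b,
                                           ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(near); si <- S4Vectors::subjectHits(near)
  dist <- if (measure == "gap") {
    S4Vectors::mcols(near)$distance
  } else {
    ctr <- function(g) GenomicRanges::start(g) +
      floor((GenomicRanges::width(g) - 1) / 2)
    abs(ctr(hits_a[qi]) - ctr(hits_b[si]))
  }
  tab <- data.frame(a_index = qi, b_index = si,
                    chrom = as.character(GenomicRanges::seqnames(hits_a[qi])),
                    distance = dist)
  counts <- table(dist)
  modal <- as.numeric(names(counts)[which.max(counts)])
  modal_freq <- max(counts) / nrow(tab)
  repeat_frac <- NA_real_
  if (!is.null(repeat_annotation)) {
    at_modal <- which(dist == modal)
    span <- GenomicRanges::punion(
      GenomicRanges::granges(hits_a[qi[at_modal]]),
      GenomicRanges::granges(hits_b[si[at_modal]]), fill.gap = TRUE)
    repeat_frac <- mean(IRanges::overlapsAny(span, repeat_annotation,
                                                   ignore.strand = TRUE))
  }
  list(table = tab, modal_distance = modal, modal_frequency = modal_freq,
       modal_repeat_fraction = repeat_frac)
}
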