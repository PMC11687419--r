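# Circular-permutation enrichment tests and the loop-anchor relative
# enrichment table.

#' Circularly permute a region set
#'
#' Per chromosome, a single offset d ~ Uniform{0..L-1} shifts every interval
#' by d modulo the chromosome length; intervals spanning the origin are split
#' into two wrapped pieces. This preserves the per-chromosome covered length
#' and inter-interval spacing — the defining property of circular
#' randomisation.
#'
#' @param regions GRanges, all within the genome bounds.
#' @param genome Named numeric vector of chromosome lengths.
#' @param offsets Optional named vector forcing the per-chromosome offsets
#'   (used by the exhaustive exact mode); otherwise drawn from the current
#'   RNG state.
#' @return GRanges of permuted regions.
#' @export
circular_permute <- function(regions, genome, offsets = NULL) {
  chroms <- as.character(GenomicRanges::seqnames(regions))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("regions on chromosomes absent from genome: ",
         paste(missing, collapse = ", "))
  if (length(regions) &&
      (any(GenomicRanges::start(regions) < 1) ||
       any(GenomicRanges::end(regions) > genome[chroms])))
    stop("regions extend beyond genome bounds")
  if (is.null(offsets)) {
    offsets <- vapply(genome, function(L) sample.int(L, 1L) - 1L, 0)
  }
  # 0-based half-open arithmetic
  s0 <- GenomicRanges::start(regions) - 1
  e0 <- GenomicRanges::end(regions)
  L <- genome[chroms]
  d <- offsets[chroms]
  ns <- (s0 + d) %% L
  ne <- ns + (e0 - s0)
  wraps <- ne > L
  idx <- seq_along(regions)
  out_chrom <- c(chroms[!wraps], chroms[wraps], chroms[wraps])
  out_s0 <- c(ns[!wraps], ns[wraps], rep(0, sum(wraps)))
  out_e0 <- c(ne[!wraps], L[wraps], ne[wraps] - L[wraps])
  out_parent <- c(idx[!wraps], idx[wraps], idx[wraps])
  gr <- GenomicRanges::GRanges(out_chrom,
                               IRanges::IRanges(out_s0 + 1, out_e0))
  GenomicRanges::mcols(gr)$parent <- out_parent  # split pieces share parent
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Permutation test for region/feature overlap enrichment
#'
#' Observed statistic: number of regions overlapping at least one feature.
#' Null: the same count after circularly permuting the regions, either
#' \code{n_perm} Monte-Carlo permutations or — with \code{exhaustive = TRUE}
#' on a single-chromosome genome — all L offsets exactly. The Monte-Carlo
#' p-value uses the (1 + x)/(1 + n) estimator and so never equals 0.
#'
#' @param regions,features GRanges.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_perm Number of permutations (default 100).
#' @param alternative \code{"greater"} (enrichment) or \code{"less"}.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive If TRUE (single chromosome only), enumerate every
#'   offset; the p-value is then the exact null tail.
#' @return List of class \code{enrichment_result}: observed, null_mean,
#'   null_sd, fold, z, p, n_perm, alternative, and the null counts.
#' @export
permutation_enrichment <- function(regions, features, genome, n_perm = 100L,
                                   alternative = c("greater", "less"),
                                   seed = 1L, exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1L)
  degenerate <- length(regions) == 0L || length(features) == 0L
  if (degenerate)
    warning("empty regions or features: degenerate null")
  observed <- if (degenerate) 0L else count_overlapping(regions, features)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  if (length(setdiff(unique(chroms), names(genome))))
    stop("regions on chromosomes absent from genome")
  if (length(regions) &&
      (any(GenomicRanges::start(regions) < 1) ||
       any(GenomicRanges::end(regions) > genome[chroms])))
    stop("regions extend beyond genome bounds")

  # fast per-chromosome engine on plain vectors: merged feature intervals,
  # binary-search overlap test, wrapped pieces counted once via their parent
  merged_feats <- GenomicRanges::reduce(features, min.gapwidth = 0L,
                                        ignore.strand = TRUE)
  fchrom <- as.character(GenomicRanges::seqnames(merged_feats))
  per_chrom <- lapply(names(genome), function(cn) {
    rsel <- chroms == cn
    fsel <- fchrom == cn
    list(rs0 = GenomicRanges::start(regions)[rsel] - 1,
         re0 = GenomicRanges::end(regions)[rsel],
         fs0 = GenomicRanges::start(merged_feats)[fsel] - 1,
         fe0 = GenomicRanges::end(merged_feats)[fsel],
         L = genome[[cn]])
  })
  per_chrom <- per_chrom[vapply(per_chrom,
                                function(pc) length(pc$rs0) > 0, TRUE)]
  overlap_any <- function(s0, e0, fs0, fe0) {
    if (length(fs0) == 0L) return(rep(FALSE, length(s0)))
    j <- findInterval(s0, fs0)
    ov1 <- j >= 1 & fe0[pmax(j, 1L)] > s0
    ov2 <- j < length(fs0) & fs0[pmin(j + 1L, length(fs0))] < e0
    ov1 | ov2
  }
  null_count <- function(offsets) {
    total <- 0L
    for (k in seq_along(per_chrom)) {
      pc <- per_chrom[[k]]
      ns <- (pc$rs0 + offsets[k]) %% pc$L
      ne <- ns + (pc$re0 - pc$rs0)
      hit <- overlap_any(ns, pmin(ne, pc$L), pc$fs0, pc$fe0)
      wr <- ne > pc$L
      if (any(wr))
        hit[wr] <- hit[wr] | overlap_any(rep(0, sum(wr)), ne[wr] - pc$L,
                                         pc$fs0, pc$fe0)
      total <- total + sum(hit)
    }
    total
  }
  Ls <- vapply(per_chrom, `[[`, 0, "L")
  if (exhaustive) {
    if (length(genome) != 1L)
      stop("exhaustive mode requires a single-chromosome genome")
    L <- genome[[1]]
    null_counts <- vapply(seq_len(L) - 1L, function(d) null_count(d), 0L)
    p <- switch(alternative,
                greater = mean(null_counts >= observed),
                less = mean(null_counts <= observed))
    n_used <- L
  } else {
    set.seed(seed)
    null_counts <- vapply(seq_len(n_perm), function(i) {
      null_count(floor(runif(length(per_chrom)) * Ls))
    }, 0L)
    x <- switch(alternative,
                greater = sum(null_counts >= observed),
                less = sum(null_counts <= observed))
    p <- (1 + x) / (1 + n_perm)
    n_used <- n_perm
  }
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd,
                 fold = if (null_mean > 0) observed / null_mean else NA_real_,
                 z = if (!is.na(null_sd) && null_sd > 0)
                   (observed - null_mean) / null_sd else NA_real_,
                 p = p, n_perm = n_used, alternative = alternative,
                 null_counts = null_counts, degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Permutation enrichment (%s): observed %d, null %.2f +/- %.2f\n",
    x$alternative, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  fold %.3g  z %.3g  p %.3g  (n_perm %d)\n",
              x$fold, x$z, x$p, x$n_perm))
  invisible(x)
}

#' Relative enrichment of peak sets at loop anchors
#'
#' For each peak set, the fold enrichment of anchors overlapping peaks from a
#' circular-permutation test, normalised by the mean fold over the
#' reference-flagged sets only; the reference mean is applied retrospectively
#' to the non-reference rows as well. The anchor fraction (anchors containing
#' at least one peak) is computed by direct overlap.
#'
#' @param anchors GRanges of loop anchors.
#' @param peaksets Named list of GRanges.
#' @param reference_flags Logical vector, one per peak set; at least one must
#'   be TRUE.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_perm Permutations per test.
#' @param seed Integer seed; each peak set gets an offset substream.
#' @return data.frame: peakset_id, fold, relative_fold, anchor_fraction,
#'   is_reference, z, p.
#' @export
anchor_enrichment_table <- function(anchors, peaksets, reference_flags,
                                    genome, n_perm = 100L, seed = 1L) {
  stopifnot(length(peaksets) == length(reference_flags))
  if (!any(reference_flags)) stop("at least one reference flag must be TRUE")
  ids <- names(peaksets)
  if (is.null(ids)) ids <- sprintf("set%02d", seq_along(peaksets))
  rows <- lapply(seq_along(peaksets), function(i) {
    res <- permutation_enrichment(anchors, peaksets[[i]], genome,
                                  n_perm = n_perm,
                                  seed = substream_seed(seed, ids[i]))
    data.frame(peakset_id = ids[i], fold = res$fold, z = res$z, p = res$p,
               anchor_fraction = overlap_fraction(anchors, peaksets[[i]]),
               is_reference = reference_flags[i], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ref_mean <- mean(tab$fold[tab$is_reference])
  tab$relative_fold <- tab$fold / ref_mean
  tab[, c("peakset_id", "fold", "relative_fold", "anchor_fraction",
          "is_reference", "z", "p")]
}
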