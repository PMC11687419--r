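# Spike-in calibrated scaling factors and the GC-bias observed/expected
# diagnostic.

#' Spike-in calibrated ChIP scaling factors
#'
#' Per sample, immunoprecipitation efficiency is reads covering peaks divided
#' by total reads, separately for the target and spike-in genomes. The
#' absolute scaling factor is the spike-in chromatin percentage divided by
#' the spike-in reads covering peaks, normalised by the IP-efficiency ratio
#' between spike-in and target genomes; relative factors divide by the
#' largest absolute factor (so max(relative) == 1). Relative factors are
#' invariant both to expressing spike_pct as a percentage vs a fraction and
#' to a global rescaling of all read counts.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{spike_pct},
#'   \code{reads_target_total}, \code{reads_target_in_peaks},
#'   \code{reads_spike_total}, \code{reads_spike_in_peaks}.
#' @param ip_ratio Direction of the IP-efficiency normalisation:
#'   \code{"spike_over_target"} divides by eff_spike/eff_target (default);
#'   \code{"target_over_spike"} the reciprocal convention.
#' @return data.frame: sample_id, eff_target, eff_spike, absolute, relative.
#' @export
scaling_factors <- function(samples,
                            ip_ratio = c("spike_over_target",
                                         "target_over_spike")) {
  ip_ratio <- match.arg(ip_ratio)
  need <- c("sample_id", "spike_pct", "reads_target_total",
            "reads_target_in_peaks", "reads_spike_total",
            "reads_spike_in_peaks")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (nrow(samples) < 1L) stop("need at least one sample")
  with(samples, {
    if (any(reads_spike_in_peaks <= 0))
      stop("zero spike-in reads in peaks: scaling factor undefined")
    if (any(reads_target_total <= 0) || any(reads_spike_total <= 0))
      stop("total read counts must be positive")
    if (any(reads_target_in_peaks > reads_target_total) ||
        any(reads_spike_in_peaks > reads_spike_total))
      stop("reads in peaks exceed total reads")
    eff_t <- reads_target_in_peaks / reads_target_total
    eff_s <- reads_spike_in_peaks / reads_spike_total
    ratio <- if (ip_ratio == "spike_over_target") eff_s / eff_t
             else eff_t / eff_s
    absolute <- (spike_pct / reads_spike_in_peaks) / ratio
    data.frame(sample_id = sample_id, eff_target = eff_t, eff_spike = eff_s,
               absolute = absolute, relative = absolute / max(absolute),
               stringsAsFactors = FALSE)
  })
}

#' GC-bias observed/expected read-count profile
#'
#' Reads are binned by their fragment GC fraction. The expected counts come
#' from the empirical GC distribution of uniformly placed fragments drawn
#' with the observed reads' length distribution, rescaled so that the
#' expected total equals the observed total. A flat ratio near 1 across bins
#' indicates no GC bias; a rising ratio indicates a GC-rich skew.
#'
#' @param reads GRanges of fragments.
#' @param sequences Named DNAStringSet (the genome).
#' @param n_bins Number of equal-width GC bins over [0, 1] (default 20).
#' @param n_expected_samples Fragments sampled for the expected distribution.
#' @param seed Integer seed for the expected-fragment sampling.
#' @return List of class \code{gc_bias_profile}: \code{table} (bin_lo,
#'   bin_hi, observed, expected, ratio — NA where expected is 0),
#'   \code{n_dropped} reads extending past chromosome ends,
#'   \code{n_scored}.
#' @export
gc_bias_profile <- function(reads, sequences, n_bins = 20L,
                            n_expected_samples = 200000L, seed = 1L) {
  stopifnot(n_bins >= 2L)
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  chroms <- as.character(GenomicRanges::seqnames(reads))
  keep <- GenomicRanges::end(reads) <= lens[chroms] &
    GenomicRanges::start(reads) >= 1
  n_dropped <- sum(!keep)
  reads <- reads[keep]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin_of <- function(gc) pmin(pmax(findInterval(gc, edges,
                                                rightmost.closed = TRUE), 1L),
                              n_bins)
  cumgc <- lapply(names(sequences), function(nm) {
    v <- as.integer(strsplit(as.character(sequences[[nm]]), "")[[1]] %in%
                      c("G", "C"))
    cumsum(c(0L, v))
  })
  names(cumgc) <- names(sequences)
  frag_gc <- function(chrom, start1, width) {
    vapply(seq_along(chrom), function(i) {
      cg <- cumgc[[chrom[i]]]
      (cg[start1[i] + width[i]] - cg[start1[i]]) / width[i]
    }, 0)
  }
  observed <- tabulate(
    bin_of(frag_gc(as.character(GenomicRanges::seqnames(reads)),
                   GenomicRanges::start(reads),
                   GenomicRanges::width(reads))), n_bins)
  n_scored <- length(reads)
  # expected: uniform placement, read-length distribution matched
  set.seed(seed)
  if (n_scored > 0L) {
    wsamp <- sample(GenomicRanges::width(reads), n_expected_samples,
                    replace = TRUE)
    ci <- sample(names(sequences), n_expected_samples, replace = TRUE,
                 prob = lens)
    valid_max <- lens[ci] - wsamp + 1L
    ok <- valid_max >= 1L
    st <- floor(runif(sum(ok)) * valid_max[ok]) + 1L
    exp_counts <- tabulate(bin_of(frag_gc(ci[ok], st, wsamp[ok])), n_bins)
    expected <- exp_counts / sum(exp_counts) * n_scored
  } else {
    expected <- rep(0, n_bins)
  }
  ratio <- ifelse(expected > 0, observed / expected, NA_real_)
  structure(list(table = data.frame(bin_lo = edges[-length(edges)],
                                    bin_hi = edges[-1],
                                    observed = observed, expected = expected,
                                    ratio = ratio),
                 n_dropped = n_dropped, n_scored = n_scored),
            class = "gc_bias_profile")
}

#' @export
print.gc_bias_profile <- function(x, ...) {
  cat("GC-bias profile:", x$n_scored, "reads scored,",
      x$n_dropped, "dropped\n")
  nz <- x$table[x$table$observed > 0 | x$table$expected > 0, ]
  print(transform(nz, expected = round(expected, 1),
                  ratio = round(ratio, 3)), row.names = FALSE)
  invisible(x)
}
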