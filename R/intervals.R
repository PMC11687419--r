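#' @importFrom methods is
#' @importFrom stats median rnbinom rbinom runif rgamma setNames aggregate
#' @importFrom utils read.table write.table head
NULL

# Peak sets are GRanges; assembly / provenance live in metadata():
#   genome_id, antibody, cell_type, dataset_id (all optional free strings).

#' Construct a peak set
#'
#' A peak set is a \link[GenomicRanges]{GRanges} carrying optional provenance
#' in its \code{metadata()}: \code{genome_id} (assembly label), plus free
#' strings such as \code{antibody}, \code{cell_type}, \code{dataset_id}.
#' Intervals are 1-based closed as usual for GRanges; the BED readers and
#' writers convert from/to 0-based half-open at the file boundary.
#' Construction sorts by (chrom, start).
#'
#' @param gr A GRanges (or something coercible via \code{GRanges()}).
#' @param genome_id Assembly label attached to the set; overlap operations
#'   refuse to combine sets with differing non-NULL labels.
#' @param ... Further metadata entries (e.g. \code{antibody = "X"}).
#' @return A sorted GRanges with metadata set.
#' @export
peak_set <- function(gr, genome_id = NULL, ...) {
  gr <- GenomicRanges::GRanges(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  md <- list(genome_id = genome_id, ...)
  for (nm in names(md)) S4Vectors::metadata(gr)[[nm]] <- md[[nm]]
  gr
}

#' @rdname peak_set
#' @export
genome_id <- function(gr) S4Vectors::metadata(gr)$genome_id

check_same_genome <- function(a, b) {
  ga <- genome_id(a); gb <- genome_id(b)
  if (!is.null(ga) && !is.null(gb) && !identical(ga, gb))
    stop("genome_id mismatch: '", ga, "' vs '", gb, "'")
  invisible(TRUE)
}

#' Read a chromosome-size table
#'
#' Two-column TSV (name, length). Returns a named numeric vector, the
#' package's genome table: chromosome name -> length in bp.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names in ", path)
  if (any(tab$length <= 0)) stop("non-positive chromosome length in ", path)
  setNames(tab$length, tab$chrom)
}

#' @rdname read_genome_table
#' @param genome Named numeric vector of chromosome lengths.
#' @export
write_genome_table <- function(genome, path) {
  write.table(data.frame(names(genome), as.integer(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED / narrowPeak intervals
#'
#' Parses BED3-BED6 or ENCODE narrowPeak (10-column) files into a peak set.
#' Input coordinates are 0-based half-open and are converted to the 1-based
#' closed GRanges convention. For narrowPeak, column 10 (summit offset from
#' start) is stored in \code{mcols()$summit} when >= 0.
#'
#' @param path File path.
#' @param dialect One of \code{"bed3"}, \code{"bed4"}, \code{"bed5"},
#'   \code{"bed6"}, \code{"narrowPeak"}.
#' @param genome_id Optional assembly label for the returned set.
#' @return A sorted GRanges (empty file -> empty GRanges).
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "bed4", "bed5",
                                       "narrowPeak"),
                     genome_id = NULL) {
  dialect <- match.arg(dialect)
  ncol_needed <- switch(dialect, bed3 = 3L, bed4 = 4L, bed5 = 5L,
                        bed6 = 6L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(peak_set(GenomicRanges::GRanges(), genome_id = genome_id))
  fields <- strsplit(lines, "\t| +")
  bad <- which(vapply(fields, length, 0L) < ncol_needed)
  if (length(bad))
    stop("line ", bad[1], " of ", path, ": expected >= ", ncol_needed,
         " fields for dialect ", dialect)
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(1)
  start0 <- suppressWarnings(as.numeric(get(2)))
  end0 <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start0) || anyNA(end0))
    stop("line ", which(is.na(start0) | is.na(end0))[1], " of ", path,
         ": non-numeric coordinates")
  if (any(start0 >= end0))
    stop("line ", which(start0 >= end0)[1], " of ", path,
         ": start >= end")
  strand <- if (ncol_needed >= 6L) {
    s <- get(6); s[!s %in% c("+", "-")] <- "*"; s
  } else "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (ncol_needed >= 4L) {
    nm <- get(4)
    if (any(nm != ".")) names(gr) <- nm
  }
  if (ncol_needed >= 5L) {
    sc <- suppressWarnings(as.numeric(get(5)))
    GenomicRanges::mcols(gr)$score <- sc
  }
  if (dialect == "narrowPeak") {
    GenomicRanges::mcols(gr)$signalValue <- as.numeric(get(7))
    GenomicRanges::mcols(gr)$pValue <- as.numeric(get(8))
    GenomicRanges::mcols(gr)$qValue <- as.numeric(get(9))
    summit <- as.numeric(get(10))
    bad_summit <- summit >= (end0 - start0)
    if (any(bad_summit))
      stop("line ", which(bad_summit)[1], " of ", path,
           ": summit offset outside interval")
    summit[summit < 0] <- NA_real_
    GenomicRanges::mcols(gr)$summit <- summit
  }
  peak_set(gr, genome_id = genome_id)
}

#' Write intervals as BED / narrowPeak
#'
#' Converts back to 0-based half-open coordinates; a BED round trip is
#' coordinate-exact.
#'
#' @param gr GRanges to write.
#' @param path Output path.
#' @param dialect Output dialect, as in \code{\link{read_bed}}.
#' @export
write_bed <- function(gr, path, dialect = c("bed6", "bed3", "bed4", "bed5",
                                            "narrowPeak")) {
  dialect <- match.arg(dialect)
  n <- length(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  nm <- if (!is.null(names(gr))) names(gr) else rep(".", n)
  sc <- GenomicRanges::mcols(gr)$score
  if (is.null(sc)) sc <- rep(0, n)
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  cols <- switch(dialect,
    bed3 = data.frame(chrom, start0, end0),
    bed4 = data.frame(chrom, start0, end0, nm),
    bed5 = data.frame(chrom, start0, end0, nm, sc),
    bed6 = data.frame(chrom, start0, end0, nm, sc, st),
    narrowPeak = {
      mc <- GenomicRanges::mcols(gr)
      pull <- function(col) if (!is.null(mc[[col]])) mc[[col]] else rep(0, n)
      summit <- if (!is.null(mc$summit)) {
        s <- mc$summit; s[is.na(s)] <- -1; s
      } else rep(-1, n)
      data.frame(chrom, start0, end0, nm, sc, st,
                 pull("signalValue"), pull("pValue"), pull("qValue"), summit)
    })
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count query intervals overlapping a subject set
#'
#' Number of query intervals with at least \code{min_overlap} shared bases
#' with any subject interval (half-open semantics at the BED level: intervals
#' that merely touch do not overlap). Strand is ignored.
#'
#' @param query,subject GRanges; their \code{genome_id}s must agree when both
#'   are set.
#' @param min_overlap Minimum shared bases (default 1, the BEDTools default).
#' @return Integer count, always <= length(query).
#' @export
count_overlapping <- function(query, subject, min_overlap = 1L) {
  check_same_genome(query, subject)
  hits <- GenomicRanges::findOverlaps(query, subject,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  length(unique(S4Vectors::queryHits(hits)))
}

#' Fraction of query intervals overlapping a subject set
#'
#' \code{count_overlapping(query, subject) / length(query)}.
#'
#' @inheritParams count_overlapping
#' @return Real in [0, 1]. Errors on an empty query (undefined fraction).
#' @export
overlap_fraction <- function(query, subject, min_overlap = 1L) {
  if (length(query) == 0L) stop("overlap_fraction undefined for empty query")
  count_overlapping(query, subject, min_overlap) / length(query)
}

#' Collapse overlapping intervals across peak sets
#'
#' Pools the given sets and merges maximal runs of (strictly) overlapping
#' intervals into consensus intervals. Intervals that only touch (adjacent
#' under half-open coordinates) are not merged.
#'
#' @param sets A list of GRanges, or a single GRanges.
#' @return A sorted GRanges of consensus intervals, carrying the shared
#'   genome_id if all inputs agree.
#' @export
merge_union <- function(sets) {
  if (is(sets, "GRanges")) sets <- list(sets)
  if (length(sets) > 1L)
    for (i in seq_along(sets)[-1]) check_same_genome(sets[[1]], sets[[i]])
  gid <- genome_id(sets[[1]])
  pooled <- suppressWarnings(do.call(c, lapply(unname(sets), function(g) {
    names(g) <- NULL
    GenomicRanges::mcols(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  })))
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
  peak_set(merged, genome_id = gid)
}

#' Total bases covered by a set of intervals
#'
#' @param gr GRanges.
#' @return Numeric: width of the union of \code{gr}.
#' @export
covered_bases <- function(gr) {
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE))))
}
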