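# Cross-reactivity screen: profile a query peak set against a reference
# compendium, build reproducible peak sets across replicates, and classify
# peaks into common / A-specific / B-specific categories.

#' Overlap profile of a query peak set against a reference compendium
#'
#' For each reference set, the fraction of query peaks overlapping at least
#' one reference peak. An unusually high median fraction against an
#' off-target factor's compendium is the signature of antibody
#' cross-reactivity. Reference sets are deliberately not matched by cell
#' type; provenance (cell type, dataset id) is carried through from each
#' reference set's metadata when present.
#'
#' @param query Nonempty GRanges.
#' @param compendium List of GRanges reference sets (optionally named).
#' @return List of class \code{overlap_profile}: \code{query_id},
#'   \code{table} (one row per reference: reference_id, reference_cell_type,
#'   n_query, n_overlapping, fraction), \code{median_fraction}.
#' @export
compendium_overlap <- function(query, compendium) {
  if (length(query) == 0L) stop("empty query peak set")
  if (is(compendium, "GRanges")) compendium <- list(compendium)
  if (length(compendium) == 0L) stop("empty compendium")
  ids <- names(compendium)
  if (is.null(ids)) ids <- sprintf("ref%03d", seq_along(compendium))
  rows <- lapply(seq_along(compendium), function(i) {
    ref <- compendium[[i]]
    ct <- S4Vectors::metadata(ref)$cell_type
    n_ov <- count_overlapping(query, ref)
    data.frame(reference_id = ids[i],
               reference_cell_type = if (is.null(ct)) NA_character_ else ct,
               n_query = length(query), n_overlapping = n_ov,
               fraction = n_ov / length(query), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(query_id = S4Vectors::metadata(query)$dataset_id,
                 table = tab, median_fraction = median(tab$fraction)),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat("Overlap profile", if (!is.null(x$query_id)) paste0("for ", x$query_id),
      "\n  references:", nrow(x$table),
      "\n  median fraction:", signif(x$median_fraction, 3), "\n")
  invisible(x)
}

#' Reproducible peaks across replicate sets
#'
#' Under \code{rule = "all"}: peaks of the first replicate overlapping at
#' least one peak in every other replicate. Under \code{"any"}: the merged
#' union of all replicates. Under \code{"at_least_k"}: first-replicate peaks
#' supported by at least \code{k} of the sets (the first set supports its own
#' peaks).
#'
#' @param replicate_sets List of GRanges (>= 1).
#' @param rule One of \code{"all"}, \code{"any"}, \code{"at_least_k"}.
#' @param k Required support for \code{"at_least_k"}.
#' @return GRanges.
#' @export
reproducible_peaks <- function(replicate_sets,
                               rule = c("all", "any", "at_least_k"),
                               k = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(replicate_sets) >= 1L)
  if (rule == "any") return(merge_union(replicate_sets))
  if (rule == "all") k <- length(replicate_sets)
  if (is.null(k)) stop("rule 'at_least_k' needs k")
  if (k > length(replicate_sets))
    stop("k (", k, ") exceeds number of replicate sets (",
         length(replicate_sets), ")")
  first <- replicate_sets[[1]]
  support <- rep(1L, length(first))
  for (other in replicate_sets[-1]) {
    check_same_genome(first, other)
    hit <- IRanges::overlapsAny(first, other, ignore.strand = TRUE)
    support <- support + as.integer(hit)
  }
  first[support >= k]
}

#' Classify peaks from two antibodies into common and specific categories
#'
#' Anchored on A's intervals: \code{common} are A peaks overlapping at least
#' one B peak, \code{a_specific} the remaining A peaks, and \code{b_specific}
#' the B peaks overlapping no A peak. common and a_specific partition A
#' exactly.
#'
#' @param set_a,set_b GRanges from the two antibodies (same genome_id).
#' @return List of class \code{peak_classification} with GRanges
#'   \code{common}, \code{a_specific}, \code{b_specific} and a
#'   \code{counts} vector.
#' @export
classify_peaks <- function(set_a, set_b) {
  check_same_genome(set_a, set_b)
  a_hits <- IRanges::overlapsAny(set_a, set_b, ignore.strand = TRUE)
  b_hits <- IRanges::overlapsAny(set_b, set_a, ignore.strand = TRUE)
  res <- list(common = set_a[a_hits],
              a_specific = set_a[!a_hits],
              b_specific = set_b[!b_hits])
  res$counts <- c(common = length(res$common),
                  a_specific = length(res$a_specific),
                  b_specific = length(res$b_specific))
  class(res) <- "peak_classification"
  res
}

#' @export
print.peak_classification <- function(x, ...) {
  cat("Peak classification (anchored on set A):\n")
  print(x$counts)
  invisible(x)
}
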