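# Ranked TSS-window peak-to-gene assignment and conserved binding-site
# construction across cell types.

DEFAULT_ALLOWED_TYPES <- c("protein_coding", "lincRNA",
                           "processed_transcript",
                           "bidirectional_promoter_lncRNA", "antisense")

KNOWN_TRANSCRIPT_TYPES <- c(DEFAULT_ALLOWED_TYPES,
                            "miRNA", "snRNA", "snoRNA", "rRNA", "misc_RNA",
                            "pseudogene", "processed_pseudogene", "TEC",
                            "nonsense_mediated_decay", "retained_intron")

type_rank <- function(type) {
  ifelse(type == "protein_coding", 3L, ifelse(type == "lincRNA", 2L, 1L))
}

has_canonical_name <- function(gene_name, gene_id) {
  !is.na(gene_name) & nzchar(gene_name) & gene_name != gene_id
}

#' Assign peaks to genes through ranked TSS windows
#'
#' Implements the ranked promoter-window assignment: (1) transcripts are
#' filtered to the allowed types, allowed support levels, and expressed
#' entries; (2) a transcript is a candidate when its strand-aware TSS window
#' (\code{upstream} bp upstream to \code{downstream} bp downstream of the
#' TSS) overlaps a peak \emph{and} the TSS-to-peak-centre distance is below
#' \code{max_center_distance}; (3) per gene, one (transcript, peak) pair is
#' kept by the ranked criteria best support level, smallest distance,
#' highest expression, maximum length (final tie: transcript_id); (4) peaks
#' claimed by several same-strand genes are resolved by transcript-type
#' priority (protein_coding > lincRNA > other), then support level 1-2 over
#' others, then named over unnamed genes — a residual tie discards the tied
#' genes; genes sharing a peak from opposite strands are both kept and the
#' peak is flagged as a bidirectional promoter.
#'
#' @param peaks GRanges (names used as peak ids; generated if absent).
#' @param annotation data.frame with columns gene_id, gene_name,
#'   transcript_id, transcript_type, transcript_support_level, chrom,
#'   strand, tss (1-based position of the first transcribed base), length,
#'   expression.
#' @param allowed_types Transcript types retained.
#' @param tsl_allowed Support levels retained (default 1:5; NA excluded).
#' @param min_expression Transcripts with expression strictly above this are
#'   considered expressed (default 0).
#' @param upstream,downstream TSS window extent in bp (defaults 2000 / 1000).
#' @param max_center_distance Maximum TSS-to-peak-centre distance in bp
#'   (strict; default 2000).
#' @param center \code{"midpoint"} (start + floor(width/2), the default) or
#'   \code{"summit"} (requires \code{mcols(peaks)$summit}).
#' @return List of class \code{gene_assignment}: data.frames
#'   \code{bound_genes} (gene_id, transcript_id, peak_id, distance),
#'   \code{assigned_peaks} (peak_id, gene_ids, bidirectional),
#'   \code{discarded} (peak_id, gene_ids, reason).
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  allowed_types = DEFAULT_ALLOWED_TYPES,
                                  tsl_allowed = 1:5,
                                  min_expression = 0,
                                  upstream = 2000L, downstream = 1000L,
                                  max_center_distance = 2000L,
                                  center = c("midpoint", "summit")) {
  center <- match.arg(center)
  need <- c("gene_id", "gene_name", "transcript_id", "transcript_type",
            "transcript_support_level", "chrom", "strand", "tss",
            "length", "expression")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols))
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(annotation) == 0L) stop("empty annotation")
  unknown <- setdiff(unique(annotation$transcript_type),
                     union(KNOWN_TRANSCRIPT_TYPES, allowed_types))
  if (length(unknown))
    stop("unknown transcript_type value(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(names(peaks)))
    names(peaks) <- sprintf("peak_%05d", seq_along(peaks))

  ann <- annotation[annotation$transcript_type %in% allowed_types &
                      annotation$transcript_support_level %in% tsl_allowed &
                      annotation$expression > min_expression, , drop = FALSE]
  empty_out <- function() {
    structure(list(
      bound_genes = data.frame(gene_id = character(0),
                               transcript_id = character(0),
                               peak_id = character(0),
                               distance = numeric(0)),
      assigned_peaks = data.frame(peak_id = character(0),
                                  gene_ids = character(0),
                                  bidirectional = logical(0)),
      discarded = data.frame(peak_id = character(0),
                             gene_ids = character(0),
                             reason = character(0))),
      class = "gene_assignment")
  }
  if (nrow(ann) == 0L) return(empty_out())

  win_start <- ifelse(ann$strand == "+", ann$tss - upstream,
                      ann$tss - downstream + 1L)
  win_end <- ifelse(ann$strand == "+", ann$tss + downstream - 1L,
                    ann$tss + upstream)
  windows <- GenomicRanges::GRanges(ann$chrom,
                                    IRanges::IRanges(pmax(win_start, 1L),
                                                     win_end))
  centers <- if (center == "midpoint") {
    GenomicRanges::start(peaks) + floor(GenomicRanges::width(peaks) / 2)
  } else {
    summit <- GenomicRanges::mcols(peaks)$summit
    if (is.null(summit)) stop("center = 'summit' but peaks lack a summit")
    GenomicRanges::start(peaks) + summit
  }
  hits <- GenomicRanges::findOverlaps(windows, peaks, ignore.strand = TRUE)
  ti <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  dist <- abs(ann$tss[ti] - centers[pi])
  keep <- dist < max_center_distance
  ti <- ti[keep]; pi <- pi[keep]; dist <- dist[keep]
  if (length(ti) == 0L) return(empty_out())

  cand <- data.frame(gene_id = ann$gene_id[ti],
                     gene_name = ann$gene_name[ti],
                     transcript_id = ann$transcript_id[ti],
                     transcript_type = ann$transcript_type[ti],
                     tsl = ann$transcript_support_level[ti],
                     strand = ann$strand[ti],
                     expression = ann$expression[ti],
                     length = ann$length[ti],
                     peak_id = names(peaks)[pi],
                     distance = dist, stringsAsFactors = FALSE)
  # per gene: one (transcript, peak) pair by the ranked criteria
  ord <- order(cand$gene_id, cand$tsl, cand$distance, -cand$expression,
               -cand$length, cand$transcript_id)
  cand <- cand[ord, ]
  best <- cand[!duplicated(cand$gene_id), ]

  # resolve peaks claimed by several genes
  bound_keep <- rep(TRUE, nrow(best))
  bidir_peaks <- character(0)
  disc <- list()
  for (pk in unique(best$peak_id[duplicated(best$peak_id)])) {
    rows <- which(best$peak_id == pk)
    for (st in unique(best$strand[rows])) {
      grp <- rows[best$strand[rows] == st]
      if (length(grp) < 2L) next
      prio <- cbind(type_rank(best$transcript_type[grp]),
                    as.integer(best$tsl[grp] %in% c(1, 2)),
                    as.integer(has_canonical_name(best$gene_name[grp],
                                                  best$gene_id[grp])))
      key <- prio[, 1] * 4L + prio[, 2] * 2L + prio[, 3]
      top <- which(key == max(key))
      if (length(top) == 1L) {
        losers <- grp[-top]
        bound_keep[losers] <- FALSE
        disc[[length(disc) + 1L]] <- data.frame(
          peak_id = pk,
          gene_ids = paste(sort(best$gene_id[losers]), collapse = ","),
          reason = "outranked_same_strand", stringsAsFactors = FALSE)
      } else {
        tied <- grp[top]; losers <- grp[-top]
        bound_keep[c(tied, losers)] <- FALSE
        disc[[length(disc) + 1L]] <- data.frame(
          peak_id = pk,
          gene_ids = paste(sort(best$gene_id[tied]), collapse = ","),
          reason = "ambiguous_same_strand", stringsAsFactors = FALSE)
        if (length(losers))
          disc[[length(disc) + 1L]] <- data.frame(
            peak_id = pk,
            gene_ids = paste(sort(best$gene_id[losers]), collapse = ","),
            reason = "outranked_same_strand", stringsAsFactors = FALSE)
      }
    }
    kept <- which(best$peak_id == pk & bound_keep)
    if (length(kept) > 1L && length(unique(best$strand[kept])) > 1L)
      bidir_peaks <- c(bidir_peaks, pk)
  }
  bound <- best[bound_keep, c("gene_id", "transcript_id", "peak_id",
                              "distance")]
  bound <- bound[order(bound$gene_id), , drop = FALSE]
  rownames(bound) <- NULL

  assigned <- if (nrow(bound)) {
    agg <- aggregate(gene_id ~ peak_id, data = bound,
                     FUN = function(g) paste(sort(g), collapse = ","))
    names(agg)[2] <- "gene_ids"
    agg$bidirectional <- agg$peak_id %in% bidir_peaks
    agg[order(agg$peak_id), , drop = FALSE]
  } else {
    data.frame(peak_id = character(0), gene_ids = character(0),
               bidirectional = logical(0))
  }
  rownames(assigned) <- NULL
  discarded <- if (length(disc)) {
    d <- do.call(rbind, disc)
    d <- d[order(d$peak_id, d$reason), , drop = FALSE]
    rownames(d) <- NULL
    d
  } else {
    data.frame(peak_id = character(0), gene_ids = character(0),
               reason = character(0))
  }
  structure(list(bound_genes = bound, assigned_peaks = assigned,
                 discarded = discarded),
            class = "gene_assignment")
}

#' @export
print.gene_assignment <- function(x, ...) {
  cat("Gene assignment:", nrow(x$bound_genes), "bound genes,",
      nrow(x$assigned_peaks), "assigned peaks (",
      sum(x$assigned_peaks$bidirectional), "bidirectional ),",
      nrow(x$discarded), "discard records\n")
  invisible(x)
}

#' Binding sites conserved across cell types
#'
#' Pools all datasets' peaks into consensus regions (merged union) and keeps
#' the regions supported by at least one dataset of \emph{every} cell type.
#'
#' @param peaksets Named list of GRanges (dataset id -> peaks).
#' @param cell_type_of Named character vector mapping dataset id to cell
#'   type; every dataset must be mapped.
#' @return GRanges of conserved consensus regions, with
#'   \code{mcols()$n_cell_types}.
#' @export
conserved_sites <- function(peaksets, cell_type_of) {
  stopifnot(length(peaksets) >= 1L)
  ids <- names(peaksets)
  if (is.null(ids)) stop("peaksets must be named")
  unmapped <- setdiff(ids, names(cell_type_of))
  if (length(unmapped))
    stop("datasets without a cell type: ", paste(unmapped, collapse = ", "))
  consensus <- merge_union(peaksets)
  types <- unique(cell_type_of[ids])
  support <- vapply(types, function(ct) {
    members <- ids[cell_type_of[ids] == ct]
    Reduce(`|`, lapply(peaksets[members], function(s)
      IRanges::overlapsAny(consensus, s, ignore.strand = TRUE)))
  }, logical(length(consensus)))
  support <- matrix(support, ncol = length(types))
  keep <- rowSums(support) == length(types)
  out <- consensus[keep]
  GenomicRanges::mcols(out)$n_cell_types <- rep(length(types), length(out))
  out
}
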