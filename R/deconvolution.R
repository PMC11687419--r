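# ICA-based estimation of cell-type proportions in bulk accessibility
# samples from single-cell pseudobulk references.

#' Pseudobulk profiles from single-cell counts
#'
#' Sums counts per peak across all cells of each cluster. Cluster column
#' order is the first-appearance order of the labels.
#'
#' @param sc_counts Peaks x cells non-negative integer matrix.
#' @param cluster_labels Cluster label per cell (length = ncol).
#' @return Peaks x clusters matrix.
#' @export
pseudobulk <- function(sc_counts, cluster_labels) {
  if (length(cluster_labels) != ncol(sc_counts))
    stop("one cluster label per cell required")
  if (anyNA(cluster_labels)) stop("unlabeled cell (NA cluster label)")
  clusters <- unique(cluster_labels)
  out <- vapply(clusters, function(cl)
    rowSums(sc_counts[, cluster_labels == cl, drop = FALSE]),
    numeric(nrow(sc_counts)))
  out <- matrix(out, nrow = nrow(sc_counts),
                dimnames = list(rownames(sc_counts), clusters))
  out
}

#' Median-of-ratios size factors
#'
#' The reference is the per-peak geometric mean across samples, computed
#' over peaks with no zero count; each sample's size factor is the median
#' over those peaks of count/reference.
#'
#' @param counts Peaks x samples matrix with at least one all-positive peak.
#' @param reference Optional externally supplied per-peak reference (named
#'   by peak); used to normalise new samples against a stored model frame.
#' @return Named numeric vector of size factors (attribute
#'   \code{"reference"} carries the per-peak reference used).
#' @export
median_of_ratios_size_factors <- function(counts, reference = NULL) {
  counts <- as.matrix(counts)
  if (is.null(reference)) {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) stop("no peak with all-positive counts across samples")
    reference <- rep(NA_real_, nrow(counts))
    reference[pos] <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    names(reference) <- rownames(counts)
  } else {
    reference <- reference[rownames(counts)]
  }
  use <- !is.na(reference) & reference > 0
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    median(col / reference[use]))
  if (any(sf <= 0)) stop("non-positive size factor")
  attr(sf, "reference") <- reference
  sf
}

vst_log2 <- function(norm_counts) log2(norm_counts + 1)

#' Fit an ICA deconvolution model on pseudobulk profiles
#'
#' Pipeline: median-of-ratios size-factor normalisation, a
#' variance-stabilising log2(x + 1) transform, per-peak centring across
#' pseudobulk columns (offsets stored), then FastICA
#' (\code{\link[ica]{icafast}}, logcosh contrast) into \code{k}
#' statistically independent components. Each component is assigned to the
#' cluster with the largest absolute mixing weight and sign-flipped so that
#' weight is positive; assignment collisions are resolved greedily
#' best-weight-first and flagged.
#'
#' @param pb Peaks x clusters pseudobulk count matrix.
#' @param k Number of components (default 7; must be <= number of clusters).
#' @param max_iter Maximum FastICA iterations (default 100).
#' @param seed Integer seed (FastICA initialisation is random).
#' @return List of class \code{deconv_model}: \code{S} (peaks x k source
#'   matrix), \code{M} (clusters x k mixing estimates),
#'   \code{component_cluster} (named integer map, with signs applied),
#'   \code{offsets} (per-peak centring means), \code{reference}
#'   (median-of-ratios reference), \code{size_factors}, \code{clusters},
#'   \code{peaks}, \code{converged}, \code{collision}.
#' @export
fit_deconv <- function(pb, k = 7L, max_iter = 100L, seed = 1L) {
  pb <- as.matrix(pb)
  if (k > ncol(pb))
    stop("k (", k, ") exceeds number of pseudobulk clusters (", ncol(pb), ")")
  sf <- median_of_ratios_size_factors(pb)
  norm <- sweep(pb, 2, sf, "/")
  v <- vst_log2(norm)
  # per-peak means across pseudobulk columns, stored for bulk centring.
  # The ICA itself centres each column (the icafast default): per-peak
  # centring would make the columns sum to zero and lose one rank, which
  # forbids k components for k clusters.
  offsets <- rowMeans(v)
  set.seed(seed)
  fit <- ica::icafast(v, nc = k, center = TRUE, maxit = max_iter,
                      fun = "logcosh")
  if (!isTRUE(fit$converged))
    warning("FastICA did not converge within ", max_iter, " iterations")
  S <- fit$S; M <- fit$M
  rownames(S) <- rownames(pb); rownames(M) <- colnames(pb)
  colnames(S) <- colnames(M) <- paste0("IC", seq_len(k))
  # greedy best-weight-first component -> cluster assignment with signs
  W <- abs(M)
  naive <- apply(W, 2, which.max)
  map <- rep(NA_integer_, k)
  free_clusters <- rep(TRUE, nrow(M)); free_comps <- rep(TRUE, k)
  for (step in seq_len(k)) {
    Wm <- W; Wm[!free_clusters, ] <- -Inf; Wm[, !free_comps] <- -Inf
    idx <- arrayInd(which.max(Wm), dim(Wm))
    map[idx[2]] <- idx[1]
    free_clusters[idx[1]] <- FALSE; free_comps[idx[2]] <- FALSE
  }
  collision <- any(map != naive)
  sgn <- sign(M[cbind(map, seq_len(k))])
  sgn[sgn == 0] <- 1
  S <- sweep(S, 2, sgn, "*")
  M <- sweep(M, 2, sgn, "*")
  names(map) <- colnames(S)
  structure(list(S = S, M = M, component_cluster = map,
                 offsets = offsets, reference = attr(sf, "reference"),
                 size_factors = sf, clusters = colnames(pb),
                 peaks = rownames(pb), converged = isTRUE(fit$converged),
                 collision = collision, k = k),
            class = "deconv_model")
}

#' @export
print.deconv_model <- function(x, ...) {
  cat("ICA deconvolution model: k =", x$k, "components over",
      length(x$peaks), "peaks,", length(x$clusters), "clusters\n")
  cat("  component -> cluster:",
      paste(names(x$component_cluster), x$clusters[x$component_cluster],
            sep = ":", collapse = " "), "\n")
  if (x$collision) cat("  note: assignment collision resolved greedily\n")
  if (!x$converged) cat("  note: FastICA did not converge\n")
  invisible(x)
}

#' Estimate cell-type proportions in bulk samples
#'
#' Bulk counts are normalised with their own median-of-ratios factors
#' computed against the model's stored reference, transformed with the same
#' VST, and centred with the model's stored per-peak offsets (the
#' pseudobulk frame the components were learned in; the source columns are
#' zero-mean, so the centring convention cannot leak into the projection).
#' Per-sample component contributions are obtained by least-squares
#' projection onto the source matrix, then unmixed into cluster
#' contributions. Negatives are clipped to zero and rows normalised to sum
#' to one.
#'
#' With \code{method = "unmix"} (default) the cluster contributions solve
#' the mixing-matrix system under the unit-sum constraint — exact when a
#' bulk sample truly is a mixture of the pseudobulk profiles. With
#' \code{method = "map"} each component's contribution is credited to its
#' mapped cluster directly; this cruder route only uses the
#' component-to-cluster map.
#'
#' @param model A \code{\link{fit_deconv}} model.
#' @param bulk Peaks x samples count matrix over the model's peak set.
#' @param method \code{"unmix"} or \code{"map"}.
#' @return Samples x clusters proportion matrix; rows sum to 1 (all-zero
#'   rows are left at zero and listed in attribute \code{"zero_rows"}).
#' @export
estimate_proportions <- function(model, bulk, method = c("unmix", "map")) {
  method <- match.arg(method)
  bulk <- as.matrix(bulk)
  missing_peaks <- setdiff(model$peaks, rownames(bulk))
  if (length(missing_peaks))
    stop("bulk matrix lacks model peaks: ",
         paste(head(missing_peaks, 5), collapse = ", "),
         if (length(missing_peaks) > 5) " ...")
  bulk <- bulk[model$peaks, , drop = FALSE]
  sf <- median_of_ratios_size_factors(bulk, reference = model$reference)
  v <- vst_log2(sweep(bulk, 2, sf, "/"))
  centred <- v - model$offsets
  contrib <- qr.coef(qr(model$S), centred)   # k x samples
  n_cl <- length(model$clusters)
  prop <- matrix(0, ncol(bulk), n_cl,
                 dimnames = list(colnames(bulk), model$clusters))
  if (method == "map") {
    for (j in seq_len(model$k))
      prop[, model$component_cluster[j]] <-
        prop[, model$component_cluster[j]] + contrib[j, ]
  } else {
    # For mixture proportions p (sum 1) of the pseudobulk profiles, the
    # component contributions satisfy a = t(M) (p - mean(p)); invert with
    # the unit-sum constraint (minimum-norm when k < clusters).
    Mt <- t(model$M)                              # k x clusters
    Mt_inv <- if (model$k == n_cl) solve(Mt) else
      crossprod(Mt, MASS::ginv(tcrossprod(Mt)))   # right pseudo-inverse
    p_hat <- Mt_inv %*% contrib + 1 / n_cl        # clusters x samples
    prop[, ] <- t(p_hat)
  }
  prop[prop < 0] <- 0
  rs <- rowSums(prop)
  zero_rows <- rownames(prop)[rs == 0]
  prop[rs > 0, ] <- prop[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(prop, "zero_rows") <- zero_rows
  prop
}
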