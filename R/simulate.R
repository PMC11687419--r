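# Synthetic fixtures with known ground truth: genome sequence, antibody peak
# sets with a planted cross-reactive fraction, GC-biased reads, transcript
# annotation with planted assignment scenarios, and single-cell accessibility
# mixed into bulk samples with known proportions.

#' Derive a reproducible substream seed
#'
#' Each generator draws from its own named substream of the global seed, so
#' changing one generator's consumption of random numbers cannot perturb the
#' outputs of the others.
#'
#' @param seed Integer global seed.
#' @param name Substream name.
#' @return An integer seed < 2^31.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1000003
  as.integer(((seed %% 1000003) * 1009 + h) %% 2147483647L)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe a
#' compact two-chromosome genome with several hundred binding sites per
#' factor, a cross-reactive ("dirty") antibody reporting half of the
#' off-target factor's sites, and a five-cell-type accessibility atlas mixed
#' into twenty bulk samples.
#'
#' @param seed Global integer seed; all generators derive named substreams.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_true_sites_a,n_true_sites_b Genuine binding sites for factor A
#'   (the target) and factor B (the off-target the dirty antibody also sees).
#' @param cross_reactive_fraction Fraction of B sites the dirty antibody
#'   reports, in [0, 1].
#' @param peak_width Width in bp of simulated peaks.
#' @param noise_peaks Random false-positive peaks added to each antibody set.
#' @param gc Genome GC content in [0, 1].
#' @param gc_bias_strength Exponential GC tilt for read sampling (0 = none).
#' @param k_cell_types,n_cells_per_type,n_peaks_atac,n_bulk Single-cell
#'   accessibility atlas dimensions and number of bulk mixtures.
#' @param dirichlet_alpha Concentration of the bulk mixing proportions.
#' @param nb_dispersion Negative-binomial size parameter for per-cell counts.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chrS1 = 400000, chrS2 = 300000),
                       n_true_sites_a = 400L,
                       n_true_sites_b = 400L,
                       cross_reactive_fraction = 0.5,
                       peak_width = 200L,
                       noise_peaks = 50L,
                       gc = 0.45,
                       gc_bias_strength = 0,
                       k_cell_types = 5L,
                       n_cells_per_type = 40L,
                       n_peaks_atac = 2000L,
                       n_bulk = 20L,
                       dirichlet_alpha = 1,
                       nb_dispersion = 10) {
  stopifnot(cross_reactive_fraction >= 0, cross_reactive_fraction <= 1,
            n_true_sites_a >= 0, n_true_sites_b >= 0, noise_peaks >= 0,
            gc >= 0, gc <= 1, gc_bias_strength >= 0, all(genome > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genome sequence
#'
#' I.i.d. nucleotides at the configured GC content, one sequence per
#' chromosome of the configured genome table.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
simulate_genome <- function(config) {
  set.seed(substream_seed(config$seed, "genome"))
  gc <- config$gc
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(config$genome, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }, "")
  Biostrings::DNAStringSet(setNames(seqs, names(config$genome)))
}

# Non-overlapping site placement: carve each chromosome into slots of
# 3 * peak_width and sample distinct slots, so truth labels stay unambiguous.
place_sites <- function(genome, n, peak_width, exclude_slots = NULL) {
  slot_w <- 3L * peak_width
  slots_per_chrom <- floor(genome / slot_w)
  total <- sum(slots_per_chrom)
  offsets <- cumsum(c(0, head(slots_per_chrom, -1)))
  names(offsets) <- names(genome)
  avail <- setdiff(seq_len(total), exclude_slots)
  if (n > length(avail))
    stop("cannot place ", n, " sites: only ", length(avail),
         " free slots in genome")
  chosen <- sort(sample(avail, n))
  chrom_idx <- findInterval(chosen - 1, cumsum(slots_per_chrom),
                            left.open = FALSE) + 1L
  chrom <- names(genome)[chrom_idx]
  local_slot <- chosen - offsets[chrom_idx] - 1L
  start1 <- local_slot * slot_w + peak_width + 1L  # centred third of the slot
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start1,
                                                width = peak_width))
  list(gr = gr, slots = chosen)
}

#' Simulate two antibodies' peak sets with planted cross-reactivity
#'
#' Factor A sites and factor B sites are placed disjointly. The clean
#' antibody's set covers the A sites (+ noise); the dirty antibody's set
#' covers the A sites plus a Bernoulli(\code{cross_reactive_fraction}) subset
#' of the B sites (+ noise); factor B's own set covers the B sites. Noise
#' peaks are placed uniformly outside all true-site footprints. Truth labels
#' in \code{mcols()$origin} partition every peak
#' (\code{a_site} / \code{b_site} / \code{b_crossreactive} / \code{noise}).
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with GRanges \code{clean_a}, \code{dirty_a}, \code{b},
#'   the planted site coordinates \code{a_sites}, \code{b_sites}, and the
#'   index vector \code{crossreactive_idx} of B sites present in the dirty
#'   set.
#' @export
simulate_antibody_peaksets <- function(config) {
  set.seed(substream_seed(config$seed, "antibody_peaks"))
  g <- config$genome
  w <- config$peak_width
  a <- place_sites(g, config$n_true_sites_a, w)
  b <- place_sites(g, config$n_true_sites_b, w, exclude_slots = a$slots)
  used <- c(a$slots, b$slots)

  cross <- which(runif(length(b$gr)) < config$cross_reactive_fraction)

  label <- function(gr, origin) {
    GenomicRanges::mcols(gr)$origin <- rep(origin, length(gr))
    gr
  }
  noise <- function() {
    if (config$noise_peaks == 0L)
      return(label(GenomicRanges::GRanges(), character(0)))
    label(place_sites(g, config$noise_peaks, w, exclude_slots = used)$gr,
          "noise")
  }
  clean_a <- peak_set(c(label(a$gr, "a_site"), noise()),
                      genome_id = "sim1", antibody = "clean_A")
  dirty_a <- peak_set(c(label(a$gr, "a_site"),
                        label(b$gr[cross], "b_crossreactive"), noise()),
                      genome_id = "sim1", antibody = "dirty_A")
  b_set <- peak_set(c(label(b$gr, "b_site"), noise()),
                    genome_id = "sim1", antibody = "B")
  list(clean_a = clean_a, dirty_a = dirty_a, b = b_set,
       a_sites = peak_set(a$gr, genome_id = "sim1"),
       b_sites = peak_set(b$gr, genome_id = "sim1"),
       crossreactive_idx = cross)
}

#' Plant motif instances into a genome sequence
#'
#' Writes one instance sampled from the PWM (random strand) at the centre of
#' each given interval. Used to give planted binding sites a recoverable
#' sequence signature.
#'
#' @param sequences Named DNAStringSet.
#' @param sites GRanges of sites to stamp.
#' @param pwm A \code{\link{pwm}} object.
#' @param seed Integer seed.
#' @return The modified DNAStringSet.
#' @export
plant_motifs <- function(sequences, sites, pwm, seed) {
  set.seed(seed)
  chars <- lapply(as.character(sequences), function(s) strsplit(s, "")[[1]])
  w <- ncol(pwm$mat)
  bases <- rownames(pwm$mat)
  for (i in seq_along(sites)) {
    chrom <- as.character(GenomicRanges::seqnames(sites[i]))
    mid <- GenomicRanges::start(sites[i]) +
      floor(GenomicRanges::width(sites[i]) / 2)
    inst <- vapply(seq_len(w), function(j)
      sample(bases, 1, prob = pwm$mat[, j]), "")
    if (runif(1) < 0.5)
      inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
    pos <- mid - floor(w / 2)
    chars[[chrom]][pos:(pos + w - 1)] <- inst
  }
  Biostrings::DNAStringSet(setNames(
    vapply(chars, paste, "", collapse = ""), names(sequences)))
}

#' Simulate reads with a GC tilt
#'
#' Fragments of the given length are sampled with probability proportional to
#' \code{exp(bias * gc_fraction)} (rejection sampling); \code{bias = 0} gives
#' uniform placement.
#'
#' @param sequences Named DNAStringSet (the genome).
#' @param n_reads Number of fragments to draw.
#' @param bias GC tilt strength, >= 0.
#' @param read_length Fragment length in bp.
#' @param seed Integer seed.
#' @return GRanges of fragments.
#' @export
simulate_reads_gc <- function(sequences, n_reads, bias = 0,
                              read_length = 100L, seed = 1L) {
  stopifnot(bias >= 0)
  set.seed(seed)
  lens <- Biostrings::width(sequences)
  # cumulative GC per chromosome for O(1) window GC
  cumgc <- lapply(seq_along(sequences), function(i) {
    v <- as.integer(strsplit(as.character(sequences[[i]]), "")[[1]] %in%
                      c("G", "C"))
    cumsum(c(0L, v))
  })
  out_chrom <- character(0); out_start <- integer(0)
  need <- n_reads
  while (need > 0) {
    m <- max(2L * need, 1000L)
    ci <- sample(seq_along(sequences), m, replace = TRUE,
                 prob = lens - read_length + 1)
    st <- vapply(ci, function(i)
      sample.int(lens[i] - read_length + 1L, 1L), 1L)
    gc <- vapply(seq_len(m), function(j) {
      cg <- cumgc[[ci[j]]]
      (cg[st[j] + read_length] - cg[st[j]]) / read_length
    }, 0)
    keep <- runif(m) < exp(bias * (gc - 1))
    take <- which(keep)[seq_len(min(need, sum(keep)))]
    out_chrom <- c(out_chrom, names(sequences)[ci[take]])
    out_start <- c(out_start, st[take])
    need <- n_reads - length(out_start)
  }
  GenomicRanges::GRanges(out_chrom,
                         IRanges::IRanges(out_start, width = read_length))
}

# ---- annotation fixture -----------------------------------------------------

# Scenario templates for the peak-to-gene assignment rules. Each scenario
# occupies a 20 kb block; the expected assignment is written down from the
# construction itself, never by running the assigner.
annotation_scenarios <- function() {
  list(
    list(id = "clean", genes = list(
      list(gene_id = "G01", gene_name = "Alpha1", strand = "+",
           transcripts = list(list(tid = "G01.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2500,
                                   expr = 8)))),
      peak = c(9900, 10099),          # centre 10000, distance 0
      expect_bound = list(c("G01", "G01.t1", 0)),
      expect_peak = list(genes = "G01", bidirectional = FALSE)),
    list(id = "ranked_tsl", genes = list(
      list(gene_id = "G02", gene_name = "Beta2", strand = "+",
           transcripts = list(
             list(tid = "G02.t1", type = "protein_coding", tsl = 3,
                  tss_off = 10000, len = 3000, expr = 9),
             list(tid = "G02.t2", type = "protein_coding", tsl = 1,
                  tss_off = 10800, len = 2000, expr = 4)))),
      peak = c(9900, 10099),          # centre 10000; TSL1 wins at distance 800
      expect_bound = list(c("G02", "G02.t2", 800)),
      expect_peak = list(genes = "G02", bidirectional = FALSE)),
    list(id = "bidirectional", genes = list(
      list(gene_id = "G03", gene_name = "Gamma3", strand = "+",
           transcripts = list(list(tid = "G03.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 1800,
                                   expr = 5))),
      list(gene_id = "G04", gene_name = "Delta4", strand = "-",
           transcripts = list(list(tid = "G04.t1", type = "lincRNA",
                                   tsl = 2, tss_off = 9800, len = 1200,
                                   expr = 3)))),
      peak = c(9800, 9999),           # centre 9900; 100 bp to both TSSs
      expect_bound = list(c("G03", "G03.t1", 100), c("G04", "G04.t1", 100)),
      expect_peak = list(genes = c("G03", "G04"), bidirectional = TRUE)),
    list(id = "resolve_type", genes = list(
      list(gene_id = "G05", gene_name = "Eps5", strand = "+",
           transcripts = list(list(tid = "G05.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2200,
                                   expr = 6))),
      list(gene_id = "G06", gene_name = "Zeta6", strand = "+",
           transcripts = list(list(tid = "G06.t1", type = "lincRNA",
                                   tsl = 1, tss_off = 10300, len = 900,
                                   expr = 6)))),
      peak = c(10050, 10249),         # centre 10150; protein_coding wins
      expect_bound = list(c("G05", "G05.t1", 150)),
      expect_peak = list(genes = "G05", bidirectional = FALSE),
      expect_discard = list(genes = "G06", reason = "outranked_same_strand")),
    list(id = "resolve_tsl", genes = list(
      list(gene_id = "G07", gene_name = "Eta7", strand = "+",
           transcripts = list(list(tid = "G07.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2000,
                                   expr = 6))),
      list(gene_id = "G08", gene_name = "Theta8", strand = "+",
           transcripts = list(list(tid = "G08.t1", type = "protein_coding",
                                   tsl = 3, tss_off = 10300, len = 2000,
                                   expr = 6)))),
      peak = c(10050, 10249),
      expect_bound = list(c("G07", "G07.t1", 150)),
      expect_peak = list(genes = "G07", bidirectional = FALSE),
      expect_discard = list(genes = "G08", reason = "outranked_same_strand")),
    list(id = "resolve_name", genes = list(
      list(gene_id = "G09", gene_name = "Iota9", strand = "+",
           transcripts = list(list(tid = "G09.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2000,
                                   expr = 6))),
      list(gene_id = "G10", gene_name = NA, strand = "+",
           transcripts = list(list(tid = "G10.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10300, len = 2000,
                                   expr = 6)))),
      peak = c(10050, 10249),
      expect_bound = list(c("G09", "G09.t1", 150)),
      expect_peak = list(genes = "G09", bidirectional = FALSE),
      expect_discard = list(genes = "G10", reason = "outranked_same_strand")),
    list(id = "irresolvable", genes = list(
      list(gene_id = "G11", gene_name = "Kappa11", strand = "+",
           transcripts = list(list(tid = "G11.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2000,
                                   expr = 6))),
      list(gene_id = "G12", gene_name = "Lambda12", strand = "+",
           transcripts = list(list(tid = "G12.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10300, len = 2000,
                                   expr = 6)))),
      peak = c(10050, 10249),
      expect_bound = list(),
      expect_peak = NULL,
      expect_discard = list(genes = c("G11", "G12"),
                            reason = "ambiguous_same_strand")),
    list(id = "filtered_type", genes = list(
      list(gene_id = "G13", gene_name = "Mu13", strand = "+",
           transcripts = list(list(tid = "G13.t1", type = "miRNA",
                                   tsl = 1, tss_off = 10000, len = 80,
                                   expr = 6)))),
      peak = c(9900, 10099),
      expect_bound = list(), expect_peak = NULL),
    list(id = "not_expressed", genes = list(
      list(gene_id = "G14", gene_name = "Nu14", strand = "+",
           transcripts = list(list(tid = "G14.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2000,
                                   expr = 0)))),
      peak = c(9900, 10099),
      expect_bound = list(), expect_peak = NULL),
    list(id = "far_centre", genes = list(
      list(gene_id = "G15", gene_name = "Xi15", strand = "+",
           transcripts = list(list(tid = "G15.t1", type = "protein_coding",
                                   tsl = 1, tss_off = 10000, len = 2000,
                                   expr = 6)))),
      # window [8000, 10999] overlaps, but peak centre 12449 is >= 2 kb away
      peak = c(10900, 13999),
      expect_bound = list(), expect_peak = NULL)
  )
}

#' Simulate a transcript annotation with planted assignment scenarios
#'
#' Builds a compact annotation exercising every rule of the ranked TSS-window
#' peak-to-gene assignment: a clean single-transcript case, transcript choice
#' by support level, a bidirectional promoter pair, same-strand conflicts
#' resolved by type / support level / named-over-unnamed, an irresolvable
#' same-strand pair, a filtered transcript type, an unexpressed gene, and a
#' peak too far from the TSS. The expected assignment is constructed from the
#' scenario templates themselves.
#'
#' @param config A \code{\link{sim_config}} (only the seed is used; the
#'   annotation lives on its own chromosome \code{chrAnn}).
#' @return List with \code{annotation} (data.frame), \code{peaks} (GRanges,
#'   named), \code{genome} (named length vector), and \code{expected} — a
#'   list of data.frames \code{bound_genes}, \code{assigned_peaks},
#'   \code{discarded}.
#' @export
simulate_annotation <- function(config) {
  scen <- annotation_scenarios()
  block <- 20000L
  ann <- list(); peaks <- list(); bound <- list(); assigned <- list()
  disc <- list()
  for (i in seq_along(scen)) {
    s <- scen[[i]]
    off <- (i - 1L) * block
    for (g in s$genes) for (tr in g$transcripts) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = g$gene_id, gene_name = g$gene_name,
        transcript_id = tr$tid, transcript_type = tr$type,
        transcript_support_level = tr$tsl, chrom = "chrAnn",
        strand = g$strand, tss = off + tr$tss_off,
        length = tr$len, expression = tr$expr,
        stringsAsFactors = FALSE)
    }
    pid <- sprintf("peak_%02d", i)
    peaks[[pid]] <- c(off + s$peak[1], off + s$peak[2])
    for (b in s$expect_bound)
      bound[[length(bound) + 1L]] <- data.frame(
        gene_id = b[1], transcript_id = b[2], peak_id = pid,
        distance = as.numeric(b[3]), stringsAsFactors = FALSE)
    if (!is.null(s$expect_peak))
      assigned[[length(assigned) + 1L]] <- data.frame(
        peak_id = pid,
        gene_ids = paste(s$expect_peak$genes, collapse = ","),
        bidirectional = s$expect_peak$bidirectional,
        stringsAsFactors = FALSE)
    if (!is.null(s$expect_discard))
      disc[[length(disc) + 1L]] <- data.frame(
        peak_id = pid,
        gene_ids = paste(s$expect_discard$genes, collapse = ","),
        reason = s$expect_discard$reason, stringsAsFactors = FALSE)
  }
  pk <- GenomicRanges::GRanges("chrAnn", IRanges::IRanges(
    vapply(peaks, `[`, 0, 1), vapply(peaks, `[`, 0, 2)))
  names(pk) <- names(peaks)
  list(annotation = do.call(rbind, ann),
       peaks = peak_set(pk, genome_id = "simAnn"),
       genome = c(chrAnn = length(scen) * block),
       expected = list(bound_genes = do.call(rbind, bound),
                       assigned_peaks = do.call(rbind, assigned),
                       discarded = do.call(rbind, disc)))
}

# ---- single-cell accessibility ---------------------------------------------

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate single-cell accessibility counts and bulk mixtures
#'
#' Each cell type gets an intensity profile over peaks (a shared baseline
#' with type-specific marker peaks boosted). Per-cell counts are negative
#' binomial around the type profile; bulk samples are negative binomial
#' around Dirichlet-weighted sums of the type profiles. True mixing
#' proportions are returned.
#'
#' @param config A \code{\link{sim_config}}.
#' @param marker_boost Fold boost of a type's marker peaks over baseline.
#' @return List with \code{sc_counts} (peaks x cells), \code{cell_types}
#'   (label per cell), \code{bulk_counts} (peaks x bulk samples),
#'   \code{true_proportions} (bulk samples x types), \code{profiles}
#'   (peaks x types mean intensities).
#' @export
simulate_sc_accessibility <- function(config, marker_boost = 4) {
  stopifnot(config$k_cell_types >= 2)
  set.seed(substream_seed(config$seed, "sc_accessibility"))
  k <- config$k_cell_types
  np <- config$n_peaks_atac
  types <- paste0("type", seq_len(k))
  base <- rgamma(np, shape = 2, rate = 0.5) + 0.5
  marker_of <- sample(k, np, replace = TRUE)
  profiles <- matrix(base, np, k)
  for (t in seq_len(k))
    profiles[marker_of == t, t] <- profiles[marker_of == t, t] * marker_boost
  dimnames(profiles) <- list(sprintf("peak%04d", seq_len(np)), types)

  nc <- config$n_cells_per_type
  cell_types <- rep(types, each = nc)
  sc <- matrix(0L, np, k * nc,
               dimnames = list(rownames(profiles),
                               sprintf("cell%04d", seq_len(k * nc))))
  for (j in seq_len(k * nc)) {
    t <- match(cell_types[j], types)
    sc[, j] <- rnbinom(np, mu = profiles[, t], size = config$nb_dispersion)
  }
  props <- rdirichlet(config$n_bulk, rep(config$dirichlet_alpha, k))
  dimnames(props) <- list(sprintf("bulk%02d", seq_len(config$n_bulk)), types)
  bulk_mu <- profiles %*% t(props) * nc   # depth comparable to a pseudobulk
  bulk <- matrix(rnbinom(length(bulk_mu), mu = bulk_mu, size = 50),
                 np, config$n_bulk,
                 dimnames = list(rownames(profiles), rownames(props)))
  list(sc_counts = sc, cell_types = cell_types, bulk_counts = bulk,
       true_proportions = props, profiles = profiles)
}

#' Write a complete synthetic fixture directory
#'
#' Emits genome FASTA, chromosome sizes, the three antibody peak sets
#' (narrowPeak), annotation and expression tables (TSV), and the
#' accessibility matrices (TSV), all generated from one config.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_fixture_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  ab <- simulate_antibody_peaksets(config)
  genome <- plant_motifs(genome, ab$a_sites, example_pwm("A"),
                         seed = substream_seed(config$seed, "plant_a"))
  genome <- plant_motifs(genome, ab$b_sites, example_pwm("B"),
                         seed = substream_seed(config$seed, "plant_b"))
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_genome_table(config$genome, file.path(dir, "genome.sizes"))
  for (nm in c("clean_a", "dirty_a", "b"))
    write_bed(ab[[nm]], file.path(dir, paste0(nm, ".narrowPeak")),
              dialect = "narrowPeak")
  annfix <- simulate_annotation(config)
  write.table(annfix$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(annfix$peaks, file.path(dir, "annotation_peaks.bed"),
            dialect = "bed6")
  scfix <- simulate_sc_accessibility(config)
  write.table(scfix$sc_counts, file.path(dir, "sc_counts.tsv"),
              sep = "\t", quote = FALSE)
  write.table(scfix$bulk_counts, file.path(dir, "bulk_counts.tsv"),
              sep = "\t", quote = FALSE)
  write.table(data.frame(cell = colnames(scfix$sc_counts),
                         cell_type = scfix$cell_types),
              file.path(dir, "cell_types.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
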