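.checkCount <- function(x, nm) {
  if (length(x) != 1L || is.na(x) || x < 1)
    stop("configuration error: ", nm, " must be a positive count")
}

# deterministic allocation: floor(fraction * n), remainders in config order
.allocateLabels <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("configuration error: fractions must sum to 1")
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
  rep(names(fractions), base)
}

.randomPeptide <- function(n, len = 10L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

#' Configuration for the growth-phase proteome simulator
#'
#' Defines the study conditions emulated by [simulateProteomeExperiment()]:
#' a TMT-style experiment with total-proteome and OOPS extractions over
#' three growth phases, four replicates in lag and three each in exponential
#' and stationary phase per extraction.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein mean of the peptide-count distribution; counts
#'   are drawn as `1 + Poisson(mean - 1)`, capped at 30.
#' @param phases ordered growth-phase labels.
#' @param replicates_per_phase replicates per phase within each extraction.
#' @param class_fractions proportions of dynamics classes i / ii / iii
#'   (must sum to 1); allocated deterministically as `floor(fraction * n)`
#'   with remainders assigned in order.
#' @param effect_size log2 fold-change magnitude of true phase effects,
#'   applied at the stationary phase with random sign.
#' @param sigma0 baseline peptide-level noise SD (log2 units).
#' @param variance_count_slope strength of the peptide-count dependence of
#'   the noise: SD is `sigma0 * (1 + slope / peptide_count)`.
#' @param missing_rate completely-at-random missingness probability per cell.
#' @param seed RNG seed.
#' @return A validated list of class `"ProteomeSimConfig"`.
#' @export
proteomeSimConfig <- function(n_proteins = 1000L, peptides_per_protein = 4,
                              phases = c("lag", "exponential", "stationary"),
                              replicates_per_phase = c(4L, 3L, 3L),
                              class_fractions = c(i = 0.5, ii = 0.3,
                                                  iii = 0.2),
                              effect_size = 2, sigma0 = 0.25,
                              variance_count_slope = 1,
                              missing_rate = 0.05, seed = 1L) {
  .checkCount(n_proteins, "n_proteins")
  if (peptides_per_protein < 1)
    stop("configuration error: peptides_per_protein must be >= 1")
  if (any(replicates_per_phase < 1))
    stop("configuration error: replicates_per_phase must be >= 1")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("configuration error: class_fractions must sum to 1")
  if (sigma0 <= 0) stop("configuration error: sigma0 must be > 0")
  if (effect_size < 0) stop("configuration error: effect_size must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("configuration error: missing_rate must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = peptides_per_protein,
                 phases = phases,
                 replicates_per_phase = as.integer(replicates_per_phase),
                 class_fractions = class_fractions,
                 effect_size = effect_size, sigma0 = sigma0,
                 variance_count_slope = variance_count_slope,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "ProteomeSimConfig")
}

#' Simulate a growth-phase proteomics experiment with known ground truth
#'
#' Generates peptide-level log2-intensity matrices for a total-proteome and
#' an OOPS extraction over the configured growth phases.  Each protein draws
#' a baseline log2 abundance; class-ii proteins receive a phase effect in
#' both extractions (RNA binding tracks abundance), class-iii proteins in
#' the OOPS extraction only (abundance-independent binding change), class-i
#' proteins in neither.  Peptide values are the protein value plus a
#' peptide-specific offset plus Gaussian noise whose SD decreases with the
#' protein's peptide count; cells are then masked completely at random.
#'
#' @param config a [proteomeSimConfig()].
#' @return List with [PeptideQuant-class] elements `total` and `oops`, and
#'   `truth`, a data.frame with `protein`, `true_class` and `true_effect`.
#' @export
simulateProteomeExperiment <- function(config = proteomeSimConfig()) {
  stopifnot(inherits(config, "ProteomeSimConfig"))
  set.seed(config$seed)
  np <- config$n_proteins
  prot <- sprintf("P%04d", seq_len(np))
  cls <- .allocateLabels(np, config$class_fractions)
  phase <- rep(config$phases, config$replicates_per_phase)
  ns <- length(phase)
  baseline <- rnorm(np, mean = 20, sd = 2)
  sign_eff <- sample(c(-1, 1), np, replace = TRUE)
  eff <- config$effect_size * sign_eff
  # phase effect profile: shift at the stationary phase
  shift <- as.numeric(phase == "stationary")
  pep_n <- pmin(1L + rpois(np, max(config$peptides_per_protein - 1, 0)), 30L)
  total_shift <- outer(eff * (cls == "ii"), shift)
  oops_shift <- outer(eff * (cls %in% c("ii", "iii")), shift)

  makeMatrix <- function(protein_vals) {
    rows <- rep(seq_len(np), pep_n)
    pep_offset <- rnorm(sum(pep_n), 0, 1)
    sdv <- config$sigma0 * (1 + config$variance_count_slope / pep_n[rows])
    m <- protein_vals[rows, , drop = FALSE] + pep_offset +
      matrix(rnorm(length(rows) * ns, 0, sdv), length(rows), ns)
    if (config$missing_rate > 0)
      m[matrix(runif(length(m)) < config$missing_rate, nrow(m))] <- NA
    colnames(m) <- paste0("s", seq_len(ns))
    list(m = m, rows = rows)
  }
  tot <- makeMatrix(baseline + total_shift)
  oop <- makeMatrix(baseline + oops_shift)
  seqs <- .randomPeptide(sum(pep_n))
  meta <- function(type) data.frame(
    phase = phase, type = type,
    replicate = unlist(lapply(config$replicates_per_phase, seq_len)),
    treatment = "none", stringsAsFactors = FALSE)
  mk <- function(x, type) {
    colnames(x$m) <- paste0(type, "_", phase, "_",
                            unlist(lapply(config$replicates_per_phase,
                                          seq_len)))
    PeptideQuant(x$m, sequence = seqs[seq_along(x$rows)],
                 proteins = prot[x$rows], sampleData = meta(type))
  }
  list(total = mk(tot, "total"), oops = mk(oop, "oops"),
       truth = data.frame(protein = prot, true_class = cls,
                          true_effect = eff * (cls != "i"),
                          peptide_count = pep_n,
                          stringsAsFactors = FALSE))
}

#' Configuration for the RNase-sensitivity assay simulator
#'
#' @param n_proteins number of simulated proteins (spike-in added on top).
#' @param frac_rbp proportion of true RBPs, allocated deterministically.
#' @param depletion_effect mean log2 depletion of true RBPs upon RNase
#'   treatment.
#' @param n_replicates treated/untreated sample pairs.
#' @param spike_id accession of the spike-in protein (zero true effect).
#' @param peptides_per_protein,sigma0,variance_count_slope,missing_rate as in
#'   [proteomeSimConfig()].
#' @param sample_offset_sd SD of the per-sample global offsets injected so
#'   spike-in normalisation is exercised.
#' @param seed RNG seed.
#' @return A validated list of class `"RnaseSimConfig"`.
#' @export
rnaseSimConfig <- function(n_proteins = 500L, frac_rbp = 0.2,
                           depletion_effect = 2, n_replicates = 3L,
                           spike_id = "P00761",
                           peptides_per_protein = 4, sigma0 = 0.3,
                           variance_count_slope = 1, missing_rate = 0.02,
                           sample_offset_sd = 0.5, seed = 1L) {
  .checkCount(n_proteins, "n_proteins")
  .checkCount(n_replicates, "n_replicates")
  if (frac_rbp < 0 || frac_rbp > 1)
    stop("configuration error: frac_rbp must be in [0, 1]")
  if (depletion_effect < 0)
    stop("configuration error: depletion_effect must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins), frac_rbp = frac_rbp,
                 depletion_effect = depletion_effect,
                 n_replicates = as.integer(n_replicates),
                 spike_id = spike_id,
                 peptides_per_protein = peptides_per_protein,
                 sigma0 = sigma0,
                 variance_count_slope = variance_count_slope,
                 missing_rate = missing_rate,
                 sample_offset_sd = sample_offset_sd,
                 seed = as.integer(seed)),
            class = "RnaseSimConfig")
}

#' Simulate an RNase-sensitivity assay with known ground truth
#'
#' True RBPs receive a mean log2 depletion of `depletion_effect` in the
#' treated samples; the spike-in protein has zero true effect and is present
#' in every sample (never masked).  Per-sample global offsets are injected
#' into both conditions so that spike-in normalisation has something to
#' remove.
#'
#' @param config an [rnaseSimConfig()].
#' @return List with [PeptideQuant-class] elements `treated` and
#'   `untreated`, a `pairing` data.frame, and `truth` with `protein`,
#'   `true_class` (`"RBP"` / `"non-RBP"`) and `true_effect`.
#' @export
simulateRnaseAssay <- function(config = rnaseSimConfig()) {
  stopifnot(inherits(config, "RnaseSimConfig"))
  set.seed(config$seed)
  np <- config$n_proteins
  prot <- sprintf("R%04d", seq_len(np))
  labels <- .allocateLabels(np, c(RBP = config$frac_rbp,
                                  `non-RBP` = 1 - config$frac_rbp))
  nr <- config$n_replicates
  baseline <- rnorm(np, 20, 2)
  effect <- -config$depletion_effect * (labels == "RBP")
  pep_n <- pmin(1L + rpois(np, max(config$peptides_per_protein - 1, 0)), 30L)
  off_t <- rnorm(nr, 0, config$sample_offset_sd)
  off_u <- rnorm(nr, 0, config$sample_offset_sd)

  rows <- rep(seq_len(np), pep_n)
  # the same peptides are observed in both conditions: shared offsets
  pep_offset <- rnorm(sum(pep_n), 0, 1)
  makeMatrix <- function(protein_vals, offsets) {
    sdv <- config$sigma0 * (1 + config$variance_count_slope / pep_n[rows])
    m <- protein_vals[rows] + pep_offset +
      matrix(rnorm(length(rows) * nr, 0, sdv), length(rows), nr)
    m <- sweep(m, 2, offsets, "+")
    if (config$missing_rate > 0)
      m[matrix(runif(length(m)) < config$missing_rate, nrow(m))] <- NA
    list(m = m, rows = rows)
  }
  tr <- makeMatrix(baseline + effect, off_t)
  un <- makeMatrix(baseline, off_u)
  # spike-in: constant input, two peptides, never masked
  spike_base <- 22
  addSpike <- function(x, offsets) {
    sp <- matrix(spike_base + rnorm(2 * nr, 0, 0.01), 2, nr) +
      matrix(offsets, 2, nr, byrow = TRUE)
    x$m <- rbind(x$m, sp)
    x$rows <- c(x$rows, NA, NA)
    x
  }
  tr <- addSpike(tr, off_t)
  un <- addSpike(un, off_u)
  seqs <- c(.randomPeptide(sum(pep_n)), "SPIKEPEPA", "SPIKEPEPB")
  accs <- c(prot[tr$rows[seq_len(sum(pep_n))]], config$spike_id,
            config$spike_id)
  meta <- function(treatment, pref) data.frame(
    phase = "interphase", type = "oops", replicate = seq_len(nr),
    treatment = treatment, stringsAsFactors = FALSE)
  mk <- function(x, treatment, pref) {
    colnames(x$m) <- paste0(pref, seq_len(nr))
    PeptideQuant(x$m, sequence = seqs, proteins = accs,
                 sampleData = meta(treatment, pref))
  }
  list(treated = mk(tr, "rnase", "T"),
       untreated = mk(un, "control", "U"),
       pairing = data.frame(treated = paste0("T", seq_len(nr)),
                            untreated = paste0("U", seq_len(nr)),
                            stringsAsFactors = FALSE),
       truth = data.frame(protein = prot, true_class = labels,
                          true_effect = effect, peptide_count = pep_n,
                          stringsAsFactors = FALSE))
}

#' Configuration for the iCLIP simulator
#'
#' @param genome_length genome size in bp (single chromosome `"chr"`).
#' @param biotype_layout `GRanges` with a `biotype` column tiling part of
#'   the genome (non-overlapping); default: a small layout of CDS, tRNA,
#'   rRNA and ncRNA features.
#' @param n_true_targets number of planted binding targets.
#' @param target_width width (bp) of each planted target.
#' @param n_cl_replicates cross-linked replicates (default 3).
#' @param n_control_samples non-cross-linked controls (default 1).
#' @param signal_rate,background_rate expected cross-links per bp inside
#'   targets (CL samples) and elsewhere.
#' @param peak_threshold minimum summed cross-link count for an emitted peak.
#' @param peak_gap maximum gap (bp of zero-count positions) bridged when
#'   merging cross-linked positions into a peak.
#' @param seed RNG seed.
#' @return A validated list of class `"IclipSimConfig"`.
#' @export
iclipSimConfig <- function(genome_length = 100000L, biotype_layout = NULL,
                           n_true_targets = 20L, target_width = 100L,
                           n_cl_replicates = 3L, n_control_samples = 1L,
                           signal_rate = 0.5, background_rate = 0.001,
                           peak_threshold = 5, peak_gap = 20L, seed = 1L) {
  .checkCount(genome_length, "genome_length")
  .checkCount(n_true_targets, "n_true_targets")
  .checkCount(n_cl_replicates, "n_cl_replicates")
  if (!(signal_rate >= background_rate && background_rate >= 0))
    stop("configuration error: need signal_rate >= background_rate >= 0")
  if (is.null(biotype_layout)) {
    step <- genome_length %/% 10
    biotype_layout <- GenomicRanges::GRanges("chr", IRanges::IRanges(
      start = c(1, 2 * step + 1, 4 * step + 1, 6 * step + 1),
      end = c(2 * step, 3 * step, 5 * step, 7 * step)))
    biotype_layout$biotype <- c("CDS", "tRNA", "rRNA", "ncRNA")
  }
  if (max(GenomicRanges::end(biotype_layout)) > genome_length)
    stop("configuration error: biotype interval outside the genome")
  red <- GenomicRanges::reduce(biotype_layout, ignore.strand = TRUE)
  if (sum(GenomicRanges::width(red)) <
      sum(GenomicRanges::width(biotype_layout)))
    stop("configuration error: overlapping biotype intervals")
  structure(list(genome_length = as.integer(genome_length),
                 biotype_layout = biotype_layout,
                 n_true_targets = as.integer(n_true_targets),
                 target_width = as.integer(target_width),
                 n_cl_replicates = as.integer(n_cl_replicates),
                 n_control_samples = as.integer(n_control_samples),
                 signal_rate = signal_rate,
                 background_rate = background_rate,
                 peak_threshold = peak_threshold,
                 peak_gap = as.integer(peak_gap),
                 seed = as.integer(seed)),
            class = "IclipSimConfig")
}

.emitPeaks <- function(counts, threshold, gap, sample_name) {
  pos <- which(counts > 0)
  if (!length(pos)) return(GenomicRanges::GRanges(score = numeric(),
                                                  name = character()))
  brk <- c(0, which(diff(pos) > gap), length(pos))
  runs <- lapply(seq_len(length(brk) - 1), function(i)
    pos[(brk[i] + 1):brk[i + 1]])
  score <- vapply(runs, function(r) sum(counts[r]), 0)
  keep <- score > threshold
  runs <- runs[keep]; score <- score[keep]
  if (!length(runs)) return(GenomicRanges::GRanges(score = numeric(),
                                                   name = character()))
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = vapply(runs, min, 0), end = vapply(runs, max, 0)),
    strand = "+")
  gr$name <- paste0(sample_name, "_peak", seq_along(gr))
  gr$score <- score
  gr
}

#' Simulate iCLIP cross-link tracks and peaks with known ground truth
#'
#' Per-position cross-link counts are Poisson: `background_rate` everywhere,
#' raised to `signal_rate` inside the planted target intervals of the
#' cross-linked (CL) replicates; control samples see background only.
#' Peaks per sample are positions with at least one cross-link merged across
#' gaps of up to `peak_gap` bp, kept when their summed count exceeds
#' `peak_threshold`, scored by the summed count.
#'
#' @param config an [iclipSimConfig()].
#' @return List with `cl_tracks` / `control_tracks` (lists of width-1
#'   `GRanges` with `count`), `cl_peaks` / `control_peaks` (lists of peak
#'   `GRanges`), `targets` (the planted intervals) and the `annotation`
#'   layout.
#' @export
simulateIclip <- function(config = iclipSimConfig()) {
  stopifnot(inherits(config, "IclipSimConfig"))
  set.seed(config$seed)
  G <- config$genome_length
  w <- config$target_width
  # non-overlapping target placement on a grid
  n_slots <- G %/% (2 * w)
  if (config$n_true_targets > n_slots)
    stop("configuration error: too many targets for the genome")
  slots <- sort(sample.int(n_slots, config$n_true_targets))
  starts <- (slots - 1) * 2 * w + 1
  targets <- GenomicRanges::GRanges("chr",
                                    IRanges::IRanges(starts, width = w),
                                    strand = "+")
  targets$name <- paste0("target", seq_along(targets))
  targets$score <- 0
  in_target <- rep(FALSE, G)
  for (i in seq_along(starts)) in_target[starts[i]:(starts[i] + w - 1)] <- TRUE
  rate_cl <- ifelse(in_target, config$signal_rate, config$background_rate)

  track <- function(counts) {
    pos <- which(counts > 0)
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(pos, width = 1),
                                 strand = "+")
    gr$count <- counts[pos]
    gr
  }
  cl_counts <- lapply(seq_len(config$n_cl_replicates), function(i)
    rpois(G, rate_cl))
  nc_counts <- lapply(seq_len(config$n_control_samples), function(i)
    rpois(G, config$background_rate))
  list(cl_tracks = lapply(cl_counts, track),
       control_tracks = lapply(nc_counts, track),
       cl_peaks = lapply(seq_along(cl_counts), function(i)
         .emitPeaks(cl_counts[[i]], config$peak_threshold, config$peak_gap,
                    paste0("CL", i))),
       control_peaks = lapply(seq_along(nc_counts), function(i)
         .emitPeaks(nc_counts[[i]], config$peak_threshold, config$peak_gap,
                    paste0("NC", i))),
       targets = targets,
       annotation = config$biotype_layout)
}
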