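#' Derive cross-link sites from aligned reads
#'
#' In iCLIP, the reverse transcriptase truncates at the cross-linked
#' nucleotide, so the cross-link site is the base immediately 5' of the read:
#' for a plus-strand alignment starting at 0-based position `s`, the site is
#' `s - 1`; for a minus-strand alignment over the half-open interval
#' `[s, e)`, the mirrored convention places the site at `e` (the pre-start
#' base in read orientation).  Sites falling before the chromosome start are
#' dropped and the number of drops reported.
#'
#' @param reads a `GRanges` of stranded alignments.
#' @return A `GRanges` of width-1 sites with a `count` metadata column, one
#'   row per distinct (chrom, site, strand).
#' @export
crosslinkSites <- function(reads) {
  strand <- as.character(GenomicRanges::strand(reads))
  if (any(strand == "*")) stop("unstranded alignment record")
  pos1 <- ifelse(strand == "+",
                 GenomicRanges::start(reads) - 1L,   # 0-based start - 1
                 GenomicRanges::end(reads) + 1L)     # 0-based end (mirror)
  keep <- pos1 >= 1L
  dropped <- sum(!keep)
  if (dropped) message(dropped, " site(s) before chromosome start dropped")
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    gr$count <- integer()
    return(gr)
  }
  key <- paste(GenomicRanges::seqnames(reads)[keep], pos1[keep],
               strand[keep], sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  gr <- GenomicRanges::GRanges(parts[, 1],
                               IRanges::IRanges(as.integer(parts[, 2]),
                                                width = 1L),
                               strand = parts[, 3])
  gr$count <- as.integer(tab)
  sort(gr)
}

#' Blacklist peaks overlapping negative-control peaks
#'
#' Removes every peak that overlaps any control peak by at least one base,
#' strand-insensitively by default (mirroring `bedtools intersect -v` without
#' a strand flag).  Input order is preserved.
#'
#' @param peaks,control_peaks `GRanges` of peaks.
#' @param ignore_strand overlap regardless of strand (default TRUE).
#' @return The retained subset of `peaks`.
#' @export
blacklistPeaks <- function(peaks, control_peaks, ignore_strand = TRUE) {
  if (length(control_peaks) == 0L) return(peaks)
  hit <- GenomicRanges::countOverlaps(peaks, control_peaks, minoverlap = 1L,
                                      ignore.strand = ignore_strand) > 0L
  peaks[!hit]
}

#' Intersect peaks across replicates with reciprocal overlap
#'
#' A peak of the anchor replicate is retained when every other replicate
#' contains a peak overlapping it by at least `min_fraction` of *both*
#' intervals (the `bedtools intersect -f 0.1 -r` semantics).  When several
#' peaks of a replicate qualify, the one with the largest overlap is taken as
#' the match.  Strand is ignored by default.
#'
#' @param peak_lists list of >= 2 `GRanges`, one per replicate.
#' @param min_fraction minimum overlap fraction of each interval.
#' @param reciprocal require the fraction on both intervals (default TRUE);
#'   when FALSE only the anchor-interval fraction is required.
#' @param anchor index of the replicate whose peaks define the consensus
#'   coordinates.
#' @param ignore_strand overlap regardless of strand.
#' @return List with `consensus` (the retained anchor peaks) and `matches`,
#'   a list (one element per consensus peak) of the matched peak per
#'   replicate (including the anchor itself).
#' @export
intersectReplicates <- function(peak_lists, min_fraction = 0.1,
                                reciprocal = TRUE, anchor = 1L,
                                ignore_strand = TRUE) {
  if (length(peak_lists) < 2L) stop("need at least two replicates")
  anchor_peaks <- peak_lists[[anchor]]
  others <- setdiff(seq_along(peak_lists), anchor)
  match_tbl <- vector("list", length(peak_lists))
  keep <- rep(TRUE, length(anchor_peaks))
  for (j in others) {
    rep_peaks <- peak_lists[[j]]
    ov <- GenomicRanges::findOverlaps(anchor_peaks, rep_peaks,
                                      ignore.strand = ignore_strand)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    inter <- GenomicRanges::pintersect(anchor_peaks[qh], rep_peaks[sh],
                                       ignore.strand = ignore_strand)
    w <- GenomicRanges::width(inter)
    ok <- w >= min_fraction * GenomicRanges::width(anchor_peaks[qh])
    if (reciprocal)
      ok <- ok & (w >= min_fraction * GenomicRanges::width(rep_peaks[sh]))
    qh <- qh[ok]; sh <- sh[ok]; w <- w[ok]
    best <- rep(NA_integer_, length(anchor_peaks))
    if (length(qh)) {
      o <- order(qh, -w, sh)
      first <- !duplicated(qh[o])
      best[qh[o][first]] <- sh[o][first]
    }
    keep <- keep & !is.na(best)
    match_tbl[[j]] <- best
  }
  match_tbl[[anchor]] <- seq_along(anchor_peaks)
  idx <- which(keep)
  matches <- lapply(idx, function(i)
    lapply(seq_along(peak_lists), function(j)
      peak_lists[[j]][match_tbl[[j]][i]]))
  list(consensus = anchor_peaks[idx], matches = matches)
}

#' Summarise consensus peaks across replicates
#'
#' For each consensus peak, the median of the matched peaks' scores and the
#' median of their sizes (bp) across replicates; even-count medians are the
#' midpoint of the middle two values.
#'
#' @param intersected output of [intersectReplicates()].
#' @return data.frame with `chrom`, `start` (0-based), `end`, `name`,
#'   `median_score`, `median_size`, `n_replicates`.
#' @export
summarizePeaks <- function(intersected) {
  cons <- intersected$consensus
  ms <- vapply(intersected$matches, function(mm)
    median(vapply(mm, function(g) g$score, 0)), 0)
  sz <- vapply(intersected$matches, function(mm)
    median(vapply(mm, function(g) as.numeric(GenomicRanges::width(g)), 0)),
    0)
  data.frame(chrom = as.character(GenomicRanges::seqnames(cons)),
             start = GenomicRanges::start(cons) - 1L,
             end = GenomicRanges::end(cons),
             name = if (!is.null(cons$name)) cons$name else
               paste0("peak", seq_along(cons)),
             median_score = ms, median_size = sz,
             n_replicates = lengths(intersected$matches),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call binding targets from peak summaries
#'
#' A consensus peak is a target when `log2(median_score)` strictly exceeds
#' `log2_score_min` and `log2(median_size)` strictly exceeds
#' `log2_size_min`.  Peaks with non-positive score are excluded with a
#' warning.
#'
#' @param summaries data.frame from [summarizePeaks()].
#' @param log2_score_min,log2_size_min thresholds on the log2 scale
#'   (defaults 5 and 2).
#' @return The subset of `summaries` passing both thresholds, with a
#'   `target` logical column added to the full table as attribute-free
#'   convenience; the returned rows are the targets.
#' @export
callTargets <- function(summaries, log2_score_min = 5, log2_size_min = 2) {
  bad <- summaries$median_score <= 0
  if (any(bad)) {
    warning(sum(bad), " peak(s) with non-positive score excluded")
    summaries <- summaries[!bad, , drop = FALSE]
  }
  pass <- log2(summaries$median_score) > log2_score_min &
    log2(summaries$median_size) > log2_size_min
  summaries[pass, , drop = FALSE]
}

#' Cross-link density per biotype, normalised by genomic space
#'
#' Assigns each cross-link site (or peak midpoint) to a biotype by position
#' containment, with ties resolved by a priority order, and divides the
#' summed counts per biotype by the biotype's total genomic space (bp, after
#' merging overlapping intervals).  Positions covered by no annotation fall
#' in an `"unannotated"` bucket whose space is the remaining genome.  An
#' optional `remap` (e.g. `c(tRNA = "intergenic", rRNA = "intergenic")`) is
#' applied only to the reported labels, after normalisation.
#'
#' @param sites `GRanges` with a `count` column (absent = 1 per row).
#' @param annotation `GRanges` with a `biotype` metadata column.
#' @param priority biotype order used when a position is covered by several
#'   biotypes; default: order of first appearance in `annotation`.
#' @param genome_size total genome length (bp) for the unannotated bucket;
#'   when NA that bucket's density is reported as NA.
#' @param remap optional named character vector relabelling biotypes at
#'   report time (densities are summed over merged labels' counts and
#'   spaces).
#' @return data.frame with `biotype`, `count`, `space_bp`, `density`.
#' @export
biotypeDensity <- function(sites, annotation, priority = NULL,
                           genome_size = NA, remap = NULL) {
  if (length(annotation) == 0L) stop("empty annotation")
  if (is.null(annotation$biotype)) stop("annotation needs a 'biotype' column")
  if (is.null(priority)) priority <- unique(annotation$biotype)
  cnt <- if (!is.null(sites$count)) sites$count else rep(1L, length(sites))
  ov <- GenomicRanges::findOverlaps(sites, annotation, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  bt <- annotation$biotype[S4Vectors::subjectHits(ov)]
  pr <- match(bt, priority)
  assigned <- rep("unannotated", length(sites))
  if (length(qh)) {
    o <- order(qh, pr)
    first <- !duplicated(qh[o])
    assigned[qh[o][first]] <- bt[o][first]
  }
  space <- vapply(priority, function(b) {
    sum(GenomicRanges::width(GenomicRanges::reduce(
      annotation[annotation$biotype == b], ignore.strand = TRUE)))
  }, 0)
  all_space <- sum(GenomicRanges::width(GenomicRanges::reduce(
    annotation, ignore.strand = TRUE)))
  space <- c(space, unannotated = if (is.na(genome_size)) NA_real_ else
    genome_size - all_space)
  counts <- vapply(names(space), function(b) sum(cnt[assigned == b]), 0)
  out <- data.frame(biotype = names(space), count = counts,
                    space_bp = as.numeric(space),
                    density = counts / as.numeric(space),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (is.na(genome_size) && counts[["unannotated"]] == 0)
    out <- out[out$biotype != "unannotated", , drop = FALSE]
  if (!is.null(remap)) {
    lab <- out$biotype
    hit <- lab %in% names(remap)
    lab[hit] <- remap[lab[hit]]
    agg_c <- tapply(out$count, lab, sum)
    agg_s <- tapply(out$space_bp, lab, sum)
    out <- data.frame(biotype = names(agg_c), count = as.numeric(agg_c),
                      space_bp = as.numeric(agg_s),
                      density = as.numeric(agg_c) / as.numeric(agg_s),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
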