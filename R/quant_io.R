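#' Read a peptide quantification table with its sample metadata
#'
#' The quantification table is tab-separated with header: column 1 the peptide
#' sequence, column 2 the semicolon-separated candidate protein accessions,
#' then one numeric column per sample (log2 intensity, empty or NA for
#' missing).  The metadata table is tab-separated with a `sample` column plus
#' annotation columns (`phase`, `type`, `replicate`, `treatment`, ...); every
#' sample column of the quantification table must appear in it.  Unknown
#' metadata columns are carried along unchanged.
#'
#' @param path path to the quantification table.
#' @param metadata_path path to the sample metadata table.
#' @return A [PeptideQuant-class] object.
#' @export
readPeptideTable <- function(path, metadata_path) {
  if (!file.exists(path)) stop("quantification table not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata table not found: ", metadata_path)
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("expected sequence, proteins and at least one sample column")
  meta <- read.table(metadata_path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(meta))
    stop("metadata must contain a 'sample' column")
  samples <- colnames(tab)[-(1:2)]
  missing_meta <- setdiff(samples, meta$sample)
  if (length(missing_meta))
    stop("metadata lacks sample(s): ", paste(missing_meta, collapse = ", "))
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!is.na(vals) & is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric intensity at row %d, sample '%s'",
                   bad[1, 1], samples[bad[1, 2]]))
    vals <- matrix(as.numeric(vals), nrow(vals),
                   dimnames = dimnames(vals))
  }
  meta <- meta[match(samples, meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample
  PeptideQuant(vals, sequence = tab[[1]], proteins = tab[[2]],
               sampleData = meta[, setdiff(colnames(meta), "sample"),
                                 drop = FALSE])
}

#' Write a peptide or protein quantification table with metadata sidecar
#'
#' Inverse of [readPeptideTable()]; values are written in full double
#' precision so a round-trip is lossless to ~1e-15 relative error.
#'
#' @param x a [PeptideQuant-class] or [ProteinQuant-class] object.
#' @param path output path for the quantification table.
#' @param metadata_path output path for the sample metadata.
#' @return Invisibly, `path`.
#' @export
writeQuantTable <- function(x, path, metadata_path) {
  m <- quantMatrix(x)
  if (methods::is(x, "PeptideQuant")) {
    rd <- SummarizedExperiment::rowData(x)
    out <- data.frame(sequence = rd$sequence, proteins = rd$proteins,
                      check.names = FALSE)
  } else {
    out <- data.frame(protein = rownames(m),
                      peptide_count = peptideCount(x), check.names = FALSE)
  }
  vals <- as.data.frame(m, check.names = FALSE)
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  vals[is.na(m)] <- NA_character_
  out <- cbind(out, vals)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  meta <- cbind(sample = colnames(m), sampleInfo(x))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Assign peptides to master proteins by parsimony
#'
#' Peptides whose candidate set intersects `contaminants` are flagged and
#' mapped to the sentinel group `"CONTAMINANT"` (accessions listed in
#' `keep` are exempt, e.g. a spike-in protein retained for normalisation).
#' The remaining peptides are assigned by greedy set cover: proteins are
#' ranked by the number of still-unexplained peptides they cover, ties broken
#' by accession lexicographic order, and shared peptides go to the first
#' covering protein (razor rule).  The result is deterministic and
#' independent of input row order.
#'
#' @param peptides a [PeptideQuant-class] object.
#' @param contaminants character vector of contaminant accessions.
#' @param keep accessions exempt from the contaminant filter.
#' @return data.frame with columns `sequence`, `master` and logical
#'   `contaminant`, one row per input peptide row.
#' @export
assignMasterProteins <- function(peptides, contaminants = character(),
                                 keep = character()) {
  rd <- SummarizedExperiment::rowData(peptides)
  cand <- strsplit(rd$proteins, ";", fixed = TRUE)
  if (any(lengths(cand) == 0L)) stop("empty candidate list")
  contam_set <- setdiff(contaminants, keep)
  is_contam <- vapply(cand, function(p) any(p %in% contam_set), logical(1))
  master <- rep(NA_character_, length(cand))
  master[is_contam] <- "CONTAMINANT"
  idx <- which(!is_contam)
  # greedy cover over the non-contaminant peptides, order-independent
  remaining <- idx
  while (length(remaining)) {
    tab <- sort(table(unlist(cand[remaining])), decreasing = TRUE)
    best_n <- tab[1]
    best <- sort(names(tab)[tab == best_n])[1]
    covered <- remaining[vapply(cand[remaining],
                                function(p) best %in% p, logical(1))]
    master[covered] <- best
    remaining <- setdiff(remaining, covered)
  }
  data.frame(sequence = rd$sequence, master = master,
             contaminant = is_contam, stringsAsFactors = FALSE)
}

#' Aggregate modified peptides sharing a sequence
#'
#' Rows with the same peptide sequence (e.g. differing only by modification)
#' are merged by summing their linear-scale intensities per sample: values
#' are exponentiated from log2, summed over observed entries, and re-logged.
#' A cell missing in every merged row stays missing.  Candidate protein
#' lists are unioned.
#'
#' @param peptides a [PeptideQuant-class] object on the log2 scale.
#' @return A [PeptideQuant-class] with one row per distinct sequence.
#' @export
aggregateModifiedPeptides <- function(peptides) {
  rd <- SummarizedExperiment::rowData(peptides)
  m <- quantMatrix(peptides)
  f <- factor(rd$sequence, levels = unique(rd$sequence))
  lin <- 2^m
  lin[is.na(lin)] <- 0
  summed <- rowsum(lin, f)
  nobs <- rowsum((!is.na(m)) + 0, f)
  out <- log2(summed)
  out[nobs == 0] <- NA
  prot <- vapply(split(rd$proteins, f), function(p)
    paste(sort(unique(unlist(strsplit(p, ";", fixed = TRUE)))),
          collapse = ";"), character(1))
  PeptideQuant(out, sequence = levels(f), proteins = prot,
               sampleData = SummarizedExperiment::colData(peptides))
}

#' Read / write BED6 interval files
#'
#' Intervals use the BED convention (0-based, half-open) on disk and are
#' returned as a \link[GenomicRanges]{GRanges} (1-based, closed) with `name`
#' and `score` metadata columns.  `writeBed()` is the inverse.
#'
#' @param path file path.
#' @return `readBed()`: a `GRanges`.  `writeBed()`: invisibly, `path`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- read.table(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED needs at least 3 columns")
  start0 <- as.numeric(tab[[2]]); end0 <- as.numeric(tab[[3]])
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) at line %d", bad[1]))
  if (any(start0 < 0)) stop("negative start coordinate")
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = if (ncol(tab) >= 6) tab[[6]] else "*")
  gr$name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("iv", seq_along(gr))
  gr$score <- if (ncol(tab) >= 5) as.numeric(tab[[5]]) else 0
  gr
}

#' @rdname readBed
#' @param gr a `GRanges` with optional `name` and `score` metadata columns.
#' @export
writeBed <- function(gr, path) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- if (!is.null(gr$name)) gr$name else paste0("iv", seq_along(gr))
  sc <- if (!is.null(gr$score)) gr$score else 0
  out <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr), nm, sc, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
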