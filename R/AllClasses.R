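#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps reduce
#'   pintersect width start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom stats .lm.fit approx coef complete.cases cor dist hclust cutree lm.fit
#'   lm.wfit lowess mad median model.matrix na.omit p.adjust phyper pnorm pt
#'   qt quantile rbinom rnorm rpois runif sd setNames t.test var
#' @importFrom utils read.table write.table packageVersion
NULL

#' Peptide-level quantification container
#'
#' A \linkS4class{SummarizedExperiment} holding a peptide x sample matrix of
#' log2 intensities (assay \code{"log2intensity"}).  Row metadata carries the
#' peptide sequence and the semicolon-separated candidate protein accessions;
#' column metadata carries the sample annotation (growth \code{phase},
#' extraction \code{type} (\code{"total"} or \code{"oops"}),
#' \code{replicate} and \code{treatment}).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [PeptideQuant()] for the constructor.
#' @export
setClass("PeptideQuant", contains = "SummarizedExperiment")

#' Protein-level quantification container
#'
#' A \linkS4class{SummarizedExperiment} holding a protein x sample matrix of
#' log2 abundances (assay \code{"log2abundance"}).  Row metadata carries
#' \code{peptide_count}, the number of distinct quantified peptide sequences
#' behind each protein.  Column metadata is as in
#' \linkS4class{PeptideQuant}.
#'
#' @seealso [ProteinQuant()] for the constructor.
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

.validPeptideQuant <- function(object) {
  msg <- NULL
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("sequence", "proteins") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'sequence' and 'proteins'")
  else if (any(is.na(rd$proteins) | rd$proteins == ""))
    msg <- c(msg, "every peptide needs at least one candidate accession")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  a <- SummarizedExperiment::assay(object, "log2intensity")
  if (any(is.infinite(a)))
    msg <- c(msg, "intensities must be finite or missing (NA)")
  if (is.null(msg)) TRUE else msg
}
setValidity("PeptideQuant", .validPeptideQuant)

.validProteinQuant <- function(object) {
  msg <- NULL
  if (!"log2abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2abundance' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"peptide_count" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'peptide_count'")
  else if (any(rd$peptide_count < 1))
    msg <- c(msg, "peptide_count must be >= 1")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("ProteinQuant", .validProteinQuant)

#' Construct a PeptideQuant object
#'
#' @param log2intensity numeric matrix, peptides x samples, log2 scale, NA for
#'   missing.
#' @param sequence character vector of peptide sequences (one per row).
#' @param proteins character vector of candidate accessions per peptide,
#'   semicolon-separated when a peptide maps to several proteins.
#' @param sampleData `DataFrame` or data.frame with one row per sample;
#'   typically columns `phase`, `type`, `replicate`, `treatment`.  Extra
#'   columns are preserved untouched.
#' @return A [PeptideQuant-class] object.
#' @examples
#' m <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' pq <- PeptideQuant(m, sequence = c("PEPTIDEA", "PEPTIDEB"),
#'                    proteins = c("P1", "P1;P2"),
#'                    sampleData = data.frame(phase = c("exp", "stat"),
#'                                            type = "oops",
#'                                            replicate = 1:2,
#'                                            treatment = "none"))
#' @export
PeptideQuant <- function(log2intensity, sequence, proteins, sampleData) {
  log2intensity <- as.matrix(log2intensity)
  if (is.null(colnames(log2intensity)))
    colnames(log2intensity) <- paste0("sample", seq_len(ncol(log2intensity)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2intensity = log2intensity),
    rowData = S4Vectors::DataFrame(sequence = as.character(sequence),
                                   proteins = as.character(proteins)),
    colData = S4Vectors::DataFrame(sampleData,
                                   row.names = colnames(log2intensity)))
  methods::new("PeptideQuant", se)
}

#' Construct a ProteinQuant object
#'
#' @param log2abundance numeric matrix, proteins x samples, log2 scale.
#' @param peptide_count integer vector, distinct quantified peptide sequences
#'   per protein.
#' @param sampleData per-sample annotation, as for [PeptideQuant()].
#' @return A [ProteinQuant-class] object.
#' @export
ProteinQuant <- function(log2abundance, peptide_count, sampleData) {
  log2abundance <- as.matrix(log2abundance)
  if (is.null(colnames(log2abundance)))
    colnames(log2abundance) <- paste0("sample", seq_len(ncol(log2abundance)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2abundance = log2abundance),
    rowData = S4Vectors::DataFrame(peptide_count = as.integer(peptide_count)),
    colData = S4Vectors::DataFrame(sampleData,
                                   row.names = colnames(log2abundance)))
  methods::new("ProteinQuant", se)
}

#' Accessors for quantification containers
#'
#' `quantMatrix()` returns the quantification matrix (log2 scale);
#' `peptideCount()` the per-protein count of distinct quantified peptides;
#' `sampleInfo()` the per-sample annotation as a data.frame.
#'
#' @param x a [PeptideQuant-class] or [ProteinQuant-class] object.
#' @return See description.
#' @export
setGeneric("quantMatrix", function(x) standardGeneric("quantMatrix"))

#' @rdname quantMatrix
#' @export
setMethod("quantMatrix", "PeptideQuant", function(x)
  SummarizedExperiment::assay(x, "log2intensity"))

#' @rdname quantMatrix
#' @export
setMethod("quantMatrix", "ProteinQuant", function(x)
  SummarizedExperiment::assay(x, "log2abundance"))

#' @rdname quantMatrix
#' @export
setGeneric("peptideCount", function(x) standardGeneric("peptideCount"))

#' @rdname quantMatrix
#' @export
setMethod("peptideCount", "ProteinQuant", function(x)
  setNames(SummarizedExperiment::rowData(x)$peptide_count, rownames(x)))

#' @rdname quantMatrix
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname quantMatrix
#' @export
setMethod("sampleInfo", "SummarizedExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))
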