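#' Spike-in normalisation
#'
#' Subtracts the spike-in protein's log2 value in each sample from all
#' proteins in that sample, removing per-sample loading/pipetting offsets.
#' The spike row becomes identically zero; the operation is idempotent.
#'
#' @param x a [ProteinQuant-class] or numeric matrix with protein rownames.
#' @param spike_id row name of the spike-in protein (e.g. porcine trypsin,
#'   `"P00761"`).
#' @return Object of the same class, normalised.
#' @export
spikeNormalize <- function(x, spike_id) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, 1) <-
      spikeNormalize(quantMatrix(x), spike_id)
    return(x)
  }
  m <- as.matrix(x)
  if (!spike_id %in% rownames(m)) stop("spike-in '", spike_id, "' not found")
  sp <- m[spike_id, ]
  if (anyNA(sp)) {
    bad <- colnames(m)[which(is.na(sp))[1]]
    stop("spike-in missing in sample: ", bad)
  }
  sweep(m, 2, sp, "-")
}

#' Per-pair log2 treated/untreated ratios
#'
#' Computes, for every protein and every treated/untreated sample pair, the
#' log2 ratio `treated - untreated` (both on the log2 scale).  A protein
#' missing in either member of a pair contributes no ratio for that pair;
#' proteins observed in only one condition overall are excluded entirely.
#'
#' @param treated,untreated [ProteinQuant-class] objects or matrices with
#'   identical protein sets (rows matched by name; proteins present in only
#'   one object are excluded).
#' @param pairing data.frame with columns `treated` and `untreated` naming
#'   the paired sample columns.
#' @return Numeric matrix, proteins x pairs, of log2 ratios (NA where a pair
#'   is incomplete); proteins with no usable pair are dropped.
#' @export
perSampleRatio <- function(treated, untreated, pairing) {
  if (nrow(pairing) == 0L) stop("empty pairing")
  tm <- if (methods::is(treated, "SummarizedExperiment"))
    quantMatrix(treated) else as.matrix(treated)
  um <- if (methods::is(untreated, "SummarizedExperiment"))
    quantMatrix(untreated) else as.matrix(untreated)
  common <- intersect(rownames(tm), rownames(um))
  tm <- tm[common, pairing$treated, drop = FALSE]
  um <- um[common, pairing$untreated, drop = FALSE]
  r <- tm - um
  colnames(r) <- paste0("pair", seq_len(ncol(r)))
  # exclude proteins never observed in one of the two conditions
  seen_t <- rowSums(!is.na(tm)) > 0L
  seen_u <- rowSums(!is.na(um)) > 0L
  r[seen_t & seen_u, , drop = FALSE]
}

#' Peptide-count-aware moderated one-sample test on ratios
#'
#' For each protein the mean log2 ratio is tested against zero with a
#' moderated t-statistic whose prior variance follows a lowess trend of
#' pooled log-variance on log2 peptide count (see [ebayesModerate()]),
#' so that proteins quantified by many peptides are shrunk towards a smaller
#' prior variance than single-peptide proteins.  With fewer than five
#' testable proteins the trend is skipped and a global prior used.
#'
#' @param ratios matrix from [perSampleRatio()], proteins x pairs.
#' @param peptide_counts named vector of peptide counts covering the tested
#'   proteins (unnamed scalar recycled).
#' @param span lowess span for the variance trend.
#' @param prior optional fixed prior, see [ebayesModerate()].
#' @return data.frame with one row per tested protein: `protein`,
#'   `mean_log2_ratio`, `median_log2_ratio`, `n_pairs`, `peptide_count`,
#'   `s2`, `t_mod`, `df_total`, `p`, `adj_p`.  Proteins with fewer than two
#'   observed pairs are omitted (they cannot be tested).
#' @export
countDependentModeration <- function(ratios, peptide_counts, span = 0.75,
                                     prior = NULL) {
  n <- rowSums(!is.na(ratios))
  m <- rowMeans(ratios, na.rm = TRUE)
  md <- apply(ratios, 1, median, na.rm = TRUE)
  m[n == 0L] <- NA
  cnt <- if (is.null(names(peptide_counts)))
    rep_len(peptide_counts, nrow(ratios)) else
      peptide_counts[rownames(ratios)]
  cnt[is.na(cnt)] <- 1
  testable <- n >= 2L
  out <- data.frame(protein = rownames(ratios), mean_log2_ratio = m,
                    median_log2_ratio = md, n_pairs = n,
                    peptide_count = as.numeric(cnt), s2 = NA_real_,
                    t_mod = NA_real_, df_total = NA_real_, p = NA_real_,
                    adj_p = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (any(testable)) {
    r <- ratios[testable, , drop = FALSE]
    nt <- n[testable]
    s2 <- apply(r, 1, var, na.rm = TRUE)
    df <- nt - 1
    eb <- ebayesModerate(s2, df, covariate = log2(cnt[testable]),
                         span = span, prior = prior)
    tt <- moderatedTTest(m[testable], u = 1 / sqrt(nt),
                         s2_post = eb$s2_post, d0 = eb$d0, df = df)
    out$s2[testable] <- s2
    out$t_mod[testable] <- tt$t
    out$df_total[testable] <- eb$d0 + df
    out$p[testable] <- tt$p
    out$adj_p[testable] <- bhAdjust(tt$p)
  }
  out
}

#' Classify the RBPome from RNase-sensitivity results
#'
#' Applies the decision rule: a protein is called an RBP (RNase-depleted)
#' when its mean log2 treated/untreated ratio is negative with BH-adjusted
#' p below `alpha`; `enriched` when the ratio is positive and significant;
#' `excluded` when either condition has fewer than `min_hits` quantified
#' observations; otherwise `not-significant`.
#'
#' @param results data.frame from [countDependentModeration()].
#' @param hits_treated,hits_untreated named vectors of observation counts per
#'   condition (default: `n_pairs` used for both, i.e. complete pairs only).
#' @param alpha BH-adjusted significance level (default 0.01, i.e. 1\% FDR).
#' @param min_hits minimum observations required per condition (default 2).
#' @param include_enriched when TRUE, `rbpSet()` also returns enriched calls.
#' @return `classifyRbpome()`: the input data.frame with a `call` column.
#' @export
classifyRbpome <- function(results, alpha = 0.01,
                           hits_treated = NULL, hits_untreated = NULL,
                           min_hits = 2L) {
  ht <- if (is.null(hits_treated)) results$n_pairs else
    hits_treated[results$protein]
  hu <- if (is.null(hits_untreated)) results$n_pairs else
    hits_untreated[results$protein]
  call <- rep("not-significant", nrow(results))
  sig <- !is.na(results$adj_p) & results$adj_p < alpha
  call[sig & results$mean_log2_ratio < 0] <- "RBP"
  call[sig & results$mean_log2_ratio > 0] <- "enriched"
  call[is.na(ht) | is.na(hu) | ht < min_hits | hu < min_hits] <- "excluded"
  results$call <- call
  results
}

#' @rdname classifyRbpome
#' @param classified output of `classifyRbpome()`.
#' @return `rbpSet()`: character vector of protein ids called RBP.
#' @export
rbpSet <- function(classified, include_enriched = FALSE) {
  keep <- classified$call == "RBP"
  if (include_enriched) keep <- keep | classified$call == "enriched"
  classified$protein[keep]
}

#' Full RNase-sensitivity assay analysis
#'
#' Convenience wrapper: spike-in normalisation of both conditions, per-pair
#' ratios, peptide-count-aware moderation, and RBP classification.
#'
#' @param treated,untreated [ProteinQuant-class] objects.
#' @param pairing see [perSampleRatio()].
#' @param spike_id spike-in accession; `NULL` skips spike normalisation.
#' @param alpha significance level on BH-adjusted p-values.
#' @param ... passed to [countDependentModeration()].
#' @return Classified results data.frame (see [classifyRbpome()]).
#' @export
rnaseAssay <- function(treated, untreated, pairing, spike_id = "P00761",
                       alpha = 0.01, ...) {
  if (!is.null(spike_id)) {
    treated <- spikeNormalize(treated, spike_id)
    untreated <- spikeNormalize(untreated, spike_id)
  }
  ratios <- perSampleRatio(treated, untreated, pairing)
  if (!is.null(spike_id)) ratios <- ratios[rownames(ratios) != spike_id, ,
                                           drop = FALSE]
  counts <- peptideCount(treated)
  tm <- quantMatrix(treated)[rownames(ratios), pairing$treated, drop = FALSE]
  um <- quantMatrix(untreated)[rownames(ratios), pairing$untreated,
                               drop = FALSE]
  res <- countDependentModeration(ratios, counts, ...)
  classifyRbpome(res, alpha = alpha,
                 hits_treated = setNames(rowSums(!is.na(tm)), rownames(tm)),
                 hits_untreated = setNames(rowSums(!is.na(um)), rownames(um)))
}
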