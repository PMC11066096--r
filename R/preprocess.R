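#' Centre-median normalisation
#'
#' Subtracts, within each sample (column), the median of its non-missing
#' log2 values, so that every output column has median zero.  The operation
#' is idempotent.
#'
#' @param x numeric matrix (log2), or a quantification container; NA for
#'   missing values.
#' @return Object of the same class with normalised values.
#' @export
centreMedianNormalize <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- quantMatrix(x)
    SummarizedExperiment::assay(x, 1) <- centreMedianNormalize(m)
    return(x)
  }
  m <- as.matrix(x)
  med <- apply(m, 2, median, na.rm = TRUE)
  if (any(is.na(med))) {
    bad <- colnames(m)[which(is.na(med))[1]]
    if (is.null(bad)) bad <- which(is.na(med))[1]
    stop("sample with no observed values: ", bad)
  }
  sweep(m, 2, med, "-")
}

#' Robust two-factor summarisation of one protein's peptides
#'
#' Fits the additive model \eqn{y_{ps} = sample_s + peptide_p + e} to the
#' observed log2 peptide intensities of one protein by iteratively
#' reweighted least squares with Huber weights (tuning constant `k`,
#' at most `maxit` iterations, convergence when the largest coefficient
#' change drops below `tol`).  Identification constrains the peptide
#' effects to sum to zero, so the returned sample effects are on the scale
#' of an average peptide.  Missing cells are omitted from the fit; a sample
#' with no observed peptide is returned as NA.
#'
#' @param m numeric matrix, peptides x samples, log2 scale.
#' @param k Huber tuning constant (default 1.345, 95\% Gaussian efficiency).
#' @param maxit,tol iteration cap and convergence tolerance.
#' @return Named numeric vector of per-sample protein values.
#' @export
robustSummarize <- function(m, k = 1.345, maxit = 20L, tol = 1e-6) {
  m <- as.matrix(m)
  if (nrow(m) == 0L) stop("no peptide rows")
  if (nrow(m) == 1L) return(setNames(as.numeric(m[1, ]), colnames(m)))
  obs <- !is.na(m)
  out <- rep(NA_real_, ncol(m))
  names(out) <- colnames(m)
  use_s <- colSums(obs) > 0L
  if (!any(use_s)) return(out)
  mm <- m[, use_s, drop = FALSE]
  keep_p <- rowSums(!is.na(mm)) > 0L
  mm <- mm[keep_p, , drop = FALSE]
  if (nrow(mm) == 1L) { out[use_s] <- mm[1, ]; return(out) }
  ok <- !is.na(mm)
  y <- mm[ok]
  sidx <- col(mm)[ok]
  pidx <- row(mm)[ok]
  ns <- ncol(mm)
  np <- nrow(mm)
  nobs <- length(y)
  # design: one column per sample plus sum-to-zero peptide contrasts
  X <- matrix(0, nobs, ns + np - 1L)
  X[cbind(seq_len(nobs), sidx)] <- 1
  inner <- pidx < np
  X[cbind(which(inner), ns + pidx[inner])] <- 1
  X[pidx == np, (ns + 1L):(ns + np - 1L)] <- -1
  w <- rep(1, nobs)
  beta_old <- rep(Inf, ncol(X))
  beta <- NULL
  for (it in seq_len(maxit)) {
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, y * sw)
    if (fit$rank < ncol(X)) {
      beta <- qr.coef(qr(X * sw), y * sw)  # pivot-aware for odd patterns
    } else {
      beta <- numeric(ncol(X))
      beta[fit$pivot] <- fit$coefficients
    }
    beta[is.na(beta)] <- 0
    if (max(abs(beta - beta_old)) < tol) break
    beta_old <- beta
    r <- y - drop(X %*% beta)
    ar <- abs(r)
    s <- median(ar) / 0.6745
    if (s < 1e-10) break
    w <- pmin(1, k * s / pmax(ar, 1e-300))
  }
  out[which(use_s)] <- beta[seq_len(ns)]
  out
}

#' Summarise peptides to proteins
#'
#' Maps every peptide row to its master protein (see
#' [assignMasterProteins()]), drops contaminant-flagged peptides, applies
#' [robustSummarize()] per protein, and retains proteins identified by at
#' least `min_peptides` distinct sequences.
#'
#' @param peptides a [PeptideQuant-class] (aggregated; see
#'   [aggregateModifiedPeptides()]).
#' @param master data.frame from [assignMasterProteins()]; by default every
#'   peptide is assigned its first listed candidate.
#' @param min_peptides identification filter; proteins supported by fewer
#'   distinct peptide sequences are dropped (default 2, the usual
#'   two-high-confidence-peptides rule).
#' @param ... passed to [robustSummarize()].
#' @return A [ProteinQuant-class] object.
#' @export
summarizeProteins <- function(peptides, master = NULL, min_peptides = 2L,
                              ...) {
  rd <- SummarizedExperiment::rowData(peptides)
  if (is.null(master)) {
    master <- data.frame(
      sequence = rd$sequence,
      master = vapply(strsplit(rd$proteins, ";", fixed = TRUE), `[`, "", 1L),
      contaminant = FALSE, stringsAsFactors = FALSE)
  }
  keep <- !master$contaminant
  m <- quantMatrix(peptides)[keep, , drop = FALSE]
  grp <- master$master[keep]
  counts <- vapply(split(seq_along(grp), grp), length, 0L)
  prots <- sort(names(counts)[counts >= min_peptides])
  vals <- t(vapply(prots, function(p)
    robustSummarize(m[grp == p, , drop = FALSE], ...),
    numeric(ncol(m))))
  ProteinQuant(vals, peptide_count = counts[prots],
               sampleData = SummarizedExperiment::colData(peptides))
}

#' Per-protein z-scores within sample groups
#'
#' Standardises each protein profile to mean 0 and sample standard deviation
#' (denominator n-1) 1, separately within each level of `group` (for example
#' extraction type, so total and OOPS samples are scaled independently).
#' Constant rows within a group are set to zero and flagged with a warning.
#'
#' @param x numeric matrix or [ProteinQuant-class].
#' @param group vector with one group label per sample (column).
#' @return Matrix of z-scores with the input dimensions.
#' @export
zscoreByGroup <- function(x, group) {
  m <- if (methods::is(x, "SummarizedExperiment")) quantMatrix(x) else
    as.matrix(x)
  if (length(group) != ncol(m)) stop("one group label per sample required")
  out <- m
  flagged <- FALSE
  for (g in unique(group)) {
    j <- which(group == g)
    sub <- m[, j, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, sd, na.rm = TRUE)
    zero <- !is.na(sdv) & sdv == 0
    if (any(zero)) flagged <- TRUE
    sdv[zero | is.na(sdv)] <- 1
    out[, j] <- (sub - mu) / sdv
    out[zero, j] <- 0
  }
  if (flagged) warning("constant row(s) within a group set to zero")
  out
}

#' Filter proteins to complete cases across required conditions
#'
#' Retains proteins observed (non-missing) in at least one sample of every
#' required condition, e.g. every growth phase.
#'
#' @param x a [ProteinQuant-class].
#' @param condition vector with one condition label per sample.
#' @param required condition labels that must each be observed; defaults to
#'   all levels present.
#' @return The filtered [ProteinQuant-class]; the numbers retained/dropped
#'   are reported via `message()`.
#' @export
filterCompleteCases <- function(x, condition,
                                required = unique(condition)) {
  m <- quantMatrix(x)
  ok <- rep(TRUE, nrow(m))
  for (cond in required) {
    j <- which(condition == cond)
    ok <- ok & rowSums(!is.na(m[, j, drop = FALSE])) > 0L
  }
  message(sum(ok), " proteins retained, ", sum(!ok), " dropped")
  x[ok, ]
}
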