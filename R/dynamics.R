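.groupStats <- function(m, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  p <- nrow(m)
  means <- counts <- matrix(NA_real_, p, length(levs),
                            dimnames = list(rownames(m), levs))
  ss <- 0
  for (g in levs) {
    j <- which(groups == g)
    sub <- m[, j, drop = FALSE]
    n_g <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[n_g == 0L] <- NA
    means[, g] <- mu
    counts[, g] <- n_g
    dev <- sub - mu
    ss <- ss + rowSums(dev^2, na.rm = TRUE)
  }
  nonempty <- rowSums(counts > 0)
  df <- rowSums(counts) - nonempty
  s2 <- ifelse(df > 0, ss / df, NA_real_)
  list(means = means, counts = counts, s2 = s2, df = df, levels = levs)
}

#' Fit the growth-phase model per protein
#'
#' Ordinary least squares of log2 abundance on growth phase as a categorical
#' factor, fitted for every protein at once.  For a one-way layout the OLS
#' estimates are the phase means; the residual variance pools the
#' within-phase sums of squares.  Proteins with residual df 0 (e.g. a single
#' replicate everywhere) are flagged untestable (`df = 0`, `s2 = NA`).
#'
#' @param m numeric matrix, proteins x samples (or [ProteinQuant-class]).
#' @param phase vector of phase labels, one per sample.
#' @param reference reference phase for coefficient reporting.
#' @return A list of class `"phaseFit"` with phase `means`, observation
#'   `counts`, pooled residual variance `s2`, residual `df`, the reference
#'   coefficients (`coef`, phase mean minus reference mean), and the phase
#'   `levels`.
#' @export
fitPhaseModel <- function(m, phase, reference = "exponential") {
  if (methods::is(m, "SummarizedExperiment")) m <- quantMatrix(m)
  if (length(phase) != ncol(m)) stop("one phase label per sample required")
  if (length(unique(phase)) < 2L) stop("need at least two phases")
  gs <- .groupStats(m, phase)
  if (!reference %in% gs$levels) stop("reference phase not present")
  gs$reference <- reference
  gs$coef <- gs$means - gs$means[, reference]
  class(gs) <- "phaseFit"
  gs
}

#' Contrast between two phases from a phase-model fit
#'
#' @param fit a `"phaseFit"` from [fitPhaseModel()].
#' @param a,b phase labels; the contrast is `b - a` (e.g. `a =
#'   "exponential"`, `b = "stationary"` gives the stationary-vs-exponential
#'   log2 fold change).
#' @return data.frame with `estimate` and the unit-variance standard error
#'   `u` (so the ordinary standard error is `u * sqrt(s2)`); NA where a
#'   phase has no observations.
#' @export
phaseContrast <- function(fit, a, b) {
  est <- fit$means[, b] - fit$means[, a]
  u <- sqrt(1 / fit$counts[, a] + 1 / fit$counts[, b])
  u[!is.finite(u)] <- NA
  data.frame(estimate = est, u = u)
}

#' Fit the phase-by-extraction interaction model per protein
#'
#' OLS of log2 abundance on growth phase, extraction type and their
#' interaction (`abundance ~ phase + type + phase:type`), fitted jointly on
#' the total-proteome and OOPS matrices as a cell-means model: estimates are
#' the phase-by-type cell means, and the residual variance pools
#' within-cell sums of squares.  The interaction contrast between phases
#' `a` and `b` equals `(OOPS_b - OOPS_a) - (total_b - total_a)`, i.e. the
#' divergence of the RNA-bound profile from the total-abundance profile.
#' A protein with an empty cell is untestable for contrasts touching it.
#'
#' @param total,oops matrices or [ProteinQuant-class] objects over the same
#'   proteins (rows matched by name).
#' @param phase_total,phase_oops phase labels per sample of each matrix.
#' @return A list of class `"interactionFit"` with cell `means` and `counts`
#'   (columns named `phase.type`), pooled `s2`, residual `df`, and `levels`.
#' @export
fitInteractionModel <- function(total, oops, phase_total, phase_oops) {
  tm <- if (methods::is(total, "SummarizedExperiment")) quantMatrix(total)
    else as.matrix(total)
  om <- if (methods::is(oops, "SummarizedExperiment")) quantMatrix(oops)
    else as.matrix(oops)
  common <- intersect(rownames(tm), rownames(om))
  m <- cbind(tm[common, , drop = FALSE], om[common, , drop = FALSE])
  cells <- c(paste(phase_total, "total", sep = "."),
             paste(phase_oops, "oops", sep = "."))
  gs <- .groupStats(m, cells)
  class(gs) <- "interactionFit"
  gs
}

#' Interaction and per-extraction contrasts from an interaction-model fit
#'
#' @param fit an `"interactionFit"` from [fitInteractionModel()].
#' @param a,b phase labels; contrasts are `b - a`.
#' @return data.frame with the total-proteome fold change `dT`, the OOPS
#'   fold change `dO`, the interaction `estimate = dO - dT`, and unscaled
#'   standard errors `u_dT`, `u_dO`, `u` for each.
#' @export
interactionContrast <- function(fit, a, b) {
  cell <- function(ph, ty) paste(ph, ty, sep = ".")
  mns <- fit$means; cnt <- fit$counts
  gv <- function(nm) if (nm %in% colnames(mns)) mns[, nm] else
    rep(NA_real_, nrow(mns))
  gn <- function(nm) if (nm %in% colnames(cnt)) cnt[, nm] else
    rep(0, nrow(cnt))
  dT <- gv(cell(b, "total")) - gv(cell(a, "total"))
  dO <- gv(cell(b, "oops")) - gv(cell(a, "oops"))
  u_dT <- sqrt(1 / gn(cell(a, "total")) + 1 / gn(cell(b, "total")))
  u_dO <- sqrt(1 / gn(cell(a, "oops")) + 1 / gn(cell(b, "oops")))
  u <- sqrt(1 / gn(cell(a, "total")) + 1 / gn(cell(b, "total")) +
              1 / gn(cell(a, "oops")) + 1 / gn(cell(b, "oops")))
  u_dT[!is.finite(u_dT)] <- NA
  u_dO[!is.finite(u_dO)] <- NA
  u[!is.finite(u)] <- NA
  data.frame(dT = dT, dO = dO, estimate = dO - dT,
             u_dT = u_dT, u_dO = u_dO, u = u)
}

#' Classify proteins into dynamics classes i / ii / iii
#'
#' Class iii (RNA binding changes independently of abundance) when the
#' interaction adjusted p-value is below `alpha`; otherwise class ii
#' (RNA binding tracks total abundance) when the OOPS phase-effect adjusted
#' p-value is below `alpha`; otherwise class i (static).  The hierarchy
#' iii > ii > i makes the partition unambiguous.  Untestable proteins (NA
#' p-values) are returned as NA.
#'
#' @param adjp_interaction,adjp_oops BH-adjusted p-value vectors.
#' @param alpha significance level (default 0.01, 1\% FDR).
#' @return Character vector of `"i"`, `"ii"`, `"iii"` or NA.
#' @export
classifyDynamics <- function(adjp_interaction, adjp_oops, alpha = 0.01) {
  cls <- ifelse(adjp_interaction < alpha, "iii",
                ifelse(adjp_oops < alpha, "ii", "i"))
  cls[is.na(adjp_interaction) | is.na(adjp_oops)] <- NA
  cls
}

#' Assign fold-change quadrants
#'
#' Q1: both total and OOPS fold changes positive (abundance and RNA binding
#' both increase); Q3: both negative; Q2: total down, OOPS up; Q4: total up,
#' OOPS down.  Exact zeros fall in no quadrant (`"none"`).
#'
#' @param dT,dO total-proteome and OOPS log2 fold changes.
#' @return Character vector of `"Q1"`..`"Q4"` or `"none"`.
#' @export
assignQuadrant <- function(dT, dO) {
  q <- rep("none", length(dT))
  q[dT > 0 & dO > 0] <- "Q1"
  q[dT < 0 & dO > 0] <- "Q2"
  q[dT < 0 & dO < 0] <- "Q3"
  q[dT > 0 & dO < 0] <- "Q4"
  q[is.na(dT) | is.na(dO)] <- NA
  q
}

#' Sign patterns over consecutive phase transitions
#'
#' For each protein, each transition (e.g. lag to exponential, exponential to
#' stationary) is summarised as `+` or `-` by the sign of its estimate when
#' the adjusted p-value is below `alpha`, and `0` otherwise.  Proteins
#' sharing a pattern form a profile group.
#'
#' @param estimates matrix, proteins x transitions, of contrast estimates.
#' @param adjp matching matrix of BH-adjusted p-values.
#' @param alpha significance level.
#' @return Character vector of patterns such as `"+,-"`; `groupSizes()` of
#'   the result tabulates group membership.
#' @export
profilePatterns <- function(estimates, adjp, alpha = 0.01) {
  sig <- !is.na(adjp) & adjp < alpha
  sgn <- matrix("0", nrow(estimates), ncol(estimates))
  sgn[sig & estimates > 0] <- "+"
  sgn[sig & estimates < 0] <- "-"
  apply(sgn, 1, paste, collapse = ",")
}

#' Hierarchical clustering of profiles with Pearson distance
#'
#' Clusters protein profiles with distance `1 - r` (Pearson correlation
#' between rows) and average linkage (UPGMA).  Constant rows, whose
#' correlation is undefined, are excluded with a warning.
#'
#' @param m numeric matrix of profiles (no missing values in clustered rows).
#' @param k optional number of flat clusters to cut.
#' @param h optional cut height.
#' @return List with the `hclust` tree, the `clusters` vector (if `k` or `h`
#'   given) and `excluded` row names.
#' @export
hierarchicalCluster <- function(m, k = NULL, h = NULL) {
  m <- as.matrix(m)
  sds <- apply(m, 1, sd)
  excl <- rownames(m)[is.na(sds) | sds == 0]
  if (length(excl)) {
    warning("excluding ", length(excl), " constant row(s)")
    m <- m[!(rownames(m) %in% excl), , drop = FALSE]
  }
  d <- stats::as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = "average")
  clusters <- if (!is.null(k) || !is.null(h))
    cutree(tree, k = k, h = h) else NULL
  list(tree = tree, clusters = clusters, excluded = excl)
}

#' Growth-phase dynamics analysis of total and OOPS proteomes
#'
#' Runs the full dynamics stage: phase models per extraction, the
#' phase-by-extraction interaction model, empirical-Bayes moderation within
#' each coefficient family (total phase effect, OOPS phase effect,
#' interaction), BH adjustment within each family, classification into
#' classes i/ii/iii, fold-change quadrants for the contrast of interest, and
#' sign patterns over consecutive transitions of the total proteome.
#'
#' @param total,oops [ProteinQuant-class] objects or matrices over the same
#'   proteins.
#' @param phase_total,phase_oops phase labels per sample (defaults taken
#'   from `sampleInfo()` when containers are supplied).
#' @param contrast length-2 character vector `c(reference, test)` for the
#'   headline fold changes (default exponential vs stationary).
#' @param phases ordered phase labels for transition patterns.
#' @param alpha significance level on adjusted p-values.
#' @return data.frame with one row per protein: `dT`, `dO`, per-family
#'   `p_*`/`adjp_*`, `class`, `quadrant`, `pattern`.
#' @export
runDynamics <- function(total, oops, phase_total = NULL, phase_oops = NULL,
                        contrast = c("exponential", "stationary"),
                        phases = c("lag", "exponential", "stationary"),
                        alpha = 0.01) {
  if (is.null(phase_total)) phase_total <- sampleInfo(total)$phase
  if (is.null(phase_oops)) phase_oops <- sampleInfo(oops)$phase
  tm <- if (methods::is(total, "SummarizedExperiment")) quantMatrix(total)
    else as.matrix(total)
  om <- if (methods::is(oops, "SummarizedExperiment")) quantMatrix(oops)
    else as.matrix(oops)
  common <- intersect(rownames(tm), rownames(om))
  tm <- tm[common, , drop = FALSE]; om <- om[common, , drop = FALSE]
  a <- contrast[1]; b <- contrast[2]

  fit_t <- fitPhaseModel(tm, phase_total, reference = a)
  fit_o <- fitPhaseModel(om, phase_oops, reference = a)
  fit_i <- fitInteractionModel(tm, om, phase_total, phase_oops)

  testFamily <- function(fit, con) {
    ok <- !is.na(fit$s2) & fit$df >= 1 & !is.na(con$u)
    p <- rep(NA_real_, length(fit$s2))
    if (any(ok)) {
      eb <- ebayesModerate(fit$s2[ok], fit$df[ok])
      p[ok] <- moderatedTTest(con$estimate[ok], con$u[ok], eb$s2_post,
                              eb$d0, fit$df[ok])$p
    }
    list(p = p, adjp = bhAdjust(p))
  }

  con_t <- phaseContrast(fit_t, a, b)
  con_o <- phaseContrast(fit_o, a, b)
  con_i0 <- interactionContrast(fit_i, a, b)
  con_i <- data.frame(estimate = con_i0$estimate, u = con_i0$u)

  ft <- testFamily(fit_t, con_t)
  fo <- testFamily(fit_o, con_o)
  fi <- testFamily(fit_i, con_i)

  # transition patterns on the total proteome, one eBayes fit for the family
  trans <- cbind(utils::head(phases, -1), phases[-1])
  est_tr <- matrix(NA_real_, length(common), nrow(trans))
  adj_tr <- matrix(NA_real_, length(common), nrow(trans))
  for (i in seq_len(nrow(trans))) {
    ctr <- phaseContrast(fit_t, trans[i, 1], trans[i, 2])
    fam <- testFamily(fit_t, ctr)
    est_tr[, i] <- ctr$estimate
    adj_tr[, i] <- fam$adjp
  }

  data.frame(protein = common,
             dT = con_t$estimate, dO = con_o$estimate,
             interaction = con_i$estimate,
             p_total = ft$p, adjp_total = ft$adjp,
             p_oops = fo$p, adjp_oops = fo$adjp,
             p_inter = fi$p, adjp_inter = fi$adjp,
             class = classifyDynamics(fi$adjp, fo$adjp, alpha),
             quadrant = assignQuadrant(con_t$estimate, con_o$estimate),
             pattern = profilePatterns(est_tr, adj_tr, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}
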