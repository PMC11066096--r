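#' Term over-representation by Fisher's exact test
#'
#' For every term, the one-sided (over-representation) Fisher exact p-value
#' of the 2x2 table (foreground/background x in-term/not-in-term), i.e. the
#' hypergeometric upper tail, with Bonferroni correction over the tested
#' terms by default.  Terms with no background member are skipped with a
#' warning.
#'
#' @param foreground character vector of proteins of interest (subset of
#'   `background`).
#' @param background character vector defining the universe.
#' @param annotations data.frame with columns `protein` and `term`.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param two_sided when TRUE, use the two-sided Fisher exact p instead of
#'   over-representation only.
#' @return data.frame with one row per term: counts `k` (foreground hits),
#'   `n` (foreground size), `K` (background hits), `N` (background size),
#'   `p`, `adj_p`, and the fold `effect = (k/n)/(K/N)`.
#' @export
fisherEnrichment <- function(foreground, background, annotations,
                             correction = c("bonferroni", "BH"),
                             two_sided = FALSE) {
  correction <- match.arg(correction)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  foreground <- unique(foreground); background <- unique(background)
  ann <- annotations[annotations$protein %in% background, , drop = FALSE]
  skipped <- setdiff(unique(annotations$term), unique(ann$term))
  if (length(skipped))
    warning("term(s) with no background member skipped: ",
            paste(skipped, collapse = ", "))
  N <- length(background); n <- length(foreground)
  terms <- sort(unique(ann$term))
  res <- lapply(terms, function(tm) {
    hits <- unique(ann$protein[ann$term == tm])
    K <- length(hits)
    k <- sum(foreground %in% hits)
    p <- if (two_sided)
      stats::fisher.test(matrix(c(k, n - k, K - k, N - n - (K - k)), 2))$p.value
    else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               effect = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- if (correction == "bonferroni")
    pmin(1, out$p * nrow(out)) else bhAdjust(out$p)
  out
}

#' Abundance-bias-corrected term enrichment by weighted resampling
#'
#' Tests term over-representation while accounting for protein abundance:
#' null foregrounds of the observed size are drawn without replacement from
#' the background with sampling weights that reproduce the foreground's
#' abundance distribution (background abundances are cut into `n_bins`
#' equal-count bins and each background protein is weighted by the
#' foreground/background ratio of its bin).  The p-value per term is the
#' proportion of resamples whose term count reaches the observed count, with
#' the (x+1)/(n+1) correction; BH adjustment across terms.
#'
#' @inheritParams fisherEnrichment
#' @param abundance named numeric vector covering the background.
#' @param n_resamples number of null foregrounds (>= 100).
#' @param n_bins number of equal-count abundance bins.
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame as in [fisherEnrichment()] with BH-adjusted p-values.
#' @export
abundanceWeightedEnrichment <- function(foreground, background, annotations,
                                        abundance, n_resamples = 10000L,
                                        n_bins = 10L, seed = NULL) {
  if (n_resamples < 100L) stop("n_resamples must be at least 100")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  if (!all(background %in% names(abundance)))
    stop("abundance value required for every background protein")
  if (!is.null(seed)) set.seed(seed)
  foreground <- unique(foreground); background <- unique(background)
  ab <- abundance[background]
  brks <- unique(quantile(ab, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(brks) < 2) rep(1L, length(ab)) else
    cut(ab, brks, include.lowest = TRUE, labels = FALSE)
  nb <- max(bins)
  fg_frac <- tabulate(bins[match(foreground, background)],
                      nbins = nb) / length(foreground)
  bg_frac <- tabulate(bins, nbins = nb) / length(background)
  w <- fg_frac[bins] / bg_frac[bins]
  w[!is.finite(w) | w <= 0] <- 1e-9
  ann <- annotations[annotations$protein %in% background, , drop = FALSE]
  terms <- sort(unique(ann$term))
  term_sets <- lapply(terms, function(tm)
    background %in% unique(ann$protein[ann$term == tm]))
  obs <- vapply(term_sets, function(s)
    sum(background[s] %in% foreground), 0L)
  nfg <- length(foreground)
  ge <- integer(length(terms))
  for (i in seq_len(n_resamples)) {
    draw <- sample.int(length(background), nfg, prob = w)
    cnt <- vapply(term_sets, function(s) sum(s[draw]), 0L)
    ge <- ge + (cnt >= obs)
  }
  p <- (ge + 1) / (n_resamples + 1)
  N <- length(background)
  K <- vapply(term_sets, sum, 0L)
  data.frame(term = terms, k = obs, n = nfg, K = K, N = N, p = p,
             adj_p = bhAdjust(p), effect = (obs / nfg) / (K / N),
             stringsAsFactors = FALSE)
}
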