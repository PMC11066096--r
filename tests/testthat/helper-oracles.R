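# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written with the most literal algorithms available
# (quadratic loops, direct formulas) and share no code with the package.

# step-up FDR adjustment straight from the definition
directBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# UPGMA on a distance matrix by explicit enumeration: returns the sequence
# of merge heights and cluster sizes
bruteUPGMA <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  d <- D
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      if (d[a, b] < bh) { bh <- d[a, b]; best <- c(b, a) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bh)
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (k in active) if (k != a && k != b)
      d[a, k] <- d[k, a] <- (na * d[a, k] + nb * d[b, k]) / (na + nb)
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  heights
}

# all-pairs interval overlap (0-based half-open coordinates)
bruteOverlapAny <- function(q, s) {
  # q, s: data.frames with chrom, start, end (0-based half-open)
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] & s$start < q$end[i] & q$start[i] < s$end)
  }, logical(1))
}

# reciprocal-fraction replicate intersection, literal translation of the
# bedtools -f x -r rule, anchored on the first list
bruteReciprocalKeep <- function(lists, f) {
  anchor <- lists[[1]]
  keep <- rep(TRUE, nrow(anchor))
  for (j in seq_along(lists)[-1]) {
    other <- lists[[j]]
    for (i in seq_len(nrow(anchor))) {
      if (!keep[i]) next
      ok <- FALSE
      for (m in seq_len(nrow(other))) {
        if (anchor$chrom[i] != other$chrom[m]) next
        ov <- min(anchor$end[i], other$end[m]) -
          max(anchor$start[i], other$start[m])
        if (ov <= 0) next
        wa <- anchor$end[i] - anchor$start[i]
        wb <- other$end[m] - other$start[m]
        if (ov >= f * wa && ov >= f * wb) { ok <- TRUE; break }
      }
      if (!ok) keep[i] <- FALSE
    }
  }
  keep
}

# moment equations for the inverse-chi-squared prior, coded directly from
# their definition with stats::uniroot for the trigamma inversion
momentPriorOracle <- function(s2, df, efit = NULL) {
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  if (is.null(efit)) efit <- rep(mean(e), length(e))
  n <- length(e)
  rhs <- mean((e - efit)^2 * n / (n - 1) - trigamma(df / 2))
  if (rhs <= 0)  # fixed-variance limit, level calibrated by the plain mean
    return(list(d0 = Inf, s02 = exp(efit) * mean(s2) / mean(exp(efit))))
  g <- function(y) trigamma(y) - rhs
  y <- uniroot(g, c(1e-6, 1e6), tol = 1e-12)$root
  d0 <- 2 * y
  list(d0 = d0, s02 = exp(efit + digamma(d0 / 2) - log(d0 / 2)))
}

# GRanges helpers for random interval fixtures
randomIntervals <- function(n, genome = 10000, max_w = 50, seed = 1) {
  set.seed(seed)
  start <- sample.int(genome - max_w, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  df <- data.frame(chrom = "chr", start = start, end = start + w)
  gr <- GenomicRanges::GRanges("chr",
                               IRanges::IRanges(start + 1, width = w),
                               strand = "+")
  gr$name <- paste0("iv", seq_len(n))
  gr$score <- seq_len(n)
  list(df = df, gr = gr)
}

# small simulated dynamics experiment, summarised to protein level
runSmallDynamics <- function(n = 200, effect = 2, seed = 1, ...) {
  sim <- simulateProteomeExperiment(proteomeSimConfig(
    n_proteins = n, effect_size = effect, seed = seed, ...))
  prep <- lapply(sim[c("total", "oops")], function(pq)
    centreMedianNormalize(summarizeProteins(aggregateModifiedPeptides(pq))))
  list(dyn = runDynamics(prep$total, prep$oops), truth = sim$truth)
}
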