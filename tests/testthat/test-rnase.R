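test_that("spike-in normalisation cancels per-sample offsets and is
           idempotent", {
  m <- rbind(P00761 = c(1, 2), PA = c(3, 5))
  colnames(m) <- c("s1", "s2")
  out <- spikeNormalize(m, "P00761")
  expect_equal(out["P00761", ], c(s1 = 0, s2 = 0))
  expect_equal(out["PA", ], c(s1 = 2, s2 = 3))
  expect_equal(spikeNormalize(out, "P00761"), out)

  # adding a constant to one column changes nothing after normalisation
  m2 <- m; m2[, 2] <- m2[, 2] + 5
  expect_equal(spikeNormalize(m2, "P00761"), out)

  m3 <- m; m3["P00761", 2] <- NA
  expect_error(spikeNormalize(m3, "P00761"), "s2")
  expect_error(spikeNormalize(m, "nope"), "not found")
})

test_that("per-pair ratios follow the pairing and exclusion rules", {
  tm <- rbind(PA = c(1, 1), PB = c(2, 2), Ponly_t = c(1, 1))
  um <- rbind(PA = c(0, 2), PB = c(2, 2), Ponly_u = c(3, 3))
  colnames(tm) <- c("T1", "T2"); colnames(um) <- c("U1", "U2")
  pairing <- data.frame(treated = c("T1", "T2"),
                        untreated = c("U1", "U2"))
  r <- perSampleRatio(tm, um, pairing)
  expect_equal(unname(r["PA", ]), c(1, -1))
  expect_equal(mean(r["PA", ]), 0)
  expect_equal(unname(r["PB", ]), c(0, 0))
  # proteins present in only one condition are excluded
  expect_false("Ponly_t" %in% rownames(r))
  expect_false("Ponly_u" %in% rownames(r))
  expect_error(perSampleRatio(tm, um, pairing[0, ]), "empty pairing")
})

test_that("flat variance structure reduces the moderated test to the
           ordinary one-sample t-test", {
  # identical s2 and counts: trend is flat, d0 = Inf... so force d0 = 0 via
  # prior-free comparison on exactly equal variances instead: with all s2
  # equal the posterior variance equals the common s2 and t matches the
  # ordinary statistic
  x <- c(0.8, 1.1, 1.4)
  ratios <- matrix(rep(x, each = 8), 8, 3, byrow = FALSE,
                   dimnames = list(paste0("P", 1:8), NULL))
  res <- countDependentModeration(ratios, peptide_counts = 4)
  t_ord <- mean(x) / sqrt(var(x) / 3)
  expect_equal(res$t_mod, rep(t_ord, 8), tolerance = 1e-10)

  # d0 = Inf forced: posterior variance equals the prior for every protein
  set.seed(5)
  r2 <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("P", 1:10), NULL))
  res2 <- countDependentModeration(r2, peptide_counts = 3,
                                   prior = list(d0 = Inf, s02 = 0.5))
  expect_equal(res2$t_mod,
               unname(rowMeans(r2)) / sqrt(0.5 / 4), tolerance = 1e-12)
})

test_that("count-dependent variances produce a falling trend and statistics
           matching the directly coded moment equations", {
  set.seed(6)
  n <- 200
  cnt <- sample(1:16, n, replace = TRUE)
  sdv <- 0.3 * (1 + 1 / cnt)
  ratios <- matrix(rnorm(n * 4, 0, rep(sdv, 4)), n, 4,
                   dimnames = list(paste0("P", 1:n), NULL))
  res <- countDependentModeration(ratios,
                                  setNames(cnt, rownames(ratios)))
  s2 <- apply(ratios, 1, var)
  # trend of pooled log-variance on log2 count is decreasing
  lo <- lowess(log2(cnt), log(s2), f = 0.75)
  expect_lt(lo$y[length(lo$y)], lo$y[1])

  # independent recomputation of the moment equations, given the same trend
  e <- log(pmax(s2, 1e-12)) - digamma(3 / 2) + log(3 / 2)
  lo_e <- lowess(log2(cnt), e, f = 0.75)
  efit <- approx(lo_e$x, lo_e$y, xout = log2(cnt), rule = 2,
                 ties = mean)$y
  or <- momentPriorOracle(s2, rep(3, n), efit = efit)
  s2_post <- if (is.infinite(or$d0)) or$s02 else
    (or$d0 * or$s02 + 3 * s2) / (or$d0 + 3)
  t_or <- rowMeans(ratios) / sqrt(s2_post / 4)
  expect_equal(res$t_mod, unname(t_or), tolerance = 1e-6)
  p_or <- if (is.infinite(or$d0)) 2 * pnorm(-abs(t_or)) else
    2 * pt(-abs(t_or), or$d0 + 3)
  expect_equal(res$p, unname(p_or), tolerance = 1e-6)
})

test_that("moderated p-values are uniform under the null", {
  set.seed(31)
  n <- 2000
  cnt <- 1 + rpois(n, 3)
  sdv <- 0.3 * (1 + 1 / cnt)
  ratios <- matrix(rnorm(n * 3, 0, rep(sdv, 3)), n, 3,
                   dimnames = list(paste0("P", 1:n), NULL))
  res <- countDependentModeration(ratios, setNames(cnt, rownames(ratios)))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("RBPome classification applies the sign, significance and hits
           rules, antisymmetrically", {
  res <- data.frame(protein = c("A", "B", "C", "D"),
                    mean_log2_ratio = c(-2, 1.5, -1, 0.2),
                    n_pairs = c(3, 3, 1, 3),
                    adj_p = c(0.001, 0.004, NA, 0.3))
  out <- classifyRbpome(res, alpha = 0.01)
  expect_equal(out$call, c("RBP", "enriched", "excluded", "not-significant"))

  # one observation in a condition -> excluded
  out2 <- classifyRbpome(res, alpha = 0.01,
                         hits_treated = c(A = 3, B = 3, C = 2, D = 1),
                         hits_untreated = c(A = 2, B = 2, C = 2, D = 3))
  expect_equal(out2$call[4], "excluded")

  # sign flip swaps RBP and enriched exactly
  flipped <- res; flipped$mean_log2_ratio <- -flipped$mean_log2_ratio
  outf <- classifyRbpome(flipped, alpha = 0.01)
  expect_equal(outf$call, c("enriched", "RBP", "excluded",
                            "not-significant"))
})

test_that("the full assay recovers planted RBPs on simulated data", {
  sim <- simulateRnaseAssay(rnaseSimConfig(n_proteins = 150, seed = 13))
  prep <- lapply(sim[c("treated", "untreated")], function(pq)
    summarizeProteins(aggregateModifiedPeptides(pq), min_peptides = 1L))
  res <- rnaseAssay(prep$treated, prep$untreated, sim$pairing)
  called <- rbpSet(res)
  truth_rbp <- sim$truth$protein[sim$truth$true_class == "RBP"]
  expect_gt(length(called), 0)
  expect_gt(mean(called %in% truth_rbp), 0.95)
  expect_gt(sum(called %in% truth_rbp) / length(truth_rbp), 0.85)
  # spike-in excluded from the result table
  expect_false("P00761" %in% res$protein)
})
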