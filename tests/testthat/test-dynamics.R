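test_that("phase model equals group means on balanced data", {
  m <- matrix(c(0, 0, 1, 1, 2, 2), 1, 6)
  ph <- rep(c("lag", "exponential", "stationary"), each = 2)
  fit <- fitPhaseModel(m, ph, reference = "lag")
  expect_equal(unname(fit$coef[1, ]), c(0, 1, 2))
  expect_equal(unname(fit$s2), 0)
  expect_equal(unname(fit$df), 3)

  # all values equal: zero contrasts
  fit0 <- fitPhaseModel(matrix(5, 1, 6), ph, reference = "lag")
  expect_equal(unname(fit0$coef[1, ]), c(0, 0, 0))

  # single replicate per phase: residual df 0, untestable
  fit1 <- fitPhaseModel(matrix(1:3, 1, 3), unique(ph), reference = "lag")
  expect_equal(unname(fit1$df), 0)
  expect_true(is.na(fit1$s2))
})

test_that("interaction contrast measures divergence of OOPS from total", {
  ph <- rep(c("exponential", "stationary"), each = 2)
  # parallel profiles: interaction 0
  tot <- matrix(c(0, 0, 1, 1), 1, 4, dimnames = list("P1", NULL))
  oop <- matrix(c(0, 0, 1, 1), 1, 4, dimnames = list("P1", NULL))
  fit <- fitInteractionModel(tot, oop, ph, ph)
  con <- interactionContrast(fit, "exponential", "stationary")
  expect_equal(con$estimate, 0)
  expect_equal(con$dT, 1); expect_equal(con$dO, 1)

  # total flat, OOPS shifts by 2: interaction 2
  oop2 <- matrix(c(0, 0, 2, 2), 1, 4, dimnames = list("P1", NULL))
  tot2 <- matrix(0, 1, 4, dimnames = list("P1", NULL))
  con2 <- interactionContrast(fitInteractionModel(tot2, oop2, ph, ph),
                              "exponential", "stationary")
  expect_equal(con2$estimate, 2)

  # permutation of samples leaves estimates unchanged
  o <- c(3, 1, 4, 2)
  con3 <- interactionContrast(
    fitInteractionModel(tot2[, o, drop = FALSE], oop2[, o, drop = FALSE],
                        ph[o], ph[o]),
    "exponential", "stationary")
  expect_equal(con3, con2)

  # invariance to protein-specific constants and to common phase profiles
  set.seed(2)
  tot4 <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), NULL))
  oop4 <- matrix(rnorm(8), 2, 4, dimnames = list(c("A", "B"), NULL))
  base <- interactionContrast(fitInteractionModel(tot4, oop4, ph, ph),
                              "exponential", "stationary")
  common <- c(0.3, 0.3, -1, -1)  # same phase profile in both extractions
  shifted <- interactionContrast(fitInteractionModel(
    tot4 + 5 + rep(common, each = 2), oop4 + 5 + rep(common, each = 2),
    ph, ph), "exponential", "stationary")
  expect_equal(shifted$estimate, base$estimate, tolerance = 1e-12)

  # a missing phase-by-type cell makes the contrast untestable
  oop5 <- matrix(c(0, 0, NA, NA), 1, 4, dimnames = list("P1", NULL))
  con5 <- interactionContrast(fitInteractionModel(tot2, oop5, ph, ph),
                              "exponential", "stationary")
  expect_true(is.na(con5$u))
})

test_that("dynamics classes follow the iii > ii > i hierarchy", {
  expect_equal(classifyDynamics(c(0.001, 0.5, 0.5, NA),
                                c(0.5, 0.001, 0.5, 0.5)),
               c("iii", "ii", "i", NA))
})

test_that("quadrants follow the sign convention with zero boundary", {
  expect_equal(assignQuadrant(c(1, -1, -1, 1, 0),
                              c(1, 1, -1, -1, 1)),
               c("Q1", "Q2", "Q3", "Q4", "none"))
  expect_true(is.na(assignQuadrant(NA, 1)))
})

test_that("profile patterns encode signed significant transitions", {
  est <- rbind(c(2, -2), c(1, 1), c(0.1, 0.2))
  adjp <- rbind(c(0.001, 0.001), c(0.5, 0.001), c(0.5, 0.5))
  expect_equal(profilePatterns(est, adjp), c("+,-", "0,+", "0,0"))
})

test_that("UPGMA with Pearson distance matches brute-force enumeration", {
  set.seed(9)
  m <- matrix(rnorm(48), 6, 8)
  rownames(m) <- paste0("P", 1:6)
  res <- hierarchicalCluster(m)
  D <- 1 - cor(t(m))
  expect_equal(sort(res$tree$height), sort(bruteUPGMA(D)),
               tolerance = 1e-12)

  # identical profiles merge first at distance 0
  m2 <- rbind(m[1, ], m[1, ], m[3:6, ])
  res2 <- hierarchicalCluster(m2)
  expect_equal(min(res2$tree$height), 0)

  # anti-correlated profiles sit at distance 2
  x <- rnorm(8)
  expect_equal(max(1 - cor(t(rbind(x, -x)))), 2)

  # per-row affine rescaling leaves the tree unchanged
  m3 <- m * 3 + 7
  expect_equal(hierarchicalCluster(m3)$tree$height, res$tree$height,
               tolerance = 1e-12)

  # constant rows are excluded with a warning
  m4 <- rbind(const = rep(1, 8), m)
  expect_warning(res4 <- hierarchicalCluster(m4), "constant")
  expect_equal(res4$excluded, "const")
})

test_that("simulated experiments recover planted classes and patterns", {
  out <- runSmallDynamics(n = 300, effect = 2, seed = 17)
  truth <- out$truth$true_class[match(out$dyn$protein, out$truth$protein)]
  ok <- !is.na(out$dyn$class)
  expect_gt(mean(out$dyn$class[ok] == truth[ok]), 0.95)

  # planted stationary shifts give (0,+) or (0,-) patterns for class ii
  cls_ii <- ok & truth == "ii"
  expect_gt(mean(out$dyn$pattern[cls_ii] %in% c("0,+", "0,-")), 0.9)
})

test_that("six planted transition patterns are recovered as groups", {
  set.seed(23)
  patterns <- list(c(0, 2, 2), c(0, -2, -2), c(0, 2, 0), c(0, -2, 0),
                   c(0, 0, 2), c(0, 0, -2))
  per <- 30
  ph <- rep(c("lag", "exponential", "stationary"), each = 4)
  m <- do.call(rbind, lapply(patterns, function(pp)
    matrix(rep(rep(pp, each = 4), per), per, 12, byrow = TRUE)))
  m <- m + matrix(rnorm(length(m), 0, 0.25), nrow(m))
  rownames(m) <- paste0("P", seq_len(nrow(m)))
  fit <- fitPhaseModel(m, ph, reference = "lag")
  tr <- list(c("lag", "exponential"), c("exponential", "stationary"))
  est <- sapply(tr, function(x) phaseContrast(fit, x[1], x[2])$estimate)
  adjp <- sapply(tr, function(x) {
    con <- phaseContrast(fit, x[1], x[2])
    eb <- ebayesModerate(fit$s2, fit$df)
    bhAdjust(moderatedTTest(con$estimate, con$u, eb$s2_post, eb$d0,
                            fit$df)$p)
  })
  pat <- profilePatterns(est, adjp)
  expected <- c("+,0", "-,0", "+,-", "-,+", "0,+", "0,-")
  truth <- rep(expected, each = per)
  expect_gte(mean(pat == truth), 0.95)
  expect_setequal(unique(pat[pat %in% expected]), expected)
})
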