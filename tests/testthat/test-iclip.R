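grFromDf <- function(df, strand = "+") {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               strand = strand)
  gr$name <- paste0("p", seq_len(nrow(df)))
  gr$score <- seq_len(nrow(df))
  gr
}

test_that("cross-link sites sit one base upstream of the read start", {
  # + strand read with 0-based start 100 -> site 99 (0-based)
  reads <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 130),
                                  strand = "+")
  s <- crosslinkSites(reads)
  expect_equal(GenomicRanges::start(s) - 1, 99)

  # - strand read over [100, 120) -> site 120 (0-based)
  readm <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 120),
                                  strand = "-")
  sm <- crosslinkSites(readm)
  expect_equal(GenomicRanges::start(sm) - 1, 120)

  # read starting at position 0 has no upstream base: dropped with a note
  read0 <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 30),
                                  strand = "+")
  expect_message(s0 <- crosslinkSites(read0), "dropped")
  expect_length(s0, 0)

  # counts accumulate per position
  reads3 <- GenomicRanges::GRanges("chr",
                                   IRanges::IRanges(c(101, 101, 201), 300),
                                   strand = "+")
  s3 <- crosslinkSites(reads3)
  expect_equal(s3$count, c(2L, 1L))
})

test_that("blacklisting removes any >= 1 bp overlap with half-open
           boundaries", {
  peaks <- grFromDf(data.frame(chrom = "chr", start = c(10, 10),
                               end = c(20, 20)))
  ctrl1 <- grFromDf(data.frame(chrom = "chr", start = 19, end = 30))
  expect_length(blacklistPeaks(peaks[1], ctrl1), 0)  # 1 bp overlap
  ctrl2 <- grFromDf(data.frame(chrom = "chr", start = 20, end = 30))
  expect_length(blacklistPeaks(peaks[1], ctrl2), 1)  # adjacent, kept
})

test_that("blacklisting agrees with the all-pairs oracle on random
           intervals", {
  q <- randomIntervals(500, seed = 31)
  s <- randomIntervals(300, seed = 32)
  kept <- blacklistPeaks(q$gr, s$gr)
  oracle_keep <- !bruteOverlapAny(q$df, s$df)
  expect_equal(kept$name, q$gr$name[oracle_keep])
})

test_that("reciprocal replicate intersection applies the fraction to both
           intervals", {
  # overlap 10 bp: 0.10 of a 100 bp peak but < 0.1 of a 210 bp peak
  a <- grFromDf(data.frame(chrom = "chr", start = 100, end = 200))
  b <- grFromDf(data.frame(chrom = "chr", start = 190, end = 400))
  out <- intersectReplicates(list(a, b), min_fraction = 0.1)
  expect_length(out$consensus, 0)
  # without reciprocity the anchor fraction alone suffices
  out_nr <- intersectReplicates(list(a, b), min_fraction = 0.1,
                                reciprocal = FALSE)
  expect_length(out_nr$consensus, 1)

  # 50 bp overlap of two 100 bp peaks: match
  a2 <- grFromDf(data.frame(chrom = "chr", start = 0, end = 100))
  b2 <- grFromDf(data.frame(chrom = "chr", start = 50, end = 150))
  out2 <- intersectReplicates(list(a2, b2), min_fraction = 0.1)
  expect_length(out2$consensus, 1)

  # identical peaks in all replicates are all retained
  out3 <- intersectReplicates(list(a2, a2, a2))
  expect_length(out3$consensus, 1)
  expect_error(intersectReplicates(list(a2)), "two replicates")
})

test_that("replicate intersection agrees with the literal bedtools-style
           oracle on random intervals", {
  lists_df <- lapply(1:3, function(i) randomIntervals(120, seed = 40 + i))
  out <- intersectReplicates(lapply(lists_df, `[[`, "gr"),
                             min_fraction = 0.1)
  keep <- bruteReciprocalKeep(lapply(lists_df, `[[`, "df"), f = 0.1)
  expect_equal(out$consensus$name, lists_df[[1]]$gr$name[keep])
})

test_that("peak summaries take medians of matched scores and sizes", {
  mk <- function(start, end, score) {
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(start + 1, end),
                                 strand = "+")
    gr$name <- "p"; gr$score <- score
    gr
  }
  reps <- list(mk(0, 100, 10), mk(10, 110, 20), mk(20, 120, 40))
  out <- summarizePeaks(intersectReplicates(reps))
  expect_equal(out$median_score, 20)
  expect_equal(out$median_size, 100)

  # even count: midpoint median
  reps2 <- list(mk(0, 4, 3), mk(0, 6, 5))
  out2 <- summarizePeaks(intersectReplicates(reps2))
  expect_equal(out2$median_size, 5)
  expect_equal(out2$median_score, 4)
})

test_that("target calling applies the strict log2 thresholds", {
  s <- data.frame(chrom = "chr", start = 0, end = 10,
                  name = c("a", "b", "c"),
                  median_score = c(40, 32, 100),
                  median_size = c(5, 4, 1), n_replicates = 3)
  out <- callTargets(s)
  expect_equal(out$name, "a")  # log2(40) > 5 and log2(5) > 2
  # log2(32) = 5 and log2(4) = 2 exactly: excluded by the strict rule
  expect_false("b" %in% out$name)
  expect_false("c" %in% out$name)
  s$median_score[2] <- -1
  expect_warning(callTargets(s), "non-positive")
})

test_that("biotype densities divide counts by merged genomic space", {
  ann <- GenomicRanges::GRanges("chr",
                                IRanges::IRanges(c(1, 1001), c(1000, 101000)))
  ann$biotype <- c("tRNA", "CDS")
  sites <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(5, 2000), width = 1),
                                  strand = "+")
  sites$count <- c(50L, 50L)
  d <- biotypeDensity(sites, ann)
  expect_equal(d$density[d$biotype == "tRNA"], 50 / 1000)
  expect_equal(d$density[d$biotype == "CDS"], 50 / 100000)

  # no cross-links: all densities zero
  d0 <- biotypeDensity(sites[0], ann)
  expect_true(all(d0$density == 0))

  # doubling the space halves the density
  ann2 <- c(ann, GenomicRanges::shift(ann, 200000))
  ann2$biotype <- rep(c("tRNA", "CDS"), 2)
  d2 <- biotypeDensity(sites, ann2)
  expect_equal(d2$density[d2$biotype == "tRNA"],
               d$density[d$biotype == "tRNA"] / 2)

  # report-time remapping of tRNA into intergenic
  dr <- biotypeDensity(sites, ann, remap = c(tRNA = "intergenic"))
  expect_true("intergenic" %in% dr$biotype)
  expect_false("tRNA" %in% dr$biotype)
  expect_error(biotypeDensity(sites, ann[0]), "empty annotation")
})

test_that("biotype assignment agrees with a containment oracle under
           priority", {
  set.seed(50)
  ann <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = seq(1, 2000, by = 100), width = 150))  # overlapping tiles
  ann$biotype <- rep(c("A", "B"), 10)
  pos <- sample.int(2500, 200)
  sites <- GenomicRanges::GRanges("chr", IRanges::IRanges(pos, width = 1),
                                  strand = "+")
  sites$count <- rep(1L, 200)
  d <- biotypeDensity(sites, ann, priority = c("A", "B"),
                      genome_size = 2500)
  # literal per-position assignment
  lab <- vapply(pos, function(p) {
    hit <- which(GenomicRanges::start(ann) <= p & GenomicRanges::end(ann) >= p)
    if (!length(hit)) return("unannotated")
    bts <- ann$biotype[hit]
    if ("A" %in% bts) "A" else "B"
  }, character(1))
  expect_equal(d$count[match(c("A", "B", "unannotated"), d$biotype)],
               unname(c(sum(lab == "A"), sum(lab == "B"),
                        sum(lab == "unannotated"))))
})

test_that("the iCLIP chain recovers planted targets and blacklisting
           commutes with intersection", {
  rec <- numeric(2)
  for (s in 1:2) {
    sim <- simulateIclip(iclipSimConfig(genome_length = 50000,
                                        n_true_targets = 10, seed = s))
    ctrl <- do.call(c, sim$control_peaks)
    bl_first <- intersectReplicates(lapply(sim$cl_peaks, blacklistPeaks,
                                           control_peaks = ctrl))
    int_first <- intersectReplicates(sim$cl_peaks)
    int_then_bl <- blacklistPeaks(int_first$consensus, ctrl)
    expect_equal(bl_first$consensus$name, int_then_bl$name)

    tg <- callTargets(summarizePeaks(bl_first))
    tgr <- GenomicRanges::GRanges(tg$chrom,
                                  IRanges::IRanges(tg$start + 1, tg$end))
    rec[s] <- mean(GenomicRanges::countOverlaps(sim$targets, tgr) > 0)
    # the control carries no signal, so no true target is blacklisted
    expect_false(any(GenomicRanges::countOverlaps(sim$targets, ctrl) > 0))
  }
  expect_gte(mean(rec), 0.9)
})
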