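.writeStage <- function(df, path, seed, params) {
  hash <- sum(utf8ToInt(paste(names(params), unlist(params),
                              collapse = ";"))) %% 100000L
  con <- file(path, "w")
  writeLines(sprintf("# rbpdyn %s | seed=%d | params=%05d",
                     as.character(packageVersion("rbpdyn")), seed, hash),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full simulated pipeline end to end
#'
#' Simulates a growth-phase proteomics experiment, an RNase-sensitivity
#' assay and an iCLIP experiment, runs every analysis stage (peptide
#' aggregation, robust summarisation, centre-median normalisation, RNase
#' RBP classification, dynamics classes/quadrants/patterns, enrichment on a
#' synthetic annotation, iCLIP blacklist/intersect/summarise/threshold), and
#' writes one tab-separated summary per stage plus a run manifest into
#' `output_dir`.  Every output carries a header with the package version,
#' seed and a parameter hash, so two runs with the same seed are
#' byte-identical.
#'
#' @param output_dir directory for the report files (created if needed).
#' @param seed global RNG seed; stage seeds are derived from it.
#' @param alpha significance level used by all classification stages
#'   (must be in (0, 1]).
#' @param n_proteins proteins in the simulated experiments.
#' @return Invisibly, a named list of the per-stage result objects.
#' @export
runDemo <- function(output_dir = tempfile("rbpdyn_demo"), seed = 1L,
                    alpha = 0.01, n_proteins = 300L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("invalid parameter 'alpha': must be in (0, 1]")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = seed, alpha = alpha, n_proteins = n_proteins)

  # dynamics stage
  sim <- simulateProteomeExperiment(proteomeSimConfig(
    n_proteins = n_proteins, seed = seed))
  prep <- lapply(sim[c("total", "oops")], function(pq)
    centreMedianNormalize(summarizeProteins(aggregateModifiedPeptides(pq))))
  dyn <- runDynamics(prep$total, prep$oops, alpha = alpha)
  .writeStage(dyn, file.path(output_dir, "dynamics.tsv"), seed, params)

  # RNase stage
  rsim <- simulateRnaseAssay(rnaseSimConfig(n_proteins = n_proteins,
                                            seed = seed + 1L))
  rprep <- lapply(rsim[c("treated", "untreated")], function(pq)
    summarizeProteins(aggregateModifiedPeptides(pq), min_peptides = 1L))
  rres <- rnaseAssay(rprep$treated, rprep$untreated, rsim$pairing,
                     spike_id = "P00761", alpha = alpha)
  .writeStage(rres, file.path(output_dir, "rnase.tsv"), seed, params)

  # enrichment stage: synthetic annotation marking true dynamic proteins
  truth <- sim$truth
  ann <- data.frame(protein = truth$protein,
                    term = ifelse(truth$true_class == "i", "static_term",
                                  "dynamic_term"))
  fg <- dyn$protein[!is.na(dyn$class) & dyn$class != "i"]
  enr <- fisherEnrichment(fg, dyn$protein, ann)
  .writeStage(enr, file.path(output_dir, "enrichment.tsv"), seed, params)

  # iCLIP stage
  isim <- simulateIclip(iclipSimConfig(seed = seed + 2L))
  peaks <- lapply(isim$cl_peaks, blacklistPeaks,
                  control_peaks = do.call(c, isim$control_peaks))
  cons <- intersectReplicates(peaks)
  summ <- summarizePeaks(cons)
  targets <- callTargets(summ)
  .writeStage(targets, file.path(output_dir, "iclip_targets.tsv"), seed,
              params)

  manifest <- data.frame(
    stage = c("dynamics", "rnase", "enrichment", "iclip"),
    n = c(nrow(dyn), nrow(rres), nrow(enr), nrow(targets)),
    seed = seed, alpha = alpha)
  .writeStage(manifest, file.path(output_dir, "manifest.tsv"), seed, params)
  invisible(list(dynamics = dyn, rnase = rres, enrichment = enr,
                 iclip_targets = targets, output_dir = output_dir))
}
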