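# Kyte-Doolittle hydropathy scale (J Mol Biol 157:105, 1982)
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

# Lehninger pKa set (termini from glycine; side chains as tabulated)
.PKA <- list(nTerm = 9.69, cTerm = 2.34,
             pos = c(K = 10.53, R = 12.48, H = 6.0),
             neg = c(D = 3.86, E = 4.25, C = 8.33, Y = 10.07))

#' Physicochemical properties of a protein sequence
#'
#' Computes the GRAVY score (mean Kyte-Doolittle hydropathy over the
#' sequence), the net charge at a given pH by Henderson-Hasselbalch with the
#' Lehninger pKa set including both termini, and the amino-acid frequency
#' vector (sums to 1).  Only the 20 standard amino acids are accepted.
#'
#' @param sequence a single amino-acid string, or an
#'   \link[Biostrings]{AAStringSet} / named character vector (then a
#'   data.frame is returned).
#' @param pH pH at which the net charge is evaluated (default 7.0).
#' @return For a single sequence: list with `gravy`, `net_charge`, and
#'   `aa_frequencies`.  For multiple sequences: data.frame with `gravy` and
#'   `net_charge` per sequence.
#' @examples
#' physchemProperties("AAKK")$gravy  # (1.8 + 1.8 - 3.9 - 3.9) / 4 = -1.05
#' @export
physchemProperties <- function(sequence, pH = 7.0) {
  if (methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  if (length(sequence) > 1L) {
    res <- lapply(sequence, physchemProperties, pH = pH)
    return(data.frame(id = if (is.null(names(sequence)))
      seq_along(sequence) else names(sequence),
      gravy = vapply(res, `[[`, 0, "gravy"),
      net_charge = vapply(res, `[[`, 0, "net_charge"),
      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(.KD))
  if (length(bad)) stop("non-standard amino acid: ", bad[1])
  counts <- table(factor(aa, levels = names(.KD)))
  freq <- as.numeric(counts) / length(aa)
  names(freq) <- names(.KD)
  pos <- 1 / (1 + 10^(pH - .PKA$nTerm)) +
    sum(counts[names(.PKA$pos)] / (1 + 10^(pH - .PKA$pos)))
  neg <- 1 / (1 + 10^(.PKA$cTerm - pH)) +
    sum(counts[names(.PKA$neg)] / (1 + 10^(.PKA$neg - pH)))
  list(gravy = mean(.KD[aa]), net_charge = pos - neg,
       aa_frequencies = freq)
}

#' Compare a property between two protein groups
#'
#' Tests equality of variances with the Brown-Forsythe test (median-centred
#' Levene test, via \code{car::leveneTest}), then compares means with a
#' pooled-variance t-test when the variances are compatible at
#' `var_alpha`, or Welch's t-test otherwise.
#'
#' @param values_a,values_b numeric vectors (>= 3 values each).
#' @param var_alpha significance level of the variance test deciding which
#'   t-test is used.
#' @return List with `levene_p`, `t_test` (`"pooled"` or `"welch"`),
#'   `t`, `df` and `p`.
#' @export
groupPropertyTest <- function(values_a, values_b, var_alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("need at least 3 values per group")
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      length(unique(c(values_a, values_b))) == 1L)
    return(list(levene_p = 1, t_test = "pooled", t = 0,
                df = length(values_a) + length(values_b) - 2, p = 1))
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  lev <- car::leveneTest(c(values_a, values_b) ~ g, center = median)
  lev_p <- lev[["Pr(>F)"]][1]
  welch <- !is.na(lev_p) && lev_p < var_alpha
  tt <- t.test(values_a, values_b, var.equal = !welch)
  list(levene_p = lev_p, t_test = if (welch) "welch" else "pooled",
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
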