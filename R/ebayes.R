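#' Invert the trigamma function by monotone bisection
#'
#' Solves \eqn{\psi'(y) = x} for \eqn{y > 0}.  The trigamma function is
#' strictly decreasing on the positive axis, so the root is unique and a
#' plain bisection is exact to the requested tolerance.
#'
#' @param x positive target value.
#' @param tol absolute tolerance on the solution.
#' @return The solution `y`; `Inf` when `x <= 0`.
#' @export
trigammaInverse <- function(x, tol = 1e-8) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    lo <- 1e-8
    hi <- 1
    while (trigamma(hi) > xi) hi <- hi * 2
    while (trigamma(lo) < xi) lo <- lo / 2
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > xi) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Empirical-Bayes moderation of sample variances
#'
#' Estimates the parameters of a scaled inverse-chi-squared prior on the true
#' residual variances from the observed sample variances `s2` with `df`
#' degrees of freedom, by the moment method on log variances: with
#' \eqn{e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)}, the prior df `d0`
#' solves \eqn{\psi'(d_0/2) = \mathrm{mean}[(e_g-\bar e)^2 n/(n-1) -
#' \psi'(d_g/2)]} (set to `Inf` when the right-hand side is non-positive) and
#' the prior variance is \eqn{s_0^2 = \exp(\bar e + \psi(d_0/2) -
#' \log(d_0/2))}.  Posterior (moderated) variances are
#' \eqn{(d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)}.
#'
#' When `covariate` is supplied (e.g. log2 peptide count), the prior mean
#' \eqn{\bar e} is replaced by a lowess trend of `e` on the covariate
#' (`span`), giving a covariate-specific prior variance: the moderation used
#' for peptide-count-dependent variance in the RNase assay.
#'
#' @param s2 numeric vector of sample variances (>= 0).
#' @param df residual degrees of freedom, scalar or vector.
#' @param covariate optional numeric covariate for a variance trend.
#' @param span lowess span for the trend fit.
#' @param prior optional list with fixed `d0` and `s02` (scalar or
#'   per-observation), bypassing estimation.
#' @return List with `d0`, `s02` (scalar, or vector when trended),
#'   `s2_post`, and `df_total = d0 + df`.
#' @export
ebayesModerate <- function(s2, df, covariate = NULL, span = 0.75,
                           prior = NULL) {
  n <- length(s2)
  if (any(s2 < 0, na.rm = TRUE)) stop("negative variance")
  df <- rep_len(df, n)
  if (any(df < 1)) stop("df must be >= 1")
  if (!is.null(prior)) {
    d0 <- prior$d0
    s02 <- rep_len(prior$s02, n)
  } else {
    s2f <- pmax(s2, 1e-12)
    if (any(s2 < 1e-12)) message("zero variances floored at 1e-12")
    z <- log(s2f)
    e <- z - digamma(df / 2) + log(df / 2)
    if (is.null(covariate) || n < 5L ||
        length(unique(covariate)) < 2L) {
      if (!is.null(covariate) && n < 5L)
        message("fewer than 5 observations: global prior used, trend skipped")
      efit <- rep(mean(e), n)
    } else {
      lo <- lowess(covariate, e, f = span)
      efit <- approx(lo$x, lo$y, xout = covariate, rule = 2, ties = mean)$y
    }
    r <- e - efit
    rhs <- mean(r^2 * n / (n - 1) - trigamma(df / 2))
    if (rhs <= 0) {
      # no excess dispersion beyond sampling noise: fixed-variance limit;
      # calibrate the level by the unbiased arithmetic mean of s2
      d0 <- Inf
      s02 <- exp(efit) * mean(s2) / mean(exp(efit))
    } else {
      d0 <- 2 * trigammaInverse(rhs)
      s02 <- exp(efit + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) rep_len(s02, n) else
    (d0 * rep_len(s02, n) + df * s2) / (d0 + df)
  list(d0 = d0,
       s02 = if (length(unique(s02)) == 1L) s02[1] else s02,
       s2_post = s2_post, df_total = d0 + df)
}

#' Moderated t-test
#'
#' Computes \eqn{t = \hat\beta / (u \, s_{post})} where `u` is the
#' unit-variance standard error of the estimate from the design (so that the
#' ordinary standard error is \eqn{u \cdot s}), and a two-sided p-value from
#' the t distribution with `d0 + df` degrees of freedom (standard normal when
#' `d0` is infinite).
#'
#' @param estimate effect estimate(s).
#' @param u unscaled standard error(s) from the design matrix.
#' @param s2_post moderated variance(s) from [ebayesModerate()].
#' @param d0 prior degrees of freedom.
#' @param df residual degrees of freedom.
#' @return data.frame with columns `t` and `p`.
#' @export
moderatedTTest <- function(estimate, u, s2_post, d0, df) {
  t <- estimate / (u * sqrt(s2_post))
  dft <- d0 + df
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df = dft)
  data.frame(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' \eqn{\tilde p_{(i)} = \min(1, \min_{j \ge i} p_{(j)} n / j)}, mapped back
#' to the input order.  Input p-values outside [0, 1] are rejected.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
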