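#' Satterthwaite scaled chi-squared null model for the smoothed statistic
#'
#' Under the null each local statistic `Y_j` is an F(mu, nu) variable with nu
#' large, so approximately `mu * Y_j ~ chi^2_mu`, giving `E[Y_j] = 1` and
#' `Var[Y_j] = 2/mu`. The weighted sum `S_KY` then has mean `S_K` and
#' variance `(2/mu) * S_KK`, and is modelled as `a * chi^2_b` with the scale
#' and degrees of freedom chosen to match those two moments:
#' `a = S_KK / (mu * S_K)` and `b = mu * S_K^2 / S_KK`. For an isolated site
#' (`S_K = S_KK = 1`) this reduces to `b = mu`, i.e. the unsmoothed
#' reference; `b` grows with local CpG density, reflecting the added support.
#'
#' @param S_K,S_KK per-site kernel sums from [smooth_sums()] (both >= the
#'   self weight, so > 0).
#' @param mu numerator degrees of freedom of the local statistic.
#' @return list of class `satterthwaite_fit` with per-site `a`, `b` and
#'   `expected = a * b` (the null mean of `S_KY`, equal to `S_K`).
#' @export
satterthwaite <- function(S_K, S_KK, mu) {
  if (any(S_K <= 0) || any(S_KK <= 0) || any(mu <= 0)) {
    stop("S_K, S_KK and mu must all be positive")
  }
  # guard against pathological S_KK ~ 0 relative to S_K^2
  S_KK <- pmax(S_KK, .Machine$double.eps * S_K^2)
  a <- S_KK / (mu * S_K)
  b <- mu * S_K^2 / S_KK
  structure(list(a = a, b = b, expected = a * b), class = "satterthwaite_fit")
}

#' Per-site P values from the scaled chi-squared model
#'
#' `P_i` is the upper-tail probability of `S_KY(i) / a_i` under a
#' chi-squared distribution with `b_i` (fractional) degrees of freedom.
#'
#' @param S_KY per-site smoothed statistics.
#' @param fit the matching [satterthwaite()] fit.
#' @return list of class `site_p` with `chi2_stat = S_KY / a` and `P`.
#' @export
site_pvalues <- function(S_KY, fit) {
  stopifnot(inherits(fit, "satterthwaite_fit"))
  if (length(S_KY) != length(fit$a)) {
    stop("S_KY must align with the Satterthwaite fit")
  }
  stat <- S_KY / fit$a
  p <- stats::pchisq(stat, df = fit$b, lower.tail = FALSE)
  structure(list(chi2_stat = stat, P = p), class = "site_p")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR correction applied genome-wide, in one family over
#' all sites at which the smoothed statistic is computed.
#'
#' @param P vector of P values in \[0, 1\].
#' @return adjusted P values `Q` in input order.
#' @export
bh_adjust <- function(P) {
  if (any(!is.finite(P)) || any(P < 0 | P > 1)) {
    stop("P values must lie in [0, 1]")
  }
  stats::p.adjust(P, method = "BH")
}
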