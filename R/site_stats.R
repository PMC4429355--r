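#' Describe the experimental design and analysis option
#'
#' Three analysis options are supported. `two_group` and `contrast` test a
#' difference in mean methylation (DMRs): each CpG site gets an
#' empirical-Bayes moderated t statistic whose square is the local statistic
#' `Y` with numerator df `mu = 1` and denominator df `nu = nu_star`.
#' `model_F` tests all non-intercept terms of the linear model jointly
#' (`Y = F`, `mu = d - 1`). `variability` targets variably methylated
#' regions (VMRs): `Y = V / Vbar` where `V` is the per-site (optionally
#' within-block pooled) variance of M values, with `mu = n - k` and an
#' infinite denominator df.
#'
#' @param design samples x d numeric model matrix (full column rank). For
#'   `two_group` it may be omitted and built from `group`.
#' @param contrast length-d numeric contrast vector (options `two_group` and
#'   `contrast`; for `two_group` with `group` it defaults to the
#'   treatment-minus-control coefficient).
#' @param option one of `"two_group"`, `"contrast"`, `"model_F"`,
#'   `"variability"`.
#' @param group two-level factor over samples (convenience for `two_group`;
#'   the second level is treated as "treatment").
#' @param block optional factor over samples with k < n levels
#'   (`variability` option only): variances are pooled within blocks.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(design = NULL, contrast = NULL,
                        option = c("two_group", "contrast", "model_F", "variability"),
                        group = NULL, block = NULL) {
  option <- match.arg(option)
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) != 2L) stop("'group' must have exactly two levels")
    if (is.null(design)) {
      design <- stats::model.matrix(~group)
      colnames(design) <- c("(Intercept)", paste0("group", levels(group)[2]))
      rownames(design) <- NULL
      if (is.null(contrast)) contrast <- c(0, 1)
    }
  }
  if (option != "variability") {
    if (is.null(design)) stop("a design matrix (or 'group') is required")
    design <- as.matrix(design)
    qr_x <- qr(design)
    if (qr_x$rank < ncol(design)) {
      bad <- colnames(design)[-(qr_x$pivot[seq_len(qr_x$rank)])]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    if (option %in% c("two_group", "contrast")) {
      if (is.null(contrast)) stop("a contrast vector is required for this option")
      contrast <- as.numeric(contrast)
      if (length(contrast) != ncol(design)) {
        stop("contrast length must equal the number of design columns")
      }
    }
  }
  if (!is.null(block)) {
    block <- as.factor(block)
    if (option != "variability") {
      stop("'block' is only used by the variability option")
    }
  }
  structure(list(design = design, contrast = contrast, option = option,
                 group = group, block = block),
            class = "design_spec")
}

trigamma_inverse <- function(x) {
  vapply(x, function(y) {
    if (!is.finite(y) || y <= 0) return(NaN)
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    z <- 0.5 + 1 / y
    for (i in 1:75) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / y) / psigamma(z, 2L)
      z <- z + dif
      if (abs(dif) < 1e-10 * z) break
    }
    z
  }, numeric(1))
}

# Empirical-Bayes hyperparameters of the scaled inverse-chi-squared prior on
# the per-site variances: moment/trigamma matching of log(s2) to a scaled-F
# distribution with (d_res, d0) df. Returns prior df d0 (possibly Inf) and
# prior variance s0^2.
estimate_variance_prior <- function(s2, d_res) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    stop("need at least two sites with positive residual variance ",
         "to estimate the variance prior")
  }
  z <- log(s2[ok])
  e <- z - digamma(d_res / 2) + log(d_res / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d_res / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Empirical-Bayes moderated linear-model fit per CpG site
#'
#' Fits the same linear model to every CpG site's M values by least squares,
#' shrinks the per-site residual variances towards a pooled prior estimated
#' from all sites, and computes moderated t statistics for the requested
#' contrast. The prior is a scaled inverse-chi-squared with df `d0` and scale
#' `s0^2`, estimated by matching the moments of `log(s2)` (trigamma
#' matching); the posterior variance is
#' `s2_tilde = (d0*s0^2 + d_res*s2) / (d0 + d_res)` and the moderated t has
#' `nu_star = d0 + d_res` degrees of freedom.
#'
#' @param m probes x samples matrix of M values.
#' @param spec a [design_spec()].
#' @param prior_df,prior_var optional overrides of the estimated (d0, s0^2);
#'   `prior_df = 0` reproduces the ordinary per-site OLS t, `prior_df = Inf`
#'   the fully pooled t.
#' @return list of class `site_stats` with per-site `t` (and `F` for the
#'   `model_F` option), `s2`, `s2_tilde`, `coef_contrast`, scalar `nu_star`,
#'   `d0`, `s0sq`, `d_res`.
#' @export
fit_moderated <- function(m, spec, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(spec, "design_spec"), is.matrix(m))
  if (spec$option == "variability") {
    stop("the variability option does not use a linear-model fit; ",
         "call site_statistic() directly")
  }
  x <- spec$design
  n <- ncol(m)
  if (nrow(x) != n) stop("design rows must match the number of samples")
  d <- ncol(x)
  d_res <- n - d
  if (d_res < 1L) stop("at least one residual degree of freedom is required")
  if (nrow(m) < 2L) stop("at least two sites are needed to estimate the variance prior")

  fit <- stats::lm.fit(x, t(m))
  coefs <- fit$coefficients              # d x p
  res <- fit$residuals                   # n x p
  s2 <- colSums(res^2) / d_res

  if (is.null(prior_df)) {
    pr <- estimate_variance_prior(s2, d_res)
    d0 <- pr$d0
    s0sq <- pr$s0sq
  } else {
    d0 <- prior_df
    s0sq <- if (is.null(prior_var)) mean(s2) else prior_var
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0sq, length(s2)) else {
    (d0 * s0sq + d_res * s2) / (d0 + d_res)
  }
  nu_star <- d0 + d_res

  xtxinv <- chol2inv(qr.R(qr(x)))
  out <- list(s2 = s2, s2_tilde = s2_tilde, d0 = d0, s0sq = s0sq,
              d_res = d_res, nu_star = nu_star, n = n, d = d)

  if (spec$option %in% c("two_group", "contrast")) {
    cc <- spec$contrast
    cbeta <- colSums(coefs * cc)
    u <- sqrt(drop(t(cc) %*% xtxinv %*% cc))
    t_stat <- cbeta / (sqrt(s2_tilde) * u)
    bad <- !is.finite(t_stat)
    if (any(bad)) {
      warning(sum(bad), " site(s) have undefined moderated t ",
              "(zero posterior variance); set to NA")
      t_stat[bad] <- NA_real_
    }
    out$t <- t_stat
    out$coef_contrast <- cbeta
  } else { # model_F: all non-intercept terms jointly
    rss1 <- colSums(res^2)
    mbar <- rowMeans(m)
    rss0 <- rowSums((m - mbar)^2)
    if (d < 2L) stop("model_F requires at least two design columns")
    out$F <- pmax(rss0 - rss1, 0) / ((d - 1) * s2_tilde)
  }
  class(out) <- "site_stats"
  out
}

#' Per-site local statistic Y and its degrees of freedom
#'
#' Maps the fitted per-site statistics to the nonnegative local statistic
#' `Y` smoothed downstream, together with the numerator df `mu` and the
#' denominator df `nu` of its null F reference:
#' * `two_group` / `contrast`: `Y = t^2`, `mu = 1`, `nu = nu_star`;
#' * `model_F`: `Y = F`, `mu = d - 1`, `nu = nu_star`;
#' * `variability`: `Y = V / Vbar` with `V` the per-site variance of M
#'   across samples (pooled within blocks if a block factor is given),
#'   `Vbar = mean(V)`, `mu = n - k`, `nu = Inf`. `mean(Y)` is exactly 1.
#'
#' @param stats a `site_stats` object from [fit_moderated()]
#'   (options other than `variability`), or the M-value matrix itself for
#'   the `variability` option.
#' @param spec a [design_spec()].
#' @return list of class `local_stats` with `Y`, `mu`, `nu` (and `V`,
#'   `Vbar` for the variability option; `nu_star` carried through otherwise).
#' @export
site_statistic <- function(stats, spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$option == "variability") {
    m <- stats
    stopifnot(is.matrix(m))
    n <- ncol(m)
    if (is.null(spec$block)) {
      k <- 1L
      v <- rowSums((m - rowMeans(m))^2) / (n - k)
    } else {
      block <- spec$block
      k <- nlevels(block)
      if (k >= n) stop("the block factor must have fewer levels than samples")
      ss <- 0
      for (lev in levels(block)) {
        cols <- which(block == lev)
        mg <- m[, cols, drop = FALSE]
        ss <- ss + rowSums((mg - rowMeans(mg))^2)
      }
      v <- ss / (n - k)
    }
    vbar <- mean(v)
    if (vbar == 0) stop("all per-site variances are zero (constant matrix)")
    out <- list(Y = v / vbar, mu = n - k, nu = Inf, V = v, Vbar = vbar)
  } else if (spec$option %in% c("two_group", "contrast")) {
    stopifnot(inherits(stats, "site_stats"))
    if (is.null(stats$t)) stop("moderated t statistics are not populated")
    out <- list(Y = stats$t^2, mu = 1, nu = stats$nu_star,
                nu_star = stats$nu_star, t = stats$t)
  } else { # model_F
    stopifnot(inherits(stats, "site_stats"))
    if (is.null(stats$F)) stop("model F statistics are not populated")
    out <- list(Y = stats$F, mu = stats$d - 1L, nu = stats$nu_star,
                nu_star = stats$nu_star)
  }
  class(out) <- "local_stats"
  out
}

#' Per-site beta fold change
#'
#' The signed difference in mean beta value implied by the contrast: the
#' contrast applied to the least-squares coefficients of beta on the design.
#' For a two-group design this is mean(beta | treatment) - mean(beta |
#' control). Used as an effect-size filter on called regions; the bounded
#' difference scale matches methylation proportions.
#'
#' @param beta probes x samples matrix of beta values.
#' @param spec a [design_spec()] with option `two_group` or `contrast`.
#' @return numeric vector of per-site beta differences.
#' @export
compute_betafc <- function(beta, spec) {
  stopifnot(inherits(spec, "design_spec"), is.matrix(beta))
  if (!spec$option %in% c("two_group", "contrast")) {
    stop("beta fold change is defined for the two_group and contrast options")
  }
  if (!is.null(spec$group)) {
    g <- spec$group
    if (any(table(g) == 0L)) stop("each group must contain at least one sample")
    trt <- levels(g)[2]
    ctl <- levels(g)[1]
    rowMeans(beta[, g == trt, drop = FALSE]) -
      rowMeans(beta[, g == ctl, drop = FALSE])
  } else {
    fit <- stats::lm.fit(spec$design, t(beta))
    colSums(fit$coefficients * spec$contrast)
  }
}
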