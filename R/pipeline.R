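#' Full region-calling pipeline
#'
#' Runs the complete chain on a filtered beta matrix: M transform, per-site
#' statistics for the chosen analysis option, Gaussian kernel smoothing of
#' the squared statistics per chromosome, Satterthwaite scaled chi-squared
#' P values, genome-wide BH correction, and agglomeration of significant
#' sites into ranked regions.
#'
#' @param beta probes x samples matrix of beta values in (0, 1) (clip before
#'   calling if needed), rownames = probe ids.
#' @param manifest a [as_manifest()] data frame covering every row of `beta`.
#' @param spec a [design_spec()].
#' @param lambda agglomeration bandwidth, bp (default 1000).
#' @param C kernel scale divisor (default 2, i.e. sigma = 500 bp).
#' @param q_threshold adjusted-P threshold for region calling (default 0.05).
#' @param betafc_min optional minimum absolute beta fold change a region must
#'   reach in at least one constituent CpG.
#' @param consecutive treat probes as equally spaced (index-space smoothing).
#' @return list of class `dmr_fit` with `sites` (per-site table: probe_id,
#'   chrom, pos, Y, S_KY, S_K, S_KK, a, b, expected, chi2_stat, P, Q,
#'   betafc, gene_assoc), `regions` (ranked [call_regions()] output) and
#'   `config` (lambda, C, sigma, q_threshold, betafc_min, option,
#'   consecutive, nu_star).
#' @export
dmr_pipeline <- function(beta, manifest, spec, lambda = 1000, C = 2,
                         q_threshold = 0.05, betafc_min = NULL,
                         consecutive = FALSE) {
  stopifnot(is.matrix(beta), inherits(spec, "design_spec"))
  if (!setequal(rownames(beta), manifest$probe_id)) {
    stop("beta rows and manifest probes must match; run filter_probes() first")
  }
  beta <- beta[manifest$probe_id, , drop = FALSE]
  if (!is.null(spec$design) && !is.null(rownames(spec$design)) &&
      !is.null(colnames(beta))) {
    bad <- which(rownames(spec$design) != colnames(beta))
    if (length(bad)) {
      stop("sample ids disagree between matrix and design: ",
           paste(colnames(beta)[bad], collapse = ", "))
    }
  }
  man_work <- if (consecutive) consecutive_positions(manifest) else manifest

  m <- beta_to_m(beta)
  if (spec$option == "variability") {
    local <- site_statistic(m, spec)
    nu_star <- Inf
    betafc <- rep(NA_real_, nrow(beta))
  } else {
    fitted <- fit_moderated(m, spec)
    local <- site_statistic(fitted, spec)
    nu_star <- fitted$nu_star
    betafc <- if (spec$option %in% c("two_group", "contrast")) {
      compute_betafc(beta, spec)
    } else rep(NA_real_, nrow(beta))
  }

  config <- kernel_config(lambda = lambda, C = C)
  y <- local$Y
  y[!is.finite(y)] <- 0   # sites excluded from modelling contribute no signal
  sm <- smooth_by_chrom(man_work, y, config)
  sat <- satterthwaite(sm$S_K, sm$S_KK, local$mu)
  sp <- site_pvalues(sm$S_KY, sat)
  q <- bh_adjust(sp$P)

  sites <- data.frame(
    probe_id = manifest$probe_id,
    chrom = manifest$chrom,
    pos = man_work$pos,
    genomic_pos = manifest$pos,
    Y = y, S_KY = sm$S_KY, S_K = sm$S_K, S_KK = sm$S_KK,
    a = sat$a, b = sat$b, expected = sat$expected,
    chi2_stat = sp$chi2_stat, P = sp$P, Q = q,
    betafc = betafc,
    gene_assoc = if (!is.null(manifest$gene_assoc)) manifest$gene_assoc else NA_character_,
    stringsAsFactors = FALSE
  )

  regions <- call_regions(sites, q_threshold = q_threshold, lambda = lambda)
  if (!is.null(betafc_min) && spec$option %in% c("two_group", "contrast")) {
    regions <- filter_regions_by_betafc(regions, betafc_min)
  }

  structure(list(
    sites = sites,
    regions = regions,
    config = list(lambda = lambda, C = C, sigma = config$sigma,
                  truncation_radius = config$truncation_radius,
                  q_threshold = q_threshold, betafc_min = betafc_min,
                  option = spec$option, consecutive = consecutive,
                  nu_star = nu_star, mu = local$mu)
  ), class = "dmr_fit")
}

#' @export
print.dmr_fit <- function(x, ...) {
  cat("Kernel-smoothed region fit\n")
  cat(sprintf("  option: %s   lambda: %g bp   sigma: %g bp\n",
              x$config$option, x$config$lambda, x$config$sigma))
  cat(sprintf("  sites: %d   regions at Q < %g: %d\n",
              nrow(x$sites), x$config$q_threshold, nrow(x$regions)))
  invisible(x)
}
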