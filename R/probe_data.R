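#' Probe manifest construction and validation
#'
#' A probe manifest is a data frame describing the genomic backbone of the
#' assay: one row per probe, with the interrogated CpG coordinate and any
#' quality annotations used by [filter_probes()]. Rows are sorted by
#' chromosome and position; positions must be strictly increasing within a
#' chromosome and probe ids unique.
#'
#' @param df data frame with at least `probe_id`, `chrom` and `pos`
#'   (1-based bp). Optional columns: `gene_assoc`, `island_assoc`,
#'   `snp_distance` (bp to nearest known SNP), `snp_maf`, `cross_reactive`
#'   (logical), `is_sex_chrom` (logical; derived from `chrom` when absent).
#' @return the validated, sorted manifest with class `probe_manifest`.
#' @export
as_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  }
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  if (anyDuplicated(df$probe_id)) stop("manifest probe_id values must be unique")
  if (any(!is.finite(df$pos)) || any(df$pos < 1)) {
    stop("manifest positions must be finite and >= 1")
  }
  if (is.null(df$is_sex_chrom)) {
    df$is_sex_chrom <- df$chrom %in% c("chrX", "chrY", "X", "Y")
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  dup <- unlist(lapply(split(df$pos, df$chrom), function(p) duplicated(p)))
  if (any(dup)) {
    stop("positions must be strictly increasing within a chromosome ",
         "(duplicated coordinates found)")
  }
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Beta / M value transforms
#'
#' Methylation proportions (beta values) are modelled on the logit2 scale:
#' `M = log2(beta / (1 - beta))`. The M scale is unbounded and closer to
#' homoscedastic, which suits linear modelling; beta stays in \[0, 1\] and is
#' the interpretable effect-size scale.
#'
#' @param beta numeric in (0, 1); vector or matrix.
#' @return M values of the same shape.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta values must lie strictly inside (0, 1); clip or filter first")
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m numeric M values.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Probe-level quality filters
#'
#' Drops probes whose measurements are unreliable or confounded before any
#' modelling: probes with a detection P value above `detection_p_max` in any
#' sample; probes whose target CpG lies within `snp_dist_max` nucleotides of
#' a known SNP with minor allele frequency above `snp_maf_min`; optionally
#' cross-reactive probes and probes on sex chromosomes. Filters are applied
#' in that order and each dropped probe is attributed to the first rule that
#' fires, so the per-filter counts always sum to the total dropped.
#'
#' Probes with no SNP annotation (`NA` in `snp_distance`/`snp_maf`) are
#' treated as having no nearby SNP and retained. Manifest rows without a
#' matching matrix row are ignored with a warning.
#'
#' @param beta probes x samples matrix of beta values, rownames = probe ids.
#' @param manifest a [as_manifest()] data frame covering every row of `beta`.
#' @param detection_p optional probes x samples matrix of detection P values,
#'   aligned with `beta`. Required if a detection filter is requested
#'   explicitly; if absent and `detection_p_max` is left at its default the
#'   detection filter is skipped.
#' @param detection_p_max per-sample detection P ceiling (default 0.05).
#' @param snp_dist_max maximum nucleotides to a known SNP (default 2).
#' @param snp_maf_min SNP minor allele frequency above which the SNP filter
#'   fires (default 0.05).
#' @param drop_cross_reactive drop probes flagged `cross_reactive`.
#' @param drop_sex_chroms drop probes on the X and Y chromosomes.
#' @return list with elements `beta`, `detection_p` (possibly NULL),
#'   `manifest` restricted to retained probes, and `drops`, a named integer
#'   vector of per-filter drop counts.
#' @export
filter_probes <- function(beta, manifest, detection_p = NULL,
                          detection_p_max = 0.05, snp_dist_max = 2,
                          snp_maf_min = 0.05, drop_cross_reactive = FALSE,
                          drop_sex_chroms = FALSE) {
  detection_requested <- !missing(detection_p_max) && !is.null(detection_p_max)
  stopifnot(is.matrix(beta))
  if (is.null(rownames(beta))) stop("beta matrix must carry probe ids as rownames")

  extra <- setdiff(manifest$probe_id, rownames(beta))
  if (length(extra)) {
    warning(length(extra), " manifest probe(s) absent from the matrix; ignored")
    manifest <- manifest[!manifest$probe_id %in% extra, , drop = FALSE]
  }
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes)) {
    stop("matrix rows not covered by the manifest: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  beta <- beta[manifest$probe_id, , drop = FALSE]
  if (!is.null(detection_p)) {
    if (is.null(rownames(detection_p))) {
      stop("detection_p matrix must carry probe ids as rownames")
    }
    detection_p <- detection_p[manifest$probe_id, , drop = FALSE]
  }

  n <- nrow(manifest)
  dropped_by <- rep(NA_character_, n)

  if (!is.null(detection_p_max)) {
    if (is.null(detection_p)) {
      if (detection_requested) {
        stop("detection-P filter requested but no detection_p matrix supplied")
      }
    } else {
      bad <- apply(detection_p > detection_p_max, 1L, any, na.rm = TRUE)
      dropped_by[bad & is.na(dropped_by)] <- "detection_p"
    }
  }

  sd <- manifest$snp_distance
  maf <- manifest$snp_maf
  if (!is.null(sd) && !is.null(maf)) {
    snp_bad <- !is.na(sd) & !is.na(maf) & sd <= snp_dist_max & maf > snp_maf_min
    dropped_by[snp_bad & is.na(dropped_by)] <- "snp"
  }

  if (drop_cross_reactive && !is.null(manifest$cross_reactive)) {
    xr <- !is.na(manifest$cross_reactive) & manifest$cross_reactive
    dropped_by[xr & is.na(dropped_by)] <- "cross_reactive"
  }

  if (drop_sex_chroms) {
    sx <- manifest$is_sex_chrom
    dropped_by[sx & is.na(dropped_by)] <- "sex_chrom"
  }

  keep <- is.na(dropped_by)
  drops <- c(
    detection_p = sum(dropped_by == "detection_p", na.rm = TRUE),
    snp = sum(dropped_by == "snp", na.rm = TRUE),
    cross_reactive = sum(dropped_by == "cross_reactive", na.rm = TRUE),
    sex_chrom = sum(dropped_by == "sex_chrom", na.rm = TRUE)
  )

  man_out <- manifest[keep, , drop = FALSE]
  rownames(man_out) <- NULL
  class(man_out) <- c("probe_manifest", "data.frame")
  list(
    beta = beta[keep, , drop = FALSE],
    detection_p = if (!is.null(detection_p)) detection_p[keep, , drop = FALSE],
    manifest = man_out,
    drops = drops
  )
}
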