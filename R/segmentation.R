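#' Agglomerate significant CpG sites into ranked regions
#'
#' Retains the sites whose adjusted P value is strictly below `q_threshold`
#' and, per chromosome, partitions them into maximal runs in which
#' consecutive sites are at most `lambda` bp apart. Each run becomes one
#' region spanning its first to its last constituent CpG (singletons are
#' permitted; no flanking padding is added). Regions are ranked by their
#' representative minimum adjusted P value, ties broken by descending
#' constituent count, then coordinate.
#'
#' @param sites data frame with columns `chrom`, `pos`, `Q` and optionally
#'   `probe_id`, `betafc`, `gene_assoc` (e.g. the per-site table from
#'   [dmr_pipeline()]).
#' @param q_threshold adjusted-P threshold (default 0.05; strict `<`).
#' @param lambda maximum merged gap in bp (default 1000).
#' @param annotate aggregate constituent probe ids and gene associations into
#'   the region table (default TRUE); disable when calling regions at many
#'   thresholds, e.g. while drawing a precision-recall curve.
#' @return data frame of class `dmr_regions` with columns `chrom`, `start`,
#'   `end`, `width`, `n_cpgs`, `min_q`, `max_betafc` (constituent betafc of
#'   largest magnitude, sign kept) and, when `annotate`, `gene_assocs`,
#'   `probe_ids`.
#' @export
call_regions <- function(sites, q_threshold = 0.05, lambda = 1000,
                         annotate = TRUE) {
  stopifnot(is.data.frame(sites), lambda > 0)
  req <- c("chrom", "pos", "Q")
  if (!all(req %in% names(sites))) {
    stop("'sites' must have columns: ", paste(req, collapse = ", "))
  }
  sig <- sites[!is.na(sites$Q) & sites$Q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    empty <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), width = numeric(0),
                        n_cpgs = integer(0), min_q = numeric(0),
                        max_betafc = numeric(0), gene_assocs = character(0),
                        probe_ids = character(0), stringsAsFactors = FALSE)
    class(empty) <- c("dmr_regions", "data.frame")
    return(empty)
  }

  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 diff(sig$pos) > lambda)
  rid <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(sig))

  # per-run minimum Q and largest-magnitude betafc via sorted deduplication
  oq <- order(rid, sig$Q)
  min_q <- sig$Q[oq][!duplicated(rid[oq])]
  if (!is.null(sig$betafc)) {
    ob <- order(rid, -abs(sig$betafc))
    max_betafc <- sig$betafc[ob][!duplicated(rid[ob])]
  } else {
    max_betafc <- rep(NA_real_, length(first))
  }

  regions <- data.frame(
    chrom = sig$chrom[first],
    start = sig$pos[first],
    end = sig$pos[last],
    width = sig$pos[last] - sig$pos[first] + 1,
    n_cpgs = last - first + 1L,
    min_q = min_q,
    max_betafc = max_betafc,
    stringsAsFactors = FALSE
  )
  if (annotate) {
    idx <- split(seq_len(nrow(sig)), rid)
    regions$gene_assocs <- if (!is.null(sig$gene_assoc)) {
      vapply(idx, function(i) {
        g <- unique(sig$gene_assoc[i])
        paste(g[!is.na(g) & g != ""], collapse = ";")
      }, character(1), USE.NAMES = FALSE)
    } else ""
    regions$probe_ids <- if (!is.null(sig$probe_id)) {
      vapply(idx, function(i) paste(sig$probe_id[i], collapse = ","),
             character(1), USE.NAMES = FALSE)
    } else ""
  }
  regions <- regions[order(regions$min_q, -regions$n_cpgs,
                           regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("dmr_regions", "data.frame")
  regions
}

#' Filter regions on effect size
#'
#' Keeps a region only if at least one constituent CpG has an absolute beta
#' fold change strictly greater than `min_abs_betafc`. Order is preserved.
#'
#' @param regions a [call_regions()] data frame (with `max_betafc`).
#' @param min_abs_betafc minimum absolute beta difference.
#' @return the retained regions.
#' @export
filter_regions_by_betafc <- function(regions, min_abs_betafc) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) == 0L) return(regions)
  if (is.null(regions$max_betafc) || all(is.na(regions$max_betafc))) {
    stop("regions do not carry beta fold changes")
  }
  keep <- !is.na(regions$max_betafc) & abs(regions$max_betafc) > min_abs_betafc
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replace genomic coordinates with consecutive ranks
#'
#' The consecutive option treats all assayed CpGs as equally spaced: the
#' i-th probe on each chromosome gets position `i * unit`. Downstream
#' smoothing and segmentation then operate in index space, which removes
#' spacing effects entirely (useful when probe density, not distance, should
#' drive region calls).
#'
#' @param manifest a sorted [as_manifest()] data frame.
#' @param unit spacing unit applied to the rank (default 1).
#' @return the manifest with `pos` replaced by rank order per chromosome.
#' @export
consecutive_positions <- function(manifest, unit = 1) {
  stopifnot(unit > 0)
  pos <- manifest$pos
  for (chrom in unique(manifest$chrom)) {
    idx <- which(manifest$chrom == chrom)
    pos[idx] <- seq_along(idx) * unit
  }
  manifest$pos <- pos
  manifest
}
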