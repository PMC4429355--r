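intervals_to_granges <- function(x) {
  if (is.null(x) || nrow(x) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(x$end < x$start)) stop("negative-width interval supplied")
  GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  ))
}

#' Nucleotide-resolution confusion counts
#'
#' Scores a set of called regions against ground-truth intervals at
#' single-nucleotide resolution: `tp` is the total width of their
#' intersection, `fp` the called width outside truth, `fn` the truth width
#' not called. Intervals within each set are unioned before scoring, so
#' overlapping calls are not double counted. True negatives are never
#' computed (genome size does not enter precision-recall statistics).
#'
#' @param called,truth data frames with columns `chrom`, `start`, `end`
#'   (1-based inclusive coordinates).
#' @return list of class `nt_confusion` with `tp`, `fp`, `fn`, `precision`,
#'   `recall` (NA when undefined).
#' @export
nt_confusion <- function(called, truth) {
  g_called <- intervals_to_granges(called)
  g_truth <- intervals_to_granges(truth)
  tp <- sum(GenomicRanges::width(GenomicRanges::intersect(g_called, g_truth)))
  called_w <- sum(GenomicRanges::width(g_called))
  truth_w <- sum(GenomicRanges::width(g_truth))
  fp <- called_w - tp
  fn <- truth_w - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ), class = "nt_confusion")
}

#' Titrate a threshold series over a score distribution
#'
#' Returns `n_points` thresholds spanning the observed score range (quantiles
#' of the score distribution), so that calls made at successive thresholds
#' sweep from (near) zero genomic coverage to maximal coverage. Duplicate
#' thresholds arising from tied scores are removed, order preserved.
#'
#' @param scores numeric scores (e.g. per-site adjusted P values).
#' @param n_points number of thresholds (default 200).
#' @return ordered numeric vector of thresholds.
#' @export
titrate_thresholds <- function(scores, n_points = 200) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no finite scores supplied")
  if (length(unique(scores)) == 1L) {
    warning("all scores identical; degenerate single-threshold series")
    return(unique(scores))
  }
  th <- unname(stats::quantile(scores, probs = seq(0, 1, length.out = n_points),
                               names = FALSE, type = 7))
  unique(th)
}

#' Precision-recall curve and AUCPR over a threshold series
#'
#' Evaluates the caller at every threshold, scores each call set against the
#' truth at nucleotide resolution, orders the points by recall and integrates
#' precision over the achieved recall range by the trapezoid rule. Points at
#' which nothing is called (undefined precision) are dropped; no
#' extrapolation to recall 0 or 1 is performed.
#'
#' @param caller function of one threshold returning a data frame of called
#'   intervals (`chrom`, `start`, `end`; possibly zero rows).
#' @param thresholds numeric thresholds, e.g. from [titrate_thresholds()].
#' @param truth nonempty data frame of ground-truth intervals.
#' @return list of class `pr_curve` with `points` (data frame: threshold,
#'   tp, fp, fn, precision, recall, ordered by recall), `aucpr` and
#'   `integration = "trapezoid"`.
#' @export
pr_curve <- function(caller, thresholds, truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("truth set must be nonempty")
  thresholds <- unique(thresholds)
  rows <- lapply(thresholds, function(th) {
    cf <- nt_confusion(caller(th), truth)
    data.frame(threshold = th, tp = cf$tp, fp = cf$fp, fn = cf$fn,
               precision = cf$precision, recall = cf$recall)
  })
  pts <- do.call(rbind, rows)
  pts <- pts[!is.na(pts$precision), , drop = FALSE]
  pts <- pts[order(pts$recall, pts$threshold), , drop = FALSE]
  rownames(pts) <- NULL
  aucpr <- if (nrow(pts) >= 2L) {
    dr <- diff(pts$recall)
    sum(dr * (pts$precision[-1] + pts$precision[-nrow(pts)]) / 2)
  } else 0
  structure(list(points = pts, aucpr = aucpr, integration = "trapezoid"),
            class = "pr_curve")
}

#' Position-shuffled null caller
#'
#' Relocates each region to a uniformly random start on its own chromosome,
#' preserving widths and per-chromosome counts. Serves as a spatial null
#' against which the pipeline's precision-recall performance is compared.
#'
#' @param regions data frame of intervals (`chrom`, `start`, `end`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return shuffled intervals with the same widths.
#' @export
shuffle_intervals <- function(regions, chrom_lengths) {
  if (nrow(regions) == 0L) return(regions)
  if (any(!regions$chrom %in% names(chrom_lengths))) {
    stop("all region chromosomes must appear in chrom_lengths")
  }
  w <- regions$end - regions$start + 1
  maxstart <- pmax(chrom_lengths[regions$chrom] - w + 1, 1)
  start <- floor(stats::runif(nrow(regions), 1, maxstart + 1))
  data.frame(chrom = regions$chrom, start = start, end = start + w - 1,
             stringsAsFactors = FALSE)
}
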