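# Readers and writers for the pipeline's external formats. All tabular
# formats are tab-separated text with a header row. Internal coordinates are
# 1-based inclusive; BED and BedGraph writers convert to 0-based half-open in
# one place.

#' Read / write a probe manifest
#' @param path file path (tab-separated, header: probe_id, chrom, pos,
#'   optional annotation columns).
#' @return a validated [as_manifest()] data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_manifest(df)
}

#' @rdname read_manifest
#' @param manifest the manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probes x samples numeric matrix
#'
#' First column = probe id, header row = sample ids. Used for beta and
#' detection-P matrices.
#' @param path file path.
#' @return numeric matrix with probe rownames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix
#' @param m matrix to write (rownames = probe ids).
#' @param id_col name of the first column in the file.
#' @export
write_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design matrix
#'
#' Tab-separated, first column = sample id, remaining columns numeric
#' covariates.
#' @param path file path.
#' @return numeric matrix with sample rownames.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  storage.mode(x) <- "double"
  x
}

#' Write / read per-site and region tables
#' @param x data frame to write.
#' @param path file path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export regions as BED
#'
#' Converts 1-based inclusive regions to 0-based half-open BED lines. The
#' name field is the rank (row order) and the score is `-log10(min_q)`
#' capped at 1000 (0 when `min_q` is unavailable).
#'
#' @param regions a [call_regions()] data frame or any interval table with
#'   `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  score <- if (!is.null(regions$min_q)) {
    pmin(-log10(pmax(regions$min_q, 1e-300)), 1000)
  } else rep(0, nrow(regions))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1,
                    end = regions$end,
                    name = seq_len(max(nrow(regions), 0)),
                    score = round(score, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the smoothed statistic as BedGraph
#'
#' Writes the per-site chi-squared statistic `S_KY / a` (or any per-site
#' value) as a single-nucleotide BedGraph track in 0-based half-open
#' coordinates.
#'
#' @param manifest probe manifest providing coordinates.
#' @param values per-site values aligned with the manifest.
#' @param path output path.
#' @param name track name.
#' @export
write_bedgraph <- function(manifest, values, path, name = "smoothed_stat") {
  stopifnot(length(values) == nrow(manifest))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  bg <- data.frame(chrom = manifest$chrom, start = manifest$pos - 1,
                   end = manifest$pos, value = signif(values, 6))
  utils::write.table(bg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a truth set as BED plus a side table
#'
#' @param truth the `truth` data frame from [simulate_dataset()].
#' @param bed_path BED output (0-based half-open).
#' @param table_path optional side table with direction and modes.
#' @export
write_truth <- function(truth, bed_path, table_path = NULL) {
  bed <- data.frame(chrom = truth$chrom, start = truth$start - 1,
                    end = truth$end, name = truth$cluster_id,
                    score = 0, strand = ifelse(truth$direction == "hyper", "+", "-"))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(table_path)) write_table_tsv(truth, table_path)
  invisible(bed_path)
}
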