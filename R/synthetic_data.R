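#' Specification of a synthetic reduced-representation manifest
#'
#' The synthetic methylome mimics the spatial structure of a methylation
#' array: tight promoter-like clusters of probes (candidate regions for
#' planting DMRs) interspersed with sparse background probes. Intra-cluster
#' gaps are short (2 bp minimum plus Poisson jitter); gaps between elements
#' (clusters or background probes) are exponential with a long mean, so most
#' clusters are well separated at the default 1 kb bandwidth while occasional
#' close neighbours occur, as on the real array.
#'
#' @param n_clusters number of promoter-like clusters.
#' @param cluster_size integer range (min, max) of probes per cluster.
#' @param cluster_gap_mean mean intra-cluster gap in bp (>= 2).
#' @param background_n number of isolated background probes.
#' @param background_gap_mean mean gap between consecutive elements, bp.
#' @param n_chrom number of autosomes to spread probes over.
#' @return list of class `manifest_spec`.
#' @export
manifest_spec <- function(n_clusters = 15000, cluster_size = c(10, 30),
                          cluster_gap_mean = 40, background_n = 185000,
                          background_gap_mean = 8000, n_chrom = 22) {
  stopifnot(n_clusters >= 1, length(cluster_size) == 2,
            cluster_size[1] >= 2, cluster_size[2] >= cluster_size[1],
            cluster_gap_mean >= 2, background_n >= 0,
            background_gap_mean > 0, n_chrom >= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_size = as.integer(cluster_size),
                 cluster_gap_mean = cluster_gap_mean,
                 background_n = as.integer(background_n),
                 background_gap_mean = background_gap_mean,
                 n_chrom = as.integer(n_chrom)),
            class = "manifest_spec")
}

#' Generate a synthetic probe manifest
#'
#' @param spec a [manifest_spec()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used. The same seed always yields an identical manifest.
#' @return a [as_manifest()] data frame with an extra `cluster_id` column
#'   (NA for background probes); cluster probes carry `island_assoc =
#'   "island"` and a synthetic `gene_assoc`.
#' @export
make_manifest <- function(spec = manifest_spec(), seed = NULL) {
  stopifnot(inherits(spec, "manifest_spec"))
  if (!is.null(seed)) set.seed(seed)

  # spread clusters and background probes over chromosomes
  cl_chrom <- sort(sample.int(spec$n_chrom, spec$n_clusters, replace = TRUE))
  bg_chrom <- sort(sample.int(spec$n_chrom, spec$background_n, replace = TRUE))
  size_range <- seq(spec$cluster_size[1], spec$cluster_size[2])
  cl_sizes <- size_range[sample.int(length(size_range), spec$n_clusters,
                                    replace = TRUE)]

  pieces <- vector("list", spec$n_chrom)
  cluster_counter <- 0L
  for (ch in seq_len(spec$n_chrom)) {
    sizes_c <- cl_sizes[cl_chrom == ch]
    ncl <- length(sizes_c)
    nbg <- sum(bg_chrom == ch)
    n_elem <- ncl + nbg
    if (n_elem == 0L) next
    # element layout: clusters and singleton background probes in random order
    sz <- c(sizes_c, rep(1L, nbg))
    elem_is_cluster <- c(rep(TRUE, ncl), rep(FALSE, nbg))
    ord <- sample.int(n_elem)
    sz <- sz[ord]
    elem_is_cluster <- elem_is_cluster[ord]

    total <- sum(sz)
    first_idx <- cumsum(c(1L, sz[-n_elem]))
    gaps <- 2 + stats::rpois(total, max(spec$cluster_gap_mean - 2, 0))
    gaps[first_idx] <- 1 + round(stats::rexp(n_elem, 1 / spec$background_gap_mean))
    pos <- cumsum(as.numeric(gaps))

    elem_id <- rep.int(seq_len(n_elem), sz)
    cl_num <- rep(NA_integer_, n_elem)
    cl_num[elem_is_cluster] <- cluster_counter + seq_len(ncl)
    cluster_counter <- cluster_counter + ncl
    cid <- cl_num[elem_id]

    pieces[[ch]] <- data.frame(
      chrom = sprintf("chr%d", ch),
      pos = pos,
      cluster_id = ifelse(is.na(cid), NA_character_, sprintf("CL%06d", cid)),
      island_assoc = ifelse(is.na(cid), "open_sea", "island"),
      gene_assoc = ifelse(is.na(cid), NA_character_, sprintf("GENE%06d", cid)),
      stringsAsFactors = FALSE
    )
  }
  man <- do.call(rbind, pieces)
  man$probe_id <- sprintf("cg%08d", seq_len(nrow(man)))
  man$is_sex_chrom <- FALSE
  man <- man[, c("probe_id", "chrom", "pos", "gene_assoc", "island_assoc",
                 "cluster_id", "is_sex_chrom")]
  n_cand <- length(unique(stats::na.omit(man$cluster_id)))
  if (n_cand < 1L) stop("manifest spec produced no candidate clusters")
  as_manifest(man)
}

#' Beta-distribution shape parameters from a mode
#'
#' Parameterises a beta distribution by its mode and a concentration
#' (sharpness) parameter: `alpha = mode * (concentration - 2) + 1`,
#' `beta = (1 - mode) * (concentration - 2) + 1`, so that
#' `(alpha - 1) / (alpha + beta - 2) = mode` exactly and larger
#' concentrations give tighter distributions.
#'
#' @param mode target mode in (0, 1).
#' @param concentration `alpha + beta` (> 2; the mode is undefined at or
#'   below 2).
#' @return list with vectors `alpha` and `beta`.
#' @export
mode_beta_params <- function(mode, concentration) {
  if (any(mode <= 0 | mode >= 1)) stop("mode must lie strictly in (0, 1)")
  if (any(concentration <= 2)) stop("concentration must exceed 2")
  list(alpha = mode * (concentration - 2) + 1,
       beta = (1 - mode) * (concentration - 2) + 1)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout: 10 control
#' vs 10 treatment samples, 2,162 promoter clusters planted as true DMRs
#' (half hypermethylated in treatment, half hypomethylated) with a group
#' mode difference of exactly 0.2 on the beta scale, two-mode background
#' (unmethylated mode 0.03, methylated mode 0.93) and all values clipped to
#' \[0.01, 0.99\].
#'
#' @param n_control,n_treat samples per group.
#' @param n_true_dmrs number of clusters planted as DMRs (must be even).
#' @param beta_diff group mode difference on the beta scale.
#' @param clip_low,clip_high final clipping bounds on beta.
#' @param background_modes length-2 vector: modes of the unmethylated and
#'   fully methylated background states.
#' @param background_meth_prob per-probe probability of the fully methylated
#'   background state.
#' @param concentration beta-distribution concentration (alpha + beta) used
#'   for all draws.
#' @param manifest_spec a [manifest_spec()] describing the probe backbone.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_control = 10, n_treat = 10,
                              n_true_dmrs = 2162, beta_diff = 0.2,
                              clip_low = 0.01, clip_high = 0.99,
                              background_modes = c(unmeth = 0.03, meth = 0.93),
                              background_meth_prob = 0.5,
                              concentration = 50,
                              manifest_spec = kdmr::manifest_spec()) {
  stopifnot(n_control >= 2, n_treat >= 2, n_true_dmrs >= 2,
            n_true_dmrs %% 2 == 0, beta_diff > 0, beta_diff < 1,
            clip_low < clip_high, clip_low > 0, clip_high < 1,
            length(background_modes) == 2,
            all(background_modes > 0 & background_modes < 1),
            background_meth_prob >= 0, background_meth_prob <= 1,
            concentration > 2)
  structure(list(n_control = as.integer(n_control),
                 n_treat = as.integer(n_treat),
                 n_true_dmrs = as.integer(n_true_dmrs),
                 beta_diff = beta_diff, clip_low = clip_low,
                 clip_high = clip_high, background_modes = background_modes,
                 background_meth_prob = background_meth_prob,
                 concentration = concentration,
                 manifest_spec = manifest_spec),
            class = "simulation_config")
}

#' Desk-scale simulation preset
#'
#' A reduced configuration (about 5e4 probes, 200 planted DMRs) preserving
#' every distributional feature of the full-scale default; intended for unit
#' tests and quick pipeline checks.
#'
#' @param ... overrides passed to [simulation_config()].
#' @export
desk_scale_config <- function(...) {
  simulation_config(
    n_true_dmrs = 200,
    manifest_spec = manifest_spec(n_clusters = 1500, cluster_size = c(8, 20),
                                  background_n = 29000),
    ...
  )
}

#' Simulate one methylation dataset with planted DMRs
#'
#' Selects `n_true_dmrs` clusters without replacement as true DMRs, half
#' hyper- and half hypomethylated in treatment. Each DMR gets a control-group
#' mode drawn uniformly over the values for which both group modes stay
#' inside (0, 1), and a treatment mode exactly `beta_diff` away in the
#' assigned direction; all samples of a group draw their beta values from the
#' beta distribution with that mode. Every other probe is assigned a
#' background state (unmethylated or fully methylated), identically
#' distributed in both groups. Betas are finally clipped to
#' \[`clip_low`, `clip_high`\].
#'
#' @param config a [simulation_config()].
#' @param manifest optional pre-built manifest; generated from
#'   `config$manifest_spec` when `NULL`.
#' @param seed optional integer seed; the same seed yields byte-identical
#'   output.
#' @return list with `beta` (probes x samples, dimnames set), `manifest`,
#'   `truth` (data frame: chrom, start, end, direction, control_mode,
#'   treat_mode, cluster_id), `group` (factor, levels control < treatment)
#'   and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), manifest = NULL,
                             seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(manifest)) manifest <- make_manifest(config$manifest_spec)
  if (is.null(manifest$cluster_id)) {
    stop("manifest carries no cluster_id column; candidate clusters unknown")
  }
  clusters <- unique(stats::na.omit(manifest$cluster_id))
  nd <- config$n_true_dmrs
  if (length(clusters) < nd) {
    stop("manifest has ", length(clusters), " candidate clusters but ",
         nd, " true DMRs were requested")
  }

  sel <- sample(clusters, nd)
  direction <- sample(rep(c("hyper", "hypo"), nd / 2))
  lo <- config$clip_low
  span_hi <- 1 - config$beta_diff - lo
  base <- stats::runif(nd, lo, span_hi)    # lower of the two modes
  control_mode <- ifelse(direction == "hyper", base, base + config$beta_diff)
  treat_mode <- ifelse(direction == "hyper", base + config$beta_diff, base)

  n_ctl <- config$n_control
  n_trt <- config$n_treat
  nc <- n_ctl + n_trt
  np <- nrow(manifest)
  beta <- matrix(NA_real_, np, nc)

  dmr_of <- match(manifest$cluster_id, sel)   # NA outside true DMRs
  in_dmr <- !is.na(dmr_of)

  # background probes: two-mode state, identical across groups
  nbg <- sum(!in_dmr)
  state_meth <- stats::rbinom(nbg, 1L, config$background_meth_prob) == 1L
  bg_mode <- ifelse(state_meth, config$background_modes[2],
                    config$background_modes[1])
  bp <- mode_beta_params(bg_mode, config$concentration)
  beta[!in_dmr, ] <- stats::rbeta(nbg * nc, bp$alpha, bp$beta)

  # DMR probes: group-specific modes shared across a DMR's probes
  ndp <- sum(in_dmr)
  cm <- control_mode[dmr_of[in_dmr]]
  tm <- treat_mode[dmr_of[in_dmr]]
  cp <- mode_beta_params(cm, config$concentration)
  tp <- mode_beta_params(tm, config$concentration)
  beta[in_dmr, seq_len(n_ctl)] <- stats::rbeta(ndp * n_ctl, cp$alpha, cp$beta)
  beta[in_dmr, n_ctl + seq_len(n_trt)] <- stats::rbeta(ndp * n_trt, tp$alpha, tp$beta)

  beta <- pmin(pmax(beta, config$clip_low), config$clip_high)
  dimnames(beta) <- list(manifest$probe_id,
                         c(sprintf("ctrl%02d", seq_len(n_ctl)),
                           sprintf("trt%02d", seq_len(n_trt))))

  # truth intervals span first-to-last probe of each selected cluster
  sel_rows <- manifest[in_dmr, c("chrom", "pos", "cluster_id")]
  agg_start <- tapply(sel_rows$pos, sel_rows$cluster_id, min)
  agg_end <- tapply(sel_rows$pos, sel_rows$cluster_id, max)
  agg_chrom <- tapply(sel_rows$chrom, sel_rows$cluster_id, `[`, 1L)
  idx <- match(sel, names(agg_start))
  truth <- data.frame(chrom = unname(agg_chrom[idx]),
                      start = unname(agg_start[idx]),
                      end = unname(agg_end[idx]),
                      direction = direction,
                      control_mode = control_mode,
                      treat_mode = treat_mode,
                      cluster_id = sel,
                      stringsAsFactors = FALSE)

  group <- factor(rep(c("control", "treatment"), c(n_ctl, n_trt)),
                  levels = c("control", "treatment"))
  list(beta = beta, manifest = manifest, truth = truth, group = group,
       config = config)
}
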