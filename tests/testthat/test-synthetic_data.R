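test_that("mode parameterisation of the beta distribution is exact", {
  p <- mode_beta_params(0.5, 6)
  expect_equal(p$alpha, 3)
  expect_equal(p$beta, 3)
  p2 <- mode_beta_params(0.2, 12)
  expect_equal(p2$alpha, 3)
  expect_equal(p2$beta, 9)
  expect_equal((p2$alpha - 1) / (p2$alpha + p2$beta - 2), 0.2)
  # identity holds across the parameter space
  modes <- seq(0.05, 0.95, by = 0.05)
  pr <- mode_beta_params(modes, 50)
  expect_equal((pr$alpha - 1) / (pr$alpha + pr$beta - 2), modes)
  expect_error(mode_beta_params(0.5, 2), "exceed 2")
  expect_error(mode_beta_params(1, 10), "strictly in")
})

test_that("synthetic manifests have clustered and background probes", {
  spec <- manifest_spec(n_clusters = 3, cluster_size = c(10, 10),
                        cluster_gap_mean = 2, background_n = 5, n_chrom = 1)
  man <- make_manifest(spec, seed = 5)
  expect_equal(sum(!is.na(man$cluster_id)), 30)
  expect_equal(sum(is.na(man$cluster_id)), 5)
  intra <- unlist(lapply(split(man$pos, man$cluster_id), diff))
  expect_true(all(intra >= 2))
  expect_true(all(diff(man$pos) > 0))

  # determinism
  man2 <- make_manifest(spec, seed = 5)
  expect_identical(man, man2)

  # default spec supports the default DMR count
  ds <- manifest_spec()
  expect_gte(ds$n_clusters, 2162)
})

test_that("the desk-scale generator honours the simulation contract", {
  cfg <- desk_scale_config()
  sim <- simulate_dataset(cfg, seed = 21)
  expect_equal(nrow(sim$truth), 200)
  expect_equal(as.integer(table(sim$truth$direction)), c(100, 100))
  expect_equal(abs(sim$truth$treat_mode - sim$truth$control_mode),
               rep(0.2, 200))
  expect_true(all(sim$truth$control_mode > 0 & sim$truth$control_mode < 1))
  expect_gte(min(sim$beta), 0.01)
  expect_lte(max(sim$beta), 0.99)
  expect_equal(ncol(sim$beta), 20)
  expect_equal(rownames(sim$beta), sim$manifest$probe_id)
  # hyper means treatment mode above control mode
  hyper <- sim$truth$direction == "hyper"
  expect_true(all(sim$truth$treat_mode[hyper] > sim$truth$control_mode[hyper]))
  expect_true(all(sim$truth$treat_mode[!hyper] < sim$truth$control_mode[!hyper]))
  # determinism
  sim2 <- simulate_dataset(cfg, seed = 21)
  expect_identical(sim$beta, sim2$beta)
  expect_identical(sim$truth, sim2$truth)
})

test_that("planted effects have the recorded direction at almost every probe", {
  sim <- simulate_dataset(desk_scale_config(), seed = 31)
  g <- sim$group
  diff_means <- rowMeans(sim$beta[, g == "treatment"]) -
    rowMeans(sim$beta[, g == "control"])
  in_dmr <- !is.na(sim$manifest$cluster_id) &
    sim$manifest$cluster_id %in% sim$truth$cluster_id
  dir_of <- sim$truth$direction[match(sim$manifest$cluster_id[in_dmr],
                                      sim$truth$cluster_id)]
  agree <- sign(diff_means[in_dmr]) == ifelse(dir_of == "hyper", 1, -1)
  expect_gte(mean(agree), 0.99)
})

test_that("outside truth intervals the group labels are exchangeable", {
  sim <- simulate_dataset(desk_scale_config(), seed = 41)
  out <- is.na(sim$manifest$cluster_id) |
    !(sim$manifest$cluster_id %in% sim$truth$cluster_id)
  # probes touching the clip bounds carry tied values, which break the
  # continuity assumption behind the uniform null of the KS test
  cfg <- desk_scale_config()
  clipped <- rowSums(sim$beta <= cfg$clip_low | sim$beta >= cfg$clip_high) > 0
  keep <- which(out & !clipped)
  idx <- keep[seq(1, length(keep), by = 10)]  # thin for speed
  m <- beta_to_m(sim$beta[idx, ])
  fit <- fit_moderated(m, design_spec(group = sim$group))
  p <- stats::pf(fit$t^2, 1, fit$nu_star, lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth intervals span their cluster's probes", {
  sim <- simulate_dataset(desk_scale_config(), seed = 51)
  man <- sim$manifest
  for (i in sample(nrow(sim$truth), 10)) {
    cl <- sim$truth$cluster_id[i]
    probes <- man[!is.na(man$cluster_id) & man$cluster_id == cl, ]
    expect_equal(sim$truth$start[i], min(probes$pos))
    expect_equal(sim$truth$end[i], max(probes$pos))
    expect_equal(sim$truth$chrom[i], probes$chrom[1])
  }
})

test_that("requesting more DMRs than clusters fails loudly", {
  spec <- manifest_spec(n_clusters = 4, cluster_size = c(5, 5),
                        background_n = 10, n_chrom = 1)
  man <- make_manifest(spec, seed = 6)
  cfg <- desk_scale_config()
  expect_error(simulate_dataset(cfg, manifest = man, seed = 1),
               "candidate clusters")
})
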