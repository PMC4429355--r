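fixture_m <- function(seed = 101, p = 60, n = 6) {
  set.seed(seed)
  matrix(rnorm(p * n, sd = sqrt(rchisq(p, 4) / 4)), p, n)
}

test_that("moderated t is zero when both groups are identical at a site", {
  m <- fixture_m()
  m[1, ] <- rep(c(1, 2, 3), 2)  # same values in both groups
  g <- factor(rep(c("ctl", "trt"), each = 3))
  fit <- fit_moderated(m, design_spec(group = g))
  expect_equal(fit$t[1], 0)
})

test_that("prior df limits recover the ordinary and fully pooled t", {
  m <- fixture_m()
  g <- factor(rep(c("ctl", "trt"), each = 3))
  spec <- design_spec(group = g)

  fit0 <- fit_moderated(m, spec, prior_df = 0)
  t_ols <- apply(m, 1, function(y) summary(stats::lm(y ~ g))$coefficients[2, 3])
  expect_equal(unname(fit0$t), unname(t_ols), tolerance = 1e-10)
  expect_equal(fit0$nu_star, 4)

  s2 <- apply(m, 1, function(y) sum(stats::lm(y ~ g)$residuals^2) / 4)
  fit_inf <- fit_moderated(m, spec, prior_df = Inf, prior_var = mean(s2))
  num <- rowMeans(m[, 4:6]) - rowMeans(m[, 1:3])
  t_pool <- num / sqrt(mean(s2) * (1 / 3 + 1 / 3))
  expect_equal(unname(fit_inf$t), unname(t_pool), tolerance = 1e-10)
})

test_that("estimated shrinkage matches a formula-by-formula posterior oracle", {
  m <- fixture_m(seed = 7)
  g <- factor(rep(c("ctl", "trt"), each = 3))
  fit <- fit_moderated(m, design_spec(group = g))

  # oracle: recompute every quantity from first principles on the fixture
  x <- cbind(1, as.integer(g) - 1)
  d_res <- ncol(m) - 2
  s2 <- apply(m, 1, function(y) sum(stats::lsfit(x, y, intercept = FALSE)$residuals^2)) / d_res
  e <- log(s2) - digamma(d_res / 2) + log(d_res / 2)
  evar <- stats::var(e) - trigamma(d_res / 2)
  # invert trigamma by a grid/uniroot, independent of the package's Newton step
  d0 <- 2 * stats::uniroot(function(z) trigamma(z) - evar,
                           lower = 1e-4, upper = 1e6, tol = 1e-12)$root
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2t <- (d0 * s0sq + d_res * s2) / (d0 + d_res)
  cvec <- c(0, 1)
  u <- sqrt(drop(t(cvec) %*% solve(crossprod(x)) %*% cvec))
  bhat <- apply(m, 1, function(y) sum(stats::lsfit(x, y, intercept = FALSE)$coefficients * cvec))
  t_oracle <- bhat / (sqrt(s2t) * u)

  expect_equal(fit$d0, d0, tolerance = 1e-6)
  expect_equal(unname(fit$t), unname(t_oracle), tolerance = 1e-6)
  expect_gte(fit$nu_star, d_res)  # shrinkage adds df
})

test_that("moderated fit agrees with limma as an independent oracle", {
  skip_if_not_installed("limma")
  m <- fixture_m(seed = 13, p = 300, n = 8)
  g <- factor(rep(c("ctl", "trt"), each = 4))
  fit <- fit_moderated(m, design_spec(group = g))
  lf <- limma::eBayes(limma::lmFit(m, stats::model.matrix(~g)))
  expect_equal(fit$d0, unname(lf$df.prior), tolerance = 1e-9)
  expect_equal(fit$s0sq, unname(lf$s2.prior), tolerance = 1e-9)
  expect_equal(unname(fit$t), unname(lf$t[, 2]), tolerance = 1e-9)
})

test_that("local statistics follow the analysis-option table", {
  m <- fixture_m()
  g <- factor(rep(c("ctl", "trt"), each = 3))
  spec <- design_spec(group = g)
  fit <- fit_moderated(m, spec)
  loc <- site_statistic(fit, spec)
  expect_equal(loc$Y, fit$t^2)
  expect_equal(loc$mu, 1)
  expect_equal(loc$nu, fit$nu_star)
  expect_true(all(loc$Y >= 0))

  # model_F: mu = d - 1 and for d = 2 the F equals t^2 with the same shrinkage
  spec_f <- design_spec(design = stats::model.matrix(~g), option = "model_F")
  fit_f <- fit_moderated(m, spec_f)
  loc_f <- site_statistic(fit_f, spec_f)
  expect_equal(loc_f$mu, 1)
  expect_equal(unname(loc_f$Y), unname(fit$t^2), tolerance = 1e-10)
})

test_that("variability option normalises variances to mean one", {
  m <- fixture_m(seed = 23, p = 80, n = 6)
  spec <- design_spec(option = "variability")
  loc <- site_statistic(m, spec)
  expect_equal(mean(loc$Y), 1)
  expect_equal(loc$mu, 5)   # n - k with k = 1
  expect_equal(loc$nu, Inf)
  expect_equal(loc$V, apply(m, 1, stats::var), tolerance = 1e-12)

  # all V equal -> all Y equal 1
  m_eq <- matrix(rep(c(-1, 0, 1, 1, 0, -1), 4), 4, 6, byrow = TRUE)
  loc_eq <- site_statistic(m_eq, spec)
  expect_equal(loc_eq$Y, rep(1, 4))

  # 2-level block over 6 samples: mu = n - k = 4, pooled within-block variance
  blk <- factor(rep(c("a", "b"), each = 3))
  spec_b <- design_spec(option = "variability", block = blk)
  loc_b <- site_statistic(m, spec_b)
  expect_equal(loc_b$mu, 4)
  v_pooled <- apply(m, 1, function(y) {
    (sum((y[1:3] - mean(y[1:3]))^2) + sum((y[4:6] - mean(y[4:6]))^2)) / 4
  })
  expect_equal(loc_b$V, v_pooled, tolerance = 1e-12)
  expect_error(site_statistic(m, design_spec(option = "variability",
                                             block = factor(1:6))),
               "fewer levels")
})

test_that("null t^2 follows its F(1, nu_star) reference", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    m <- matrix(rnorm(2000 * 10), 2000, 10)
    g <- factor(rep(c("ctl", "trt"), each = 5))
    fit <- fit_moderated(m, design_spec(group = g))
    ks <- suppressWarnings(
      stats::ks.test(fit$t^2, function(q) stats::pf(q, 1, fit$nu_star))
    )
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("beta fold change is the contrast on group beta means", {
  beta <- rbind(c(0.8, 0.8, 0.6, 0.6),
                c(0.5, 0.5, 0.5, 0.5),
                c(0.3, 0.5, 0.6, 0.8))
  rownames(beta) <- paste0("p", 1:3)
  g <- factor(rep(c("ctl", "trt"), each = 2))
  spec <- design_spec(group = g)
  bfc <- compute_betafc(beta, spec)
  expect_equal(unname(bfc),
               c(0.6 - 0.8, 0, mean(c(0.6, 0.8)) - mean(c(0.3, 0.5))))
  # same answer through the general design/contrast route
  spec_c <- design_spec(design = stats::model.matrix(~g), contrast = c(0, 1),
                        option = "contrast")
  expect_equal(unname(compute_betafc(beta, spec_c)), unname(bfc),
               tolerance = 1e-12)
})

test_that("degenerate designs are rejected with named columns", {
  x <- cbind(a = rep(1, 6), b = rep(1, 6))
  expect_error(design_spec(design = x, contrast = c(0, 1), option = "contrast"),
               "rank deficient")
  expect_error(design_spec(design = cbind(1, 0:5), contrast = c(0, 1, 1),
                           option = "contrast"),
               "contrast length")
})
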