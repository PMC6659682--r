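test_that("prior fit recovers known hyperparameters and degenerate limits", {
  set.seed(101)
  # homogeneous truth (no variance heterogeneity): s0^2 = 1, residual df 2
  v <- rchisq(10000, df = 2) / 2
  pr <- estimate_prior(v, df = 2)
  expect_lt(abs(pr$s0_squared - 1), 0.05)
  expect_true(is.infinite(pr$d0) || pr$d0 > 50)

  # heterogeneous truth: scaled inverse-chi-square prior with d0 = 4
  set.seed(102)
  sig2 <- 4 * 1 / rchisq(5000, df = 4)
  v2 <- sig2 * rchisq(5000, df = 2) / 2
  pr2 <- estimate_prior(v2, df = 2)
  expect_lt(abs(pr2$d0 - 4) / 4, 0.25)

  # two identical positive variances: zero spread limit
  pr3 <- estimate_prior(c(0.3, 0.3), df = 2)
  expect_identical(pr3$d0, Inf)
  expect_equal(pr3$s0_squared, 0.3)

  expect_error(estimate_prior(c(0, 0, 0), df = 2),
               class = "phosfx_degenerate_error")
})

test_that("prior fit matches limma's empirical-Bayes moment equations", {
  skip_if_not_installed("limma")
  set.seed(103)
  sig2 <- 4 * 0.25 / rchisq(2000, df = 4)
  v <- sig2 * rchisq(2000, df = 3) / 3
  pr <- estimate_prior(v, df = 3)
  sq <- limma::squeezeVar(v, df = 3)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_squared, sq$var.prior, tolerance = 1e-6)
  expect_equal((pr$d0 * pr$s0_squared + 3 * v) / (pr$d0 + 3), sq$var.post,
               tolerance = 1e-6)
})

test_that("moderated t matches its closed form, the ordinary t, and limits", {
  # d0 = 0 reduces to the ordinary one-sample t-test
  mt <- moderated_t(c(-1.2, -0.8, -1.0), d0 = 0, s0_squared = 1)
  tt <- t.test(c(-1.2, -0.8, -1.0))
  expect_equal(mt$t_mod, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(mt$t_mod, -8.6602540378, tolerance = 1e-9)
  expect_equal(mt$p, tt$p.value, tolerance = 1e-10)
  expect_equal(mt$df_total, 2)

  # zero-variance values: shrinkage target carries the whole posterior
  mz <- moderated_t(c(-1, -1, -1), d0 = 3, s0_squared = 0.09)
  expect_equal(mz$s2, 0)
  expect_equal(mz$s2_post, 3 * 0.09 / (3 + 2))
  expect_equal(mz$t_mod, -1 / sqrt(mz$s2_post / 3))

  # symmetric values: t = 0, p = 1
  ms <- moderated_t(c(-0.4, 0, 0.4), d0 = 2, s0_squared = 0.1)
  expect_equal(ms$t_mod, 0)
  expect_equal(ms$p, 1)

  # d0 = Inf: fully pooled variance, normal reference
  mi <- moderated_t(c(-0.5, -0.7, -0.6), d0 = Inf, s0_squared = 0.04)
  expect_equal(mi$t_mod, -0.6 / sqrt(0.04 / 3))
  expect_equal(mi$p, 2 * pnorm(-abs(mi$t_mod)))

  # n < 2: NA result
  expect_true(is.na(moderated_t(c(-1), 2, 0.1)$p))

  # 50 random small instances against an independent transcription
  set.seed(104)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    v <- rnorm(n, -0.5, 0.4)
    d0 <- sample(c(0.5, 2, 7, Inf), 1)
    s02 <- runif(1, 0.01, 0.5)
    a <- moderated_t(v, d0, s02)
    b <- transcribed_moderated_t(v, d0, s02)
    expect_equal(a$t_mod, b$t, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
    expect_equal(a$s2_post, b$s2_post, tolerance = 1e-10)
  }
})

test_that("moderated t posterior variance lies between s2 and the prior", {
  set.seed(105)
  for (i in 1:30) {
    v <- rnorm(3, 0, 0.3)
    d0 <- runif(1, 0.1, 10); s02 <- runif(1, 0.01, 0.5)
    mt <- moderated_t(v, d0, s02)
    expect_gte(mt$s2_post, min(mt$s2, s02) - 1e-12)
    expect_lte(mt$s2_post, max(mt$s2, s02) + 1e-12)
  }
})

test_that("BH adjustment equals the brute-force step-up and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 0)), class = "phosfx_input_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "phosfx_input_error")

  set.seed(106)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    p <- runif(n)
    if (i %% 3 == 0) p <- round(p, 1)  # force ties
    p[p == 0] <- 0.05
    adj <- bh_fdr(p)
    expect_equal(adj, brute_force_bh(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("moderated test pipeline agrees with limma's eBayes", {
  skip_if_not_installed("limma")
  sim <- simulate_experiment(sim_config(n_sites = 400L, missing_rate = 0,
                                        frac_class2 = 0, seed = 21L))
  norm <- normalize_sites(sim$sites, sim$proteins)
  res <- moderated_test(norm)
  res1 <- res[res$condition == "BRAFi", ]
  mat <- matrix(norm$log2fc[norm$condition == "BRAFi"], ncol = 3, byrow = TRUE,
                dimnames = list(unique(norm$site_id), NULL))
  fit <- limma::eBayes(limma::lmFit(mat, design = cbind(rep(1, 3))))
  ord <- match(res1$site_id, rownames(mat))
  expect_equal(res1$t_mod, fit$t[ord, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res1$p, fit$p.value[ord, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res1$fdr, p.adjust(fit$p.value[, 1], "BH")[ord],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("type-I error of the moderated test is nominal on null data", {
  # ~21000 null site-tests across three conditions
  sim <- simulate_experiment(sim_config(n_sites = 7000L, frac_shared = 0,
                                        frac_specific = 0, frac_orphan = 0,
                                        seed = 31L))
  norm <- normalize_sites(filter_class1(sim$sites)$kept, sim$proteins)
  res <- moderated_test(norm)
  p <- res$p[!is.na(res$p)]
  expect_gt(length(p), 17000)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("bait enrichment z-score follows (mean diff)/control sd with imputation", {
  expect_equal(bait_enrichment_z(c(10, 10, 10), c(1, 1.1, 0.9)), 90)
  expect_equal(bait_enrichment_z(c(1, 2), c(1.6, 1.4)), 0)  # equal means
  expect_error(bait_enrichment_z(c(5, 5), c(NA, NA)), class = "phosfx_input_error")
  # missing controls imputed at half the smallest observed intensity
  z <- bait_enrichment_z(c(10, 10), c(2, NA, 4))
  expect_equal(z, (10 - mean(c(2, 1, 4))) / sd(c(2, 1, 4)))
  expect_warning(zi <- bait_enrichment_z(c(5, 6), c(2, 2, 2)), "zero spread")
  expect_identical(zi, Inf)
})
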