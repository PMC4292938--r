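test_that("mean centering to a reference set zeroes the reference mean", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f", c("a", "b", "c")))
  expect_equal(unname(mean_center_to_reference(x, c("a", "b"))),
               matrix(c(-0.5, 0.5, 1.5), 1, 3))
  # constant feature centered to all samples vanishes; recentering idempotent
  y <- matrix(rnorm(12), 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  c1 <- mean_center_to_reference(y, LETTERS[1:4])
  expect_equal(unname(rowMeans(c1)), rep(0, 3))
  expect_equal(mean_center_to_reference(c1, LETTERS[1:4]), c1)
  expect_error(mean_center_to_reference(y, "nope"), "reference")
})

test_that("profiled REML matches lme4 on a crossed two-factor design", {
  skip_if_not_installed("lme4")
  dat <- make_signature_data(10, 5, sigma_b = 1, sigma_e = 0.5,
                             group_shift = 0.5, seed = 3)
  fit <- fit_signature_mixed_model(dat)
  lf <- lme4::lmer(value ~ probeset * group + (1 | sample_id), dat,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(fit$sigma2_random, vc[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, vc[2], tolerance = 1e-5)
  ord <- names(lme4::fixef(lf))
  expect_equal(unname(fit$beta[ord]), unname(lme4::fixef(lf)),
               tolerance = 1e-5)
  expect_true(fit$converged)
  # group F uses the whole-plot degrees of freedom (samples - groups)
  expect_equal(c(fit$group_f$df1, fit$group_f$df2), c(1, 18))
})

test_that("mixed model collapses to ordinary least squares when lambda -> 0", {
  # independent noise only: between-sample variation is below the residual
  # level, so the REML optimum sits at the lambda = 0 boundary
  found <- FALSE
  for (seed in 1:10) {
    dat <- make_signature_data(8, 4, sigma_b = 0, sigma_e = 1, seed = seed)
    fit <- fit_signature_mixed_model(dat)
    if (fit$lambda == 0) {
      ols <- stats::lm(value ~ probeset * group, dat)
      expect_equal(unname(fit$beta[names(stats::coef(ols))]),
                   unname(stats::coef(ols)), tolerance = 1e-4)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("mixed model recovers both variance components", {
  err_b <- err_e <- numeric(6)
  for (i in 1:6) {
    dat <- make_signature_data(20, 10, sigma_b = 1, sigma_e = 0.5,
                               group_shift = 0.5, seed = 200 + i)
    fit <- fit_signature_mixed_model(dat)
    err_b[i] <- fit$sigma2_random
    err_e[i] <- fit$sigma2_resid
  }
  expect_lt(abs(mean(err_b) - 1) / 1, 0.2)
  expect_lt(abs(mean(err_e) - 0.25) / 0.25, 0.2)
})

test_that("purely additive data give zero interaction estimates", {
  dat <- make_signature_data(5, 4, sigma_b = 0, sigma_e = 0,
                             group_shift = 1, seed = 9)
  fit <- fit_signature_mixed_model(dat)
  inter <- fit$beta[grepl(":", names(fit$beta))]
  expect_lt(max(abs(inter)), 1e-8)
})

test_that("per-probeset contrasts report calibrated folds and P-values", {
  # a known log2 difference of 1 is a fold of 2
  dat <- make_signature_data(6, 3, sigma_b = 0, sigma_e = 1e-4,
                             group_shift = 1, seed = 12)
  fit <- fit_signature_mixed_model(dat)
  ct <- per_probeset_contrast(fit, "ps02", c("case", "ref"))
  expect_equal(ct$log2_difference, 1, tolerance = 1e-3)
  expect_equal(ct$fold, 2, tolerance = 1e-3)

  # power simulation: true fold 2.5, n = 30/group, sigma = 0.5
  folds <- ps <- numeric(5)
  for (i in 1:5) {
    dat <- make_signature_data(30, 4, sigma_b = 0.25, sigma_e = 0.4,
                               group_shift = log2(2.5), seed = 300 + i)
    fit <- fit_signature_mixed_model(dat)
    ct <- per_probeset_contrast(fit, "ps01", c("case", "ref"))
    folds[i] <- ct$fold
    ps[i] <- ct$p
  }
  expect_true(all(folds > 2.0 & folds < 3.1))
  expect_true(all(ps < 0.05))
})

test_that("index-expression correlation matches the regression oracle", {
  # published-scale arithmetic: r = -0.35 with n = 896 gives F ~ 124.8
  n <- 896
  f <- 0.35^2 * (n - 2) / (1 - 0.35^2)
  expect_equal(f, 124.8, tolerance = 0.01)

  # perfectly linear decreasing data
  res <- index_expression_correlation(1:10, seq(30, 3, length.out = 10))
  expect_equal(res$r, -1)

  # random vectors agree with the lm/ANOVA oracle to 1e-8
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(10); y <- 0.4 * x + rnorm(10)
    res <- index_expression_correlation(x, y)
    an <- stats::anova(stats::lm(y ~ x))
    expect_equal(res$f, an$`F value`[1], tolerance = 1e-8)
    expect_equal(res$p, an$`Pr(>F)`[1], tolerance = 1e-8)
  }
  expect_true(index_expression_correlation(rep(1, 5), rnorm(5))$degenerate)
})

test_that("classical F identities hold across the three test routes", {
  set.seed(81)
  g1 <- rnorm(15); g2 <- rnorm(15, 0.6)
  f_anova <- one_way_anova(list(g1, g2))$f
  t_pooled <- t.test(g1, g2, var.equal = TRUE)$statistic
  f_cor <- index_expression_correlation(rep(c(0, 1), each = 15),
                                        c(g1, g2))$f
  expect_equal(f_anova, unname(t_pooled)^2, tolerance = 1e-10)
  expect_equal(f_anova, f_cor, tolerance = 1e-10)
})

test_that("signatures map across species through the ortholog table", {
  genes <- sprintf("gene%02d", 1:10)
  map <- data.frame(
    source_gene = rep(genes, times = c(3, 3, 3, 3, 3, 2, 2, 2, 2, 2)),
    target_probeset = sprintf("hs_ps%02d", 1:25))
  ss <- map_signature_across_species(genes, map)
  expect_equal(length(ss$probesets), 25)
  expect_equal(ss$unmapped, character(0))

  idmap <- data.frame(source_gene = c("a", "b"), target_probeset = c("a", "b"))
  expect_equal(map_signature_across_species(c("a", "b"), idmap)$probesets,
               c("a", "b"))
  ss2 <- map_signature_across_species(c("a", "zzz"), idmap)
  expect_equal(ss2$unmapped, "zzz")
})
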