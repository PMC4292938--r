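test_that("printed alignment records parse into 3 target + 7 flanking probes", {
  fx <- load_fixtures()
  al <- fx$probe_alignments
  expect_equal(nrow(al), 10)
  expect_equal(sum(al$exon_label == "Exon 12"), 3)
  expect_equal(sum(al$exon_label %in%
                     c("Exon 10", "Exon 11", "Exon 13", "Exon 14")), 7)
  expect_true(all(al$start <= al$end))
  expect_equal(al$start[al$probe_id == "HG-U133_PLUS_2:217422_S_AT_7"], 35836590)

  emap <- build_exon_map(al, "Exon 12")
  expect_equal(sum(emap$groups == "target"), 3)
  expect_equal(sum(emap$groups == "flanking"), 7)

  expect_equal(nrow(parse_probe_alignments(character())), 0)
  expect_error(parse_probe_alignments("probe_7 somewhere chr19"), "malformed")
  expect_error(build_exon_map(al[al$exon_label == "Exon 12", ], "Exon 12"),
               "flanking")
  expect_error(build_exon_map(al, "Exon 99"), "target exon")
})

test_that("median centering and the delta index follow the hand examples", {
  v <- c(4, 4, 4, 5, 5, 5, 5, 5, 5, 5)
  names(v) <- paste0("p", 1:10)
  centered <- median_center_sample(v)
  expect_equal(unname(centered), c(-1, -1, -1, rep(0, 7)))
  expect_equal(median(centered), 0)
  # shift invariance and the constant-vector case
  expect_equal(median_center_sample(v + 3.7), centered)
  cst <- setNames(rep(2, 5), paste0("p", 1:5))
  expect_equal(unname(median_center_sample(cst)), rep(0, 5))

  emap <- build_exon_map(
    data.frame(probe_id = paste0("p", 1:10),
               exon_label = c(rep("Exon 12", 3), rep("Exon 13", 7))),
    "Exon 12")
  expect_equal(compute_delta_index(centered, emap), -1)
  expect_equal(compute_delta_index(cst - 2, build_exon_map(
    data.frame(probe_id = paste0("p", 1:5),
               exon_label = c("Exon 12", "Exon 12", rep("Exon 13", 3))),
    "Exon 12")), 0)
  # swapping the target and flanking roles negates the index
  emap_sw <- build_exon_map(
    data.frame(probe_id = paste0("p", 1:10),
               exon_label = c(rep("Exon 12", 3), rep("Exon 13", 7))),
    "Exon 13")
  expect_equal(compute_delta_index(centered, emap_sw),
               -compute_delta_index(centered, emap))
  # an unlisted probe feeds the centering but neither group mean
  v11 <- c(v, p11 = 9)
  c11 <- median_center_sample(v11)
  expect_equal(compute_delta_index(c11, emap), -1)
})

test_that("index is shift invariant and responds linearly to target loss", {
  set.seed(31)
  probes <- paste0("p", 1:11)
  emap <- build_exon_map(
    data.frame(probe_id = probes[1:10],
               exon_label = c(rep("Exon 12", 3), rep("Exon 11", 7))),
    "Exon 12")
  x <- matrix(rnorm(11 * 6, 8, 1), 11, 6,
              dimnames = list(probes, paste0("s", 1:6)))
  idx <- exon_skip_index(x, emap)
  # adding a per-sample constant (array effect) leaves the index unchanged
  shifted <- sweep(x, 2, runif(6, -5, 5), `+`)
  expect_equal(exon_skip_index(shifted, emap), idx, tolerance = 1e-12)
  # with the median attained in the flanking group, lowering all target
  # probes by delta lowers the index by exactly delta
  y <- x
  y[1:3, ] <- y[1:3, ] + 10  # keep the 11-probe median among the flank
  delta <- 0.8
  y2 <- y
  y2[1:3, ] <- y2[1:3, ] - delta
  expect_equal(exon_skip_index(y2, emap),
               exon_skip_index(y, emap) - delta, tolerance = 1e-12)
})

test_that("reference interval is the t-based CI on the group mean", {
  ri <- reference_interval(c(1, 2, 3, 4))
  expect_equal(ri$mean, 2.5)
  expect_equal(ri$se, sd(c(1, 2, 3, 4)) / 2)
  expect_equal(ri$lower, 2.5 - qt(0.975, 3) * ri$se, tolerance = 1e-12)
  expect_equal(round(c(ri$lower, ri$upper), 3), c(0.446, 4.554))

  expect_warning(rc <- reference_interval(rep(2, 5)), "zero variance")
  expect_equal(c(rc$lower, rc$upper), c(2, 2))

  # a sample with mean 0.52 and SE 0.07 (n = 74) gives an interval that
  # brackets the published pediatric bounds (0.394, 0.655)
  set.seed(41)
  z <- as.numeric(scale(rnorm(74)))
  x <- 0.52 + z * 0.07 * sqrt(74)
  ri74 <- reference_interval(x)
  expect_equal(ri74$lower, 0.52 - qt(0.975, 73) * 0.07, tolerance = 1e-10)
  expect_lt(abs(ri74$lower - 0.394), 0.02)
  expect_lt(abs(ri74$upper - 0.655), 0.02)
  expect_error(reference_interval(1), "n >= 2")
})

test_that("incidence calling counts cases strictly below the lower bound", {
  ri <- reference_interval(c(1, 2, 3, 4))
  inc <- call_incidence(c(-1, 0.5, 2), ri)
  expect_equal(inc$n_below, 1)
  expect_equal(inc$incidence, 1 / 3, tolerance = 1e-12)
  expect_equal(inc$below_lower, c(TRUE, FALSE, FALSE))
  expect_true(inc$incidence_ci[1] <= inc$incidence &&
                inc$incidence <= inc$incidence_ci[2])
  # all cases above the interval: incidence 0; boundary value is not below
  expect_equal(call_incidence(c(5, 6, ri$lower), ri)$incidence, 0)
  expect_error(call_incidence(rep(NA_real_, 3), ri), "no cases")

  # monotone incidence: lowering the case mean never decreases incidence
  means <- c(0.3, 0.0, -0.3, -0.6)
  incs <- vapply(seq_along(means), function(i) {
    coh <- simulate_index_cohort(74, 0.52, 0.07, 200, means[i], 0.03,
                                 seed = 100)  # shared seed: shared noise
    call_incidence(coh$case, reference_interval(coh$reference))$incidence
  }, numeric(1))
  expect_true(all(diff(incs) >= 0))
})

test_that("one-way ANOVA matches the hand decomposition and t identity", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$f, 13.5, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  # F = t^2 for two groups
  set.seed(51)
  g1 <- rnorm(8); g2 <- rnorm(9, 0.5)
  f2 <- one_way_anova(list(g1, g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(f2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f2$p, tt$p.value, tolerance = 1e-10)

  # equal means, nonzero variance: small F, large P
  set.seed(52)
  h <- one_way_anova(list(rnorm(50), rnorm(50)))
  expect_lt(h$f, 4)
  expect_true(one_way_anova(list(c(1, 1), c(1, 1)))$degenerate)
  expect_error(one_way_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("Monte-Carlo Dunnett reduces to the t-test for two groups", {
  set.seed(61)
  ctl <- rnorm(12); trt <- rnorm(12, 0.7)
  dn <- dunnett_posthoc(list(control = ctl, treated = trt),
                        control_index = 1, n_mc = 2e5, seed = 99)
  pt_ref <- t.test(trt, ctl, var.equal = TRUE)$p.value
  expect_lt(abs(dn$p_adjusted - pt_ref), 3 * max(dn$mc_se, 1e-4))
  expect_equal(dn$estimate, mean(trt) - mean(ctl), tolerance = 1e-12)

  # degenerate constant groups
  dg <- dunnett_posthoc(list(a = c(1, 1), b = c(1, 1)), n_mc = 1000)
  expect_equal(dg$p_adjusted, 1)
  expect_error(dunnett_posthoc(list(rnorm(3), rnorm(3)), n_mc = 500),
               "n_mc")
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t quadrature", {
  skip_if_not_installed("multcomp")
  set.seed(62)
  groups <- list(control = rnorm(10), a = rnorm(10, 0.8), b = rnorm(10, -0.4))
  dn <- dunnett_posthoc(groups, control_index = 1, n_mc = 2e5, seed = 7)
  dat <- data.frame(y = unlist(groups),
                    g = factor(rep(names(groups), times = lengths(groups)),
                               levels = names(groups)))
  gl <- multcomp::glht(stats::aov(y ~ g, dat),
                       linfct = multcomp::mcp(g = "Dunnett"))
  p_ref <- summary(gl)$test$pvalues
  expect_lt(max(abs(dn$p_adjusted - p_ref)), 0.01)
})

test_that("pipeline on a skewed cohort separates groups with the right sign", {
  spec <- cohort_spec(n_reference = 40, n_case = 40,
                      skip_fraction_reference = list(mean = 0, concentration = Inf),
                      skip_fraction_case = list(mean = 0.9, concentration = Inf),
                      target_affinities = c(rep(2^0.52, 3), rep(1, 7), 1),
                      n_background_probesets = 60, seed = 71)
  res <- run_pipeline(spec)
  ref <- res$index[res$groups == "reference"]
  cs <- res$index[res$groups == "case"]
  expect_lt(mean(cs), mean(ref))  # cases lower: matches the sign convention
  expect_gt(oracle_auc(ref, cs), 0.9)
  # moderate skipping still separates, more weakly (single-draw probe
  # noise caps the attainable AUC; see the methods vignette)
  spec2 <- spec
  spec2$skip_fraction_case <- list(mean = 0.7, concentration = Inf)
  res2 <- run_pipeline(spec2)
  expect_gt(oracle_auc(res2$index[res2$groups == "reference"],
                       res2$index[res2$groups == "case"]), 0.8)
})

test_that("calibrated default cohort lands near the published group means", {
  res <- run_pipeline(default_cohort_spec(seed = 11))
  ref_mean <- mean(res$index[res$groups == "reference"])
  case_mean <- mean(res$index[res$groups == "case"])
  expect_lt(abs(ref_mean - 0.52), 0.3)
  expect_lt(abs(case_mean - (-0.15)), 0.3)
  expect_gt(res$incidence$incidence, 0.4)
  expect_lt(res$anova$p, 1e-4)
})
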