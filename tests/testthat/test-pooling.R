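test_that("inverse-variance fixed-effect pooling on the bundled studies", {
  eff <- fixture_effects("rs2808630", "recessive")
  pooled <- pool_fixed(eff)
  # metafor-verified values for the five studies (zero-cell arm corrected)
  expect_equal(pooled$or, 0.8654067, tolerance = 1e-6)
  expect_equal(pooled$ci_low, 0.6273, tolerance = 1e-4)
  expect_equal(pooled$ci_high, 1.1938, tolerance = 1e-4)
  expect_equal(pooled$method, "fixed_iv")
  expect_equal(pooled$k, 5L)
  expect_equal(pooled$se, 1 / sqrt(sum(1 / eff$variance)))
  expect_equal(pooled$heterogeneity$p_h, 0.8110, tolerance = 1e-3)
})

test_that("single effects and replicated effects pool as expected", {
  eff <- fixture_effects()[2, ]
  one <- pool_fixed(eff)
  expect_equal(one$log_or, eff$log_or)
  expect_equal(one$se^2, eff$variance)
  expect_true(is.na(one$heterogeneity$p_h))
  expect_equal(one$heterogeneity$df, 0L)

  k <- 4
  reps <- eff[rep(1, k), ]
  reps$study_id <- paste0("r", 1:k)
  many <- pool_fixed(reps)
  expect_equal(many$log_or, eff$log_or)
  expect_equal(many$se^2, eff$variance / k)
  expect_equal(many$heterogeneity$q_statistic, 0)
  expect_equal(many$heterogeneity$tau_squared, 0)
  expect_equal(many$heterogeneity$i_squared, 0)
})

test_that("Cochran's Q matches the chi-square oracle", {
  lung <- crp_studies("rs1417938")
  lung <- lung[lung$cancer_type == "Lung", ]
  eff <- estimate_effects(apply_continuity(collapse_counts(lung, "recessive")))
  h <- heterogeneity(eff)
  expect_equal(h$q_statistic, 0.3713, tolerance = 1e-3)
  expect_equal(h$df, 1L)
  expect_equal(h$p_h, pchisq(h$q_statistic, 1, lower.tail = FALSE))
  expect_equal(h$p_h, 0.5423, tolerance = 1e-3)

  # Q is invariant under study reordering
  h2 <- heterogeneity(fixture_effects()[c(3, 1, 5, 2, 4), ])
  expect_equal(h2$q_statistic, heterogeneity(fixture_effects())$q_statistic)
})

test_that("DerSimonian-Laird collapses to fixed when tau^2 = 0", {
  eff <- fixture_effects("rs2808630", "recessive")
  expect_equal(heterogeneity(eff)$tau_squared, 0)
  fx <- pool_fixed(eff)
  rd <- pool_random(eff)
  for (field in c("log_or", "se", "or", "ci_low", "ci_high", "weights")) {
    expect_equal(rd[[field]], fx[[field]])
  }
  expect_equal(rd$method, "random_dl")
})

test_that("random-effects pooling widens under real heterogeneity", {
  # two equal-variance effects at +/- x pool to zero under any tau^2
  eff <- effects_from_cells(c(40, 10), c(10, 40), c(20, 20), c(20, 20))
  expect_equal(eff$log_or[1], -eff$log_or[2])
  expect_equal(pool_random(eff)$log_or, 0, tolerance = 1e-12)
  expect_equal(pool_fixed(eff)$log_or, 0, tolerance = 1e-12)

  sim <- simulate_corpus(k = 30, n_cases = 2000, n_controls = 2000, p = 0.3,
                         psi_hom = 1.5, tau = 0.4, seed = 99)
  effs <- estimate_effects(apply_continuity(collapse_counts(sim, "recessive")))
  fx <- pool_fixed(effs)
  rd <- pool_random(effs)
  expect_gt(rd$heterogeneity$tau_squared, 0)
  expect_gt(rd$se, fx$se)
  expect_gt(rd$ci_high - rd$ci_low, fx$ci_high - fx$ci_low)
})

test_that("the heterogeneity-guided rule picks the reported model", {
  eff <- fixture_effects("rs2808630", "recessive")
  expect_equal(pool_auto(eff)$method, "fixed_iv")
  expect_equal(pool_auto(eff[1, ])$method, "fixed_iv")  # k = 1: always fixed

  het_eff <- effects_from_cells(c(55, 45), c(45, 55), c(45, 55), c(55, 45))
  ph <- heterogeneity(het_eff)$p_h
  expect_lt(ph, 0.05)
  expect_equal(pool_auto(het_eff)$method, "random_dl")
  # a stricter alpha keeps the fixed model
  expect_gt(ph, 0.001)
  expect_equal(pool_auto(het_eff, alpha_h = 0.001)$method, "fixed_iv")
})

test_that("Mantel-Haenszel pooling and its relation to inverse-variance", {
  tabs <- collapse_counts(crp_studies("rs2808630"), "recessive")
  single <- pool_mh(tabs[1, ])
  expect_equal(single$or, oracle_or(13, 162, 148, 1786), tolerance = 1e-9)

  # raw-count MH differs from IV in the second decimal on these studies
  raw <- pool_mh(tabs, correct = FALSE)
  expect_equal(raw$or, 0.85, tolerance = 0.005)
  # corrected MH reproduces the published pooled value
  corr <- pool_mh(tabs, correct = TRUE)
  expect_equal(corr$or, 0.86, tolerance = 0.005)
  expect_equal(corr$method, "fixed_mh")

  # homogeneous null tables pool to exactly 1
  null_tabs <- data.frame(study_id = c("n1", "n2", "n3"), model = "recessive",
                          a = c(10, 20, 40), b = c(30, 60, 120),
                          c = c(5, 10, 20), d = c(15, 30, 60),
                          continuity_applied = FALSE)
  expect_equal(pool_mh(null_tabs)$or, 1)

  big <- simulate_corpus(k = 5, n_cases = 1e5, n_controls = 1e5, p = 0.3,
                         psi_hom = 1.5, seed = 11)
  bt <- collapse_counts(big, "recessive")
  iv <- pool_fixed(estimate_effects(apply_continuity(bt)))
  expect_lt(abs(pool_mh(bt)$log_or - iv$log_or), 0.01)
})

test_that("pooled estimates stay inside the convex hull of study effects", {
  for (seed in c(3, 13, 31)) {
    sim <- simulate_corpus(k = 12, n_cases = c(100, 800),
                           n_controls = c(100, 800), p = c(0.15, 0.5),
                           psi_hom = 1.4, tau = 0.3, seed = seed)
    eff <- estimate_effects(apply_continuity(
      collapse_counts(sim, "recessive")))
    for (pooled in list(pool_fixed(eff), pool_random(eff),
                        pool_mh(collapse_counts(sim, "recessive")))) {
      expect_gte(pooled$log_or, min(eff$log_or) - 1e-9)
      expect_lte(pooled$log_or, max(eff$log_or) + 1e-9)
    }
  }
})

test_that("pooling rejects empty and mixed-model inputs", {
  eff <- fixture_effects()
  expect_error(pool_fixed(eff[0, ]), "at least one")
  mixed <- rbind(eff, fixture_effects("rs2808630", "dominant"))
  expect_error(pool_fixed(mixed), "one contrast model")
  expect_error(pool_mh(collapse_counts(crp_studies("rs2808630"),
                                       "recessive")[0, ]), "at least one")
})

test_that("fixed and random pooling agree with metafor", {
  skip_if_not_installed("metafor")
  sim <- simulate_corpus(k = 15, n_cases = 300, n_controls = 300, p = 0.25,
                         psi_hom = 1.6, tau = 0.25, seed = 5)
  eff <- estimate_effects(apply_continuity(collapse_counts(sim, "recessive")))
  fe <- metafor::rma(eff$log_or, eff$variance, method = "FE")
  dl <- metafor::rma(eff$log_or, eff$variance, method = "DL")
  expect_equal(pool_fixed(eff)$log_or, as.numeric(coef(fe)))
  expect_equal(pool_fixed(eff)$se, fe$se)
  expect_equal(pool_random(eff)$log_or, as.numeric(coef(dl)))
  expect_equal(pool_random(eff)$heterogeneity$tau_squared, dl$tau2)
  expect_equal(heterogeneity(eff)$q_statistic, fe$QE)
})
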