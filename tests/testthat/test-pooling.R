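test_that("Mantel-Haenszel pooling matches the brute-force oracle on toys", {
  tabs <- list(c(5, 2, 13, 16), c(55, 23, 49, 46), c(7, 11, 3, 9))
  corp <- make_corpus(rbind(c(2, 0, 5), c(23, 0, 55), c(11, 0, 7)),
                      rbind(c(16, 0, 13), c(46, 0, 49), c(9, 0, 3)))
  fit <- pool_fixed_mh(build_contrast(corp, "homozygote"))
  expect_equal(fit$or, oracle_mh_or(tabs), tolerance = 1e-12)
  # single study: pooled OR equals the study OR exactly
  one <- pool_fixed_mh(build_contrast(make_corpus(c(2, 0, 5), c(16, 0, 13)),
                                      "homozygote"))
  expect_equal(one$or, 5 * 16 / (2 * 13), tolerance = 1e-12)
  expect_equal(one$k, 1L)
})

test_that("MH reproduces the published two-study subgroup odds ratios", {
  # CHB codon 10, homozygote: Basturk (5,2,13,16) + Eskandari (55,23,49,46)
  chb <- make_corpus(rbind(c(2, 20, 5), c(23, 118, 55)),
                     rbind(c(16, 31, 13), c(46, 103, 49)))
  fit <- pool_fixed_mh(build_contrast(chb, "homozygote"))
  expect_near(fit$or, 2.33, 0.005, info = "CHB hom OR")
  expect_near(fit$ci_low, 1.28, 0.005, info = "CHB hom lo")
  expect_near(fit$ci_high, 4.22, 0.005, info = "CHB hom hi")
  # AIH codon 25: Paladino + Yousefi
  aih <- make_corpus(rbind(c(154, 15, 9), c(26, 7, 10)),
                     rbind(c(156, 32, 1), c(119, 17, 2)))
  expect_near(pool_fixed_mh(build_contrast(aih, "homozygote"))$or,
              14.73, 0.01, info = "AIH hom OR")
  expect_near(pool_fixed_mh(build_contrast(aih, "recessive"))$or,
              14.69, 0.01, info = "AIH rec OR")
})

test_that("inverse-variance FE pooling is a weighted mean and near-agrees with MH", {
  # identical effects pool to the common value
  corp <- make_corpus(rbind(c(20, 30, 10), c(20, 30, 10)),
                      rbind(c(25, 25, 10), c(25, 25, 10)))
  eff <- or_estimate(build_contrast(corp, "allele"))
  expect_equal(pool_fixed_iv(eff)$log_or, eff$log_or[1], tolerance = 1e-12)
  # two-study toy against hand-computed weighted mean
  eff2 <- data.frame(study_id = c("x", "y"), log_or = c(0.2, 0.8),
                     se = c(0.1, 0.4))
  w <- 1 / eff2$se^2
  expect_equal(pool_fixed_iv(eff2)$log_or,
               sum(w * eff2$log_or) / sum(w), tolerance = 1e-12)
  # MH and IV nearly agree on the CHB pair (independent estimators)
  chb <- make_corpus(rbind(c(2, 20, 5), c(23, 118, 55)),
                     rbind(c(16, 31, 13), c(46, 103, 49)))
  tab <- build_contrast(chb, "homozygote")
  expect_equal(pool_fixed_iv(or_estimate(tab))$or, pool_fixed_mh(tab)$or,
               tolerance = 0.01)
})

test_that("heterogeneity statistics match direct evaluation of the formulas", {
  y <- c(0.1, 0.5, -0.2); v <- c(0.04, 0.09, 0.02)
  eff <- data.frame(study_id = letters[1:3], log_or = y, se = sqrt(v))
  het <- heterogeneity(eff)
  o <- oracle_q_tau(y, v)
  expect_equal(het$q, o$q, tolerance = 1e-12)
  expect_equal(het$tau2, o$tau2, tolerance = 1e-12)
  expect_equal(het$p_het, pchisq(o$q, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(het$i2, max(0, (o$q - 2) / o$q) * 100, tolerance = 1e-12)
  # identical effects: no heterogeneity
  eff0 <- data.frame(study_id = c("a", "b"), log_or = c(0.3, 0.3),
                     se = c(0.1, 0.1))
  het0 <- heterogeneity(eff0)
  expect_equal(het0$q, 0)
  expect_equal(het0$i2, 0)
  expect_equal(het0$tau2, 0)
  # k = 1 conventions
  het1 <- heterogeneity(eff0[1, ])
  expect_equal(het1$p_het, 1)
  expect_equal(het1$tau2, 0)
})

test_that("published heterogeneity columns are reproduced", {
  fit509 <- meta_analyze(load_fixture("tgfb1_509"), "allele")
  expect_near(fit509$het$i2, 78, 0.5, info = "-509 allele I2")  # printed 78%
  fit10 <- meta_analyze(load_fixture("tgfb1_codon10"), "allele")
  expect_near(fit10$het$i2, 18, 0.5, info = "codon-10 allele I2")  # printed 18%
  expect_near(fit10$het$p_het, 0.27, 0.01, info = "codon-10 allele p_het")
})

test_that("DerSimonian-Laird reduces to FE-IV when tau2 = 0 and widens otherwise", {
  eff0 <- data.frame(study_id = c("a", "b", "c"),
                     log_or = c(0.3, 0.3, 0.3), se = c(0.1, 0.2, 0.3))
  dl <- pool_random_dl(eff0)
  iv <- pool_fixed_iv(eff0)
  expect_equal(dl$het$tau2, 0)
  expect_equal(dl$log_or, iv$log_or, tolerance = 1e-14)
  expect_equal(dl$se, iv$se, tolerance = 1e-14)
  # heterogeneous effects: RE interval at least as wide as FE-IV
  effh <- data.frame(study_id = letters[1:4],
                     log_or = c(-0.5, 0.1, 0.6, 1.2),
                     se = c(0.15, 0.2, 0.1, 0.25))
  expect_gte(pool_random_dl(effh)$se, pool_fixed_iv(effh)$se)
})

test_that("MH pooled OR lies between the extreme study ORs", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    corp <- simulate_corpus(synthetic_config(
      k = k, q = 0.4, or_het = 1.3, or_hom = 1.7, tau2 = 0.1,
      n_case_range = c(50, 200), n_control_range = c(50, 200),
      seed = 5000 + rep))
    tab <- build_contrast(corp, "allele")
    fit <- pool_fixed_mh(tab)
    ors <- or_estimate(tab, continuity = 0)$or
    expect_gte(fit$or, min(ors) - 1e-12)
    expect_lte(fit$or, max(ors) + 1e-12)
  }
})

test_that("model selection follows the heterogeneity rule with RE at boundaries", {
  mk <- function(p_het, i2) {
    structure(list(q = 1, df = 1L, p_het = p_het, i2 = i2, tau2 = 0, k = 2L),
              class = "heterogeneity")
  }
  expect_equal(select_model(mk(1e-6, 78)), "RE")
  expect_equal(select_model(mk(0.27, 18)), "FE")
  expect_equal(select_model(mk(0.5, 50)), "RE")   # I2 boundary
  expect_equal(select_model(mk(0.1, 10)), "RE")   # p_het boundary
  expect_equal(select_model(mk(0.11, 49.9)), "FE")
})

test_that("meta_analyze orchestrates filter, contrast, selection and pooling", {
  fit <- meta_analyze(load_fixture("tgfb1_509"), "allele")
  expect_s3_class(fit, "meta_or")
  expect_equal(fit$k, 17L)
  expect_equal(fit$model, "RE-DL")
  expect_near(fit$or, 1.25, 0.01, info = "-509 allele OR")
  expect_equal(fit$n_case, 2611L)
  expect_equal(fit$n_control, 3387L)

  fit10 <- meta_analyze(load_fixture("tgfb1_codon10"), "homozygote")
  expect_equal(fit10$model, "FE-MH")
  expect_equal(fit10$k, 13L)
  expect_near(fit10$or, 1.28, 0.01, info = "codon-10 hom OR")

  # codon 25 homozygote: double-zero studies drop 19 -> 14
  fit25 <- meta_analyze(load_fixture("tgfb1_codon25"), "homozygote")
  expect_equal(fit25$k, 14L)
  expect_setequal(fit25$dropped,
                  c("Falleti 2008", "Maria 2013", "Sanchez-Parada 2013",
                    "Zein 2004 Caucasian", "Zein 2004 Egyptian"))

  # forcing the model overrides selection
  expect_equal(meta_analyze(load_fixture("tgfb1_509"), "allele",
                            model = "fe")$model, "FE-MH")
  # empty post-filter corpus errors with the stage name
  mono <- make_corpus(c(5, 5, 5), c(30, 1, 10))  # control far from HWE
  expect_error(meta_analyze(mono, "allele"), "hwe_filter")
})

test_that("pooling agrees with metafor as an independent implementation", {
  skip_if_not_installed("metafor")
  fit <- meta_analyze(load_fixture("tgfb1_509"), "allele")
  eff <- fit$effects
  ref <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
  expect_equal(fit$log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(fit$het$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(fit$het$q, ref$QE, tolerance = 1e-10)
  expect_equal(fit$het$i2, ref$I2, tolerance = 1e-6)

  fit10 <- meta_analyze(load_fixture("tgfb1_codon10"), "allele")
  tab10 <- build_contrast(
    apply_hwe_filter(load_fixture("tgfb1_codon10"))$retained, "allele")
  ref_mh <- metafor::rma.mh(ai = tab10$a, bi = tab10$b, ci = tab10$c,
                            di = tab10$d, correct = FALSE)
  expect_equal(fit10$log_or, as.numeric(ref_mh$beta), tolerance = 1e-10)
  expect_equal(fit10$se, ref_mh$se, tolerance = 1e-10)
})

test_that("fit methods expose the estimate coherently", {
  fit <- meta_analyze(load_fixture("tgfb1_codon10"), "recessive")
  expect_equal(unname(coef(fit)), fit$log_or)
  ci <- confint(fit)
  expect_equal(exp(ci[1, 1]), fit$ci_low, tolerance = 1e-10)
  expect_equal(exp(ci[1, 2]), fit$ci_high, tolerance = 1e-10)
  r <- residuals(fit)
  expect_equal(length(r), fit$k)
  expect_equal(unname(r), fit$effects$log_or - fit$log_or)
  expect_output(print(fit), "Pooled odds ratio")
  expect_output(summary(fit), "Per-study effects")
  fd <- forest_data(fit)
  expect_equal(nrow(fd), fit$k + 1L)
  expect_equal(sum(fd$weight_pct[-nrow(fd)]), 100, tolerance = 1e-8)
})
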