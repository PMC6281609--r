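test_that("cross_design validates its invariants", {
  expect_error(cross_design("four_way", n_animals = 0), "positive")
  expect_error(cross_design("four_way", n_animals = 100, sex_ratio = 1.5),
               "sex_ratio")
  expect_error(cross_design("f2", n_animals = 100, n_litters = 2,
                            litter_size_range = c(4, 6)),
               "capacity")
  d <- four_way_design()
  expect_s3_class(d, "cross_design")
  expect_identical(d$kind, "four_way")
})

test_that("mediation_model enforces topology constraints", {
  m <- mediation_model("null")
  expect_equal(c(m$beta_GE, m$beta_ET, m$beta_GT), c(0, 0, 0))
  expect_error(mediation_model("causal", beta_GT = 0.5), "beta_GT")
  expect_error(mediation_model("causal", beta_GE = 0), "non-zero")
  expect_error(mediation_model("causal", sigma_E = -1), ">= 0")
  m_ind <- mediation_model("independent")
  expect_equal(m_ind$beta_ET, 0)
  expect_equal(m_ind$beta_GT, 1.13 * -0.31)
})

test_that("four-way cross segregates 1:1:1:1 and is litter-complete", {
  d <- cross_design("four_way", n_animals = 4000, n_litters = 500)
  co <- simulate_four_way_cross(d, mediation_model("null"), seed = 11)
  counts <- table(co$ko_allele, co$qtl_allele)
  # each cell within 4 binomial SDs of n/4
  sd4 <- 4 * sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 1000) < sd4))
  expect_false(anyNA(co$litter_id))
  expect_true(all(table(co$litter_id) <= 10))
  expect_true(all(co$litter_size >= 1))
})

test_that("same seed reproduces a cohort field for field", {
  d <- four_way_design(96)
  m <- mediation_model("null")
  expect_identical(simulate_four_way_cross(d, m, seed = 42),
                   simulate_four_way_cross(d, m, seed = 42))
  d2 <- f2_design(96)
  m2 <- mediation_model("causal")
  expect_identical(simulate_f2_intercross(d2, m2, seed = 42),
                   simulate_f2_intercross(d2, m2, seed = 42))
})

test_that("F2 genotypes fit 1:2:1 and traits respect domain invariants", {
  d <- cross_design("f2", n_animals = 10000, n_litters = 1250)
  co <- simulate_f2_intercross(d, mediation_model("causal"), seed = 5)
  gt <- table(co$b6j_copies)
  expect_gt(stats::chisq.test(gt, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  trait_cols <- c("inguinal_fat", "gonadal_fat", "perirenal_fat", "liver_wt")
  expect_true(all(as.matrix(co[, trait_cols]) >= 0))
  expect_true(all(as.matrix(co[, paste0("bw_wk", c(1, 3, 6, 10, 13, 16))]) > 0))
  expect_true(all(is.na(co$testis_wt[co$sex == "F"])))
})

test_that("causal topology gives the closed-form expression contrast", {
  # difference between extreme genotype groups is 2 * beta_GE in expectation
  d <- cross_design("f2", n_animals = 6000, n_litters = 750)
  m <- mediation_model("causal", beta_GE = 1.13, sigma_E = 0.02,
                       sigma_litter_E = 0)
  co <- simulate_f2_intercross(d, m, seed = 9)
  means <- tapply(co$expression, co$b6j_copies, mean)
  expect_equal(unname(means["2"] - means["0"]), 2 * 1.13, tolerance = 0.01)
})

test_that("null topology leaves genotype and trait uncorrelated", {
  d <- cross_design("f2", n_animals = 1000, n_litters = 125)
  co <- simulate_f2_intercross(d, mediation_model("null"), seed = 21)
  expect_lt(abs(stats::cor(co$b6j_copies, co$inguinal_fat)), 0.1)
})

test_that("mediation structure shows in partial correlations", {
  d <- cross_design("f2", n_animals = 4000, n_litters = 500)
  pcor_GT_given_E <- function(co) {
    r_gt <- stats::cor(co$b6j_copies, co$inguinal_fat)
    r_ge <- stats::cor(co$b6j_copies, co$expression)
    r_et <- stats::cor(co$expression, co$inguinal_fat)
    (r_gt - r_ge * r_et) / sqrt((1 - r_ge^2) * (1 - r_et^2))
  }
  co_c <- simulate_f2_intercross(d, mediation_model("causal",
                                                    sigma_litter = 0,
                                                    sigma_litter_E = 0,
                                                    beta_bw = 0), seed = 3)
  # causal: conditioning on E wipes out the G-T association
  expect_lt(abs(pcor_GT_given_E(co_c)), 0.06)
  # independent: conditioning changes little relative to the marginal.
  # (A moderate G-E coupling is used: when E is an almost perfect proxy for
  # G, conditioning attenuates the partial correlation by sqrt(1 - r_GE^2)
  # even without mediation.)
  co_i <- simulate_f2_intercross(d, mediation_model("independent",
                                                    beta_GE = 0.3,
                                                    beta_GT = -0.35,
                                                    sigma_litter = 0,
                                                    sigma_litter_E = 0,
                                                    beta_bw = 0), seed = 3)
  marg <- stats::cor(co_i$b6j_copies, co_i$inguinal_fat)
  expect_gt(abs(pcor_GT_given_E(co_i)), abs(marg) * 0.7)
})

test_that("litter random effects induce the expected intra-litter correlation", {
  d <- cross_design("f2", n_animals = 4800, n_litters = 600)
  m <- mediation_model("causal", sigma_litter = 0.3, sigma_T = 0.3,
                       beta_bw = 0, beta_GE = 0.01, beta_ET = 0.01)
  co <- simulate_f2_intercross(d, m, seed = 13)
  fit <- lme4::lmer(inguinal_fat ~ 1 + (1 | litter_id), data = co, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(icc, 0.3^2 / (0.3^2 + 0.3^2), tolerance = 0.12)
})

test_that("ct panel follows the log2 inverse relation", {
  co <- data.frame(animal_id = c("a", "b"), genotype = "KO/B6J",
                   expression = c(1, 2))
  p0 <- simulate_ct_panel(co, qpcr_params = list(replicate_sd = 0),
                          seed = 1)
  mean_ct <- tapply(p0$ct[p0$gene == "target"],
                    p0$sample_id[p0$gene == "target"], mean)
  expect_equal(unname(mean_ct["a"] - mean_ct["b"]), 1, tolerance = 1e-12)
  # zero replicate noise -> identical replicates
  expect_true(all(tapply(p0$ct, interaction(p0$sample_id, p0$gene),
                         function(x) diff(range(x))) == 0))
  expect_error(simulate_ct_panel(data.frame(animal_id = "a",
                                            genotype = "x",
                                            expression = -1)),
               "positive")
})
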