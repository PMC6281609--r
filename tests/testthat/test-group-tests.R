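test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(1)
  y <- stats::rnorm(30)
  g <- rep(c("a", "b"), 15)
  res <- one_way_anova(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("identical values give F = 0, P = 1", {
  res <- one_way_anova(rep(5, 30), rep(letters[1:3], 10))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("ANOVA F matches the projection-matrix oracle on random instances", {
  set.seed(2)
  for (i in 1:20) {
    d <- random_groups(k = 3, n_per = 10)
    res <- one_way_anova(d$y, d$g)
    orc <- f_oneway_oracle(d$y, d$g)
    expect_equal(res$F, orc$F, tolerance = 1e-9)
    expect_equal(res$p, orc$p, tolerance = 1e-9)
  }
})

test_that("ANOVA F is invariant to location and positive scale", {
  set.seed(3)
  d <- random_groups()
  f0 <- one_way_anova(d$y, d$g)$F
  expect_equal(one_way_anova(3.7 * d$y + 11, d$g)$F, f0, tolerance = 1e-10)
})

test_that("least-squares means adjust for the sex covariate", {
  set.seed(4)
  g <- rep(c("a", "b"), each = 30)
  sex <- rep(c("M", "F"), 30)
  y <- stats::rnorm(60) + 2 * (sex == "M") + 0.5 * (g == "b")
  res <- one_way_anova(y, g, sex = sex)
  # ls means sit between the raw sex-specific means, equidistant by balance
  expect_equal(res$lsmeans$lsmean[2] - res$lsmeans$lsmean[1],
               unname(coef(stats::lm(y ~ sex + g))["gb"]), tolerance = 1e-9)
})

test_that("group-comparison input validation", {
  expect_error(one_way_anova(1:5, rep("a", 5)), "2 groups")
  expect_error(one_way_anova(1:3, c("a", "b", "b")), "2 observations")
})

test_that("a far-shifted group carries a unique letter", {
  set.seed(5)
  y <- c(stats::rnorm(10), stats::rnorm(10), stats::rnorm(10) + 100)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- tukey_hsd(y, g)
  lets <- res$letters
  expect_false(grepl(lets$letters[lets$group == "c"], paste0(
    lets$letters[lets$group != "c"], collapse = "")))
  expect_true(all(nchar(lets$letters) >= 1))
})

test_that("letter display is a valid covering of the significance matrix", {
  set.seed(6)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    d <- random_groups(k = k, unbalanced = TRUE)
    res <- tukey_hsd(d$y, d$g, alpha = 0.05)
    lets <- stats::setNames(res$letters$letters, res$letters$group)
    share <- function(a, b) {
      any(strsplit(lets[a], "")[[1]] %in% strsplit(lets[b], "")[[1]])
    }
    for (r in seq_len(nrow(res$pairs))) {
      expect_identical(share(res$pairs$g1[r], res$pairs$g2[r]),
                       res$pairs$p[r] >= 0.05)
    }
    expect_true(all(nchar(lets) >= 1))
  }
})

test_that("null groups share one letter most of the time", {
  set.seed(7)
  one_letter <- replicate(80, {
    y <- stats::rnorm(90)
    g <- rep(letters[1:3], each = 30)
    all(tukey_hsd(y, g)$letters$letters == "a")
  })
  expect_gte(mean(one_letter), 0.9)
})

test_that("Tukey P values match the numeric studentized-range oracle", {
  set.seed(8)
  d <- random_groups(k = 4, n_per = 8, unbalanced = TRUE)
  res <- tukey_hsd(d$y, d$g)
  for (r in seq_len(nrow(res$pairs))) {
    expect_equal(res$pairs$p[r],
                 ptukey_oracle(res$pairs$q[r], k = 4, df = res$df),
                 tolerance = 1e-4)
  }
})

test_that("two groups degenerate to a single comparison", {
  set.seed(9)
  res <- tukey_hsd(stats::rnorm(20), rep(c("a", "b"), 10))
  expect_identical(nrow(res$pairs), 1L)
})

test_that("single-response MANOVA reduces exactly to one-way ANOVA", {
  set.seed(10)
  d <- data.frame(y = stats::rnorm(45), g = factor(rep(1:3, 15)))
  mv <- trait_group_manova(d, "y", "g")
  uni <- one_way_anova(d$y, d$g)
  expect_equal(unique(round(mv$p, 12)), round(uni$p, 12), tolerance = 1e-8)
  expect_true(all(abs(mv$approx_F - uni$F) < 1e-8))
})

test_that("Wilks P is uniform under the multivariate null", {
  set.seed(11)
  p <- replicate(400, {
    d <- data.frame(y1 = stats::rnorm(36), y2 = stats::rnorm(36),
                    g = factor(rep(1:3, 12)))
    mv <- trait_group_manova(d, c("y1", "y2"), "g")
    mv$p[mv$statistic == "Wilks"]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("MANOVA guards its preconditions", {
  set.seed(12)
  d <- data.frame(y1 = stats::rnorm(30), g = factor(rep(1:2, 15)))
  d$y2 <- 2 * d$y1 # collinear responses
  expect_error(trait_group_manova(d, c("y1", "y2"), "g"), "collinear")
  d3 <- data.frame(y1 = stats::rnorm(4), y2 = stats::rnorm(4),
                   y3 = stats::rnorm(4), g = factor(c(1, 1, 2, 2)))
  expect_error(trait_group_manova(d3, c("y1", "y2", "y3"), "g"), "few")
  expect_error(trait_group_manova(d, c("missing_col"), "g"), "absent")
})

test_that("significance summary reads any- and all-statistic flags", {
  set.seed(13)
  # strong effect on one response: all four significant
  d <- data.frame(y1 = stats::rnorm(40) + rep(c(0, 3), 20),
                  y2 = stats::rnorm(40), g = factor(rep(1:2, 20)))
  s <- significance_summary(trait_group_manova(d, c("y1", "y2"), "g"))
  expect_true(s$significant_any_statistic[s$term == "g"])
  expect_true(s$significant_all_statistics[s$term == "g"])
  # null: both flags false (check at a tiny alpha to make it deterministic)
  d0 <- data.frame(y1 = stats::rnorm(40), y2 = stats::rnorm(40),
                   g = factor(rep(1:2, 20)))
  s0 <- significance_summary(trait_group_manova(d0, c("y1", "y2"), "g"),
                             alpha = 1e-12)
  expect_false(any(s0$significant_any_statistic))
  expect_false(any(s0$significant_all_statistics))
})

test_that("the eight default trait groups cover the category scheme", {
  tg <- default_trait_groups()
  expect_identical(names(tg),
                   c("body_weight", "weight_gain", "body_length",
                     "organ_weight", "fat_pad_weight",
                     "adjusted_body_length", "adjusted_organ_weight",
                     "adjusted_fat_pad_weight"))
  expect_identical(length(tg), 8L)
  expect_true(all(grepl("^adj_", unlist(tg[6:8]))))
  # composite and single-sex traits stay out of the grouped tests
  expect_false(any(c("total_fat", "total_length", "testis_wt",
                     "adj_testis_wt") %in% unlist(tg)))
})
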