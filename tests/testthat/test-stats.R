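test_that("balanced data with zero subject SDs gives the raw mean difference", {
  tab <- sim_table(6, 30, delta = 2.5, sd_int = 0, sd_slope = 0, seed = 3)
  fit <- suppressWarnings(fit_lmm(tab, "intercept_only"))
  raw <- mean(tab$Outcome[tab$Config == "Wrap"]) -
    mean(tab$Outcome[tab$Config == "Lace"])
  expect_equal(unname(fit$fixed["ConfigWrap", "Estimate"]), raw,
               tolerance = 1e-8)
})

test_that("the random-slope estimate equals the paired subject-means oracle", {
  tab <- sim_table(12, 40, delta = 1.2, seed = 7)
  fit <- suppressWarnings(fit_lmm(tab, "random_slope"))
  agg <- tapply(tab$Outcome, list(tab$Subject, tab$Config), mean)
  oracle <- mean(agg[, "Wrap"] - agg[, "Lace"])
  expect_equal(unname(fit$fixed["ConfigWrap", "Estimate"]), oracle,
               tolerance = 1e-6)
  # emmeans difference equals the Config fixed effect for this design
  ct <- emm_contrast(fit)
  expect_equal(ct$difference, unname(fit$fixed["ConfigWrap", "Estimate"]),
               tolerance = 1e-8)
})

test_that("an injected condition effect is recovered within 2 SE", {
  tab <- sim_table(20, 50, delta = -1.5, seed = 21)
  fit <- suppressWarnings(fit_lmm(tab, "random_slope"))
  est <- unname(fit$fixed["ConfigWrap", "Estimate"])
  se <- unname(fit$fixed["ConfigWrap", "Std. Error"])
  expect_lt(abs(est - (-1.5)), 2 * se)
  expect_lt(fit$fixed["ConfigWrap", "Pr(>|t|)"], 0.05)
})

test_that("emmeans match brute-force prediction averaging on balanced data", {
  tab <- sim_table(10, 25, delta = 0.8, seed = 13)
  fit <- suppressWarnings(fit_lmm(tab, "random_slope"))
  ct <- emm_contrast(fit)
  beta <- lme4::fixef(fit$model)
  expect_equal(unname(ct$emmeans["Lace"]), unname(beta[1]),
               tolerance = 1e-8)
  expect_equal(unname(ct$emmeans["Wrap"]), unname(beta[1] + beta[2]),
               tolerance = 1e-8)
})

test_that("percent differences reproduce the published eversion contrast", {
  # emm_Wrap = 328.1, emm_Lace = 343.8 -> -15.7 deg/s, about -4.6%
  set.seed(2)
  n <- 24
  tab <- data.frame(
    Outcome = c(rnorm(n * 30, 343.8, 1e-6), rnorm(n * 30, 328.1, 1e-6)),
    Config = rep(c("Lace", "Wrap"), each = n * 30),
    Subject = rep(rep(seq_len(n), each = 30), 2))
  fit <- suppressWarnings(fit_lmm(tab, "intercept_only"))
  ct <- emm_contrast(fit)
  expect_equal(ct$difference, -15.7, tolerance = 1e-3)
  expect_equal(ct$percent_difference, 100 * (328.1 - 343.8) / 343.8,
               tolerance = 1e-3)
  expect_equal(round(-ct$percent_difference), 5)
})

test_that("equal emmeans give a zero percent difference", {
  tab <- sim_table(8, 20, delta = 0, sd_slope = 0, sd_eps = 0, seed = 5)
  fit <- suppressWarnings(fit_lmm(tab, "intercept_only"))
  ct <- emm_contrast(fit)
  expect_equal(ct$percent_difference, 0, tolerance = 1e-8)
})

test_that("REML criterion improves (or ties) as random effects grow", {
  tab <- sim_table(15, 30, delta = 1, seed = 17)
  f1 <- suppressWarnings(fit_lmm(tab, "intercept_only"))
  f2 <- suppressWarnings(fit_lmm(tab, "random_slope"))
  expect_lte(as.numeric(lme4::REMLcrit(f2$model)),
             as.numeric(lme4::REMLcrit(f1$model)) + 1e-6)
})

test_that("singular random-slope fits fall back with a warning", {
  # no slope variance and no residual headroom: slope variance degenerates
  tab <- sim_table(4, 3, delta = 0.5, sd_slope = 0, sd_eps = 1, seed = 2)
  expect_warning(fit <- fit_lmm(tab, "random_slope"),
                 "falling back")
  expect_true(fit$fallback_intercept_only)
})

test_that("input contracts are enforced", {
  tab <- sim_table(5, 10, delta = 0)
  expect_error(fit_lmm(tab, "random_slope_with_speed"), "Speed")
  tab$Subject <- 1
  expect_error(suppressWarnings(fit_lmm(tab, "random_slope")),
               "2 subjects")
  tab2 <- sim_table(5, 10, delta = 0)
  tab2$Config[1] <- NA
  expect_error(fit_lmm(tab2, "random_slope"), "complete")
})
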