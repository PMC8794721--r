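make_table <- function(seed, params = cohort_params()) {
  simulate_analysis_table(params, seed = seed)
}

test_that("Fulton's K follows the millimetre-based formula", {
  expect_equal(fulton_k(1, 100), 1e-4)
  expect_equal(fulton_k(1.08, 42.5), 108 / 76765.625)
  expect_equal(fulton_k(2, 50), 2 * fulton_k(1, 50))  # linear in mass
  expect_equal(fulton_k(1, 42.5, length_unit = "cm"),
               1000 * fulton_k(1, 42.5))
  expect_error(fulton_k(-1, 50), "positive")
})

test_that("analysis tables are complete and correctly coded", {
  tab <- make_table(1)
  expect_equal(nrow(tab), 150L)
  expect_identical(levels(tab$vgll3), c("EE", "LL"))
  expect_identical(levels(tab$sex), c("F", "M"))
  expect_false(anyNA(tab))
  expect_true(all(tab$condition_K > 0))
})

test_that("noise-free data reproduce the generating fixed effects exactly", {
  p <- cohort_params(sd_family = 0, sd_batch = 0, sd_residual = 0,
                     beta_vgll3 = 0.02, beta_sex = -0.01,
                     beta_interaction = 0.005, beta_temp = 0.01)
  tab <- make_table(3, p)
  fit <- fit_mixed(tab, "full")
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["log10_mass"]), 0.88, tolerance = 1e-6)
  expect_equal(unname(est["vgll3LL"]), 0.02, tolerance = 1e-6)
  expect_equal(unname(est["sexM"]), -0.01, tolerance = 1e-6)
  expect_equal(unname(est["vgll3LL:sexM"]), 0.005, tolerance = 1e-6)
  expect_equal(unname(est["avg_temp_C"]), 0.01, tolerance = 1e-6)
})

test_that("with vanishing random-effect variance the fit matches OLS", {
  p <- cohort_params(sd_family = 0, sd_batch = 0)
  tab <- make_table(2, p)  # a draw whose variance estimates hit the boundary
  fit <- fit_mixed(tab, "full")
  expect_true(all(fit$varcomp[c("sd_family", "sd_batch")] < 1e-10))
  ols <- lm(log10_smr ~ log10_mass + vgll3 + sex + vgll3:sex + avg_temp_C,
            data = tab)
  expect_true(fit$singular)
  expect_equal(fit$fixed$estimate, unname(coef(ols)[fit$fixed$term]),
               tolerance = 1e-6)
  # REML and ML agree on fixed effects when variances are zero
  fit_ml <- fit_mixed(tab, "full", reml = FALSE)
  expect_equal(fit_ml$fixed$estimate, fit$fixed$estimate, tolerance = 1e-6)
})

test_that("the mass exponent is recovered without bias and with 95% coverage", {
  hits <- 0L
  ests <- numeric(200)
  for (r in 1:200) {
    tab <- make_table(1000 + r)
    fit <- fit_mixed(tab, "full")
    b <- fit$fixed[fit$fixed$term == "log10_mass", ]
    ests[r] <- b$estimate
    ci <- b$estimate + c(-1, 1) * qt(0.975, b$df) * b$se
    if (ci[1] <= 0.88 && 0.88 <= ci[2]) hits <- hits + 1L
  }
  expect_lt(abs(mean(ests) - 0.88), 0.01)
  expect_gte(hits, 184L)  # 92% - 98% observed coverage band
  expect_lte(hits, 196L)
})

test_that("AIC identity and reporting hold for every fit", {
  tab <- make_table(7)
  for (m in c("full", "no_interaction", "sex_only", "simple",
              "condition_full")) {
    for (reml in c(TRUE, FALSE)) {
      fit <- fit_mixed(tab, m, reml = reml)
      expect_equal(fit$AIC, 2 * fit$df_logLik - 2 * fit$logLik,
                   tolerance = 1e-8)
      expect_true(all(fit$varcomp >= 0, na.rm = TRUE))
      expect_equal(fit$n, nrow(tab))
    }
  }
})

test_that("F equals squared t for single-df effects (type III)", {
  tab <- make_table(9)
  fit <- fit_mixed(tab, "full")
  ft <- test_fixed_effects(fit)
  expect_identical(unique(ft$test_type), "III")
  for (term in c("log10_mass", "avg_temp_C")) {
    tt <- fit$fixed[fit$fixed$term == term, ]
    expect_equal(ft$F[ft$term == term], tt$t^2, tolerance = 1e-8)
    expect_equal(ft$den_df[ft$term == term], tt$df, tolerance = 1e-6)
  }
  # models without an interaction default to type II
  ft2 <- test_fixed_effects(fit_mixed(tab, "no_interaction"))
  expect_identical(unique(ft2$test_type), "II")
})

test_that("Satterthwaite df collapses to residual df without random variance", {
  p <- cohort_params(sd_family = 0, sd_batch = 0)
  tab <- make_table(11, p)
  fit <- fit_mixed(tab, "full")
  ft <- test_fixed_effects(fit)
  resid_df <- nrow(tab) - 6  # 6 fixed-effect columns
  expect_true(all(abs(ft$den_df - resid_df) < 2))
})

test_that("model selection responds to the presence of a genotype effect", {
  null_wins <- 0L
  effect_wins <- 0L
  p_null <- cohort_params()
  p_eff <- cohort_params(beta_vgll3 = log10(1.05))
  for (r in 1:100) {
    cmp <- compare_models(make_table(3000 + r, p_null))
    if (cmp$model_id[which.min(cmp$AIC)] %in% c("sex_only", "simple")) {
      null_wins <- null_wins + 1L
    }
    cmp <- compare_models(make_table(4000 + r, p_eff))
    if (cmp$model_id[which.min(cmp$AIC)] %in% c("full", "no_interaction")) {
      effect_wins <- effect_wins + 1L
    }
  }
  expect_gt(null_wins, 50L)
  expect_gt(effect_wins, 50L)
})

test_that("nested ML log-likelihoods are monotone", {
  cmp <- compare_models(make_table(13))
  ll <- setNames(cmp$logLik, cmp$model_id)
  expect_gte(ll["full"], ll["no_interaction"] - 1e-6)
  expect_gte(ll["no_interaction"], ll["sex_only"] - 1e-6)
  expect_gte(ll["sex_only"], ll["simple"] - 1e-6)
  expect_equal(cmp$dAIC[which.min(cmp$AIC)], 0)
})

test_that("cross-validation is exact on noise-free data and tracks sigma", {
  p0 <- cohort_params(sd_family = 0, sd_batch = 0, sd_residual = 0)
  cv0 <- suppressWarnings(cross_validate(make_table(15, p0), "simple"))
  expect_true(all(cv0$rmse < 1e-6))

  rmse <- vapply(1:10, function(r) {
    cv <- cross_validate(make_table(5000 + r), "full")
    cv$rmse[cv$split == "pooled"]
  }, numeric(1))
  expect_lt(abs(mean(rmse) - 0.027), 0.005)

  # at ten times the cohort size the pooled RMSE pins down sigma_res
  p_big <- cohort_params(n_fish_total = 1500, fish_per_family = 108,
                         chambers_per_batch = 150)
  cv_big <- suppressWarnings(cross_validate(make_table(77, p_big), "full"))
  expect_lt(abs(cv_big$rmse[cv_big$split == "pooled"] - 0.027), 0.002)
})

test_that("omitting body mass degrades held-out prediction", {
  worse <- 0L
  for (r in 1:60) {
    tab <- make_table(6000 + r)
    full <- suppressWarnings(cross_validate(tab, "full"))
    nomass <- suppressWarnings(cross_validate(tab, "no_mass"))
    if (nomass$rmse[3] > full$rmse[3]) worse <- worse + 1L
  }
  expect_gte(worse, 57L)  # >= 95%
})

test_that("residual CV rescales log10 spread to percent", {
  expect_equal(residual_cv(0.027), 2.7 * log(10), tolerance = 1e-12)
  expect_equal(residual_cv(0), 0)
  expect_equal(residual_cv(0.054), 2 * residual_cv(0.027))
  fit <- fit_mixed(make_table(17), "full")
  expect_equal(residual_cv(fit),
               sd(residuals(fit$fit)) * log(10) * 100)
})
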