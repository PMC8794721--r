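test_that("default cohort matches the study design", {
  p <- cohort_params()
  cohort <- generate_cohort(p, seed = 1)
  expect_equal(nrow(cohort), 150L)
  expect_equal(length(unique(cohort$family_id)), 14L)
  fam_geno <- unique(cohort[c("family_id", "genotype")])
  expect_equal(as.vector(table(fam_geno$genotype)), c(7L, 7L))
  expect_true(all(tabulate(cohort$batch, 10) <= 16L))
  expect_equal(length(unique(cohort$batch)), 10L)
  # genotype constant within family
  expect_equal(nrow(fam_geno), 14L)
  # chambers unique within batch
  expect_true(all(tapply(cohort$chamber, cohort$batch,
                         function(x) !anyDuplicated(x))))
})

test_that("minimal two-family design yields one fish per genotype", {
  p <- cohort_params(n_families = 2, families_per_genotype = 1,
                     fish_per_family = 1, n_fish_total = 2, n_batches = 1)
  cohort <- generate_cohort(p, seed = 1)
  expect_equal(nrow(cohort), 2L)
  expect_setequal(as.character(cohort$genotype), c("EE", "LL"))
})

test_that("infeasible chamber allocation is a design error", {
  expect_error(cohort_params(n_batches = 5, chambers_per_batch = 16),
               "chambers")
})

test_that("body-mass distribution matches its configured moments", {
  p <- cohort_params()
  masses <- unlist(lapply(1:500, function(s) generate_cohort(p, seed = s)$mass_g))
  target <- exp(p$mass_meanlog + p$mass_sdlog^2 / 2)
  mc_se <- sd(masses) / sqrt(length(masses))
  expect_lt(abs(mean(masses) - target), 3 * mc_se)
  expect_equal(target, 1.08, tolerance = 1e-12)
})

test_that("noise-free generating model is an exact identity", {
  p <- cohort_params(mass_meanlog = 0, mass_sdlog = 0, length_sdlog = 0,
                     allometric_intercept = 0.2, allometric_exponent = 0.88,
                     sd_family = 0, sd_batch = 0, sd_residual = 0,
                     temp_sd_C = 0)
  cohort <- simulate_true_smr(generate_cohort(p, seed = 1), p, seed = 2)
  expect_true(all(cohort$mass_g == 1))
  expect_equal(cohort$true_smr_mg_h, rep(0.2, 150), tolerance = 1e-12)
})

test_that("variance components add up in large cohorts", {
  p <- cohort_params(n_fish_total = 1000, fish_per_family = 72,
                     chambers_per_batch = 100)
  cohort <- simulate_true_smr(generate_cohort(p, seed = 3), p, seed = 4)
  dev <- log10(cohort$true_smr_mg_h) -
    (log10(p$allometric_intercept) +
       p$allometric_exponent * log10(cohort$mass_g))
  target <- sqrt(p$sd_family^2 + p$sd_batch^2 + p$sd_residual^2)
  mc_se <- target / sqrt(2 * nrow(cohort))
  expect_lt(abs(sd(dev) - target), 3 * mc_se)
})

test_that("a log10(1.05) genotype coefficient shifts geometric-mean SMR by 5%", {
  p <- cohort_params(n_fish_total = 2000, fish_per_family = 143,
                     n_batches = 20, chambers_per_batch = 100,
                     beta_vgll3 = log10(1.05), sd_family = 0, sd_batch = 0)
  cohort <- simulate_true_smr(generate_cohort(p, seed = 5), p, seed = 6)
  adj <- log10(cohort$true_smr_mg_h) -
    p$allometric_exponent * log10(cohort$mass_g)
  diff_log10 <- mean(adj[cohort$genotype == "LL"]) -
    mean(adj[cohort$genotype == "EE"])
  se <- p$sd_residual * sqrt(4 / nrow(cohort))
  expect_lt(abs(10^diff_log10 - 1.05), 1.05 * log(10) * 3 * se)
})

test_that("simulators are deterministic under a fixed seed", {
  p <- cohort_params()
  tp <- trace_params()
  c1 <- simulate_true_smr(generate_cohort(p, seed = 7), p, seed = 8)
  c2 <- simulate_true_smr(generate_cohort(p, seed = 7), p, seed = 8)
  expect_identical(c1, c2)
  t1 <- simulate_trace(c1[1, ], tp, seed = 9)
  t2 <- simulate_trace(c2[1, ], tp, seed = 9)
  expect_identical(t1, t2)
  b1 <- simulate_blank_trace(tp, 0.02, "pre", seed = 10)
  b2 <- simulate_blank_trace(tp, 0.02, "pre", seed = 10)
  expect_identical(b1, b2)
  # and the global RNG stream is untouched
  withr::with_seed(99, {
    before <- .Random.seed
    invisible(simulate_trace(c1[2, ], tp, seed = 11))
    expect_identical(.Random.seed, before)
  })
})

test_that("a resting fish with no background leaves oxygen at saturation", {
  fish <- fixed_fish(true_smr = 0)
  tp <- quiet_trace_params()
  tr <- simulate_trace(fish, tp, seed = 1)
  expect_true(all(tr$samples$o2_mgL == tp$o2_saturation_mgL))
})

test_that("closed-phase decline follows the MO2/V_eff line exactly", {
  # MO2 = 0.249 mg/h into V_eff = 0.25 - 0.001 = 0.249 L: slope -1 mg/L/h,
  # a 15-min closed phase drops 0.25 mg/L
  fish <- fixed_fish(true_smr = 0.249, mass_g = 1.0)
  tp <- quiet_trace_params()
  tr <- simulate_trace(fish, tp, seed = 1)
  s <- estimate_slopes(tr, tp, wait_trim_s = 0)
  expect_equal(s$slope_mgL_per_h, rep(-1, 57), tolerance = 1e-9)
  m <- tr$samples[tr$samples$phase == "M" & tr$samples$cycle == 2, ]
  span_s <- m$time_s[nrow(m)] - m$time_s[1]
  expect_equal(m$o2_mgL[1] - m$o2_mgL[nrow(m)], span_s / 3600,
               tolerance = 1e-9)
  # extrapolated over the full 900 s closed phase: 0.25 mg/L
  expect_equal(1 * 900 / 3600, 0.25)
})

test_that("oxygen deficit integrates to MO2 * dt / V_eff (mass conservation)", {
  fish <- fixed_fish(true_smr = 0.4, mass_g = 1.2)
  tp <- quiet_trace_params()
  tr <- simulate_trace(fish, tp, seed = 1)
  v_eff <- tp$chamber_volume_L - fish$mass_g / 1000
  for (cyc in c(1, 25, 57)) {
    m <- tr$samples[tr$samples$phase == "M" & tr$samples$cycle == cyc, ]
    span_s <- m$time_s[nrow(m)] - m$time_s[1]
    deficit <- m$o2_mgL[1] - m$o2_mgL[nrow(m)]
    expect_equal(deficit, fish$true_smr_mg_h * (span_s / 3600) / v_eff,
                 tolerance = 1e-9)
  }
})

test_that("oxygen is truncated at zero with a warning for extreme consumption", {
  fish <- fixed_fish(true_smr = 60, mass_g = 1.0)
  tp <- quiet_trace_params()
  expect_warning(tr <- simulate_trace(fish, tp, seed = 1), "truncated")
  expect_true(tr$truncated)
  expect_true(all(tr$samples$o2_mgL >= 0))
})

test_that("blank traces reflect the configured background fraction", {
  # with no activity/acclimation and no drift, blank slope over fish-trace
  # slope equals f = bg / (fish + bg) by construction
  f <- 0.075
  fish <- fixed_fish(true_smr = 0.3)
  tp <- quiet_trace_params(sensor_noise_sd = 0.002)
  tp$background_fraction <- f
  tr <- simulate_trace(fish, tp, seed = 21)
  bg0 <- f / (1 - f) * fish$true_smr_mg_h
  blank <- simulate_blank_trace(tp, bg0, "pre", seed = 22)
  s_total <- mean(estimate_slopes(tr, tp, wait_trim_s = 0)$slope_mgL_per_h)
  s_bg <- estimate_slope(segment_cycles(blank, tp, wait_trim_s = 0)[[1]])
  # the blank runs in the full chamber volume; compare MO2, not raw slopes
  mo2_bg <- -s_bg$slope_mgL_per_h * tp$chamber_volume_L
  mo2_total <- -s_total * (tp$chamber_volume_L - fish$mass_g / 1000)
  expect_equal(mo2_bg / (mo2_total), f, tolerance = 0.02)
})

test_that("flat blank traces arise when background is zero", {
  tp <- quiet_trace_params()
  blank <- simulate_blank_trace(tp, 0, "pre", seed = 1)
  expect_true(all(blank$samples$o2_mgL == tp$o2_saturation_mgL))
})

test_that("YAML configuration round-trips into parameter objects", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("cohort:", "  n_fish_total: 30", "  fish_per_family: 3",
               "trace:", "  duration_h: 2"), cfg)
  out <- read_simulation_config(cfg)
  expect_equal(out$cohort$n_fish_total, 30L)
  expect_equal(out$trace$duration_h, 2)
  expect_equal(out$trace$flush_s, 300)
})
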