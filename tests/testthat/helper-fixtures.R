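# Shared fixture builders; everything is generated in code at test time.

# A closed-phase window data.frame on a regular grid with O2(t) = a + b_h * t/3600.
linear_window <- function(n = 450, dt = 2, intercept = 10, slope_per_h = -0.5,
                          noise_sd = 0, t0 = 0, seed = NULL) {
  build <- function() {
    t <- t0 + (seq_len(n) - 1) * dt
    y <- intercept + slope_per_h * t / 3600
    if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
    data.frame(time_s = t, o2_mgL = y, temp_C = 10.5, phase = "M", cycle = 1L)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Closed-form OLS oracle used against the package's slope estimator.
ols_oracle <- function(t, y) {
  tc <- t - mean(t)
  slope <- sum(tc * (y - mean(y))) / sum(tc^2)
  intercept <- mean(y) - slope * mean(t)
  r2 <- if (var(y) == 0) NA_real_ else {
    1 - sum((y - intercept - slope * t)^2) / sum((y - mean(y))^2)
  }
  list(slope_per_h = slope * 3600, intercept = intercept, r2 = r2)
}

# One fish with everything fixed; convenient for trace arithmetic tests.
fixed_fish <- function(true_smr = 0.249, mass_g = 1.0, chamber = 1L) {
  data.frame(fish_id = "T001", family_id = 1L,
             genotype = factor("EE", levels = c("EE", "LL")),
             sex = factor("F", levels = c("F", "M")),
             mass_g = mass_g, length_mm = 41.4, batch = 1L,
             chamber = chamber, avg_temp_C = 10.3,
             true_smr_mg_h = true_smr, stringsAsFactors = FALSE)
}

# Deterministic trace settings: no activity, no acclimation, no noise.
quiet_trace_params <- function(...) {
  args <- utils::modifyList(
    list(p_active = 0, activity_mean = 0, acclimation_amplitude = 0,
         sensor_noise_sd = 0, background_fraction = 0, background_drift = 1),
    list(...)
  )
  do.call(trace_params, args)
}

# Per-cycle MO2 values for a default-simulator fish, with small multiplicative
# measurement noise standing in for slope-estimation error.
contaminated_mo2 <- function(fish, seed, noise = 0.01,
                             params = trace_params()) {
  cyc <- simulate_cycle_mo2(fish, params, seed = seed)
  withr::with_seed(seed + 1L, {
    cyc$mo2_mg_h <- cyc$mo2_mg_h * exp(rnorm(nrow(cyc), 0, noise))
  })
  cyc
}
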