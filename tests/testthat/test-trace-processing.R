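test_that("trace CSVs round-trip losslessly and count 19 h of samples", {
  fish <- fixed_fish()
  tp <- trace_params()
  tr <- simulate_trace(fish, tp, seed = 2)
  expect_equal(nrow(tr$samples), 19 * 3600 / 2)  # 34,200 samples
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path, kind = "fish", fish_id = fish$fish_id,
                     protocol = tp)
  expect_equal(back$samples$o2_mgL, tr$samples$o2_mgL, tolerance = 1e-9)
  expect_identical(back$samples$phase, tr$samples$phase)
  expect_identical(back$samples$cycle, tr$samples$cycle)
  expect_equal(back$chamber, tr$chamber)
})

test_that("malformed trace files are rejected with line diagnostics", {
  path <- tempfile(fileext = ".csv")
  d <- data.frame(time_s = c(0, 2, 1, 6), chamber = 1, phase = "M",
                  cycle = 1, o2_mgL = 10, temp_C = 10.5)
  write.csv(d, path, row.names = FALSE)
  expect_error(read_trace(path), "line 4")
  d$time_s <- c(0, 2, 4, 6)
  d$phase <- c("M", "M", "X", "M")
  write.csv(d, path, row.names = FALSE)
  expect_error(read_trace(path), "phase code 'X' at line 4")
  write.csv(d[c("time_s", "phase")], path, row.names = FALSE)
  expect_error(read_trace(path), "missing column")
})

test_that("cycle segmentation honours the protocol arithmetic", {
  fish <- fixed_fish()
  tp <- quiet_trace_params()
  tr <- simulate_trace(fish, tp, seed = 1)
  wins <- segment_cycles(tr, tp)  # default 120 s trim
  expect_length(wins, 57)         # floor(19*3600 / 1200)
  expect_true(all(vapply(wins, nrow, integer(1)) == (900 - 120) / 2))
  wins0 <- segment_cycles(tr, tp, wait_trim_s = 0)
  expect_true(all(vapply(wins0, nrow, integer(1)) == 900 / 2))
  # windows time-ordered and non-overlapping
  starts <- vapply(wins, function(w) w$time_s[1], numeric(1))
  ends <- vapply(wins, function(w) w$time_s[nrow(w)], numeric(1))
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts[-1] > ends[-length(ends)]))
  # over-long trim drops every cycle with a warning
  expect_warning(expect_error(estimate_slopes(tr, tp, wait_trim_s = 899)),
                 "dropped")
})

test_that("cycle count equals floor(duration / cycle length) across protocols", {
  fish <- fixed_fish()
  for (dur in c(2, 4.5, 6)) {
    tp <- quiet_trace_params(duration_h = dur)
    tr <- simulate_trace(fish, tp, seed = 1)
    expect_length(segment_cycles(tr, tp, wait_trim_s = 0),
                  floor(dur * 3600 / 1200))
  }
})

test_that("slope estimator handles flat and exact linear signals", {
  flat <- linear_window(slope_per_h = 0, intercept = 10)
  s <- estimate_slope(flat)
  expect_equal(s$slope_mgL_per_h, 0)
  expect_true(is.na(s$r2))
  line <- linear_window(slope_per_h = -0.5)
  s <- estimate_slope(line)
  expect_equal(s$slope_mgL_per_h, -0.5, tolerance = 1e-12)
  expect_equal(s$r2, 1, tolerance = 1e-12)
  expect_error(estimate_slope(line[1:5, ]), "at least 10")
})

test_that("slope sampling error matches the OLS variance formula", {
  # analytic slope SE for N(0, 0.01^2) noise on a 450-sample window
  n <- 450; dt <- 2; sd_noise <- 0.01
  t <- (seq_len(n) - 1) * dt
  se_h <- sd_noise / sqrt(sum((t - mean(t))^2)) * 3600
  slopes <- vapply(1:60, function(s) {
    estimate_slope(linear_window(noise_sd = sd_noise, seed = s))$slope_mgL_per_h
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.5), 3 * se_h / sqrt(60))
  expect_gt(sd(slopes), se_h * 0.7)
  expect_lt(sd(slopes), se_h * 1.4)
})

test_that("whole-trace slopes equal per-window least squares", {
  fish <- fixed_fish(true_smr = 0.3)
  tp <- trace_params()
  tr <- simulate_trace(fish, tp, seed = 11)
  ref <- do.call(rbind, lapply(segment_cycles(tr, tp), estimate_slope))
  fast <- estimate_slopes(tr, tp)
  expect_equal(fast$slope_mgL_per_h, ref$slope_mgL_per_h, tolerance = 1e-12)
  expect_equal(fast$r2, ref$r2, tolerance = 1e-12)
  expect_equal(fast$t_mid_s, ref$t_mid_s)
  expect_equal(fast$min_o2_mgL, ref$min_o2_mgL)
})

test_that("background interpolation subtracts the blank line at cycle midpoints", {
  slopes <- data.frame(cycle = 1:3, slope_mgL_per_h = c(-1, -1, -1),
                       t_mid_s = c(0, 9.5, 19) * 3600)
  pre <- data.frame(slope_mgL_per_h = -0.1)
  post <- data.frame(slope_mgL_per_h = -0.3)
  out <- correct_background(slopes, pre, post, mode = "interpolate",
                            trial_duration_s = 19 * 3600)
  expect_equal(out$bg_slope_mgL_per_h, c(-0.1, -0.2, -0.3))
  expect_equal(out$slope_corrected_mgL_per_h[2], -0.8)
  out_mean <- correct_background(slopes, pre, post, mode = "mean")
  expect_equal(out_mean$bg_slope_mgL_per_h, rep(-0.2, 3))
  # zero blanks leave slopes unchanged
  zero <- data.frame(slope_mgL_per_h = 0)
  out0 <- correct_background(slopes, zero, zero)
  expect_equal(out0$slope_corrected_mgL_per_h, slopes$slope_mgL_per_h)
  # a single blank falls back with a warning
  expect_warning(one <- correct_background(slopes, pre, NULL), "one blank")
  expect_equal(one$bg_slope_mgL_per_h, rep(-0.1, 3))
})

test_that("MO2 conversion follows the effective-volume arithmetic", {
  expect_equal(compute_mo2(0, 0.25, 1)$mo2_mg_h, 0)
  out <- compute_mo2(-1.2 - (-0.2), 0.25, 1.0)
  expect_equal(out$mo2_mg_h, 0.249)
  expect_equal(out$mo2_mgkg_h, 249)
  expect_error(compute_mo2(-1, 0.25, 260), "chamber volume")
})

test_that("background correction commutes with MO2 conversion (linearity)", {
  v <- 0.25; m <- 1.1
  s_fish <- -c(1.2, 0.9, 1.5); s_bg <- -c(0.1, 0.12, 0.14)
  a <- compute_mo2(s_fish - s_bg, v, m)$mo2_mg_h
  b <- compute_mo2(s_fish, v, m)$mo2_mg_h - compute_mo2(s_bg, v, m)$mo2_mg_h
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noise-free constant-MO2 traces are recovered to 0.1%", {
  fish <- fixed_fish(true_smr = 0.31, mass_g = 1.3)
  tp <- quiet_trace_params()
  tp$background_fraction <- 0.075
  tr <- simulate_trace(fish, tp, seed = 1)
  bg0 <- 0.075 / (1 - 0.075) * fish$true_smr_mg_h
  bpre <- simulate_blank_trace(tp, bg0, "pre", seed = 2)
  bpost <- simulate_blank_trace(tp, bg0, "post", seed = 3)
  out <- process_trace(tr, bpre, bpost, fish, protocol = tp)
  expect_true(all(abs(out$records$mo2_mg_h / fish$true_smr_mg_h - 1) < 0.001))
})

test_that("QC excludes poor fits and flags (but keeps) low-oxygen cycles", {
  rec <- data.frame(fish_id = "F1", cycle = 1:4, r2 = c(0.99, 0.97, 0.80, 0.99),
                    min_o2_mgL = c(9.5, 5.8, 9.1, 9.4))
  out <- qc_filter(rec, r2_min = 0.95, o2_floor_mgL = 6)
  expect_equal(out$report$n_excluded_r2, 1L)
  expect_equal(out$report$n_kept, 3L)
  expect_equal(out$records$cycle[out$records$flag_low_o2], 2L)
  expect_equal(out$report$n_flagged_low_o2, 1L)
  # unchanged when everything passes
  all_ok <- qc_filter(rec[rec$r2 > 0.9, ], r2_min = 0.9)
  expect_equal(all_ok$report$n_excluded_r2, 0L)
  expect_equal(nrow(all_ok$records), 3L)
  # total exclusion is an error naming the fish
  expect_error(qc_filter(rec, r2_min = 0.999), "F1")
})
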