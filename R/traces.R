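# Raw-trace simulation: intermittent-flow oxygen dynamics for one chamber.
#
# Within a closed measurement phase the oxygen decline is linear because the
# per-cycle oxygen consumption (fish + background) is held constant within the
# cycle; flush phases relax exponentially back toward saturation. This makes
# the generating slope of every cycle available in closed form, which the
# round-trip tests exploit.

# Per-cycle fish MO2 multipliers; must be called inside with_seed().
cycle_mo2_draws <- function(true_smr_mg_h, params) {
  cycle_s <- params$flush_s + params$measure_s
  n_cycles <- floor(params$duration_h * 3600 / cycle_s)
  t_mid <- (seq_len(n_cycles) - 1) * cycle_s + params$flush_s +
    params$measure_s / 2
  active <- rbinom(n_cycles, 1L, params$p_active) *
    rexp(n_cycles, rate = 1 / max(params$activity_mean, 1e-300))
  if (params$activity_mean == 0) active <- numeric(n_cycles)
  acclim <- params$acclimation_amplitude *
    exp(-(t_mid / 3600) / params$acclimation_tau_h)
  data.frame(
    cycle = seq_len(n_cycles),
    t_mid_s = t_mid,
    mo2_mg_h = true_smr_mg_h * (1 + active + acclim)
  )
}

#' Simulate per-cycle oxygen consumption for one fish
#'
#' Returns the cycle-level whole-animal MO2 values (mg O2/h) that
#' [simulate_trace()] would embed in a raw trace under the same seed:
#' true SMR inflated by spontaneous-activity elevations (per-cycle Bernoulli
#' times exponential) and an exponentially decaying acclimation elevation.
#' Useful for testing SMR estimators without simulating full traces.
#'
#' @param fish one-row cohort data.frame with `true_smr_mg_h` filled in.
#' @param params a [trace_params()] object.
#' @param seed integer seed.
#' @return data.frame with `cycle`, `t_mid_s`, `mo2_mg_h`.
#' @export
simulate_cycle_mo2 <- function(fish, params = trace_params(), seed = 1L) {
  stopifnot(inherits(params, "trace_params"), nrow(fish) == 1L,
            is.finite(fish$true_smr_mg_h))
  with_seed(seed, cycle_mo2_draws(fish$true_smr_mg_h, params))
}

# Shared closed-phase integrator. mo2_total_mg_h is per-cycle total (fish +
# background) consumption; returns the full sample grid for `n_cycles` cycles.
build_trace_samples <- function(params, mo2_cycle_mg_h, v_eff_L, start_o2) {
  dt <- params$sample_interval_s
  cycle_s <- params$flush_s + params$measure_s
  # the protocol runs whole flush+measure cycles
  n_cycles_full <- floor(params$duration_h * 3600 / cycle_s)
  n_samples <- n_cycles_full * cycle_s / dt
  t <- (seq_len(n_samples) - 1) * dt
  offset <- t %% cycle_s
  cycle <- as.integer(t %/% cycle_s) + 1L
  phase <- c("F", "M")[(offset >= params$flush_s) + 1L]
  sat <- params$o2_saturation_mgL
  n_cycles_grid <- max(cycle)
  rate <- c(mo2_cycle_mg_h / v_eff_L / 3600,
            rep(0, max(0L, n_cycles_grid - length(mo2_cycle_mg_h))))
  rate <- rate[seq_len(n_cycles_grid)]
  # per-cycle start/end values follow a scalar recursion; the sample grid is
  # then filled with vectorised expressions indexed by cycle
  decay <- exp(-params$flush_s / params$flush_tau_s)
  s_start <- numeric(n_cycles_grid)
  flush_end <- numeric(n_cycles_grid)
  s_c <- start_o2
  for (c in seq_len(n_cycles_grid)) {
    s_start[c] <- s_c
    flush_end[c] <- sat + (s_c - sat) * decay
    s_c <- flush_end[c] - rate[c] * params$measure_s
  }
  in_flush <- offset < params$flush_s
  o2 <- numeric(n_samples)
  o2[in_flush] <- sat + (s_start[cycle[in_flush]] - sat) *
    exp(-offset[in_flush] / params$flush_tau_s)
  o2[!in_flush] <- flush_end[cycle[!in_flush]] -
    rate[cycle[!in_flush]] * (offset[!in_flush] - params$flush_s)
  list(time_s = t, o2_mgL = o2, phase = phase, cycle = cycle)
}

new_raw_trace <- function(samples, chamber, kind, fish_id, protocol,
                          truncated) {
  structure(
    list(chamber = chamber, kind = kind, fish_id = fish_id,
         samples = samples, protocol = protocol, truncated = truncated),
    class = "raw_trace"
  )
}

#' Simulate a raw oxygen trace for one fish
#'
#' Generates the full intermittent-flow trace for one chamber holding one
#' fish: repeated flush (exponential re-oxygenation) and closed measurement
#' phases during which oxygen declines at
#' `(MO2_cycle + MO2_background) / V_eff` mg/L per hour, with effective water
#' volume `V_eff = chamber_volume_L - mass_g/1000` litres. Per-cycle MO2
#' follows [simulate_cycle_mo2()]; background respiration starts at
#' `background_fraction/(1-background_fraction) * true_smr` (so it is the
#' configured fraction of total chamber respiration for a fish at rest) and
#' drifts linearly to `background_drift` times that by trial end. Gaussian
#' sensor noise is added to every sample.
#'
#' Oxygen is truncated at zero (with a warning and a `truncated` flag) if
#' consumption would drive it negative.
#'
#' @inheritParams simulate_cycle_mo2
#' @return a `raw_trace` object: list with `chamber`, `kind = "fish"`,
#'   `fish_id`, `samples` (data.frame `time_s`, `o2_mgL`, `temp_C`, `phase`,
#'   `cycle`), `protocol`, `truncated`.
#' @examples
#' p <- cohort_params()
#' cohort <- simulate_true_smr(generate_cohort(p, seed = 1), p, seed = 2)
#' tr <- simulate_trace(cohort[1, ], trace_params(), seed = 3)
#' tr
#' @export
simulate_trace <- function(fish, params = trace_params(), seed = 1L) {
  stopifnot(inherits(params, "trace_params"), is.data.frame(fish),
            nrow(fish) == 1L)
  if (!is.finite(fish$true_smr_mg_h)) {
    stop("fish has no `true_smr_mg_h`; run simulate_true_smr() first",
         call. = FALSE)
  }
  v_eff <- params$chamber_volume_L - fish$mass_g / 1000
  if (v_eff <= 0) {
    stop("fish volume (mass/1000 L) must be smaller than the chamber volume",
         call. = FALSE)
  }
  with_seed(seed, {
    cyc <- cycle_mo2_draws(fish$true_smr_mg_h, params)
    f <- params$background_fraction
    bg0 <- f / (1 - f) * fish$true_smr_mg_h
    t_end <- params$duration_h * 3600
    bg <- bg0 * (1 + (params$background_drift - 1) * cyc$t_mid_s / t_end)
    grid <- build_trace_samples(params, cyc$mo2_mg_h + bg, v_eff,
                                start_o2 = params$o2_saturation_mgL)
    o2 <- grid$o2_mgL
    truncated <- any(o2 < 0)
    if (truncated) {
      warning("oxygen concentration truncated at 0 mg/L", call. = FALSE)
      o2[o2 < 0] <- 0
    }
    o2 <- o2 + rnorm(length(o2), 0, params$sensor_noise_sd)
    samples <- data.frame(
      time_s = grid$time_s, o2_mgL = o2, temp_C = params$temp_C,
      phase = grid$phase, cycle = grid$cycle, stringsAsFactors = FALSE
    )
    new_raw_trace(samples, chamber = fish$chamber, kind = "fish",
                  fish_id = fish$fish_id, protocol = params,
                  truncated = truncated)
  })
}

#' Simulate a blank (background-only) trace
#'
#' One 15-minute closed cycle driven only by microbial background
#' respiration, as recorded per chamber before (`when = "pre"`) and after
#' (`when = "post"`) a trial; the post-trial blank is scaled by
#' `background_drift`. The same sensor-noise model as fish traces applies.
#'
#' @param params a [trace_params()] object.
#' @param background_mo2_mg_h background oxygen consumption at trial start,
#'   mg O2/h (for a chamber that held a fish at SMR `s`, this is
#'   `background_fraction/(1-background_fraction) * s`).
#' @param when `"pre"` or `"post"`.
#' @param chamber chamber identifier recorded on the trace.
#' @param seed integer seed.
#' @return a `raw_trace` with `kind = "blank_pre"` or `"blank_post"`.
#' @export
simulate_blank_trace <- function(params = trace_params(),
                                 background_mo2_mg_h,
                                 when = c("pre", "post"),
                                 chamber = 1L, seed = 1L) {
  stopifnot(inherits(params, "trace_params"),
            is.numeric(background_mo2_mg_h), background_mo2_mg_h >= 0)
  when <- match.arg(when)
  mo2 <- background_mo2_mg_h *
    if (when == "post") params$background_drift else 1
  rate <- mo2 / params$chamber_volume_L / 3600
  dt <- params$sample_interval_s
  t <- seq(0, params$measure_s - dt, by = dt)
  with_seed(seed, {
    o2 <- params$o2_saturation_mgL - rate * t +
      rnorm(length(t), 0, params$sensor_noise_sd)
    samples <- data.frame(
      time_s = t, o2_mgL = o2, temp_C = params$temp_C,
      phase = "M", cycle = 1L, stringsAsFactors = FALSE
    )
    new_raw_trace(samples, chamber = chamber,
                  kind = paste0("blank_", when), fish_id = NA_character_,
                  protocol = params, truncated = FALSE)
  })
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> kind=%s chamber=%s fish=%s: %d samples, %d cycles%s\n",
              x$kind, as.character(x$chamber),
              if (is.na(x$fish_id)) "-" else x$fish_id,
              nrow(x$samples), max(x$samples$cycle),
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Write a raw trace to CSV
#'
#' Columns: `time_s`, `chamber`, `phase`, `cycle`, `o2_mgL`, `temp_C`.
#'
#' @param trace a `raw_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  out <- data.frame(
    time_s = trace$samples$time_s,
    chamber = trace$chamber,
    phase = trace$samples$phase,
    cycle = trace$samples$cycle,
    o2_mgL = trace$samples$o2_mgL,
    temp_C = trace$samples$temp_C
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw trace from CSV
#'
#' Validates the schema written by [write_trace()]: required columns, strictly
#' increasing time, phase codes in `{F, M}` and non-decreasing cycle indices.
#' Violations are reported with the offending file line number (header is
#' line 1).
#'
#' @param path input CSV path.
#' @param kind `"fish"`, `"blank_pre"` or `"blank_post"`.
#' @param fish_id optional fish identifier to attach.
#' @param protocol optional [trace_params()] describing the protocol.
#' @return a `raw_trace`.
#' @export
read_trace <- function(path, kind = c("fish", "blank_pre", "blank_post"),
                       fish_id = NA_character_, protocol = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "chamber", "phase", "cycle", "o2_mgL", "temp_C")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("trace file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_t <- which(diff(d$time_s) <= 0)
  if (length(bad_t)) {
    stop(sprintf("time_s is not strictly increasing at line %d of %s",
                 bad_t[1] + 2L, path), call. = FALSE)
  }
  bad_p <- which(!d$phase %in% c("F", "M"))
  if (length(bad_p)) {
    stop(sprintf("unknown phase code '%s' at line %d of %s",
                 d$phase[bad_p[1]], bad_p[1] + 1L, path), call. = FALSE)
  }
  bad_c <- which(diff(d$cycle) < 0)
  if (length(bad_c)) {
    stop(sprintf("cycle index decreases at line %d of %s",
                 bad_c[1] + 2L, path), call. = FALSE)
  }
  samples <- data.frame(
    time_s = d$time_s, o2_mgL = d$o2_mgL, temp_C = d$temp_C,
    phase = d$phase, cycle = d$cycle, stringsAsFactors = FALSE
  )
  new_raw_trace(samples, chamber = d$chamber[1], kind = kind,
                fish_id = fish_id, protocol = protocol, truncated = FALSE)
}
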