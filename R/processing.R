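# Trace processing: closed-phase segmentation, per-cycle OLS slopes,
# background correction and conversion to whole-animal oxygen consumption.

#' Segment a trace into closed-phase measurement windows
#'
#' Extracts one sample window per closed (measurement) phase, discarding the
#' first `wait_trim_s` seconds of each window as a mixing/transition period.
#' Windows are non-overlapping and time ordered. Cycles whose closed phase is
#' not longer than `wait_trim_s` are dropped with a warning.
#'
#' @param trace a `raw_trace`.
#' @param protocol a [trace_params()] object; defaults to the protocol stored
#'   on the trace.
#' @param wait_trim_s seconds trimmed from the start of each closed phase
#'   (default 120).
#' @return list of data.frames (columns of `trace$samples`), one per retained
#'   cycle, each carrying attributes `cycle` and `t_mid_s` (the midpoint of
#'   the full closed phase).
#' @examples
#' p <- cohort_params()
#' cohort <- simulate_true_smr(generate_cohort(p, seed = 1), p, seed = 2)
#' tr <- simulate_trace(cohort[1, ], trace_params(), seed = 3)
#' length(segment_cycles(tr))  # floor(19 h / 20 min) = 57 windows
#' @export
segment_cycles <- function(trace, protocol = NULL, wait_trim_s = 120) {
  stopifnot(inherits(trace, "raw_trace"))
  protocol <- protocol %||% trace$protocol
  if (is.null(protocol)) {
    stop("no protocol available: pass `protocol` or use a trace that carries one",
         call. = FALSE)
  }
  check_number(wait_trim_s, "wait_trim_s", lower = 0)
  s <- trace$samples
  m <- s[s$phase == "M", , drop = FALSE]
  if (!nrow(m)) stop("trace contains no closed-phase samples", call. = FALSE)
  cyc_f <- factor(m$cycle, levels = unique(m$cycle))
  t0 <- stats::ave(m$time_s, cyc_f, FUN = min)
  t1 <- stats::ave(m$time_s, cyc_f, FUN = max)
  keep <- m$time_s - t0 >= wait_trim_s
  mids <- tapply((t0 + t1) / 2, cyc_f, `[`, 1L)
  pieces <- split(m[keep, , drop = FALSE], cyc_f[keep], drop = FALSE)
  windows <- list()
  dropped <- 0L
  for (i in seq_along(pieces)) {
    out <- pieces[[i]]
    if (!nrow(out)) {
      dropped <- dropped + 1L
      next
    }
    attr(out, "cycle") <- out$cycle[1]
    attr(out, "t_mid_s") <- unname(mids[[i]])
    windows[[length(windows) + 1L]] <- out
  }
  if (dropped > 0L) {
    warning(sprintf("%d cycle(s) shorter than wait_trim_s dropped", dropped),
            call. = FALSE)
  }
  windows
}

#' Ordinary least-squares slope of a closed-phase window
#'
#' Regresses oxygen concentration on time within one measurement window and
#' reports the slope in mg O2 L^-1 h^-1 (signed: consumption gives a negative
#' slope). R-squared is `NA` when the oxygen signal has zero variance (the
#' slope is then 0 by construction).
#'
#' @param window a data.frame with `time_s` and `o2_mgL` (as produced by
#'   [segment_cycles()]).
#' @return one-row data.frame: `cycle`, `slope_mgL_per_h`, `intercept_mgL`,
#'   `r2`, `n_samples`, `min_o2_mgL`, `t_mid_s`.
#' @export
estimate_slope <- function(window) {
  n <- nrow(window)
  if (is.null(n) || n < 10L) {
    stop("slope estimation needs at least 10 samples", call. = FALSE)
  }
  t <- window$time_s
  y <- window$o2_mgL
  if (var(t) == 0) stop("zero time variance in window", call. = FALSE)
  fit <- lm.fit(cbind(1, t - mean(t)), y)
  slope_s <- fit$coefficients[2]
  intercept <- fit$coefficients[1] - slope_s * mean(t)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum(fit$residuals^2) / tss
  data.frame(
    cycle = attr(window, "cycle") %||% window$cycle[1],
    slope_mgL_per_h = unname(slope_s) * 3600,
    intercept_mgL = unname(intercept),
    r2 = r2,
    n_samples = n,
    min_o2_mgL = min(y),
    t_mid_s = attr(window, "t_mid_s") %||% ((min(t) + max(t)) / 2)
  )
}

#' Per-cycle slopes for a whole trace
#'
#' Computes every closed-phase slope in one pass over the trace using grouped
#' centred sufficient statistics (algebraically the same least squares as
#' [estimate_slope()], which fits each window by QR decomposition; the two
#' agree to numerical precision). Windows left with fewer than 10 samples
#' after trimming are dropped with a warning.
#'
#' @inheritParams segment_cycles
#' @return data.frame of [estimate_slope()] rows, one per retained cycle.
#' @export
estimate_slopes <- function(trace, protocol = NULL, wait_trim_s = 120) {
  stopifnot(inherits(trace, "raw_trace"))
  check_number(wait_trim_s, "wait_trim_s", lower = 0)
  s <- trace$samples
  m_idx <- s$phase == "M"
  if (!any(m_idx)) stop("trace contains no closed-phase samples", call. = FALSE)
  t_all <- s$time_s[m_idx]
  y_all <- s$o2_mgL[m_idx]
  g_all <- s$cycle[m_idx]
  nm <- length(g_all)
  # closed-phase samples of each cycle are contiguous and time-sorted
  starts <- which(c(TRUE, g_all[-1] != g_all[-nm]))
  ends <- c(starts[-1] - 1L, nm)
  sizes <- ends - starts + 1L
  t0 <- t_all[starts]
  mids <- (t0 + t_all[ends]) / 2
  keep <- t_all - rep(t0, sizes) >= wait_trim_s
  grp <- rep(seq_along(starts), sizes)
  kept_n <- as.vector(rowsum(as.numeric(keep), grp, reorder = FALSE))
  dropped <- sum(kept_n < 10L)
  if (dropped > 0L) {
    warning(sprintf("%d cycle(s) with fewer than 10 samples after trimming dropped",
                    dropped), call. = FALSE)
  }
  ok_grp <- kept_n >= 10L
  if (!any(ok_grp)) {
    stop("no closed-phase window survives trimming", call. = FALSE)
  }
  keep <- keep & ok_grp[grp]
  x <- t_all[keep]
  y <- y_all[keep]
  gi <- grp[keep]
  s1 <- rowsum(cbind(one = 1, t = x, y = y), gi, reorder = FALSE)
  n <- s1[, "one"]
  tm <- s1[, "t"] / n
  ym <- s1[, "y"] / n
  # gi values are sorted; map them to 1..G for indexing
  gj <- cumsum(c(TRUE, gi[-1] != gi[-length(gi)]))
  xc <- x - tm[gj]
  yc <- y - ym[gj]
  s2 <- rowsum(cbind(xx = xc * xc, xy = xc * yc, yy = yc * yc), gi,
               reorder = FALSE)
  slope_s <- s2[, "xy"] / s2[, "xx"]
  tss <- s2[, "yy"]
  r2 <- ifelse(tss == 0, NA_real_, slope_s^2 * s2[, "xx"] / tss)
  # trimming removes the head of each window, so kept samples per window are
  # still contiguous: window minima come from slice scans
  ks <- which(c(TRUE, gi[-1] != gi[-length(gi)]))
  ke <- c(ks[-1] - 1L, length(gi))
  min_o2 <- vapply(seq_along(ks),
                   function(j) min(y[ks[j]:ke[j]]), numeric(1))
  sel <- which(ok_grp)
  data.frame(
    cycle = g_all[starts][sel],
    slope_mgL_per_h = unname(slope_s) * 3600,
    intercept_mgL = unname(ym - slope_s * tm),
    r2 = unname(r2),
    n_samples = as.integer(n),
    min_o2_mgL = min_o2,
    t_mid_s = mids[sel],
    row.names = NULL
  )
}

#' Background-correct per-cycle slopes
#'
#' Subtracts microbial background respiration, measured as the slope of blank
#' (empty-chamber) runs recorded before and after the trial in the same
#' chamber. The default mode interpolates linearly in time between the pre-
#' and post-trial blank slopes, evaluated at each cycle's midpoint;
#' `mode = "mean"` subtracts their average. With only one blank available in
#' interpolate mode, that blank is used alone with a warning.
#'
#' Corrected slopes are expected to stay negative (net fish consumption);
#' cycles whose corrected slope turns positive are flagged.
#'
#' @param slopes data.frame from [estimate_slopes()].
#' @param blank_pre,blank_post one-row data.frames from [estimate_slope()] on
#'   the corresponding blank traces, or `NULL` if missing.
#' @param mode `"interpolate"` (default) or `"mean"`.
#' @param trial_duration_s time from trial start to the post-trial blank;
#'   used as the interpolation span.
#' @return `slopes` with columns `bg_slope_mgL_per_h`,
#'   `slope_corrected_mgL_per_h` and logical `flag_positive_slope` added.
#' @export
correct_background <- function(slopes, blank_pre = NULL, blank_post = NULL,
                               mode = c("interpolate", "mean"),
                               trial_duration_s = NULL) {
  mode <- match.arg(mode)
  if (is.null(blank_pre) && is.null(blank_post)) {
    stop("at least one blank slope is required", call. = FALSE)
  }
  pre <- if (!is.null(blank_pre)) blank_pre$slope_mgL_per_h else NULL
  post <- if (!is.null(blank_post)) blank_post$slope_mgL_per_h else NULL
  if (mode == "interpolate" && (is.null(pre) || is.null(post))) {
    warning("only one blank available; falling back to constant background",
            call. = FALSE)
    mode <- "mean"
  }
  bg <- if (mode == "mean") {
    rep(mean(c(pre, post)), nrow(slopes))
  } else {
    span <- trial_duration_s %||% max(slopes$t_mid_s)
    pre + (post - pre) * slopes$t_mid_s / span
  }
  slopes$bg_slope_mgL_per_h <- bg
  slopes$slope_corrected_mgL_per_h <- slopes$slope_mgL_per_h - bg
  slopes$flag_positive_slope <- slopes$slope_corrected_mgL_per_h > 0
  slopes
}

#' Convert a corrected slope to oxygen consumption
#'
#' `MO2 = -slope * (chamber_volume_L - mass_g/1000)` mg O2/h, taking the fish
#' body volume as mass at a density of 1 g/mL; the mass-specific rate divides
#' by mass in kg.
#'
#' @param corrected_slope_mgL_per_h background-corrected slope(s),
#'   mg L^-1 h^-1 (negative for consumption).
#' @param chamber_volume_L respirometer volume, litres.
#' @param mass_g fish body mass, grams.
#' @return data.frame with `mo2_mg_h` (whole animal) and `mo2_mgkg_h`
#'   (mass-specific, mg O2 kg^-1 h^-1).
#' @examples
#' compute_mo2(-1.0, chamber_volume_L = 0.25, mass_g = 1)  # 0.249 mg O2/h
#' @export
compute_mo2 <- function(corrected_slope_mgL_per_h, chamber_volume_L, mass_g) {
  check_number(chamber_volume_L, "chamber_volume_L", lower = 0,
               allow_equal_lower = FALSE)
  check_number(mass_g, "mass_g", lower = 0, allow_equal_lower = FALSE)
  v_eff <- chamber_volume_L - mass_g / 1000
  if (v_eff <= 0) {
    stop("fish volume (mass_g/1000 L) must be below the chamber volume",
         call. = FALSE)
  }
  mo2 <- -corrected_slope_mgL_per_h * v_eff
  data.frame(mo2_mg_h = mo2, mo2_mgkg_h = mo2 / (mass_g / 1000))
}

#' Quality-control filter for per-cycle MO2 records
#'
#' Excludes cycles whose within-cycle regression fit is poor
#' (`r2 < r2_min`, or undefined) and flags — without excluding — cycles in
#' which oxygen dipped below `o2_floor_mgL` (hypoxia can itself depress
#' metabolic rate, so such cycles are reported rather than silently used).
#'
#' @param records data.frame of per-cycle records carrying `r2` and
#'   `min_o2_mgL` columns (see [process_trace()]).
#' @param r2_min minimum acceptable within-cycle R-squared (default 0.95).
#' @param o2_floor_mgL oxygen floor for the low-oxygen flag (default 6 mg/L).
#' @return list with `records` (kept rows, `flag_low_o2` added) and `report`
#'   (data.frame: `n_input`, `n_excluded_r2`, `n_flagged_low_o2`, `n_kept`).
#' @export
qc_filter <- function(records, r2_min = 0.95, o2_floor_mgL = 6) {
  check_number(r2_min, "r2_min", lower = 0, upper = 1)
  check_number(o2_floor_mgL, "o2_floor_mgL", lower = 0)
  ok <- !is.na(records$r2) & records$r2 >= r2_min
  kept <- records[ok, , drop = FALSE]
  if (!nrow(kept)) {
    who <- if (!is.null(records$fish_id)) unique(records$fish_id) else "trace"
    stop("all cycles excluded by QC for ", paste(who, collapse = ", "),
         call. = FALSE)
  }
  kept$flag_low_o2 <- kept$min_o2_mgL < o2_floor_mgL
  report <- data.frame(
    n_input = nrow(records),
    n_excluded_r2 = sum(!ok),
    n_flagged_low_o2 = sum(kept$flag_low_o2),
    n_kept = nrow(kept)
  )
  list(records = kept, report = report)
}

#' Process one fish trace to per-cycle MO2 records
#'
#' Full single-chamber processing chain: segment closed phases, fit per-cycle
#' OLS slopes, subtract blank-derived background respiration, convert to
#' whole-animal and mass-specific oxygen consumption, and apply QC.
#'
#' @param trace `raw_trace` of kind `"fish"`.
#' @param blank_pre,blank_post blank `raw_trace`s for the same chamber (either
#'   may be `NULL`).
#' @param fish one-row cohort data.frame for the fish in the chamber.
#' @param protocol a [trace_params()]; defaults to the trace's own.
#' @param wait_trim_s seconds trimmed at the start of each closed phase.
#' @param mode background-correction mode, see [correct_background()].
#' @param r2_min,o2_floor_mgL QC thresholds, see [qc_filter()].
#' @return list with `records` (data.frame: `fish_id`, `cycle`, `t_mid_s`,
#'   `slope_mgL_per_h`, `bg_slope_mgL_per_h`, `slope_corrected_mgL_per_h`,
#'   `r2`, `min_o2_mgL`, `mo2_mg_h`, `mo2_mgkg_h`, flags) and `report`.
#' @export
process_trace <- function(trace, blank_pre = NULL, blank_post = NULL,
                          fish, protocol = NULL, wait_trim_s = 120,
                          mode = "interpolate",
                          r2_min = 0.95, o2_floor_mgL = 6) {
  stopifnot(inherits(trace, "raw_trace"), nrow(fish) == 1L)
  protocol <- protocol %||% trace$protocol
  slopes <- estimate_slopes(trace, protocol, wait_trim_s)
  pre_s <- if (!is.null(blank_pre)) {
    estimate_slope(segment_cycles(blank_pre, protocol, wait_trim_s = 0)[[1]])
  }
  post_s <- if (!is.null(blank_post)) {
    estimate_slope(segment_cycles(blank_post, protocol, wait_trim_s = 0)[[1]])
  }
  slopes <- correct_background(slopes, pre_s, post_s, mode = mode,
                               trial_duration_s = protocol$duration_h * 3600)
  mo2 <- compute_mo2(slopes$slope_corrected_mgL_per_h,
                     protocol$chamber_volume_L, fish$mass_g)
  records <- cbind(
    data.frame(fish_id = fish$fish_id, stringsAsFactors = FALSE),
    slopes, mo2
  )
  records$flag_truncated <- isTRUE(trace$truncated)
  out <- qc_filter(records, r2_min = r2_min, o2_floor_mgL = o2_floor_mgL)
  out$report$fish_id <- fish$fish_id
  out
}
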