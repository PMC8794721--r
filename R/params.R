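#' Cohort-level simulation parameters
#'
#' Describes a study cohort: family/genotype structure, batch layout, the body
#' mass distribution, and the generating model for true standard metabolic
#' rate (SMR) on the log10 scale,
#' \deqn{\log_{10} SMR = \log_{10} a + b \log_{10} M + \beta X + u_{fam} + v_{batch} + e.}
#'
#' Defaults emulate a common-garden design of 150 juvenile Atlantic salmon
#' (~1 g) from 14 full-sib families, each family homozygous for one vgll3
#' age-at-maturity genotype (7 EE families, 7 LL), measured in 10 respirometry
#' batches of up to 16 chambers.
#'
#' @param n_families number of full-sib families.
#' @param families_per_genotype families carrying each genotype; must satisfy
#'   `2 * families_per_genotype == n_families`.
#' @param fish_per_family fish sampled per family before trimming.
#' @param n_fish_total total cohort size; families are trimmed round-robin
#'   from the last family backwards until this total is reached.
#' @param n_batches number of respirometry batches (days).
#' @param chambers_per_batch chambers available per batch.
#' @param mass_meanlog,mass_sdlog log-normal body-mass parameters (natural
#'   log, grams). Defaults give mean ~1.08 g with ~0.5-1.9 g range.
#' @param length_coef,length_sdlog fork length is
#'   `length_coef * mass_g^(1/3)` mm with multiplicative log-normal noise
#'   (isometric length-mass allometry).
#' @param allometric_intercept whole-animal SMR in mg O2 h^-1 for a 1 g fish.
#' @param allometric_exponent metabolic mass-scaling exponent `b` (default
#'   0.88).
#' @param beta_vgll3,beta_sex,beta_interaction fixed effects on log10 SMR for
#'   genotype LL, sex M, and their interaction (treatment coding, reference
#'   EE females).
#' @param beta_temp fixed effect of holding temperature (per degree C,
#'   centred at `temp_C`).
#' @param sd_family,sd_batch,sd_residual standard deviations of the family
#'   and batch random intercepts and the residual, all on the log10 scale.
#'   The residual default 0.027 corresponds to a residual coefficient of
#'   variation of ~6.2% (see [residual_cv()]).
#' @param temp_C nominal holding temperature, degrees C.
#' @param temp_sd_C between-batch SD of the average holding temperature
#'   covariate. Kept positive by default so the temperature covariate is not
#'   constant (a constant column would make the full model rank-deficient).
#'
#' @return an object of class `cohort_params` (a validated named list).
#' @seealso [generate_cohort()], [simulate_true_smr()], [trace_params()]
#' @examples
#' p <- cohort_params()
#' p$allometric_exponent
#' @export
cohort_params <- function(n_families = 14L,
                          families_per_genotype = 7L,
                          fish_per_family = 11L,
                          n_fish_total = 150L,
                          n_batches = 10L,
                          chambers_per_batch = 16L,
                          mass_meanlog = log(1.08) - 0.25^2 / 2,
                          mass_sdlog = 0.25,
                          length_coef = 41.4,
                          length_sdlog = 0.02,
                          allometric_intercept = 0.25,
                          allometric_exponent = 0.88,
                          beta_vgll3 = 0,
                          beta_sex = 0,
                          beta_interaction = 0,
                          beta_temp = 0,
                          sd_family = 0.008,
                          sd_batch = 0.005,
                          sd_residual = 0.027,
                          temp_C = 10.3,
                          temp_sd_C = 0.3) {
  p <- list(
    n_families = check_count(n_families, "n_families", 2L),
    families_per_genotype = check_count(families_per_genotype,
                                        "families_per_genotype", 1L),
    fish_per_family = check_count(fish_per_family, "fish_per_family", 1L),
    n_fish_total = check_count(n_fish_total, "n_fish_total", 2L),
    n_batches = check_count(n_batches, "n_batches", 1L),
    chambers_per_batch = check_count(chambers_per_batch,
                                     "chambers_per_batch", 1L),
    mass_meanlog = check_number(mass_meanlog, "mass_meanlog"),
    mass_sdlog = check_number(mass_sdlog, "mass_sdlog", lower = 0),
    length_coef = check_number(length_coef, "length_coef", lower = 0,
                               allow_equal_lower = FALSE),
    length_sdlog = check_number(length_sdlog, "length_sdlog", lower = 0),
    allometric_intercept = check_number(allometric_intercept,
                                        "allometric_intercept", lower = 0,
                                        allow_equal_lower = FALSE),
    allometric_exponent = check_number(allometric_exponent,
                                       "allometric_exponent",
                                       lower = 0, upper = 2,
                                       allow_equal_lower = FALSE,
                                       allow_equal_upper = FALSE),
    beta_vgll3 = check_number(beta_vgll3, "beta_vgll3"),
    beta_sex = check_number(beta_sex, "beta_sex"),
    beta_interaction = check_number(beta_interaction, "beta_interaction"),
    beta_temp = check_number(beta_temp, "beta_temp"),
    sd_family = check_number(sd_family, "sd_family", lower = 0),
    sd_batch = check_number(sd_batch, "sd_batch", lower = 0),
    sd_residual = check_number(sd_residual, "sd_residual", lower = 0),
    temp_C = check_number(temp_C, "temp_C"),
    temp_sd_C = check_number(temp_sd_C, "temp_sd_C", lower = 0)
  )
  if (2L * p$families_per_genotype != p$n_families) {
    stop("`n_families` must equal twice `families_per_genotype` ",
         "(balanced genotype design)", call. = FALSE)
  }
  if (p$n_fish_total > p$n_families * p$fish_per_family) {
    stop("`n_fish_total` exceeds n_families * fish_per_family", call. = FALSE)
  }
  if (ceiling(p$n_fish_total / p$n_batches) > p$chambers_per_batch) {
    stop("infeasible design: more fish per batch than available chambers",
         call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' Respirometry trace simulation parameters
#'
#' Describes the intermittent-flow protocol and the within-trial dynamics used
#' to simulate raw oxygen traces: flush/measurement cycling, chamber geometry,
#' microbial background respiration, spontaneous activity, acclimation decay
#' and sensor noise.
#'
#' During a closed measurement phase the chamber oxygen declines as
#' `dO2/dt = -(MO2_cycle + MO2_background) / V_eff` with effective volume
#' `V_eff = chamber_volume_L - mass_g/1000` (fish density taken as 1 g/mL).
#' Flush phases relax oxygen back toward saturation exponentially.
#'
#' @param flush_s open flush-phase duration, seconds.
#' @param measure_s closed measurement-phase duration, seconds.
#' @param sample_interval_s oxygen sampling interval, seconds.
#' @param duration_h total trial duration, hours. The defaults give
#'   `floor(19 * 3600 / 1200) = 57` flush+measure cycles.
#' @param chamber_volume_L respirometer volume, litres. A free design
#'   parameter of the simulator; all MO2 arithmetic is parameterised by it.
#' @param o2_saturation_mgL dissolved-oxygen saturation at the holding
#'   temperature, mg/L (fixed constant; no solubility tables).
#' @param background_fraction microbial background respiration as a fraction
#'   of total chamber respiration at trial start, for a fish at rest.
#' @param background_drift multiplier on background MO2 from the pre-trial to
#'   the post-trial blank (microbial growth over the trial).
#' @param p_active per-cycle probability of a spontaneous-activity elevation.
#' @param activity_mean mean of the exponential multiplicative MO2 elevation
#'   when active.
#' @param acclimation_amplitude initial multiplicative MO2 elevation from
#'   handling stress, decaying exponentially.
#' @param acclimation_tau_h e-folding time of the acclimation decay, hours.
#' @param sensor_noise_sd Gaussian sensor noise SD per sample, mg/L.
#' @param flush_tau_s time constant of the exponential return to saturation
#'   during the flush phase, seconds.
#' @param temp_C water temperature recorded on the trace, degrees C.
#'
#' @return an object of class `trace_params`.
#' @seealso [simulate_trace()], [simulate_blank_trace()], [segment_cycles()]
#' @export
trace_params <- function(flush_s = 300,
                         measure_s = 900,
                         sample_interval_s = 2,
                         duration_h = 19,
                         chamber_volume_L = 0.25,
                         o2_saturation_mgL = 10.8,
                         background_fraction = 0.075,
                         background_drift = 1.5,
                         p_active = 0.3,
                         activity_mean = 0.5,
                         acclimation_amplitude = 0.5,
                         acclimation_tau_h = 3,
                         sensor_noise_sd = 0.005,
                         flush_tau_s = 60,
                         temp_C = 10.53) {
  p <- list(
    flush_s = check_number(flush_s, "flush_s", lower = 0),
    measure_s = check_number(measure_s, "measure_s", lower = 0,
                             allow_equal_lower = FALSE),
    sample_interval_s = check_number(sample_interval_s, "sample_interval_s",
                                     lower = 0, allow_equal_lower = FALSE),
    duration_h = check_number(duration_h, "duration_h", lower = 0,
                              allow_equal_lower = FALSE),
    chamber_volume_L = check_number(chamber_volume_L, "chamber_volume_L",
                                    lower = 0, allow_equal_lower = FALSE),
    o2_saturation_mgL = check_number(o2_saturation_mgL, "o2_saturation_mgL",
                                     lower = 0, allow_equal_lower = FALSE),
    background_fraction = check_number(background_fraction,
                                       "background_fraction",
                                       lower = 0, upper = 1,
                                       allow_equal_upper = FALSE),
    background_drift = check_number(background_drift, "background_drift",
                                    lower = 0),
    p_active = check_number(p_active, "p_active", lower = 0, upper = 1),
    activity_mean = check_number(activity_mean, "activity_mean", lower = 0),
    acclimation_amplitude = check_number(acclimation_amplitude,
                                         "acclimation_amplitude", lower = 0),
    acclimation_tau_h = check_number(acclimation_tau_h, "acclimation_tau_h",
                                     lower = 0, allow_equal_lower = FALSE),
    sensor_noise_sd = check_number(sensor_noise_sd, "sensor_noise_sd",
                                   lower = 0),
    flush_tau_s = check_number(flush_tau_s, "flush_tau_s", lower = 0,
                               allow_equal_lower = FALSE),
    temp_C = check_number(temp_C, "temp_C")
  )
  cycle_s <- p$flush_s + p$measure_s
  if (p$duration_h * 3600 < cycle_s) {
    stop("`duration_h` is shorter than one flush+measure cycle", call. = FALSE)
  }
  structure(p, class = "trace_params")
}

#' Read simulation parameters from a YAML configuration file
#'
#' The file may contain top-level `cohort:` and `trace:` blocks whose entries
#' correspond to the arguments of [cohort_params()] and [trace_params()];
#' omitted entries keep their defaults.
#'
#' @param path path to a YAML file.
#' @return list with elements `cohort` and `trace`.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read configuration files",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  list(
    cohort = do.call(cohort_params, cfg$cohort %||% list()),
    trace = do.call(trace_params, cfg$trace %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_params <- function(x, ...) {
  cat("Cohort parameters:", x$n_fish_total, "fish,", x$n_families,
      "families (", x$families_per_genotype, "EE /",
      x$families_per_genotype, "LL ),", x$n_batches, "batches\n")
  cat(sprintf("  allometry: SMR = %.3g * mass^%.2f mg O2/h; sd(family/batch/resid) = %.3g/%.3g/%.3g (log10)\n",
              x$allometric_intercept, x$allometric_exponent,
              x$sd_family, x$sd_batch, x$sd_residual))
  invisible(x)
}

#' @export
print.trace_params <- function(x, ...) {
  n_cycles <- floor(x$duration_h * 3600 / (x$flush_s + x$measure_s))
  cat(sprintf("Trace protocol: %g s flush / %g s measure, %g s sampling, %g h (%d cycles)\n",
              x$flush_s, x$measure_s, x$sample_interval_s, x$duration_h,
              n_cycles))
  cat(sprintf("  chamber %g L, background %g of total (drift x%g), sensor noise %g mg/L\n",
              x$chamber_volume_L, x$background_fraction, x$background_drift,
              x$sensor_noise_sd))
  invisible(x)
}
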