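#' Generate a study cohort
#'
#' Creates the fish-level metadata for a simulated cohort: family and genotype
#' structure, sex, body mass and length, and the allocation of fish to
#' respirometry batches and chambers. Fish are dealt to batches round-robin in
#' family order, so every family is spread across batches and every batch
#' holds an (almost) equal number of fish; chambers are numbered within batch.
#'
#' Each family carries exactly one vgll3 genotype; half of the families are
#' EE and half LL. When `fish_per_family * n_families` exceeds
#' `n_fish_total`, one fish at a time is trimmed from the last family
#' backwards until the target total is reached.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed; the result is a deterministic function of
#'   `params` and `seed`.
#' @return a `data.frame` with one row per fish: `fish_id`, `family_id`,
#'   `genotype` (factor EE/LL), `sex` (factor F/M), `mass_g`, `length_mm`,
#'   `batch`, `chamber`, `avg_temp_C`, and `true_smr_mg_h` (NA until
#'   [simulate_true_smr()] is applied).
#' @examples
#' cohort <- generate_cohort(cohort_params(), seed = 1)
#' table(cohort$genotype)
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    sizes <- rep(params$fish_per_family, params$n_families)
    excess <- sum(sizes) - params$n_fish_total
    i <- params$n_families
    while (excess > 0L) {
      sizes[i] <- sizes[i] - 1L
      excess <- excess - 1L
      i <- if (i == 1L) params$n_families else i - 1L
    }
    family_id <- rep(seq_len(params$n_families), times = sizes)
    geno_map <- rep(c("EE", "LL"), each = params$families_per_genotype)
    n <- params$n_fish_total

    # Deal fish (listed family by family) to batches round-robin: batches end
    # up balanced and each family spans as many batches as it has fish.
    batch <- rep_len(seq_len(params$n_batches), n)
    chamber <- integer(n)
    for (b in seq_len(params$n_batches)) {
      idx <- which(batch == b)
      chamber[idx] <- seq_along(idx)
    }
    if (max(tabulate(batch, params$n_batches)) > params$chambers_per_batch) {
      stop("infeasible design: more fish per batch than available chambers",
           call. = FALSE)
    }

    mass_g <- rlnorm(n, params$mass_meanlog, params$mass_sdlog)
    length_mm <- params$length_coef * mass_g^(1 / 3) *
      exp(rnorm(n, 0, params$length_sdlog))
    batch_temp <- params$temp_C + rnorm(params$n_batches, 0, params$temp_sd_C)

    data.frame(
      fish_id = sprintf("F%03d", seq_len(n)),
      family_id = family_id,
      genotype = factor(geno_map[family_id], levels = c("EE", "LL")),
      sex = factor(ifelse(runif(n) < 0.5, "M", "F"), levels = c("F", "M")),
      mass_g = mass_g,
      length_mm = length_mm,
      batch = batch,
      chamber = chamber,
      avg_temp_C = batch_temp[batch],
      true_smr_mg_h = NA_real_,
      stringsAsFactors = FALSE
    )
  })
}

#' Fill in ground-truth SMR for a cohort
#'
#' Draws each fish's true whole-animal standard metabolic rate from the
#' allometric mixed-model structure
#' `log10(SMR) = log10(a) + b*log10(mass) + beta_vgll3*LL + beta_sex*M +
#' beta_interaction*(LL:M) + beta_temp*(temp - temp_C) + u_family + v_batch + e`
#' with independent zero-mean Gaussian family, batch and residual components
#' of the configured SDs.
#'
#' @inheritParams generate_cohort
#' @param cohort a cohort from [generate_cohort()].
#' @return the cohort with `true_smr_mg_h` filled in.
#' @examples
#' p <- cohort_params()
#' cohort <- simulate_true_smr(generate_cohort(p, seed = 1), p, seed = 2)
#' @export
simulate_true_smr <- function(cohort, params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"), is.data.frame(cohort))
  with_seed(seed, {
    u <- rnorm(params$n_families, 0, params$sd_family)
    v <- rnorm(params$n_batches, 0, params$sd_batch)
    e <- rnorm(nrow(cohort), 0, params$sd_residual)
    ll <- as.integer(cohort$genotype == "LL")
    m <- as.integer(cohort$sex == "M")
    log10_smr <- log10(params$allometric_intercept) +
      params$allometric_exponent * log10(cohort$mass_g) +
      params$beta_vgll3 * ll +
      params$beta_sex * m +
      params$beta_interaction * ll * m +
      params$beta_temp * (cohort$avg_temp_C - params$temp_C) +
      u[cohort$family_id] + v[cohort$batch] + e
    cohort$true_smr_mg_h <- 10^log10_smr
    cohort
  })
}

#' Simulate an analysis table directly from the generating model
#'
#' Convenience wrapper combining [generate_cohort()], [simulate_true_smr()]
#' and [build_analysis_table()] with the true SMR used in place of a
#' respirometry-derived estimate. This is the model-level simulator used for
#' parameter-recovery experiments and the power analysis, where the
#' trace-processing stages are not under study.
#'
#' @inheritParams generate_cohort
#' @return an analysis table as produced by [build_analysis_table()].
#' @export
simulate_analysis_table <- function(params = cohort_params(), seed = 1L) {
  cohort <- generate_cohort(params, seed = seed)
  cohort <- simulate_true_smr(cohort, params, seed = seed + 1L)
  smr <- data.frame(fish_id = cohort$fish_id,
                    smr_mg_h = cohort$true_smr_mg_h,
                    stringsAsFactors = FALSE)
  build_analysis_table(cohort, smr)
}
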