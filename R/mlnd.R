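# SMR estimation from per-cycle MO2 values.
#
# The primary estimator is the mean of the lowest normal distribution (MLND):
# a univariate Gaussian mixture is fitted to the per-cycle values by EM, the
# number of components is chosen by BIC, and SMR is the mean of the component
# with the smallest mean. Elevated cycles (spontaneous activity, incomplete
# acclimation) populate the upper components and are thereby removed from the
# SMR estimate without any explicit early-cycle exclusion.

# Fit a k-component mixture with multiple restarts; returns the best
# screening run (polished later if it wins model selection).
fit_gmm <- function(x, k, equal_var, n_restarts = 10L, tol = 1e-8,
                    max_iter = 500L) {
  n <- length(x)
  s <- sd(x)
  sd_floor <- max(s * 1e-6, 1e-12)
  if (k == 1L) {
    mu <- mean(x)
    sig <- max(sqrt(sum((x - mu)^2) / n), sd_floor)
    ll <- sum(dnorm(x, mu, sig, log = TRUE))
    return(list(loglik = ll, mu = mu, sd = sig, w = 1,
                converged = TRUE, equal_var = TRUE))
  }
  probs <- seq(0.5 / k, 1 - 0.5 / k, length.out = k)
  base_mu <- as.numeric(quantile(x, probs, type = 7))
  # restart 1 from the quantile spread, the rest jittered; short screening
  # runs here, the BIC winner is polished to full tolerance afterwards —
  # the usual multi-start economy
  init <- matrix(base_mu, n_restarts, k, byrow = TRUE)
  if (n_restarts > 1L) {
    jit <- matrix(runif((n_restarts - 1L) * k, -0.5, 0.5) * s,
                  n_restarts - 1L, k)
    init[-1L, ] <- t(apply(init[-1L, , drop = FALSE] + jit, 1L, sort))
  }
  run <- gmm_em_multi(x, init, s, equal_var, max(tol, 1e-4),
                      min(max_iter, 40L), sd_floor)
  if (!isTRUE(run$ok)) return(NULL)
  run$equal_var <- equal_var
  run
}

# Posterior responsibilities for hard assignment, from final parameters.
gmm_assign <- function(x, mu, sigma, w) {
  dens <- vapply(seq_along(mu),
                 function(j) w[j] * dnorm(x, mu[j], max(sigma[j], 1e-300)),
                 numeric(length(x)))
  max.col(matrix(dens, nrow = length(x)), ties.method = "first")
}

new_smr_estimate <- function(fish_id, method, smr_mg_h, mass_g, n_used,
                             n_components = NA_integer_,
                             component_means = NULL,
                             component_sds = NULL,
                             component_weights = NULL,
                             component_model = NA_character_,
                             cv_within = NA_real_, q = NA_real_) {
  structure(
    list(fish_id = fish_id, method = method, smr_mg_h = smr_mg_h,
         smr_mgkg_h = if (is.null(mass_g) || is.na(mass_g)) NA_real_ else
           smr_mg_h / (mass_g / 1000),
         n_cycles_used = n_used, n_components = n_components,
         component_means = component_means, component_sds = component_sds,
         component_weights = component_weights,
         component_model = component_model,
         cv_within = cv_within, q = q),
    class = "smr_estimate"
  )
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("<smr_estimate> %s [%s]: SMR = %.4g mg O2/h", x$fish_id,
              x$method, x$smr_mg_h))
  if (!is.na(x$smr_mgkg_h)) cat(sprintf(" (%.4g mg/kg/h)", x$smr_mgkg_h))
  if (!is.na(x$n_components)) {
    cat(sprintf("; %d component(s), %d cycles, CV within %.2g%%",
                x$n_components, x$n_cycles_used, x$cv_within))
  }
  cat("\n")
  invisible(x)
}

#' SMR by the mean of the lowest normal distribution (MLND)
#'
#' Fits univariate Gaussian mixtures with 1 to `k_max` components to the
#' per-cycle MO2 values by EM (multiple restarts from quantile-spread means),
#' fitting both equal-variance and free-variance component models, and selects
#' the model with the lowest BIC. SMR is the mean of the mixture component
#' with the smallest mean. BIC ties break toward fewer components;
#' equal-mean ties break toward the larger mixing weight.
#'
#' Values recorded during acclimation or activity bouts fall into
#' higher-mean components, so no explicit early-cycle removal is needed; an
#' optional `drop_first_h` switch excludes the first hours of record anyway.
#'
#' @param mo2_values numeric vector of per-cycle whole-animal MO2 values
#'   (mg O2/h); at least 10 values are required (mixture fitting is unstable
#'   below that; use [estimate_smr_quantile()] for sparser records).
#' @param k_max maximum number of mixture components (default 4).
#' @param seed integer seed for the EM restarts.
#' @param n_restarts EM restarts per model (default 10).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param mass_g optional fish mass, to fill in the mass-specific rate.
#' @param fish_id optional identifier carried into the result.
#' @param t_mid_s optional per-value cycle midpoints (seconds), required when
#'   `drop_first_h > 0`.
#' @param drop_first_h optionally discard values from the first hours of the
#'   trial before fitting (default 0: the mixture handles acclimation).
#' @return an `smr_estimate` object; see [batch_estimate()] for a tabular
#'   interface.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(40, 10, 0.3), rnorm(15, 14, 0.5))  # rest + activity cycles
#' estimate_smr_mlnd(x, seed = 1)
#' @export
estimate_smr_mlnd <- function(mo2_values, k_max = 4L, seed = 1L,
                              n_restarts = 10L, tol = 1e-8, max_iter = 500L,
                              mass_g = NULL, fish_id = NA_character_,
                              t_mid_s = NULL, drop_first_h = 0) {
  x <- mo2_values
  if (drop_first_h > 0) {
    if (is.null(t_mid_s) || length(t_mid_s) != length(x)) {
      stop("`t_mid_s` must accompany `mo2_values` when `drop_first_h` > 0",
           call. = FALSE)
    }
    x <- x[t_mid_s >= drop_first_h * 3600]
  }
  x <- x[is.finite(x)]
  if (length(x) < 10L) {
    stop("MLND needs at least 10 cycle values; ",
         "consider estimate_smr_quantile() for sparse records", call. = FALSE)
  }
  k_max <- check_count(k_max, "k_max", 1L)
  if (k_max > 8L) stop("`k_max` above 8 is not supported", call. = FALSE)
  n <- length(x)

  if (sd(x) == 0) {
    return(new_smr_estimate(fish_id, "mlnd", x[1], mass_g, n,
                            n_components = 1L, component_means = x[1],
                            component_sds = 0, component_weights = 1,
                            component_model = "equal", cv_within = 0))
  }

  fits <- with_seed(seed, {
    out <- list()
    for (k in seq_len(k_max)) {
      models <- if (k == 1L) "equal" else c("equal", "free")
      for (m in models) {
        fit <- fit_gmm(x, k, equal_var = (m == "equal"),
                       n_restarts = n_restarts, tol = tol,
                       max_iter = max_iter)
        if (is.null(fit)) next
        n_par <- if (m == "equal") 2L * k else 3L * k - 1L
        fit$k <- k
        fit$model <- m
        fit$bic <- -2 * fit$loglik + n_par * log(n)
        out[[length(out) + 1L]] <- fit
      }
    }
    out
  })
  if (!length(fits)) {
    stop("EM failed to converge for every model and restart", call. = FALSE)
  }
  # Candidates are ordered by k (and equal before free), so which.min on BIC
  # breaks ties toward fewer components.
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(round(bics / 1e-9) * 1e-9)]]
  if (best$k > 1L) {
    # polish the selected model to the full convergence tolerance
    sd_floor <- max(sd(x) * 1e-6, 1e-12)
    run <- gmm_em_run(x, best$mu, best$sd, best$w,
                      best$model == "equal", tol, max_iter, sd_floor)
    if (isTRUE(run$ok) && is.finite(run$loglik)) {
      best[c("loglik", "mu", "sd", "w", "converged")] <-
        run[c("loglik", "mu", "sd", "w", "converged")]
    }
  }

  mu <- as.numeric(best$mu)
  low <- which(mu == min(mu))
  if (length(low) > 1L) low <- low[which.max(as.numeric(best$w)[low])]
  assign_hard <- gmm_assign(x, mu, as.numeric(best$sd), as.numeric(best$w))
  in_low <- x[assign_hard == low]
  cv <- if (length(in_low) >= 2L && mean(in_low) != 0) {
    100 * sd(in_low) / mean(in_low)
  } else {
    0
  }
  new_smr_estimate(fish_id, "mlnd", mu[low], mass_g, n,
                   n_components = best$k, component_means = mu,
                   component_sds = as.numeric(best$sd),
                   component_weights = as.numeric(best$w),
                   component_model = best$model, cv_within = cv)
}

#' SMR as a low sample quantile of per-cycle MO2
#'
#' Linear-interpolation sample quantile with the `h = (n - 1) q + 1`
#' convention (`stats::quantile()` type 7). A common alternative to the
#' mixture-based MLND estimator; `q` near 0.2 is customary.
#'
#' @param mo2_values numeric vector of per-cycle MO2 values (>= 2 values).
#' @param q quantile in (0, 1).
#' @inheritParams estimate_smr_mlnd
#' @return an `smr_estimate` object with `method = "quantile"`.
#' @examples
#' estimate_smr_quantile(1:10, q = 0.2)$smr_mg_h  # 2.8
#' @export
estimate_smr_quantile <- function(mo2_values, q = 0.2, mass_g = NULL,
                                  fish_id = NA_character_) {
  x <- mo2_values[is.finite(mo2_values)]
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  check_number(q, "q", lower = 0, upper = 1, allow_equal_lower = FALSE,
               allow_equal_upper = FALSE)
  new_smr_estimate(fish_id, "quantile",
                   as.numeric(quantile(x, q, type = 7)), mass_g,
                   length(x), q = q)
}

# Mean of the 10 lowest values; a simple robust alternative.
estimate_smr_low10 <- function(mo2_values, mass_g = NULL,
                               fish_id = NA_character_) {
  x <- sort(mo2_values[is.finite(mo2_values)])
  if (length(x) < 10L) stop("need at least 10 values", call. = FALSE)
  new_smr_estimate(fish_id, "low10", mean(x[1:10]), mass_g, length(x))
}

#' Estimate SMR for every fish in a per-cycle MO2 table
#'
#' Applies the chosen estimator per `fish_id`. Per-fish failures (for example
#' too few QC-passing cycles) are collected into the output rather than
#' aborting the batch.
#'
#' @param mo2_table data.frame with columns `fish_id` and `mo2_mg_h`
#'   (optionally `t_mid_s`).
#' @param method `"mlnd"` (default), `"quantile"` or `"low10"`.
#' @param cohort optional cohort data.frame supplying `mass_g` per fish for
#'   mass-specific rates.
#' @param q quantile for `method = "quantile"`.
#' @param k_max,seed,drop_first_h passed to [estimate_smr_mlnd()]; each fish
#'   receives a sub-seed derived from `seed`, so results are deterministic.
#' @return data.frame with one row per fish: `fish_id`, `method`,
#'   `smr_mg_h`, `smr_mgkg_h`, `n_cycles_used`, `n_components`, `cv_within`,
#'   `error` (NA on success).
#' @export
batch_estimate <- function(mo2_table, method = c("mlnd", "quantile", "low10"),
                           cohort = NULL, q = 0.2, k_max = 4L, seed = 1L,
                           drop_first_h = 0) {
  method <- match.arg(method)
  stopifnot(is.data.frame(mo2_table))
  if (!nrow(mo2_table)) {
    return(data.frame(fish_id = character(), method = character(),
                      smr_mg_h = numeric(), smr_mgkg_h = numeric(),
                      n_cycles_used = integer(), n_components = integer(),
                      cv_within = numeric(), error = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(mo2_table$fish_id)
  seeds <- derive_seeds(seed, length(ids))
  idx_by_fish <- split(seq_len(nrow(mo2_table)),
                       factor(mo2_table$fish_id, levels = ids))
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    d <- mo2_table[idx_by_fish[[i]], , drop = FALSE]
    mass <- if (!is.null(cohort)) {
      cohort$mass_g[match(id, cohort$fish_id)]
    } else {
      NA_real_
    }
    est <- tryCatch(
      switch(method,
        mlnd = estimate_smr_mlnd(d$mo2_mg_h, k_max = k_max, seed = seeds[i],
                                 mass_g = mass, fish_id = id,
                                 t_mid_s = d$t_mid_s,
                                 drop_first_h = drop_first_h),
        quantile = estimate_smr_quantile(d$mo2_mg_h, q = q, mass_g = mass,
                                         fish_id = id),
        low10 = estimate_smr_low10(d$mo2_mg_h, mass_g = mass, fish_id = id)
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(est)) {
      data.frame(fish_id = id, method = method, smr_mg_h = NA_real_,
                 smr_mgkg_h = NA_real_, n_cycles_used = nrow(d),
                 n_components = NA_integer_, cv_within = NA_real_,
                 error = est, stringsAsFactors = FALSE)
    } else {
      data.frame(fish_id = id, method = method, smr_mg_h = est$smr_mg_h,
                 smr_mgkg_h = est$smr_mgkg_h,
                 n_cycles_used = est$n_cycles_used,
                 n_components = est$n_components %||% NA_integer_,
                 cv_within = est$cv_within, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
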