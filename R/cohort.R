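# Synthetic patient cohorts: one phantom per patient, a true risk volume
# (tumour subvolume with Ktrans below the planted threshold), survival times
# whose hazard depends on that risk volume, and independent clinical
# covariates. Everything is deterministic given the config seed.

#' Cohort configuration
#'
#' @param n_patients Number of patients (>= 2).
#' @param hazard_model `"step"` (hazard multiplied by `hazard_ratio` for
#'   patients in the high-risk-volume group) or `"loglinear"`
#'   (log hazard linear in the standardised risk volume, slope
#'   `log(hazard_ratio)`).
#' @param planted_threshold Ktrans cut (1/min) defining the true risk volume.
#' @param hazard_ratio Hazard multiplier (> 0) between risk groups.
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censoring_rate Independent exponential censoring rate, per month.
#' @param followup_months Administrative censoring horizon (months).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 80,
                          hazard_model = c("step", "loglinear"),
                          planted_threshold = 0.13,
                          hazard_ratio = 3,
                          baseline_hazard = 0.01,
                          censoring_rate = 0.005,
                          followup_months = 60,
                          seed = 1L) {
  hazard_model <- match.arg(hazard_model)
  stopifnot(n_patients >= 2, hazard_ratio > 0, baseline_hazard >= 0,
            censoring_rate >= 0, followup_months > 0)
  structure(list(n_patients = as.integer(n_patients),
                 hazard_model = hazard_model,
                 planted_threshold = planted_threshold,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 followup_months = followup_months,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw right-censored exponential survival times
#'
#' Event times are exponential with per-subject `hazard`; censoring is the
#' minimum of an independent exponential (`censoring_rate`) and the
#' administrative horizon. Used for both endpoints of the synthetic cohort and
#' for null-calibration simulations.
#'
#' @param hazard Per-subject event hazard(s), events/month (recycled).
#' @param n Number of subjects.
#' @param censoring_rate Exponential censoring rate per month.
#' @param followup_months Administrative horizon (months).
#' @return A tibble with columns `time_months` (> 0) and `event` (0/1).
#' @export
simulate_survival <- function(n, hazard, censoring_rate = 0.005,
                              followup_months = 60) {
  hazard <- rep_len(hazard, n)
  t_event <- stats::rexp(n, rate = pmax(hazard, 1e-12))
  t_cens <- if (censoring_rate > 0) stats::rexp(n, rate = censoring_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, followup_months)
  tibble::tibble(time_months = pmax(pmin(t_event, t_cens), 1e-6),
                 event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic patient cohort with linked phantoms
#'
#' Each patient receives a phantom whose low-Ktrans fraction is drawn from
#' `low_fraction_range` (so risk volumes vary across the cohort), a true risk
#' volume `rv_true_cm3` counted directly on the ground-truth Ktrans map at the
#' planted threshold, DFS and OS endpoints generated from the configured
#' hazard model, and clinical covariates drawn independently of the risk
#' volume (tumour volume comes from the mask; FIGO stage, nodal status,
#' histology and age from fixed distributions).
#'
#' The high-risk group of the step model is the third of patients with the
#' largest true risk volumes (ties broken by patient order). The OS latent
#' time is the DFS latent time plus an exponential post-progression survival
#' (mean 12 months); both share one censoring time.
#'
#' @param config A [cohort_config()].
#' @param phantom_cfg Template [phantom_config()]; per-patient seeds and
#'   low-region fractions are varied from it.
#' @param low_fraction_range Range the per-patient low-Ktrans fraction is
#'   drawn from (uniform).
#' @param keep_phantoms Keep the phantom objects in the result (memory-heavy
#'   for large cohorts).
#' @return A list of class `synthetic_cohort`: `cohort` (tibble, one row per
#'   patient), `phantoms` (list or NULL), `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            phantom_cfg = phantom_config(),
                            low_fraction_range = c(0.02, 0.6),
                            keep_phantoms = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  rng <- .local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  low_fr <- stats::runif(n, low_fraction_range[1], low_fraction_range[2])
  # independent inter-patient heterogeneity in the rest of the distribution:
  # range endpoints and the mass between the planted cut and a mid knot vary
  # per patient, so risk volumes at different thresholds are not simply
  # rank-equivalent across the cohort
  mid_fr <- pmin(stats::runif(n, 0.15, 0.55), 0.95 - low_fr)
  k_lo <- stats::runif(n, 0.5, 0.9) * config$planted_threshold
  k_hi <- stats::runif(n, 0.7, 1.0)
  seeds <- sample.int(2^30, n)
  vox_cm3 <- prod(phantom_cfg$voxel_dims_mm) / 1000

  phantoms <- vector("list", n)
  rv_true <- numeric(n); tumor_vol <- numeric(n)
  for (p in seq_len(n)) {
    cfg <- phantom_cfg
    cfg$low_region_fraction <- low_fr[p]
    cfg$low_cut <- config$planted_threshold
    cfg$mid_cut <- config$planted_threshold + 0.04
    cfg$mid_region_fraction <- mid_fr[p]
    cfg$ktrans_range <- c(k_lo[p], k_hi[p])
    cfg$seed <- seeds[p]
    ph <- generate_phantom(cfg)
    kt <- ph$ktrans_map$values[ph$tumor_mask & !ph$fluid_mask]
    rv_true[p] <- sum(kt < config$planted_threshold) * vox_cm3
    tumor_vol[p] <- sum(ph$tumor_mask) * vox_cm3
    if (keep_phantoms) phantoms[[p]] <- ph
  }

  # high-risk group: largest third of true risk volumes, stable order on ties
  n_risk <- floor(n / 3)
  ord <- order(-rv_true, seq_len(n))
  risk <- logical(n); risk[ord[seq_len(n_risk)]] <- TRUE

  h0 <- config$baseline_hazard
  hazard <- switch(config$hazard_model,
    step = h0 * ifelse(risk, config$hazard_ratio, 1),
    loglinear = {
      z <- as.numeric(scale(rv_true))
      h0 * exp(log(config$hazard_ratio) * z)
    })

  t_dfs <- stats::rexp(n, rate = pmax(hazard, 1e-12))
  t_os <- t_dfs + stats::rexp(n, rate = 1 / 12)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(n, rate = config$censoring_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, config$followup_months)

  cohort <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    dfs_months = pmax(pmin(t_dfs, t_cens), 1e-6),
    dfs_event = as.integer(t_dfs <= t_cens),
    os_months = pmax(pmin(t_os, t_cens), 1e-6),
    os_event = as.integer(t_os <= t_cens),
    rv_true_cm3 = rv_true,
    true_risk = risk,
    tumor_volume_cm3 = tumor_vol,
    figo_stage = sample(c("IIB", "IIIA", "IIIB", "IVA"), n, replace = TRUE,
                        prob = c(0.45, 0.1, 0.35, 0.1)),
    lymph_node_positive = stats::rbinom(n, 1, 0.45),
    histology = sample(c("squamous", "adeno"), n, replace = TRUE,
                       prob = c(0.85, 0.15)),
    age_years = round(stats::rnorm(n, 55, 11)))

  structure(list(cohort = cohort,
                 phantoms = if (keep_phantoms) phantoms else NULL,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%s hazard model, HR %.2g), %d DFS events\n",
              nrow(x$cohort), x$config$hazard_model, x$config$hazard_ratio,
              sum(x$cohort$dfs_event)))
  invisible(x)
}
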