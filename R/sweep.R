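# Biomarker-discovery engine: split the cohort one-third/two-thirds on each
# candidate statistic, sweep integer percentiles and Ktrans thresholds with a
# log-rank test at every grid point, and select the optimum by ROC AUC.
#
# Risk-direction conventions are fixed, not configurable: a LOW percentile
# value marks risk (poor outcome is associated with low Ktrans), and a LARGE
# risk volume marks risk. The sweeps perform 99 (or ~200) highly correlated
# tests; raw p-value curves are reported without multiplicity correction, and
# the result carries a multiplicity note in its attributes.

#' One-third / two-thirds cohort split
#'
#' The risk group is the `floor(n/3)` patients most extreme in the risk
#' direction: the lowest values when `direction = "low-is-risk"` (percentile
#' statistics), the largest when `"high-is-risk"` (risk volumes). Boundary
#' ties are broken by stable patient order. An 80-patient cohort splits into
#' groups of 26 and 54.
#'
#' @param values Per-patient statistic.
#' @param direction `"low-is-risk"` or `"high-is-risk"`.
#' @return Logical vector, `TRUE` for the risk group.
#' @export
split_one_third <- function(values, direction = c("low-is-risk", "high-is-risk")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 3) stop("need at least 3 patients to split")
  n_risk <- floor(n / 3)
  key <- if (direction == "low-is-risk") values else -values
  ord <- order(key, seq_len(n))
  risk <- logical(n)
  risk[ord[seq_len(n_risk)]] <- TRUE
  risk
}

# One grid point: log-rank p and AUC for both endpoints.
# score: continuous statistic; risk_high: TRUE if LARGE score = risk.
.sweep_point <- function(cohort, score, risk_high, horizon_months) {
  grp <- split_one_third(score,
                         if (risk_high) "high-is-risk" else "low-is-risk")
  oriented <- if (risk_high) score else -score
  res <- list()
  for (ep in c("dfs", "os")) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    lr <- tryCatch(
      logrank_test(tibble::tibble(time_months = cohort[[tcol]],
                                  event = cohort[[ecol]],
                                  group = grp)),
      error = function(e) tibble::tibble(p_value = NA_real_))
    lab <- event_by_horizon(cohort[[tcol]], cohort[[ecol]], horizon_months)
    auc <- tryCatch(roc_auc(oriented, lab), error = function(e) NA_real_)
    res[[paste0("logrank_p_", ep)]] <- lr$p_value[1]
    res[[paste0("auc_", ep)]] <- auc
  }
  res
}

.as_sweep_result <- function(grid_tbl, axis_type) {
  structure(grid_tbl,
            class = c("sweep_result", class(grid_tbl)),
            axis_type = axis_type,
            multiplicity_note = paste(
              "p-value curves are raw: the sweep performs many correlated",
              "tests and applies no multiplicity correction"))
}

#' Percentile sweep
#'
#' For each integer percentile p, computes every patient's percentile-p value
#' from their Ktrans (or ve) frequency distribution, splits the cohort
#' one-third/two-thirds with low values marking risk, and records the log-rank
#' p-value and the ROC AUC of the continuous percentile value against the
#' event-by-horizon outcome, for DFS and OS.
#'
#' @param cohort Data frame with columns `dfs_months`, `dfs_event`,
#'   `os_months`, `os_event` (one row per patient).
#' @param distributions List of [frequency_distribution()] objects (or sorted
#'   numeric vectors), one per cohort row.
#' @param percentiles Integer grid (default 1:99).
#' @param horizon_months ROC outcome horizon (default 60).
#' @return A `sweep_result` tibble: `axis`, `logrank_p_dfs`, `logrank_p_os`,
#'   `auc_dfs`, `auc_os`. Use [select_optimum()] and [significant_range()].
#' @export
percentile_sweep <- function(cohort, distributions, percentiles = 1:99,
                             horizon_months = 60) {
  stopifnot(length(distributions) == nrow(cohort))
  vals <- lapply(distributions,
                 function(d) if (inherits(d, "freq_dist")) d$values else sort(d))
  if (sum(cohort$dfs_event) < 1 && sum(cohort$os_event) < 1)
    stop("no events in either endpoint")
  rows <- purrr::map(percentiles, function(p) {
    score <- vapply(vals, percentile_value, numeric(1), p = p)
    c(list(axis = p),
      .sweep_point(cohort, score, risk_high = FALSE, horizon_months))
  })
  .as_sweep_result(dplyr::bind_rows(rows), "percentile")
}

#' Default Ktrans threshold grid
#'
#' One increment up to the sweep ceiling: `seq(step, max, by = step)`; the
#' default 0.0025 to 0.50 1/min gives 200 grid points. The grid starts one
#' step above zero because the risk volume at threshold 0 is identically
#' empty.
#'
#' @param max_threshold Upper bound (1/min).
#' @param step Increment (1/min).
#' @export
threshold_grid <- function(max_threshold = 0.50, step = 0.0025) {
  seq(step, max_threshold, by = step)
}

#' Threshold sweep
#'
#' For each Ktrans threshold on the grid, computes every patient's risk volume
#' (tumour subvolume with Ktrans strictly below the threshold), splits the
#' cohort one-third/two-thirds with large risk volumes marking risk, and
#' records the log-rank p-value and ROC AUC per endpoint.
#'
#' @inheritParams percentile_sweep
#' @param distributions Per-patient [frequency_distribution()]s of Ktrans
#'   (sorted voxel values + voxel volume); risk volumes are counted from them.
#' @param thresholds Threshold grid in 1/min (default [threshold_grid()]).
#' @return A `sweep_result` tibble (axis = threshold in 1/min).
#' @export
threshold_sweep <- function(cohort, distributions,
                            thresholds = threshold_grid(),
                            horizon_months = 60) {
  stopifnot(length(distributions) == nrow(cohort))
  vals <- lapply(distributions,
                 function(d) if (inherits(d, "freq_dist")) d$values else sort(d))
  vox_cm3 <- vapply(distributions, function(d) {
    if (inherits(d, "freq_dist")) d$voxel_volume_mm3 / 1000 else 1
  }, numeric(1))
  rows <- purrr::map(thresholds, function(th) {
    rv <- vapply(seq_along(vals),
                 function(i) sum(vals[[i]] < th) * vox_cm3[i], numeric(1))
    c(list(axis = th),
      .sweep_point(cohort, rv, risk_high = TRUE, horizon_months))
  })
  .as_sweep_result(dplyr::bind_rows(rows), "threshold")
}

#' Select the sweep optimum by ROC AUC
#'
#' Argmax of the AUC curve for the requested endpoint; ties (including an
#' all-equal curve, which triggers a warning) resolve to the smallest grid
#' value. Also reports whether the DFS and OS optima coincide.
#'
#' @param result A `sweep_result`.
#' @param endpoint `"dfs"` or `"os"`.
#' @return A one-row tibble: `endpoint`, `optimum` (grid value), `auc`,
#'   `logrank_p`, `agrees_other_endpoint`.
#' @export
select_optimum <- function(result, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  pick <- function(ep) {
    auc <- result[[paste0("auc_", ep)]]
    if (all(is.na(auc))) return(NA_real_)
    mx <- max(auc, na.rm = TRUE)
    if (isTRUE(all.equal(mx, min(auc, na.rm = TRUE))))
      warning("all AUC values equal: optimum defaults to the smallest grid value")
    result$axis[which(auc >= mx - 1e-12)[1]]
  }
  opt <- pick(endpoint)
  other <- pick(setdiff(c("dfs", "os"), endpoint))
  i <- which(result$axis == opt)[1]
  tibble::tibble(endpoint = endpoint, optimum = opt,
                 auc = result[[paste0("auc_", endpoint)]][i],
                 logrank_p = result[[paste0("logrank_p_", endpoint)]][i],
                 agrees_other_endpoint = isTRUE(all.equal(opt, other)))
}

#' Contiguous grid region significant for both endpoints
#'
#' The longest contiguous run of grid points with raw log-rank p < alpha for
#' DFS and OS simultaneously.
#'
#' @param result A `sweep_result`.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble with `from`, `to`, `n_points` (all `NA` if no
#'   point is significant for both endpoints).
#' @export
significant_range <- function(result, alpha = 0.05) {
  sig <- !is.na(result$logrank_p_dfs) & !is.na(result$logrank_p_os) &
    result$logrank_p_dfs < alpha & result$logrank_p_os < alpha
  if (!any(sig)) return(tibble::tibble(from = NA_real_, to = NA_real_,
                                       n_points = 0L))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- which(r$values)[which.max(r$lengths[r$values])]
  tibble::tibble(from = result$axis[starts[best]],
                 to = result$axis[ends[best]],
                 n_points = r$lengths[best])
}

#' @rdname select_optimum
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @export
glance.sweep_result <- function(x, ...) {
  dplyr::bind_rows(select_optimum(x, "dfs"), select_optimum(x, "os")) |>
    dplyr::mutate(axis_type = attr(x, "axis_type"))
}
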