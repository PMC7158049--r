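# Scalar imaging biomarkers from parameter maps and dynamic series:
# frequency-distribution percentiles, threshold-defined risk volumes with
# binary maps, and non-model-based proxies (low-enhancing volume in the first
# minute, late-phase increasing-signal volume).

#' Refine a tumour mask using T2-weighted intensities
#'
#' Removes voxels whose T2 intensity is consistent with air (below a low
#' quantile of the in-mask distribution, or below `lower_cut`) or with
#' water/necrotic fluid (above a high quantile, or above `upper_cut`),
#' mirroring the exclusion of body cavities and necrosis from analysis.
#'
#' @param tumor_mask 3-D logical array.
#' @param t2_volume 3-D numeric array, same shape.
#' @param lower_quantile,upper_quantile In-mask quantile cutoffs; voxels with
#'   intensity strictly below/above them are removed. Use 0 / 1 to disable a
#'   side.
#' @param lower_cut,upper_cut Optional absolute intensity cutoffs overriding
#'   the quantile rule.
#' @param enabled Set `FALSE` to return the mask unchanged.
#' @return The refined logical mask, with attribute `n_removed`.
#' @export
exclude_voxels <- function(tumor_mask, t2_volume,
                           lower_quantile = 0, upper_quantile = 1,
                           lower_cut = NULL, upper_cut = NULL,
                           enabled = TRUE) {
  stopifnot(all(dim(tumor_mask) == dim(t2_volume)))
  if (!enabled) {
    attr(tumor_mask, "n_removed") <- 0L
    return(tumor_mask)
  }
  v <- t2_volume[tumor_mask]
  lo <- if (!is.null(lower_cut)) lower_cut
        else if (lower_quantile > 0) stats::quantile(v, lower_quantile, type = 1)
        else -Inf
  hi <- if (!is.null(upper_cut)) upper_cut
        else if (upper_quantile < 1) stats::quantile(v, upper_quantile, type = 1)
        else Inf
  keep <- tumor_mask & t2_volume >= lo & t2_volume <= hi
  n_removed <- sum(tumor_mask) - sum(keep)
  if (!any(keep)) stop("all voxels excluded: refined mask is empty")
  attr(keep, "n_removed") <- n_removed
  keep
}

#' Frequency distribution of a parametric map
#'
#' Collects the masked voxel values of a parameter map, sorted ascending.
#' Voxels flagged non-enhancing are already absent from the map mask, so they
#' never enter the distribution.
#'
#' @param map A [parametric_map()].
#' @param mask Optional refined mask (e.g. from [exclude_voxels()]) intersected
#'   with the map's own mask.
#' @return An object of class `freq_dist`: sorted `values`, `n_voxels`,
#'   `voxel_volume_mm3`, `parameter_name`.
#' @export
frequency_distribution <- function(map, mask = NULL) {
  m <- map$mask
  if (!is.null(mask)) m <- m & mask
  if (!any(m)) stop("mask is empty")
  structure(list(values = sort(map$values[m]),
                 n_voxels = sum(m),
                 voxel_volume_mm3 = voxel_volume_mm3(map),
                 parameter_name = map$parameter_name),
            class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat(sprintf("Frequency distribution <%s>: %d voxels, range %.4g-%.4g\n",
              x$parameter_name, x$n_voxels, min(x$values), max(x$values)))
  invisible(x)
}

#' Value at an integer percentile (nearest rank)
#'
#' The p-th percentile is the `ceiling(p/100 * n)`-th order statistic of the
#' sorted voxel values (nearest-rank convention, no interpolation). The
#' 35th-percentile Ktrans of a tumour is `percentile_value(dist, 35)`.
#'
#' @param dist A [frequency_distribution()] result, or a sorted numeric vector.
#' @param p Integer percentile(s) in 1-99.
#' @return Parameter value(s) at the requested percentile(s).
#' @export
percentile_value <- function(dist, p) {
  if (any(p < 1 | p > 99)) stop("percentile must be in 1..99")
  v <- if (inherits(dist, "freq_dist")) dist$values else sort(dist)
  n <- length(v)
  if (n == 0) stop("empty distribution")
  v[pmin(ceiling(p / 100 * n), n)]
}

#' Threshold-defined risk volume
#'
#' Counts masked voxels with parameter value strictly below `threshold` and
#' converts to a physical volume; also emits the binary sub-threshold map.
#' The strictly-below convention is fixed and tested.
#'
#' @param map A [parametric_map()].
#' @param threshold Threshold in the map's units (>= 0), e.g. 1/min for Ktrans.
#' @param mask Optional refined mask intersected with the map mask.
#' @return An object of class `risk_volume_result`: `threshold`,
#'   `voxel_count`, `volume_cm3`, `binary_map`.
#' @export
risk_volume <- function(map, threshold, mask = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  m <- map$mask
  if (!is.null(mask)) m <- m & mask
  binary <- array(FALSE, dim(map$values))
  binary[m] <- map$values[m] < threshold
  count <- sum(binary)
  structure(list(threshold = threshold, voxel_count = count,
                 volume_cm3 = count * voxel_volume_mm3(map) / 1000,
                 binary_map = binary),
            class = "risk_volume_result")
}

#' @export
print.risk_volume_result <- function(x, ...) {
  cat(sprintf("Risk volume below %.4g: %d voxels = %.3f cm^3\n",
              x$threshold, x$voxel_count, x$volume_cm3))
  invisible(x)
}

# per-voxel matrix of masked curves + relative enhancement helper
.masked_curves <- function(series, mask) {
  m <- series$mask
  if (!is.null(mask)) m <- m & mask
  if (!any(m)) stop("mask is empty")
  mat <- matrix(series$data, ncol = dim(series$data)[4])[which(m), , drop = FALSE]
  list(mat = mat, n = sum(m))
}

#' Low-enhancing tumour volume in the first minute (proxy)
#'
#' Volume of voxels whose maximal relative signal enhancement within the first
#' 60 s after injection stays below `enhancement_cutoff`. A simplified proxy
#' for the low-enhancing-tumour-volume biomarker; the cutoff is a free
#' parameter, not a reproduction of any published calibration.
#'
#' @param series A `dce_series` holding signal intensities.
#' @param mask Optional refined mask.
#' @param enhancement_cutoff Relative enhancement cutoff. The default 0.07 is
#'   the enhancement a voxel at the 0.13 1/min Ktrans boundary reaches within
#'   60 s under the package's default SPGR simulation settings, so
#'   sub-threshold voxels classify as low-enhancing on the phantom.
#' @param window_s Early window length after injection (default 60 s).
#' @return Volume in cm^3 with attribute `voxel_count`.
#' @export
letv_volume <- function(series, mask = NULL, enhancement_cutoff = 0.07,
                        window_s = 60) {
  early <- series$times_s > 0 & series$times_s <= window_s
  if (!any(early)) stop("no frames within the early window")
  mc <- .masked_curves(series, mask)
  pre <- series$times_s <= 0
  s0 <- rowMeans(mc$mat[, pre, drop = FALSE])
  enh <- (mc$mat[, early, drop = FALSE] - s0) / s0
  low <- apply(enh, 1, max) < enhancement_cutoff
  out <- sum(low) * prod(series$voxel_dims_mm) / 1000
  attr(out, "voxel_count") <- sum(low)
  out
}

#' Late-phase increasing-signal tumour volume (proxy)
#'
#' Fits a straight line of signal versus time per voxel over a late-phase
#' window and counts voxels whose slope exceeds `slope_cutoff` (a
#' noise-scaled cutoff; 0 counts any positive slope).
#'
#' @param series A `dce_series` holding signal intensities.
#' @param mask Optional refined mask.
#' @param window_s Late window `c(start, end)` in seconds (default the last
#'   6 minutes of a 10-minute acquisition).
#' @param slope_cutoff Minimum slope (signal units per second).
#' @return Volume in cm^3 with attribute `voxel_count`.
#' @export
tvis_volume <- function(series, mask = NULL, window_s = c(240, 600),
                        slope_cutoff = 0) {
  inw <- series$times_s >= window_s[1] & series$times_s <= window_s[2]
  if (sum(inw) < 3) stop("late window must contain at least 3 frames")
  mc <- .masked_curves(series, mask)
  tt <- series$times_s[inw]
  y <- mc$mat[, inw, drop = FALSE]
  tc <- tt - mean(tt)
  slope <- as.vector(y %*% tc) / sum(tc^2)
  inc <- slope > slope_cutoff
  out <- sum(inc) * prod(series$voxel_dims_mm) / 1000
  attr(out, "voxel_count") <- sum(inc)
  out
}

#' Per-patient biomarker row
#'
#' Convenience wrapper computing the standard biomarker set for one patient:
#' the 35th-percentile Ktrans (configurable percentile), the risk volume below
#' a Ktrans threshold, tumour volume, and (when a signal series is supplied)
#' the low-enhancement and increasing-signal proxies.
#'
#' @param ktrans_map A [parametric_map()] of Ktrans.
#' @param mask Optional refined analysis mask.
#' @param percentile Percentile for the point biomarker (default 35).
#' @param threshold Risk-volume threshold, 1/min (default 0.13).
#' @param series Optional `dce_series` (signal) for the proxies.
#' @param ... Passed to [letv_volume()] / [tvis_volume()].
#' @return A one-row tibble.
#' @export
compute_biomarkers <- function(ktrans_map, mask = NULL, percentile = 35,
                               threshold = 0.13, series = NULL, ...) {
  fd <- frequency_distribution(ktrans_map, mask)
  rv <- risk_volume(ktrans_map, threshold, mask)
  out <- tibble::tibble(
    p_ktrans = percentile_value(fd, percentile),
    percentile = percentile,
    rv_ktrans_cm3 = rv$volume_cm3,
    rv_threshold = threshold,
    tumor_volume_cm3 = fd$n_voxels * fd$voxel_volume_mm3 / 1000)
  if (!is.null(series)) {
    out$letv_cm3 <- as.numeric(letv_volume(series, mask, ...))
    out$tvis_cm3 <- as.numeric(tvis_volume(series, mask))
  }
  out
}
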