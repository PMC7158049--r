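# Digital tumour phantoms: spatially correlated Ktrans/ve fields with a
# configurable low-Ktrans subvolume, a fluid/necrosis compartment visible on a
# synthetic T2-weighted volume, and forward-simulated dynamic acquisitions.

#' Phantom configuration
#'
#' Parameters of the digital tumour phantom. Parameter fields are Gaussian
#' random fields (smoothed white noise) transformed monotonically so that the
#' in-mask Ktrans distribution spans `ktrans_range` and the fraction of tumour
#' voxels with Ktrans below `low_cut` matches `low_region_fraction`; low-Ktrans
#' voxels are therefore spatially contiguous, mimicking confluent
#' poorly-perfused regions.
#'
#' @param grid_shape Voxel counts per axis (each >= 3).
#' @param voxel_dims_mm Physical voxel size (mm). Default 0.78 x 0.78 x 5.0.
#' @param ktrans_range Min/max of true Ktrans (1/min).
#' @param ve_range Min/max of true ve (fraction in (0, 1]).
#' @param low_region_fraction Target fraction of tumour voxels with
#'   Ktrans < `low_cut`.
#' @param low_cut The Ktrans cut (1/min) defining the low region. Default 0.13.
#' @param mid_cut Optional second distribution knot (1/min). Together with
#'   `mid_region_fraction` it decouples the tumour's mid-range Ktrans mass
#'   from its low-Ktrans mass, so that tumours with equal risk volumes can
#'   still differ higher up the distribution (inter-patient shape
#'   heterogeneity). `NULL` disables the knot.
#' @param mid_region_fraction Target fraction of tumour voxels with Ktrans
#'   between `low_cut` and `mid_cut`.
#' @param smoothness_mm Spatial correlation length (Gaussian kernel sd, mm).
#' @param necrosis_fraction Fraction of tumour voxels flagged fluid/necrotic.
#' @param seed RNG seed; identical config + seed gives identical phantoms.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(20, 20, 8),
                           voxel_dims_mm = c(0.78, 0.78, 5.0),
                           ktrans_range = c(0.01, 1.0),
                           ve_range = c(0.1, 0.6),
                           low_region_fraction = 0.3,
                           low_cut = 0.13,
                           mid_cut = NULL,
                           mid_region_fraction = 0,
                           smoothness_mm = 3,
                           necrosis_fraction = 0.05,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, length(voxel_dims_mm) == 3,
            all(voxel_dims_mm > 0),
            ktrans_range[1] >= 0, diff(ktrans_range) > 0,
            ve_range[1] > 0, ve_range[2] <= 1, diff(ve_range) > 0,
            low_region_fraction >= 0, low_region_fraction <= 1,
            mid_region_fraction >= 0, low_region_fraction + mid_region_fraction <= 1,
            necrosis_fraction >= 0, necrosis_fraction <= 1,
            smoothness_mm >= 0)
  if (any(grid_shape < 3)) stop("degenerate grid: every axis needs >= 3 voxels")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_dims_mm = as.numeric(voxel_dims_mm),
                 ktrans_range = ktrans_range, ve_range = ve_range,
                 low_region_fraction = low_region_fraction, low_cut = low_cut,
                 mid_cut = mid_cut, mid_region_fraction = mid_region_fraction,
                 smoothness_mm = smoothness_mm,
                 necrosis_fraction = necrosis_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Separable Gaussian smoothing of a 3-D array (reflecting boundaries), kernel
# sd given per axis in voxels. Zero sd on an axis leaves it untouched.
.smooth3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(seq(-r, r), sd = s)
    kern <- kern / sum(kern)
    arr <- .conv_axis(arr, kern, ax)
  }
  arr
}

.conv_axis <- function(arr, kern, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  r <- (length(kern) - 1L) / 2L
  # reflect-pad along the first dimension
  top <- m[pmin(pmax(seq(r, 1) , 1), n), , drop = FALSE]
  bot <- m[pmin(pmax(seq(n, n - r + 1), 1), n), , drop = FALSE]
  mp <- rbind(top, m, bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(kern)) {
    out <- out + kern[i] * mp[seq_len(n) + (i - 1L), , drop = FALSE]
  }
  a2 <- array(out, dim = dim(a))
  aperm(a2, order(perm))
}

# Monotone rank transform of a field's in-mask values to a piecewise-uniform
# target distribution: `cuts` are interior breakpoints and `cumfr` the
# cumulative probability below each, so the achieved fraction below every cut
# equals its target up to 1/n. With no cuts this is a plain uniform stretch to
# [lo, hi]; a cut with cumulative fraction 0 simply truncates the range at it.
.rank_to_range <- function(vals, lo, hi, cuts = numeric(0), cumfr = numeric(0)) {
  n <- length(vals)
  u <- (rank(vals, ties.method = "first") - 0.5) / n
  xs <- c(lo, pmin(pmax(cuts, lo), hi), hi)
  ps <- pmin(pmax(c(0, cumfr, 1), 0), 1)
  out <- numeric(n)
  nseg <- length(xs) - 1
  for (s in seq_len(nseg)) {
    if (ps[s + 1] <= ps[s]) next
    in_s <- u >= ps[s] & (u < ps[s + 1] | s == nseg)
    out[in_s] <- xs[s] + (u[in_s] - ps[s]) / (ps[s + 1] - ps[s]) *
      (xs[s + 1] - xs[s])
  }
  out
}

#' Generate a ground-truth tumour phantom
#'
#' Builds an ellipsoidal tumour mask inscribed in the grid, smooth correlated
#' Ktrans and ve fields on it, a fluid/necrosis mask (spatially contiguous,
#' drawn from a third smoothed field), and a synthetic T2-weighted volume in
#' which fluid voxels come from a distinct high-intensity distribution.
#'
#' @param config A [phantom_config()].
#' @return An object of class `ground_truth_phantom` with elements
#'   `ktrans_map`, `ve_map` ([parametric_map()]s on the tumour mask),
#'   `tumor_mask`, `fluid_mask`, `synthetic_t2`, `voxel_dims_mm`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  rng <- .local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  # ellipsoidal tumour mask with semi-axes at 90% of the half-grid
  ctr <- (d + 1) / 2
  ax <- pmax((d - 1) / 2 * 0.9, 1)
  gi <- slice.index(array(0, d), 1)
  gj <- slice.index(array(0, d), 2)
  gk <- slice.index(array(0, d), 3)
  tumor_mask <- ((gi - ctr[1]) / ax[1])^2 + ((gj - ctr[2]) / ax[2])^2 +
    ((gk - ctr[3]) / ax[3])^2 <= 1

  sigma_vox <- config$smoothness_mm / config$voxel_dims_mm
  fld <- function() .smooth3d(array(stats::rnorm(prod(d)), d), sigma_vox)
  f_kt <- fld(); f_ve <- fld(); f_fl <- fld()

  cuts <- config$low_cut
  cumfr <- config$low_region_fraction
  if (!is.null(config$mid_cut)) {
    cuts <- c(cuts, config$mid_cut)
    cumfr <- c(cumfr, min(1, cumfr + config$mid_region_fraction))
  }
  kt <- array(NA_real_, d); ve <- array(NA_real_, d)
  kt[tumor_mask] <- .rank_to_range(f_kt[tumor_mask],
                                   config$ktrans_range[1], config$ktrans_range[2],
                                   cuts = cuts, cumfr = cumfr)
  ve[tumor_mask] <- .rank_to_range(f_ve[tumor_mask],
                                   config$ve_range[1], config$ve_range[2])

  # fluid/necrosis: the most extreme tail of a third correlated field
  fluid_mask <- array(FALSE, d)
  n_in <- sum(tumor_mask)
  n_fluid <- round(config$necrosis_fraction * n_in)
  if (n_fluid > 0) {
    v <- f_fl[tumor_mask]
    cut <- sort(v, decreasing = TRUE)[n_fluid]
    fluid_mask[tumor_mask] <- v >= cut
  }

  # synthetic T2: tissue ~ N(100, 15); fluid clearly hyperintense ~ N(300, 20)
  t2 <- array(stats::rnorm(prod(d), mean = 100, sd = 15), d)
  t2[fluid_mask] <- stats::rnorm(sum(fluid_mask), mean = 300, sd = 20)

  structure(list(
    ktrans_map = parametric_map(kt, tumor_mask, config$voxel_dims_mm, "ktrans"),
    ve_map = parametric_map(ve, tumor_mask, config$voxel_dims_mm, "ve"),
    tumor_mask = tumor_mask, fluid_mask = fluid_mask, synthetic_t2 = t2,
    voxel_dims_mm = config$voxel_dims_mm, config = config
  ), class = "ground_truth_phantom")
}

#' @export
print.ground_truth_phantom <- function(x, ...) {
  cat(sprintf("Tumour phantom: %s grid, %d tumour voxels (%d fluid), Ktrans %.3g-%.3g 1/min\n",
              paste(dim(x$tumor_mask), collapse = "x"), sum(x$tumor_mask),
              sum(x$fluid_mask), min(x$ktrans_map$values, na.rm = TRUE),
              max(x$ktrans_map$values, na.rm = TRUE)))
  invisible(x)
}

# Run code under a private RNG state; returns a restore function.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a dynamic contrast-enhanced acquisition from a phantom
#'
#' Per-voxel tissue concentration curves follow the closed-form Tofts model at
#' the acquisition frame times; fluid voxels do not enhance. Concentrations
#' are mapped to SPGR signal with per-voxel baseline T1 `t10_s` and
#' equilibrium magnetisation `m0`, Gaussian noise of sd `noise_sd` is added,
#' and two calibration-tube chamber signals (saline, and
#' `tube_concentration_mM` Gd) are embedded as per-frame readings.
#'
#' @param phantom A [generate_phantom()] result.
#' @param aif An [aif_params()] object.
#' @param acquisition An [acquisition_config()].
#' @param noise_sd Gaussian signal noise sd (a.u.; 0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param m0 Tissue equilibrium magnetisation (a.u.).
#' @param t10_s Precontrast tissue T1 (s).
#' @param t1_saline_s T1 of the saline chamber (s).
#' @param tube_concentration_mM Gd concentration of the second chamber (mM).
#' @return An object of class `dce_series`: 4-D signal array `data`
#'   (x, y, z, frame), `times_s`, `acquisition`, `mask` (tumour mask),
#'   `voxel_dims_mm`, `tube` (per-frame chamber signals), `kind = "signal"`.
#' @export
simulate_dce_series <- function(phantom, aif = aif_params(),
                                acquisition = acquisition_config(),
                                noise_sd = 0, seed = 1L,
                                m0 = 1000, t10_s = 1.4,
                                t1_saline_s = 3.0,
                                tube_concentration_mM = 0.5) {
  stopifnot(inherits(phantom, "ground_truth_phantom"))
  times <- acquisition$frame_times_s
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  d <- dim(phantom$tumor_mask)
  nframes <- length(times)
  enh <- phantom$tumor_mask & !phantom$fluid_mask

  conc <- matrix(0, nrow = prod(d), ncol = nframes)
  lin <- which(enh)
  kt <- phantom$ktrans_map$values[enh]
  ve <- phantom$ve_map$values[enh]
  for (v in seq_along(lin)) {
    conc[lin[v], ] <- tofts_forward(times, kt[v], ve[v], aif)
  }

  r1 <- 1 / t10_s + acquisition$relaxivity_r1 * conc
  sig <- spgr_signal(m0, 1 / as.vector(r1), acquisition)
  sig <- matrix(sig, ncol = nframes)

  tube_sal <- rep(spgr_signal(m0, t1_saline_s, acquisition), nframes)
  r1_gd <- 1 / t1_saline_s + acquisition$relaxivity_r1 * tube_concentration_mM
  tube_gd <- rep(spgr_signal(m0, 1 / r1_gd, acquisition), nframes)

  if (noise_sd > 0) {
    rng <- .local_rng(seed)
    on.exit(rng(), add = TRUE)
    sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
    tube_sal <- tube_sal + stats::rnorm(nframes, sd = noise_sd)
    tube_gd <- tube_gd + stats::rnorm(nframes, sd = noise_sd)
  }

  structure(list(
    data = array(sig, dim = c(d, nframes)),
    times_s = times,
    acquisition = acquisition,
    mask = phantom$tumor_mask,
    voxel_dims_mm = phantom$voxel_dims_mm,
    tube = tibble::tibble(frame = seq_len(nframes),
                          saline = tube_sal, gd = tube_gd),
    kind = "signal",
    provenance = list(simulation = list(noise_sd = noise_sd, seed = seed,
                                        m0 = m0, t10_s = t10_s))
  ), class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  cat(sprintf("DCE series (%s): %s voxels x %d frames, %d precontrast, dt ~ %.0f s\n",
              x$kind, paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$acquisition$n_precontrast, stats::median(diff(x$times_s))))
  invisible(x)
}

#' Tidy per-voxel curves from a DCE series
#'
#' @param x A `dce_series`.
#' @param ... Unused.
#' @return A tibble with one row per masked voxel and frame: `i, j, k,
#'   time_s, value`.
#' @export
as_tibble.dce_series <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  lin <- which(x$mask)
  mat <- matrix(x$data, ncol = dim(x$data)[4])[lin, , drop = FALSE]
  tibble::tibble(
    i = rep(idx[, 1], times = length(x$times_s)),
    j = rep(idx[, 2], times = length(x$times_s)),
    k = rep(idx[, 3], times = length(x$times_s)),
    time_s = rep(x$times_s, each = nrow(idx)),
    value = as.vector(mat))
}
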