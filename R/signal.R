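# Spoiled gradient-recalled echo (SPGR) signal model and the conversion of
# dynamic signal intensities to Gd-DTPA concentration. Two conversions are
# provided: a tube-calibrated linear relative-enhancement map (default) and a
# full SPGR inversion referenced to a known equilibrium magnetisation. Both
# record which method produced the output.

#' Acquisition configuration for the dynamic T1-weighted series
#'
#' Defaults reproduce a pelvic DCE protocol: SPGR with TR 160 ms, TE 3.5 ms,
#' flip 90 degrees, 29 s temporal resolution over 10 minutes, three
#' precontrast frames. Frame times are mid-frame and relative to injection,
#' so precontrast frames carry negative times.
#'
#' @param tr_ms Repetition time (ms).
#' @param te_ms Echo time (ms).
#' @param flip_deg Flip angle (degrees), 0 < flip <= 90.
#' @param frame_times_s Frame times (s) relative to injection, strictly
#'   increasing. Default: 29 s spacing, 3 precontrast + 20 dynamic frames.
#' @param n_precontrast Number of baseline frames (>= 1).
#' @param relaxivity_r1 Longitudinal relaxivity of the contrast agent,
#'   1/(s mM). Default 4.5 (Gd-DTPA at 1.5 T).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(tr_ms = 160, te_ms = 3.5, flip_deg = 90,
                               frame_times_s = default_frame_times(),
                               n_precontrast = 3, relaxivity_r1 = 4.5) {
  stopifnot(tr_ms > 0, flip_deg > 0, flip_deg <= 90, n_precontrast >= 1,
            relaxivity_r1 > 0)
  if (any(diff(frame_times_s) <= 0)) stop("frame times must be strictly increasing")
  if (sum(frame_times_s <= 0) != n_precontrast)
    stop("exactly `n_precontrast` frame times must be <= 0 (precontrast)")
  structure(list(tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 frame_times_s = frame_times_s, n_precontrast = n_precontrast,
                 relaxivity_r1 = relaxivity_r1),
            class = "acquisition_config")
}

#' Default mid-frame acquisition times
#'
#' @param dt_s Temporal resolution (s per frame).
#' @param total_s Dynamic sampling duration after injection (s).
#' @param n_precontrast Number of baseline frames before injection.
#' @return Times (s) relative to injection; frame k is centred at
#'   `(k - n_precontrast - 1/2) * dt_s`.
#' @export
default_frame_times <- function(dt_s = 29, total_s = 600, n_precontrast = 3) {
  n_post <- floor(total_s / dt_s)
  (seq_len(n_precontrast + n_post) - n_precontrast - 0.5) * dt_s
}

#' SPGR signal equation
#'
#' \eqn{S = M_0 \sin\alpha (1 - E_1) / (1 - \cos\alpha E_1) \cdot e^{-TE/T_2^*}}
#' with \eqn{E_1 = e^{-TR/T_1}}. The T2* factor defaults to 1 (no attenuation):
#' at TE = 3.5 ms it is close to unity and cancels in signal ratios.
#'
#' @param m0 Equilibrium magnetisation (arbitrary units, >= 0), vectorised.
#' @param t1_s Longitudinal relaxation time (s, > 0), vectorised.
#' @param acquisition An [acquisition_config()].
#' @param t2star_s Optional T2* (s); `NULL` disables the attenuation term.
#' @return Signal in the same arbitrary units as `m0`.
#' @export
spgr_signal <- function(m0, t1_s, acquisition = acquisition_config(),
                        t2star_s = NULL) {
  if (any(t1_s <= 0)) stop("`t1_s` must be positive")
  if (any(m0 < 0)) stop("`m0` must be non-negative")
  a <- acquisition$flip_deg * pi / 180
  e1 <- exp(-(acquisition$tr_ms / 1000) / t1_s)
  s <- m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  if (!is.null(t2star_s)) s <- s * exp(-(acquisition$te_ms / 1000) / t2star_s)
  s
}

#' Invert the SPGR equation for T1
#'
#' @param signal Measured signal (a.u.).
#' @param m0 Equilibrium magnetisation (a.u.).
#' @param acquisition An [acquisition_config()].
#' @return T1 in seconds; `NA` where the signal is outside the invertible
#'   range (e.g. signal >= the saturation plateau).
#' @export
spgr_invert_t1 <- function(signal, m0, acquisition = acquisition_config()) {
  a <- acquisition$flip_deg * pi / 180
  x <- signal / (m0 * sin(a))
  e1 <- (1 - x) / (1 - cos(a) * x)
  out <- rep(NA_real_, length(e1))
  ok <- !is.na(e1) & e1 > 0 & e1 < 1
  out[ok] <- -(acquisition$tr_ms / 1000) / log(e1[ok])
  out
}

#' Two-point calibration from the vaginal tube
#'
#' Fits the linear relative-enhancement model through the two chamber signals:
#' the saline chamber maps to 0 mM and the Gd chamber to
#' `reference_concentration` exactly, giving
#' `slope = reference_concentration / ((gd - saline)/saline)` in mM per unit
#' relative enhancement.
#'
#' @param saline_signal Mean signal of the saline chamber (a.u., > 0).
#' @param gd_signal Mean signal of the Gd chamber (a.u., > 0).
#' @param reference_concentration Gd concentration of the second chamber (mM).
#' @return An object of class `calibration_model` with a `$concentration(signal)`
#'   function and the fitted `slope`.
#' @export
calibrate_from_tube <- function(saline_signal, gd_signal,
                                reference_concentration = 0.5) {
  stopifnot(saline_signal > 0, gd_signal > 0, reference_concentration > 0)
  if (isTRUE(all.equal(saline_signal, gd_signal)))
    stop("degenerate calibration: chamber signals are equal")
  slope <- reference_concentration / ((gd_signal - saline_signal) / saline_signal)
  model <- structure(list(method = "linear-enhancement", slope = slope,
                          reference_signal_saline = saline_signal,
                          reference_signal_gd = gd_signal,
                          reference_concentration = reference_concentration),
                     class = "calibration_model")
  model$concentration <- function(signal) {
    slope * (signal - saline_signal) / saline_signal
  }
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Tube calibration (%s): slope %.4g mM per unit relative enhancement\n",
              x$method, x$slope))
  invisible(x)
}

#' Convert a dynamic signal series to Gd-DTPA concentration
#'
#' The baseline S0 is the per-voxel arithmetic mean of the precontrast frames.
#' Two methods:
#' \describe{
#'   \item{linear}{Tube-calibrated relative enhancement:
#'     \eqn{C(t) = slope \cdot (S(t) - S_0)/S_0}. Requires `calibration`
#'     (taken from the series' embedded tube signals when omitted).}
#'   \item{spgr}{Full SPGR inversion: the precontrast T1 (`t10_s`) fixes the
#'     equilibrium magnetisation per voxel from S0, each frame's signal is
#'     inverted for R1(t), and \eqn{C(t) = (R_1(t) - R_{1,0})/r_1}.}
#' }
#' Voxels with S0 <= 0, or (spgr method) any frame outside the invertible
#' signal range, are flagged unconvertible and removed from the series mask.
#'
#' @param series A `dce_series` (see [simulate_dce_series()] / [read_dce_series()])
#'   holding signal intensities.
#' @param calibration Optional [calibrate_from_tube()] model (linear method).
#' @param method `"linear"` or `"spgr"`.
#' @param t10_s Precontrast tissue T1 (s), spgr method only.
#' @return A `dce_series` with `kind = "concentration"` (mM), the conversion
#'   method recorded in `$provenance`, and unconvertible voxels dropped from
#'   `$mask`.
#' @export
concentration_from_signal <- function(series, calibration = NULL,
                                      method = c("linear", "spgr"),
                                      t10_s = 1.4) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dce_series"))
  if (series$kind != "signal") stop("series does not hold signal intensities")
  acq <- series$acquisition
  npre <- acq$n_precontrast
  nframes <- dim(series$data)[4]
  if (nframes < npre) stop("fewer frames than precontrast count")

  mat <- matrix(series$data, ncol = nframes)
  s0 <- rowMeans(mat[, seq_len(npre), drop = FALSE])
  bad <- s0 <= 0

  if (method == "linear") {
    if (is.null(calibration)) {
      if (is.null(series$tube)) stop("no calibration model and no embedded tube signals")
      calibration <- calibrate_from_tube(mean(series$tube$saline),
                                         mean(series$tube$gd))
    }
    conc <- calibration$slope * (mat - s0) / s0
  } else {
    e10 <- exp(-(acq$tr_ms / 1000) / t10_s)
    a <- acq$flip_deg * pi / 180
    m0 <- s0 * (1 - cos(a) * e10) / (sin(a) * (1 - e10))
    t1 <- spgr_invert_t1(as.vector(mat), rep(m0, nframes), acq)
    r1 <- 1 / matrix(t1, ncol = nframes)
    conc <- (r1 - 1 / t10_s) / acq$relaxivity_r1
    bad <- bad | apply(is.na(conc), 1, any)
  }
  conc[bad, ] <- NA_real_

  mask <- series$mask
  mask[which(bad)] <- FALSE
  out <- series
  out$data <- array(conc, dim = dim(series$data))
  out$kind <- "concentration"
  out$mask <- mask
  out$provenance <- c(series$provenance,
                      list(conversion = list(method = method,
                                             t10_s = if (method == "spgr") t10_s else NA,
                                             n_unconvertible = sum(bad & series$mask))))
  out
}
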