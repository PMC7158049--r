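# Standard Tofts model: forward evaluation and voxelwise fitting.
# Public Ktrans/kep are in 1/min (the conventional reporting unit); the AIF
# decay constants are in 1/s, so all internal arithmetic converts once by /60.

SEC_PER_MIN <- 60

#' Standard Tofts forward model
#'
#' Tissue concentration
#' \eqn{C_t(T) = K^{trans} \int_0^T C_p(t)\, e^{-k_{ep}(T-t)} dt} with
#' \eqn{k_{ep} = K^{trans}/v_e} and a biexponential AIF. The closed-form path
#' evaluates the analytic solution of the convolution; the quadrature path
#' integrates numerically and exists as an internal cross-check.
#'
#' Times at or before the injection (t <= 0) return 0 mM.
#'
#' @param times_s Frame times in seconds relative to injection.
#' @param ktrans Volume transfer constant, 1/min.
#' @param ve Fractional distribution volume (0 < ve <= 1).
#' @param aif An [aif_params()] object.
#' @param method `"closed-form"` (default) or `"quadrature"`.
#' @return Tissue concentration in mM at each time.
#' @export
#' @examples
#' tofts_forward(seq(29, 600, by = 29), ktrans = 0.2, ve = 0.3)
tofts_forward <- function(times_s, ktrans, ve, aif = aif_params(),
                          method = c("closed-form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(length(ktrans) == 1, length(ve) == 1)
  if (ktrans < 0) stop("`ktrans` must be non-negative")
  if (ve <= 0 || ve > 1) stop("`ve` must be in (0, 1]")
  if (ktrans == 0) return(rep(0, length(times_s)))

  k_s <- ktrans / SEC_PER_MIN      # 1/s
  kep_s <- k_s / ve                # 1/s
  out <- numeric(length(times_s))
  pos <- times_s > 0
  if (!any(pos)) return(out)
  tt <- times_s[pos]

  if (method == "closed-form") {
    out[pos] <- k_s * (.conv_exp_term(tt, aif$A, aif$B, kep_s) +
                         .conv_exp_term(tt, aif$C, aif$D, kep_s))
  } else {
    out[pos] <- vapply(tt, function(Tend) {
      k_s * stats::integrate(function(u) {
        aif_concentration(u, aif) * exp(-kep_s * (Tend - u))
      }, lower = 0, upper = Tend, rel.tol = 1e-12, abs.tol = 1e-14,
      subdivisions = 500L)$value
    }, numeric(1))
  }
  out
}

# Analytic convolution of amp * exp(-rate * t) with exp(-kep * t):
# amp * (e^{-rate T} - e^{-kep T}) / (kep - rate), with the limiting form
# amp * T * e^{-kep T} when kep ~= rate (series expansion guard).
.conv_exp_term <- function(Tt, amp, rate, kep) {
  if (abs(kep - rate) < 1e-9) {
    amp * Tt * exp(-kep * Tt)
  } else {
    amp * (exp(-rate * Tt) - exp(-kep * Tt)) / (kep - rate)
  }
}

#' Fit the Tofts model to one concentration curve
#'
#' Levenberg-Marquardt least squares over (Ktrans, ve) within bounds, with a
#' multi-start grid of initial values (the objective is multi-modal at low
#' SNR); the start with the lowest residual sum of squares wins. Only frames
#' with time > 0 (post injection) enter the residual.
#'
#' A curve with no positive post-injection concentration is flagged
#' non-enhancing and returned with Ktrans pinned to the lower bound rather
#' than raising an error; such voxels are excluded from downstream frequency
#' distributions.
#'
#' @param times_s Frame times (s) relative to injection; precontrast frames
#'   carry non-positive times and are ignored by the fit.
#' @param conc_mM Observed tissue concentration (mM), same length as `times_s`.
#' @param aif An [aif_params()] object.
#' @param starts Data frame of starting values with columns `ktrans`, `ve`.
#' @param lower,upper Length-2 bounds `c(ktrans, ve)`; defaults
#'   `c(0, 0.001)` and `c(5, 1)`.
#' @return A list with elements `ktrans`, `ve`, `kep` (1/min), `rss`,
#'   `converged`, `n_iter`, `non_enhancing`, `boundary_hit`.
#' @export
fit_tofts_voxel <- function(times_s, conc_mM, aif = aif_params(),
                            starts = tofts_starts(),
                            lower = c(0, 0.001), upper = c(5, 1)) {
  stopifnot(length(times_s) == length(conc_mM))
  post <- times_s > 0
  if (sum(post) < 4) stop("need at least 4 post-injection frames")
  tt <- times_s[post]
  cc <- conc_mM[post]

  if (!any(cc > 0)) {
    return(list(ktrans = lower[1], ve = NA_real_, kep = NA_real_,
                rss = sum(cc^2), converged = TRUE, n_iter = 0L,
                non_enhancing = TRUE, boundary_hit = FALSE))
  }

  resid_fn <- function(par) {
    cc - tofts_forward(tt, par[1], par[2], aif)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(c(starts$ktrans[i], starts$ve[i]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(ktrans = NA_real_, ve = NA_real_, kep = NA_real_,
                rss = NA_real_, converged = FALSE, n_iter = 0L,
                non_enhancing = FALSE, boundary_hit = FALSE))
  }
  par <- best$fit$par
  tol <- 1e-8
  list(ktrans = par[1], ve = par[2], kep = par[1] / par[2],
       rss = best$rss,
       converged = best$fit$info %in% 1:4,
       n_iter = best$fit$niter,
       non_enhancing = FALSE,
       boundary_hit = any(par <= lower + tol) || any(par >= upper - tol))
}

#' Default multi-start grid for the Tofts fit
#'
#' @return A tibble with columns `ktrans` (1/min) and `ve`.
#' @export
tofts_starts <- function() {
  tidyr::expand_grid(ktrans = c(0.05, 0.2, 0.6), ve = c(0.1, 0.3, 0.5))
}

#' Voxelwise Tofts fit over a masked volume
#'
#' Applies [fit_tofts_voxel()] independently to every masked voxel of a 4-D
#' concentration array. Voxels failing convergence are dropped from the output
#' map mask and counted in the summary.
#'
#' @param conc_4d 4-D array (x, y, z, frame) of tissue concentration in mM.
#' @param times_s Frame times (s), length = `dim(conc_4d)[4]`.
#' @param mask 3-D logical array of voxels to fit; must be non-empty.
#' @param aif An [aif_params()] object.
#' @param voxel_dims_mm Physical voxel size, length 3 (mm).
#' @param ... Passed to [fit_tofts_voxel()].
#' @return An object of class `tofts_volume_fit`: list with `ktrans` and `ve`
#'   [parametric_map()]s, a per-voxel tibble `fits`, and convergence counts.
#'   Use [tidy()] / [glance()] to extract tables.
#' @export
fit_tofts_volume <- function(conc_4d, times_s, mask, aif = aif_params(),
                             voxel_dims_mm = c(0.78, 0.78, 5.0), ...) {
  stopifnot(length(dim(conc_4d)) == 4, length(dim(mask)) == 3)
  if (!all(dim(conc_4d)[1:3] == dim(mask))) stop("mask shape must match volume")
  if (!any(mask)) stop("mask is empty: nothing to fit")

  idx <- which(mask, arr.ind = TRUE)
  nvox <- nrow(idx)
  mat <- matrix(conc_4d, ncol = dim(conc_4d)[4])
  lin <- which(mask)

  rows <- vector("list", nvox)
  for (v in seq_len(nvox)) {
    f <- fit_tofts_voxel(times_s, mat[lin[v], ], aif = aif, ...)
    rows[[v]] <- tibble::tibble(
      i = idx[v, 1], j = idx[v, 2], k = idx[v, 3],
      ktrans = f$ktrans, ve = f$ve, kep = f$kep, rss = f$rss,
      converged = f$converged, n_iter = f$n_iter,
      non_enhancing = f$non_enhancing, boundary_hit = f$boundary_hit)
  }
  fits <- dplyr::bind_rows(rows)

  ok <- fits$converged & !fits$non_enhancing
  kt <- array(NA_real_, dim(mask)); ve <- array(NA_real_, dim(mask))
  fmask <- array(FALSE, dim(mask))
  lin_ok <- lin[ok]
  kt[lin_ok] <- fits$ktrans[ok]
  ve[lin_ok] <- fits$ve[ok]
  fmask[lin_ok] <- TRUE

  structure(list(
    ktrans = parametric_map(kt, fmask, voxel_dims_mm, "ktrans"),
    ve = parametric_map(ve, fmask, voxel_dims_mm, "ve"),
    fits = fits,
    n_voxels = nvox,
    n_converged = sum(fits$converged),
    n_non_enhancing = sum(fits$non_enhancing)
  ), class = "tofts_volume_fit")
}

#' @export
print.tofts_volume_fit <- function(x, ...) {
  cat(sprintf("Voxelwise Tofts fit: %d voxels, %d converged (%.1f%%), %d non-enhancing\n",
              x$n_voxels, x$n_converged, 100 * x$n_converged / x$n_voxels,
              x$n_non_enhancing))
  invisible(x)
}

#' @rdname fit_tofts_volume
#' @param x A `tofts_volume_fit` object.
#' @export
tidy.tofts_volume_fit <- function(x, ...) x$fits

#' @rdname fit_tofts_volume
#' @export
glance.tofts_volume_fit <- function(x, ...) {
  tibble::tibble(
    n_voxels = x$n_voxels,
    n_converged = x$n_converged,
    n_non_enhancing = x$n_non_enhancing,
    convergence_rate = x$n_converged / x$n_voxels,
    median_rss = stats::median(x$fits$rss, na.rm = TRUE))
}

#' Parametric map container
#'
#' A 3-D grid of one fitted parameter together with the mask of voxels on
#' which it is defined and the physical voxel size.
#'
#' @param values 3-D numeric array; `NA` outside the mask.
#' @param mask 3-D logical array, same shape.
#' @param voxel_dims_mm Length-3 voxel size in mm (all > 0).
#' @param parameter_name e.g. `"ktrans"` or `"ve"`.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, mask, voxel_dims_mm = c(0.78, 0.78, 5.0),
                           parameter_name = "ktrans") {
  stopifnot(length(dim(values)) == 3, all(dim(values) == dim(mask)),
            length(voxel_dims_mm) == 3, all(voxel_dims_mm > 0))
  if (any(is.na(values[mask]))) stop("map values must be defined on every masked voxel")
  structure(list(values = values, mask = mask,
                 voxel_dims_mm = as.numeric(voxel_dims_mm),
                 parameter_name = parameter_name),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("Parametric map <%s>: %s grid, %d masked voxels, voxel %.2fx%.2fx%.1f mm\n",
              x$parameter_name, paste(dim(x$values), collapse = "x"),
              sum(x$mask), x$voxel_dims_mm[1], x$voxel_dims_mm[2],
              x$voxel_dims_mm[3]))
  invisible(x)
}

#' Voxel volume of a parametric map in mm^3
#' @param map A [parametric_map()].
#' @export
voxel_volume_mm3 <- function(map) prod(map$voxel_dims_mm)

#' @export
as_tibble.parametric_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                 value = x$values[x$mask],
                 parameter = x$parameter_name)
}
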