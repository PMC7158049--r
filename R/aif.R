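#' Population arterial input function parameters
#'
#' Biexponential plasma concentration model
#' \eqn{C_p(t) = A e^{-Bt} + C e^{-Dt}} describing the decay of Gd-DTPA in
#' plasma after a bolus injection. The defaults are the published population
#' constants for a standard 0.1 mmol/kg Gd-DTPA bolus.
#'
#' @param A Amplitude of the fast component (mM). Default 5.10.
#' @param B Decay rate of the fast component (1/s). Default 14.2.
#' @param C Amplitude of the slow component (mM). Default 0.99.
#' @param D Decay rate of the slow component (1/s). Default 0.159.
#'
#' @return An object of class `aif_params`.
#' @export
#' @examples
#' aif <- aif_params()
#' aif_concentration(0, aif)   # A + C = 6.09 mM at injection
aif_params <- function(A = 5.10, B = 14.2, C = 0.99, D = 0.159) {
  stopifnot(A > 0, B > 0, C > 0, D > 0, B != D)
  structure(list(A = A, B = B, C = C, D = D), class = "aif_params")
}

#' @export
print.aif_params <- function(x, ...) {
  cat(sprintf("Biexponential AIF: Cp(t) = %.3g e^(-%.3g t) + %.3g e^(-%.3g t) mM (t in s)\n",
              x$A, x$B, x$C, x$D))
  invisible(x)
}

#' Plasma Gd-DTPA concentration at time t
#'
#' @param t_s Time since injection, seconds (vectorised). Must be >= 0.
#' @param aif An [aif_params()] object.
#' @return Plasma concentration in mM.
#' @export
aif_concentration <- function(t_s, aif = aif_params()) {
  if (any(t_s < 0)) stop("`t_s` must be non-negative (time since injection)")
  aif$A * exp(-aif$B * t_s) + aif$C * exp(-aif$D * t_s)
}

#' Cumulative integral of the AIF from 0 to t
#'
#' Closed form of \eqn{\int_0^t C_p(u)\,du}, used for the limiting case
#' kep -> 0 of the Tofts model.
#'
#' @inheritParams aif_concentration
#' @return Integral in mM * s.
#' @export
aif_integral <- function(t_s, aif = aif_params()) {
  if (any(t_s < 0)) stop("`t_s` must be non-negative")
  aif$A * (1 - exp(-aif$B * t_s)) / aif$B +
    aif$C * (1 - exp(-aif$D * t_s)) / aif$D
}
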