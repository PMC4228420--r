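# Forward pharmacokinetic model curves.
#
# Conventions used throughout: the time argument `t` is in SECONDS since
# injection (negative times are pre-contrast and return the baseline value);
# all rate constants (Ktrans, kep, kel, m_i) are in 1/min; concentrations in
# mM. Rates and times are reconciled internally.

# gap below which the removable singularity (m ~ kep) switches to its
# analytic limit branch, in 1/min
.RATE_GAP <- 1e-8

# sum_i a_i (exp(-kep tm) - exp(-m_i tm)) / (m_i - kep), with the limit
# branch a_i * tm * exp(-kep tm) when |m_i - kep| < .RATE_GAP; tm in minutes
.biexp_washout_sum <- function(a, m, kep, tm) {
  out <- numeric(length(tm))
  for (i in seq_along(a)) {
    if (abs(m[i] - kep) < .RATE_GAP)
      out <- out + a[i] * tm * exp(-kep * tm)
    else
      out <- out + a[i] * (exp(-kep * tm) - exp(-m[i] * tm)) / (m[i] - kep)
  }
  out
}

#' Discrete convolution with an exponential washout kernel
#'
#' Computes `Ct = Cp (*) Ktrans * exp(-kep t)` on a uniform frame grid.
#' `Cp` is treated as piecewise linear between samples and each interval is
#' integrated against the exponential kernel in closed form, accumulated by
#' the exact O(n) recursion `Ct[j] = E*Ct[j-1] + Ktrans*I[j]`,
#' `E = exp(-kep dt)`. This first-order-hold quadrature is exact for a
#' piecewise-linear input, so it remains accurate even when `kep * dt` is
#' not small (fast-washout pixels); at `kep = 0` it reduces to the running
#' trapezoidal integral. It is the numerical work-horse behind the
#' Tofts-family and reference-region models when the input function is
#' sampled.
#'
#' @param t uniform time grid, seconds; `Cp` must already be zero before
#'   injection.
#' @param Cp plasma concentration samples on `t`, mM.
#' @param Ktrans transfer constant, 1/min.
#' @param kep washout rate, 1/min.
#' @return Tissue concentration series, mM, with `Ct[1] = 0`.
#' @export
exp_kernel_convolve <- function(t, Cp, Ktrans, kep) {
  if (length(t) != length(Cp)) stop("t and Cp must have equal length")
  if (length(t) < 2L) return(numeric(length(t)))
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("exp_kernel_convolve requires a uniform grid; resample first")
  dtm <- dt[1] / 60
  n <- length(Cp)
  c0 <- c(0, Cp[-n])                          # left sample of each interval
  x <- kep * dtm
  if (x > 1e-6) {
    E <- exp(-x)
    w0 <- (1 - E) / kep                       # integral of e^{-kep(dt-s)}
    w1 <- (1 - (1 - E) / x) / kep             # ramp term
  } else {
    # series limits, exact at kep = 0 (trapezoid)
    E <- exp(-x)
    w0 <- dtm * (1 - x / 2 + x^2 / 6)
    w1 <- dtm * (1 / 2 - x / 6 + x^2 / 24)
  }
  inc <- Ktrans * (c0 * w0 + (Cp - c0) * w1)
  inc[1] <- 0
  as.numeric(stats::filter(inc, E, method = "recursive"))
}

#' Analytic Tofts model with a bi-exponential input function
#'
#' Closed-form tissue concentration for an instantaneous bolus:
#' `Ct(t) = D*Ktrans * sum_i a_i (exp(-kep t) - exp(-m_i t)) / (m_i - kep)`,
#' `kep = Ktrans/ve`. Rates within `1e-8` 1/min of `kep` use the removable-
#' singularity limit `a_i t exp(-kep t)`.
#'
#' @param Ktrans transfer constant plasma -> EES, 1/min (>= 0).
#' @param ve fractional EES volume, in (0, 1].
#' @param aif a [biexp_aif()].
#' @param t time since injection, seconds; values `< 0` return 0.
#' @return Tissue concentration, mM.
#' @export
tofts_ct_analytic <- function(Ktrans, ve, aif, t) {
  stopifnot(inherits(aif, "biexp_aif"))
  if (Ktrans < 0) stop("Ktrans must be non-negative")
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]")
  kep <- Ktrans / ve
  tm <- pmax(t, 0) / 60
  ct <- aif$D * Ktrans * .biexp_washout_sum(aif$a, aif$m, kep, tm)
  ct[t <= 0] <- 0
  ct
}

#' Extended Tofts model
#'
#' Adds the intravascular plasma contribution `vp * Cp(t)` to the Tofts
#' curve. With a [biexp_aif()] the convolution term is evaluated
#' analytically; with a [sampled_aif()] it is computed by
#' [exp_kernel_convolve()] on the (uniform) frame grid.
#'
#' @inheritParams tofts_ct_analytic
#' @param vp fractional plasma volume, in [0, 1]; `ve + vp <= 1`.
#' @return Tissue concentration, mM.
#' @export
ext_tofts_ct <- function(Ktrans, ve, vp, aif, t) {
  if (vp < 0 || vp > 1) stop("vp must lie in [0, 1]")
  if (ve + vp > 1 + 1e-12) stop("ve + vp must not exceed 1")
  cp <- .cp_on_grid(aif, t)
  cp[t < 0] <- 0
  if (inherits(aif, "biexp_aif")) {
    conv <- tofts_ct_analytic(Ktrans, ve, aif, t)
  } else {
    conv <- exp_kernel_convolve(t, cp, Ktrans, Ktrans / ve)
  }
  vp * cp + conv
}

#' Hoffmann signal model
#'
#' Direct signal-enhancement model requiring no input function or
#' concentration calibration:
#' `S(t)/S0 = 1 + A_H kep (exp(-kep t) - exp(-kel t)) / (kel - kep)`.
#' When `|kel - kep|` is below `1e-8` 1/min the removable singularity is
#' replaced by its limit `S/S0 = 1 + A_H kep t exp(-kep t)`.
#'
#' @param A_H dimensionless amplitude (approximately the EES size).
#' @param kep washout rate EES -> plasma, 1/min.
#' @param kel renal elimination rate, 1/min.
#' @param S0 pre-injection baseline signal.
#' @param t time since injection, seconds; `t < 0` returns `S0`.
#' @return Modelled signal.
#' @export
hoffmann_signal <- function(A_H, kep, kel, S0, t) {
  if (A_H < 0 || kep < 0 || kel < 0)
    stop("A_H, kep and kel must be non-negative")
  tm <- pmax(t, 0) / 60
  if (abs(kel - kep) < .RATE_GAP)
    enh <- A_H * kep * tm * exp(-kep * tm)
  else
    enh <- A_H * kep * (exp(-kep * tm) - exp(-kel * tm)) / (kel - kep)
  S0 * (1 + enh)
}

#' Larsson signal model
#'
#' Linear-signal model driven by the shape of a multi-exponential plasma
#' curve: `S(t) = S0 + Sdot0 * g(t)`, where
#' `g(t) = [sum_i a_i (exp(-kep t) - exp(-m_i t)) / (m_i - kep)] / sum_i a_i`
#' is normalised so its initial slope is exactly 1; `Sdot0` is therefore the
#' initial post-bolus signal slope, in signal units per minute.
#'
#' @param kep washout rate, 1/min.
#' @param S0 pre-injection baseline signal (> 0).
#' @param Sdot0 initial signal slope, signal/min.
#' @param a,m amplitudes and rates (1/min) of the plasma-curve exponentials
#'   (any length >= 1).
#' @param t time since injection, seconds; `t < 0` returns `S0`.
#' @return Modelled signal.
#' @export
larsson_signal <- function(kep, S0, Sdot0, a, m, t) {
  if (kep < 0) stop("kep must be non-negative")
  if (S0 <= 0) stop("S0 must be positive")
  stopifnot(length(a) == length(m), length(a) >= 1L)
  tm <- pmax(t, 0) / 60
  g <- numeric(length(tm))
  for (i in seq_along(a)) {
    if (abs(m[i] - kep) < .RATE_GAP)
      g <- g + a[i] * tm * exp(-kep * tm)
    else
      g <- g + a[i] * (exp(-kep * tm) - exp(-m[i] * tm)) / (m[i] - kep)
  }
  S0 + Sdot0 * g / sum(a)
}

#' Reference-region model
#'
#' Predicts the tissue concentration from the concentration in a
#' well-characterised reference tissue, eliminating the arterial input
#' function:
#' `Ct(t) = (Kt/Kt_r) * [Ct_r(t) + (Kt_r/ve_r - Kt/ve) *
#'  int_0^t Ct_r(u) exp(-(Kt/ve)(t-u)) du]`.
#' The integral is evaluated by trapezoidal quadrature on the frame grid.
#'
#' @param Ktrans,ve tissue-of-interest parameters (1/min, fraction).
#' @param Ktrans_r,ve_r reference-region parameters, assumed known.
#' @param t uniform time grid, seconds since injection start of the series
#'   (values `< 0` are pre-contrast).
#' @param Ct_r reference-region concentration on `t`, mM, zero before
#'   injection.
#' @return Tissue concentration series, mM.
#' @export
rr_ct <- function(Ktrans, ve, Ktrans_r, ve_r, t, Ct_r) {
  if (Ktrans < 0 || Ktrans_r <= 0) stop("Ktrans must be >= 0, Ktrans_r > 0")
  if (ve <= 0 || ve > 1 || ve_r <= 0 || ve_r > 1)
    stop("ve and ve_r must lie in (0, 1]")
  kep <- Ktrans / ve
  integral <- exp_kernel_convolve(t, Ct_r, 1, kep)   # unit-amplitude kernel
  (Ktrans / Ktrans_r) *
    (Ct_r + (Ktrans_r / ve_r - Ktrans / ve) * integral)
}
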