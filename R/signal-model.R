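#' Spin-echo signal equation
#'
#' Forward signal model for a T1-weighted spin-echo sequence at short echo
#' time: `S = S0 * (1 - exp(-TR/T1))`. `S0` here is the equilibrium signal
#' amplitude, not a measured baseline.
#'
#' @param S0 equilibrium signal amplitude (arbitrary units).
#' @param T1 longitudinal relaxation time, ms.
#' @param TR repetition time, ms.
#' @return Signal intensity, same units as `S0`. Vectorised over all
#'   arguments.
#' @examples
#' spin_echo_signal(1, T1 = 1000, TR = 200)   # 1 - exp(-0.2)
#' @export
spin_echo_signal <- function(S0, T1, TR) {
  if (any(T1 <= 0)) stop("T1 must be positive (ms)")
  if (any(TR <= 0)) stop("TR must be positive (ms)")
  S0 * (1 - exp(-TR / T1))
}

#' Spoiled gradient-echo signal equation
#'
#' Forward SPGR signal model
#' `S = S0 * (1 - E) * sin(a) / (1 - E cos(a))`, `E = exp(-TR/T1)`.
#' At `alpha = 90` degrees this reduces to the saturation-recovery form.
#'
#' @param S0 equilibrium signal amplitude.
#' @param T1 longitudinal relaxation time, ms.
#' @param TR repetition time, ms.
#' @param alpha flip angle, degrees, in (0, 90].
#' @return Signal intensity. Vectorised.
#' @export
spgr_signal <- function(S0, T1, TR, alpha) {
  if (any(T1 <= 0)) stop("T1 must be positive (ms)")
  if (any(TR <= 0)) stop("TR must be positive (ms)")
  if (any(alpha <= 0 | alpha > 90)) stop("alpha must lie in (0, 90] degrees")
  a <- alpha * pi / 180
  E <- exp(-TR / T1)
  S0 * (1 - E) * sin(a) / (1 - E * cos(a))
}

#' Relaxation-rate calibration between T1 and concentration
#'
#' The fast-exchange (Solomon-Bloembergen) linear relation
#' `1/T1 = 1/T10 + r1 * Ct`, with `r1` in s^-1 mM^-1 and T1/T10 in ms at the
#' interface (converted to seconds internally).
#'
#' @param Ct contrast-agent concentration, mM (non-negative).
#' @param relax a [relaxation_params()] object.
#' @return `t1_from_concentration`: T1 in ms. `concentration_from_t1`: Ct in
#'   mM; values for `T1 > T10` are negative concentrations and are reported
#'   with an `invalid` attribute flagging those entries.
#' @examples
#' rp <- relaxation_params(4.5, 1000)
#' t1_from_concentration(0.5, rp)   # 307.69 ms
#' @export
t1_from_concentration <- function(Ct, relax) {
  stopifnot(inherits(relax, "relaxation_params"))
  if (any(Ct < 0)) stop("Ct must be non-negative (mM)")
  1000 / (1000 / relax$T10 + relax$r1 * Ct)
}

#' @rdname t1_from_concentration
#' @param T1 longitudinal relaxation time, ms.
#' @export
concentration_from_t1 <- function(T1, relax) {
  stopifnot(inherits(relax, "relaxation_params"))
  if (any(T1 <= 0)) stop("T1 must be positive (ms)")
  ct <- (1000 / T1 - 1000 / relax$T10) / relax$r1
  bad <- ct < 0
  if (any(bad)) attr(ct, "invalid") <- bad
  ct
}

# clamp x into [lo, hi] shrunk by eps * (hi - lo); returns list(x, clamped)
.clamp_range <- function(x, lo, hi, eps = 1e-6) {
  span <- hi - lo
  lo2 <- lo + eps * span
  hi2 <- hi - eps * span
  clamped <- x <= lo2 | x >= hi2
  list(x = pmin(pmax(x, lo2), hi2), clamped = clamped)
}

#' Concentration from spin-echo dynamic signal
#'
#' Inverts the spin-echo forward model against the measured pre-injection
#' baseline:
#' `Ct = (1/r1) * [ (1/TR) * log(S0b / (S0b - S*(1 - exp(-TR/T10)))) - 1/T10 ]`
#' (times in seconds internally). `S_t = S0_base` maps to exactly zero
#' concentration. When noise pushes the log argument out of its valid range
#' the value is clamped to within `1e-6` of the range and flagged.
#'
#' @param S_t dynamic signal (vector ok).
#' @param S0_base measured mean pre-injection signal (positive scalar, or
#'   vector matching `S_t`).
#' @param acq an [acquisition_params()] (uses `TR`).
#' @param relax a [relaxation_params()] object.
#' @return Concentration in mM with attribute `invalid`: logical vector
#'   marking clamped entries.
#' @export
concentration_from_spinecho <- function(S_t, S0_base, acq, relax) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(relax, "relaxation_params"))
  if (any(S0_base <= 0)) stop("S0_base must be positive")
  TRs <- acq$TR / 1000                       # s
  T10s <- relax$T10 / 1000
  # valid range of S_t (1 - exp(-TR/T10))/S0b ratio: denominator must be > 0
  f <- S_t * (1 - exp(-TRs / T10s)) / S0_base
  cl <- .clamp_range(f, 0, 1)                # denominator S0b(1 - f) > 0
  r1t1 <- (1 / TRs) * log(1 / (1 - cl$x)) - 1 / T10s   # 1/T1 - ... in s^-1
  # noise below baseline yields small negative Ct; kept as-is (unflagged)
  structure(r1t1 / relax$r1, invalid = cl$clamped)
}

#' Dynamic T1 from SPGR signal
#'
#' Inverts the spoiled gradient-echo forward model against the measured
#' pre-injection baseline. With `m = exp(-TR/T10)` and
#' `q = (S_t/S0_base) * (1 - m) / (1 - m cos(a))`, the post-contrast
#' relaxation satisfies `exp(-TR/T1) = (1 - q)/(1 - q cos(a))`; `T1` follows.
#' `S_t = S0_base` returns exactly `T10`. Out-of-range intermediates are
#' clamped to within `1e-6` of the invertible range and flagged.
#'
#' @inheritParams concentration_from_spinecho
#' @return T1 in ms with attribute `invalid` (logical, clamped entries).
#' @export
t1_from_spgr <- function(S_t, S0_base, acq, relax) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(relax, "relaxation_params"))
  if (any(S0_base <= 0)) stop("S0_base must be positive")
  a <- acq$flip_angle * pi / 180
  m <- exp(-acq$TR / relax$T10)
  q <- (S_t / S0_base) * (1 - m) / (1 - m * cos(a))
  cl <- .clamp_range(q, 0, 1)                # E in (0,1) <=> q in (0,1)
  E <- (1 - cl$x) / (1 - cl$x * cos(a))
  structure(-acq$TR / log(E), invalid = cl$clamped)
}

#' Concentration from SPGR dynamic signal
#'
#' Convenience composition of [t1_from_spgr()] and the relaxation-rate
#' calibration. Noise below baseline yields small negative concentrations,
#' which are kept (and left unflagged) so they average out in fitting; the
#' `invalid` flag marks only genuine inversion-range clamps.
#'
#' @inheritParams concentration_from_spinecho
#' @return Concentration in mM with attribute `invalid`.
#' @export
concentration_from_spgr <- function(S_t, S0_base, acq, relax) {
  T1 <- t1_from_spgr(S_t, S0_base, acq, relax)
  ct <- (1000 / as.numeric(T1) - 1000 / relax$T10) / relax$r1
  structure(ct, invalid = attr(T1, "invalid"))
}

# dispatch calibration by sequence kind; returns list(ct, invalid)
.signal_to_concentration <- function(y, S0_base, acq, relax) {
  ct <- switch(acq$sequence_kind,
               spin_echo = concentration_from_spinecho(y, S0_base, acq, relax),
               spgr = concentration_from_spgr(y, S0_base, acq, relax))
  list(ct = as.numeric(ct),
       invalid = isTRUE(any(attr(ct, "invalid"))))
}

#' Pre-contrast T1 mapping from variable-TR spin-echo images
#'
#' Estimates T10 per pixel from two or more spin-echo images acquired with
#' different repetition times. The two-image method solves
#' `S1/S2 = (1 - exp(-TR1/T1)) / (1 - exp(-TR2/T1))` by bracketed
#' root-finding; with more images (or `method = "least_squares"`) the pair
#' `(S0, T10)` is fitted to the spin-echo equation per pixel by
#' Levenberg-Marquardt.
#'
#' @param images list of numeric matrices (or scalars), one per TR, all the
#'   same shape.
#' @param TRs repetition times in ms, one per image, all distinct.
#' @param method `"two_point_ratio"` (first two images) or
#'   `"least_squares"` (all images).
#' @param t1_range search bracket for T1, ms.
#' @return List with `T10` (matrix of estimates, ms; `NA` where the pixel's
#'   ratio is unattainable) and `invalid` (logical matrix).
#' @export
estimate_t10 <- function(images, TRs,
                         method = c("two_point_ratio", "least_squares"),
                         t1_range = c(1, 20000)) {
  method <- match.arg(method)
  if (length(images) < 2L) stop("at least two images are required")
  if (length(TRs) != length(images)) stop("one TR per image is required")
  if (anyDuplicated(TRs)) stop("TRs must be distinct")
  images <- lapply(images, as.matrix)
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    stop("all images must share the same shape")
  T10 <- matrix(NA_real_, shp[1], shp[2])
  invalid <- matrix(FALSE, shp[1], shp[2])

  if (method == "two_point_ratio") {
    ord <- order(TRs[1:2])                  # TR1 < TR2
    TR1 <- TRs[1:2][ord[1]]; TR2 <- TRs[1:2][ord[2]]
    S1 <- images[[ord[1]]]; S2 <- images[[ord[2]]]
    ratio <- S1 / S2
    # attainable ratios: (TR1/TR2, 1) — T1 -> Inf and T1 -> 0 limits
    for (i in seq_along(ratio)) {
      r <- ratio[i]
      if (!is.finite(r) || r <= TR1 / TR2 || r >= 1) {
        invalid[i] <- TRUE
        next
      }
      f <- function(T1) (1 - exp(-TR1 / T1)) / (1 - exp(-TR2 / T1)) - r
      lo <- t1_range[1]; hi <- t1_range[2]
      if (f(lo) * f(hi) > 0) { invalid[i] <- TRUE; next }
      T10[i] <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
    }
  } else {
    S <- vapply(images, as.numeric, numeric(prod(shp)))  # pixels x images
    if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
    for (i in seq_len(nrow(S))) {
      y <- S[i, ]
      if (any(!is.finite(y)) || all(y == y[1])) { invalid[i] <- TRUE; next }
      init <- c(S0 = max(y) * 1.05, T10 = mean(t1_range) / 10)
      fit <- try(minpack.lm::nls.lm(
        par = init,
        lower = c(1e-12, t1_range[1]), upper = c(Inf, t1_range[2]),
        fn = function(p) y - p[1] * (1 - exp(-TRs / p[2]))),
        silent = TRUE)
      if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) {
        invalid[i] <- TRUE
      } else {
        T10[i] <- fit$par[2]
      }
    }
  }
  list(T10 = T10, invalid = invalid)
}
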