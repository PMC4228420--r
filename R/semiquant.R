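# Model-free descriptive parameters: RCE, IAUC, TTM.

#' Relative contrast enhancement
#'
#' `RCE = 100 * (max post-injection signal - baseline) / baseline`, with the
#' baseline taken as the mean of the pre-injection frames. Only
#' post-injection frames compete for the maximum, so baseline noise cannot
#' set it.
#'
#' @param curve signal time series (one pixel or cell).
#' @param injection_frame 0-based index of the first post-injection frame.
#' @return Enhancement in percent.
#' @examples
#' rce(c(100, 100, 250, 200), injection_frame = 2)   # 150
#' @export
rce <- function(curve, injection_frame) {
  injection_frame <- as.integer(injection_frame)
  if (injection_frame < 1L || injection_frame >= length(curve))
    stop("injection_frame must leave >= 1 baseline and >= 1 post frame")
  base <- mean(curve[seq_len(injection_frame)])
  100 * (max(curve[(injection_frame + 1L):length(curve)]) - base) / base
}

#' Initial area under the curve
#'
#' Trapezoidal integral of the curve from the injection time over a fixed
#' early window. Computed on calibrated concentration (mM s) when a
#' concentration curve is supplied, else on whatever the curve's units are
#' (e.g. percent enhancement, giving percent s).
#'
#' @param curve series on the uniform frame grid.
#' @param injection_frame 0-based first post-injection frame.
#' @param frame_interval seconds per frame.
#' @param window integration window in seconds after injection (default the
#'   conventional 60 s). Must not extend beyond the series.
#' @return Area in (curve units) x seconds.
#' @export
iauc <- function(curve, injection_frame, frame_interval, window = 60) {
  injection_frame <- as.integer(injection_frame)
  t <- (seq_along(curve) - 1L) * frame_interval
  t0 <- injection_frame * frame_interval
  if (t0 + window > t[length(t)] + 1e-9)
    stop("IAUC window extends beyond the acquired series")
  grid <- seq(t0, t0 + window, by = frame_interval)
  y <- stats::approx(t, curve, xout = grid)$y
  sum((y[-1] + y[-length(y)]) / 2) * frame_interval
}

#' Time to maximal enhancement
#'
#' Seconds from injection to the first post-injection frame attaining the
#' maximal value (ties broken by the earliest frame).
#'
#' @inheritParams iauc
#' @return Time in seconds (0 if the maximum is at the injection frame).
#' @export
ttm <- function(curve, injection_frame, frame_interval) {
  injection_frame <- as.integer(injection_frame)
  if (injection_frame >= length(curve))
    stop("no post-injection frames")
  post <- curve[(injection_frame + 1L):length(curve)]
  (which.max(post) - 1L) * frame_interval
}

#' Semi-quantitative parameter maps over an ROI
#'
#' Computes RCE, IAUC and TTM per binned cell — the closed-form, model-free
#' counterpart of [fit_roi()]; no solver is involved and every cell
#' "converges". IAUC is computed on calibrated concentration when `relax` is
#' given (units mM s, recorded in the configuration snapshot), otherwise on
#' relative enhancement in percent (percent s).
#'
#' @param series a [dce_series()].
#' @param roi a [dce_roi()].
#' @param relax optional [relaxation_params()] enabling concentration-domain
#'   IAUC.
#' @param window IAUC window, seconds.
#' @return A `parameter_map` with planes `RCE`, `IAUC`, `TTM`.
#' @export
semiquant_map <- function(series, roi, relax = NULL, window = 60) {
  acq <- series$acq
  b <- bin_signals(series, roi)
  mk <- function() matrix(NA_real_, b$grid_dim[1], b$grid_dim[2])
  params <- list(RCE = mk(), IAUC = mk(), TTM = mk())
  invalid <- matrix(FALSE, b$grid_dim[1], b$grid_dim[2])
  fitted_cells <- matrix(FALSE, b$grid_dim[1], b$grid_dim[2])
  for (i in seq_len(nrow(b$cells))) {
    yc <- b$curves[i, ]
    r <- b$cells$row[i] + 1L; cc <- b$cells$col[i] + 1L
    fitted_cells[r, cc] <- TRUE
    S0b <- baseline_mean(yc, acq$injection_frame)
    if (is.null(relax)) {
      icurve <- 100 * (yc - S0b) / S0b            # percent enhancement
    } else {
      cal <- .signal_to_concentration(yc, S0b, acq, relax)
      icurve <- cal$ct
      invalid[r, cc] <- cal$invalid
    }
    params$RCE[r, cc] <- rce(yc, acq$injection_frame)
    params$IAUC[r, cc] <- iauc(icurve, acq$injection_frame,
                               acq$frame_interval, window)
    params$TTM[r, cc] <- ttm(yc, acq$injection_frame, acq$frame_interval)
  }
  structure(list(model = "semiquant", params = params,
                 stderr = NULL, converged = fitted_cells, invalid = invalid,
                 fitted_cells = fitted_cells,
                 residual_norm = mk(), n_iter = mk(),
                 roi = roi, grid_dim = b$grid_dim, origin = b$origin,
                 config = list(acq = acq, relax = relax, window = window,
                               iauc_units = if (is.null(relax))
                                 "percent*s" else "mM*s")),
            class = "parameter_map")
}
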