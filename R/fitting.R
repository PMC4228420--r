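# Levenberg-Marquardt estimation of pharmacokinetic model parameters for a
# single curve (dce_fit) and pixel/cell-wise over an ROI (fit_roi).

#' Fitting control settings
#'
#' MINPACK-style stopping criteria used by [dce_fit()].
#'
#' @param maxiter maximum LM iterations.
#' @param ftol relative tolerance on the cost reduction.
#' @param ptol relative tolerance on the parameter step.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxiter = 200, ftol = 1e-8, ptol = 1e-8) {
  structure(list(maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol),
            class = "fit_control")
}

# Model registry: fitted parameter names, default inits and box bounds, and
# the curve evaluator. `extras` carries model-specific fixed inputs
# (aif, S0 baseline, reference curve/constants). t is seconds since
# injection (negative = baseline frames).
.model_def <- function(model, extras) {
  switch(model,
    tofts = list(
      par = c(Ktrans = 0.1, ve = 0.3),
      lower = c(Ktrans = 0, ve = 1e-6),
      upper = c(Ktrans = Inf, ve = 1),
      fn = function(t, p)
        if (inherits(extras$aif, "biexp_aif"))
          tofts_ct_analytic(p[["Ktrans"]], p[["ve"]], extras$aif, t)
        else
          exp_kernel_convolve(t, extras$cp_grid, p[["Ktrans"]],
                              p[["Ktrans"]] / p[["ve"]])),
    ext_tofts = list(
      par = c(Ktrans = 0.1, ve = 0.3, vp = 0.02),
      lower = c(Ktrans = 0, ve = 1e-6, vp = 0),
      upper = c(Ktrans = Inf, ve = 1, vp = 1),
      fn = function(t, p) {
        if (inherits(extras$aif, "biexp_aif")) {
          cp <- biexp_cp(extras$aif, t)
          cp[t < 0] <- 0
          conv <- tofts_ct_analytic(p[["Ktrans"]], p[["ve"]], extras$aif, t)
        } else {
          cp <- extras$cp_grid
          conv <- exp_kernel_convolve(t, cp, p[["Ktrans"]],
                                      p[["Ktrans"]] / p[["ve"]])
        }
        p[["vp"]] * cp + conv
      }),
    hoffmann = list(
      par = c(A_H = 1, kep = 1, kel = 0.05),
      lower = c(A_H = 0, kep = 0, kel = 0),
      upper = c(A_H = Inf, kep = Inf, kel = Inf),
      fn = function(t, p)
        hoffmann_signal(p[["A_H"]], p[["kep"]], p[["kel"]], extras$S0, t)),
    larsson = list(
      par = c(kep = 1, Sdot0 = NA),          # Sdot0 init is data-driven
      lower = c(kep = 0, Sdot0 = -Inf),
      upper = c(kep = Inf, Sdot0 = Inf),
      fn = function(t, p)
        larsson_signal(p[["kep"]], extras$S0, p[["Sdot0"]],
                       extras$aif$a, extras$aif$m, t)),
    rr = list(
      par = c(Ktrans = 0.1, ve = 0.3),
      lower = c(Ktrans = 1e-8, ve = 1e-6),
      upper = c(Ktrans = Inf, ve = 1),
      fn = function(t, p)
        rr_ct(p[["Ktrans"]], p[["ve"]], extras$Ktrans_r, extras$ve_r,
              t, extras$Ct_r)),
    stop("unknown model: ", model)
  )
}

.concentration_models <- c("tofts", "ext_tofts", "rr")

#' Fit a pharmacokinetic model to one dynamic curve
#'
#' The central estimator: bounded Levenberg-Marquardt least squares of one of
#' the five compartmental models against a single time-intensity (Hoffmann,
#' Larsson) or time-concentration (Tofts, extended Tofts, reference region)
#' curve. Pixel maps ([fit_roi()]) are built by applying this per binned
#' cell.
#'
#' @param t frame times in seconds since injection; negative entries are
#'   pre-contrast baseline frames (the model value there is the baseline).
#' @param y observed curve: concentration in mM for `"tofts"`,
#'   `"ext_tofts"`, `"rr"`; raw signal for `"hoffmann"`, `"larsson"`.
#'   Frames with `NA`/`NaN` are dropped.
#' @param model one of `"tofts"`, `"ext_tofts"`, `"hoffmann"`,
#'   `"larsson"`, `"rr"`.
#' @param aif a [biexp_aif()] or [sampled_aif()]; required for `"tofts"`,
#'   `"ext_tofts"` and `"larsson"` (only its exponential shape is used by
#'   Larsson).
#' @param S0 fixed baseline signal for the signal-domain models; by default
#'   the mean of the `t < 0` samples.
#' @param Ct_r reference-region concentration series on `t` (for
#'   `model = "rr"`).
#' @param Ktrans_r,ve_r known reference-region constants (for `"rr"`).
#' @param init named numeric vector overriding the default starting values.
#' @param lower,upper named vectors overriding the default box bounds.
#' @param control a [fit_control()].
#' @param invalid flag carried through from calibration clamping (stored on
#'   the result, not used by the optimiser).
#' @return An object of class `dce_fit` with components `par`, `stderr`
#'   (1-sigma, from the residual-variance-scaled `(J'J)^-1`),
#'   `residual_norm`, `converged`, `n_iter`, `reason`, plus the data and
#'   model closure used. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`.
#' @examples
#' aif <- biexp_aif()
#' t <- seq(-30, 300, by = 2)
#' ct <- tofts_ct_analytic(0.25, 0.4, aif, t)
#' fit <- dce_fit(t, ct, "tofts", aif = aif)
#' coef(fit)
#' @export
dce_fit <- function(t, y, model = c("tofts", "ext_tofts", "hoffmann",
                                    "larsson", "rr"),
                    aif = NULL, S0 = NULL, Ct_r = NULL,
                    Ktrans_r = NULL, ve_r = NULL,
                    init = NULL, lower = NULL, upper = NULL,
                    control = fit_control(), invalid = FALSE) {
  model <- match.arg(model)
  stopifnot(length(t) == length(y))

  extras <- list()
  if (model %in% c("tofts", "ext_tofts", "larsson")) {
    if (is.null(aif)) stop("model '", model, "' requires an AIF")
    extras$aif <- aif
    if (model == "larsson" && inherits(aif, "sampled_aif"))
      stop("the Larsson model needs the exponential AIF shape (biexp_aif)")
    if (model %in% c("tofts", "ext_tofts") &&
          inherits(aif, "sampled_aif")) {
      cp <- .cp_on_grid(aif, t)
      cp[t < 0] <- 0
      extras$cp_grid <- cp
    }
  }
  if (model == "rr") {
    if (is.null(Ct_r) || is.null(Ktrans_r) || is.null(ve_r))
      stop("model 'rr' requires Ct_r, Ktrans_r and ve_r")
    stopifnot(length(Ct_r) == length(t))
    extras$Ct_r <- Ct_r; extras$Ktrans_r <- Ktrans_r; extras$ve_r <- ve_r
  }
  if (model %in% c("hoffmann", "larsson")) {
    if (is.null(S0)) {
      if (!any(t < 0)) stop("no baseline frames; supply S0")
      S0 <- mean(y[t < 0], na.rm = TRUE)
    }
    if (!is.finite(S0) || S0 <= 0) stop("baseline S0 must be positive")
    extras$S0 <- S0
  }

  keep <- is.finite(y)
  def <- .model_def(model, extras)
  npar <- length(def$par)
  if (model == "rr") keep <- keep & is.finite(Ct_r)
  if (sum(keep) < npar + 1L)
    stop("need at least ", npar + 1L, " finite observations")
  drop_any <- !all(keep)
  tf <- t[keep]; yf <- y[keep]
  # model evaluators that need the full uniform grid (sampled-AIF
  # convolution, rr integral) are computed on the full grid, then subset
  needs_grid <- (model %in% c("tofts", "ext_tofts") &&
                   inherits(aif, "sampled_aif")) || model == "rr"
  fn_res <- if (needs_grid)
    function(p) yf - def$fn(t, p)[keep]
  else
    function(p) yf - def$fn(tf, p)

  p0 <- def$par
  if (model == "larsson") {
    # data-driven initial slope: first post-injection rise per minute
    post <- which(tf >= 0)
    p0[["Sdot0"]] <- if (length(post) >= 2L)
      max((yf[post[2]] - extras$S0) /
            ((tf[post[2]] - max(tf[post[1]], 0)) / 60 + 1e-9), 1e-3)
    else 1
  }
  if (!is.null(init)) p0[names(init)] <- init
  lo <- def$lower; hi <- def$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  res <- list(model = model, par = stats::setNames(rep(NA_real_, npar),
                                                   names(p0)),
              stderr = NULL, residual_norm = NA_real_, converged = FALSE,
              n_iter = 0L, reason = "", invalid = isTRUE(invalid),
              dropped_frames = sum(!keep), t = t, y = y,
              extras = extras, fn = def$fn, needs_grid = needs_grid,
              n = sum(keep))
  class(res) <- "dce_fit"

  if (stats::sd(yf) == 0) {                  # flat curve: nothing to fit
    res$reason <- "degenerate"
    return(res)
  }

  fit <- try(minpack.lm::nls.lm(
    par = p0, lower = lo, upper = hi, fn = fn_res,
    control = minpack.lm::nls.lm.control(
      maxiter = control$maxiter, ftol = control$ftol, ptol = control$ptol)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    res$reason <- paste("solver error:", attr(fit, "condition")$message)
    return(res)
  }
  res$par[] <- fit$par
  res$n_iter <- fit$niter
  res$residual_norm <- sqrt(fit$deviance)
  res$converged <- !(fit$info %in% c(0L, 5L, 9L))
  res$reason <- if (res$converged) "converged" else fit$message
  if (res$converged) {
    dof <- max(sum(keep) - npar, 1L)
    covm <- try(solve(fit$hessian) * fit$deviance / dof, silent = TRUE)
    res$stderr <- if (inherits(covm, "try-error"))
      stats::setNames(rep(NA_real_, npar), names(p0))
    else
      stats::setNames(sqrt(pmax(diag(covm), 0)), names(p0))
  }
  res
}

#' @export
coef.dce_fit <- function(object, ...) object$par

#' @export
fitted.dce_fit <- function(object, ...) {
  if (!object$converged && all(is.na(object$par))) return(rep(NA_real_,
                                                              length(object$t)))
  object$fn(object$t, object$par)
}

#' @export
residuals.dce_fit <- function(object, ...) object$y - fitted(object)

#' Predict a fitted model curve on new times
#'
#' @param object a [dce_fit()] result.
#' @param t times in seconds since injection; defaults to the fitted grid.
#'   Models that integrate on the acquisition grid (sampled-AIF convolution,
#'   reference region) can only be evaluated on that grid.
#' @param ... unused.
#' @export
predict.dce_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(fitted(object))
  if (object$needs_grid)
    stop("this fit is defined on its acquisition grid; use predict() without t")
  object$fn(t, object$par)
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d frames%s)\n", x$model, x$n,
              if (x$dropped_frames) sprintf(", %d dropped", x$dropped_frames)
              else ""))
  if (all(is.na(x$par))) {
    cat("  not fitted:", x$reason, "\n")
    return(invisible(x))
  }
  est <- format(signif(x$par, 5))
  if (!is.null(x$stderr))
    est <- paste0(est, " +/- ", format(signif(x$stderr, 2)))
  for (i in seq_along(x$par)) cat(sprintf("  %-7s %s\n", names(x$par)[i],
                                          est[i]))
  if ("Ktrans" %in% names(x$par) && "ve" %in% names(x$par))
    cat(sprintf("  kep     %s (derived)\n",
                format(signif(x$par[["Ktrans"]] / x$par[["ve"]], 5))))
  cat(sprintf("  residual norm %.6g | %s after %d iterations\n",
              x$residual_norm,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (x$invalid) cat("  note: calibration clamping occurred on this curve\n")
  invisible(x)
}

#' @export
summary.dce_fit <- function(object, ...) {
  out <- list(model = object$model,
              coefficients = cbind(Estimate = object$par,
                                   `Std. Error` = if (is.null(object$stderr))
                                     NA_real_ else object$stderr),
              converged = object$converged, n_iter = object$n_iter,
              residual_norm = object$residual_norm, n = object$n,
              reason = object$reason)
  class(out) <- "summary.dce_fit"
  out
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(sprintf("Model: %s | n = %d | %s (%s, %d iter) | ||r|| = %.6g\n",
              x$model, x$n,
              if (x$converged) "converged" else "not converged",
              x$reason, x$n_iter, x$residual_norm))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
plot.dce_fit <- function(x, ...) {
  graphics::plot(x$t, x$y, pch = 20, col = "grey40",
                 xlab = "time since injection (s)",
                 ylab = if (x$model %in% .concentration_models)
                   "Ct (mM)" else "signal",
                 main = paste(x$model, "fit"), ...)
  if (!all(is.na(x$par)))
    graphics::lines(x$t, fitted(x), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Average pixel curves into coarse-resolution cells
#'
#' Partitions the ROI's bounding box into `k x k` non-overlapping blocks
#' (anchored at the bounding-box origin) and averages, per block, the time
#' curves of the masked member pixels. `k = 1` returns the per-pixel curves
#' unchanged. Averaging i.i.d. pixel noise over a full `k x k` cell reduces
#' its standard deviation by `1/k`.
#'
#' @param series a [dce_series()].
#' @param roi a [dce_roi()]; its `bin_factor` sets `k`.
#' @return List: `curves` (cells x frames matrix), `cells` (data.frame of
#'   0-based binned-grid `row`, `col` and member pixel count), `grid_dim`
#'   (binned rows, cols), `origin` (0-based y, x of the bounding box).
#' @export
bin_signals <- function(series, roi) {
  stopifnot(inherits(series, "dce_series"), inherits(roi, "dce_roi"))
  d <- dim(series$data)
  z <- roi$slice_index + 1L
  if (z < 1L || z > d[3]) stop("ROI slice outside the series")
  if (nrow(roi$mask) > d[2] || ncol(roi$mask) > d[1])
    stop("ROI mask exceeds series bounds")
  k <- roi$bin_factor
  idx <- which(roi$mask, arr.ind = TRUE)       # (row=Y, col=X), 1-based
  y0 <- min(idx[, 1]); x0 <- min(idx[, 2])
  y1 <- max(idx[, 1]); x1 <- max(idx[, 2])
  nrb <- ceiling((y1 - y0 + 1) / k)
  ncb <- ceiling((x1 - x0 + 1) / k)
  cell_row <- (idx[, 1] - y0) %/% k
  cell_col <- (idx[, 2] - x0) %/% k
  cell_id <- cell_row * ncb + cell_col
  # slice as (X*Y) x time matrix; pixel (y, x) -> linear x + (y-1)*X
  sl <- series$data[, , z, , drop = FALSE]
  dim(sl) <- c(d[1] * d[2], d[4])
  lin <- idx[, 2] + (idx[, 1] - 1L) * d[1]
  groups <- split(seq_along(lin), cell_id)
  curves <- t(vapply(groups, function(g) {
    if (length(g) == 1L) sl[lin[g], ] else colMeans(sl[lin[g], , drop = FALSE])
  }, numeric(d[4])))
  ids <- as.integer(names(groups))
  cells <- data.frame(row = ids %/% ncb, col = ids %% ncb,
                      n_pixels = lengths(groups))
  list(curves = curves, cells = cells, grid_dim = c(nrb, ncb),
       origin = c(y = y0 - 1L, x = x0 - 1L))
}

#' Fit a pharmacokinetic model over an ROI
#'
#' The batch pipeline: bin pixel curves to the ROI's resolution, calibrate
#' signal to concentration where the model requires it, fit every cell with
#' [dce_fit()], and assemble parameter/uncertainty/flag maps on the binned
#' grid. Cells are independent; results do not depend on processing order.
#'
#' @param series a [dce_series()].
#' @param roi a [dce_roi()].
#' @param model model name as in [dce_fit()].
#' @param relax a [relaxation_params()]; required for the concentration
#'   models (`"tofts"`, `"ext_tofts"`, `"rr"`).
#' @param aif AIF object for the models that need one.
#' @param Ct_r,Ktrans_r,ve_r reference-region inputs for `model = "rr"`
#'   (`Ct_r` in mM on the frame grid).
#' @param init,lower,upper,control passed to [dce_fit()].
#' @return An object of class `parameter_map`: per-parameter estimate and
#'   standard-error matrices on the binned grid (`NA` in non-fitted or
#'   non-converged cells), convergence / calibration-clamp flag matrices,
#'   iteration and residual-norm matrices, plus the ROI and a configuration
#'   snapshot. Methods: `print`, `summary`, `plot`.
#' @export
fit_roi <- function(series, roi, model = c("tofts", "ext_tofts", "hoffmann",
                                           "larsson", "rr"),
                    relax = NULL, aif = NULL, Ct_r = NULL,
                    Ktrans_r = NULL, ve_r = NULL,
                    init = NULL, lower = NULL, upper = NULL,
                    control = fit_control()) {
  model <- match.arg(model)
  acq <- series$acq
  if (model %in% .concentration_models && is.null(relax))
    stop("model '", model,
         "' requires relaxation parameters ([relaxation_params]) for ",
         "signal-to-concentration calibration")
  if (model %in% c("tofts", "ext_tofts", "larsson") && is.null(aif))
    stop("model '", model, "' requires an AIF ([aif] configuration block)")
  if (model == "rr" && (is.null(Ct_r) || is.null(Ktrans_r) || is.null(ve_r)))
    stop("model 'rr' requires Ct_r, Ktrans_r and ve_r ([rr] configuration block)")

  b <- bin_signals(series, roi)
  t_model <- series$frame_times -
    series$frame_times[acq$injection_frame + 1L]
  par_names <- names(.model_def(model, list(aif = aif, S0 = 1, Ct_r = Ct_r,
                                            Ktrans_r = Ktrans_r,
                                            ve_r = ve_r))$par)
  mk <- function() matrix(NA_real_, b$grid_dim[1], b$grid_dim[2])
  params <- stats::setNames(lapply(par_names, function(i) mk()), par_names)
  stderrs <- stats::setNames(lapply(par_names, function(i) mk()), par_names)
  converged <- matrix(FALSE, b$grid_dim[1], b$grid_dim[2])
  invalid <- matrix(FALSE, b$grid_dim[1], b$grid_dim[2])
  fitted_cells <- matrix(FALSE, b$grid_dim[1], b$grid_dim[2])
  resnorm <- mk(); niter <- mk()

  for (i in seq_len(nrow(b$cells))) {
    yc <- b$curves[i, ]
    flag <- FALSE
    if (model %in% .concentration_models) {
      S0b <- baseline_mean(yc, acq$injection_frame)
      cal <- .signal_to_concentration(yc, S0b, acq, relax)
      yc <- cal$ct
      flag <- cal$invalid
    }
    f <- try(dce_fit(t_model, yc, model, aif = aif, Ct_r = Ct_r,
                     Ktrans_r = Ktrans_r, ve_r = ve_r, init = init,
                     lower = lower, upper = upper, control = control,
                     invalid = flag),
             silent = TRUE)
    r <- b$cells$row[i] + 1L; cc <- b$cells$col[i] + 1L
    fitted_cells[r, cc] <- TRUE
    invalid[r, cc] <- flag
    if (inherits(f, "try-error")) next
    converged[r, cc] <- f$converged
    resnorm[r, cc] <- f$residual_norm
    niter[r, cc] <- f$n_iter
    if (f$converged) {
      for (pn in par_names) {
        params[[pn]][r, cc] <- f$par[[pn]]
        stderrs[[pn]][r, cc] <- f$stderr[[pn]]
      }
    }
  }

  structure(list(model = model, params = params, stderr = stderrs,
                 converged = converged, invalid = invalid,
                 fitted_cells = fitted_cells, residual_norm = resnorm,
                 n_iter = niter, roi = roi, grid_dim = b$grid_dim,
                 origin = b$origin,
                 config = list(acq = acq, relax = relax, aif = aif,
                               Ktrans_r = Ktrans_r, ve_r = ve_r,
                               init = init, lower = lower, upper = upper,
                               control = control)),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("Parameter map (%s): %d x %d cells (%dx%d binning), %d fitted, %d converged\n",
              x$model, x$grid_dim[1], x$grid_dim[2],
              x$roi$bin_factor, x$roi$bin_factor,
              sum(x$fitted_cells), sum(x$converged)))
  cat("  parameters:", paste(names(x$params), collapse = ", "), "\n")
  invisible(x)
}

#' ROI summary statistics of a parameter map
#'
#' Unweighted mean, standard deviation and count per parameter over the
#' converged, non-clamped cells. A single-cell map reports `sd = 0` by
#' convention.
#'
#' @param map a `parameter_map` from [fit_roi()] or [semiquant_map()].
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(map) {
  stopifnot(inherits(map, "parameter_map"))
  ok <- map$converged & !map$invalid
  if (!any(ok)) stop("no converged cells")
  rows <- lapply(names(map$params), function(pn) {
    v <- map$params[[pn]][ok]
    v <- v[is.finite(v)]
    data.frame(parameter = pn, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' @export
summary.parameter_map <- function(object, ...) {
  out <- list(model = object$model, stats = roi_statistics(object),
              n_fitted = sum(object$fitted_cells),
              n_converged = sum(object$converged),
              n_invalid = sum(object$invalid),
              grid_dim = object$grid_dim, bin = object$roi$bin_factor)
  class(out) <- "summary.parameter_map"
  out
}

#' @export
print.summary.parameter_map <- function(x, ...) {
  cat(sprintf("%s map on %d x %d grid (%dx%d binning): %d fitted, %d converged, %d clamped\n",
              x$model, x$grid_dim[1], x$grid_dim[2], x$bin, x$bin,
              x$n_fitted, x$n_converged, x$n_invalid))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' @export
plot.parameter_map <- function(x, parameter = names(x$params)[1], ...) {
  m <- x$params[[parameter]]
  # image() draws x along rows; transpose and flip so row 1 is at the top
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = paste(x$model, "-", parameter), ...)
  invisible(x)
}
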