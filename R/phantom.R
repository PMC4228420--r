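# Digital reference object generator: parameter-grid patch phantoms with a
# vascular strip, synthesised through the package's own forward models so
# that every pipeline stage can be validated against known ground truth.

#' Phantom specification
#'
#' Full description of a synthetic validation object: a rectangular grid of
#' homogeneous 10x10-pixel patches, one per combination of the kinetic
#' parameter values, plus a whole-blood vascular strip along the bottom of
#' the image. Signals are synthesised frame-exactly with the package's
#' signal equations; optional zero-mean Gaussian noise is expressed as a
#' fraction of the per-pixel baseline.
#'
#' @param model `"tofts"` or `"ext_tofts"` — the kinetic model generating
#'   the tissue curves. Patch columns sweep `Ktrans`; patch rows sweep `ve`
#'   (and, for the extended model, the `ve` x `vp` combinations, `vp`
#'   varying fastest).
#' @param Ktrans_values,ve_values,vp_values kinetic parameter grids
#'   (`vp_values` used only by the extended model).
#' @param patch_size patch edge length in pixels.
#' @param acq an [acquisition_params()].
#' @param T10_tissue,T10_blood pre-contrast T1, ms.
#' @param hematocrit haematocrit fraction; the strip carries whole-blood
#'   concentration `(1 - Hct) * Cp`.
#' @param duration total simulated time, seconds.
#' @param injection_time injection instant, seconds from series start.
#' @param aif a [biexp_aif()] driving both tissue and strip.
#' @param S0 equilibrium signal amplitude, arbitrary units.
#' @param noise_sigma_fraction Gaussian noise sigma as a fraction of the
#'   baseline signal (0 = noise free).
#' @param seed RNG seed used when noise is added.
#' @param vascular_strip_rows height of the whole-blood strip, pixels.
#' @return An object of class `phantom_spec`.
#' @seealso [default_tofts_spec()], [default_ext_tofts_spec()],
#'   [generate_phantom()]
#' @export
phantom_spec <- function(model = c("tofts", "ext_tofts"),
                         Ktrans_values, ve_values, vp_values = NULL,
                         patch_size = 10L, acq,
                         T10_tissue = 1000, T10_blood = 1440,
                         hematocrit = 0.45,
                         duration, injection_time,
                         aif = biexp_aif(), S0 = 1000,
                         noise_sigma_fraction = 0, seed = 1L,
                         vascular_strip_rows = 10L) {
  model <- match.arg(model)
  stopifnot(length(Ktrans_values) >= 1L, length(ve_values) >= 1L,
            inherits(acq, "acquisition_params"),
            inherits(aif, "biexp_aif"))
  if (model == "ext_tofts" && is.null(vp_values))
    stop("ext_tofts phantom needs vp_values")
  if (any(ve_values <= 0 | ve_values > 1)) stop("ve values must be in (0,1]")
  if (!is.null(vp_values) && any(vp_values < 0 | vp_values > 1))
    stop("vp values must be in [0,1]")
  if (duration <= injection_time)
    stop("duration must exceed injection_time")
  structure(list(model = model,
                 Ktrans_values = as.numeric(Ktrans_values),
                 ve_values = as.numeric(ve_values),
                 vp_values = if (is.null(vp_values)) NULL
                             else as.numeric(vp_values),
                 patch_size = as.integer(patch_size), acq = acq,
                 T10_tissue = T10_tissue, T10_blood = T10_blood,
                 hematocrit = hematocrit, duration = duration,
                 injection_time = injection_time, aif = aif, S0 = S0,
                 noise_sigma_fraction = noise_sigma_fraction,
                 seed = as.integer(seed),
                 vascular_strip_rows = as.integer(vascular_strip_rows)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  n_comb <- length(x$Ktrans_values) * length(x$ve_values) *
    max(1L, length(x$vp_values))
  cat(sprintf("Phantom spec (%s): %d parameter combinations in %dx%d patches\n",
              x$model, n_comb, x$patch_size, x$patch_size))
  cat(sprintf("  %g s study, injection at %g s, noise sigma %g%% of baseline\n",
              x$duration, x$injection_time,
              100 * x$noise_sigma_fraction))
  invisible(x)
}

#' Standard single-compartment validation phantom
#'
#' Six `Ktrans` values (0.01-0.35 1/min) crossed with five `ve` values
#' (0.01-0.5) in 10x10 patches: a 50x60-pixel tissue region over a
#' whole-blood strip. SPGR sequence at flip angle 30 deg, TR 5 ms, 0.5 s
#' frames; 10-minute study with injection at 60 s; tissue T10 1000 ms, blood
#' T10 1440 ms, haematocrit 45%.
#'
#' @param noise_sigma_fraction,seed noise level (fraction of baseline) and
#'   RNG seed.
#' @return A [phantom_spec()].
#' @export
default_tofts_spec <- function(noise_sigma_fraction = 0, seed = 1L) {
  phantom_spec(
    model = "tofts",
    Ktrans_values = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35),
    ve_values = c(0.01, 0.05, 0.1, 0.2, 0.5),
    acq = acquisition_params("spgr", TR = 5, flip_angle = 30,
                             frame_interval = 0.5, injection_frame = 120L),
    T10_tissue = 1000, T10_blood = 1440, hematocrit = 0.45,
    duration = 600, injection_time = 60,
    S0 = 1000, noise_sigma_fraction = noise_sigma_fraction, seed = seed,
    vascular_strip_rows = 10L)
}

#' Standard extended-model validation phantom
#'
#' Six `Ktrans` values (0-0.2 1/min) crossed with three `ve` (0.1, 0.2,
#' 0.5) and six `vp` values (0.001-0.1): 108 combinations in 10x10 patches,
#' a 60x180-pixel tissue region over a 20-row whole-blood strip. SPGR at
#' flip angle 25 deg, TR 5 ms, 0.5 s frames; 3.5-minute study with injection
#' at 5 s; a lower equilibrium amplitude (250) mirrors the coarser signal
#' discretisation of this set.
#'
#' @inheritParams default_tofts_spec
#' @return A [phantom_spec()].
#' @export
default_ext_tofts_spec <- function(noise_sigma_fraction = 0, seed = 1L) {
  phantom_spec(
    model = "ext_tofts",
    Ktrans_values = c(0, 0.01, 0.02, 0.05, 0.1, 0.2),
    ve_values = c(0.1, 0.2, 0.5),
    vp_values = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
    acq = acquisition_params("spgr", TR = 5, flip_angle = 25,
                             frame_interval = 0.5, injection_frame = 10L),
    T10_tissue = 1000, T10_blood = 1440, hematocrit = 0.45,
    duration = 210, injection_time = 5,
    S0 = 250, noise_sigma_fraction = noise_sigma_fraction, seed = seed,
    vascular_strip_rows = 20L)
}

#' Generate a phantom series with ground truth
#'
#' Synthesises the 4D series described by a [phantom_spec()]: per tissue
#' patch, the kinetic model's concentration curve is converted to T1(t) by
#' the relaxation calibration and to signal by the spin-echo or SPGR
#' equation; the vascular strip carries the whole-blood signal with the
#' blood T10. Pre-injection frames sit exactly at baseline. Ground-truth
#' parameter planes are returned alongside; seeded Gaussian noise is added
#' when requested.
#'
#' @param spec a [phantom_spec()].
#' @param r1 contrast-agent relaxivity used at synthesis, s^-1 mM^-1.
#' @return List of class `dce_phantom`: `series` (a [dce_series()]),
#'   `truth` (per-parameter matrices over the tissue region, row = Y,
#'   col = X), `tissue_roi` (a [dce_roi()] covering the tissue region),
#'   `relax` (the [relaxation_params()] to use when analysing), `spec`.
#' @export
generate_phantom <- function(spec, r1 = 4.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  acq <- spec$acq
  nt <- round(spec$duration / acq$frame_interval)
  tsec <- (seq_len(nt) - 1) * acq$frame_interval
  tmod <- tsec - spec$injection_time
  relax_t <- relaxation_params(r1, spec$T10_tissue)
  relax_b <- relaxation_params(r1, spec$T10_blood)

  combos <- if (spec$model == "tofts") {
    expand.grid(vp = 0, ve = spec$ve_values, Ktrans = spec$Ktrans_values)
  } else {
    expand.grid(vp = spec$vp_values, ve = spec$ve_values,
                Ktrans = spec$Ktrans_values)
  }
  n_rows_comb <- nrow(combos) / length(spec$Ktrans_values)

  ps <- spec$patch_size
  nx <- length(spec$Ktrans_values) * ps          # Ktrans sweeps X (columns)
  ny_tissue <- n_rows_comb * ps                  # ve (x vp) sweeps Y (rows)
  ny <- ny_tissue + spec$vascular_strip_rows
  data <- array(0, dim = c(nx, ny_tissue + spec$vascular_strip_rows, 1L, nt))

  signal_of_ct <- function(ct, relax) {
    T1 <- t1_from_concentration(ct, relax)
    switch(acq$sequence_kind,
           spgr = spgr_signal(spec$S0, T1, acq$TR, acq$flip_angle),
           spin_echo = spin_echo_signal(spec$S0, T1, acq$TR))
  }

  truth_K <- matrix(NA_real_, ny_tissue, nx)
  truth_ve <- matrix(NA_real_, ny_tissue, nx)
  truth_vp <- matrix(NA_real_, ny_tissue, nx)

  # combos are ordered vp fastest, then ve, then Ktrans; patch (i_row, j_col)
  # with j_col sweeping Ktrans and i_row sweeping the ve (x vp) combinations
  for (j in seq_along(spec$Ktrans_values)) {
    for (i in seq_len(n_rows_comb)) {
      cb <- combos[(j - 1L) * n_rows_comb + i, ]
      ct <- if (spec$model == "tofts")
        tofts_ct_analytic(cb$Ktrans, cb$ve, spec$aif, tmod)
      else
        ext_tofts_ct(cb$Ktrans, cb$ve, cb$vp, spec$aif, tmod)
      sig <- signal_of_ct(ct, relax_t)
      xs <- ((j - 1L) * ps + 1L):(j * ps)
      yy <- ((i - 1L) * ps + 1L):(i * ps)
      data[xs, yy, 1L, ] <- rep(sig, each = length(xs) * length(yy))
      truth_K[yy, xs] <- cb$Ktrans
      truth_ve[yy, xs] <- cb$ve
      truth_vp[yy, xs] <- cb$vp
    }
  }

  if (spec$vascular_strip_rows > 0L) {
    cp <- biexp_cp(spec$aif, tmod)
    cp[tmod < 0] <- 0
    cb_blood <- (1 - spec$hematocrit) * cp       # whole-blood concentration
    sig_b <- signal_of_ct(cb_blood, relax_b)
    ys <- (ny_tissue + 1L):ny
    data[, ys, 1L, ] <- rep(sig_b, each = nx * length(ys))
  }

  series <- dce_series(data, acq, frame_times = tsec,
                       provenance = sprintf("synthetic %s phantom",
                                            spec$model))
  if (spec$noise_sigma_fraction > 0)
    series <- add_gaussian_noise(series, spec$noise_sigma_fraction,
                                 spec$seed)

  mask <- matrix(FALSE, ny, nx)
  mask[seq_len(ny_tissue), ] <- TRUE
  structure(list(series = series,
                 truth = list(Ktrans = truth_K, ve = truth_ve,
                              vp = if (spec$model == "ext_tofts") truth_vp
                                   else NULL),
                 tissue_roi = dce_roi(mask, 0L, 1L, kind = "box"),
                 relax = relax_t, spec = spec),
            class = "dce_phantom")
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat("Synthetic phantom:\n")
  print(x$spec)
  print(x$series)
  invisible(x)
}

#' Add seeded Gaussian noise to a series
#'
#' Adds i.i.d. zero-mean Gaussian noise to every frame, with a per-pixel
#' standard deviation of `sigma_fraction` times that pixel's pre-injection
#' baseline mean. Reproducible given the seed; `sigma_fraction = 0` returns
#' the series unchanged.
#'
#' @param series a [dce_series()].
#' @param sigma_fraction noise sigma as a fraction of the baseline signal.
#' @param seed integer RNG seed.
#' @return A new [dce_series()].
#' @export
add_gaussian_noise <- function(series, sigma_fraction, seed = 1L) {
  stopifnot(inherits(series, "dce_series"))
  if (sigma_fraction < 0) stop("sigma_fraction must be >= 0")
  if (sigma_fraction == 0) return(series)
  d <- dim(series$data)
  nb <- series$acq$injection_frame
  base <- apply(series$data[, , , seq_len(nb), drop = FALSE], 1:3, mean)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  noise <- array(stats::rnorm(prod(d)), dim = d) *
    as.vector(base) * sigma_fraction
  out <- series
  out$data <- series$data + noise
  out$provenance <- sprintf("%s + %g%% baseline Gaussian noise (seed %d)",
                            series$provenance, 100 * sigma_fraction,
                            as.integer(seed))
  out
}
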