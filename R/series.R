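#' Acquisition parameters for a dynamic T1-weighted series
#'
#' Bundles the sequence constants needed to relate MR signal to contrast-agent
#' concentration: the pulse-sequence family, repetition time, flip angle (for
#' spoiled gradient-echo only), the dynamic frame interval and the index of
#' the first post-injection frame.
#'
#' @param sequence_kind `"spin_echo"` or `"spgr"` (spoiled gradient echo).
#' @param TR repetition time, ms.
#' @param flip_angle excitation flip angle in degrees; used only for
#'   `sequence_kind = "spgr"`.
#' @param frame_interval time between dynamic frames, seconds.
#' @param injection_frame 0-based index of the first post-injection frame;
#'   frames `0 .. injection_frame - 1` are the pre-contrast baseline, so at
#'   least one baseline frame must exist.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params("spgr", TR = 5, flip_angle = 30,
#'                    frame_interval = 0.5, injection_frame = 120)
#' @export
acquisition_params <- function(sequence_kind = c("spin_echo", "spgr"),
                               TR,
                               flip_angle = 90,
                               frame_interval,
                               injection_frame) {
  sequence_kind <- match.arg(sequence_kind)
  stopifnot(is.numeric(TR), length(TR) == 1L, is.finite(TR))
  if (TR <= 0) stop("TR must be positive (ms)")
  stopifnot(is.numeric(flip_angle), length(flip_angle) == 1L)
  if (flip_angle <= 0 || flip_angle > 90)
    stop("flip_angle must lie in (0, 90] degrees")
  if (frame_interval <= 0) stop("frame_interval must be positive (s)")
  injection_frame <- as.integer(injection_frame)
  if (injection_frame < 1L)
    stop("injection_frame must be >= 1 (at least one baseline frame)")
  structure(list(sequence_kind = sequence_kind,
                 TR = as.numeric(TR),
                 flip_angle = as.numeric(flip_angle),
                 frame_interval = as.numeric(frame_interval),
                 injection_frame = injection_frame),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("Acquisition:", x$sequence_kind,
      sprintf("| TR %.4g ms", x$TR),
      if (x$sequence_kind == "spgr") sprintf("| flip %g deg", x$flip_angle)
      else "",
      sprintf("| frame interval %.4g s | injection at frame %d",
              x$frame_interval, x$injection_frame), "\n")
  invisible(x)
}

#' Relaxation parameters for concentration calibration
#'
#' @param r1 longitudinal relaxivity of the contrast agent, s^-1 mM^-1.
#' @param T10 pre-contrast longitudinal relaxation time, ms; a scalar or a
#'   per-pixel map (any numeric array).
#' @return An object of class `relaxation_params`.
#' @examples
#' relaxation_params(r1 = 4.5, T10 = 1000)
#' @export
relaxation_params <- function(r1, T10) {
  if (!is.numeric(r1) || length(r1) != 1L || r1 <= 0)
    stop("r1 must be a positive scalar (s^-1 mM^-1)")
  if (!is.numeric(T10) || any(T10 <= 0))
    stop("all T10 values must be positive (ms)")
  structure(list(r1 = as.numeric(r1), T10 = T10),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, ...) {
  cat(sprintf("Relaxation: r1 = %.4g s^-1 mM^-1, T10 = %s ms\n", x$r1,
              if (length(x$T10) == 1L) format(x$T10) else
                sprintf("map [%s]", paste(dim(as.array(x$T10)),
                                          collapse = "x"))))
  invisible(x)
}

#' Dynamic contrast-enhanced MRI series
#'
#' The central input container: a 4D intensity array in X-Y-Z-time order with
#' a uniform time axis and its acquisition parameters.
#'
#' @param data 4D numeric array, dimensions (X, Y, Z, time).
#' @param acq an [acquisition_params()] object. Frame times are derived from
#'   `acq$frame_interval` when `frame_times` is `NULL`.
#' @param frame_times optional explicit frame times in seconds; must be
#'   uniformly spaced (tolerance 1e-6 of the step).
#' @param provenance free-text description of where the data came from.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, acq, frame_times = NULL,
                       provenance = "in-memory") {
  if (length(dim(data)) == 3L)       # single-slice convenience: X-Y-time
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array ordered X-Y-Z-time")
  stopifnot(inherits(acq, "acquisition_params"))
  nt <- dim(data)[4]
  if (is.null(frame_times))
    frame_times <- (seq_len(nt) - 1) * acq$frame_interval
  if (length(frame_times) != nt)
    stop("frame_times length must match the time dimension")
  if (nt > 1L) {
    dt <- diff(frame_times)
    if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
      stop("frame_times must be uniformly spaced")
  }
  structure(list(data = data, frame_times = as.numeric(frame_times),
                 acq = acq, provenance = provenance),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DCE-MRI series: %d x %d x %d pixels, %d frames (%.4g s apart)\n",
              d[1], d[2], d[3], d[4], x$acq$frame_interval))
  cat("  source:", x$provenance, "\n")
  print(x$acq)
  invisible(x)
}

#' @export
dim.dce_series <- function(x) dim(x$data)

#' Region of interest on one Z-slice
#'
#' A binary pixel mask plus the coarse-resolution bin factor. The mask is
#' stored in display order (row = Y, column = X). Binned-grid cells are
#' `bin_factor x bin_factor` non-overlapping blocks anchored at the origin of
#' the mask's bounding box.
#'
#' @param mask 2D logical matrix (rows = Y, cols = X); must select at least
#'   one pixel.
#' @param slice_index 0-based Z-slice index the mask lives on.
#' @param bin_factor integer pixel-binning factor, 1 (intrinsic resolution)
#'   to 10.
#' @param kind how the ROI was defined: `"box"`, `"full"` or `"free"`.
#' @return An object of class `dce_roi`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:6, 2:7] <- TRUE
#' dce_roi(m, bin_factor = 2)
#' @export
dce_roi <- function(mask, slice_index = 0L, bin_factor = 1L,
                    kind = c("box", "full", "free")) {
  kind <- match.arg(kind)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask selects no pixels")
  bin_factor <- as.integer(bin_factor)
  if (bin_factor < 1L || bin_factor > 10L)
    stop("bin_factor must be an integer in 1..10")
  structure(list(mask = mask, slice_index = as.integer(slice_index),
                 bin_factor = bin_factor, kind = kind),
            class = "dce_roi")
}

#' Whole-slice ROI helper
#'
#' @param series a [dce_series()].
#' @param slice_index 0-based Z index.
#' @param bin_factor pixel binning factor.
#' @return A `dce_roi` covering the full slice.
#' @export
full_roi <- function(series, slice_index = 0L, bin_factor = 1L) {
  d <- dim(series$data)
  dce_roi(matrix(TRUE, d[2], d[1]), slice_index, bin_factor, kind = "full")
}

#' Rectangular ROI helper
#'
#' @param series a [dce_series()].
#' @param x0,x1,y0,y1 0-based inclusive pixel bounds of the box.
#' @param slice_index 0-based Z index.
#' @param bin_factor pixel binning factor.
#' @return A `dce_roi` of kind `"box"`.
#' @export
box_roi <- function(series, x0, x1, y0, y1, slice_index = 0L,
                    bin_factor = 1L) {
  d <- dim(series$data)
  stopifnot(x0 >= 0, y0 >= 0, x1 < d[1], y1 < d[2], x0 <= x1, y0 <= y1)
  m <- matrix(FALSE, d[2], d[1])
  m[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
  dce_roi(m, slice_index, bin_factor, kind = "box")
}

#' @export
print.dce_roi <- function(x, ...) {
  cat(sprintf("ROI (%s): %d pixels on slice %d, %dx%d binning\n",
              x$kind, sum(x$mask), x$slice_index, x$bin_factor,
              x$bin_factor))
  invisible(x)
}

# mean signal of the pre-injection frames, per curve (vector) or matrix of
# curves (frames in columns)
baseline_mean <- function(y, injection_frame) {
  if (is.matrix(y)) rowMeans(y[, seq_len(injection_frame), drop = FALSE])
  else mean(y[seq_len(injection_frame)])
}
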