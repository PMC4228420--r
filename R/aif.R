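#' Parametric bi-exponential arterial input function
#'
#' The classic population plasma curve for a fast bolus,
#' `Cp(t) = D * sum_i a_i * exp(-m_i * t)` with two exponential terms.
#' Defaults are the standard Weinmann/Tofts population constants for
#' Gd-DTPA — literature values, not measured by this package — and should be
#' replaced by study-specific values where available.
#'
#' @param D injected dose, mmol/kg.
#' @param a term amplitudes, kg/L (length 2, positive).
#' @param m term decay rates, 1/min (length 2, positive). Terms are stored
#'   sorted by descending rate (canonical order).
#' @return Object of class `biexp_aif`.
#' @examples
#' biexp_aif()                      # population defaults
#' biexp_cp(biexp_aif(), t = 0)     # peak plasma concentration, mM
#' @export
biexp_aif <- function(D = 0.2, a = c(3.99, 4.78), m = c(0.144, 0.0111)) {
  stopifnot(length(a) == 2L, length(m) == 2L)
  if (D < 0) stop("dose D must be non-negative")
  if (any(a <= 0) || any(m <= 0)) stop("amplitudes and rates must be positive")
  ord <- order(m, decreasing = TRUE)
  structure(list(D = as.numeric(D), a = as.numeric(a[ord]),
                 m = as.numeric(m[ord])),
            class = "biexp_aif")
}

#' @export
print.biexp_aif <- function(x, ...) {
  cat(sprintf("Bi-exponential AIF: D = %.4g mmol/kg; a = (%s) kg/L; m = (%s) min^-1\n",
              x$D, paste(format(x$a), collapse = ", "),
              paste(format(x$m), collapse = ", ")))
  invisible(x)
}

#' Evaluate a bi-exponential AIF
#'
#' @param aif a [biexp_aif()].
#' @param t time since injection, seconds (vector ok). Negative times give 0.
#' @return Plasma concentration Cp in mM.
#' @export
biexp_cp <- function(aif, t) {
  stopifnot(inherits(aif, "biexp_aif"))
  tm <- t / 60                               # rates are per minute
  cp <- aif$D * (aif$a[1] * exp(-aif$m[1] * tm) +
                 aif$a[2] * exp(-aif$m[2] * tm))
  cp[t < 0] <- 0
  cp
}

#' Sampled arterial input function
#'
#' An externally measured plasma (or whole-blood) concentration curve on an
#' arbitrary strictly increasing time grid.
#'
#' @param times sample times, seconds, strictly increasing.
#' @param Cp concentrations, mM, non-negative, same length as `times`.
#' @param is_blood if `TRUE` the samples are whole-blood concentrations and
#'   are converted to plasma via [blood_to_plasma()] on construction.
#' @param hematocrit haematocrit fraction in [0, 1); used when
#'   `is_blood = TRUE`.
#' @return Object of class `sampled_aif` (always stores plasma values).
#' @export
sampled_aif <- function(times, Cp, is_blood = FALSE, hematocrit = 0.45) {
  if (length(times) != length(Cp)) stop("times and Cp must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(Cp < 0)) stop("Cp must be non-negative")
  if (is_blood) Cp <- blood_to_plasma(Cp, hematocrit)
  structure(list(times = as.numeric(times), Cp = as.numeric(Cp)),
            class = "sampled_aif")
}

#' @export
print.sampled_aif <- function(x, ...) {
  cat(sprintf("Sampled AIF: %d samples over [%.4g, %.4g] s, peak %.4g mM\n",
              length(x$times), min(x$times), max(x$times), max(x$Cp)))
  invisible(x)
}

#' Whole-blood to plasma concentration
#'
#' `Cp = Cb / (1 - Hct)`: the agent stays in plasma, so plasma concentration
#' exceeds the whole-blood value by the plasma-fraction factor.
#'
#' @param Cb whole-blood concentration, mM.
#' @param hematocrit haematocrit fraction, in [0, 1).
#' @return Plasma concentration, mM.
#' @examples
#' blood_to_plasma(1, 0.45)   # 1.8182 mM
#' @export
blood_to_plasma <- function(Cb, hematocrit) {
  if (hematocrit < 0 || hematocrit >= 1)
    stop("hematocrit must lie in [0, 1)")
  Cb / (1 - hematocrit)
}

#' Resample a sampled AIF onto a frame grid
#'
#' Linear interpolation inside the sampled span; zero before the first
#' sample (pre-injection), last value held after the last sample.
#'
#' @param aif a [sampled_aif()].
#' @param frame_times target times, seconds.
#' @return A new `sampled_aif` on `frame_times`.
#' @export
resample_aif <- function(aif, frame_times) {
  stopifnot(inherits(aif, "sampled_aif"))
  cp <- stats::approx(aif$times, aif$Cp, xout = frame_times,
                      method = "linear", rule = 2)$y
  cp[frame_times < aif$times[1]] <- 0
  if (any(diff(frame_times) <= 0)) stop("frame_times must be increasing")
  structure(list(times = as.numeric(frame_times), Cp = cp),
            class = "sampled_aif")
}

#' Read / write a sampled AIF as two-column text
#'
#' Plain delimited text with `#`-prefixed header lines; columns are time in
#' seconds and plasma concentration in mM.
#'
#' @param path file path.
#' @return `read_aif`: a [sampled_aif()]. `write_aif`: the path, invisibly.
#' @export
read_aif <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("time_s", "Cp_mM"))
  sampled_aif(tab$time_s, tab$Cp_mM)
}

#' @rdname read_aif
#' @param aif a [sampled_aif()].
#' @export
write_aif <- function(aif, path) {
  stopifnot(inherits(aif, "sampled_aif"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sampled arterial input function",
               "# time_s Cp_mM"), con)
  utils::write.table(data.frame(t = sprintf("%.10g", aif$times),
                                c = sprintf("%.10g", aif$Cp)),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# evaluate any supported AIF on a frame grid (seconds since injection)
.cp_on_grid <- function(aif, t) {
  if (inherits(aif, "biexp_aif")) biexp_cp(aif, t)
  else if (inherits(aif, "sampled_aif")) resample_aif(aif, t)$Cp
  else stop("aif must be a biexp_aif or sampled_aif")
}
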