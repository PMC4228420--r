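# Readers and writers: raw 4D binary + sidecar, ROI persistence, parametric
# map export, a minimal DICOM Part-10 subset, YAML analysis configs.
#
# Coordinate convention (fixed): 0-based indices in all file formats; X is
# the fastest-varying axis in raw binary; masks are stored and displayed in
# (row = Y, col = X) order.

#' Write / read a 4D series as raw binary with a JSON sidecar
#'
#' The binary file holds the values in X-Y-Z-time order (X fastest); the
#' sidecar (`<path>.json`) records dimensions, element type, byte order and
#' the acquisition parameters, so the pair round-trips losslessly.
#'
#' @param series a [dce_series()].
#' @param path data-file path; the sidecar is written next to it.
#' @param type element type: `"double"`, `"float"` or `"integer"` (4-byte).
#' @param endian `"little"` or `"big"`.
#' @return `write_raw_4d`: the path, invisibly. `read_raw_4d`: a
#'   [dce_series()].
#' @export
write_raw_4d <- function(series, path, type = c("double", "float",
                                                "integer"),
                         endian = c("little", "big")) {
  stopifnot(inherits(series, "dce_series"))
  type <- match.arg(type); endian <- match.arg(endian)
  size <- switch(type, double = 8L, float = 4L, integer = 4L)
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.vector(series$data)
  if (type == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = size, endian = endian)
  acq <- series$acq
  sidecar <- list(dims = dim(series$data), type = type, endian = endian,
                  order = "x-y-z-t",
                  acq = list(sequence_kind = acq$sequence_kind, TR = acq$TR,
                             flip_angle = acq$flip_angle,
                             frame_interval = acq$frame_interval,
                             injection_frame = acq$injection_frame))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raw_4d
#' @param sidecar optional explicit sidecar path (default `<path>.json`).
#' @export
read_raw_4d <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar config: ", sidecar)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dims <- as.integer(sc$dims)
  size <- switch(sc$type, double = 8L, float = 4L, integer = 4L,
                 stop("unsupported element type: ", sc$type))
  expected <- prod(dims) * size
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("size mismatch: expected %d bytes (%s %s), found %d",
                 expected, paste(dims, collapse = "x"), sc$type, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  what <- if (sc$type == "integer") integer() else numeric()
  v <- readBin(con, what, n = prod(dims), size = size, endian = sc$endian)
  acq <- acquisition_params(sc$acq$sequence_kind, TR = sc$acq$TR,
                            flip_angle = sc$acq$flip_angle,
                            frame_interval = sc$acq$frame_interval,
                            injection_frame = sc$acq$injection_frame)
  dce_series(array(as.numeric(v), dim = dims), acq,
             provenance = paste("raw binary:", path))
}

# run-length encode / decode a logical vector (values alternate starting
# with FALSE)
.rle_encode <- function(x) {
  r <- rle(as.logical(x))
  if (r$values[1]) c(0L, r$lengths) else r$lengths
}
.rle_decode <- function(lengths, n) {
  vals <- rep(c(FALSE, TRUE), length.out = length(lengths))
  out <- rep(vals, lengths)
  if (length(out) != n) stop("corrupt run-length mask")
  out
}

.ROI_FORMAT_VERSION <- 1L

#' Save / load an ROI
#'
#' Versioned JSON with a run-length-encoded mask; mask, slice index, bin
#' factor and kind round-trip losslessly.
#'
#' @param roi a [dce_roi()].
#' @param path file path.
#' @return `save_roi`: the path, invisibly. `load_roi`: a [dce_roi()].
#' @export
save_roi <- function(roi, path) {
  stopifnot(inherits(roi, "dce_roi"))
  obj <- list(format = "dcefit-roi", version = .ROI_FORMAT_VERSION,
              shape = dim(roi$mask), slice_index = roi$slice_index,
              bin_factor = roi$bin_factor, kind = roi$kind,
              mask_rle = .rle_encode(roi$mask))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_roi
#' @export
load_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dcefit-roi"))
    stop("not an ROI file: ", path)
  if (obj$version != .ROI_FORMAT_VERSION)
    stop("unsupported ROI format version ", obj$version,
         " (this build reads version ", .ROI_FORMAT_VERSION, ")")
  mask <- matrix(.rle_decode(as.integer(obj$mask_rle), prod(obj$shape)),
                 obj$shape[1], obj$shape[2])
  dce_roi(mask, obj$slice_index, obj$bin_factor, obj$kind)
}

#' Export / parse a parameter map as text
#'
#' Three layouts: `single_column` (one value per line in row-major cell
#' order, one block per parameter), `multi_column` (x, y cell coordinates
#' then one column per parameter) and `matrix` (one 2D block per parameter).
#' Headers name the parameters and grid shape; missing (non-fitted or
#' non-converged) cells are written as `NaN`. Values use `%.10g`, so an
#' export/parse round trip reproduces the map to ~1e-12 relative.
#'
#' @param map a `parameter_map`.
#' @param path output path.
#' @param layout `"single_column"`, `"multi_column"` or `"matrix"`.
#' @return `export_map`: the path, invisibly. `read_map`: a named list of
#'   numeric matrices (one per parameter).
#' @export
export_map <- function(map, path, layout = c("single_column",
                                             "multi_column", "matrix")) {
  stopifnot(inherits(map, "parameter_map"))
  layout <- match.arg(layout)
  g <- map$grid_dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dcefit parameter map | model %s | layout %s | grid %d %d | parameters %s",
                     map$model, layout, g[1], g[2],
                     paste(names(map$params), collapse = " ")), con)
  fmt <- function(v) ifelse(is.na(v), "NaN", sprintf("%.10g", v))
  if (layout == "single_column") {
    for (pn in names(map$params)) {
      writeLines(sprintf("# parameter %s", pn), con)
      writeLines(fmt(as.vector(t(map$params[[pn]]))), con)   # row-major
    }
  } else if (layout == "multi_column") {
    writeLines(paste(c("# x y", names(map$params)), collapse = " "), con)
    for (r in seq_len(g[1])) for (cc in seq_len(g[2])) {
      vals <- vapply(map$params, function(m) m[r, cc], numeric(1))
      writeLines(paste(c(cc - 1L, r - 1L, fmt(vals)), collapse = " "), con)
    }
  } else {
    for (pn in names(map$params)) {
      writeLines(sprintf("# matrix %s (%d rows x %d cols)", pn, g[1], g[2]),
                 con)
      m <- map$params[[pn]]
      for (r in seq_len(g[1]))
        writeLines(paste(fmt(m[r, ]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname export_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# dcefit parameter map \\| ", "", lines[1]),
                  " \\| ")[[1]]
  if (!startsWith(lines[1], "# dcefit parameter map"))
    stop("not a dcefit map file: ", path)
  layout <- sub("^layout ", "", hdr[2])
  g <- as.integer(strsplit(sub("^grid ", "", hdr[3]), " ")[[1]])
  pars <- strsplit(sub("^parameters ", "", hdr[4]), " ")[[1]]
  body <- lines[-1]
  out <- stats::setNames(vector("list", length(pars)), pars)
  if (layout == "single_column") {
    starts <- grep("^# parameter ", body)
    for (i in seq_along(starts)) {
      pn <- sub("^# parameter ", "", body[starts[i]])
      end <- if (i < length(starts)) starts[i + 1] - 1L else length(body)
      v <- as.numeric(body[(starts[i] + 1L):end])
      out[[pn]] <- matrix(v, g[1], g[2], byrow = TRUE)
    }
  } else if (layout == "multi_column") {
    tab <- utils::read.table(text = body[-1])
    for (i in seq_along(pars)) {
      m <- matrix(NA_real_, g[1], g[2])
      m[cbind(tab[[2]] + 1L, tab[[1]] + 1L)] <- tab[[i + 2L]]
      out[[pars[i]]] <- m
    }
  } else if (layout == "matrix") {
    starts <- grep("^# matrix ", body)
    for (i in seq_along(starts)) {
      pn <- sub(" \\(.*$", "", sub("^# matrix ", "", body[starts[i]]))
      rows <- body[(starts[i] + 1L):(starts[i] + g[1])]
      out[[pn]] <- do.call(rbind, lapply(strsplit(rows, " +"), as.numeric))
    }
  } else stop("unknown layout: ", layout)
  out
}

#' Read an analysis configuration file
#'
#' YAML configuration mirroring the analysis inputs: blocks `mr_signal`
#' (sequence, TR, flip_angle, frame_interval), `ca` (injection_frame, r1,
#' T10), `aif` (D, a, m, or `file` pointing to a sampled two-column AIF),
#' `rr` (Ktrans_r, ve_r, ct_file) and `fit` (init, lower, upper, bin_factor,
#' maxiter, ftol, ptol).
#'
#' @param path YAML file.
#' @return Named list with parsed `acq` ([acquisition_params()]), `relax`
#'   ([relaxation_params()]), `aif`, `rr` and `fit` entries (those present).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  if (!is.null(cfg$mr_signal) && !is.null(cfg$ca)) {
    ms <- cfg$mr_signal
    out$acq <- acquisition_params(
      ms$sequence %||% "spgr", TR = ms$TR,
      flip_angle = ms$flip_angle %||% 90,
      frame_interval = ms$frame_interval,
      injection_frame = cfg$ca$injection_frame)
  }
  if (!is.null(cfg$ca) && !is.null(cfg$ca$r1))
    out$relax <- relaxation_params(cfg$ca$r1, cfg$ca$T10 %||% 1000)
  if (!is.null(cfg$aif)) {
    out$aif <- if (!is.null(cfg$aif$file)) read_aif(cfg$aif$file)
    else biexp_aif(D = cfg$aif$D %||% 0.2,
                   a = unlist(cfg$aif$a %||% c(3.99, 4.78)),
                   m = unlist(cfg$aif$m %||% c(0.144, 0.0111)))
  }
  if (!is.null(cfg$rr)) out$rr <- cfg$rr
  if (!is.null(cfg$fit)) out$fit <- cfg$fit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
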