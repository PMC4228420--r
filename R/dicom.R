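# Minimal DICOM Part-10 support: explicit-VR little-endian, one single-frame
# 16-bit image per file. Covers what a dynamic series needs — geometry,
# temporal ordering, rescale slope/intercept, TR/flip angle — and is the
# writer/reader pair used for phantom export. Sequences (SQ) with undefined
# length and implicit-VR syntax are out of scope and rejected explicitly.

.UID_ROOT <- "1.2.826.0.1.3680043.9.7434"     # generated-UID prefix
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_state <- new.env(parent = emptyenv())
.dcm_state$counter <- 0L

.dcm_write_elem <- function(con, group, elem, vr, value) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("UI", "DS", "IS", "LO", "SH", "CS")) {
    raw <- charToRaw(as.character(value))
    if (length(raw) %% 2 == 1)                 # pad to even length
      raw <- c(raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
    writeBin(as.integer(length(raw)), con, size = 2, endian = "little")
    writeBin(raw, con)
  } else if (vr == "US") {
    writeBin(2L * length(value), con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  } else if (vr == "UL") {
    writeBin(4L * length(value), con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")  # reserved
    writeBin(as.integer(length(value)), con, size = 4, endian = "little")
    writeBin(value, con)
  } else stop("unsupported VR in writer: ", vr)
}

#' Write a series as a DICOM directory
#'
#' One explicit-VR little-endian single-frame file per (slice, frame), 16-bit
#' unsigned pixels with a series-wide rescale slope/intercept chosen to span
#' the data range (integer data in [0, 65535] is stored losslessly with
#' slope 1). Temporal position, instance number, slice location, TR, flip
#' angle and frame time are recorded; the series description carries the
#' sequence kind and injection frame so a round trip restores the
#' acquisition parameters.
#'
#' @param series a [dce_series()].
#' @param directory output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dicom_series <- function(series, directory) {
  stopifnot(inherits(series, "dce_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$data)
  acq <- series$acq
  rng <- range(series$data)
  lossless <- all(series$data == round(series$data)) &&
    rng[1] >= 0 && rng[2] <= 65535
  if (lossless) {
    slope <- 1; intercept <- 0
  } else {
    intercept <- rng[1]
    slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 65535 else 1
  }
  .dcm_state$counter <- .dcm_state$counter + 1L
  series_uid <- paste0(.UID_ROOT, ".", format(as.integer(Sys.time())), ".",
                       Sys.getpid(), ".", .dcm_state$counter)
  desc <- sprintf("dcefit sequence=%s injection_frame=%d",
                  acq$sequence_kind, acq$injection_frame)
  n <- 0L
  for (tt in seq_len(d[4])) for (z in seq_len(d[3])) {
    n <- n + 1L
    px <- round((series$data[, , z, tt] - intercept) / slope)
    px <- pmin(pmax(px, 0), 65535)
    px[px > 32767] <- px[px > 32767] - 65536     # two's complement for writeBin
    path <- file.path(directory, sprintf("frame_%05d.dcm", n))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, nchars = 4, eos = NULL)
    .dcm_write_elem(con, 0x0002, 0x0001, "OB", as.raw(c(0, 1)))
    .dcm_write_elem(con, 0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    .dcm_write_elem(con, 0x0008, 0x0016, "UI",
                    "1.2.840.10008.5.1.4.1.1.7")  # secondary capture
    .dcm_write_elem(con, 0x0008, 0x0018, "UI",
                    paste0(series_uid, ".", n))
    .dcm_write_elem(con, 0x0008, 0x103E, "LO", desc)
    .dcm_write_elem(con, 0x0018, 0x0080, "DS", format(acq$TR))
    .dcm_write_elem(con, 0x0018, 0x1063, "DS",
                    format(acq$frame_interval * 1000))  # frame time, ms
    .dcm_write_elem(con, 0x0018, 0x1314, "DS", format(acq$flip_angle))
    .dcm_write_elem(con, 0x0020, 0x000E, "UI", series_uid)
    .dcm_write_elem(con, 0x0020, 0x0013, "IS", format(n))
    .dcm_write_elem(con, 0x0020, 0x0100, "IS", format(tt))
    .dcm_write_elem(con, 0x0020, 0x1041, "DS", format(z - 1))
    .dcm_write_elem(con, 0x0028, 0x0002, "US", 1L)
    .dcm_write_elem(con, 0x0028, 0x0010, "US", d[2])   # rows = Y
    .dcm_write_elem(con, 0x0028, 0x0011, "US", d[1])   # cols = X
    .dcm_write_elem(con, 0x0028, 0x0100, "US", 16L)
    .dcm_write_elem(con, 0x0028, 0x0101, "US", 16L)
    .dcm_write_elem(con, 0x0028, 0x0102, "US", 15L)
    .dcm_write_elem(con, 0x0028, 0x0103, "US", 0L)
    .dcm_write_elem(con, 0x0028, 0x1052, "DS", sprintf("%.10g", intercept))
    .dcm_write_elem(con, 0x0028, 0x1053, "DS", sprintf("%.10g", slope))
    # pixel order: row by row (Y), X fastest — column-major (x,y) vector
    writeBin(as.integer(c(0x7FE0, 0x0010)), con, size = 2,
             endian = "little")
    writeChar("OW", con, nchars = 2, eos = NULL)
    writeBin(0L, con, size = 2, endian = "little")
    writeBin(as.integer(2 * length(px)), con, size = 4, endian = "little")
    writeBin(as.integer(as.vector(px)), con, size = 2, endian = "little")
    close(con)
  }
  invisible(directory)
}

# parse one file into a named list of elements keyed "GGGG,EEEE"
.dcm_parse_file <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, raw(), 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  elems <- list()
  repeat {
    hdr <- readBin(con, integer(), 2, size = 2, signed = FALSE,
                   endian = "little")
    if (length(hdr) < 2) break
    vr <- readChar(con, 2, useBytes = TRUE)
    if (!grepl("^[A-Z][A-Z]$", vr))
      stop("implicit-VR or corrupt element in ", path,
           " (only explicit VR little endian is supported)")
    if (vr %in% .LONG_VRS) {
      readBin(con, raw(), 2)
      len <- readBin(con, integer(), 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, integer(), 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    if (len == -1)
      stop("undefined-length element (sequences unsupported) in ", path)
    key <- sprintf("%04X,%04X", hdr[1], hdr[2])
    if (key == "7FE0,0010") {
      elems[[key]] <- readBin(con, integer(), len / 2, size = 2,
                              signed = FALSE, endian = "little")
    } else {
      val <- readBin(con, raw(), len)
      elems[[key]] <- list(vr = vr, raw = val)
    }
    if (seek(con) >= sz) break
  }
  elems
}

.dcm_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}
.dcm_num <- function(elems, key) {
  s <- .dcm_str(elems, key)
  if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, integer(), length(e$raw) / 2, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a DICOM series directory
#'
#' Reads a directory of explicit-VR little-endian single-frame files forming
#' one dynamic series. Frames are sorted by temporal position identifier
#' then slice location; when temporal tags are absent the filename order is
#' used with a warning. Pixel values are scaled by rescale slope/intercept;
#' TR, flip angle, frame time and — when written by [write_dicom_series()] —
#' the sequence kind and injection frame are harvested into the acquisition
#' parameters.
#'
#' @param directory directory of `.dcm` files.
#' @param injection_frame override for the 0-based first post-injection
#'   frame when the series description does not carry one.
#' @return A [dce_series()].
#' @export
read_dicom_series <- function(directory, injection_frame = NULL) {
  files <- sort(list.files(directory, pattern = "\\.dcm$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no DICOM files in ", directory)
  parsed <- lapply(files, .dcm_parse_file)
  uids <- unique(vapply(parsed, function(e)
    .dcm_str(e, "0020,000E") %||% "<missing>", character(1)))
  if (length(uids) > 1)
    stop("directory mixes multiple series: ",
         paste(uids, collapse = ", "))
  rows <- .dcm_us(parsed[[1]], "0028,0010")
  cols <- .dcm_us(parsed[[1]], "0028,0011")
  temporal <- vapply(parsed, function(e) {
    v <- .dcm_num(e, "0020,0100")
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  slice <- vapply(parsed, function(e) {
    v <- .dcm_num(e, "0020,1041")
    if (is.null(v)) 0 else v
  }, numeric(1))
  if (anyNA(temporal)) {
    warning("temporal ordering tags missing; falling back to filename order")
    temporal <- seq_along(parsed)
  }
  zs <- sort(unique(slice))
  ts <- sort(unique(temporal))
  data <- array(NA_real_, dim = c(cols, rows, length(zs), length(ts)))
  for (i in seq_along(parsed)) {
    e <- parsed[[i]]
    slope <- (.dcm_num(e, "0028,1053") %||% 1)
    intercept <- (.dcm_num(e, "0028,1052") %||% 0)
    px <- e[["7FE0,0010"]] * slope + intercept
    data[, , match(slice[i], zs), match(temporal[i], ts)] <- px
  }
  if (anyNA(data)) stop("incomplete series: missing slice/frame combinations")
  e1 <- parsed[[1]]
  desc <- .dcm_str(e1, "0008,103E") %||% ""
  seq_kind <- if (grepl("sequence=spin_echo", desc)) "spin_echo" else "spgr"
  if (is.null(injection_frame)) {
    m <- regmatches(desc, regexpr("injection_frame=[0-9]+", desc))
    injection_frame <- if (length(m)) as.integer(sub(".*=", "", m)) else 1L
  }
  frame_time <- (.dcm_num(e1, "0018,1063") %||% 1000) / 1000
  acq <- acquisition_params(seq_kind,
                            TR = .dcm_num(e1, "0018,0080") %||% 1,
                            flip_angle = .dcm_num(e1, "0018,1314") %||% 90,
                            frame_interval = frame_time,
                            injection_frame = injection_frame)
  dce_series(data, acq, provenance = paste("DICOM series:", directory))
}
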