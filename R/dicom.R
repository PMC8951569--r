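## Minimal DICOM codec for uncompressed grayscale cine loops.
##
## No DICOM library is available in the deployment environment, so the package
## carries its own reader/writer for the small corner of the standard that
## cine-angiography export actually uses: Part 10 files, implicit or explicit
## VR little endian, single-sample MONOCHROME1/2 pixel data, 8 or 16 bits,
## multi-frame objects or single-frame series. Compressed transfer syntaxes
## and sequences with undefined length are rejected with a format error.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE  <- "1.2.840.10008.5.1.4.1.1.7"

## VRs whose explicit encoding uses a 4-byte length after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

## ---- writer ---------------------------------------------------------------

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), u32le(length(value_raw)), value_raw)
  } else {
    c(head, u16le(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) dcm_element(group, element, vr, charToRaw(s))
dcm_us  <- function(group, element, x)    dcm_element(group, element, "US", u16le(x))

#' Write a grayscale cine loop as a multi-frame DICOM file
#'
#' Stored pixel values are 16-bit unsigned, explicit VR little endian,
#' MONOCHROME2 (larger = brighter). A [cine_sequence()] has its `[0, 1]`
#' intensities scaled to the stored range `0..65535`; alternatively a list of
#' integer-valued matrices is written verbatim (fixture use).
#'
#' @param x a [cine_sequence()] or list of >= 1 numeric matrices with
#'   non-negative integer values < 65536.
#' @param path output file path.
#' @param frame_rate frames/second stored as FrameTime; taken from the
#'   sequence when `x` is a [cine_sequence()].
#' @param photometric `"MONOCHROME2"` (default) or `"MONOCHROME1"` (stored
#'   inverted on disk, for reader testing).
#' @return `path`, invisibly.
#' @export
write_cine_dicom <- function(x, path, frame_rate = NULL,
                             photometric = c("MONOCHROME2", "MONOCHROME1")) {
  photometric <- match.arg(photometric)
  if (inherits(x, "cine_sequence")) {
    if (is.null(frame_rate)) frame_rate <- x$frame_rate
    frames <- lapply(x$frames, function(f) round(f * 65535))
  } else {
    frames <- x
  }
  if (length(frames) < 1L) ct_input_error("nothing to write")
  d <- dim(frames[[1]])
  stored <- unlist(frames, use.names = FALSE)
  if (any(stored < 0) || any(stored > 65535) || any(stored != round(stored)))
    ct_validation_error("stored pixel values must be integers in [0, 65535]")
  if (photometric == "MONOCHROME1") stored <- 65535 - stored

  ## pixel bytes: frames sequential, each row-major
  px <- writeBin(as.integer(t_block(stored, d, length(frames))), raw(),
                 size = 2, endian = "little")

  sop_uid <- sprintf("1.2.826.0.1.3680043.9590.%d.%d.%d",
                     length(frames), d[1], d[2])
  meta <- c(
    dcm_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dcm_str(2L, 2L, "UI", UID_SC_STORAGE),
    dcm_str(2L, 3L, "UI", sop_uid),
    dcm_str(2L, 16L, "UI", UID_EXPLICIT_LE)
  )
  body <- c(
    dcm_str(8L, 0x16L, "UI", UID_SC_STORAGE),
    dcm_str(8L, 0x18L, "UI", sop_uid),
    dcm_str(8L, 0x60L, "CS", "XA"),
    if (!is.null(frame_rate))
      dcm_str(0x18L, 0x1063L, "DS", sprintf("%.6g", 1000 / frame_rate)),
    dcm_str(0x20L, 0x13L, "IS", "1"),
    dcm_us(0x28L, 0x02L, 1L),
    dcm_str(0x28L, 0x04L, "CS", photometric),
    dcm_str(0x28L, 0x08L, "IS", as.character(length(frames))),
    dcm_us(0x28L, 0x10L, d[1]),
    dcm_us(0x28L, 0x11L, d[2]),
    dcm_us(0x28L, 0x100L, 16L),
    dcm_us(0x28L, 0x101L, 16L),
    dcm_us(0x28L, 0x102L, 15L),
    dcm_us(0x28L, 0x103L, 0L),
    dcm_element(0x7FE0L, 0x10L, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(2L, 0L, "UL", u32le(length(meta))), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

## column-major R matrices -> row-major frame-sequential vector
t_block <- function(stored, d, n_frames) {
  arr <- array(stored, dim = c(d[1], d[2], n_frames))
  as.vector(aperm(arr, c(2, 1, 3)))
}

## ---- reader ---------------------------------------------------------------

#' Parse one DICOM file into a tag table plus pixel payload.
#' @noRd
parse_dicom <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 140) ct_format_error(sprintf("not a readable DICOM file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", sz)
  if (!identical(buf[129:132], charToRaw("DICM")))
    ct_format_error(sprintf("missing DICM magic: %s", path))

  rd_u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  rd_u32 <- function(i) rd_u16(i) + 65536 * rd_u16(i + 2L)
  rd_str <- function(i, len) {
    if (len == 0) return("")
    bytes <- buf[i:(i + len - 1L)]
    bytes <- bytes[bytes != as.raw(0L)]     # strip UI nul padding
    trimws(rawToChar(bytes))
  }

  elems <- list()
  pos <- 133L
  explicit <- TRUE      # file meta group is always explicit VR LE
  ts <- UID_EXPLICIT_LE
  meta_end <- Inf
  while (pos + 7L <= sz + 1L) {
    group <- rd_u16(pos); element <- rd_u16(pos + 2L)
    if (pos >= meta_end && is.finite(meta_end)) {
      explicit <- (ts == UID_EXPLICIT_LE)
      if (!(ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)))
        ct_format_error(sprintf("unsupported transfer syntax %s (compressed data?)", ts))
      meta_end <- Inf
    }
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- rd_u32(pos + 8L); hdr <- 12L
      } else {
        len <- rd_u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- "UN"; len <- rd_u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      ct_format_error("undefined-length element: compressed or sequence data is unsupported")
    vstart <- pos + hdr
    key <- sprintf("%04x%04x", group, element)
    elems[[key]] <- list(group = group, element = element, vr = vr,
                         start = vstart, len = len)
    if (group == 2L && element == 0L)
      meta_end <- vstart + 4L + rd_u32(vstart)
    if (group == 2L && element == 16L)
      ts <- rd_str(vstart, len)
    pos <- vstart + len
  }

  get_str <- function(key, default = NULL) {
    e <- elems[[key]]
    if (is.null(e)) return(default)
    rd_str(e$start, e$len)
  }
  get_u16 <- function(key, default = NULL) {
    e <- elems[[key]]
    if (is.null(e)) return(default)
    rd_u16(e$start)
  }

  rows <- get_u16("00280010"); cols <- get_u16("00280011")
  if (is.null(rows) || is.null(cols))
    ct_format_error(sprintf("no image dimensions in %s", path))
  samples <- get_u16("00280002", 1L)
  photometric <- get_str("00280004", "MONOCHROME2")
  if (samples != 1L || !(photometric %in% c("MONOCHROME1", "MONOCHROME2")))
    ct_format_error(sprintf(
      "unsupported format (%s, %d samples/pixel): only grayscale is supported",
      photometric, samples))
  bits <- get_u16("00280100", 16L)
  if (!(bits %in% c(8L, 16L)))
    ct_format_error(sprintf("unsupported bit depth %d", bits))
  signed <- identical(get_u16("00280103", 0L), 1L)
  n_frames <- suppressWarnings(as.integer(get_str("00280008", "1")))
  if (is.na(n_frames) || n_frames < 1L) n_frames <- 1L

  pe <- elems[["7fe00010"]]
  if (is.null(pe)) ct_format_error(sprintf("no pixel data in %s", path))
  bytes_per <- bits / 8L
  need <- rows * cols * n_frames * bytes_per
  if (pe$len < need)
    ct_format_error(sprintf("pixel data truncated in %s", path))
  vals <- readBin(buf[pe$start:(pe$start + need - 1L)], "integer",
                  n = rows * cols * n_frames, size = bytes_per,
                  signed = signed, endian = "little")
  frames <- lapply(seq_len(n_frames), function(k) {
    off <- (k - 1L) * rows * cols
    matrix(vals[(off + 1L):(off + rows * cols)], nrow = rows, ncol = cols,
           byrow = TRUE)
  })
  if (photometric == "MONOCHROME1")   # invert so radio-opaque is dark
    frames <- lapply(frames, function(f) -f)

  ft <- suppressWarnings(as.numeric(get_str("00181063", "")))
  cine_rate <- suppressWarnings(as.numeric(get_str("00180040", "")))
  frame_rate <- if (!is.na(ft) && length(ft) && ft > 0) 1000 / ft
  else if (!is.na(cine_rate) && length(cine_rate) && cine_rate > 0) cine_rate
  else NULL

  spacing <- get_str("00280030", default = get_str("00181164"))
  pixel_spacing <- if (!is.null(spacing) && nzchar(spacing)) {
    ps <- suppressWarnings(as.numeric(strsplit(spacing, "\\\\")[[1]]))
    if (length(ps) == 2L && all(is.finite(ps))) ps else NULL
  } else NULL

  instance <- suppressWarnings(as.integer(get_str("00200013", "0")))
  list(frames = frames, frame_rate = frame_rate, pixel_spacing = pixel_spacing,
       instance_number = if (is.na(instance)) 0L else instance)
}

#' Read a cine-angiography acquisition from DICOM
#'
#' Accepts either a multi-frame grayscale DICOM file or a directory of
#' single-frame DICOM files (ordered by InstanceNumber, ties broken by
#' filename). Stored intensities are min-max normalized to `[0, 1]`
#' *globally over the whole sequence* so inter-frame brightness dynamics (the
#' contrast bolus) are preserved. MONOCHROME1 images are inverted before
#' normalization so that radio-opaque structures are always dark.
#'
#' @param path DICOM file or directory of `.dcm` files.
#' @return a [cine_sequence()].
#' @export
read_cine <- function(path) {
  if (length(path) != 1L || !file.exists(path))
    ct_format_error(sprintf("input path does not exist: %s", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(dcm|DCM|dicom)$", full.names = TRUE)
    if (length(files) == 0L) files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L)
      ct_format_error(sprintf("no DICOM files in directory %s", path))
    parsed <- lapply(sort(files), parse_dicom)
    ord <- order(vapply(parsed, function(p) p$instance_number, integer(1)))
    parsed <- parsed[ord]
    frames <- unlist(lapply(parsed, function(p) p$frames), recursive = FALSE)
    meta <- parsed[[1]]
  } else {
    meta <- parse_dicom(path)
    frames <- meta$frames
  }
  if (length(frames) < 2L)
    ct_input_error("cine sequence must contain at least 2 frames")
  frames <- lapply(frames, function(f) f * 1.0)
  cine_sequence(normalize_frames(frames),
                frame_rate = meta$frame_rate,
                pixel_spacing = meta$pixel_spacing,
                source_id = normalizePath(path))
}
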