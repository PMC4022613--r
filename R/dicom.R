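# Minimal DICOM support: uncompressed little-endian grayscale Part-10 files
# (implicit VR "1.2.840.10008.1.2" and explicit VR "1.2.840.10008.1.2.1"),
# single- or multi-frame, MONOCHROME1/2, 8- or 16-bit unsigned. This covers
# the B-mode export case; compressed transfer syntaxes and big-endian files
# are rejected. No DICOM library exists in the deployment environment, so
# the subset is parsed directly.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SC_STORAGE  <- "1.2.840.10008.5.1.4.1.1.7"

u16le <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
u32le <- function(b) as.integer(b[1]) + 256L * as.integer(b[2]) +
  65536L * as.integer(b[3]) + 16777216 * as.integer(b[4])

# VRs carrying a 2-byte reserved field + 4-byte length in explicit encoding
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read one frame from an uncompressed grayscale DICOM file
#'
#' @param path path to a Part-10 DICOM file (little-endian, uncompressed,
#'   single-sample grayscale).
#' @param frame_index 0-based frame index (multi-frame sources).
#' @param rescale allow >8-bit pixel data, min-max rescaled to 8 bits.
#' @param source_id provenance label stored on the frame.
#' @return An [echo_frame()].
#' @export
read_dicom_frame <- function(path, frame_index = 0L, rescale = FALSE,
                             source_id = basename(path)) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) >= 132L &&
      identical(rawToChar(bytes[129:132]), "DICM")) pos <- 133L
  # file meta group (0002,xxxx) is always explicit little endian
  ts <- UID_EXPLICIT_LE
  meta <- parse_dicom_elements(bytes, pos, explicit = TRUE,
                               stop_after_group = 0x0002)
  if (!is.null(meta$elements[["0002,0010"]]))
    ts <- dicom_str(meta$elements[["0002,0010"]])
  explicit <- switch(ts,
    "1.2.840.10008.1.2"   = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax ", ts,
         " (only uncompressed little endian)"))
  ds <- parse_dicom_elements(bytes, meta$pos, explicit = explicit)
  el <- ds$elements
  need <- function(tag, what) {
    if (is.null(el[[tag]])) stop("DICOM missing required element ", what)
    el[[tag]]
  }
  rows <- u16le(need("0028,0010", "Rows"))
  cols <- u16le(need("0028,0011", "Columns"))
  bits <- u16le(need("0028,0100", "BitsAllocated"))
  photo <- if (!is.null(el[["0028,0004"]])) dicom_str(el[["0028,0004"]])
           else "MONOCHROME2"
  spp <- if (!is.null(el[["0028,0002"]])) u16le(el[["0028,0002"]]) else 1L
  if (spp != 1L) stop("unsupported DICOM: SamplesPerPixel must be 1")
  nframes <- if (!is.null(el[["0028,0008"]]))
    as.integer(dicom_str(el[["0028,0008"]])) else 1L
  if (is.na(nframes) || nframes < 1L) nframes <- 1L
  pd <- need("7FE0,0010", "PixelData")
  frame_index <- as.integer(frame_index)
  if (frame_index < 0L || frame_index >= nframes)
    stop("frame index out of range: ", frame_index, " of ", nframes)
  npx <- rows * cols
  if (bits == 8L) {
    off <- frame_index * npx
    if (length(pd) < off + npx) stop("unreadable file: truncated PixelData")
    vals <- as.integer(pd[(off + 1L):(off + npx)])
  } else if (bits == 16L) {
    off <- frame_index * npx * 2L
    if (length(pd) < off + 2L * npx)
      stop("unreadable file: truncated PixelData")
    b <- as.integer(pd[(off + 1L):(off + 2L * npx)])
    vals <- b[seq(1L, 2L * npx, 2L)] + 256L * b[seq(2L, 2L * npx, 2L)]
  } else stop("unsupported DICOM BitsAllocated ", bits)
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (photo == "MONOCHROME1") m <- max(m) - m   # inverted grayscale
  if (bits > 8L || max(m) > 255L) {
    if (!rescale)
      stop("bit depth ", bits, " exceeds 8; pass rescale = TRUE to rescale")
    warning("rescaling ", bits, "-bit DICOM to 8 bits (min-max)")
    m <- minmax_rescale_255(m)
  }
  echo_frame(m, frame_index = frame_index, source_id = source_id)
}

# Walk the element stream from byte offset `pos`; returns raw values keyed
# "GGGG,EEEE" (uppercase hex) plus the final offset. Sequences are skipped.
parse_dicom_elements <- function(bytes, pos, explicit,
                                 stop_after_group = NA) {
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- u16le(bytes[pos:(pos + 1L)])
    elem  <- u16le(bytes[(pos + 2L):(pos + 3L)])
    if (!is.na(stop_after_group) && group > stop_after_group) break
    force_explicit <- group == 0x0002   # file meta is always explicit
    if (explicit || force_explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- u32le(bytes[(pos + 8L):(pos + 11L)]); pos <- pos + 12L
      } else {
        len <- u16le(bytes[(pos + 6L):(pos + 7L)]); pos <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- u32le(bytes[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
    }
    tag <- sprintf("%04X,%04X", group, elem)
    if (!is.na(len) && len == 4294967295) {        # undefined length: skip items
      pos <- skip_undefined_length(bytes, pos)
      next
    }
    if (pos + len - 1L > n) stop("unreadable file: truncated DICOM element")
    if (is.na(vr) || vr != "SQ")
      out[[tag]] <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    if (tag == "7FE0,0010") break
  }
  list(elements = out, pos = pos)
}

skip_undefined_length <- function(bytes, pos) {
  n <- length(bytes)
  depth <- 1L
  while (pos + 7L <= n && depth > 0L) {
    group <- u16le(bytes[pos:(pos + 1L)])
    elem  <- u16le(bytes[(pos + 2L):(pos + 3L)])
    len <- u32le(bytes[(pos + 4L):(pos + 7L)])
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) depth <- depth - 1L
    else if (group == 0xFFFE && elem == 0xE000 && len == 4294967295) next
    else if (!is.na(len) && len == 4294967295) depth <- depth + 1L
    else pos <- pos + max(len, 0L)
  }
  pos
}

dicom_str <- function(raw_val) {
  s <- rawToChar(raw_val[raw_val != as.raw(0)])
  trimws(s)
}

# ---- writer (secondary-capture style, explicit VR little endian) ---------

raw_u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
raw_u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                  (x %/% 65536) %% 256,
                                  (x %/% 16777216) %% 256))

dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) value <- charToRaw(value)
  if (length(value) %% 2L == 1L)
    value <- c(value, as.raw(if (vr %in% c("UI", "OB")) 0L else 32L))
  hdr <- c(raw_u16le(group), raw_u16le(elem), charToRaw(vr))
  if (vr %in% .long_vrs)
    c(hdr, as.raw(c(0, 0)), raw_u32le(length(value)), value)
  else
    c(hdr, raw_u16le(length(value)), value)
}

#' Write frames as an uncompressed grayscale DICOM file
#'
#' Writes one or more 8-bit frames as an explicit-VR little-endian
#' secondary-capture DICOM file (multi-frame when several frames are given).
#' Intended for phantom export and round-trip testing.
#'
#' @param frames an [echo_frame()] or list of frames with equal dimensions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(frames, path) {
  if (is_echo_frame(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is_echo_frame, TRUE)))
  rows <- frames[[1]]$height; cols <- frames[[1]]$width
  if (!all(vapply(frames, function(f) f$height == rows && f$width == cols,
                  TRUE)))
    stop("all frames must share dimensions")
  px <- unlist(lapply(frames, function(f) as.integer(t(f$pixels))))
  # content-derived instance UID: deterministic, does not touch the RNG
  sop_uid <- sprintf("1.2.826.0.1.3680043.9.9999.%d.%d.%d.%d",
                     rows, cols, length(frames),
                     sum(as.numeric(px)) %% 1000000)
  meta_body <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_element(0x0002, 0x0002, "UI", UID_SC_STORAGE),
    dicom_element(0x0002, 0x0003, "UI", sop_uid),
    dicom_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dicom_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.9999.1"))
  meta <- c(dicom_element(0x0002, 0x0000, "UL", raw_u32le(length(meta_body))),
            meta_body)
  ds <- c(
    dicom_element(0x0008, 0x0016, "UI", UID_SC_STORAGE),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0028, 0x0002, "US", raw_u16le(1L)),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    if (length(frames) > 1L)
      dicom_element(0x0028, 0x0008, "IS", as.character(length(frames))),
    dicom_element(0x0028, 0x0010, "US", raw_u16le(rows)),
    dicom_element(0x0028, 0x0011, "US", raw_u16le(cols)),
    dicom_element(0x0028, 0x0100, "US", raw_u16le(8L)),
    dicom_element(0x0028, 0x0101, "US", raw_u16le(8L)),
    dicom_element(0x0028, 0x0102, "US", raw_u16le(7L)),
    dicom_element(0x0028, 0x0103, "US", raw_u16le(0L)),
    dicom_element(0x7FE0, 0x0010, "OB", as.raw(px)))
  writeBin(c(as.raw(rep(0L, 128L)), charToRaw("DICM"), meta, ds), path)
  invisible(path)
}
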