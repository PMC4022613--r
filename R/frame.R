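#' EchoFrame: an 8-bit grayscale B-mode frame
#'
#' Constructs an `echo_frame`, the container used throughout the package for
#' a single B-mode echocardiographic image. Pixels are stored as an integer
#' matrix in row-major display convention (`pixels[row, col]`), row 1 at the
#' top of the image. Coordinates elsewhere in the package are 0-based
#' `(row, col)` with pixel centers at integer coordinates.
#'
#' @param pixels integer matrix of intensities in `[0, 255]`.
#' @param frame_index 0-based index of the frame within its source (relevant
#'   for multi-frame DICOM); defaults to 0.
#' @param source_id free-text provenance label.
#' @return An object of class `echo_frame` with fields `pixels`, `bit_depth`
#'   (always 8), `height`, `width`, `frame_index`, `source_id`.
#' @examples
#' f <- echo_frame(matrix(128L, 32, 32))
#' f$height
#' @export
echo_frame <- function(pixels, frame_index = 0L, source_id = "memory") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("pixels contain NA")
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("intensities must lie in [0, 255] (bit_depth 8)")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("frame must be at least 16x16 pixels")
  structure(
    list(pixels = pixels, bit_depth = 8L,
         height = nrow(pixels), width = ncol(pixels),
         frame_index = as.integer(frame_index),
         source_id = as.character(source_id)),
    class = "echo_frame")
}

#' @export
print.echo_frame <- function(x, ...) {
  cat(sprintf("<echo_frame %dx%d 8-bit, frame %d, source '%s'>\n",
              x$height, x$width, x$frame_index, x$source_id))
  cat(sprintf("  intensity range [%d, %d], mean %.1f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

is_echo_frame <- function(x) inherits(x, "echo_frame")

# ITU-R BT.601 luma weights, the convention used for grayscale conversion of
# color sources.
.luma <- c(0.299, 0.587, 0.114)

# Collapse an array returned by png/jpeg readers (values in [0,1], optionally
# with 3 or 4 channels) to a single grayscale channel in [0,1].
collapse_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1L])
  if (nc == 2L) return(arr[, , 1L])            # gray + alpha
  .luma[1] * arr[, , 1L] + .luma[2] * arr[, , 2L] + .luma[3] * arr[, , 3L]
}

# Min-max rescale arbitrary numeric matrix to integers 0..255.
minmax_rescale_255 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(m), ncol(m)))
  matrix(as.integer(round((m - rng[1]) / (rng[2] - rng[1]) * 255)),
         nrow(m), ncol(m))
}

png_bit_depth <- function(path) {
  # IHDR is always the first chunk: 8-byte signature, 4-byte length, "IHDR",
  # width (4), height (4), bit depth (1).
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("unreadable file: truncated PNG")
  as.integer(hdr[25L])
}

#' Read a single 8-bit grayscale frame
#'
#' Reads one frame from a PNG, JPEG, PGM (P2/P5) or uncompressed grayscale
#' DICOM source and returns an [echo_frame()]. Color sources are converted
#' to grayscale with BT.601 luma weights. Sources with more than 8 bits per
#' sample are rejected unless `rescale = TRUE`, in which case they are
#' min-max rescaled to `[0, 255]` with a warning.
#'
#' @param path path to the image file; format is detected from content
#'   (magic bytes), falling back to the file extension.
#' @param frame_index 0-based frame index for multi-frame DICOM sources;
#'   must be 0 for single-frame formats.
#' @param rescale if `TRUE`, sources deeper than 8 bits are min-max rescaled
#'   to 8 bits instead of rejected.
#' @return An [echo_frame()].
#' @seealso [write_frame_png()], [read_roi_file()]
#' @export
read_frame <- function(path, frame_index = 0L, rescale = FALSE) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  frame_index <- as.integer(frame_index)
  fmt <- detect_image_format(path)
  px <- switch(fmt,
    png  = read_png_pixels(path, rescale),
    jpeg = read_jpeg_pixels(path),
    pgm  = read_pgm_pixels(path, rescale),
    dicom = return(read_dicom_frame(path, frame_index, rescale,
                                    source_id = basename(path))),
    stop("unsupported image format for ", path,
         " (expected PNG, JPEG, PGM, or DICOM)"))
  if (frame_index != 0L)
    stop("frame index out of range: ", fmt, " sources hold a single frame")
  echo_frame(px, frame_index = 0L, source_id = basename(path))
}

detect_image_format <- function(path) {
  magic <- readBin(path, "raw", n = 132L)
  if (length(magic) >= 8L &&
      identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4E, 0x47,
                                     0x0D, 0x0A, 0x1A, 0x0A)))) return("png")
  if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xFF, 0xD8))))
    return("jpeg")
  if (length(magic) >= 2L && magic[1] == as.raw(0x50) &&
      magic[2] %in% as.raw(c(0x32, 0x35))) return("pgm")
  if (length(magic) >= 132L &&
      identical(rawToChar(magic[129:132]), "DICM")) return("dicom")
  # headerless (no-preamble) DICOM fallback by extension
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom")) return("dicom")
  stop("unreadable file: unrecognized image format for ", path)
}

read_png_pixels <- function(path, rescale) {
  depth <- png_bit_depth(path)
  arr <- png::readPNG(path)
  g <- collapse_to_gray(arr)
  if (depth > 8L) {
    if (!rescale)
      stop("bit depth ", depth, " exceeds 8; pass rescale = TRUE to rescale")
    warning("rescaling ", depth, "-bit source to 8 bits (min-max)")
    return(minmax_rescale_255(g))
  }
  matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
}

read_jpeg_pixels <- function(path) {
  g <- collapse_to_gray(jpeg::readJPEG(path))
  matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
}

#' Write a frame (or mask) as 8-bit grayscale PNG
#'
#' PNG writing is lossless: `read_frame()` of the written file reproduces
#' the pixel matrix exactly.
#'
#' @param frame an [echo_frame()], or a logical mask matrix (written as
#'   0/255).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  px <- if (is_echo_frame(frame)) frame$pixels
        else if (is.logical(frame)) matrix(255L * as.integer(frame),
                                           nrow(frame), ncol(frame))
        else stop("frame must be an echo_frame or a logical mask")
  png::writePNG(px / 255, target = path)
  invisible(path)
}

# ---- PGM (portable graymap), ASCII P2 and binary P5 ----------------------
# Kept as the plain-text fixture format: an 8-bit P2 file is human-readable
# and survives text-only pipelines. maxval > 255 implies 2-byte big-endian
# samples (P5) or larger integers (P2).

read_pgm_pixels <- function(path, rescale = FALSE) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("unreadable file: not a PGM")
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (anyNA(c(w, h, maxv)) || w < 1L || h < 1L || maxv < 1L)
    stop("unreadable file: bad PGM header")
  n <- w * h
  if (magic == "P2") {
    vals <- integer(n)
    for (i in seq_len(n)) vals[i] <- as.integer(tok())
  } else {
    if (maxv <= 255L) {
      vals <- as.integer(readBin(con, "raw", n = n))
    } else {
      bts <- as.integer(readBin(con, "raw", n = 2L * n))
      vals <- bts[seq(1L, 2L * n, 2L)] * 256L + bts[seq(2L, 2L * n, 2L)]
    }
  }
  if (length(vals) < n || anyNA(vals)) stop("unreadable file: truncated PGM")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxv > 255L) {
    if (!rescale)
      stop("bit depth exceeds 8 (maxval ", maxv,
           "); pass rescale = TRUE to rescale")
    warning("rescaling >8-bit PGM to 8 bits (min-max)")
    m <- minmax_rescale_255(m)
  }
  m
}

# whitespace/comment-aware token reader for PGM headers and P2 bodies
pgm_tokenizer <- function(con) {
  function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch)) return(NA_character_)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || !nzchar(ch) || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || !nzchar(ch) || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    tok
  }
}

#' Write a frame as ASCII PGM (P2)
#'
#' @param frame an [echo_frame()] or an integer matrix in `[0, 255]`
#'   (possibly wider range when `maxval` is raised).
#' @param path output path.
#' @param maxval maximum sample value declared in the header (default 255).
#' @return `path`, invisibly.
#' @export
write_frame_pgm <- function(frame, path, maxval = 255L) {
  px <- if (is_echo_frame(frame)) frame$pixels else frame
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  apply(px, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
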