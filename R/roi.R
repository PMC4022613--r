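#' Region of interest: a labeled simple polygon in pixel coordinates
#'
#' Vertices are 0-based `(row, col)` coordinates of pixel centers; the
#' polygon is implicitly closed. Two labels are recognized, mirroring the
#' measurement protocol: `"myocardial"` (the general ROI over the
#' inferolateral mid-to-basal segment) and `"pericardial"` (the specific ROI
#' over the adjacent, parallel pericardial interface from which the SIC is
#' computed).
#'
#' @param label `"myocardial"` or `"pericardial"`.
#' @param vertices numeric matrix with columns `(row, col)`, at least 3
#'   rows, describing a simple (non-self-intersecting) polygon of nonzero
#'   area.
#' @return An object of class `echo_roi`.
#' @examples
#' roi("pericardial", cbind(c(10, 10, 20, 20), c(10, 30, 30, 10)))
#' @export
roi <- function(label, vertices) {
  label <- match.arg(label, c("myocardial", "pericardial"))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be a 2-column (row,col) matrix")
  if (nrow(vertices) < 3L) stop("polygon needs ≥ 3 vertices")
  if (anyNA(vertices)) stop("vertices contain NA")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("row", "col")
  if (!polygon_is_simple(vertices)) stop("polygon is self-intersecting")
  if (abs(polygon_area(vertices)) < 1e-12) stop("degenerate polygon (area 0)")
  structure(list(label = label, vertices = vertices, closed = TRUE),
            class = "echo_roi")
}

#' @export
print.echo_roi <- function(x, ...) {
  cat(sprintf("<echo_roi '%s', %d vertices, area %.1f px^2>\n",
              x$label, nrow(x$vertices), abs(polygon_area(x$vertices))))
  invisible(x)
}

is_echo_roi <- function(x) inherits(x, "echo_roi")

# signed shoelace area
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# simple-polygon check: no two non-adjacent edges intersect; adjacent edges
# may share only their common endpoint
polygon_is_simple <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  segs <- cbind(v, v[j, , drop = FALSE])
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      adjacent <- (b == a + 1L) || (a == 1L && b == n)
      if (adjacent) next
      if (segments_intersect(segs[a, 1:2], segs[a, 3:4],
                             segs[b, 1:2], segs[b, 3:4])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
  (a[2] - o[2]) * (b[1] - o[1])

on_segment <- function(p, q, r) {
  min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
  min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
  d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (abs(d1) < 1e-12 && on_segment(p3, p4, p1)) ||
  (abs(d2) < 1e-12 && on_segment(p3, p4, p2)) ||
  (abs(d3) < 1e-12 && on_segment(p1, p2, p3)) ||
  (abs(d4) < 1e-12 && on_segment(p1, p2, p4))
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd
#' (crossing-number) rule for the polygon; pixel centers lying exactly on a
#' polygon edge are included. This rule is deterministic and is checked in
#' the test suite against an exhaustive per-pixel point-in-polygon oracle.
#'
#' @param roi an [roi()].
#' @param frame an [echo_frame()] giving the mask extent.
#' @param min_pixels minimum acceptable mask size (default 32).
#' @return Logical matrix of the frame's dimensions.
#' @export
rasterize_roi <- function(roi, frame, min_pixels = 32L) {
  stopifnot(is_echo_roi(roi), is_echo_frame(frame))
  v <- roi$vertices
  if (min(v) < 0 || max(v[, 1]) > frame$height - 1 ||
      max(v[, 2]) > frame$width - 1)
    stop("ROI vertices fall outside frame bounds")
  mask <- matrix(FALSE, frame$height, frame$width)
  r0 <- max(0L, floor(min(v[, 1]))); r1 <- min(frame$height - 1L,
                                               ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2]))); c1 <- min(frame$width - 1L,
                                               ceiling(max(v[, 2])))
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))       # candidate pixel centers
  px <- rep(cols, each = length(rows))
  inside <- rep(FALSE, length(py))
  onedge <- rep(FALSE, length(py))
  n <- nrow(v)
  jj <- c(2:n, 1L)
  for (e in seq_len(n)) {
    y1 <- v[e, 1]; x1 <- v[e, 2]; y2 <- v[jj[e], 1]; x2 <- v[jj[e], 2]
    # crossing test: ray from the pixel center in the +col direction
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xi))
    }
    # exact on-edge centers
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    hit <- abs(d) < 1e-9 &
      px >= pmin(x1, x2) - 1e-9 & px <= pmax(x1, x2) + 1e-9 &
      py >= pmin(y1, y2) - 1e-9 & py <= pmax(y1, y2) + 1e-9
    onedge <- onedge | hit
  }
  keep <- inside | onedge
  mask[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  cnt <- sum(mask)
  if (cnt < min_pixels)
    stop("mask has ", cnt, " pixels, below the configured minimum ",
         min_pixels)
  mask
}

#' Extract the ROI pixel-intensity sample from a frame
#'
#' @inheritParams rasterize_roi
#' @return An object of class `pixel_sample`: list with `intensities`
#'   (integer vector, order not meaningful), `n`, `roi_label`, `frame_ref`.
#' @export
extract_pixels <- function(frame, roi, min_pixels = 32L) {
  mask <- rasterize_roi(roi, frame, min_pixels = min_pixels)
  vals <- frame$pixels[mask]
  pixel_sample(vals, roi_label = roi$label,
               frame_ref = list(source_id = frame$source_id,
                                frame_index = frame$frame_index))
}

#' Construct a pixel-intensity sample
#'
#' @param intensities integer vector of intensities in `[0, 255]`.
#' @param roi_label `"myocardial"` or `"pericardial"`.
#' @param frame_ref provenance list (source id, frame index).
#' @return A `pixel_sample` object.
#' @export
pixel_sample <- function(intensities,
                         roi_label = c("pericardial", "myocardial"),
                         frame_ref = list(source_id = "memory",
                                          frame_index = 0L)) {
  roi_label <- match.arg(roi_label)
  intensities <- as.integer(intensities)
  if (length(intensities) < 1L) stop("empty sample")
  if (anyNA(intensities) || min(intensities) < 0L || max(intensities) > 255L)
    stop("intensities must lie in [0, 255]")
  structure(list(intensities = intensities, n = length(intensities),
                 roi_label = roi_label, frame_ref = frame_ref),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat(sprintf("<pixel_sample %s, n=%d, median %d>\n",
              x$roi_label, x$n, as.integer(stats::median(x$intensities))))
  invisible(x)
}

# ---- ROI JSON files ------------------------------------------------------
# Schema: [{"label": "...", "vertices": [[row, col], ...]}, ...]

#' Read / write ROI polygon files (JSON)
#'
#' The on-disk schema is a JSON array of objects
#' `{"label": ..., "vertices": [[row, col], ...]}` with 0-based pixel
#' coordinates. `write_roi_file()` followed by `read_roi_file()` is an
#' identity on labels and vertices.
#'
#' @param path JSON file path.
#' @return `read_roi_file()`: a list of [roi()] objects.
#' @export
read_roi_file <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!is.list(raw)) stop("ROI file schema violation: expected a JSON array")
  lapply(raw, function(item) {
    if (is.null(item$label) || is.null(item$vertices))
      stop("ROI file schema violation: need 'label' and 'vertices'")
    if (!item$label %in% c("myocardial", "pericardial"))
      stop("unknown label '", item$label, "'")
    verts <- do.call(rbind, lapply(item$vertices, function(p) {
      if (length(p) != 2L)
        stop("ROI file schema violation: vertex must be [row, col]")
      as.numeric(p)
    }))
    if (is.null(verts) || nrow(verts) < 3L)
      stop("polygon needs ≥ 3 vertices")
    roi(item$label, verts)
  })
}

#' @param rois a list of [roi()] objects (or a single one).
#' @rdname read_roi_file
#' @export
write_roi_file <- function(rois, path) {
  if (is_echo_roi(rois)) rois <- list(rois)
  stopifnot(all(vapply(rois, is_echo_roi, TRUE)))
  payload <- lapply(rois, function(r) {
    list(label = jsonlite::unbox(r$label),
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  })
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}
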