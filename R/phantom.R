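# Synthetic B-mode phantom: horizontal tissue bands (cavity, myocardium,
# pericardium, background) filled with partially developed Rayleigh speckle.
# A severity parameter theta in [0,1] couples to the two mechanisms by which
# afterload-stressed myocardium darkens the pericardial reflection:
# attenuation of the effective pericardial echogenicity (scattering /
# shadowing upstream of the interface) and inflation of myocardial speckle
# variance (tissue heterogeneity).

#' Specification of a synthetic B-mode phantom
#'
#' Per-layer pixels are drawn as `x = mu + speckle * (R - mu)` where `R` is
#' Rayleigh-distributed with mean `mu`, then rounded and clipped to
#' `[0, 255]`. `speckle = 1` is fully developed Rayleigh speckle;
#' `speckle -> 0` degenerates to a constant `mu` (a specular, coherent
#' reflector — the default for the bright pericardial line). Severity
#' `theta` rescales the effective pericardial mean by
#' `(1 - attenuation_alpha * theta)` and myocardial deviations by
#' `sqrt(1 + heterogeneity_beta * theta)`.
#'
#' @param height,width frame size in pixels.
#' @param bands named list of 0-based inclusive row ranges `c(first, last)`
#'   for `cavity`, `myocardium`, `pericardium`; remaining rows are
#'   background. Bands must be disjoint and inside the frame.
#' @param mu named intensity means (0-255) for `cavity`, `myocardium`,
#'   `pericardium`, `background`.
#' @param speckle named per-layer speckle fractions in `[0, 1]`.
#' @param severity theta in `[0, 1]`.
#' @param attenuation_alpha fractional fall of effective pericardial mean at
#'   `theta = 1`, in `[0, 1)`.
#' @param heterogeneity_beta myocardial variance multiplier is
#'   `1 + heterogeneity_beta * theta`.
#' @param seed RNG seed; identical (spec, seed) gives bit-identical frames.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         bands = list(cavity = c(0L, 99L),
                                      myocardium = c(100L, 179L),
                                      pericardium = c(180L, 215L)),
                         mu = c(cavity = 20, myocardium = 90,
                                pericardium = 200, background = 8),
                         speckle = c(cavity = 1, myocardium = 1,
                                     pericardium = 0.25, background = 1),
                         severity = 0,
                         attenuation_alpha = 0.4,
                         heterogeneity_beta = 1.0,
                         seed = 1L) {
  stopifnot(height >= 16L, width >= 16L,
            severity >= 0, severity <= 1,
            attenuation_alpha >= 0, attenuation_alpha < 1,
            heterogeneity_beta >= 0)
  need <- c("cavity", "myocardium", "pericardium")
  if (!all(need %in% names(bands))) stop("bands must name ", toString(need))
  if (!all(c(need, "background") %in% names(mu)))
    stop("mu must name all four layers")
  if (!(mu[["cavity"]] < mu[["myocardium"]] &&
        mu[["myocardium"]] < mu[["pericardium"]] &&
        mu[["pericardium"]] <= 255))
    stop("echogenicity ordering violated: need cavity < myocardium < pericardium <= 255")
  rows_used <- integer(0)
  for (b in bands) {
    if (length(b) != 2L || b[1] > b[2] || b[1] < 0L || b[2] > height - 1L)
      stop("band exceeds frame or is empty")
    rr <- b[1]:b[2]
    if (any(rr %in% rows_used)) stop("geometry bands overlap")
    rows_used <- c(rows_used, rr)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 bands = lapply(bands, as.integer), mu = mu,
                 speckle = speckle, severity = severity,
                 attenuation_alpha = attenuation_alpha,
                 heterogeneity_beta = heterogeneity_beta,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rayleigh deviates with mean `mu` (scale mu / sqrt(pi/2))
rrayleigh_mean <- function(n, mu) {
  (mu / sqrt(pi / 2)) * sqrt(-2 * log(stats::runif(n)))
}

#' Generate a phantom frame with its two measurement ROIs
#'
#' @param spec a [phantom_spec()].
#' @return List with `frame` (an [echo_frame()]), `myocardial_roi` and
#'   `pericardial_roi` (rectangular [roi()]s inset within their bands).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' compute_sic(extract_pixels(ph$frame, ph$pericardial_roi))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    theta <- spec$severity
    px <- matrix(0, h, w)
    layer_rows <- list(background = setdiff(0:(h - 1L),
                                            unlist(lapply(spec$bands,
                                                          function(b) b[1]:b[2]))))
    for (nm in names(spec$bands))
      layer_rows[[nm]] <- spec$bands[[nm]][1]:spec$bands[[nm]][2]
    for (nm in c("cavity", "myocardium", "pericardium", "background")) {
      rows <- layer_rows[[nm]]
      if (!length(rows)) next
      mu <- spec$mu[[nm]]
      if (nm == "pericardium") mu <- mu * (1 - spec$attenuation_alpha * theta)
      c_sp <- spec$speckle[[nm]]
      if (nm == "myocardium") c_sp <- c_sp * sqrt(1 + spec$heterogeneity_beta * theta)
      n <- length(rows) * w
      vals <- mu + c_sp * (rrayleigh_mean(n, mu) - mu)
      px[rows + 1L, ] <- matrix(vals, length(rows), w)
    }
    px <- matrix(as.integer(pmin(pmax(round(px), 0), 255)), h, w)
    frame <- echo_frame(px, source_id = sprintf("phantom(seed=%d,theta=%g)",
                                                spec$seed, theta))
    list(frame = frame,
         myocardial_roi = band_rectangle_roi("myocardial",
                                             spec$bands$myocardium, w,
                                             margin_rows = 4L),
         pericardial_roi = band_rectangle_roi("pericardial",
                                              spec$bands$pericardium, w,
                                              margin_rows = 2L))
  })
}

band_rectangle_roi <- function(label, band, width, margin_rows,
                               margin_cols = 8L) {
  r0 <- band[1] + margin_rows; r1 <- band[2] - margin_rows
  c0 <- margin_cols; c1 <- width - 1L - margin_cols
  roi(label, cbind(c(r0, r0, r1, r1), c(c0, c1, c1, c0)))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply a linear gain transform to a frame
#'
#' `pixel <- round(clip(gain * pixel + offset, 0, 255))`, emulating
#' acquisition-gain variation. The identity transform returns an identical
#' frame.
#'
#' @param frame an [echo_frame()].
#' @param gain multiplicative factor `> 0`.
#' @param offset additive intensity.
#' @return A transformed [echo_frame()].
#' @export
apply_gain <- function(frame, gain = 1, offset = 0) {
  stopifnot(is_echo_frame(frame))
  if (!is.numeric(gain) || gain <= 0) stop("gain must be positive")
  px <- round(pmin(pmax(gain * frame$pixels + offset, 0), 255))
  f <- echo_frame(matrix(as.integer(px), frame$height, frame$width),
                  frame_index = frame$frame_index,
                  source_id = paste0(frame$source_id,
                                     sprintf("|gain=%g,offset=%g", gain,
                                             offset)))
  f
}

#' Translate an ROI by a random integer offset (simulated reader jitter)
#'
#' Draws one offset uniformly from the integer square
#' `[-max_shift, +max_shift]^2` and rigidly translates every vertex,
#' emulating between-reader ROI placement variability for reproducibility
#' (ICC) experiments.
#'
#' @param roi an [roi()].
#' @param max_shift_px maximum |shift| per axis, integer `>= 0`.
#' @param seed RNG seed for the offset draw.
#' @param frame optional [echo_frame()]; if supplied, a shift that pushes
#'   the ROI out of bounds is an error.
#' @return The translated [roi()].
#' @export
jitter_roi <- function(roi, max_shift_px, seed, frame = NULL) {
  stopifnot(is_echo_roi(roi), max_shift_px >= 0)
  off <- with_local_seed(seed,
    sample.int(2L * max_shift_px + 1L, 2L, replace = TRUE) - max_shift_px - 1L)
  v <- sweep(roi$vertices, 2L, -as.numeric(off))
  if (!is.null(frame)) {
    if (min(v) < 0 || max(v[, 1]) > frame$height - 1 ||
        max(v[, 2]) > frame$width - 1)
      stop("jitter shift pushes ROI out of frame bounds")
  }
  roi(roi$label, v)
}
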