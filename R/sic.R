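#' Nearest-rank percentile of a pixel sample
#'
#' Returns the `ceiling(q * n / 100)`-th smallest value, i.e. the
#' nearest-rank order statistic. The result is always an observed value, so
#' for 8-bit data every percentile lies on the integer lattice `0..255` and
#' the SIC lies on the lattice `1 - k/256`. No interpolation is performed.
#'
#' @param sample a [pixel_sample()] or a numeric vector.
#' @param q percentile in `(0, 100]`.
#' @return The order statistic (integer for pixel samples).
#' @examples
#' percentile_nearest_rank(c(10, 20, 30, 40), 25)  # 10
#' @export
percentile_nearest_rank <- function(sample, q) {
  x <- if (inherits(sample, "pixel_sample")) sample$intensities else sample
  if (length(x) < 1L) stop("empty sample")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
    stop("q must lie in (0, 100]")
  sort(x)[ceiling(q * length(x) / 100)]
}

#' Summary of a signal-intensity distribution
#'
#' Hierarchically orders the sample and reports moments and nearest-rank
#' percentiles, as produced for both the myocardial and pericardial ROIs.
#' `sd` uses the `n - 1` denominator; `skewness` is `m3 / m2^(3/2)` and
#' `excess_kurtosis` is `m4 / m2^2 - 3` (central sample moments).
#'
#' @param sample a [pixel_sample()] or numeric vector, `n >= 2`.
#' @return A `distribution_summary` list: `n`, `mean`, `sd`, `percentiles`
#'   (named vector for 5, 10, 25, 50, 75, 90, 95), `skewness`,
#'   `excess_kurtosis`.
#' @export
distribution_summary <- function(sample) {
  x <- if (inherits(sample, "pixel_sample")) sample$intensities else sample
  n <- length(x)
  if (n < 2L) stop("need n >= 2 for a distribution summary")
  qs <- c(5, 10, 25, 50, 75, 90, 95)
  pct <- vapply(qs, function(q) as.numeric(percentile_nearest_rank(x, q)),
                numeric(1))
  names(pct) <- as.character(qs)
  m <- mean(x)
  dev <- x - m
  m2 <- mean(dev^2)
  structure(list(
    n = n, mean = m, sd = stats::sd(x), percentiles = pct,
    skewness = if (m2 > 0) mean(dev^3) / m2^1.5 else 0,
    excess_kurtosis = if (m2 > 0) mean(dev^4) / m2^2 - 3 else 0),
    class = "distribution_summary")
}

#' Signal Intensity Coefficient of a pericardial pixel sample
#'
#' The SIC is `1 - p/256`, where `p` is the 25th-percentile (nearest-rank)
#' intensity of the pericardial ROI sample. Darker pericardial reflections —
#' the signature of attenuation and scattering by structurally altered
#' myocardium overlying the pericardium — give higher SIC. The divisor is
#' 256 (not 255), exactly as the index is defined, so SIC ranges over
#' `[1/256, 1]`.
#'
#' @param sample a [pixel_sample()]; expected `roi_label` is
#'   `"pericardial"`.
#' @param min_n minimum sample size (default 32); smaller samples error.
#' @param strict_label if `TRUE`, a non-pericardial label is an error; by
#'   default it is a warning.
#' @return A `microstructure_result` list: `sic`, `p25`, `summary`
#'   (a [distribution_summary()]), `roi_label`, `frame_ref`.
#' @examples
#' s <- pixel_sample(rep(128L, 64))
#' compute_sic(s)$sic  # 0.5
#' @export
compute_sic <- function(sample, min_n = 32L, strict_label = FALSE) {
  stopifnot(inherits(sample, "pixel_sample"))
  if (sample$n < min_n)
    stop("sample too small: n = ", sample$n, " < ", min_n)
  if (sample$roi_label != "pericardial") {
    msg <- paste0("SIC is defined on the pericardial ROI; got '",
                  sample$roi_label, "'")
    if (strict_label) stop(msg) else warning(msg)
  }
  p25 <- percentile_nearest_rank(sample, 25)
  structure(list(
    sic = 1 - p25 / 256,
    p25 = as.integer(p25),
    summary = distribution_summary(sample),
    roi_label = sample$roi_label,
    frame_ref = sample$frame_ref),
    class = "microstructure_result")
}

#' @export
print.microstructure_result <- function(x, ...) {
  cat(sprintf("<SIC %.4f (p25 = %d, n = %d, %s ROI)>\n",
              x$sic, x$p25, x$summary$n, x$roi_label))
  invisible(x)
}

#' Myocardial Structural Index
#'
#' The MSI combines the microstructural SIC with the macrostructural
#' relative wall thickness: `MSI = SIC/0.13 + RWT/0.05`. The constants 0.13
#' and 0.05 are fixed standardization scales of the index definition, not
#' re-estimated from data.
#'
#' @param sic Signal Intensity Coefficient, in `[0, 1]`.
#' @param rwt relative wall thickness, `> 0`.
#' @return An `msi_result` list: `msi`, `sic_component`, `rwt_component`.
#' @examples
#' compute_msi(0.23, 0.45)$msi  # 10.77
#' @export
compute_msi <- function(sic, rwt) {
  if (!is.numeric(sic) || sic < 0 || sic > 1) stop("sic must lie in [0, 1]")
  if (!is.numeric(rwt) || rwt <= 0) stop("rwt must be positive")
  sic_c <- sic / 0.13
  rwt_c <- rwt / 0.05
  structure(list(msi = sic_c + rwt_c, sic_component = sic_c,
                 rwt_component = rwt_c), class = "msi_result")
}

#' Serialize a microstructure result to a JSON-ready record
#'
#' @param result a `microstructure_result` from [compute_sic()].
#' @param msi optional `msi_result` to merge in.
#' @return A named list suitable for `jsonlite::write_json()`, with fields
#'   `source_id`, `frame_index`, `roi_label`, `n`, `p25`, `sic`, optional
#'   `msi`, `percentiles`, `mean`, `sd`.
#' @export
microstructure_record <- function(result, msi = NULL) {
  stopifnot(inherits(result, "microstructure_result"))
  rec <- list(source_id = result$frame_ref$source_id,
              frame_index = result$frame_ref$frame_index,
              roi_label = result$roi_label,
              n = result$summary$n,
              p25 = result$p25,
              sic = result$sic,
              percentiles = as.list(result$summary$percentiles),
              mean = result$summary$mean,
              sd = result$summary$sd)
  if (!is.null(msi)) rec$msi <- msi$msi
  rec
}
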