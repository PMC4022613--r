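# Independent oracles used across the suite. These deliberately re-derive
# results through different algorithms than the package code paths.

# scalar even-odd point-in-polygon with explicit on-edge inclusion;
# structured as a per-pixel loop over edges (independent of the vectorized
# rasterizer)
oracle_point_in_polygon <- function(py, px, verts) {
  n <- nrow(verts)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    y1 <- verts[i, 1]; x1 <- verts[i, 2]
    y2 <- verts[j, 1]; x2 <- verts[j, 2]
    # on-edge check
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(d) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(verts, height, width) {
  mask <- matrix(FALSE, height, width)
  for (r in 0:(height - 1)) for (c in 0:(width - 1))
    mask[r + 1, c + 1] <- oracle_point_in_polygon(r, c, verts)
  mask
}

# random star-shaped (hence simple) polygon with <= max_v vertices on a
# frame of the given size
random_simple_polygon <- function(max_v = 12L, height = 64L, width = 64L) {
  nv <- sample(3:max_v, 1)
  cy <- runif(1, height * 0.3, height * 0.7)
  cx <- runif(1, width * 0.3, width * 0.7)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 4, min(height, width) * 0.28)
  cbind(pmin(pmax(cy + rad * sin(ang), 0), height - 1),
        pmin(pmax(cx + rad * cos(ang), 0), width - 1))
}

# nearest-rank percentile by explicit sort-and-index
oracle_nearest_rank <- function(x, q) {
  xs <- sort(x)
  xs[as.integer(ceiling(q * length(x) / 100))]
}

# closed-form truncated-normal moments (re-derived here, independent of the
# package-internal helper)
oracle_truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# exact distribution of round(clip(mu + c*(R - mu), 0, 255)) for Rayleigh R
# with mean mu: P(K = k) from the Rayleigh CDF. Returns E[K].
oracle_phantom_layer_mean <- function(mu, c_sp) {
  scale <- mu / sqrt(pi / 2)
  praw <- function(x) 1 - exp(-pmax(x, 0)^2 / (2 * scale^2))  # CDF of R
  # K = k iff X in [k-0.5, k+0.5) (with end clipping); X = mu + c (R - mu)
  to_r <- function(x) (x - mu) / c_sp + mu
  k <- 0:255
  lo <- ifelse(k == 0, -Inf, to_r(k - 0.5))
  hi <- ifelse(k == 255, Inf, to_r(k + 0.5))
  p <- praw(hi) - praw(ifelse(is.finite(lo), lo, 0))
  p[1] <- praw(to_r(0.5))                 # everything below 0.5 rounds to 0
  p[256] <- 1 - praw(to_r(254.5))
  sum(k * p)
}

# exhaustive label permutations for small-group rank tests: all distinct
# assignments of observations to groups with the given sizes
all_group_permutations <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  enumerate <- function(avail, sizes_left, acc) {
    if (length(sizes_left) == 1L) {
      lab <- acc
      lab[avail] <- length(sizes)
      out[[length(out) + 1L]] <<- lab
      return(invisible())
    }
    g <- length(sizes) - length(sizes_left) + 1L
    picks <- utils::combn(avail, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      lab <- acc
      lab[p] <- g
      enumerate(setdiff(avail, p), sizes_left[-1], lab)
    }
  }
  enumerate(seq_len(n), sizes, integer(n))
  out
}

# closed-form power of the pooled two-sample t test via the noncentral t
oracle_t_power <- function(m1, s1, n1, m2, s2, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- (m2 - m1) / sqrt(s1^2 / n1 + s2^2 / n2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp)
}

# small helper: SIC of a phantom spec's pericardial ROI
phantom_sic <- function(spec) {
  ph <- generate_phantom(spec)
  compute_sic(extract_pixels(ph$frame, ph$pericardial_roi))$sic
}
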