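# Independent brute-force oracles used across the suite. These are written
# from the definitions, not from the implementation paths they check.

# Grayscale erosion/dilation over a disc, by direct neighborhood scan.
brute_morph_disc <- function(x, r, f) {
  out <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    vals <- numeric(0)
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 <= r^2) {
        ii <- i + dy; jj <- j + dx
        if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x)) {
          vals <- c(vals, x[ii, jj])
        }
      }
    }
    out[i, j] <- f(vals)
  }
  out
}

brute_opening_disc <- function(x, r) {
  brute_morph_disc(brute_morph_disc(x, r, min), r, max)
}

# Otsu by exhaustive search: minimize the weighted intra-class variance
# over every cut of the 256-bin histogram (bins represented by their
# midpoints, as in the histogram-based formulation).
brute_otsu <- function(vals, n_bins = 256) {
  lo <- min(vals); hi <- max(vals)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(findInterval(vals, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  x <- mids[bin]
  best <- Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    below <- x[bin <= t]; above <- x[bin > t]
    if (!length(below) || !length(above)) next
    # population variances weighted by class probability
    v0 <- mean((below - mean(below))^2)
    v1 <- mean((above - mean(above))^2)
    wcv <- (length(below) * v0 + length(above) * v1) / length(x)
    if (wcv < best) { best <- wcv; best_t <- edges[t + 1] }
  }
  best_t
}

# Euclidean distance transform by exhaustive nearest-background search.
brute_edt <- function(mask, spacing = rep(1, length(dim(mask)))) {
  dims <- dim(mask)
  coords <- which(!mask, arr.ind = TRUE)
  out <- array(0, dims)
  fg <- which(mask, arr.ind = TRUE)
  if (is.null(dim(fg))) fg <- matrix(fg, ncol = length(dims))
  for (i in seq_len(nrow(fg))) {
    d2 <- rep(0, nrow(coords))
    for (ax in seq_along(dims)) {
      d2 <- d2 + ((fg[i, ax] - coords[, ax]) * spacing[ax])^2
    }
    out[matrix(fg[i, ], 1)] <- sqrt(min(d2))
  }
  out
}

# Exact integer translation with zero fill (no wrap-around).
translate_int <- function(im, dy, dx) {
  nr <- nrow(im); nc <- ncol(im)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- im[src_r[ok_r], src_c[ok_c]]
  out
}

# Subpixel translation by Fourier phase ramp (band-limited images only).
translate_fourier <- function(im, dy, dx) {
  nr <- nrow(im); nc <- ncol(im)
  fr <- seq_len(nr) - 1; fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- seq_len(nc) - 1; fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  ph <- exp(-2i * pi * (outer(fr * dy / nr, rep(1, nc)) +
                          outer(rep(1, nr), fc * dx / nc)))
  Re(stats::fft(stats::fft(im) * ph, inverse = TRUE)) / length(im)
}

# A small, fast scene configuration for simulator-driven tests.
small_scene_config <- function(seed, ...) {
  args <- list(image_shape = c(96L, 96L), n_sites = 120L, n_domains = 15L,
               background_site_rate = 25L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_config, args)
}

# Smooth random test image with structure at several scales.
structured_image <- function(n = 96, seed = 1, n_spots = 30, sigma = 2) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (s in seq_len(n_spots)) {
    pr <- runif(1, n * 0.15, n * 0.85); pc <- runif(1, n * 0.15, n * 0.85)
    rr <- max(1, floor(pr - 4 * sigma)):min(n, ceiling(pr + 4 * sigma))
    cc <- max(1, floor(pc - 4 * sigma)):min(n, ceiling(pc + 4 * sigma))
    img[rr, cc] <- img[rr, cc] +
      runif(1, 50, 150) * exp(-(rr - pr)^2 / (2 * sigma^2)) %o%
        exp(-(cc - pc)^2 / (2 * sigma^2))
  }
  img
}
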