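# Flat grayscale morphology with a disc structuring element.
# Erosion/dilation are separated into per-row-offset horizontal running
# min/max filters (the disc is a stack of horizontal segments), each
# computed in O(log width) vectorized passes. Pixels outside the image are
# ignored (+Inf for min, -Inf for max), i.e. the neighborhood is clipped
# to the frame.

shift_cols <- function(x, s, fill) {
  nc <- ncol(x)
  if (s == 0) return(x)
  out <- matrix(fill, nrow(x), nc)
  if (abs(s) >= nc) return(out)
  if (s > 0) out[, 1:(nc - s)] <- x[, (1 + s):nc]
  else out[, (1 - s):nc] <- x[, 1:(nc + s)]
  out
}

shift_rows <- function(x, s, fill) {
  nr <- nrow(x)
  if (s == 0) return(x)
  out <- matrix(fill, nr, ncol(x))
  if (abs(s) >= nr) return(out)
  if (s > 0) out[1:(nr - s), ] <- x[(1 + s):nr, ]
  else out[(1 - s):nr, ] <- x[1:(nr + s), ]
  out
}

# Running extreme over a centered window of half-width w along columns.
run_extreme_cols <- function(x, w, op, fill) {
  if (w == 0) return(x)
  len <- 2L * w + 1L
  block <- 2L^floor(log2(len))
  pad <- matrix(fill, nrow(x), w)
  f <- cbind(pad, x, pad)
  s <- 1L
  while (s < block) {
    f <- op(f, shift_cols(f, s, fill))
    s <- s * 2L
  }
  g <- op(f, shift_cols(f, len - block, fill))
  g[, seq_len(ncol(x)), drop = FALSE]
}

disc_half_widths <- function(radius) {
  dy <- -radius:radius
  list(dy = dy, wx = as.integer(floor(sqrt(radius^2 - dy^2 + 1e-9))))
}

morph_disc <- function(image, radius, op, fill) {
  radius <- as.integer(radius)
  disc <- disc_half_widths(radius)
  cache <- list()
  out <- matrix(fill, nrow(image), ncol(image))
  for (i in seq_along(disc$dy)) {
    w <- disc$wx[i]
    key <- as.character(w)
    if (is.null(cache[[key]])) {
      cache[[key]] <- run_extreme_cols(image, w, op, fill)
    }
    out <- op(out, shift_rows(cache[[key]], disc$dy[i], fill))
  }
  out
}

#' Grayscale erosion by a disc
#' @param image numeric matrix.
#' @param radius disc radius in pixels; the structuring element contains
#'   all offsets with `dy^2 + dx^2 <= radius^2`.
#' @return Eroded image (pixelwise minimum over the disc neighborhood,
#'   clipped to the frame).
#' @export
gray_erode <- function(image, radius) morph_disc(image, radius, pmin, Inf)

#' Grayscale dilation by a disc
#' @inheritParams gray_erode
#' @return Dilated image (pixelwise maximum over the disc neighborhood).
#' @export
gray_dilate <- function(image, radius) morph_disc(image, radius, pmax, -Inf)

#' Grayscale opening by a disc
#'
#' Erosion followed by dilation with the same disc: the tightest surface
#' that fits under the intensity landscape without entering structures
#' narrower than the disc. Used as the rolling-ball background estimate.
#'
#' @inheritParams gray_erode
#' @return Opened image.
#' @export
gray_opening <- function(image, radius) gray_dilate(gray_erode(image, radius), radius)
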