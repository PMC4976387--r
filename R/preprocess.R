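#' Rolling-ball background subtraction
#'
#' Removes smooth low-frequency background by subtracting a grayscale
#' morphological opening of the image with a disc structuring element of
#' the given radius — the classical equivalent of rolling a ball under the
#' intensity surface. The result is clipped at zero. The default radius of
#' 50 pixels is the conventional kernel size for epifluorescence
#' micrographs of this kind.
#'
#' As is conventional for rolling-ball implementations, the background is
#' estimated from a lightly mean-filtered copy of the image (window
#' `2 * presmooth + 1`) so that single-pixel noise minima do not drag the
#' estimate down; `presmooth = 0` estimates it from the raw image, making
#' the background exactly the grayscale opening.
#'
#' @param image numeric intensity matrix.
#' @param radius structuring-element radius in pixels (>= 1).
#' @param presmooth half-width of the mean filter applied to the copy used
#'   for background estimation (0 disables).
#' @return Background-subtracted image, same shape, non-negative.
#' @export
rolling_ball_subtract <- function(image, radius = 50, presmooth = 1) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    stop("parameter error: radius must be >= 1")
  }
  stopifnot(is.matrix(image))
  est_src <- image
  if (presmooth > 0) {
    w <- 2 * as.integer(presmooth) + 1
    kern <- matrix(1 / w^2, w, w)
    est_src <- as.matrix(EBImage::filter2(image, kern, boundary = "replicate"))
  }
  pmax(image - gray_opening(est_src, radius), 0)
}

#' Estimate rigid translation between two imaging rounds
#'
#' Translation-only registration by cross-correlation in the frequency
#' domain. The reported `shift` is the `(dy, dx)` translation carried by
#' the moving image relative to the reference, i.e.
#' `moving ~ translate(reference, shift)`; apply the negated shift to the
#' moving image to align it. Integer-pixel estimation by default; with
#' `subpixel = TRUE` the correlation peak is refined by an upsampled
#' discrete Fourier transform evaluated on a small neighborhood of the
#' integer peak.
#'
#' @param reference numeric matrix.
#' @param moving numeric matrix, same shape.
#' @param subpixel refine the shift below one pixel.
#' @param upsample subpixel resolution is `1/upsample` pixels.
#' @param reference_round optional integer recorded in the result.
#' @return Object of class `registration_result`: `shift` (dy, dx),
#'   `peak_quality` (normalized correlation at the peak, in \[0, 1\]),
#'   `reference_round`.
#' @export
register_rounds <- function(reference, moving, subpixel = FALSE,
                            upsample = 50, reference_round = 1L) {
  if (!identical(dim(reference), dim(moving))) {
    stop("reference and moving images must share shape")
  }
  if (all(reference == 0) || all(moving == 0)) {
    stop("degenerate input: all-zero image has no correlation peak")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  Fr <- stats::fft(reference)
  Fm <- stats::fft(moving)
  R <- Fm * Conj(Fr)
  cc <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  idx <- which.max(cc)
  i <- (idx - 1) %% nr
  j <- (idx - 1) %/% nr
  if (i > nr / 2) i <- i - nr
  if (j > nc / 2) j <- j - nc
  peak <- max(cc) / sqrt(sum(reference^2) * sum(moving^2))
  shift <- c(i, j)
  if (subpixel) {
    usfac <- upsample
    dftshift <- floor(1.5 * usfac)
    nwin <- ceiling(3 * usfac)
    roff <- dftshift - i * usfac
    coff <- dftshift - j * usfac
    fr <- seq_len(nr) - 1; fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
    fc <- seq_len(nc) - 1; fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
    kern_r <- exp(2i * pi / (nr * usfac) * outer((0:(nwin - 1)) - roff, fr))
    kern_c <- exp(2i * pi / (nc * usfac) * outer(fc, (0:(nwin - 1)) - coff))
    ccu <- Mod(kern_r %*% R %*% kern_c)
    idx2 <- which.max(ccu)
    i2 <- (idx2 - 1) %% nwin
    j2 <- (idx2 - 1) %/% nwin
    shift <- c(i + (i2 - dftshift) / usfac, j + (j2 - dftshift) / usfac)
  }
  structure(list(shift = shift, peak_quality = peak,
                 reference_round = reference_round),
            class = "registration_result")
}

#' Translate an image by an integer-rounded shift with a validity mask
#'
#' Pixels shifted in from outside the frame carry no information; they are
#' zero-filled and flagged invalid so downstream statistics can exclude
#' them.
#'
#' @param image numeric matrix.
#' @param shift `(dy, dx)`; rounded to integers before application.
#' @return List with `image` (shifted) and `valid` (logical matrix, FALSE
#'   on shifted-in borders).
#' @export
apply_shift <- function(image, shift) {
  dy <- round(shift[1]); dx <- round(shift[2])
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
    valid[ok_r, ok_c] <- TRUE
  }
  list(image = out, valid = valid)
}

#' Align a moving image onto its reference
#'
#' Convenience wrapper: estimates the shift with [register_rounds()] and
#' applies its negation with [apply_shift()].
#'
#' @inheritParams register_rounds
#' @return List with `image`, `valid` and `registration`.
#' @export
align_to_reference <- function(reference, moving, subpixel = FALSE) {
  reg <- register_rounds(reference, moving, subpixel = subpixel)
  shifted <- apply_shift(moving, -reg$shift)
  c(shifted, list(registration = reg))
}

#' Equalize the mean brightness of one round against another
#'
#' Rescales `b` so its mean over the mask equals the mean of `a` — the
#' normalization applied before comparing labeling rounds, since successive
#' rounds differ in overall gain (antigen retrieval).
#'
#' @param a reference intensity matrix.
#' @param b matrix to rescale.
#' @param mask optional logical matrix restricting the means.
#' @return `b * mean(a)/mean(b)`, with the scale factor attached as
#'   attribute `"scale"`.
#' @export
equalize_means <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("a and b must share shape")
  m <- resolve_mask(a, mask)
  mb <- mean(b[m])
  if (!is.finite(mb) || mb <= 0) {
    stop("degenerate input: mean of b over mask is not positive")
  }
  scale <- mean(a[m]) / mb
  structure(b * scale, scale = scale)
}
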