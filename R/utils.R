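#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Deterministic sub-seed derivation: one root seed is split per purpose
# (round, channel, stage) so any image can be regenerated in isolation and
# call order never matters. Plain polynomial hash kept below 2^31.
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1)
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(root) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.numeric(part)
    for (v in codes) h <- (h * 131 + (v %% m) + 17) %% m
  }
  as.integer(h)
}

# Evaluate expr under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Normalise an optional validity/selection mask against an image.
resolve_mask <- function(image, mask) {
  if (is.null(mask)) return(array(TRUE, dim = dim(image)))
  if (!identical(dim(mask), dim(image))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(image), collapse = "x"))
  }
  mask & !is.na(image)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("configuration error: ", name, " must lie in [0, 1]")
  }
  invisible(x)
}

# Bilinear upsampling of a coarse grid to a full image; used for smooth
# low-frequency background fields.
resize_bilinear <- function(coarse, shape) {
  nr <- shape[1]; nc <- shape[2]
  src_r <- seq(1, nrow(coarse), length.out = nr)
  src_c <- seq(1, ncol(coarse), length.out = nc)
  r0 <- pmin(floor(src_r), nrow(coarse) - 1L); fr <- src_r - r0
  c0 <- pmin(floor(src_c), ncol(coarse) - 1L); fc <- src_c - c0
  a <- coarse[r0, c0, drop = FALSE]; b <- coarse[r0 + 1, c0, drop = FALSE]
  cc <- coarse[r0, c0 + 1, drop = FALSE]; d <- coarse[r0 + 1, c0 + 1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc + d * wr * wc
}
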