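#' Minmax decomposition of two imaging rounds
#'
#' Splits a pair of mean-equalized rounds into a two-color composite: a
#' "shared" channel holding the pixelwise minimum (signal reproduced in
#' both rounds) and a "difference" channel holding the pixelwise absolute
#' difference (signal present in only one round, e.g. from stochastic
#' epitope labeling). By construction `shared + difference` reconstructs
#' the pixelwise maximum. The Pearson correlation between the two rounds
#' over the valid mask and a log-ratio histogram of shared versus
#' difference signal are computed alongside.
#'
#' @param a,b intensity matrices for the two rounds (background-subtracted,
#'   registered and mean-equalized).
#' @param mask optional logical validity mask.
#' @param signed_difference keep the sign of `a - b` in the difference
#'   channel instead of its absolute value (display variant; the shared +
#'   difference = max identity then no longer holds).
#' @param n_bins,pseudocount passed to [ratio_histogram()].
#' @return Object of class `minmax_result`: `shared`, `difference`,
#'   `pearson_r`, `ratio_histogram`, `mask`.
#' @export
minmax_decompose <- function(a, b, mask = NULL, signed_difference = FALSE,
                             n_bins = 64, pseudocount = 1) {
  if (!identical(dim(a), dim(b))) stop("validation error: a and b must share shape")
  m <- resolve_mask(a, mask) & resolve_mask(b, mask)
  if (stats::sd(a[m]) == 0 || stats::sd(b[m]) == 0) {
    stop("degenerate input: zero-variance image, correlation undefined")
  }
  shared <- pmin(a, b)
  difference <- if (signed_difference) a - b else abs(a - b)
  r <- stats::cor(a[m], b[m])
  hist <- ratio_histogram(a, b, n_bins = n_bins, pseudocount = pseudocount,
                          mask = m)
  structure(list(shared = shared, difference = difference, pearson_r = r,
                 ratio_histogram = hist, mask = m),
            class = "minmax_result")
}

#' @export
print.minmax_result <- function(x, ...) {
  cat("minmax_result: Pearson r =", format(x$pearson_r, digits = 4),
      "over", sum(x$mask), "valid pixels\n")
  invisible(x)
}

#' Histogram of shared-to-difference log ratios
#'
#' Per valid pixel computes `log2((shared + pseudocount) / (difference +
#' pseudocount))` — the "ratio of green to red" of the minmax composite —
#' and bins it on an axis symmetric about zero. Large positive values mean
#' signal reproduced across rounds; negative values mean round-specific
#' signal.
#'
#' @inheritParams minmax_decompose
#' @param n_bins number of bins (>= 2).
#' @param pseudocount non-negative intensity offset stabilising the ratio
#'   at empty pixels.
#' @return List with `breaks`, `mids`, `counts`; counts sum to the number
#'   of valid pixels.
#' @export
ratio_histogram <- function(a, b, n_bins = 64, pseudocount = 1, mask = NULL) {
  if (n_bins < 2) stop("parameter error: n_bins must be >= 2")
  if (pseudocount < 0) stop("parameter error: pseudocount must be >= 0")
  if (!identical(dim(a), dim(b))) stop("validation error: a and b must share shape")
  m <- resolve_mask(a, mask) & resolve_mask(b, mask)
  shared <- pmin(a, b)[m]
  difference <- abs(a - b)[m]
  ratio <- log2((shared + pseudocount) / (difference + pseudocount))
  lim <- max(abs(ratio), 1e-9)
  breaks <- seq(-lim, lim, length.out = n_bins + 1)
  h <- graphics::hist(ratio, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts)
}

#' Antibody elution efficiency
#'
#' Fraction of total fluorescence removed by an elution step, in percent:
#' `100 * (1 - sum(post) / sum(pre))` over the valid mask. Inputs should be
#' background-subtracted and registered so that the sums compare like with
#' like.
#'
#' @param pre intensity matrix imaged before elution.
#' @param post intensity matrix imaged after elution.
#' @param mask optional logical validity mask.
#' @return Percentage of signal stripped (100 = complete elution).
#' @export
elution_efficiency <- function(pre, post, mask = NULL) {
  if (!identical(dim(pre), dim(post))) stop("pre and post must share shape")
  m <- resolve_mask(pre, mask) & resolve_mask(post, mask)
  s_pre <- sum(pre[m])
  if (s_pre <= 0) stop("degenerate input: no pre-elution signal over mask")
  100 * (1 - sum(post[m]) / s_pre)
}
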