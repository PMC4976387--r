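#' Otsu threshold of an intensity image
#'
#' Chooses the cut over a fixed-bin histogram that minimizes the weighted
#' intra-class variance of pixels below and above the cut (equivalently,
#' maximizes the between-class variance). The returned threshold is the
#' histogram bin edge separating the two classes, in intensity units;
#' occupancy is intensity strictly above the threshold.
#'
#' @param image numeric intensity matrix (or vector).
#' @param n_bins histogram resolution (default 256).
#' @param mask optional logical validity mask.
#' @return Threshold intensity.
#' @export
otsu_threshold <- function(image, n_bins = 256, mask = NULL) {
  vals <- if (is.null(dim(image))) image[!is.na(image)] else image[resolve_mask(image, mask)]
  if (length(unique(vals)) < 2) {
    stop("degenerate input: image has fewer than 2 distinct values")
  }
  lo <- min(vals); hi <- max(vals)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- as.numeric(
    tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                  n_bins), nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  n <- sum(counts)
  w0 <- cumsum(counts)[-n_bins]
  w1 <- n - w0
  mu0 <- cumsum(counts * mids)[-n_bins] / pmax(w0, 1)
  mu1 <- (sum(counts * mids) - cumsum(counts * mids)[-n_bins]) / pmax(w1, 1)
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  t_idx <- which.max(between)
  edges[t_idx + 1]
}

#' Percentile threshold
#'
#' Threshold `t` such that the fraction of valid pixels strictly below `t`
#' is the smallest attainable fraction at least `percentile`. On quantized
#' (tied) data the attainable fractions jump, and ties resolve toward
#' including more pixels below the threshold. If even the image maximum
#' leaves too few pixels below it, `Inf` is returned (empty occupancy).
#'
#' @param image numeric intensity matrix (or vector).
#' @param percentile target fraction of pixels below the threshold, in
#'   (0, 1). The conventional sweep runs from 0.01 to 0.95.
#' @param mask optional logical validity mask.
#' @return Threshold intensity (possibly `Inf`).
#' @export
percentile_threshold <- function(image, percentile, mask = NULL) {
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 1) {
    stop("parameter error: percentile must lie strictly in (0, 1)")
  }
  vals <- if (is.null(dim(image))) image[!is.na(image)] else image[resolve_mask(image, mask)]
  n <- length(vals)
  u <- sort(unique(vals))
  below <- cumsum(tabulate(match(sort(vals), u), nbins = length(u)))
  # fraction strictly below u[j] is below[j-1]/n
  frac_below <- c(0, below[-length(below)]) / n
  ok <- which(frac_below >= percentile)
  if (!length(ok)) return(Inf)
  u[ok[1]]
}

#' Joint occupancy table over k binarized channels
#'
#' Counts each valid pixel into one of the `2^k` cells indexed by its
#' binary occupancy pattern (channel 1 is the leftmost bit of the pattern
#' label). This is the contingency table underlying the mutual-independence
#' test and the exceedance ratios.
#'
#' @param masks list of `k >= 2` logical matrices of occupancy
#'   (above-threshold) states, sharing one shape.
#' @param valid optional logical validity mask.
#' @param channel_names optional channel labels (default `ch1..chk`).
#' @param thresholds optional per-channel thresholds recorded for
#'   provenance.
#' @return Object of class `occupancy_table`: `k`, `counts` (named integer
#'   vector of length `2^k`, names are bit patterns like `"101"`),
#'   `n_pixels`, `channel_names`, `thresholds`.
#' @export
build_occupancy_table <- function(masks, valid = NULL, channel_names = NULL,
                                  thresholds = NULL) {
  k <- length(masks)
  if (k < 2) stop("parameter error: need at least 2 channels")
  shape <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), shape), TRUE))) {
    stop("validation error: occupancy masks must share shape")
  }
  if (is.null(valid)) valid <- array(TRUE, dim = shape)
  if (!identical(dim(valid), shape)) stop("validity mask shape mismatch")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(k))
  idx <- 0L
  for (c_i in seq_len(k)) {
    idx <- idx + as.integer(masks[[c_i]][valid]) * 2L^(k - c_i)
  }
  counts <- tabulate(idx + 1L, nbins = 2L^k)
  patterns <- vapply(0:(2^k - 1), function(p) {
    paste(rev(as.integer(intToBits(p))[seq_len(k)]), collapse = "")
  }, "")
  names(counts) <- patterns
  structure(list(k = k, counts = counts, n_pixels = sum(counts),
                 channel_names = channel_names, thresholds = thresholds),
            class = "occupancy_table")
}

#' Marginal occupied count of one channel in an occupancy table
#' @param table an [build_occupancy_table()] result.
#' @param channel channel position (1-based).
#' @return Number of valid pixels occupied in that channel.
#' @export
marginal_occupied <- function(table, channel) {
  bit <- substr(names(table$counts), channel, channel) == "1"
  sum(table$counts[bit])
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("occupancy_table: k =", x$k, ", n_pixels =", x$n_pixels, "\n")
  print(x$counts)
  invisible(x)
}

#' Occupancy table as a data.frame
#' @param x an `occupancy_table`.
#' @param ... unused.
#' @return data.frame with one row per occupancy pattern.
#' @export
as.data.frame.occupancy_table <- function(x, ...) {
  df <- data.frame(pattern = names(x$counts), count = as.integer(x$counts),
                   stringsAsFactors = FALSE)
  for (c_i in seq_len(x$k)) {
    df[[x$channel_names[c_i]]] <- substr(df$pattern, c_i, c_i) == "1"
  }
  df
}

#' Chi-squared test of mutual independence of channel occupancies
#'
#' Tests whether the joint occupancy distribution over `2^k` cells factors
#' into the product of the per-channel marginal occupancy probabilities.
#' Expected counts are formed from the empirical marginals; the statistic
#' is `sum((obs - exp)^2 / exp)` over all cells with `2^k - 1 - k` degrees
#' of freedom (cells minus one, minus the k estimated marginals), and the
#' p-value comes from the upper chi-squared tail.
#'
#' Pixels are treated as independent observations, as is conventional for
#' this analysis; with diffraction-blurred images neighbouring pixels are
#' correlated, so `n_pixels` overstates the effective sample size and
#' p-values are anti-conservative. The result records `n_pixels` so users
#' can judge this.
#'
#' @param table an [build_occupancy_table()] result.
#' @param expected_floor cells with expected count below this (default 1)
#'   are flagged in the result as unreliable for the asymptotic
#'   approximation.
#' @return Object of class `chi2_independence`: `statistic`, `df`,
#'   `p_value`, `observed`, `expected`, `n_pixels`, `min_expected`,
#'   `low_expected_cells`.
#' @export
chi2_mutual_independence <- function(table, expected_floor = 1) {
  stopifnot(inherits(table, "occupancy_table"))
  n <- table$n_pixels
  if (n <= 0) stop("degenerate input: empty occupancy table")
  k <- table$k
  p_marg <- vapply(seq_len(k), function(c_i) marginal_occupied(table, c_i) / n,
                   0)
  if (any(p_marg == 0) || any(p_marg == 1)) {
    stop("degenerate input: a channel has zero marginal occupancy or non-occupancy")
  }
  expected <- vapply(names(table$counts), function(pat) {
    bits <- as.integer(strsplit(pat, "")[[1]])
    n * prod(ifelse(bits == 1, p_marg, 1 - p_marg))
  }, 0)
  statistic <- sum((table$counts - expected)^2 / expected)
  df <- 2^k - 1 - k
  low <- sum(expected < expected_floor)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 observed = table$counts, expected = expected,
                 n_pixels = n, min_expected = min(expected),
                 low_expected_cells = low),
            class = "chi2_independence")
}

#' @export
print.chi2_independence <- function(x, ...) {
  cat(sprintf("chi-squared mutual independence: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("  n_pixels =", x$n_pixels,
      "(pixels treated as independent observations)\n")
  if (x$low_expected_cells > 0) {
    cat("  warning:", x$low_expected_cells,
        "cells with expected count below the reliability floor\n")
  }
  invisible(x)
}

default_subsets <- function(k) {
  pairs <- utils::combn(k, 2, simplify = FALSE)
  if (k > 2) c(pairs, list(seq_len(k))) else pairs
}

#' Exceedance-ratio curves over a threshold sweep
#'
#' For each percentile `p` of the sweep grid, every channel is thresholded
#' at its own `p`-quantile (fraction `p` of pixels below threshold), and
#' for each channel subset the exceedance ratio is computed: the observed
#' joint-occupancy probability divided by the product of the subset's
#' marginal occupancy probabilities. Under mutual independence the ratio
#' is 1; colocalized channels exceed 1, increasingly so at stringent
#' (high-percentile) thresholds. Ratios are recorded as missing (`NA`)
#' wherever a marginal occupancy is zero.
#'
#' @param images list of `k` intensity matrices, one per channel.
#' @param percentiles sweep grid in (0, 1); default 1% to 95% in
#'   1-percentage-point steps.
#' @param subsets list of integer channel subsets (size >= 2); default all
#'   pairs plus the full set.
#' @param valid optional logical validity mask.
#' @param channel_names optional channel labels.
#' @return Object of class `exceedance_curve` wrapping a long-format
#'   data.frame `curve` with columns `percentile`, `subset`, `observed`,
#'   `expected`, `ratio`.
#' @export
exceedance_sweep <- function(images, percentiles = seq(0.01, 0.95, by = 0.01),
                             subsets = NULL, valid = NULL,
                             channel_names = NULL) {
  k <- length(images)
  if (k < 2) stop("parameter error: need at least 2 channels")
  shape <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shape), TRUE))) {
    stop("validation error: channel images must share shape")
  }
  if (any(percentiles <= 0 | percentiles >= 1)) {
    stop("parameter error: percentiles must lie strictly in (0, 1)")
  }
  if (is.null(subsets)) subsets <- default_subsets(k)
  if (!length(subsets)) stop("parameter error: empty subset list")
  if (any(lengths(subsets) < 2)) stop("parameter error: subsets must have size >= 2")
  if (is.null(valid)) valid <- array(TRUE, dim = shape)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(k))
  vals <- lapply(images, function(im) im[valid])
  n <- length(vals[[1]])
  rows <- vector("list", length(percentiles) * length(subsets))
  ri <- 1L
  for (p in percentiles) {
    occ <- lapply(seq_len(k), function(c_i) {
      t <- percentile_threshold(vals[[c_i]], p)
      vals[[c_i]] >= t
    })
    p_marg <- vapply(occ, mean, 0)
    for (s in subsets) {
      joint <- Reduce(`&`, occ[s])
      p_joint <- mean(joint)
      p_exp <- prod(p_marg[s])
      ratio <- if (any(p_marg[s] == 0)) NA_real_ else p_joint / p_exp
      rows[[ri]] <- data.frame(
        percentile = p,
        subset = paste(channel_names[s], collapse = "+"),
        observed = p_joint, expected = p_exp, ratio = ratio,
        stringsAsFactors = FALSE)
      ri <- ri + 1L
    }
  }
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, percentiles = percentiles, subsets = subsets,
                 channel_names = channel_names, n_pixels = n),
            class = "exceedance_curve")
}

#' @export
print.exceedance_curve <- function(x, ...) {
  cat("exceedance_curve:", length(x$percentiles), "percentiles x",
      length(x$subsets), "subsets over", x$n_pixels, "pixels\n")
  invisible(x)
}
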