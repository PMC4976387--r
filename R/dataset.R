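dataset_key <- function(round, channel) paste0(round, ":", channel)

#' Multi-round, multi-channel image collection
#'
#' The central container: a set of 2-D non-negative intensity images
#' indexed by `(round, channel)`. All images must share one shape, round
#' indices must be contiguous from 1, and each `(round, channel)` pair must
#' be unique. Intensities are held as doubles; file readers promote
#' unsigned integer pixel data at this boundary.
#'
#' @param images named list of numeric matrices with names
#'   `"<round>:<channel>"` (see `dataset_key`), or a list as produced by
#'   [simulate_dataset()].
#' @param pixel_size optional physical pixel size (e.g. micrometres).
#' @param labels optional named character vector mapping channel name to
#'   antibody/protein label.
#' @return An object of class `multiround_dataset` with elements `images`,
#'   `rounds`, `channels`, `shape`, `pixel_size`, `labels`.
#' @export
multiround_dataset <- function(images, pixel_size = NULL, labels = NULL) {
  if (!length(images) || is.null(names(images))) {
    stop("images must be a non-empty named list keyed '<round>:<channel>'")
  }
  if (anyDuplicated(names(images))) {
    stop("duplicate (round, channel) keys: ",
         paste(unique(names(images)[duplicated(names(images))]), collapse = ", "))
  }
  parts <- strsplit(names(images), ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed image key; expected '<round>:<channel>'")
  rounds <- as.integer(vapply(parts, `[`, "", 1))
  channels <- vapply(parts, `[`, "", 2)
  if (any(is.na(rounds)) || !setequal(unique(rounds), seq_len(max(rounds)))) {
    stop("round indices must be contiguous integers starting at 1")
  }
  shapes <- lapply(images, dim)
  if (any(vapply(shapes, length, 0L) != 2)) stop("all images must be 2-D matrices")
  shape <- shapes[[1]]
  bad <- names(images)[!vapply(shapes, identical, TRUE, shape)]
  if (length(bad)) {
    stop("image shape mismatch for entries: ", paste(bad, collapse = ", "))
  }
  images <- lapply(images, function(im) { storage.mode(im) <- "double"; im })
  structure(list(images = images,
                 rounds = sort(unique(rounds)),
                 channels = unique(channels),
                 shape = shape,
                 pixel_size = pixel_size,
                 labels = labels),
            class = "multiround_dataset")
}

#' Fetch one image from a dataset
#' @param dataset a [multiround_dataset()].
#' @param round round index (1-based).
#' @param channel channel name.
#' @return Numeric intensity matrix.
#' @export
get_image <- function(dataset, round, channel) {
  key <- dataset_key(round, channel)
  img <- dataset$images[[key]]
  if (is.null(img)) stop("no image for round ", round, ", channel '", channel, "'")
  img
}

#' @export
print.multiround_dataset <- function(x, ...) {
  cat("multiround_dataset:", length(x$images), "images,",
      length(x$rounds), "rounds x", length(x$channels), "channels,",
      paste(x$shape, collapse = "x"), "px\n")
  invisible(x)
}

#' Write a dataset as multi-page TIFFs plus a manifest
#'
#' One 16-bit grayscale multi-page TIFF per round (one page per channel, in
#' channel order) and a tab-separated manifest with columns
#' `file, page, round, channel, label` (pages 1-based). Intensities are
#' clipped to `[0, 65535]` and rounded to integers on write.
#'
#' @param dataset a [multiround_dataset()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the per-round TIFFs.
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, basename = "round") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in dataset$rounds) {
    fname <- sprintf("%s_%02d.tif", basename, r)
    pages <- list()
    for (i in seq_along(dataset$channels)) {
      ch <- dataset$channels[i]
      img <- round(pmin(pmax(get_image(dataset, r, ch), 0), 65535))
      pages[[i]] <- img / 65535
      lab <- if (!is.null(dataset$labels) && ch %in% names(dataset$labels)) {
        dataset$labels[[ch]]
      } else ch
      rows[[length(rows) + 1]] <- data.frame(
        file = fname, page = i, round = r, channel = ch, label = lab,
        stringsAsFactors = FALSE)
    }
    tiff::writeTIFF(pages, file.path(dir, fname), bits.per.sample = 16L)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Read a dataset from a manifest
#'
#' Loads the images referenced by a tab-separated manifest
#' (`file, page, round, channel, label`; paths relative to the manifest's
#' directory; pages 1-based). Pixel data are read as stored (no rescaling)
#' and promoted to doubles. Shape consistency across all entries is
#' enforced.
#'
#' @param manifest_path path to the manifest file.
#' @return A [multiround_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  need <- c("file", "page", "round", "channel")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  images <- list()
  labels <- character(0)
  cache <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    path <- file.path(base, entry$file)
    if (!file.exists(path)) {
      stop("I/O error: file missing for manifest entry ", i, ": ", entry$file)
    }
    if (is.null(cache[[path]])) {
      pg <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      cache[[path]] <- pg
    }
    pages <- cache[[path]]
    if (entry$page < 1 || entry$page > length(pages)) {
      stop("I/O error: page ", entry$page, " missing in ", entry$file,
           " (manifest entry ", i, ")")
    }
    img <- pages[[entry$page]]
    storage.mode(img) <- "double"
    images[[dataset_key(entry$round, entry$channel)]] <- img
    if ("label" %in% names(entry)) labels[[as.character(entry$channel)]] <- entry$label
  }
  multiround_dataset(images, labels = if (length(labels)) labels else NULL)
}

#' Write a results table as CSV
#'
#' Comma-separated with a header row; floating-point columns are written at
#' full double precision so a re-read reproduces values to better than
#' 1e-12 relative.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE)
      }, "")
    }
  }
  utils::write.table(out, path, sep = ",", quote = TRUE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
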