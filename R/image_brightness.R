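#' Read an image as an 8-bit grayscale matrix
#'
#' Reads PNG or TIFF (8- or 16-bit, gray or RGB; JPEG when the EBImage
#' package is available), collapses colour channels with the Rec. 601
#' luminance weighting (0.299 R + 0.587 G + 0.114 B), and quantises to
#' integer intensities 0..255. An image that is already 8-bit grayscale is
#' returned unchanged.
#'
#' @param image Either a file path, or a numeric matrix/array: values in
#'   \[0, 1\] (as returned by [png::readPNG()]/[tiff::readTIFF()]) or integer
#'   intensities 0..255; a third array dimension holds colour channels.
#' @return Integer matrix of intensities in 0..255.
#' @export
to_gray8 <- function(image) {
  if (is.character(image)) {
    image <- read_image_array(image)
  }
  if (!is.numeric(image) || length(image) == 0) {
    stop("Image I/O error: unreadable or zero-size image.", call. = FALSE)
  }
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc >= 3) {
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else {
      image <- image[, , 1]  # gray (+alpha) stored as array
    }
  }
  if (is.null(dim(image))) dim(image) <- c(1, length(image))
  mx <- max(image)
  if (mx <= 1 && !all(image == round(image))) {
    image <- image * 255
  } else if (mx <= 1) {
    # 0/1-valued: treat as normalised intensities unless integer-coded
    image <- image * 255
  }
  out <- pmin(pmax(round(image), 0), 255)
  storage.mode(out) <- "integer"
  out
}

read_image_array <- function(path) {
  if (!file.exists(path)) {
    stop("Image I/O error: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) return(tiff::readTIFF(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("Reading JPEG requires the EBImage package.", call. = FALSE)
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x-by-y; transpose to row-by-column like png/tiff readers
    if (length(dim(img)) == 2) return(t(img))
    return(aperm(img, c(2, 1, 3)))
  }
  stop("Image I/O error: unsupported image format: .", ext, call. = FALSE)
}

#' Pixel-intensity distribution of an 8-bit image
#'
#' Tabulates the 256-bin histogram of intensities, optionally after removing
#' the dark background with [background_cutoff()].
#'
#' @param gray8 Integer matrix of intensities 0..255 (see [to_gray8()]), or a
#'   file path.
#' @param cutoff Optional background cutoff applied immediately (see
#'   [background_cutoff()]); `NULL` for none.
#' @return An object of class `intensity_distribution`: list with `counts`
#'   (integer vector of length 256 for intensities 0..255), `cutoff` (applied
#'   threshold or 0) and `n_pixels`.
#' @export
intensity_distribution <- function(gray8, cutoff = NULL) {
  if (is.character(gray8)) gray8 <- to_gray8(gray8)
  v <- as.integer(gray8)
  if (length(v) == 0) stop("Image I/O error: empty image.", call. = FALSE)
  if (any(v < 0 | v > 255)) {
    stop("Intensities must lie in 0..255; call to_gray8() first.",
         call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  dist <- structure(
    list(counts = counts, cutoff = 0L, n_pixels = sum(counts)),
    class = "intensity_distribution"
  )
  if (!is.null(cutoff)) dist <- background_cutoff(dist, cutoff) else dist
}

#' @export
print.intensity_distribution <- function(x, ...) {
  cat("<intensity_distribution> ", x$n_pixels, " pixels, cutoff ", x$cutoff,
      "\n", sep = "")
  invisible(x)
}

#' Discard dark background pixels from an intensity distribution
#'
#' Pixels darker than the threshold are treated as black background and
#' removed from the histogram. The default threshold of 60 matches a typical
#' pale-object-on-black-cloth photographic setup; it was derived empirically
#' for one lighting rig, so it is exposed as a parameter.
#'
#' @param dist An `intensity_distribution`.
#' @param threshold Integer in 0..255; bins strictly below it are zeroed.
#' @return The filtered `intensity_distribution` (with `cutoff` and
#'   `n_pixels` updated).
#' @export
background_cutoff <- function(dist, threshold = 60) {
  stopifnot(inherits(dist, "intensity_distribution"))
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in 0..255.", call. = FALSE)
  }
  thr <- as.integer(threshold)
  counts <- dist$counts
  if (thr > 0) counts[seq_len(thr)] <- 0L
  n <- sum(counts)
  if (n == 0) {
    stop("Empty foreground: all pixels fall below the cutoff (",
         thr, ").", call. = FALSE)
  }
  structure(list(counts = counts, cutoff = max(thr, dist$cutoff),
                 n_pixels = n),
            class = "intensity_distribution")
}

#' Pearson mode skewness of an intensity distribution
#'
#' Computes `(mean - mode) / sd` of the retained pixel intensities. The mode
#' is the intensity value of the maximal histogram bin (bin width 1; ties are
#' broken toward the lowest intensity, deterministically). The standard
#' deviation is the population (divide-by-n) one. A pale, earlywood-dominated
#' disc has its mode above the mean, hence a negative mode skewness.
#'
#' @param dist An `intensity_distribution` (or an integer gray8 matrix /
#'   image path, converted on the fly).
#' @return A single number; attributes `mean`, `mode`, `sd`, `n_pixels`
#'   record the ingredients.
#' @export
mode_skewness <- function(dist) {
  if (!inherits(dist, "intensity_distribution")) {
    dist <- intensity_distribution(dist)
  }
  n <- dist$n_pixels
  if (n == 0) stop("Empty foreground: no pixels retained.", call. = FALSE)
  if (n < 2) stop("Need at least 2 pixels.", call. = FALSE)
  vals <- 0:255
  cnt <- dist$counts
  mu <- sum(vals * cnt) / n
  sd_pop <- sqrt(sum(cnt * (vals - mu)^2) / n)
  if (sd_pop == 0) {
    stop("Undefined skewness: intensity distribution has zero variance.",
         call. = FALSE)
  }
  mode_val <- vals[which.max(cnt)]  # which.max -> first (lowest) on ties
  structure((mu - mode_val) / sd_pop,
            mean = mu, mode = mode_val, sd = sd_pop, n_pixels = n)
}

#' Mode skewness of a specimen photograph
#'
#' End-to-end brightness statistic for one image: convert to 8-bit gray,
#' drop the dark background, and compute the Pearson mode skewness of the
#' remaining (foreground) pixel intensities.
#'
#' @param image File path or gray8 matrix (see [to_gray8()]).
#' @param cutoff Background intensity cutoff (default 60).
#' @return One-row tibble: `n_pixels`, `mean`, `mode`, `sd`, `mode_skewness`,
#'   `cutoff`, `sd_convention` ("population").
#' @export
image_mode_skewness <- function(image, cutoff = 60) {
  dist <- intensity_distribution(to_gray8(image), cutoff = cutoff)
  ms <- mode_skewness(dist)
  tibble::tibble(
    n_pixels = attr(ms, "n_pixels"),
    mean = attr(ms, "mean"),
    mode = attr(ms, "mode"),
    sd = attr(ms, "sd"),
    mode_skewness = as.numeric(ms),
    cutoff = dist$cutoff,
    sd_convention = "population"
  )
}

#' Brightness statistics for a batch of specimen photographs
#'
#' @param paths Character vector of image paths.
#' @param specimen_id Ids to attach (defaults to file names sans extension).
#' @param cutoff Background intensity cutoff (default 60).
#' @return Tibble with one row per image: `specimen_id` plus the columns of
#'   [image_mode_skewness()].
#' @export
image_brightness_table <- function(paths, specimen_id = NULL, cutoff = 60) {
  if (is.null(specimen_id)) {
    specimen_id <- tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(specimen_id) == length(paths))
  purrr::map2_dfr(paths, specimen_id, function(p, id) {
    dplyr::bind_cols(tibble::tibble(specimen_id = id),
                     image_mode_skewness(p, cutoff = cutoff))
  })
}
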