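#' Convert a raster image to a grayscale stimulus matrix
#'
#' Stimuli are represented throughout the package as plain numeric matrices
#' with intensities in \[0, 255\] (rows = image rows). `preprocess_image()`
#' accepts a matrix (already grayscale) or a 3-d array with 1, 3 or 4
#' channels (RGBA alpha is dropped), converts to grayscale with the
#' Rec. 601 luminance weights (0.299, 0.587, 0.114) and, if `target_size`
#' is given, resamples with bilinear interpolation.
#'
#' @param raw numeric matrix (H x W) or array (H x W x channels) with
#'   intensities either in \[0, 1\] (as returned by [png::readPNG()]) or in
#'   \[0, 255\]. Values in \[0, 1\] are rescaled to \[0, 255\].
#' @param target_size integer vector `c(H, W)` or `NULL` to keep the
#'   native size.
#' @return numeric matrix (H x W) with values in \[0, 255\].
#' @examples
#' img <- matrix(runif(64, 0, 255), 8, 8)
#' small <- preprocess_image(img, target_size = c(4, 4))
#' dim(small)
#' @export
preprocess_image <- function(raw, target_size = NULL) {
  if (is.matrix(raw)) {
    img <- raw
  } else if (is.array(raw) && length(dim(raw)) == 3L) {
    nc <- dim(raw)[3L]
    if (nc == 1L) {
      img <- raw[, , 1L]
    } else if (nc == 3L || nc == 4L) {
      img <- 0.299 * raw[, , 1L] + 0.587 * raw[, , 2L] + 0.114 * raw[, , 3L]
    } else {
      stop("unsupported channel count: ", nc, " (expected 1, 3 or 4)")
    }
  } else {
    stop("`raw` must be a matrix or a 3-d array")
  }
  if (!all(is.finite(img))) stop("image contains non-finite values")
  # readPNG/readTIFF return [0,1]; rescale so downstream thresholds
  # (spike threshold 50) see the nominal 8-bit range
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  if (!is.null(target_size)) {
    target_size <- as.integer(target_size)
    if (!all(dim(img) == target_size)) {
      img <- bilinear_resize(img, target_size[1L], target_size[2L])
    }
  }
  img
}

#' Bilinear image resampling
#'
#' Center-aligned bilinear interpolation, the conventional default for
#' image downsampling. Exposed because trial images of mixed sizes must be
#' brought to a common grid before feature extraction.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @return numeric matrix `out_h` x `out_w`.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(out_h >= 1, out_w >= 1)
  # source coordinates of output pixel centers
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (a * (1 - wy) + c_ * wy) * (1 - wx) + (b * (1 - wy) + d * wy) * wx
}

#' Read all raster images in a directory as stimuli
#'
#' Files are taken in C-locale lexicographic filename order, which defines
#' the trial order; name files with zero-padded indices. PNG and TIFF are
#' supported.
#'
#' @param path directory containing `.png` / `.tif` / `.tiff` files.
#' @param target_size optional `c(H, W)` passed to [preprocess_image()].
#' @return list of stimulus matrices, named by filename.
#' @export
load_image_dir <- function(path, target_size = NULL) {
  if (!dir.exists(path)) stop("directory does not exist: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- sort(files, method = "radix")  # locale-independent order
  out <- vector("list", length(files))
  names(out) <- files
  for (k in seq_along(files)) {
    f <- file.path(path, files[k])
    ext <- tolower(sub(".*\\.", "", f))
    raw <- tryCatch(
      if (ext == "png") png::readPNG(f) else tiff::readTIFF(f),
      error = function(e) stop("unreadable image file ", files[k], ": ",
                               conditionMessage(e)))
    out[[k]] <- preprocess_image(raw, target_size)
  }
  out
}

#' Write stimuli to PNG files
#'
#' Inverse of [load_image_dir()]: writes each matrix (values in
#' \[0, 255\]) as an 8-bit grayscale PNG named `stim_0001.png`, ... so the
#' lexicographic order equals the list order.
#'
#' @param stimuli list of stimulus matrices.
#' @param path output directory (created if missing).
#' @return invisibly, the file paths written.
#' @export
write_stimuli <- function(stimuli, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- character(length(stimuli))
  for (k in seq_along(stimuli)) {
    paths[k] <- file.path(path, sprintf("stim_%04d.png", k))
    img <- pmin(pmax(stimuli[[k]] / 255, 0), 1)
    png::writePNG(img, paths[k])
  }
  invisible(paths)
}
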