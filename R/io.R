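#' Read a grayscale image from PNG or TIFF
#'
#' Images are represented throughout the package as plain numeric matrices
#' with rows indexing y (top to bottom) and columns indexing x. Pixel
#' coordinates are 0-based with pixel centers at integer positions, so the
#' intensity at coordinate (x, y) is `img[y + 1, x + 1]`.
#'
#' RGB input is collapsed to grayscale by the unweighted channel mean; an
#' alpha channel, if present, is ignored. Integer sample values are kept on
#' their native scale (an 8-bit PNG yields values in 0..255, a 16-bit image
#' values in 0..65535): the descriptor is invariant to affine intensity maps,
#' so no rescaling is applied on load.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix of intensities.
#' @export
lpm_load_image <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("cannot read image file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    arr <- arr * (2^png_bit_depth(path) - 1)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(arr)) stop("multi-page TIFF stacks are not supported")
    storage.mode(arr) <- "double"
  } else {
    stop("unsupported image format (need PNG or TIFF): ", path)
  }
  img <- collapse_gray(arr)
  validate_image(img)
  img
}

# Bit depth of a PNG from the IHDR chunk (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25)
  if (length(hdr) < 25) stop("truncated PNG file: ", path)
  as.integer(hdr[25])
}

collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr + 0)
  nc <- dim(arr)[3]
  if (nc >= 3) {
    (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  } else {
    arr[, , 1]
  }
}

validate_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a numeric matrix")
  if (nrow(img) < 1 || ncol(img) < 1) stop("zero-sized image")
  if (any(!is.finite(img))) stop("image contains non-finite intensities")
  invisible(img)
}

#' Write an image matrix to a PNG file
#'
#' Intensities are divided by `max_value` and clamped to [0, 1] before
#' encoding (8 bits per sample).
#'
#' @param img numeric matrix.
#' @param path output path.
#' @param max_value intensity mapped to white.
#' @export
lpm_write_image <- function(img, path, max_value = 255) {
  validate_image(img)
  png::writePNG(pmin(pmax(img / max_value, 0), 1), target = path)
  invisible(path)
}

#' Gaussian pre-smoothing of an input image
#'
#' The only pre-computation the descriptor pipeline performs: convolution
#' with a Gaussian of variance 1 (sigma = 1 by default), kernel truncated at
#' 4 sigma, reflective boundary handling. Both detection and description run
#' on the smoothed image.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the smoothing kernel, in pixels.
#' @return smoothed image, same dimensions.
#' @export
lpm_presmooth <- function(img, sigma = 1) {
  validate_image(img)
  smooth_gaussian(img, sigma)
}

#' Read and write feature lists
#'
#' Features are stored as CSV with header `x,y,radius`; coordinates are
#' 0-based pixel coordinates of the feature center (x = column, y = row) and
#' the radius is in pixels. `lpm_read_features` reports malformed rows with
#' their line number; a non-positive radius is rejected.
#'
#' @param features data frame with columns x, y, radius.
#' @param path CSV path.
#' @return `lpm_read_features`: data frame with columns x, y, radius, source.
#' @export
lpm_write_features <- function(features, path) {
  stopifnot(all(c("x", "y", "radius") %in% names(features)))
  utils::write.csv(features[, c("x", "y", "radius")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lpm_write_features
#' @param source provenance tag attached to the features read.
#' @export
lpm_read_features <- function(path, source = "external") {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty features file: ", path)
  hdr <- tolower(gsub("[[:space:]]", "", lines[1]))
  if (hdr != "x,y,radius") stop("features file must have header 'x,y,radius': ", path)
  n <- length(lines) - 1L
  out <- data.frame(x = numeric(n), y = numeric(n), radius = numeric(n))
  for (i in seq_len(n)) {
    ln <- lines[i + 1L]
    if (!nzchar(trimws(ln))) stop("parse error at line ", i + 1L, ": empty row")
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3 || any(!is.finite(vals))) {
      stop("parse error at line ", i + 1L, ": expected 3 numeric fields")
    }
    if (vals[3] <= 0) stop("parse error at line ", i + 1L, ": radius must be > 0")
    out[i, ] <- vals
  }
  out$source <- source
  out
}

#' Read and write match tables
#'
#' Matches are stored as CSV with header `x1,y1,x2,y2,distance,is_inlier`
#' holding the matched feature centers in the two image frames, the
#' descriptor-space squared distance, and a 0/1 inlier flag (0 before
#' verification).
#'
#' @param matches data frame with the six columns above.
#' @param path CSV path.
#' @export
lpm_write_matches <- function(matches, path) {
  cols <- c("x1", "y1", "x2", "y2", "distance", "is_inlier")
  stopifnot(all(cols %in% names(matches)))
  utils::write.csv(matches[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lpm_write_matches
#' @export
lpm_read_matches <- function(path) {
  m <- utils::read.csv(path)
  cols <- c("x1", "y1", "x2", "y2", "distance", "is_inlier")
  if (!all(cols %in% names(m))) stop("matches file must have columns ", paste(cols, collapse = ","))
  m
}

#' Read and write a homography
#'
#' Stored as 9 whitespace-separated numbers, row-major, in a plain text file.
#'
#' @param H 3x3 matrix.
#' @param path text file path.
#' @export
lpm_write_homography <- function(H, path) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  cat(sprintf("%.17g", as.vector(t(H))), file = path, sep = " ")
  cat("\n", file = path, append = TRUE)
  invisible(path)
}

#' @rdname lpm_write_homography
#' @export
lpm_read_homography <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 9) stop("homography file must contain exactly 9 numbers")
  matrix(v, 3, 3, byrow = TRUE)
}
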