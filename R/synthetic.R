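#' Seeded synthetic texture generator
#'
#' Generates test images with known content so every pipeline stage is
#' testable without external data:
#'
#' * `"blobs"`: 30-80 Gaussian spots with random widths (sigma in 2-6 px)
#'   and amplitudes on a dark background, emulating the bright dots of
#'   fluorescence micrographs. Spot centers are placed on a jittered grid so
#'   that spots stay separated and remain distinct local maxima; on very
#'   small images fewer spots than requested may fit.
#' * `"ramp_blobs"`: the same with an added horizontal intensity ramp.
#' * `"noise"`: white Gaussian noise low-pass filtered at sigma = 2 and
#'   stretched to 0-255, emulating band-limited transmission electron
#'   microscopy texture.
#'
#' Regeneration with the same seed is bit-identical; the caller's RNG state
#' is untouched.
#'
#' @param size image side length in pixels (>= 64); images are square.
#' @param kind texture family.
#' @param seed integer seed.
#' @return numeric `size` x `size` matrix with intensities roughly in 0-255.
#'   For blob textures the spot centers are attached as attribute `centers`
#'   (data frame x, y, sigma).
#' @export
lpm_make_texture <- function(size = 256, kind = c("blobs", "ramp_blobs", "noise"),
                             seed = 0) {
  kind <- match.arg(kind)
  if (size < 64) stop("texture size must be >= 64")
  with_seed(seed, {
    if (kind == "noise") {
      img <- smooth_gaussian(matrix(stats::rnorm(size * size), size, size), 2)
      img <- (img - min(img)) / (max(img) - min(img)) * 255
      return(img)
    }
    nb <- sample(30:80, 1)
    cell <- 24   # spots >= 16 px apart stay distinct local maxima for sigma <= 6
    margin <- 10
    ncell <- floor((size - 2 * margin) / cell)
    cells <- sample.int(ncell * ncell, min(nb, ncell * ncell))
    crow <- (cells - 1) %% ncell
    ccol <- (cells - 1) %/% ncell
    jit <- 4
    cx <- margin + ccol * cell + cell / 2 + stats::runif(length(cells), -jit, jit)
    cy <- margin + crow * cell + cell / 2 + stats::runif(length(cells), -jit, jit)
    sg <- stats::runif(length(cells), 2, 6)
    amp <- stats::runif(length(cells), 120, 255)
    img <- matrix(10, size, size)
    for (b in seq_along(cx)) {
      r <- ceiling(4 * sg[b])
      xs <- max(0, floor(cx[b] - r)):min(size - 1, ceiling(cx[b] + r))
      ys <- max(0, floor(cy[b] - r)):min(size - 1, ceiling(cy[b] + r))
      g <- outer(exp(-(ys - cy[b])^2 / (2 * sg[b]^2)),
                 exp(-(xs - cx[b])^2 / (2 * sg[b]^2)))
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp[b] * g
    }
    if (kind == "ramp_blobs") {
      img <- img + matrix(rep(0:(size - 1), each = size), size, size) * (100 / (size - 1))
    }
    attr(img, "centers") <- data.frame(x = cx, y = cy, sigma = sg)
    img
  })
}

# Similarity transform about the image center composed with a translation,
# as a 3x3 homography mapping source (A) coordinates to destination (B).
similarity_homography <- function(dim, theta = 0, scale = 1, translation = c(0, 0)) {
  cx <- (dim[2] - 1) / 2
  cy <- (dim[1] - 1) / 2
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  S <- diag(c(scale, scale, 1))
  T1 <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  T2 <- matrix(c(1, 0, cx + translation[1],
                 0, 1, cy + translation[2],
                 0, 0, 1), 3, 3, byrow = TRUE)
  T2 %*% S %*% R %*% T1
}

#' Synthetic image pair with ground-truth homography
#'
#' Renders a transformed copy of `base` under a similarity transform
#' (rotation `theta` about the image center, isotropic `scale`, then
#' `translation`), followed by an affine intensity map `gain * I + offset`,
#' optional Gaussian blur and additive Gaussian noise. The exact ground-truth
#' homography H mapping A (base) coordinates to B coordinates is returned
#' with the pair. Warping uses bicubic interpolation with inverse mapping;
#' an identity geometric transform reproduces the base image bit-exactly.
#'
#' Planted features default to the base texture's blob centers (radius 32),
#' filtered to those describable in A and whose H-image lands inside B, so
#' the planted list is guaranteed consistent with the pair. `planted_b`
#' additionally gives the matching ideal detections in the B frame - mapped
#' centers with radii scaled by the zoom factor - emulating a perfect
#' scale-reporting external detector, which is how descriptor behaviour can
#' be isolated from detector behaviour under scale changes.
#'
#' @param base numeric matrix, e.g. from [lpm_make_texture()].
#' @param theta rotation angle in radians.
#' @param scale isotropic scale factor.
#' @param translation length-2 vector (tx, ty) in pixels.
#' @param gain,offset affine intensity map applied to the warped image.
#' @param blur Gaussian blur sigma in pixels (0 = none).
#' @param noise additive Gaussian noise sigma in intensity units (0 = none).
#' @param seed seed for the noise.
#' @param planted optional feature data frame overriding the default.
#' @return object of class `lpm_pair`: list with `img_a`, `img_b`, `H`,
#'   `planted`, `seed` and the transform parameters.
#' @export
lpm_make_pair <- function(base, theta = 0, scale = 1, translation = c(0, 0),
                          gain = 1, offset = 0, blur = 0, noise = 0, seed = 0,
                          planted = NULL) {
  validate_image(matrix(as.vector(base), nrow(base), ncol(base)))
  H <- similarity_homography(dim(base), theta, scale, translation)
  # visibility precondition: at least half of A must land inside B's frame
  step <- 4
  gx <- seq(0, ncol(base) - 1, by = step)
  gy <- seq(0, nrow(base) - 1, by = step)
  p <- project_points(H, cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx))))
  frac <- mean(p[, 1] >= 0 & p[, 1] <= ncol(base) - 1 &
                 p[, 2] >= 0 & p[, 2] <= nrow(base) - 1)
  if (frac < 0.5) {
    stop("transform leaves less than 50% of the source image visible")
  }
  identity_geom <- theta == 0 && scale == 1 && all(translation == 0)
  img_b <- if (identity_geom) {
    matrix(as.vector(base), nrow(base), ncol(base))
  } else {
    warp_image(base, H, dim(base))
  }
  img_b <- gain * img_b + offset
  if (blur > 0) img_b <- smooth_gaussian(img_b, blur)
  if (noise > 0) {
    img_b <- img_b + with_seed(seed, matrix(stats::rnorm(length(img_b), 0, noise),
                                            nrow(img_b), ncol(img_b)))
  }
  if (is.null(planted)) {
    ctr <- attr(base, "centers")
    if (!is.null(ctr)) {
      planted <- data.frame(x = ctr$x, y = ctr$y, radius = 32, source = "planted")
      planted <- lpm_remove_border_features(planted, base)
      if (nrow(planted) > 0) {
        q <- project_points(H, cbind(planted$x, planted$y))
        keep <- q[, 1] >= 0 & q[, 1] <= ncol(base) - 1 &
          q[, 2] >= 0 & q[, 2] <= nrow(base) - 1
        planted <- planted[keep, , drop = FALSE]
      }
    }
  }
  # ideal scale-aware detections in the B frame: what a perfect external
  # detector would report (mapped centers, radii following the zoom)
  planted_b <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    q <- project_points(H, cbind(planted$x, planted$y))
    planted_b <- data.frame(x = q[, 1], y = q[, 2],
                            radius = planted$radius * scale,
                            source = "planted")
    planted_b <- planted_b[planted_b$radius >= 1, , drop = FALSE]
    planted_b <- lpm_remove_border_features(planted_b, img_b)
  }
  img_a <- matrix(as.vector(base), nrow(base), ncol(base))
  structure(list(img_a = img_a, img_b = img_b, H = H, planted = planted,
                 planted_b = planted_b, seed = seed,
                 transform = list(theta = theta, scale = scale,
                                  translation = translation, gain = gain,
                                  offset = offset, blur = blur, noise = noise)),
            class = "lpm_pair")
}

#' @export
print.lpm_pair <- function(x, ...) {
  cat(sprintf("synthetic pair %dx%d: theta=%.3f scale=%.3f t=(%g,%g) gain=%g offset=%g blur=%g noise=%g\n",
              nrow(x$img_a), ncol(x$img_a), x$transform$theta, x$transform$scale,
              x$transform$translation[1], x$transform$translation[2],
              x$transform$gain, x$transform$offset, x$transform$blur,
              x$transform$noise))
  invisible(x)
}

#' Bicubic image resizing
#'
#' Resizes by the given factor with Catmull-Rom bicubic interpolation under
#' the coordinate map `x_out = factor * x_in`. A factor of 1 returns the
#' input unchanged.
#'
#' @param img numeric matrix.
#' @param factor positive scale factor.
#' @return resized matrix of dimensions `round(dim(img) * factor)`.
#' @export
lpm_resize <- function(img, factor) {
  stopifnot(factor > 0)
  if (factor == 1) return(img)
  out_dim <- pmax(round(dim(img) * factor), 1)
  warp_image(img, diag(c(factor, factor, 1)), out_dim)
}
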