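#' Built-in feature detectors and external-detector adapter
#'
#' A feature is a circular image region given by its center (0-based pixel
#' coordinates, x = column, y = row) and radius in pixels. The descriptor
#' needs nothing else from a detector, which is what makes it detector
#' independent: any detector's output can be adapted via
#' [lpm_adapt_external()].
#'
#' `lpm_detect_harris` finds local maxima of the Harris corner response
#' (structure-tensor determinant minus k times squared trace, k = 0.04,
#' Gaussian integration sigma = 2) above a relative threshold, non-maximum
#' suppressed in a 5x5 window. `lpm_detect_hessian` does the same for the
#' determinant of the Hessian of the sigma = 2 smoothed image (a blob
#' detector). Maxima are localized to sub-pixel precision by a quadratic fit
#' through the response along each axis. Neither detector estimates a scale:
#' every returned feature carries the fixed radius (default 32 px). Both
#' expect the pre-smoothed image (see [lpm_presmooth()]).
#'
#' @param img numeric matrix (pre-smoothed image).
#' @param max_features keep at most this many strongest responses.
#' @param fixed_radius radius assigned to every feature, in pixels.
#' @param k Harris trace weight.
#' @param integration_sigma Gaussian integration scale for the structure
#'   tensor (Harris) / pre-smoothing scale for the Hessian, in pixels.
#' @param rel_threshold responses below `rel_threshold * max(response)` are
#'   discarded.
#' @return data frame with columns x, y, radius, response, source. A flat
#'   image yields an empty frame, not an error.
#' @export
lpm_detect_harris <- function(img, max_features = 500, fixed_radius = 32,
                              k = 0.04, integration_sigma = 2,
                              rel_threshold = 0.01) {
  validate_image(img)
  gx <- (shift_reflect(img, 0, 1) - shift_reflect(img, 0, -1)) / 2
  gy <- (shift_reflect(img, 1, 0) - shift_reflect(img, -1, 0)) / 2
  sxx <- smooth_gaussian(gx * gx, integration_sigma)
  syy <- smooth_gaussian(gy * gy, integration_sigma)
  sxy <- smooth_gaussian(gx * gy, integration_sigma)
  resp <- sxx * syy - sxy^2 - k * (sxx + syy)^2
  detect_from_response(resp, max_features, fixed_radius, rel_threshold, "harris")
}

#' @rdname lpm_detect_harris
#' @export
lpm_detect_hessian <- function(img, max_features = 500, fixed_radius = 32,
                               integration_sigma = 2, rel_threshold = 0.01) {
  validate_image(img)
  s <- smooth_gaussian(img, integration_sigma)
  lxx <- shift_reflect(s, 0, 1) - 2 * s + shift_reflect(s, 0, -1)
  lyy <- shift_reflect(s, 1, 0) - 2 * s + shift_reflect(s, -1, 0)
  lxy <- (shift_reflect(s, 1, 1) - shift_reflect(s, 1, -1) -
            shift_reflect(s, -1, 1) + shift_reflect(s, -1, -1)) / 4
  resp <- lxx * lyy - lxy^2
  detect_from_response(resp, max_features, fixed_radius, rel_threshold, "hessian")
}

empty_features <- function(source = character(0)) {
  data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
             response = numeric(0), source = character(0))
}

# 5x5 non-maximum suppression and relative thresholding of a response map.
detect_from_response <- function(resp, max_features, fixed_radius,
                                 rel_threshold, source, nms_half = 2) {
  mx <- max(resp)
  if (!is.finite(mx) || mx <= 0) return(empty_features())
  thr <- rel_threshold * mx
  neigh_max <- matrix(-Inf, nrow(resp), ncol(resp))
  for (dy in -nms_half:nms_half) {
    for (dx in -nms_half:nms_half) {
      if (dy == 0 && dx == 0) next
      neigh_max <- pmax(neigh_max, shift_fill(resp, dy, dx, -Inf))
    }
  }
  idx <- which(resp > thr & resp >= neigh_max)
  if (length(idx) == 0) return(empty_features())
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord][seq_len(min(max_features, length(idx)))]
  row <- (idx - 1L) %% nrow(resp) + 1L
  col <- (idx - 1L) %/% nrow(resp) + 1L
  # sub-pixel localization: 1-D quadratic fit through the response along
  # each axis, offset clamped to half a pixel
  off <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    o <- ifelse(abs(den) > 1e-12, 0.5 * (m1 - p1) / den, 0)
    pmin(pmax(o, -0.5), 0.5)
  }
  h <- nrow(resp); w <- ncol(resp)
  rl <- pmax(row - 1L, 1L); rh <- pmin(row + 1L, h)
  cl <- pmax(col - 1L, 1L); ch <- pmin(col + 1L, w)
  dy <- off(resp[cbind(rl, col)], resp[idx], resp[cbind(rh, col)])
  dx <- off(resp[cbind(row, cl)], resp[idx], resp[cbind(row, ch)])
  data.frame(x = col - 1 + dx, y = row - 1 + dy, radius = fixed_radius,
             response = resp[idx], source = source)
}

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_fill <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

#' Adapt externally detected features
#'
#' Converts a table of centers plus detector scale values into features by
#' multiplying each scale by a feature scaling coefficient expressing the
#' detector's scale units in pixels. Suitable defaults are 14 for DoG/SIFT
#' style scales and 9 for Hessian/SURF style scales.
#'
#' @param centers_scales data frame with columns x, y, scale.
#' @param sigma feature scaling coefficient (> 0).
#' @return feature data frame with radius = scale * sigma.
#' @export
lpm_adapt_external <- function(centers_scales, sigma = 14) {
  stopifnot(all(c("x", "y", "scale") %in% names(centers_scales)))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("feature scaling coefficient sigma must be a positive number")
  }
  sc <- centers_scales$scale
  if (any(!is.finite(sc)) || any(sc <= 0)) {
    stop("every external feature scale must be finite and > 0")
  }
  data.frame(x = centers_scales$x, y = centers_scales$y,
             radius = sc * sigma, source = "external")
}

#' Remove features too close to the image borders
#'
#' A feature can only be described if its sampling disc plus the 2 px margin
#' of the 5x5 interpolation mask fits inside the image; features failing
#' `x - (R + m) >= 0`, `y - (R + m) >= 0`, `x + (R + m) <= width - 1`,
#' `y + (R + m) <= height - 1` (boundaries inclusive) are dropped.
#'
#' @param features feature data frame.
#' @param img the image the features live in.
#' @param margin interpolation margin in pixels.
#' @return the subset of `features` that can be sampled. Idempotent.
#' @export
lpm_remove_border_features <- function(features, img, margin = 2) {
  if (nrow(features) == 0) return(features)
  w <- ncol(img); h <- nrow(img)
  r <- features$radius + margin
  keep <- features$x - r >= 0 & features$y - r >= 0 &
    features$x + r <= w - 1 & features$y + r <= h - 1
  features[keep, , drop = FALSE]
}
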