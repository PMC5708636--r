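#' Log-polar sampling grid of a feature
#'
#' The disc neighbourhood of a feature with center (x0, y0) and radius R is
#' resampled at N rings times N angles. Ring radii are log-uniform
#' (geometric) in [1, R]: `rho_i = R^(i / (N - 1))`, i = 0..N-1, so the
#' innermost ring has radius 1 and the outermost radius R. Angles are
#' `theta_j = 2 pi j / N`, j = 0..N-1 (the half-open range [0, 2 pi)),
#' measured from the positive x axis in array coordinates (y down). Sample
#' (i, j) lies at `(rho_i cos theta_j + x0, rho_i sin theta_j + y0)`.
#'
#' @param feature a one-row feature data frame or list with x, y, radius.
#' @param N sampling resolution (rings = angles = N).
#' @return list with N x N coordinate matrices `x` and `y` (row i = ring i,
#'   innermost first) and the `rho`, `theta` vectors.
#' @export
lpm_sampling_grid <- function(feature, N = 32) {
  R <- as.numeric(feature$radius)
  if (!is.finite(R) || R < 1) {
    stop("feature radius must be >= 1 pixel (log sampling range degenerates)")
  }
  rho <- R^((0:(N - 1)) / (N - 1))
  theta <- 2 * pi * (0:(N - 1)) / N
  list(x = outer(rho, cos(theta)) + as.numeric(feature$x),
       y = outer(rho, sin(theta)) + as.numeric(feature$y),
       rho = rho, theta = theta)
}

#' Log-polar transform of a feature neighbourhood
#'
#' Resamples the feature's disc onto its N x N log-polar square. Each sample
#' value is the Gaussian-weighted mean of the 5x5 integer-pixel neighbourhood
#' centered on the pixel nearest to the continuous sample point: weights
#' `exp(-d^2 / (2 sigma_w^2))` with d the distance from the sample point to
#' each neighbourhood pixel, normalized to sum 1 (sigma_w = 1).
#'
#' Rows are ordered with the outermost ring as row 1 (top) and the innermost
#' ring as row N (bottom); columns are the angular samples. A feature
#' rotation therefore becomes a circular shift of the columns.
#'
#' The feature must have survived [lpm_remove_border_features()]; a sampling
#' neighbourhood reaching outside the image is a contract violation and
#' raises an error.
#'
#' @inheritParams lpm_sampling_grid
#' @param img numeric matrix (pre-smoothed image).
#' @param sigma_w interpolation weight scale in pixels.
#' @return N x N numeric matrix (the LPT image).
#' @export
lpm_sample_patch <- function(img, feature, N = 32, sigma_w = 1) {
  g <- lpm_sampling_grid(feature, N)
  sx <- as.vector(g$x)
  sy <- as.vector(g$y)
  cx <- round(sx)
  cy <- round(sy)
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2))
  M <- length(sx)
  px <- outer(cx, offs[, "dx"], "+")
  py <- outer(cy, offs[, "dy"], "+")
  if (any(px < 0) || any(py < 0) || any(px > ncol(img) - 1) || any(py > nrow(img) - 1)) {
    stop("sampling neighbourhood reaches outside the image; ",
         "remove border features before sampling")
  }
  d2 <- (px - sx)^2 + (py - sy)^2
  w <- exp(-d2 / (2 * sigma_w^2))
  w <- w / rowSums(w)
  vals <- rowSums(w * matrix(img[py + 1 + px * nrow(img)], M, nrow(offs)))
  lpt <- matrix(vals, N, N)
  lpt[N:1, , drop = FALSE]
}
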