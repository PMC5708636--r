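# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric (edge-repeating) reflection of 1-based indices into 1..n.
reflect_index <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  i <- ifelse(i >= n, 2L * n - 1L - i, i)
  i + 1L
}

# Normalized 1-D Gaussian kernel truncated at `truncate` standard deviations.
gaussian_kernel1d <- function(sigma, truncate = 4) {
  r <- ceiling(truncate * sigma)
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflective boundary handling.
conv_sep_reflect <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  np <- ncol(m)
  out <- matrix(0, nrow(m), np)
  for (k in -r:r) {
    out <- out + kernel[k + r + 1L] * m[, reflect_index(seq_len(np) + k, np), drop = FALSE]
  }
  m2 <- out
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (k in -r:r) {
    out <- out + kernel[k + r + 1L] * m2[reflect_index(seq_len(nr) + k, nr), , drop = FALSE]
  }
  out
}

smooth_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep_reflect(img, gaussian_kernel1d(sigma))
}

# Shift a matrix by (dy, dx) pixels with reflective borders (value at (y, x)
# becomes the value at (y + dy, x + dx) of the input).
shift_reflect <- function(m, dy, dx) {
  m[reflect_index(seq_len(nrow(m)) + dy, nrow(m)),
    reflect_index(seq_len(ncol(m)) + dx, ncol(m)), drop = FALSE]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
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
  force(code)
}

# Apply a 3x3 homography to an n x 2 matrix of (x, y) points.
project_points <- function(H, xy) {
  xy <- rbind(t(xy), 1)
  q <- H %*% xy
  cbind(q[1, ] / q[3, ], q[2, ] / q[3, ])
}

# Catmull-Rom cubic interpolation kernel (a = -0.5), the classical "bicubic".
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, ((a + 2) * t - (a + 3)) * t * t + 1,
         ifelse(t < 2, ((a * t - 5 * a) * t + 8 * a) * t - 4 * a, 0))
}

# Bicubic interpolation of `img` at continuous pixel coordinates (x, y)
# (0-based, x = column). Points outside the image evaluate to `fill`;
# neighbourhood indices are clamped at the borders.
bicubic_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(fill, length(x))
  ins <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ins)) return(out)
  x <- x[ins]; y <- y[ins]
  xi <- floor(x); yi <- floor(y)
  fx <- x - xi; fy <- y - yi
  acc <- numeric(length(x))
  for (m in -1:2) {
    wy <- cubic_kernel(fy - m)
    ry <- pmin(pmax(yi + m, 0), h - 1)
    for (k in -1:2) {
      wx <- cubic_kernel(fx - k)
      rx <- pmin(pmax(xi + k, 0), w - 1)
      acc <- acc + wy * wx * img[ry + 1 + rx * h]
    }
  }
  out[ins] <- acc
  out
}

# Inverse-mapped warp of an image under a homography H taking source (A)
# coordinates to destination (B) coordinates. Bicubic sampling; pixels whose
# pre-image falls outside the source are set to `fill`.
warp_image <- function(img, H, out_dim = dim(img), fill = 0) {
  if (identical(out_dim, dim(img)) && identical(unname(H), diag(3))) {
    return(img)
  }
  Hi <- solve(H)
  h <- out_dim[1]; w <- out_dim[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  p <- project_points(Hi, cbind(px, py))
  matrix(bicubic_sample(img, p[, 1], p[, 2], fill), h, w)
}
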