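# Shared fixtures: analytic patterns, small oracles, convenience wrappers.

ssd <- function(a, b) sum((a - b)^2)

# Smooth band-limited radial-angular pattern centered at (cx, cy), optionally
# rotated by `rot` radians. Evaluated analytically on the pixel grid, so a
# "rotated image" is exact, with no interpolation involved.
pattern_image <- function(size, cx = (size - 1) / 2, cy = (size - 1) / 2, rot = 0) {
  xs <- 0:(size - 1)
  X <- matrix(rep(xs, each = size), size, size)
  Y <- matrix(rep(xs, times = size), size, size)
  dx <- X - cx
  dy <- Y - cy
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) - rot
  damp <- 1 - exp(-(r / 6)^2)  # keeps the angular terms smooth at the center
  100 +
    40 * damp * cos(2 * phi + 0.7) * exp(-((r - 12) / 8)^2) +
    30 * damp * sin(3 * phi) * exp(-((r - 20) / 10)^2) +
    20 * cos(2 * pi * r / 16) * exp(-((r - 16) / 14)^2)
}

# Descriptor of a single feature (center x, y; radius R) of an image.
descriptor_at <- function(img, x, y, R = 32, N = 32, mask = lpm_default_mask(N)) {
  lpm_compute_descriptor(lpm_sample_patch(img, list(x = x, y = y, radius = R), N), mask)
}

# Random unit-norm non-negative vectors, one per row (descriptor-like).
random_unit_vectors <- function(n, L, seed) {
  lpmatch:::with_seed(seed, {
    m <- matrix(abs(stats::rnorm(n * L)), n, L)
    m / sqrt(rowSums(m^2))
  })
}

# Closed-form area of the intersection of two discs of radius r at center
# distance d (circle-circle lens).
lens_area <- function(r, d) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# Planted-homography correspondence set: n_in inliers under a similarity H
# with coordinate noise sd `noise`, plus n_out uniform random outliers.
planted_matches <- function(n_in, n_out, noise = 0, seed = 1,
                            theta = 20 * pi / 180, scale = 1.2, t = c(12, -7)) {
  H <- lpmatch:::similarity_homography(c(200, 200), theta, scale, t)
  lpmatch:::with_seed(seed, {
    pa_in <- cbind(stats::runif(n_in, 0, 199), stats::runif(n_in, 0, 199))
    pb_in <- lpmatch:::project_points(H, pa_in)
    if (noise > 0) pb_in <- pb_in + matrix(stats::rnorm(2 * n_in, 0, noise), ncol = 2)
    pa_out <- cbind(stats::runif(n_out, 0, 199), stats::runif(n_out, 0, 199))
    pb_out <- cbind(stats::runif(n_out, 0, 199), stats::runif(n_out, 0, 199))
    pa <- rbind(pa_in, pa_out)
    pb <- rbind(pb_in, pb_out)
    list(H = H,
         matches = data.frame(index_a = seq_len(n_in + n_out),
                              index_b = seq_len(n_in + n_out)),
         coords_a = data.frame(x = pa[, 1], y = pa[, 2]),
         coords_b = data.frame(x = pb[, 1], y = pb[, 2]),
         planted = seq_len(n_in))
  })
}
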