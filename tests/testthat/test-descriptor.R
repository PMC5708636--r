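test_that("default masks have the advertised size and exclusion rules", {
  m16 <- lpm_default_mask(16)
  m32 <- lpm_default_mask(32)
  expect_equal(nrow(m16$selected), 48)
  expect_equal(nrow(m32$selected), 56)
  for (m in list(m16, m32)) {
    expect_false(any(m$selected[, "v"] == 0))       # horizontal artifact line
    expect_false(any(m$selected[, "u"] == 0 & m$selected[, "v"] == 0))
    key <- paste(m$selected[, 1], m$selected[, 2])
    expect_false(any(paste(-m$selected[, 1], -m$selected[, 2]) %in% key))
    expect_false(any(duplicated(key)))
  }
  expect_error(lpm_default_mask(8), "16")
})

test_that("custom masks are validated and round-trip through JSON", {
  expect_error(lpm_mask(16, rbind(c(0, 0))), "DC")
  expect_error(lpm_mask(16, rbind(c(3, 0))), "v = 0")
  expect_error(lpm_mask(16, rbind(c(1, 2), c(-1, -2))), "redundant")
  m <- lpm_mask(16, rbind(c(0, 2), c(1, 1), c(-3, 4)))
  f <- tempfile(fileext = ".json")
  lpm_write_mask(m, f)
  m2 <- lpm_read_mask(f)
  expect_equal(m2$N, 16L)
  expect_equal(unname(m2$selected), unname(m$selected))
})

test_that("constant patches are flagged degenerate", {
  d <- lpm_compute_descriptor(matrix(9, 32, 32), lpm_default_mask(32))
  expect_true(attr(d, "degenerate"))
  expect_true(all(d == 0))
})

test_that("the descriptor is invariant to column shifts and affine intensity", {
  set.seed(21)
  lpt <- matrix(runif(32 * 32, 0, 255), 32, 32)
  mask <- lpm_default_mask(32)
  d0 <- lpm_compute_descriptor(lpt, mask)
  for (k in c(1, 7, 19)) {
    dk <- lpm_compute_descriptor(lpt[, c((k + 1):32, 1:k)], mask)
    expect_lt(ssd(d0, dk), 1e-9)
  }
  da <- lpm_compute_descriptor(3.7 * lpt - 12, mask)
  expect_lt(ssd(d0, da), 1e-9)
  expect_equal(sqrt(sum(d0^2)), 1, tolerance = 1e-9)
  expect_true(all(d0 >= 0))
})

test_that("a pure angular cosine concentrates on its frequency coordinate", {
  N <- 16
  lpt <- matrix(cos(2 * pi * 2 * (0:(N - 1)) / N), N, N, byrow = TRUE)
  # brute-force DFT oracle at (u = 0, v = 2): |sum_ij x_ij e^{-2pi i (2 j / N)}|
  w <- exp(-2i * pi * 2 * (0:(N - 1)) / N)
  oracle <- abs(sum(lpt %*% w))
  expect_equal(oracle, N * N / 2, tolerance = 1e-6)
  mask <- lpm_mask(N, rbind(c(0, 2), c(1, 1), c(2, 3), c(-1, 4)))
  d <- lpm_compute_descriptor(lpt, mask)
  expect_equal(as.numeric(d), c(1, 0, 0, 0), tolerance = 1e-9)
})

test_that("the magnitude spectrum of a real patch is conjugate-symmetric", {
  set.seed(33)
  for (N in c(16, 32)) {
    lpt <- matrix(runif(N * N, 0, 100), N, N)
    f <- stats::fft(lpt)
    for (rep in 1:20) {
      u <- sample(-(N / 2 - 1):(N / 2 - 1), 1)
      v <- sample(-(N / 2 - 1):(N / 2 - 1), 1)
      m1 <- Mod(f[(u %% N) + 1, (v %% N) + 1])
      m2 <- Mod(f[((-u) %% N) + 1, ((-v) %% N) + 1])
      expect_lt(abs(m1 - m2), 1e-9 * max(1, m1))
    }
  }
})

test_that("describe_all drops undescribable features and keeps order", {
  img <- lpm_presmooth(lpm_make_texture(192, "blobs", seed = 7))
  expect_equal(nrow(lpm_describe(img, data.frame(x = numeric(0), y = numeric(0),
                                                 radius = numeric(0)))$vectors), 0)
  feats <- data.frame(x = c(96, 5), y = c(96, 5), radius = 32, source = "t")
  d <- lpm_describe(img, feats)
  expect_equal(nrow(d$vectors), 1)
  expect_equal(d$n_border_removed, 1)
  expect_equal(ncol(d$vectors), 56)
  expect_equal(sqrt(sum(d$vectors[1, ]^2)), 1, tolerance = 1e-9)
})

test_that("descriptors are stable under 90-degree image rotation", {
  size <- 129
  img <- lpm_presmooth(pattern_image(size) +
                         lpm_make_texture(129, "noise", seed = 9) * 0.2)
  ctr <- (size - 1) / 2
  rot90 <- t(img)[, size:1]  # maps pixel (x, y) -> (size-1-y, x)
  d0 <- descriptor_at(img, ctr, ctr)
  d90 <- descriptor_at(rot90, ctr, ctr)
  expect_lt(ssd(d0, d90), 0.05)
  # distinctiveness: random other features are much farther away
  other <- lpm_presmooth(lpm_make_texture(192, "noise", seed = 10))
  set.seed(12)
  dists <- replicate(20, {
    ssd(d0, descriptor_at(other, runif(1, 40, 150), runif(1, 40, 150)))
  })
  expect_gt(min(dists), 5 * ssd(d0, d90))
})

test_that("scaling image and radius together leaves the descriptor stable", {
  size <- 160
  img <- pattern_image(size)
  ctr <- (size - 1) / 2
  d1 <- descriptor_at(lpm_presmooth(img), ctr, ctr, R = 30)
  for (s in c(0.5, 2)) {
    scaled <- lpm_resize(img, s)
    ctr_s <- ctr * s
    ds <- descriptor_at(lpm_presmooth(scaled), ctr_s, ctr_s, R = 30 * s)
    expect_lt(ssd(d1, ds), 0.05)
  }
})

test_that("identical inputs give bit-identical descriptors", {
  img <- lpm_presmooth(lpm_make_texture(128, "blobs", seed = 4))
  f <- data.frame(x = 64, y = 64, radius = 28, source = "t")
  d1 <- lpm_describe(img, f)
  d2 <- lpm_describe(img, f)
  expect_identical(d1$vectors, d2$vectors)
})
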