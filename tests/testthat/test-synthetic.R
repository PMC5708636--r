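test_that("texture generation is seed-deterministic", {
  t1 <- lpm_make_texture(128, "blobs", seed = 42)
  t2 <- lpm_make_texture(128, "blobs", seed = 42)
  expect_identical(t1, t2)
  expect_false(identical(t1, lpm_make_texture(128, "blobs", seed = 43)))
  expect_error(lpm_make_texture(32), "64")
})

test_that("blob textures contain their spots as distinct local maxima", {
  img <- lpm_make_texture(256, "blobs", seed = 17)
  ctr <- attr(img, "centers")
  expect_gte(nrow(ctr), 30)
  # brute-force 3x3 local-maximum scan above background
  n_max <- 0
  for (y in 2:255) {
    for (x in 2:255) {
      v <- img[y + 1, x + 1]
      if (v > 40 && v == max(img[y:(y + 2), x:(x + 2)]) &&
          sum(img[y:(y + 2), x:(x + 2)] == v) == 1) {
        n_max <- n_max + 1
      }
    }
  }
  expect_gte(n_max, 30)
})

test_that("band-limited noise has almost no high-frequency energy", {
  img <- lpm_make_texture(128, "noise", seed = 8)
  f <- Mod(stats::fft(img - mean(img)))^2
  n <- 128
  fr <- pmin(0:(n - 1), n - (0:(n - 1))) / n  # cycles per pixel
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  high <- sum(f[rad > 0.25])
  expect_lt(high / sum(f), 0.05)
})

test_that("an identity transform reproduces the base image bit-exactly", {
  img <- lpm_make_texture(128, "blobs", seed = 2)
  p <- lpm_make_pair(img)
  expect_identical(p$img_b, p$img_a)
  expect_equal(p$H, diag(3))
})

test_that("warped pixels agree with an independent bicubic oracle", {
  img <- lpm_make_texture(128, "blobs", seed = 12)
  p <- lpm_make_pair(img, theta = 45 * pi / 180, scale = 0.65)
  Hi <- solve(p$H)
  # independent scalar Catmull-Rom interpolation
  cr <- function(t) {
    t <- abs(t)
    if (t <= 1) 1.5 * t^3 - 2.5 * t^2 + 1
    else if (t < 2) -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2
    else 0
  }
  set.seed(99)
  for (rep in 1:50) {
    xb <- sample(30:100, 1); yb <- sample(30:100, 1)
    q <- lpmatch:::project_points(Hi, cbind(xb, yb))
    if (q[1] < 2 || q[1] > 125 || q[2] < 2 || q[2] > 125) next
    xi <- floor(q[1]); yi <- floor(q[2])
    val <- 0
    for (m in -1:2) {
      for (k in -1:2) {
        val <- val + cr(q[2] - (yi + m)) * cr(q[1] - (xi + k)) *
          img[yi + m + 1, xi + k + 1]
      }
    }
    expect_equal(p$img_b[yb + 1, xb + 1], val, tolerance = 1e-6)
  }
})

test_that("intensity offset adds uniformly to the warped image", {
  img <- lpm_make_texture(96, "noise", seed = 6)
  p0 <- lpm_make_pair(img, theta = 30 * pi / 180)
  p50 <- lpm_make_pair(img, theta = 30 * pi / 180, offset = 50)
  expect_lt(max(abs((p50$img_b - p0$img_b) - 50)), 1e-12)
})

test_that("planted features land inside the transformed image", {
  img <- lpm_make_texture(256, "blobs", seed = 3)
  p <- lpm_make_pair(img, theta = 20 * pi / 180, scale = 0.9, translation = c(5, -8))
  expect_gt(nrow(p$planted), 0)
  q <- lpmatch:::project_points(p$H, cbind(p$planted$x, p$planted$y))
  inside <- q[, 1] >= 0 & q[, 1] <= 255 & q[, 2] >= 0 & q[, 2] <= 255
  expect_gte(mean(inside), 0.9)
})

test_that("transforms hiding most of the image are rejected", {
  img <- lpm_make_texture(128, "noise", seed = 1)
  expect_error(lpm_make_pair(img, translation = c(120, 0)), "visible")
})

test_that("pair generation with noise is seed-deterministic", {
  img <- lpm_make_texture(96, "noise", seed = 4)
  p1 <- lpm_make_pair(img, theta = 0.3, noise = 2, seed = 5)
  p2 <- lpm_make_pair(img, theta = 0.3, noise = 2, seed = 5)
  expect_identical(p1$img_b, p2$img_b)
  expect_false(identical(p1$img_b, lpm_make_pair(img, theta = 0.3, noise = 2, seed = 6)$img_b))
})

test_that("ramp-and-blobs textures carry the horizontal gradient", {
  img <- lpm_make_texture(128, "ramp_blobs", seed = 13)
  expect_identical(img, lpm_make_texture(128, "ramp_blobs", seed = 13))
  col_means <- colMeans(img)
  fit <- coef(lm(col_means ~ seq_along(col_means)))
  expect_gt(fit[2], 0.5)  # ~100 intensity units across the width
})
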