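# Smaller feature radius and N = 16 so features survive on the downscaled
# images of the pyramid scenarios.
pyramid_config <- function() lpm_config(N = 16, fixed_radius = 12, max_features = 150)

test_that("identical images choose the unresized scenario", {
  img <- lpm_make_texture(320, "blobs", seed = 20)
  pyr <- lpm_scale_pyramid(img, img, pyramid_config())
  expect_equal(pyr$scenario, "A_vs_B")
  expect_equal(unname(which.max(pyr$counts)), 1)
})

test_that("a four-fold zoom difference picks the scale-equalizing scenario", {
  img <- lpm_make_texture(320, "blobs", seed = 20)
  small <- lpm_resize(img, 0.25)
  pyr <- lpm_scale_pyramid(img, small, pyramid_config())
  # content scale of A is 1, of B is 0.25; after the scenario resizes the
  # effective scales must agree within a factor of 2
  eff <- pyr$factors["fa"] / (0.25 * pyr$factors["fb"])
  expect_gte(eff, 0.5)
  expect_lte(eff, 2)
  expect_gt(nrow(pyr$matches), 3)
})

test_that("winning-scenario coordinates are mapped back to the input frames", {
  img <- lpm_make_texture(320, "blobs", seed = 20)
  small <- lpm_resize(img, 0.25)
  cfg <- pyramid_config()
  pyr <- lpm_scale_pyramid(img, small, cfg)
  fa <- pyr$factors["fa"]
  expect_lt(fa, 1)  # the A side was resized in the winning scenario
  # exact bookkeeping: rescaled coordinates times the factor reproduce the
  # detections on the resized image
  resized <- lpm_presmooth(lpm_resize(img, fa))
  det <- lpm_detect_harris(resized, cfg$max_features, cfg$fixed_radius)
  mask <- lpm_default_mask(cfg$N)
  det <- lpm_describe(resized, det, cfg$N, mask)$features
  expect_equal(pyr$desc_a$features$x * fa, det$x, tolerance = 1e-12)
  expect_equal(pyr$desc_a$features$y * fa, det$y, tolerance = 1e-12)
  # structural alignment: most back-mapped centers sit near a native detection
  native <- lpm_detect_harris(lpm_presmooth(img), cfg$max_features, cfg$fixed_radius)
  near <- vapply(seq_len(nrow(pyr$desc_a$features)), function(i) {
    min(sqrt((native$x - pyr$desc_a$features$x[i])^2 +
               (native$y - pyr$desc_a$features$y[i])^2))
  }, numeric(1))
  expect_gte(mean(near <= 2 / fa), 0.6)
})

test_that("without scale difference the pyramid changes nothing", {
  img <- lpm_make_texture(256, "blobs", seed = 21)
  pair <- lpm_make_pair(img, theta = 15 * pi / 180, noise = 1.5, seed = 4)
  cfg <- pyramid_config()
  plain <- lpm_pipeline(pair$img_a, pair$img_b, cfg)
  cfg$scale_pyramid <- TRUE
  pyr <- lpm_pipeline(pair$img_a, pair$img_b, cfg)
  expect_equal(pyr$report$scenario, "A_vs_B")
  expect_identical(plain$matches, pyr$matches)
  expect_equal(plain$report$inliers, pyr$report$inliers)
})

test_that("swapping the images mirrors the winning scenario", {
  img <- lpm_make_texture(320, "blobs", seed = 22)
  small <- lpm_resize(img, 0.5)
  cfg <- pyramid_config()
  p1 <- lpm_scale_pyramid(img, small, cfg)
  p2 <- lpm_scale_pyramid(small, img, cfg)
  mirror <- c(A_vs_B = "A_vs_B", A_vs_0.5B = "0.5A_vs_B",
              `0.5A_vs_B` = "A_vs_0.5B", A_vs_0.25B = "0.25A_vs_B",
              `0.25A_vs_B` = "A_vs_0.25B")
  expect_equal(unname(mirror[p1$scenario]), p2$scenario)
})
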