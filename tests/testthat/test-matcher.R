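test_that("identical orthogonal sets match one-to-one at distance zero", {
  E <- diag(3)
  m <- lpm_match_descriptors(E, E)
  expect_equal(nrow(m), 3)
  expect_equal(m$index_a, m$index_b)
  expect_true(all(m$distance == 0))
  expect_true(all(is.infinite(m$ratio)))
})

test_that("the Lowe condition rejects ambiguous nearest neighbours", {
  # construct unit vectors with prescribed pairwise SSDs via cos = 1 - ssd/2
  base <- rep(1, 8) / sqrt(8)
  ortho <- c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(8)
  mk <- function(target_ssd) {
    a <- acos(1 - target_ssd / 2)
    cos(a) * base + sin(a) * ortho
  }
  v1 <- mk(0.004)   # nearest neighbour of the query
  v2 <- mk(0.005)   # second nearest, nearly as close
  b <- rbind(base)
  A <- rbind(v1, v2)
  expect_equal(ssd(base, v1), 0.004, tolerance = 1e-12)
  expect_equal(ssd(base, v2), 0.005, tolerance = 1e-12)
  # ratio d2/d1 = 1.25 < 1/0.6: ambiguous, rejected
  expect_equal(nrow(lpm_match_descriptors(A, b)), 0)
  # with only the nearest present the match is unambiguous and accepted
  m <- lpm_match_descriptors(rbind(v1), b)
  expect_equal(nrow(m), 1)
  expect_equal(m$distance, 0.004, tolerance = 1e-12)
})

test_that("the 1% threshold is an absolute SSD cutoff of 0.02", {
  mk_pair <- function(d) {
    b <- c(1, rep(0, 7))
    u <- c(0, 1, rep(0, 6))
    a <- (1 - d / 2) * b + sqrt(1 - (1 - d / 2)^2) * u
    list(a = rbind(a), b = rbind(b))
  }
  p <- mk_pair(0.019)
  expect_equal(nrow(lpm_match_descriptors(p$a, p$b)), 1)
  p <- mk_pair(0.021)
  expect_equal(nrow(lpm_match_descriptors(p$a, p$b)), 0)
})

test_that("with loose thresholds matching reduces to nearest neighbours", {
  A <- random_unit_vectors(100, 48, seed = 51)
  B <- random_unit_vectors(100, 48, seed = 52)
  m <- lpm_match_descriptors(A, B, threshold_pct = 1e9, tau_L = 1)
  # brute-force nearest-neighbour oracle
  expect_equal(nrow(m), 100)
  for (j in 1:100) {
    d <- colSums((t(A) - B[j, ])^2)
    expect_equal(m$index_a[m$index_b == j], which.min(d))
    expect_equal(m$distance[m$index_b == j], min(d), tolerance = 1e-12)
  }
})

test_that("loosening the distance threshold never removes matches", {
  A <- random_unit_vectors(60, 16, seed = 61)
  B <- A + random_unit_vectors(60, 16, seed = 62) * 0.02
  B <- B / sqrt(rowSums(B^2))
  key <- function(m) paste(m$index_a, m$index_b)
  m1 <- lpm_match_descriptors(A, B, threshold_pct = 0.5)
  m2 <- lpm_match_descriptors(A, B, threshold_pct = 1)
  m3 <- lpm_match_descriptors(A, B, threshold_pct = 5)
  expect_true(all(key(m1) %in% key(m2)))
  expect_true(all(key(m2) %in% key(m3)))
})

test_that("queries are unique but references may repeat (one-to-many)", {
  a <- rbind(c(1, 0, 0, 0))
  b <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  m <- lpm_match_descriptors(a, b)
  expect_equal(nrow(m), 2)
  expect_equal(m$index_a, c(1, 1))
  expect_false(any(duplicated(m$index_b)))

  expect_error(lpm_match_descriptors(diag(3), diag(4)), "lengths differ")
  expect_equal(nrow(lpm_match_descriptors(matrix(0, 0, 4), diag(4))), 0)
})
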