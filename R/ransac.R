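#' Homography estimation by the normalized Direct Linear Transform
#'
#' Least-squares homography from >= 4 point correspondences with Hartley
#' normalization (each point set translated to centroid 0 and scaled to RMS
#' distance sqrt(2)), solved via the singular value decomposition of the
#' standard 2n x 9 design matrix. The result is scaled so its bottom-right
#' element is 1 when that element is nonzero.
#'
#' @param pa,pb n x 2 matrices of (x, y) points; the returned H maps
#'   `pa` coordinates to `pb` coordinates.
#' @return 3 x 3 homography matrix.
#' @export
lpm_fit_homography <- function(pa, pb) {
  pa <- as.matrix(pa); pb <- as.matrix(pb)
  n <- nrow(pa)
  if (n < 4 || nrow(pb) != n) stop("need at least 4 point correspondences")
  na <- hartley_normalize(pa)
  nb <- hartley_normalize(pb)
  x <- na$pts[, 1]; y <- na$pts[, 2]
  u <- nb$pts[, 1]; v <- nb$pts[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  A[seq(2, 2 * n, 2), ] <- cbind(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
  s <- svd(A, nu = 0, nv = 9)
  if (s$d[8] / s$d[1] < 1e-9) {
    stop("singular fit: degenerate point configuration (collinear points?)")
  }
  Hn <- matrix(s$v[, 9], 3, 3, byrow = TRUE)
  # 3 collinear points in one set still yield a unique null vector, but the
  # fitted map collapses the plane onto a line: reject non-invertible fits
  sh <- svd(Hn)$d
  if (sh[3] / sh[1] < 1e-9) {
    stop("singular fit: degenerate point configuration (collinear points?)")
  }
  H <- solve(nb$T) %*% Hn %*% na$T
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

hartley_normalize <- function(p) {
  c0 <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, c0)^2))
  rms <- sqrt(mean(d^2))
  s <- if (rms > 0) sqrt(2) / rms else 1
  T <- matrix(c(s, 0, -s * c0[1],
                0, s, -s * c0[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  list(pts = cbind(s * (p[, 1] - c0[1]), s * (p[, 2] - c0[2])), T = T)
}

# Symmetric transfer error per correspondence: RMS of the forward (H a vs b)
# and backward (H^-1 b vs a) reprojection distances.
symmetric_transfer_error <- function(H, pa, pb) {
  Hi <- solve(H)
  f <- project_points(H, pa) - pb
  b <- project_points(Hi, pb) - pa
  sqrt((rowSums(f^2) + rowSums(b^2)) / 2)
}

# Similarity transform (rotation + isotropic scale + translation) from two
# point correspondences, solved in the complex plane. NULL when degenerate.
fit_similarity_2pt <- function(pa, pb) {
  z1 <- complex(real = pa[1, 1], imaginary = pa[1, 2])
  z2 <- complex(real = pa[2, 1], imaginary = pa[2, 2])
  w1 <- complex(real = pb[1, 1], imaginary = pb[1, 2])
  w2 <- complex(real = pb[2, 1], imaginary = pb[2, 2])
  dz <- z2 - z1
  if (Mod(dz) < 1e-9) return(NULL)
  a <- (w2 - w1) / dz
  if (!is.finite(Mod(a)) || Mod(a) < 1e-9) return(NULL)
  t <- w1 - a * z1
  matrix(c(Re(a), -Im(a), Re(t),
           Im(a), Re(a), Im(t),
           0, 0, 1), 3, 3, byrow = TRUE)
}

# TRUE when the (normalized) homography is numerically a similarity: no
# perspective terms and an orthogonal, isotropic upper-left block.
similarity_like <- function(H) {
  if (abs(H[3, 3]) < 1e-12) return(FALSE)
  H <- H / H[3, 3]
  s <- sqrt(H[1, 1]^2 + H[1, 2]^2)
  if (s < 1e-9) return(FALSE)
  max(abs(H[3, 1:2])) < 1e-4 &&
    abs(H[1, 1] - H[2, 2]) < 0.01 * s &&
    abs(H[1, 2] + H[2, 1]) < 0.01 * s
}

three_of_four <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))

# TRUE when any 3 of the 4 points are (nearly) collinear.
degenerate_sample <- function(p) {
  for (k in 1:4) {
    q <- p[three_of_four[k, ], ]
    area2 <- abs((q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
                   (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2]))
    scale2 <- max(1, max(abs(q))^2)
    if (area2 < 1e-9 * scale2) return(TRUE)
  }
  FALSE
}

#' Verify candidate matches by seeded RANSAC with local optimization
#'
#' Robustly fits a homography to the matched feature centers and returns the
#' consensus ("correct") matches. Minimal 4-point hypotheses are drawn with a
#' seeded RNG from the canonically sorted correspondences (so the result is
#' reproducible and independent of input order); each hypothesis is scored by
#' the number of correspondences with symmetric transfer error below
#' `pixel_tol`. Promising hypotheses are locally optimized: the homography is
#' re-estimated by DLT on the full consensus set and the set recomputed,
#' iterating to a fixed point (at most `max_refits` rounds). The iteration
#' count adapts to the best inlier ratio found (confidence 0.999), capped at
#' `max_iter`. This iterated re-estimation gives the stable optimal-subset
#' behaviour needed to survive heavily contaminated match sets.
#'
#' @param matches data frame with columns `index_a`, `index_b` (rows of the
#'   coordinate tables), e.g. from [lpm_match_descriptors()].
#' @param coords_a,coords_b matrices or data frames with columns x, y giving
#'   feature centers in the two images.
#' @param pixel_tol inlier threshold on the symmetric transfer error, pixels.
#' @param seed RNG seed; fixed seed implies bit-identical output.
#' @param confidence target probability of having drawn one all-inlier
#'   sample.
#' @param max_iter hypothesis cap.
#' @param max_refits local-optimization cap.
#' @return object of class `lpm_verified`: list with `inliers` (row indices
#'   into `matches`), `homography` (maps image A to image B coordinates),
#'   `iterations_used`, `seed`, and `ok` (FALSE when fewer than 4 matches or
#'   no consensus of size >= 4 was found).
#' @export
lpm_ransac_verify <- function(matches, coords_a, coords_b, pixel_tol = 3,
                              seed = 0, confidence = 0.999, max_iter = 10000,
                              max_refits = 10) {
  ca <- as.matrix(as.data.frame(coords_a)[, c("x", "y")])
  cb <- as.matrix(as.data.frame(coords_b)[, c("x", "y")])
  pa <- ca[matches$index_a, , drop = FALSE]
  pb <- cb[matches$index_b, , drop = FALSE]
  n <- nrow(pa)
  fail <- structure(list(inliers = integer(0), homography = NULL,
                         iterations_used = 0L, seed = seed, ok = FALSE),
                    class = "lpm_verified")
  if (n < 4) return(fail)
  # canonical order: sampling sequence depends only on the set of matches
  ord <- order(pa[, 1], pa[, 2], pb[, 1], pb[, 2])
  pa <- pa[ord, , drop = FALSE]
  pb <- pb[ord, , drop = FALSE]
  best <- integer(0)
  best_sse <- Inf
  best_H <- NULL
  iters <- 0L
  with_seed(seed, {
    needed <- max_iter
    while (iters < needed) {
      iters <- iters + 1L
      if (iters %% 2L == 1L) {
        # full 4-point homography hypothesis
        s <- sample.int(n, 4)
        if (degenerate_sample(pa[s, , drop = FALSE]) ||
            degenerate_sample(pb[s, , drop = FALSE])) next
        H <- tryCatch(lpm_fit_homography(pa[s, , drop = FALSE], pb[s, , drop = FALSE]),
                      error = function(e) NULL)
      } else {
        # 2-point similarity hypothesis: a cheap generator that reaches deep
        # into heavily contaminated sets when the underlying transform is
        # rigid/zoom-like; local optimization upgrades it to a full DLT fit
        s <- sample.int(n, 2)
        H <- fit_similarity_2pt(pa[s, , drop = FALSE], pb[s, , drop = FALSE])
      }
      if (is.null(H) || any(!is.finite(H)) || abs(det(H)) < 1e-12) next
      e <- symmetric_transfer_error(H, pa, pb)
      inl <- which(e < pixel_tol)
      # local optimization only for hypotheses at least as good as the
      # incumbent (and beyond the trivial self-consistent minimal sample)
      if (length(inl) > length(best) ||
          (length(inl) >= 5 && length(inl) >= length(best))) {
        res <- refit_fixed_point(pa, pb, inl, pixel_tol, max_refits)
        if (!is.null(res) &&
            (length(res$inliers) > length(best) ||
             (length(res$inliers) == length(best) && res$sse < best_sse))) {
          best <- res$inliers
          best_sse <- res$sse
          best_H <- res$H
        }
      }
      if (length(best) >= 4) {
        # per-iteration success probability: half the draws are 4-point
        # samples (w^4); the 2-point generator counts only when the best
        # transform is itself a similarity, otherwise it cannot rediscover it
        w <- length(best) / n
        p_good <- w^4 / 2 + if (similarity_like(best_H)) w^2 / 2 else 0
        needed <- if (p_good >= 1) 1L else {
          min(max_iter, ceiling(log(1 - confidence) / log(1 - p_good)))
        }
      }
    }
  })
  if (length(best) < 4 || is.null(best_H)) {
    fail$iterations_used <- iters
    return(fail)
  }
  structure(list(inliers = sort(ord[best]), homography = best_H,
                 iterations_used = iters, seed = seed, ok = TRUE),
            class = "lpm_verified")
}

# Iterate DLT re-estimation on the consensus set until the inlier set is a
# fixed point (or max_refits rounds).
refit_fixed_point <- function(pa, pb, inl, pixel_tol, max_refits) {
  if (length(inl) < 4) return(NULL)
  cur <- sort(inl)
  H <- NULL
  e <- NULL
  for (r in seq_len(max_refits)) {
    H2 <- tryCatch(lpm_fit_homography(pa[cur, , drop = FALSE], pb[cur, , drop = FALSE]),
                   error = function(err) NULL)
    if (is.null(H2) || any(!is.finite(H2))) break
    e2 <- symmetric_transfer_error(H2, pa, pb)
    nxt <- which(e2 < pixel_tol)
    H <- H2
    e <- e2
    if (identical(sort(nxt), cur)) {
      cur <- sort(nxt)
      break
    }
    if (length(nxt) < 4) break
    cur <- sort(nxt)
  }
  if (is.null(H) || length(cur) < 4) return(NULL)
  list(inliers = cur, H = H, sse = sum(e[cur]^2))
}

#' @export
print.lpm_verified <- function(x, ...) {
  if (!x$ok) {
    cat("match verification failed (no consensus of size >= 4)\n")
  } else {
    cat(sprintf("verified %d inliers in %d iterations (seed %s)\n",
                length(x$inliers), x$iterations_used, format(x$seed)))
  }
  invisible(x)
}
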