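#' Overlap error between two features under a known homography
#'
#' The disc of `feat_b` (image B frame) is mapped into image A's frame
#' through the inverse homography and compared with the disc of `feat_a`:
#' the error is `1 - |intersection| / |union|` with areas counted in pixels
#' on a common integer raster covering both regions (a raster pixel belongs
#' to the mapped B disc when its forward image under H lies inside the B
#' disc). Raw radii are used; no feature scale normalization is applied. The
#' pair is a ground-truth match when the error is below `epsilon0`
#' (default 0.4).
#'
#' @param feat_a,feat_b one-row feature data frames or lists with x, y,
#'   radius (`feat_a` in image A coordinates, `feat_b` in image B).
#' @param H 3 x 3 homography mapping A coordinates to B coordinates.
#' @param epsilon0 overlap-error threshold separating true matches from
#'   accidental overlap.
#' @return list with `error` in [0, 1] and logical `is_match`.
#' @export
lpm_overlap_error <- function(feat_a, feat_b, H = diag(3), epsilon0 = 0.4) {
  Hi <- solve(H)
  xa <- as.numeric(feat_a$x); ya <- as.numeric(feat_a$y); ra <- as.numeric(feat_a$radius)
  xb <- as.numeric(feat_b$x); yb <- as.numeric(feat_b$y); rb <- as.numeric(feat_b$radius)
  # bounding box: disc A plus the mapped boundary of disc B
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  bnd <- project_points(Hi, cbind(xb + rb * cos(t), yb + rb * sin(t)))
  x0 <- floor(min(xa - ra, bnd[, 1])); x1 <- ceiling(max(xa + ra, bnd[, 1]))
  y0 <- floor(min(ya - ra, bnd[, 2])); y1 <- ceiling(max(ya + ra, bnd[, 2]))
  if ((x1 - x0 + 1) * (y1 - y0 + 1) > 4e7) stop("overlap raster too large")
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy))
  py <- rep(gy, times = length(gx))
  in_a <- (px - xa)^2 + (py - ya)^2 <= ra^2
  q <- project_points(H, cbind(px, py))
  in_b <- (q[, 1] - xb)^2 + (q[, 2] - yb)^2 <= rb^2
  uni <- sum(in_a | in_b)
  err <- if (uni == 0) 1 else 1 - sum(in_a & in_b) / uni
  list(error = err, is_match = err < epsilon0)
}

#' Ground-truth matches from a known homography
#'
#' Enumerates all feature pairs whose overlap error under H is below
#' `epsilon0`. When the image dimensions are supplied, the comparison is
#' restricted to features fully visible in both images: the feature's disc
#' must fit inside its own frame and the bounding box of its mapped disc
#' boundary inside the other frame.
#'
#' @param feats_a,feats_b feature data frames.
#' @param H homography mapping A coordinates to B coordinates.
#' @param epsilon0 overlap-error threshold.
#' @param dim_a,dim_b optional c(height, width) of the two images; omit to
#'   skip the visibility restriction.
#' @return data frame with columns `index_a`, `index_b`, `error`, plus the
#'   visible feature counts as attributes `n_visible_a`, `n_visible_b`.
#' @export
lpm_ground_truth_matches <- function(feats_a, feats_b, H, epsilon0 = 0.4,
                                     dim_a = NULL, dim_b = NULL) {
  vis_a <- visible_both(feats_a, H, dim_a, dim_b)
  vis_b <- visible_both(feats_b, solve(H), dim_b, dim_a)
  ia <- integer(0); ib <- integer(0); er <- numeric(0)
  for (i in which(vis_a)) {
    for (j in which(vis_b)) {
      o <- lpm_overlap_error(feats_a[i, ], feats_b[j, ], H, epsilon0)
      if (o$is_match) {
        ia <- c(ia, i); ib <- c(ib, j); er <- c(er, o$error)
      }
    }
  }
  structure(data.frame(index_a = ia, index_b = ib, error = er),
            n_visible_a = sum(vis_a), n_visible_b = sum(vis_b))
}

# Fully-visible test: disc inside own frame, mapped disc's bounding box
# inside the other frame. Frames given as c(height, width); NULL skips the
# corresponding check.
visible_both <- function(feats, H, dim_own, dim_other) {
  n <- nrow(feats)
  ok <- rep(TRUE, n)
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  for (i in seq_len(n)) {
    x <- feats$x[i]; y <- feats$y[i]; r <- feats$radius[i]
    if (!is.null(dim_own)) {
      ok[i] <- x - r >= 0 && y - r >= 0 &&
        x + r <= dim_own[2] - 1 && y + r <= dim_own[1] - 1
    }
    if (ok[i] && !is.null(dim_other)) {
      p <- project_points(H, cbind(x + r * cos(t), y + r * sin(t)))
      ok[i] <- min(p[, 1]) >= 0 && min(p[, 2]) >= 0 &&
        max(p[, 1]) <= dim_other[2] - 1 && max(p[, 2]) <= dim_other[1] - 1
    }
  }
  ok
}

#' Matching score
#'
#' Correct matches divided by the smaller number of features fully visible
#' in both images.
#'
#' @param correct number of correct matches.
#' @param n_visible_a,n_visible_b co-visible feature counts in the two
#'   images.
#' @return fraction in [0, Inf) (1 when every co-visible feature matched).
#' @export
lpm_matching_score <- function(correct, n_visible_a, n_visible_b) {
  stopifnot(correct >= 0, n_visible_a >= 0, n_visible_b >= 0)
  den <- min(n_visible_a, n_visible_b)
  if (den == 0) stop("matching score undefined: no co-visible features")
  correct / den
}

#' Inlier ratio
#'
#' Verified matches divided by all candidate matches found; 0 by convention
#' when no matches were found.
#'
#' @param n_inliers verified match count.
#' @param n_matches candidate match count.
#' @return fraction in [0, 1].
#' @export
lpm_inlier_ratio <- function(n_inliers, n_matches) {
  stopifnot(n_inliers >= 0, n_matches >= 0)
  if (n_inliers > n_matches) stop("inlier count exceeds match count")
  if (n_matches == 0) return(0)
  n_inliers / n_matches
}
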