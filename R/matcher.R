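#' Exhaustive thresholded descriptor matching with the Lowe ratio test
#'
#' Every vector in `desc_b` (the transformed image) is compared against every
#' vector in `desc_a` (the reference) by the sum of squared differences. A
#' query b is matched to its nearest neighbour a when both conditions hold:
#'
#' * the SSD is below `threshold_pct`% of the maximum achievable SSD between
#'   two unit-length non-negative vectors, which is 2 (attained by orthogonal
#'   vectors), so the default 1% threshold is an absolute cutoff of 0.02;
#' * the Lowe ratio condition: the nearest neighbour must be substantially
#'   closer than the second nearest, `d1 / d2 < tau_L` (default 0.6). An
#'   exact duplicate (d1 = 0) is always accepted; a query with a single
#'   candidate has no second neighbour and its ratio is treated as infinite.
#'
#' Each query matches at most its single nearest neighbour (ties broken by
#' lowest index), but one reference vector may be the match of many queries:
#' one-to-many matches are deliberately allowed so that large scale
#' differences, where several features in one image collapse onto one in the
#' other, remain matchable.
#'
#' @param desc_a,desc_b `lpm_descriptors` objects or plain matrices with one
#'   unit-norm vector per row; both must have the same vector length.
#' @param threshold_pct match distance threshold as a percentage of the
#'   maximal SSD (2).
#' @param tau_L Lowe ratio threshold.
#' @return data frame with columns `index_a`, `index_b`, `distance` (SSD) and
#'   `ratio` (second-nearest over nearest distance, >= 1, Inf when unique or
#'   exact).
#' @export
lpm_match_descriptors <- function(desc_a, desc_b, threshold_pct = 1, tau_L = 0.6) {
  A <- descriptor_matrix(desc_a)
  B <- descriptor_matrix(desc_b)
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance = numeric(0), ratio = numeric(0))
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  if (ncol(A) != ncol(B)) stop("descriptor lengths differ between the two sets")
  # SSD(a, b) = |a|^2 + |b|^2 - 2 a.b, computed for all pairs at once
  D <- pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0)
  thr <- threshold_pct / 100 * 2
  na <- nrow(A)
  idx_a <- integer(0); idx_b <- integer(0); dist <- numeric(0); rat <- numeric(0)
  for (j in seq_len(ncol(D))) {
    col <- D[, j]
    i1 <- which.min(col)           # lowest index on ties
    d1 <- col[i1]
    d2 <- if (na >= 2) min(col[-i1]) else Inf
    ratio <- if (d1 <= 1e-15) Inf else d2 / d1
    accept <- d1 < thr && (is.infinite(ratio) || d1 < tau_L * d2)
    if (accept) {
      idx_a <- c(idx_a, i1); idx_b <- c(idx_b, j)
      dist <- c(dist, d1); rat <- c(rat, ratio)
    }
  }
  data.frame(index_a = idx_a, index_b = idx_b, distance = dist, ratio = rat)
}

descriptor_matrix <- function(d) {
  if (inherits(d, "lpm_descriptors")) return(d$vectors)
  if (is.matrix(d)) return(d)
  stop("expected an lpm_descriptors object or a matrix of row vectors")
}
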