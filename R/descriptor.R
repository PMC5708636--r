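#' Frequency masks for descriptor extraction
#'
#' The descriptor is built from magnitudes of the 2-D DFT of the log-polar
#' patch, read at a fixed set of DC-centered frequency coordinates (u, v):
#' u is the radial frequency index (along rings, i.e. down the rows of the
#' LPT image) and v the angular frequency index (along each ring).
#'
#' The default mask is a double rectangle
#' `u in [1..radial] union [-radial..-1], v in [1..4]` with radial = 6 for
#' N = 16 and 7 for N = 32, giving vectors of length 48 and 56. Three rules
#' shape it: the DC component (0, 0) is excluded (mean intensity carries no
#' pattern information and its exclusion buys illumination invariance); the
#' whole v = 0 line is excluded because the top/bottom row discontinuity of
#' the LPT image injects artifact energy there ("primarily horizontal"
#' frequencies); and only one of each conjugate pair (u, v) / (-u, -v) is
#' kept since the spectrum of a real image is conjugate-symmetric. More
#' radial than angular indices are kept: intensity changes from the feature
#' center outward are coded more finely than changes along the rings.
#'
#' `lpm_mask` builds a custom mask from an explicit coordinate list and
#' checks the same invariants, enabling application-specific masks.
#'
#' @param N sampling resolution the mask is for (16 or 32 for the default).
#' @return an object of class `lpm_mask`: list with `N`, integer matrix
#'   `selected` (columns u, v; ordered v ascending then u ascending), and the
#'   rectangle extents.
#' @export
lpm_default_mask <- function(N = 32) {
  if (!N %in% c(16L, 32L)) {
    stop("default masks are defined for N = 16 and N = 32; ",
         "use lpm_mask() for other resolutions")
  }
  radial <- if (N == 16) 6L else 7L
  angular <- 4L
  if (N < 2 * radial + 1 || N < 2 * angular + 1) {
    stop("sampling resolution too small for the mask rectangles")
  }
  us <- c(-(radial:1), 1:radial)
  sel <- cbind(u = rep(us, times = angular),
               v = rep(1:angular, each = length(us)))
  structure(list(N = as.integer(N), selected = sel,
                 radial_extent = radial, angular_extent = angular),
            class = "lpm_mask")
}

#' @rdname lpm_default_mask
#' @param selected two-column matrix (or list of pairs) of DC-centered
#'   (u, v) frequency coordinates.
#' @export
lpm_mask <- function(N, selected) {
  if (is.list(selected) && !is.data.frame(selected)) {
    selected <- do.call(rbind, lapply(selected, function(p) as.numeric(p)))
  }
  selected <- as.matrix(selected)
  if (ncol(selected) != 2) stop("mask coordinates must be (u, v) pairs")
  storage.mode(selected) <- "integer"
  colnames(selected) <- c("u", "v")
  if (any(abs(selected) > N / 2)) stop("mask coordinate outside the DC-centered spectrum")
  if (any(selected[, 1] == 0 & selected[, 2] == 0)) stop("mask must exclude the DC component (0, 0)")
  if (any(selected[, 2] == 0)) stop("mask must exclude the v = 0 artifact line")
  key <- paste(selected[, 1], selected[, 2])
  conj <- paste(-selected[, 1], -selected[, 2])
  if (any(duplicated(key))) stop("duplicate mask coordinates")
  if (any(conj %in% key)) stop("mask contains both (u, v) and (-u, -v): redundant half-spectrum pair")
  structure(list(N = as.integer(N), selected = selected,
                 radial_extent = NA_integer_, angular_extent = NA_integer_),
            class = "lpm_mask")
}

#' @export
print.lpm_mask <- function(x, ...) {
  cat(sprintf("frequency mask for N = %d: %d selected coordinates\n",
              x$N, nrow(x$selected)))
  invisible(x)
}

#' Read and write frequency masks as JSON
#'
#' Format: `{"N": 32, "selected": [[u, v], ...]}`.
#'
#' @param mask an `lpm_mask`.
#' @param path JSON file path.
#' @export
lpm_write_mask <- function(mask, path) {
  jsonlite::write_json(list(N = mask$N, selected = unname(mask$selected)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname lpm_write_mask
#' @export
lpm_read_mask <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lpm_mask(j$N, j$selected)
}

#' Compute the feature vector of one log-polar patch
#'
#' Takes the 2-D DFT of the LPT image, reads the magnitudes at the mask's
#' selected coordinates (DC-centered indexing) and normalizes the vector to
#' unit Euclidean length. A patch whose selected magnitudes are all
#' (numerically) zero - e.g. a constant patch, which has energy only at DC -
#' yields a zero vector flagged `degenerate`; callers drop such features
#' rather than emit vectors that would match everything at distance zero.
#'
#' @param lpt N x N numeric matrix from [lpm_sample_patch()].
#' @param mask an `lpm_mask` with matching N.
#' @return numeric vector of length `nrow(mask$selected)` with attribute
#'   `degenerate` (logical).
#' @export
lpm_compute_descriptor <- function(lpt, mask) {
  N <- mask$N
  if (!is.matrix(lpt) || nrow(lpt) != N || ncol(lpt) != N) {
    stop("LPT image size does not match the mask's sampling resolution")
  }
  f <- stats::fft(lpt)
  idx <- cbind((mask$selected[, 1] %% N) + 1L, (mask$selected[, 2] %% N) + 1L)
  vals <- Mod(f[idx])
  nrm <- sqrt(sum(vals^2))
  if (nrm < 1e-12) {
    return(structure(rep(0, length(vals)), degenerate = TRUE))
  }
  structure(vals / nrm, degenerate = FALSE)
}

#' Describe all features of an image
#'
#' Runs the full description pipeline per feature: border removal, log-polar
#' sampling, descriptor extraction; degenerate (flat) patches are dropped.
#' Output order follows input feature order. The image is expected to be
#' pre-smoothed (see [lpm_presmooth()]).
#'
#' @param img numeric matrix (pre-smoothed image).
#' @param features feature data frame.
#' @param N sampling resolution.
#' @param mask frequency mask; default mask for N if omitted.
#' @return an object of class `lpm_descriptors`: list with `vectors` (one row
#'   per described feature), `features` (the corresponding rows of the
#'   input), `N`, `mask`, and drop counts `n_border_removed`, `n_degenerate`.
#' @export
lpm_describe <- function(img, features, N = 32, mask = lpm_default_mask(N)) {
  validate_image(img)
  kept <- lpm_remove_border_features(features, img)
  L <- nrow(mask$selected)
  vecs <- matrix(NA_real_, nrow(kept), L)
  degen <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    lpt <- lpm_sample_patch(img, kept[i, ], N)
    d <- lpm_compute_descriptor(lpt, mask)
    degen[i] <- isTRUE(attr(d, "degenerate"))
    vecs[i, ] <- d
  }
  structure(list(vectors = vecs[!degen, , drop = FALSE],
                 features = kept[!degen, , drop = FALSE],
                 N = N, mask = mask,
                 n_input = nrow(features),
                 n_border_removed = nrow(features) - nrow(kept),
                 n_degenerate = sum(degen)),
            class = "lpm_descriptors")
}

#' @export
print.lpm_descriptors <- function(x, ...) {
  cat(sprintf("%d feature vectors of length %d (N = %d; %d border-removed, %d degenerate)\n",
              nrow(x$vectors), ncol(x$vectors), x$N,
              x$n_border_removed, x$n_degenerate))
  invisible(x)
}

#' Read and write descriptor tables
#'
#' CSV with header `x,y,radius,v0,...,v{L-1}`.
#'
#' @param desc an `lpm_descriptors` object.
#' @param path CSV path.
#' @export
lpm_write_descriptors <- function(desc, path) {
  L <- ncol(desc$vectors)
  v <- as.data.frame(desc$vectors)
  names(v) <- paste0("v", seq_len(L) - 1L)
  out <- cbind(desc$features[, c("x", "y", "radius")], v)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname lpm_write_descriptors
#' @export
lpm_read_descriptors <- function(path) {
  d <- utils::read.csv(path)
  vcols <- grep("^v[0-9]+$", names(d), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  if (length(vcols) == 0) stop("no descriptor columns (v0, v1, ...) in ", path)
  structure(list(vectors = as.matrix(d[, vcols, drop = FALSE]),
                 features = data.frame(d[, c("x", "y", "radius")], source = "file"),
                 N = NA_integer_, mask = NULL,
                 n_input = nrow(d), n_border_removed = 0L, n_degenerate = 0L),
            class = "lpm_descriptors")
}
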