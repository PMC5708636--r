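#' Pipeline configuration
#'
#' Collects every tunable of the matching pipeline with the defaults used
#' throughout: 32 x 32 log-polar sampling, the default double-rectangle
#' frequency mask, 1% match distance threshold, Lowe ratio 0.6, overlap-error
#' threshold 0.4, feature scaling coefficients 14 (DoG/SIFT-type scales) and
#' 9 (Hessian/SURF-type), fixed detector radius 32 px, RANSAC tolerance 3 px,
#' pre-smoothing sigma 1 (variance 1), seed 0.
#'
#' @param N log-polar sampling resolution.
#' @param detector built-in detector to run when no external features are
#'   supplied.
#' @param max_features cap on detected features per image.
#' @param fixed_radius radius for detector output, pixels.
#' @param threshold_pct match threshold, percent of the maximal SSD.
#' @param tau_L Lowe ratio threshold.
#' @param epsilon0 overlap-error threshold for ground-truth evaluation.
#' @param sigma_sift,sigma_surf feature scaling coefficients for external
#'   DoG-type and Hessian-type detector scales.
#' @param ransac_tol RANSAC inlier tolerance, pixels.
#' @param ransac_max_iter RANSAC hypothesis cap.
#' @param seed RNG seed used by verification.
#' @param presmooth_sigma pre-smoothing standard deviation, pixels.
#' @param mask optional `lpm_mask` overriding the default for N.
#' @param scale_pyramid logical; route matching through [lpm_scale_pyramid()].
#' @return list of class `lpm_config`.
#' @export
lpm_config <- function(N = 32, detector = c("harris", "hessian"),
                       max_features = 500, fixed_radius = 32,
                       threshold_pct = 1, tau_L = 0.6, epsilon0 = 0.4,
                       sigma_sift = 14, sigma_surf = 9, ransac_tol = 3,
                       ransac_max_iter = 10000, seed = 0,
                       presmooth_sigma = 1, mask = NULL,
                       scale_pyramid = FALSE) {
  detector <- match.arg(detector)
  structure(list(N = N, detector = detector, max_features = max_features,
                 fixed_radius = fixed_radius, threshold_pct = threshold_pct,
                 tau_L = tau_L, epsilon0 = epsilon0, sigma_sift = sigma_sift,
                 sigma_surf = sigma_surf, ransac_tol = ransac_tol,
                 ransac_max_iter = ransac_max_iter, seed = seed,
                 presmooth_sigma = presmooth_sigma, mask = mask,
                 scale_pyramid = scale_pyramid),
            class = "lpm_config")
}

#' Load a configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys take the [lpm_config()] defaults.
#' A custom mask may be given inline as `mask: {N: ..., selected: [[u,v],..]}`.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return `lpm_config`.
#' @export
lpm_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML or JSON")
  }
  # YAML 1.1 implicit typing turns a bare key `N` into boolean FALSE
  names(vals)[names(vals) == "FALSE"] <- "N"
  if (!is.null(vals$mask)) {
    mn <- vals$mask
    names(mn)[names(mn) == "FALSE"] <- "N"
    vals$mask <- lpm_mask(mn$N, mn$selected)
  }
  known <- names(formals(lpm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(lpm_config, vals)
}

#' Full feature-based matching pipeline
#'
#' Chains every stage on a pair of images: Gaussian pre-smoothing, feature
#' detection (or externally supplied features), log-polar magnitude
#' description, exhaustive thresholded matching with the Lowe ratio test,
#' and RANSAC homography verification; optionally the scale pyramid replaces
#' the single matching pass. Per-stage counts and drop reasons (border
#' removal, degenerate descriptors) are collected in the report.
#'
#' @param img_a,img_b raw images (numeric matrices).
#' @param config an [lpm_config()].
#' @param features_a,features_b optional externally detected feature data
#'   frames (already in pixels, e.g. from [lpm_adapt_external()]); when
#'   supplied the built-in detector is skipped.
#' @return object of class `lpm_result`: list with `report` (named list:
#'   features_a, features_b, candidates, inliers, inlier_ratio, ok,
#'   scenario), `matches` (candidate data frame with coordinates),
#'   `verified` (`lpm_verified`), `homography`, the descriptor objects and
#'   the config. `report$ok` is FALSE when no features, fewer than 4
#'   candidates, or no RANSAC consensus was found.
#' @export
lpm_pipeline <- function(img_a, img_b, config = lpm_config(),
                         features_a = NULL, features_b = NULL) {
  validate_image(img_a)
  validate_image(img_b)
  scenario <- "A_vs_B"
  if (config$scale_pyramid && is.null(features_a) && is.null(features_b)) {
    pyr <- lpm_scale_pyramid(img_a, img_b, config)
    da <- pyr$desc_a; db <- pyr$desc_b
    matches <- pyr$matches
    scenario <- pyr$scenario
    nfa <- da$n_input; nfb <- db$n_input
  } else {
    sa <- lpm_presmooth(img_a, config$presmooth_sigma)
    sb <- lpm_presmooth(img_b, config$presmooth_sigma)
    fa <- features_a %||% run_detector(sa, config)
    fb <- features_b %||% run_detector(sb, config)
    nfa <- nrow(fa); nfb <- nrow(fb)
    mask <- config$mask %||% lpm_default_mask(config$N)
    da <- lpm_describe(sa, fa, config$N, mask)
    db <- lpm_describe(sb, fb, config$N, mask)
    matches <- lpm_match_descriptors(da, db, config$threshold_pct, config$tau_L)
  }
  coords <- match_coordinates(matches, da, db)
  verified <- NULL
  if (nfa > 0 && nfb > 0 && nrow(matches) >= 4) {
    verified <- lpm_ransac_verify(matches, da$features, db$features,
                                  pixel_tol = config$ransac_tol,
                                  seed = config$seed,
                                  max_iter = config$ransac_max_iter)
  }
  ok <- !is.null(verified) && verified$ok
  n_inl <- if (ok) length(verified$inliers) else 0L
  coords$is_inlier <- rep(0L, nrow(coords))
  if (ok) coords$is_inlier[verified$inliers] <- 1L
  report <- list(config_hash = config_checksum(config),
                 features_a = nfa, features_b = nfb,
                 described_a = nrow(da$vectors), described_b = nrow(db$vectors),
                 border_removed_a = da$n_border_removed,
                 border_removed_b = db$n_border_removed,
                 degenerate_a = da$n_degenerate, degenerate_b = db$n_degenerate,
                 candidates = nrow(matches), inliers = n_inl,
                 inlier_ratio = lpm_inlier_ratio(n_inl, nrow(matches)),
                 scenario = scenario, seed = config$seed, ok = ok)
  structure(list(report = report, matches = coords, verified = verified,
                 homography = if (ok) verified$homography else NULL,
                 desc_a = da, desc_b = db, config = config),
            class = "lpm_result")
}

# Order-stable checksum of the configuration, logged with every report so
# runs are attributable to their exact settings.
config_checksum <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

match_coordinates <- function(matches, da, db) {
  if (nrow(matches) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), distance = numeric(0),
                      is_inlier = integer(0)))
  }
  data.frame(x1 = da$features$x[matches$index_a],
             y1 = da$features$y[matches$index_a],
             x2 = db$features$x[matches$index_b],
             y2 = db$features$y[matches$index_b],
             distance = matches$distance,
             is_inlier = 0L)
}

#' @export
print.lpm_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("lpm match result: %d/%d features, %d candidates, %d inliers (ratio %.3f)%s\n",
              r$features_a, r$features_b, r$candidates, r$inliers,
              r$inlier_ratio,
              if (r$ok) "" else " [verification FAILED]"))
  invisible(x)
}

#' @export
summary.lpm_result <- function(object, ...) {
  r <- object$report
  cat("feature matching summary\n")
  cat(sprintf("  features:        A %d, B %d\n", r$features_a, r$features_b))
  cat(sprintf("  described:       A %d (border -%d, flat -%d), B %d (border -%d, flat -%d)\n",
              r$described_a, r$border_removed_a, r$degenerate_a,
              r$described_b, r$border_removed_b, r$degenerate_b))
  cat(sprintf("  candidates:      %d (scenario %s)\n", r$candidates, r$scenario))
  cat(sprintf("  inliers:         %d (inlier ratio %.3f)\n", r$inliers, r$inlier_ratio))
  if (r$ok) {
    cat("  homography:\n")
    print(signif(object$homography, 6))
  } else {
    cat("  verification failed\n")
  }
  invisible(object)
}

#' Plot matched features
#'
#' Draws the two images side by side with line segments joining the matched
#' feature centers; verified inliers are drawn in green, rejected candidates
#' in red.
#'
#' @param x `lpm_result`.
#' @param img_a,img_b the images passed to [lpm_pipeline()].
#' @param max_value intensity mapped to white.
#' @param ... unused.
#' @export
plot.lpm_result <- function(x, img_a, img_b, max_value = 255, ...) {
  ha <- nrow(img_a); wa <- ncol(img_a)
  hb <- nrow(img_b); wb <- ncol(img_b)
  gap <- 10
  graphics::plot(NA, xlim = c(0, wa + gap + wb), ylim = c(max(ha, hb), 0),
                 asp = 1, xlab = "", ylab = "", axes = FALSE)
  graphics::rasterImage(pmin(pmax(img_a / max_value, 0), 1), 0, ha, wa, 0)
  graphics::rasterImage(pmin(pmax(img_b / max_value, 0), 1), wa + gap, hb, wa + gap + wb, 0)
  m <- x$matches
  if (nrow(m)) {
    col <- ifelse(m$is_inlier == 1, "#00cc44", "#cc3333")
    graphics::segments(m$x1, m$y1, wa + gap + m$x2, m$y2, col = col)
  }
  invisible(x)
}

#' Validate a pipeline report against the shipped schema
#'
#' The JSON report written by the CLI follows a minimal schema shipped at
#' `inst/schema/report-schema.json` (required keys and their types). Returns
#' TRUE invisibly or raises an error naming the offending key.
#'
#' @param report named list (a parsed report).
#' @export
lpm_validate_report <- function(report) {
  schema_path <- system.file("schema", "report-schema.json", package = "lpmatch")
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  for (key in schema$required) {
    if (is.null(report[[key]])) stop("report missing required key: ", key)
    type <- schema$properties[[key]]$type
    val <- report[[key]]
    ok <- switch(type,
                 number = is.numeric(val),
                 integer = is.numeric(val) && all(val == round(val)),
                 boolean = is.logical(val),
                 string = is.character(val),
                 TRUE)
    if (!ok) stop("report key has wrong type: ", key, " (expected ", type, ")")
  }
  invisible(TRUE)
}
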