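#' Scale-pyramid matching for unknown zoom differences
#'
#' When two images may differ by a large unknown zoom, five resize scenarios
#' are compared: A vs B, A vs 0.5 B, 0.5 A vs B, A vs 0.25 B and 0.25 A vs B.
#' For each scenario the designated image is resized (bicubic), the full
#' detect - describe - match chain is rerun on the resized pair, and the
#' scenario with the largest raw candidate-match count (before any
#' verification, false matches included) wins. Ties prefer the unresized
#' scenario, then the smaller resize magnitude. Feature coordinates of the
#' winning scenario are scaled back to the original image frames so that
#' verification and display happen at native resolution.
#'
#' With no scale difference between the images, the unresized scenario wins
#' and the result is identical to not using the pyramid at all.
#'
#' @param img_a,img_b raw (un-smoothed) images.
#' @param config an [lpm_config()] fixing detector, sampling resolution,
#'   mask and matching thresholds.
#' @return list with `scenario` (name), `factors` c(fa, fb), `matches`
#'   (candidate data frame), `desc_a`, `desc_b` (descriptors whose feature
#'   coordinates are already rescaled to the original frames), and
#'   `counts` of raw matches per scenario.
#' @export
lpm_scale_pyramid <- function(img_a, img_b, config = lpm_config()) {
  scen <- list(
    list(name = "A_vs_B", fa = 1, fb = 1),
    list(name = "A_vs_0.5B", fa = 1, fb = 0.5),
    list(name = "0.5A_vs_B", fa = 0.5, fb = 1),
    list(name = "A_vs_0.25B", fa = 1, fb = 0.25),
    list(name = "0.25A_vs_B", fa = 0.25, fb = 1)
  )
  best <- NULL
  counts <- stats::setNames(numeric(length(scen)), vapply(scen, `[[`, "", "name"))
  for (s in scen) {
    ia <- if (s$fa == 1) img_a else lpm_resize(img_a, s$fa)
    ib <- if (s$fb == 1) img_b else lpm_resize(img_b, s$fb)
    run <- match_pair_once(ia, ib, config)
    counts[s$name] <- nrow(run$matches)
    if (is.null(best) || nrow(run$matches) > counts[best$name]) {
      best <- c(s, run)
    }
  }
  # map winning-scenario coordinates back to original frames
  best$desc_a$features$x <- best$desc_a$features$x / best$fa
  best$desc_a$features$y <- best$desc_a$features$y / best$fa
  best$desc_a$features$radius <- best$desc_a$features$radius / best$fa
  best$desc_b$features$x <- best$desc_b$features$x / best$fb
  best$desc_b$features$y <- best$desc_b$features$y / best$fb
  best$desc_b$features$radius <- best$desc_b$features$radius / best$fb
  list(scenario = best$name, factors = c(fa = best$fa, fb = best$fb),
       matches = best$matches, desc_a = best$desc_a, desc_b = best$desc_b,
       counts = counts)
}

# One detect -> describe -> match pass on raw images (smoothing included).
match_pair_once <- function(img_a, img_b, config) {
  sa <- lpm_presmooth(img_a, config$presmooth_sigma)
  sb <- lpm_presmooth(img_b, config$presmooth_sigma)
  fa <- run_detector(sa, config)
  fb <- run_detector(sb, config)
  mask <- config$mask %||% lpm_default_mask(config$N)
  da <- lpm_describe(sa, fa, config$N, mask)
  db <- lpm_describe(sb, fb, config$N, mask)
  m <- lpm_match_descriptors(da, db, config$threshold_pct, config$tau_L)
  list(desc_a = da, desc_b = db, matches = m, features_a = fa, features_b = fb)
}

run_detector <- function(img, config) {
  switch(config$detector,
         harris = lpm_detect_harris(img, config$max_features, config$fixed_radius),
         hessian = lpm_detect_hessian(img, config$max_features, config$fixed_radius),
         stop("unknown detector: ", config$detector))
}
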