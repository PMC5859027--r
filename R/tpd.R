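#' Total perfusion deficit (TPD)
#'
#' TPD integrates the extent and the severity of hypoperfusion over the
#' analyzed LV surface into a single percentage:
#' \deqn{TPD = 100 \cdot \frac{\sum_{p \in mask,\ abnormal} w_p s_p}
#'                           {\sum_{p \in mask} w_p}}
#' where `w_p` is the pixel area weight, a pixel is abnormal when its uptake
#' falls `threshold_mad` MADs below the gender-matched normal mean, and the
#' severity `s_p` is the fractional deficit `(mean_p - value_p) / mean_p`
#' clamped to `[0, 1]`. A map with no visible uptake anywhere scores 100%; a
#' map equal to the normal mean scores 0%.
#'
#' The severity definition is a configuration hook: pass `severity_fun` to
#' substitute another map from (value, limits) to a per-pixel severity grid
#' (for example a deviation-proportional score).
#'
#' @param map a normalized [polar_map()] (or the all-zero map, which skips
#'   normalization by convention).
#' @param limits gender-matched [fit_normal_limits()].
#' @param mask a [coverage_mask()]; use [whole_heart_mask()] for full
#'   coverage or [build_three_slice_mask()] for simulated 3-slice coverage.
#' @param model the [build_segment_model()] describing the grid.
#' @param severity_fun optional `function(values, limits)` returning an
#'   `R x A` severity grid in `[0, 1]`; default is the clamped fractional
#'   deficit relative to the normal mean.
#' @return TPD as a percentage in `[0, 100]`.
#' @export
compute_tpd <- function(map, limits, mask, model, severity_fun = NULL) {
  stopifnot(is_polar_map(map), inherits(limits, "normal_limits"),
            inherits(mask, "coverage_mask"), inherits(model, "segment_model"))
  check_grid_shape(map$values, model)
  check_grid_shape(mask$include, model)
  if (!any(mask$include)) stop("coverage mask is empty")
  dev <- deviation_map(map, limits)
  abn <- abnormality_mask(dev, limits$threshold_mad)
  sev <- if (is.null(severity_fun)) {
    fractional_deficit(map$values, limits)
  } else {
    pmin(pmax(severity_fun(map$values, limits), 0), 1)
  }
  w <- model$weight
  inc <- mask$include
  100 * sum(w[inc & abn] * sev[inc & abn]) / sum(w[inc])
}

# Default severity: fractional deficit below the normal mean, clamped to
# [0, 1]. Pixels whose normal mean is ~0 carry no severity (nothing to lose).
fractional_deficit <- function(values, limits) {
  mu <- limits$mean
  s <- ifelse(mu > 0, (mu - values) / pmax(mu, .Machine$double.eps), 0)
  pmin(pmax(s, 0), 1)
}

#' Simulated 3-slice coverage mask
#'
#' Models the conventional 3-slice short-axis acquisition (basal,
#' mid-ventricular and apical positions, ~10 mm slice thickness each) by
#' selecting, in each of the apical, mid and basal ring zones, the two
#' consecutive rings centred on the zone's ring midpoint (the rings at local
#' 0-based offsets `floor((n-1)/2)` and `floor((n-1)/2) + 1`; a 2-ring zone
#' contributes both its rings). All sectors of a selected ring are included;
#' apex-cap rings are never included, which is exactly how 3-slice imaging
#' misses apical defects.
#'
#' @param model a [build_segment_model()]; the apical, mid and basal zones
#'   must each have at least 2 rings.
#' @return A [coverage_mask()] covering 6 rings (`6 * A` pixels).
#' @export
build_three_slice_mask <- function(model) {
  stopifnot(inherits(model, "segment_model"))
  include <- matrix(FALSE, nrow = model$R, ncol = model$A)
  for (zone in c("apical", "mid", "basal")) {
    rr <- model$zone_rings[[zone]]
    n <- length(rr)
    if (n < 2L) stop("zone '", zone, "' has fewer than 2 rings")
    start <- floor((n - 1) / 2)          # 0-based midpoint ring
    include[rr[start + c(1L, 2L)], ] <- TRUE
  }
  coverage_mask(include)
}

#' @rdname compute_tpd
#' @export
compute_three_slice_tpd <- function(map, limits, model, severity_fun = NULL) {
  compute_tpd(map, limits, build_three_slice_mask(model), model,
              severity_fun = severity_fun)
}

#' Per-segment defect extent
#'
#' For each AHA segment, the percentage of the segment's weighted area whose
#' pixels are abnormal (below the MAD threshold), as printed inside the
#' segments of a quantitative polar-map display.
#'
#' @inheritParams compute_tpd
#' @return named numeric vector `seg1` .. `seg17` of extents in `[0, 100]`.
#' @export
segment_extents <- function(map, limits, model) {
  stopifnot(is_polar_map(map), inherits(limits, "normal_limits"),
            inherits(model, "segment_model"))
  check_grid_shape(map$values, model)
  dev <- deviation_map(map, limits)
  abn <- abnormality_mask(dev, limits$threshold_mad)
  w <- model$weight
  ext <- vapply(seq_len(17L), function(s) {
    in_seg <- model$segment == s
    100 * sum(w[in_seg & abn]) / sum(w[in_seg])
  }, numeric(1L))
  stats::setNames(ext, paste0("seg", seq_len(17L)))
}

#' Score one patient with both coverage models
#'
#' Convenience wrapper computing the whole-heart TPD, the 3-slice TPD, the
#' abnormal area percentage and the 17 per-segment extents for one map.
#' The map is normalized on the fly unless it already is (the all-zero map
#' passes through unnormalized).
#'
#' @inheritParams compute_tpd
#' @return a one-row `data.frame` with columns `subject_id`, `gender`,
#'   `whole_heart_tpd`, `three_slice_tpd`, `abnormal_area_percent`,
#'   `seg1` .. `seg17`.
#' @export
score_patient <- function(map, limits, model, severity_fun = NULL) {
  if (!map$normalized && !is_blank_map(map)) map <- normalize_map(map)
  wh <- compute_tpd(map, limits, whole_heart_mask(model), model, severity_fun)
  ts <- compute_three_slice_tpd(map, limits, model, severity_fun)
  dev <- deviation_map(map, limits)
  abn <- abnormality_mask(dev, limits$threshold_mad)
  area <- 100 * sum(model$weight[abn]) / sum(model$weight)
  ext <- segment_extents(map, limits, model)
  cbind(
    data.frame(subject_id = map$subject_id, gender = map$gender,
               whole_heart_tpd = wh, three_slice_tpd = ts,
               abnormal_area_percent = area, stringsAsFactors = FALSE),
    as.data.frame(as.list(ext)))
}
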