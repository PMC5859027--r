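#' Gender-matched normal perfusion limits
#'
#' Normal limits summarize a defect-free reference cohort pixel by pixel: the
#' arithmetic mean of normalized uptake and the mean absolute deviation (MAD)
#' about that mean. A patient pixel is called hypoperfused when it falls at
#' least `threshold_mad` MADs below the normal mean (3.0 MAD by default,
#' equivalent to roughly 2.5 standard deviations for Gaussian pixel noise,
#' since MAD/SD -> sqrt(2/pi) ~ 0.798).
#'
#' `mad_floor` bounds the per-pixel MAD away from zero so that pixels with
#' near-deterministic normal uptake do not produce unbounded deviation scores;
#' it is expressed on the normalized 0-100 uptake scale.
#'
#' @param maps list of normalized [polar_map()]s from a single gender,
#'   at least two, all on the same grid.
#' @param gender `"male"` or `"female"`; defaults to the gender of the maps
#'   and is checked against every map.
#' @param threshold_mad abnormality threshold in MAD units (default 3.0).
#' @param mad_floor lower bound for the per-pixel MAD (default 1.0).
#'
#' @return An object of class `normal_limits` with elements `gender`, `mean`,
#'   `mad` (both `R x A` matrices), `threshold_mad`, `mad_floor`, `n_subjects`.
#' @export
fit_normal_limits <- function(maps, gender = NULL, threshold_mad = 3,
                              mad_floor = 1) {
  if (!is.list(maps) || length(maps) < 2L) {
    stop("need at least 2 normal maps to fit limits")
  }
  if (!all(vapply(maps, is_polar_map, TRUE))) stop("all inputs must be polar_map")
  genders <- unname(vapply(maps, `[[`, "", "gender"))
  if (length(unique(genders)) != 1L) {
    stop("normal limits must be fit from a single gender")
  }
  if (is.null(gender)) gender <- genders[1L]
  if (!identical(gender, genders[1L])) {
    stop("maps are ", genders[1L], " but gender = ", gender)
  }
  if (!all(vapply(maps, `[[`, TRUE, "normalized"))) {
    stop("all maps must be normalized before fitting limits")
  }
  dims <- vapply(maps, function(m) dim(m$values), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all maps must share one grid shape")
  }
  if (threshold_mad <= 0 || mad_floor <= 0) {
    stop("threshold_mad and mad_floor must be positive")
  }
  stack <- vapply(maps, `[[`, maps[[1L]]$values, "values")  # R x A x n
  mu <- apply(stack, c(1L, 2L), mean)
  mad <- apply(abs(sweep(stack, c(1L, 2L), mu)), c(1L, 2L), mean)
  structure(
    list(gender = gender, mean = mu, mad = pmax(mad, mad_floor),
         threshold_mad = threshold_mad, mad_floor = mad_floor,
         n_subjects = length(maps)),
    class = "normal_limits")
}

#' @export
print.normal_limits <- function(x, ...) {
  cat(sprintf(
    "<normal_limits> gender=%s n=%d grid=%dx%d threshold=%.1f MAD (floor %.2f)\n",
    x$gender, x$n_subjects, nrow(x$mean), ncol(x$mean),
    x$threshold_mad, x$mad_floor))
  invisible(x)
}

#' Hypoperfusion deviation grid
#'
#' Per-pixel one-sided deviation `d = max(0, (mean - value) / mad)` of a
#' normalized patient map below the gender-matched normal mean, in MAD units.
#' Super-normal uptake scores 0: only deficits count.
#'
#' @param map a normalized [polar_map()] (the all-zero map is also accepted:
#'   it cannot be count-normalized but is maximally hypoperfused by
#'   construction).
#' @param limits a [fit_normal_limits()] object of the same gender.
#' @return numeric `R x A` matrix of deviations (>= 0).
#' @export
deviation_map <- function(map, limits) {
  stopifnot(is_polar_map(map), inherits(limits, "normal_limits"))
  if (!identical(map$gender, limits$gender)) {
    stop("map gender (", map$gender, ") does not match limits gender (",
         limits$gender, ")")
  }
  if (!map$normalized && !is_blank_map(map)) {
    stop("map must be normalized (see normalize_map) before limits comparison")
  }
  if (!identical(dim(map$values), dim(limits$mean))) {
    stop("map grid shape does not match limits grid")
  }
  pmax((limits$mean - map$values) / limits$mad, 0)
}

#' Abnormality mask from a deviation grid
#'
#' Flags pixels whose hypoperfusion deviation reaches the MAD threshold.
#' The boundary is inclusive: `d >= threshold_mad` is abnormal.
#'
#' @param dev deviation grid from [deviation_map()].
#' @param threshold_mad positive threshold in MAD units.
#' @return logical matrix of the same shape.
#' @export
abnormality_mask <- function(dev, threshold_mad = 3) {
  if (threshold_mad <= 0) stop("threshold_mad must be positive")
  dev >= threshold_mad
}

#' Serialize normal limits
#'
#' Writes (or reads back) a limits object as two polar-map files
#' (`<prefix>_mean.txt`, `<prefix>_mad.txt`) plus a JSON metadata sidecar
#' (`<prefix>_meta.json`) carrying gender, threshold, MAD floor and cohort
#' size.
#'
#' @param limits a [fit_normal_limits()] object.
#' @param prefix path prefix for the three files.
#' @return `write_normal_limits()` invisibly returns `prefix`;
#'   `read_normal_limits()` returns the `normal_limits` object.
#' @export
write_normal_limits <- function(limits, prefix) {
  stopifnot(inherits(limits, "normal_limits"))
  write_polar_map(polar_map(limits$mean, "limits_mean", limits$gender,
                            normalized = TRUE),
                  paste0(prefix, "_mean.txt"))
  write_polar_map(polar_map(limits$mad, "limits_mad", limits$gender,
                            normalized = TRUE),
                  paste0(prefix, "_mad.txt"))
  meta <- list(gender = limits$gender, threshold_mad = limits$threshold_mad,
               mad_floor = limits$mad_floor, n_subjects = limits$n_subjects)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_normal_limits
#' @export
read_normal_limits <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  mean_map <- read_polar_map(paste0(prefix, "_mean.txt"))
  mad_map <- read_polar_map(paste0(prefix, "_mad.txt"))
  structure(
    list(gender = meta$gender, mean = mean_map$values, mad = mad_map$values,
         threshold_mad = meta$threshold_mad, mad_floor = meta$mad_floor,
         n_subjects = meta$n_subjects),
    class = "normal_limits")
}
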