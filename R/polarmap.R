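#' Polar map of relative myocardial tracer uptake
#'
#' A polar map ("bullseye") is the standard 2-D projection of left-ventricular
#' myocardial uptake: the apex maps to the centre of a disc and the base to its
#' rim. The grid is indexed by ring (short-axis position, ring 1 at the apex
#' centre, ring `R` at the base) and by sector (circumferential angle, sector 1
#' anchored at the anterior wall, increasing counterclockwise as viewed from
#' the apex).
#'
#' @param values numeric `R x A` matrix of non-negative relative uptake values;
#'   rows are rings (apex outward), columns are sectors.
#' @param subject_id opaque subject identifier.
#' @param gender `"male"` or `"female"`.
#' @param normalized logical; `TRUE` once [normalize_map()] has scaled the map
#'   so its reference statistic equals 100.
#'
#' @return An object of class `polar_map`.
#' @seealso [normalize_map()], [read_polar_map()], [build_segment_model()]
#' @export
polar_map <- function(values, subject_id = "unknown",
                      gender = c("male", "female"), normalized = FALSE) {
  gender <- match.arg(gender)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (rings x sectors)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("polar map values must be finite and non-missing")
  }
  if (any(values < 0)) {
    stop("polar map values must be non-negative")
  }
  structure(
    list(subject_id = as.character(subject_id), gender = gender,
         values = unname(values), normalized = isTRUE(normalized)),
    class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("<polar_map> subject=%s gender=%s grid=%dx%d normalized=%s\n",
              x$subject_id, x$gender, nrow(x$values), ncol(x$values),
              x$normalized))
  invisible(x)
}

#' @rdname polar_map
#' @param x object to test.
#' @export
is_polar_map <- function(x) inherits(x, "polar_map")

# TRUE for the degenerate no-uptake map, which cannot be count-normalized but
# is still scoreable (it is maximally abnormal against any limits).
is_blank_map <- function(map) max(map$values) <= 0

#' AHA 17-segment model on a polar-map grid
#'
#' Partitions an `R x A` polar-map grid into the standard American Heart
#' Association 17-segment left-ventricular model: six basal segments (1-6),
#' six mid-cavity segments (7-12), four apical segments (13-16) and the apex
#' cap (17). Rings are allocated to the four radial zones (apex cap, apical,
#' mid, basal, from the centre outward) by rounding `zone_fractions * R` with
#' largest-remainder tie-breaking; every zone gets at least one ring and the
#' apical/mid/basal zones at least two (so a two-ring slice band fits).
#'
#' Basal and mid zones are split into 6 equal angular sectors, the apical zone
#' into 4, and the apex cap is segment 17 regardless of angle. With sector 1
#' at the anterior wall, counterclockwise, the 60-degree bins map to segments
#' in the standard order anterior, anteroseptal, inferoseptal, inferior,
#' inferolateral, anterolateral (basal 1-6, mid 7-12) and the 90-degree bins
#' to apical anterior, septal, inferior, lateral (13-16).
#'
#' Each pixel carries an area weight `w = 2r - 1` (ring `r`, 1-based),
#' proportional to the annulus area an equal-width ring occupies on the
#' display disc. With the default quarter-ring zones this reproduces the
#' conventional bullseye area shares: apex cap 1/16, apical 3/16, mid 5/16,
#' basal 7/16 of the LV surface.
#'
#' @param R number of rings (>= 8).
#' @param A number of sectors; must be divisible by 12 so 6- and 4-sector
#'   zones tile exactly.
#' @param zone_fractions numeric length-4 vector of ring-share proportions for
#'   (apex cap, apical, mid, basal); must sum to 1.
#'
#' @return An object of class `segment_model` with elements `R`, `A`,
#'   `zone_rings` (named list of 1-based ring indices per zone), `segment`
#'   (`R x A` integer matrix of segment ids 1-17), `weight` (`R x A` area
#'   weights) and `zone_fractions`.
#' @export
build_segment_model <- function(R = 24L, A = 36L,
                                zone_fractions = c(0.25, 0.25, 0.25, 0.25)) {
  R <- as.integer(R); A <- as.integer(A)
  if (is.na(R) || R < 8L) stop("R must be an integer >= 8")
  if (is.na(A) || A < 12L || A %% 12L != 0L) {
    stop("A must be a positive multiple of 12")
  }
  if (length(zone_fractions) != 4L || any(zone_fractions < 0) ||
      abs(sum(zone_fractions) - 1) > 1e-8) {
    stop("zone_fractions must be 4 non-negative proportions summing to 1")
  }
  counts <- allocate_rings(R, zone_fractions)
  bounds <- cumsum(counts)
  zone_rings <- list(
    apex   = seq_len(counts[1L]),
    apical = seq.int(bounds[1L] + 1L, bounds[2L]),
    mid    = seq.int(bounds[2L] + 1L, bounds[3L]),
    basal  = seq.int(bounds[3L] + 1L, bounds[4L]))

  seg <- matrix(NA_integer_, nrow = R, ncol = A)
  sec6 <- rep(seq_len(6L), each = A / 6L)   # 60-degree bins
  sec4 <- rep(seq_len(4L), each = A / 4L)   # 90-degree bins
  seg[zone_rings$apex, ]   <- 17L
  seg[zone_rings$apical, ] <- matrix(12L + sec4, nrow = counts[2L],
                                     ncol = A, byrow = TRUE)
  seg[zone_rings$mid, ]    <- matrix(6L + sec6, nrow = counts[3L],
                                     ncol = A, byrow = TRUE)
  seg[zone_rings$basal, ]  <- matrix(sec6, nrow = counts[4L],
                                     ncol = A, byrow = TRUE)

  weight <- matrix(rep(2 * seq_len(R) - 1, times = A), nrow = R, ncol = A)

  structure(
    list(R = R, A = A, zone_rings = zone_rings, segment = seg,
         weight = weight, zone_fractions = zone_fractions),
    class = "segment_model")
}

# Largest-remainder apportionment of R rings to the four zones, then enforce
# the minimum ring counts (1 for the apex cap, 2 for the slice-bearing zones)
# by borrowing from the largest zone.
allocate_rings <- function(R, fractions) {
  quota <- fractions * R
  counts <- floor(quota)
  left <- R - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    for (i in order(-rem, seq_along(rem))[seq_len(left)]) {
      counts[i] <- counts[i] + 1
    }
  }
  mins <- c(1L, 2L, 2L, 2L)
  for (i in seq_len(4L)) {
    while (counts[i] < mins[i]) {
      donor <- which.max(counts - mins)
      if (counts[donor] - mins[donor] <= 0) {
        stop("cannot allocate rings: R too small for the zone minimums")
      }
      counts[donor] <- counts[donor] - 1
      counts[i] <- counts[i] + 1
    }
  }
  as.integer(counts)
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("<segment_model> %d rings x %d sectors; zone rings a/a/m/b = %s\n",
              x$R, x$A,
              paste(vapply(x$zone_rings, length, 1L), collapse = "/")))
  invisible(x)
}

#' Coverage masks over a polar-map grid
#'
#' A coverage mask is a boolean `R x A` grid selecting the polar-map pixels
#' that an acquisition "sees". [whole_heart_mask()] includes every pixel;
#' [build_three_slice_mask()] is defined with the TPD operations.
#'
#' @param include logical `R x A` matrix.
#' @return An object of class `coverage_mask`.
#' @export
coverage_mask <- function(include) {
  if (!is.matrix(include) || !is.logical(include) || anyNA(include)) {
    stop("'include' must be a logical matrix without NAs")
  }
  structure(list(include = unname(include)), class = "coverage_mask")
}

#' @rdname coverage_mask
#' @param model a [build_segment_model()] object.
#' @export
whole_heart_mask <- function(model) {
  coverage_mask(matrix(TRUE, nrow = model$R, ncol = model$A))
}

#' Count-normalize a polar map
#'
#' Scales all pixel values by a single positive constant so that a reference
#' statistic equals 100. The default reference is the mean of the brightest
#' decile of pixels, a robust stand-in for the "most normal" myocardium that
#' is insensitive to defects covering less than 90% of the surface. The
#' operation is idempotent.
#'
#' @param map a [polar_map()].
#' @param reference `"brightest_decile"` (mean of the top 10% of pixel values)
#'   or `"max"` (the single brightest pixel).
#' @return The normalized `polar_map` (with `normalized = TRUE`).
#' @export
normalize_map <- function(map, reference = c("brightest_decile", "max")) {
  stopifnot(is_polar_map(map))
  reference <- match.arg(reference)
  v <- map$values
  if (max(v) <= 0) stop("cannot normalize an all-zero polar map")
  ref <- switch(reference,
    brightest_decile = {
      k <- max(1L, ceiling(0.1 * length(v)))
      mean(sort(as.numeric(v), decreasing = TRUE)[seq_len(k)])
    },
    max = max(v))
  map$values <- v * (100 / ref)
  map$normalized <- TRUE
  map
}

#' Read and write polar-map files
#'
#' The on-disk format is a plain-text delimited matrix preceded by `#` header
#' lines `subject_id=`, `gender=`, `rings=`, `sectors=`, and optionally
#' `normalized=`. Each of the `rings` data lines holds `sectors`
#' whitespace-separated non-negative values; ring 1 (apex centre) comes first
#' and sector 1 is anchored at the anterior wall, counterclockwise viewed from
#' the apex. CRLF and LF line endings parse identically.
#'
#' @param path file path.
#' @return `read_polar_map()` returns a [polar_map()]; `write_polar_map()`
#'   invisibly returns `path`.
#' @export
read_polar_map <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  meta <- parse_header(header)
  for (key in c("subject_id", "gender", "rings", "sectors")) {
    if (is.null(meta[[key]])) stop("missing header field '", key, "' in ", path)
  }
  R <- as.integer(meta$rings); A <- as.integer(meta$sectors)
  if (length(body) != R) {
    stop(sprintf("expected %d data rows, found %d in %s", R, length(body), path))
  }
  rows <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), as.numeric)
  if (any(lengths(rows) != A)) {
    stop(sprintf("expected %d values per row in %s", A, path))
  }
  values <- do.call(rbind, rows)
  if (anyNA(values)) stop("non-numeric polar-map values in ", path)
  if (any(values < 0)) stop("negative polar-map values in ", path)
  polar_map(values, subject_id = meta$subject_id, gender = meta$gender,
            normalized = identical(meta$normalized, "TRUE"))
}

parse_header <- function(header) {
  kv <- sub("^#\\s*", "", header)
  kv <- kv[grepl("=", kv)]
  keys <- trimws(sub("=.*$", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' @rdname read_polar_map
#' @param map a [polar_map()].
#' @param digits number of significant digits stored.
#' @export
write_polar_map <- function(map, path, digits = 10) {
  stopifnot(is_polar_map(map))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# subject_id=", map$subject_id),
    paste0("# gender=", map$gender),
    paste0("# rings=", nrow(map$values)),
    paste0("# sectors=", ncol(map$values)),
    paste0("# normalized=", map$normalized)), con)
  writeLines(apply(map$values, 1L, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t")
  }), con)
  invisible(path)
}

# Shared shape check used by the scoring operations.
check_grid_shape <- function(values, model) {
  if (!identical(dim(values), c(model$R, model$A))) {
    stop(sprintf("grid shape %dx%d does not match model %dx%d",
                 nrow(values), ncol(values), model$R, model$A))
  }
  invisible(TRUE)
}
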