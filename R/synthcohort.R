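#' Coronary territory of each AHA segment
#'
#' Standard assignment of the 17 AHA segments to the three epicardial
#' coronary territories: LAD gets the anterior/anteroseptal wall and the apex
#' (1, 2, 7, 8, 13, 14, 17), RCA the inferior/inferoseptal wall
#' (3, 4, 9, 10, 15) and LCX the lateral wall (5, 6, 11, 12, 16).
#'
#' @param model a [build_segment_model()] (the assignment itself is
#'   model-independent; the model is accepted for interface symmetry and
#'   validated).
#' @return named character vector of length 17 mapping segment id to
#'   `"LAD"`, `"LCX"` or `"RCA"`.
#' @export
territory_map <- function(model = NULL) {
  if (!is.null(model)) stopifnot(inherits(model, "segment_model"))
  stats::setNames(
    c("LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
      "LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
      "LAD", "LAD", "RCA", "LCX",
      "LAD"),
    paste0("seg", 1:17))
}

#' Gender-specific baseline uptake profile
#'
#' Smooth defect-free uptake surface: a gender-specific peak at the apex with
#' a mild linear apex-to-base gradient, on the raw (pre-normalization) count
#' scale. Real normal databases show exactly this kind of gentle radial
#' falloff; the absolute level is arbitrary because downstream scoring is
#' normalization-invariant.
#'
#' @param gender `"male"` or `"female"`.
#' @param model a [build_segment_model()].
#' @param peak apex uptake level (defaults: male 90, female 86).
#' @param gradient total apex-to-base drop (default 8).
#' @return numeric `R x A` matrix.
#' @export
baseline_profile <- function(gender = c("male", "female"), model,
                             peak = NULL, gradient = 8) {
  gender <- match.arg(gender)
  if (is.null(peak)) peak <- if (gender == "male") 90 else 86
  radial <- peak - gradient * (seq_len(model$R) - 1) / (model$R - 1)
  matrix(rep(radial, times = model$A), nrow = model$R, ncol = model$A)
}

#' Generate a defect-free (normal) polar map
#'
#' Baseline profile plus independent Gaussian pixel noise, truncated at 0.
#' Draws from R's global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @inheritParams baseline_profile
#' @param noise_sd pixel noise SD on the baseline scale (> 0).
#' @param baseline optional baseline matrix overriding [baseline_profile()].
#' @param subject_id identifier for the generated map.
#' @return an unnormalized [polar_map()].
#' @export
generate_normal_map <- function(gender = c("male", "female"), model,
                                noise_sd = 8, baseline = NULL,
                                subject_id = "normal") {
  gender <- match.arg(gender)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(baseline)) baseline <- baseline_profile(gender, model)
  check_grid_shape(baseline, model)
  noise <- matrix(stats::rnorm(model$R * model$A, 0, noise_sd),
                  nrow = model$R, ncol = model$A)
  polar_map(pmax(baseline + noise, 0), subject_id = subject_id,
            gender = gender)
}

#' Disease specification for one defect
#'
#' Describes a single perfusion defect: the vessels involved, the fractional
#' uptake deficit (`defect_severity`) and the fraction of the territory's
#' weighted area affected (`defect_extent`), both in `(0, 1]`. The
#' `apical_only` variant models single-vessel LAD disease whose defect is
#' confined to the apex cap (segment 17).
#'
#' @param vessels character subset of `c("LAD", "LCX", "RCA")`.
#' @param defect_severity fractional deficit in `(0, 1]`.
#' @param defect_extent fraction of territory affected in `(0, 1]`.
#' @param apical_only logical; if `TRUE`, `vessels` must be exactly `"LAD"`
#'   and the defect is confined to segment 17.
#' @return an object of class `disease_spec`.
#' @export
disease_spec <- function(vessels, defect_severity, defect_extent,
                         apical_only = FALSE) {
  vessels <- unique(as.character(vessels))
  if (length(vessels) < 1L || !all(vessels %in% c("LAD", "LCX", "RCA"))) {
    stop("vessels must be a non-empty subset of LAD, LCX, RCA")
  }
  if (apical_only && !identical(vessels, "LAD")) {
    stop("apical_only requires vessels = 'LAD' only")
  }
  if (defect_severity <= 0 || defect_severity > 1) {
    stop("defect_severity must be in (0, 1]")
  }
  if (defect_extent <= 0 || defect_extent > 1) {
    stop("defect_extent must be in (0, 1]")
  }
  structure(list(vessels = vessels, defect_severity = defect_severity,
                 defect_extent = defect_extent,
                 apical_only = isTRUE(apical_only)),
            class = "disease_spec")
}

# Contiguous region grown from a random seed pixel inside the candidate set
# until the region's weighted area reaches `extent` of the candidate total.
# Adjacency: ring neighbours (r +/- 1, same sector) and circumferential
# neighbours (same ring, sector +/- 1 with wraparound). Returns a logical
# R x A matrix. Consumes the global RNG.
grow_region <- function(model, candidates, extent) {
  R <- model$R; A <- model$A
  w <- model$weight
  cand_idx <- which(candidates)
  target <- extent * sum(w[cand_idx])
  in_cand <- candidates
  region <- matrix(FALSE, R, A)

  neighbours <- function(i) {
    r <- (i - 1L) %% R + 1L
    a <- (i - 1L) %/% R + 1L
    a_prev <- if (a == 1L) A else a - 1L   # circumferential wraparound
    a_next <- if (a == A) 1L else a + 1L
    c(if (r > 1L) i - 1L, if (r < R) i + 1L,
      (a_prev - 1L) * R + r, (a_next - 1L) * R + r)
  }

  seed <- cand_idx[sample.int(length(cand_idx), 1L)]
  region[seed] <- TRUE
  total <- w[seed]
  frontier <- setdiff(neighbours(seed)[in_cand[neighbours(seed)]], seed)
  while (total < target - 1e-9 && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (region[pick]) next
    region[pick] <- TRUE
    total <- total + w[pick]
    nb <- neighbours(pick)
    nb <- nb[in_cand[nb] & !region[nb]]
    frontier <- unique(c(frontier, nb))
  }
  region
}

#' Generate a patient polar map with planted defects
#'
#' Builds a noisy baseline map and applies each defect multiplicatively:
#' within a contiguous region grown from a random seed pixel inside the
#' vessel's territory (or inside segment 17 for `apical_only`), uptake is
#' multiplied by `1 - defect_severity`. Noise is part of the underlying
#' count signal, so a severity-1.0 defect zeroes the affected pixels.
#'
#' @param specs a [disease_spec()] or a list of them (several defects
#'   combine multiplicatively where they overlap).
#' @inheritParams generate_normal_map
#' @return a list with elements `map` (unnormalized [polar_map()]) and
#'   `truth` (a one-row `data.frame` summarizing the planted defects).
#' @export
generate_patient_map <- function(specs, gender = c("male", "female"), model,
                                 noise_sd = 8, baseline = NULL,
                                 subject_id = "patient") {
  gender <- match.arg(gender)
  if (inherits(specs, "disease_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "disease_spec")))
  if (is.null(baseline)) baseline <- baseline_profile(gender, model)
  noise <- matrix(stats::rnorm(model$R * model$A, 0, noise_sd),
                  nrow = model$R, ncol = model$A)
  values <- pmax(baseline + noise, 0)

  terr <- territory_map(model)
  vessels_hit <- character(0)
  for (spec in specs) {
    vessels_hit <- union(vessels_hit, spec$vessels)
    for (v in spec$vessels) {
      candidates <- if (spec$apical_only) {
        model$segment == 17L
      } else {
        matrix(terr[model$segment] == v, nrow = model$R, ncol = model$A)
      }
      region <- grow_region(model, candidates, spec$defect_extent)
      values[region] <- values[region] * (1 - spec$defect_severity)
    }
  }
  truth <- data.frame(
    subject_id = subject_id, gender = gender,
    n_defects = length(specs),
    vessels = paste(sort(vessels_hit), collapse = "+"),
    apical_only = any(vapply(specs, `[[`, TRUE, "apical_only")),
    max_severity = max(vapply(specs, `[[`, 1, "defect_severity")),
    stringsAsFactors = FALSE)
  list(map = polar_map(values, subject_id = subject_id, gender = gender),
       truth = truth)
}

#' Cohort generator configuration
#'
#' Captures the statistical structure of the emulated clinical population:
#' 651 patients referred for stress imaging with correlative angiography, of
#' whom 29% have no significant CAD, 36% single-vessel, 19% two-vessel, 11%
#' three-vessel disease and ~5% stenosis only in a diagonal/marginal/PDA
#' branch (modelled as a small-extent defect in the parent territory).
#' Significant CAD means >= 70% stenosis.
#'
#' Two mechanisms decouple angiographic truth from the perfusion phenotype,
#' as in real referral populations: a stenotic vessel is hemodynamically
#' *silent* (no perfusion defect despite >= 70% stenosis) with probability
#' `silent_fraction`, and any patient can carry a mild artifactual defect
#' (attenuation, microvascular) with probability `artifact_fraction`. Both
#' are needed for imperfect sensitivity/specificity and AUCs in the realistic
#' 0.80-0.90 band.
#'
#' @param n_patients cohort size (default 651).
#' @param mixture named probabilities over
#'   `c(none, one, two, three, branch)`; must sum to 1 (defaults: the
#'   187/232/127/70/35 of 651 clinical mixture).
#' @param apical_fraction probability that a non-silent single-vessel LAD
#'   case is the apex-confined variant (default 0.3).
#' @param male_fraction probability of male gender (default 0.57).
#' @param noise_sd pixel noise SD on the 0-100 scale (default 8).
#' @param severity_range,extent_range uniform draw ranges for epicardial
#'   defects (defaults (0.3, 0.9) and (0.1, 0.6)).
#' @param apical_severity_range,apical_extent_range ranges for the severe
#'   apex-confined phenotype (defaults (0.5, 0.95) and (0.8, 1)).
#' @param branch_extent_range extent range for branch-only disease
#'   (default (0.03, 0.15)).
#' @param silent_fraction per-vessel probability of no perfusion defect
#'   despite significant stenosis (default 0.3).
#' @param artifact_fraction probability of a mild artifactual defect in any
#'   patient (default 0.4).
#' @param artifact_severity_range,artifact_extent_range ranges for artifact
#'   defects (defaults (0.2, 0.6) and (0.05, 0.4)).
#' @param seed integer RNG seed making the cohort fully reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 651L,
                          mixture = c(none = 187, one = 232, two = 127,
                                      three = 70, branch = 35) / 651,
                          apical_fraction = 0.3,
                          male_fraction = 0.57,
                          noise_sd = 8,
                          severity_range = c(0.3, 0.9),
                          extent_range = c(0.1, 0.6),
                          apical_severity_range = c(0.5, 0.95),
                          apical_extent_range = c(0.8, 1),
                          branch_extent_range = c(0.03, 0.15),
                          silent_fraction = 0.3,
                          artifact_fraction = 0.4,
                          artifact_severity_range = c(0.2, 0.6),
                          artifact_extent_range = c(0.05, 0.4),
                          seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (length(mixture) != 5L ||
      !setequal(names(mixture), c("none", "one", "two", "three", "branch"))) {
    stop("mixture must be named over none/one/two/three/branch")
  }
  mixture <- mixture[c("none", "one", "two", "three", "branch")]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture must be non-negative and sum to 1")
  }
  fr <- c(apical_fraction, male_fraction, silent_fraction, artifact_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(
    list(n_patients = as.integer(n_patients), mixture = mixture,
         apical_fraction = apical_fraction, male_fraction = male_fraction,
         noise_sd = noise_sd, severity_range = severity_range,
         extent_range = extent_range,
         apical_severity_range = apical_severity_range,
         apical_extent_range = apical_extent_range,
         branch_extent_range = branch_extent_range,
         silent_fraction = silent_fraction,
         artifact_fraction = artifact_fraction,
         artifact_severity_range = artifact_severity_range,
         artifact_extent_range = artifact_extent_range,
         seed = as.integer(seed)),
    class = "cohort_config")
}

runif1 <- function(range) stats::runif(1L, range[1L], range[2L])

#' Generate a synthetic patient cohort
#'
#' Draws each patient's disease class from the configured mixture, assigns
#' stenotic vessels uniformly among combinations of the drawn size, plants
#' perfusion defects per [generate_patient_map()] and optionally writes the
#' polar-map files plus the cohort manifest. Fully determined by
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param model a [build_segment_model()].
#' @param dir optional directory; when given, per-subject polar-map files,
#'   `manifest.csv` and `truth.csv` are written there.
#' @return an object of class `synthetic_cohort`: list with `manifest`
#'   (subject_id, gender, lad, lcx, rca, branch_only, path), `truth`
#'   (planted-defect ground truth incl. `cad`, `disease_class`,
#'   `apical_only`, `all_silent`), `maps` (named list of [polar_map()]s) and
#'   `config`.
#' @export
generate_cohort <- function(config, model, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "segment_model"))
  set.seed(config$seed)
  vessels3 <- c("LAD", "LCX", "RCA")
  n <- config$n_patients
  maps <- vector("list", n)
  manifest <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    id <- sprintf("P%04d", i)
    cls <- sample(names(config$mixture), 1L, prob = config$mixture)
    gender <- if (stats::runif(1L) < config$male_fraction) "male" else "female"
    flags <- c(LAD = 0L, LCX = 0L, RCA = 0L)
    branch_only <- 0L
    specs <- list()
    apical <- FALSE
    n_silent <- 0L
    n_true <- 0L

    if (cls %in% c("one", "two", "three")) {
      k <- match(cls, c("one", "two", "three"))
      hit <- sample(vessels3, k)
      flags[hit] <- 1L
      for (v in hit) {
        if (stats::runif(1L) < config$silent_fraction) {
          n_silent <- n_silent + 1L
          next
        }
        n_true <- n_true + 1L
        if (cls == "one" && v == "LAD" &&
            stats::runif(1L) < config$apical_fraction) {
          apical <- TRUE
          specs <- c(specs, list(disease_spec(
            "LAD", runif1(config$apical_severity_range),
            runif1(config$apical_extent_range), apical_only = TRUE)))
        } else {
          specs <- c(specs, list(disease_spec(
            v, runif1(config$severity_range), runif1(config$extent_range))))
        }
      }
    } else if (cls == "branch") {
      branch_only <- 1L
      parent <- sample(vessels3, 1L)
      if (stats::runif(1L) < config$silent_fraction) {
        n_silent <- n_silent + 1L
      } else {
        n_true <- n_true + 1L
        specs <- c(specs, list(disease_spec(
          parent, runif1(config$severity_range),
          runif1(config$branch_extent_range))))
      }
    }

    artifact <- stats::runif(1L) < config$artifact_fraction
    if (artifact) {
      specs <- c(specs, list(disease_spec(
        sample(vessels3, 1L), runif1(config$artifact_severity_range),
        runif1(config$artifact_extent_range))))
    }

    if (length(specs) > 0L) {
      gen <- generate_patient_map(specs, gender, model,
                                  noise_sd = config$noise_sd, subject_id = id)
      maps[[i]] <- gen$map
    } else {
      maps[[i]] <- generate_normal_map(gender, model,
                                       noise_sd = config$noise_sd,
                                       subject_id = id)
    }

    cad <- cls != "none"
    manifest[[i]] <- data.frame(
      subject_id = id, gender = gender,
      lad = flags[["LAD"]], lcx = flags[["LCX"]], rca = flags[["RCA"]],
      branch_only = branch_only, path = NA_character_,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      subject_id = id, gender = gender, cad = as.integer(cad),
      disease_class = cls, apical_only = apical,
      n_silent_vessels = n_silent, n_true_defects = n_true,
      all_silent = cad && n_true == 0L, artifact = artifact,
      stringsAsFactors = FALSE)
  }

  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  names(maps) <- manifest$subject_id

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      p <- file.path(dir, paste0(manifest$subject_id[i], ".txt"))
      write_polar_map(maps[[i]], p)
      manifest$path[i] <- p
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }

  structure(list(manifest = manifest, truth = truth, maps = maps,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n=%d (CAD+ %d), seed=%d\n",
              nrow(x$manifest), sum(x$truth$cad), x$config$seed))
  invisible(x)
}

#' Read a cohort manifest and its polar maps
#'
#' Counterpart of the files written by [generate_cohort()]: reads
#' `manifest.csv` (columns subject_id, gender, lad, lcx, rca, branch_only,
#' path) and every referenced polar-map file.
#'
#' @param path path to a manifest CSV.
#' @return list with `manifest` and `maps`.
#' @export
read_cohort_manifest <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gender", "lad", "lcx", "rca", "branch_only", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  maps <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    read_polar_map(p)
  })
  names(maps) <- manifest$subject_id
  list(manifest = manifest, maps = maps)
}
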