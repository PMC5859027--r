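#' Study configuration
#'
#' Bundles every knob of the end-to-end study: grid geometry, the size of the
#' gender-matched normal-limits cohort, the synthetic patient cohort
#' configuration, the MAD abnormality threshold, the TPD positivity cutoff
#' and the master seed. One seed drives the whole study; it is split into
#' independent per-stage seeds so that, e.g., changing the number of patients
#' does not perturb the normal limits.
#'
#' @param R,A grid resolution (rings x sectors), see [build_segment_model()].
#' @param zone_fractions ring-share proportions of the four radial zones.
#' @param n_normals_per_gender size of each gender's defect-free reference
#'   cohort (default 50, i.e. 50 male + 50 female).
#' @param cohort a [cohort_config()] for the patient cohort (its `seed` is
#'   overridden by the stage seed derived from `seed`).
#' @param threshold_mad abnormality threshold in MAD units (default 3).
#' @param mad_floor per-pixel MAD lower bound (default 1).
#' @param tpd_cutoff TPD positivity threshold in percent (default 3).
#' @param seed master integer seed.
#' @param out_dir optional output directory for `report.json`,
#'   `patients.csv` and the limits files.
#' @return an object of class `study_config`.
#' @export
study_config <- function(R = 24L, A = 36L,
                         zone_fractions = c(0.25, 0.25, 0.25, 0.25),
                         n_normals_per_gender = 50L,
                         cohort = cohort_config(),
                         threshold_mad = 3, mad_floor = 1,
                         tpd_cutoff = 3, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (n_normals_per_gender < 2L) stop("need >= 2 normals per gender")
  if (threshold_mad <= 0 || tpd_cutoff <= 0) stop("thresholds must be positive")
  structure(
    list(R = as.integer(R), A = as.integer(A),
         zone_fractions = zone_fractions,
         n_normals_per_gender = as.integer(n_normals_per_gender),
         cohort = cohort, threshold_mad = threshold_mad,
         mad_floor = mad_floor, tpd_cutoff = tpd_cutoff,
         seed = as.integer(seed), out_dir = out_dir),
    class = "study_config")
}

#' Fit gender-matched limits from a synthetic normal cohort
#'
#' Generates `n_per_gender` defect-free maps per gender, normalizes them and
#' fits [fit_normal_limits()] for each gender. Consumes the global RNG.
#'
#' @param model a [build_segment_model()].
#' @param n_per_gender maps per gender (>= 2).
#' @param noise_sd pixel noise SD.
#' @param threshold_mad,mad_floor limit parameters.
#' @return named list with elements `male` and `female`.
#' @export
build_synthetic_limits <- function(model, n_per_gender = 50L, noise_sd = 8,
                                   threshold_mad = 3, mad_floor = 1) {
  fit_one <- function(gender) {
    maps <- lapply(seq_len(n_per_gender), function(i) {
      normalize_map(generate_normal_map(
        gender, model, noise_sd = noise_sd,
        subject_id = sprintf("N_%s_%03d", gender, i)))
    })
    fit_normal_limits(maps, gender, threshold_mad = threshold_mad,
                      mad_floor = mad_floor)
  }
  list(male = fit_one("male"), female = fit_one("female"))
}

#' Score every patient of a cohort with both coverage models
#'
#' @param maps named list of [polar_map()]s.
#' @param limits named list with `male` and `female` [fit_normal_limits()].
#' @param model a [build_segment_model()].
#' @return data.frame with one [score_patient()] row per map.
#' @export
score_cohort <- function(maps, limits, model) {
  rows <- lapply(maps, function(m) {
    score_patient(m, limits[[m$gender]], model)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify discordant detections
#'
#' Labels every patient row relative to the paired positivity calls at
#' `cutoff`: `"concordant"` (both methods agree), `"apical-miss"`
#' (whole-heart positive, 3-slice negative, and the largest per-segment
#' defect extent lies in the apical segments 13-17), `"non-apical-miss"`
#' (whole-heart-only positive with the dominant defect elsewhere) and
#' `"reverse-discordant"` (3-slice-only positive).
#'
#' @param patients data.frame from [score_cohort()] (must carry
#'   `whole_heart_tpd`, `three_slice_tpd` and `seg1` .. `seg17`).
#' @param cutoff TPD positivity threshold (default 3).
#' @return data.frame with `subject_id` and `class`.
#' @export
classify_discordant_cases <- function(patients, cutoff = 3) {
  seg_cols <- paste0("seg", 1:17)
  stopifnot(all(c("whole_heart_tpd", "three_slice_tpd", seg_cols) %in%
                  names(patients)))
  wh <- patients$whole_heart_tpd >= cutoff
  ts <- patients$three_slice_tpd >= cutoff
  ext <- as.matrix(patients[, seg_cols])
  dominant <- max.col(ext, ties.method = "first")
  cls <- ifelse(wh & !ts,
                ifelse(dominant >= 13L, "apical-miss", "non-apical-miss"),
                ifelse(!wh & ts, "reverse-discordant", "concordant"))
  data.frame(subject_id = patients$subject_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Run the full whole-heart vs 3-slice study
#'
#' End-to-end orchestration on a synthetic cohort: fit gender-matched normal
#' limits from a defect-free reference cohort, generate the patient cohort,
#' score every patient with whole-heart and 3-slice TPD, and compute the
#' complete paired comparison: ROC/AUC with DeLong's test, Youden cutoffs,
#' sensitivity/specificity with McNemar tests at the configured cutoff,
#' categorization agreement, linear regression and Bland-Altman among CAD+
#' patients, and the discordant-case breakdown with the apical-miss tally.
#' Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`: a list of all statistics plus
#'   the per-patient table (`$patients`) and planted truth (`$truth`). When
#'   `config$out_dir` is set, `report.json`, `patients.csv` and
#'   `limits_<gender>_*` files are written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  model <- build_segment_model(config$R, config$A, config$zone_fractions)

  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 2L)

  set.seed(stage_seeds[1L])
  limits <- build_synthetic_limits(
    model, config$n_normals_per_gender, config$cohort$noise_sd,
    config$threshold_mad, config$mad_floor)

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- stage_seeds[2L]
  cohort <- generate_cohort(cohort_cfg, model)

  patients <- score_cohort(cohort$maps, limits, model)
  patients <- merge(patients, cohort$truth[, c("subject_id", "cad",
                                               "disease_class", "apical_only")],
                    by = "subject_id", sort = TRUE)

  labels <- patients$cad == 1L
  cutoff <- config$tpd_cutoff
  wh <- patients$whole_heart_tpd
  ts <- patients$three_slice_tpd

  single_class <- !any(labels) || all(labels)
  if (!single_class) {
    roc <- delong_paired_test(wh, ts, labels)
    youden <- list(whole_heart = optimal_cutoff(wh, labels),
                   three_slice = optimal_cutoff(ts, labels))
    acc_wh <- sens_spec(wh, labels, cutoff)
    acc_ts <- sens_spec(ts, labels, cutoff)
    mcn_sens <- mcnemar_test(sum(wh[labels] >= cutoff & ts[labels] < cutoff),
                             sum(ts[labels] >= cutoff & wh[labels] < cutoff))
    mcn_spec <- mcnemar_test(sum(wh[!labels] >= cutoff & ts[!labels] < cutoff),
                             sum(ts[!labels] >= cutoff & wh[!labels] < cutoff))
  } else {
    roc <- NULL; youden <- NULL; mcn_sens <- NULL; mcn_spec <- NULL
    acc_wh <- list(
      sensitivity = if (any(labels)) mean(wh[labels] >= cutoff) else NA_real_,
      specificity = if (any(!labels)) mean(wh[!labels] < cutoff) else NA_real_)
    acc_ts <- list(
      sensitivity = if (any(labels)) mean(ts[labels] >= cutoff) else NA_real_,
      specificity = if (any(!labels)) mean(ts[!labels] < cutoff) else NA_real_)
  }

  # Agreement analyses among CAD-positive patients, as in the source cohort.
  cadpos <- patients[labels, , drop = FALSE]
  agreement <- NULL
  if (nrow(cadpos) >= 3L) {
    conc <- concordance_at_threshold(cadpos$whole_heart_tpd,
                                     cadpos$three_slice_tpd, cutoff)
    reg <- linreg_with_ci(cadpos$three_slice_tpd, cadpos$whole_heart_tpd)
    ba <- bland_altman(cadpos$whole_heart_tpd, cadpos$three_slice_tpd)
    agreement <- list(concordance = conc, regression = reg,
                      bland_altman = unclass(ba))
  }

  disc <- classify_discordant_cases(patients, cutoff)
  patients$discordance <- disc$class
  cad_disc <- disc$class[labels]
  n_wh_only <- sum(cad_disc %in% c("apical-miss", "non-apical-miss"))
  n_apical <- sum(cad_disc == "apical-miss")
  wh_only_idx <- labels & disc$class %in% c("apical-miss", "non-apical-miss")
  prevalence_apical <- mean(patients$apical_only)
  frac_apical_truth <- if (any(wh_only_idx)) {
    mean(patients$apical_only[wh_only_idx])
  } else NA_real_
  discordant <- list(
    n_whole_heart_only = n_wh_only,
    n_three_slice_only = sum(cad_disc == "reverse-discordant"),
    apical_miss_count = n_apical,
    apical_miss_fraction = if (n_wh_only > 0) 100 * n_apical / n_wh_only
                           else NA_real_,
    apical_only_truth_fraction = frac_apical_truth,
    apical_only_prevalence = prevalence_apical,
    apical_enrichment = if (!is.na(frac_apical_truth) && prevalence_apical > 0)
      frac_apical_truth / prevalence_apical else NA_real_)

  report <- structure(
    list(n_patients = nrow(patients), n_cad = sum(labels),
         prevalence_cad_free = 100 * mean(!labels),
         seed = config$seed, tpd_cutoff = cutoff,
         threshold_mad = config$threshold_mad,
         single_class = single_class,
         auc = if (!single_class) list(
           whole_heart = roc$auc_a, three_slice = roc$auc_b,
           se_whole_heart = roc$se_a, se_three_slice = roc$se_b,
           ci95_whole_heart = roc$ci95_a, ci95_three_slice = roc$ci95_b,
           difference = roc$auc_diff, delong_p = roc$p_value),
         youden_cutoff = youden,
         accuracy = list(
           whole_heart = acc_wh, three_slice = acc_ts,
           mcnemar_sensitivity_p = if (!is.null(mcn_sens)) mcn_sens$p_value,
           mcnemar_specificity_p = if (!is.null(mcn_spec)) mcn_spec$p_value),
         agreement = agreement,
         discordant = discordant),
    class = "study_report")
  attr(report, "patients") <- patients
  attr(report, "truth") <- cohort$truth
  attr(report, "limits") <- limits

  if (!is.null(config$out_dir)) {
    write_study_report(report, config$out_dir)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n=%d (CAD+ %d, %.1f%% disease-free)\n",
              x$n_patients, x$n_cad, x$prevalence_cad_free))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC whole-heart %.3f vs 3-slice %.3f (DeLong p = %.3g)\n",
                x$auc$whole_heart, x$auc$three_slice, x$auc$delong_p))
    cat(sprintf("  sens %.1f%% vs %.1f%%, spec %.1f%% vs %.1f%% at TPD >= %g%%\n",
                100 * x$accuracy$whole_heart$sensitivity,
                100 * x$accuracy$three_slice$sensitivity,
                100 * x$accuracy$whole_heart$specificity,
                100 * x$accuracy$three_slice$specificity, x$tpd_cutoff))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  bias %+.2f%%, LoA %.2f to %.2f, R^2 = %.3f, agreement %.1f%%\n",
                x$agreement$bland_altman$bias, x$agreement$bland_altman$loa_low,
                x$agreement$bland_altman$loa_high,
                x$agreement$regression$r_squared,
                x$agreement$concordance$observed_agreement))
  }
  cat(sprintf("  discordant: %d whole-heart-only (%d apical-miss), %d 3-slice-only\n",
              x$discordant$n_whole_heart_only, x$discordant$apical_miss_count,
              x$discordant$n_three_slice_only))
  invisible(x)
}

#' Write a study report to disk
#'
#' Serializes the statistics as `report.json` (stable field order, full
#' precision) and the per-patient TPD table as `patients.csv`; the fitted
#' limits are written via [write_normal_limits()]. Re-running the same
#' seeded study produces byte-identical files.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(attr(report, "patients"), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  limits <- attr(report, "limits")
  for (g in names(limits)) {
    write_normal_limits(limits[[g]], file.path(dir, paste0("limits_", g)))
  }
  invisible(dir)
}
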