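# Shared fixtures: a small grid for fast unit tests and hand-built limits
# with known mean/MAD so expected TPD values can be derived by hand.

tiny_model <- function() build_segment_model(8L, 12L)

default_model <- function() build_segment_model(24L, 36L)

# Limits with constant mean/MAD everywhere; bypasses fitting on purpose so
# tests control the comparison surface exactly.
flat_limits <- function(model, mean = 80, mad = 5, gender = "male",
                        threshold_mad = 3, mad_floor = 1) {
  structure(
    list(gender = gender,
         mean = matrix(mean, model$R, model$A),
         mad = matrix(mad, model$R, model$A),
         threshold_mad = threshold_mad, mad_floor = mad_floor,
         n_subjects = 2L),
    class = "normal_limits")
}

# A map pre-flagged as normalized (unit tests construct values on the limits
# scale directly).
norm_map <- function(values, gender = "male", subject_id = "T") {
  polar_map(values, subject_id = subject_id, gender = gender,
            normalized = TRUE)
}

# Independent brute-force TPD oracle: per-pixel double loop, no shared code
# with compute_tpd beyond the formula's definition.
tpd_oracle <- function(values, mean_grid, mad_grid, threshold, weights,
                       include) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(values))) {
    for (a in seq_len(ncol(values))) {
      if (!include[r, a]) next
      den <- den + weights[r, a]
      d <- (mean_grid[r, a] - values[r, a]) / mad_grid[r, a]
      if (d >= threshold) {
        s <- (mean_grid[r, a] - values[r, a]) / mean_grid[r, a]
        num <- num + weights[r, a] * min(1, max(0, s))
      }
    }
  }
  100 * num / den
}

# Exhaustive O(n^2) pair-counting AUC oracle (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
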