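test_that("TPD anchors: no uptake scores 100, normal-mean map scores 0", {
  model <- tiny_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  zero <- polar_map(matrix(0, model$R, model$A))  # cannot be normalized
  expect_equal(compute_tpd(zero, lim, whole_heart_mask(model), model), 100)
  atmean <- norm_map(matrix(80, model$R, model$A))
  expect_equal(compute_tpd(atmean, lim, whole_heart_mask(model), model), 0)
})

test_that("TPD equals the brute-force pixel-sum oracle", {
  model <- tiny_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  wh <- whole_heart_mask(model)
  # single abnormal pixel with severity 0.5
  v <- matrix(80, model$R, model$A)
  v[2, 3] <- 40
  m <- norm_map(v)
  w <- model$weight
  expect_equal(compute_tpd(m, lim, wh, model),
               100 * w[2, 3] * 0.5 / sum(w))
  # random maps, whole-heart and 3-slice masks, against the oracle
  set.seed(40)
  ts <- build_three_slice_mask(model)
  for (i in 1:5) {
    v <- matrix(runif(model$R * model$A, 0, 110), model$R, model$A)
    m <- norm_map(v)
    for (mask in list(wh, ts)) {
      expect_equal(compute_tpd(m, lim, mask, model),
                   tpd_oracle(v, lim$mean, lim$mad, lim$threshold_mad,
                              w, mask$include))
    }
  }
})

test_that("uniform full-field defect gives equal whole-heart and 3-slice TPD", {
  model <- default_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  s <- 0.4
  m <- norm_map(matrix(80 * (1 - s), model$R, model$A))
  expect_equal(compute_tpd(m, lim, whole_heart_mask(model), model), 100 * s)
  expect_equal(compute_three_slice_tpd(m, lim, model), 100 * s)
})

test_that("apex-cap defect is invisible to the 3-slice mask", {
  model <- default_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  v <- matrix(80, model$R, model$A)
  v[model$segment == 17L] <- 0
  m <- norm_map(v)
  expect_gt(compute_tpd(m, lim, whole_heart_mask(model), model), 0)
  expect_equal(compute_three_slice_tpd(m, lim, model), 0)
})

test_that("3-slice mask selects the midpoint ring pairs and skips the apex", {
  # independent midpoint oracle applied to several geometries
  cases <- list(default_model(),
                build_segment_model(24L, 36L, c(1 / 8, 7 / 24, 7 / 24, 7 / 24)),
                tiny_model())
  for (model in cases) {
    mask <- build_three_slice_mask(model)
    expected_rings <- sort(unname(unlist(lapply(
      model$zone_rings[c("apical", "mid", "basal")], function(rr) {
        mid <- (length(rr) - 1) / 2
        rr[floor(mid) + c(1, 2)]
      }))))
    expect_equal(which(apply(mask$include, 1, any)), expected_rings)
    expect_true(all(apply(mask$include[expected_rings, , drop = FALSE], 1, all)))
    expect_equal(sum(mask$include), 6 * model$A)
    expect_false(any(mask$include[model$zone_rings$apex, ]))
  }
  # the 7-ring-zone geometry picks local 0-based rings 3 and 4 of each zone
  m7 <- build_segment_model(24L, 36L, c(1 / 8, 7 / 24, 7 / 24, 7 / 24))
  expect_equal(which(apply(build_three_slice_mask(m7)$include, 1, any)),
               c(7L, 8L, 14L, 15L, 21L, 22L))

  broken <- default_model()
  broken$zone_rings$mid <- broken$zone_rings$mid[1L]
  expect_error(build_three_slice_mask(broken), "fewer than 2")
})

test_that("segment extents count abnormal weighted area per segment", {
  model <- default_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  # defect-free
  ext0 <- segment_extents(norm_map(matrix(80, model$R, model$A)), lim, model)
  expect_equal(unname(ext0), rep(0, 17))
  # whole apex cap abnormal
  v <- matrix(80, model$R, model$A)
  v[model$segment == 17L] <- 0
  ext <- segment_extents(norm_map(v), lim, model)
  expect_equal(unname(ext[17]), 100)
  expect_equal(unname(ext[1:16]), rep(0, 16))
  # half of segment 13's sectors abnormal in every ring -> exactly 50%
  # (24 sectors so the 6-sector apical segment halves evenly)
  model24 <- build_segment_model(24L, 24L)
  lim24 <- flat_limits(model24, mean = 80, mad = 5)
  v <- matrix(80, model24$R, model24$A)
  sec13 <- which(model24$segment[model24$zone_rings$apical[1L], ] == 13L)
  half <- sec13[seq_len(length(sec13) / 2)]
  v[model24$zone_rings$apical, half] <- 0
  ext <- segment_extents(norm_map(v), lim24, model24)
  expect_equal(unname(ext[13]), 50)
})

test_that("TPD is monotone, bounded, scale-invariant and decomposable", {
  model <- tiny_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  wh <- whole_heart_mask(model)
  ts <- build_three_slice_mask(model)
  comp <- coverage_mask(!ts$include)
  set.seed(77)
  for (i in 1:10) {
    v <- matrix(runif(model$R * model$A, 0, 110), model$R, model$A)
    m <- norm_map(v)
    t_wh <- compute_tpd(m, lim, wh, model)
    t_ts <- compute_tpd(m, lim, ts, model)
    expect_gte(t_wh, 0); expect_lte(t_wh, 100)

    # monotonicity: lowering one random pixel never decreases TPD
    v2 <- v
    px <- sample(length(v2), 1)
    v2[px] <- v2[px] * runif(1, 0, 0.9)
    expect_gte(compute_tpd(norm_map(v2), lim, wh, model), t_wh)
    expect_gte(compute_tpd(norm_map(v2), lim, ts, model), t_ts)

    # restriction consistency: whole-heart TPD is the area-weighted average
    # of the 3-slice mask and its complement
    t_comp <- compute_tpd(m, lim, comp, model)
    w_ts <- sum(model$weight[ts$include])
    w_comp <- sum(model$weight[comp$include])
    expect_equal(t_wh, (t_ts * w_ts + t_comp * w_comp) / (w_ts + w_comp))

    # scale invariance through normalization
    c1 <- runif(1, 0.2, 5)
    raw <- polar_map(v)
    scaled <- polar_map(v * c1)
    expect_equal(
      compute_tpd(normalize_map(raw), lim, wh, model),
      compute_tpd(normalize_map(scaled), lim, wh, model))
  }
})

test_that("the severity hook replaces the default fractional deficit", {
  model <- tiny_model()
  lim <- flat_limits(model, mean = 80, mad = 5)
  v <- matrix(80, model$R, model$A)
  v[1, 1] <- 40  # abnormal, default severity 0.5
  m <- norm_map(v)
  wh <- whole_heart_mask(model)
  w <- model$weight
  hard <- function(values, limits) matrix(1, nrow(values), ncol(values))
  expect_equal(compute_tpd(m, lim, wh, model, severity_fun = hard),
               100 * w[1, 1] / sum(w))
  expect_equal(compute_tpd(m, lim, wh, model),
               100 * 0.5 * w[1, 1] / sum(w))
})

test_that("gender mismatch and empty masks are rejected", {
  model <- tiny_model()
  lim <- flat_limits(model, gender = "male")
  f <- norm_map(matrix(80, model$R, model$A), gender = "female")
  expect_error(compute_tpd(f, lim, whole_heart_mask(model), model), "gender")
  empty <- coverage_mask(matrix(FALSE, model$R, model$A))
  m <- norm_map(matrix(80, model$R, model$A))
  expect_error(compute_tpd(m, lim, empty, model), "empty")
})
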