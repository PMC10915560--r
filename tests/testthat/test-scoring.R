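test_that("grid prediction and scaling follow the published procedure", {
  # direct polynomial evaluation of the published coefficients
  expect_equal(predict_affect_grid(table1_pos, 4), 64.654, tolerance = 1e-3)
  expect_equal(predict_affect_grid(table1_pos, 63), 44.181, tolerance = 1e-3)
  expect_equal(predict_affect_grid(table1_neg, 4), -48.933, tolerance = 1e-3)
  expect_equal(predict_affect_grid(c(0, 0, 0), 4:63), rep(0, 60))
  expect_error(predict_affect_grid(table1_pos, numeric(0)), "empty")
  # time maps 4 -> 0 and 63 -> 1; affect starts at exactly 1
  v <- predict_affect_grid(table1_pos, 4:63)
  cv <- scale_discount_curve(v, 4:63)
  expect_equal(cv$scaled_time[1], 0)
  expect_equal(cv$scaled_time[60], 1)
  expect_identical(cv$scaled_affect[1], 1)
  expect_equal(cv$scaled_affect[60], 44.181 / 64.654, tolerance = 1e-4)
  # negative first value scales to a positive curve without absolute values
  vn <- predict_affect_grid(table1_neg, 4:63)
  cn <- scale_discount_curve(vn, 4:63)
  expect_true(all(cn$scaled_affect > 0))
  expect_error(scale_discount_curve(c(0, 1, 2), c(4, 5, 6)), "scaled")
  # scaling an already-scaled curve is the identity
  cv2 <- scale_discount_curve(cv$scaled_affect, 4:63)
  expect_equal(cv2$scaled_affect, cv$scaled_affect)
})

test_that("trapezoid AUC matches the closed-form quadratic integral", {
  # hand-checkable shapes
  const <- scale_discount_curve(rep(5, 60), 4:63)
  expect_equal(auc_trapezoid(const), 1)
  lin <- list(scaled_time = c(0, 1), scaled_affect = c(1, 0))
  expect_equal(auc_trapezoid(lin), 0.5)
  expect_error(auc_trapezoid(list(scaled_time = 0, scaled_affect = 1)),
               "2 points")
  expect_equal(auc_exact_quadratic(c(7, 0, 0)), 1)
  # published fixed-effect paths, both methods
  for (b in list(table1_pos, table1_neg)) {
    v <- predict_affect_grid(b, 4:63)
    tr <- auc_trapezoid(scale_discount_curve(v, 4:63))
    ex <- auc_exact_quadratic(b)
    expect_equal(tr, ex, tolerance = 1e-4 / ex)
  }
  expect_equal(auc_exact_quadratic(table1_pos), 0.779, tolerance = 1e-3)
  expect_equal(auc_exact_quadratic(table1_neg), 0.759, tolerance = 1e-3)
  # random paths: agreement within the trapezoid error bound
  set.seed(8)
  for (i in 1:200) {
    b <- c(runif(1, 20, 90), runif(1, -1.5, 0.2), runif(1, -0.01, 0.01))
    v <- predict_affect_grid(b, 4:63)
    cv <- scale_discount_curve(v, 4:63)
    tr <- auc_trapezoid(cv)
    ex <- auc_exact_quadratic(b)
    expect_lt(abs(tr - ex), 2e-4)
    # AUC is bounded by the curve's range
    expect_gte(tr, min(cv$scaled_affect) - 1e-12)
    expect_lte(tr, max(cv$scaled_affect) + 1e-12)
  }
  expect_error(auc_exact_quadratic(c(-4, 1, 0)), "undefined")  # v(4) = 0
})

test_that("fading-affect-bias direction holds at the published estimates", {
  expect_gt(auc_exact_quadratic(table1_pos), auc_exact_quadratic(table1_neg))
})

test_that("individual paths are fixed effects plus posterior deviations", {
  fit <- small_fit_pos()
  paths <- extract_individual_paths(fit)
  expect_equal(nrow(paths), 40)
  b <- colMeans(fit$B)
  # deviations average out across participants (shrinkage keeps them centred)
  expect_lt(abs(mean(paths$b0) - b[1]), 2)
  expect_lt(abs(mean(paths$b1) - b[2]), 0.05)
  expect_error(extract_individual_paths(fit, participants = 9999), "absent")
  sub <- extract_individual_paths(fit, participants = c(3, 1))
  expect_equal(sub$participant_id, c(3, 1))
})

test_that("cohort scoring excludes negative AUCs without cross-talk", {
  fit_pos <- small_fit_pos()
  fit_neg <- small_fit_neg()
  rec <- suppressMessages(score_cohort(fit_pos, fit_neg))
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$auc_pos[rec$included] >= 0))
  expect_true(all(is.na(rec$ptd_bias[!rec$included])))
  # a crafted path crossing zero with a dominant flipped tail scores
  # negative by the oracle and is excluded
  bad <- c(6, -1.2, 0.005)  # v(4) small positive, tail strongly negative
  expect_lt(auc_exact_quadratic(bad), 0)
  v <- predict_affect_grid(bad, 4:63)
  expect_lt(auc_trapezoid(scale_discount_curve(v, 4:63)), 0)
  # forcing one participant negative flips only that record
  rec2 <- rec
  rec2$auc_neg[5] <- -0.2
  rec2$included <- TRUE; rec2$exclusion_reason <- "none"
  rec2$included[rec2$auc_pos < 0 | rec2$auc_neg < 0] <- FALSE
  rec2 <- ptd_bias(rec2)
  expect_false(rec2$included[5])
  expect_equal(rec2$auc_pos[-5], rec$auc_pos[-5])
  # per-draw scoring runs and lands near the posterior-mean-path scores
  rec_draw <- suppressMessages(
    score_cohort(fit_pos, fit_neg, screen_config(per_draw = TRUE)))
  expect_lt(median(abs(rec_draw$auc_pos - rec$auc_pos)), 0.05)
  expect_error(score_cohort(fit_pos, fit_pos, panel = NULL), NA)
})

test_that("the abnormal-pattern screen flags sign-contradicting participants", {
  cohort <- small_cohort()
  panel <- cohort$panel
  # corrupt one participant: positive events rated negative at every wave
  pid <- 7
  sel <- panel$participant_id == pid & panel$valence == 1
  panel$affect_rating[sel] <- -abs(panel$affect_rating[sel])
  rec <- suppressMessages(
    score_cohort(small_fit_pos(), small_fit_neg(),
                 screen_config(abnormal_screen = TRUE), panel = panel))
  expect_equal(rec$exclusion_reason[rec$participant_id == pid], "abnormal_pattern")
  expect_error(score_cohort(small_fit_pos(), small_fit_neg(),
                            screen_config(abnormal_screen = TRUE)),
               "panel")
})

test_that("ptd bias is a difference of normalized scores", {
  rec <- tibble::tibble(
    participant_id = 1:6,
    auc_pos = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
    auc_neg = c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3),  # same shape, shifted
    included = TRUE, exclusion_reason = "none", ptd_bias = NA_real_)
  out <- ptd_bias(rec)
  # location/scale shifts vanish under z-scoring
  expect_equal(out$ptd_bias, rep(0, 6), tolerance = 1e-12)
  # a participant at the mean of both distributions has zero bias
  rec2 <- rec
  rec2$auc_pos <- c(0.65, 0.9, 0.4, 0.7, 0.6, 0.65)
  rec2$auc_neg <- c(0.55, 0.3, 0.8, 0.5, 0.6, 0.55)
  m <- ptd_bias(tibble::tibble(participant_id = 1:3,
                               auc_pos = c(0.5, 0.4, 0.6),
                               auc_neg = c(0.5, 0.4, 0.6),
                               included = TRUE, exclusion_reason = "none",
                               ptd_bias = NA_real_))
  expect_equal(m$ptd_bias[1], 0, tolerance = 1e-12)
  # degenerate inputs error
  rec$auc_pos <- 0.5
  expect_error(ptd_bias(rec), "variance")
  expect_error(ptd_bias(rec[rec$included & seq_len(6) == 1, ]), "2 included")
  # min-max normalization is available
  mm <- ptd_bias(rec2, normalization = "minmax")
  expect_true(all(is.finite(mm$ptd_bias)))
})
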