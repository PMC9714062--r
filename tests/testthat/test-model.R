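test_that("the vault formula reproduces hand-evaluated predictions", {
  eye <- make_eye()  # cohort-mean biometry
  expect_equal(predict_vault(eye, 12.6), 364.26, tolerance = 0.01 / 364.26)
  # one coefficient at a time: +1 mm LT lowers the prediction by coef_lt
  thicker <- make_eye(lt = 3.67 + 1)
  expect_equal(predict_vault(thicker, 12.6) - predict_vault(eye, 12.6),
               -432.497)
})

test_that("predictions are linear in the biometry and identical for identical eyes", {
  set.seed(41)
  co <- model_coefficients()
  cvec <- c(co$coef_sts_h, co$coef_lt, co$coef_sts_v)
  for (i in 1:25) {
    a <- random_biometry(1)
    b <- random_biometry(1)
    diff_pred <- predict_vault(a, 13.2) - predict_vault(b, 13.2)
    diff_coords <- c(a$sts_horizontal_mm - b$sts_horizontal_mm,
                     a$lens_thickness_mm - b$lens_thickness_mm,
                     a$sts_vertical_mm - b$sts_vertical_mm)
    expect_equal(diff_pred, sum(cvec * diff_coords), tolerance = 1e-9)
    expect_identical(predict_vault(a, 12.1), predict_vault(a, 12.1))
  }
})

test_that("out-of-range biometry is rejected with the field named", {
  expect_error(predict_vault(make_eye(sts_h = 7.9), 12.6), "sts_horizontal_mm")
  expect_error(predict_vault(make_eye(sts_v = 16.2), 12.6), "sts_vertical_mm")
  expect_error(predict_vault(make_eye(lt = 2.4), 12.6), "lens_thickness_mm")
  expect_error(predict_vault(make_eye(), 12.9), "size")
  expect_error(validate_biometry(data.frame(sts_horizontal_mm = 11)),
               "missing required")
})

test_that("size steps match the published per-step vault changes and are antisymmetric", {
  expect_identical(vault_step(12.1, 12.6), 329)
  expect_identical(vault_step(12.6, 13.2), 394)
  expect_identical(vault_step(13.2, 13.7), 329)
  expect_identical(vault_step(12.6, 12.6), 0)
  expect_identical(vault_step(12.1, 12.6), vault_step(13.2, 13.7))
  sizes <- icl_sizes()
  for (i in seq_along(sizes)) for (j in seq_along(sizes))
    expect_identical(vault_step(sizes[i], sizes[j]),
                     -vault_step(sizes[j], sizes[i]))
})

test_that("predictions increase strictly with size and the feasible set is contiguous", {
  set.seed(42)
  eyes <- random_biometry(40)
  res <- select_icl_size(eyes)
  preds <- as.matrix(res[, 1:4])
  expect_true(all(diff(t(preds)) > 0))
  w <- target_window()
  for (i in seq_len(nrow(preds))) {
    feas <- which(preds[i, ] >= w$low & preds[i, ] <= w$high)
    if (length(feas) > 1)
      expect_identical(unname(feas), seq(min(feas), max(feas)))
  }
})

test_that("size selection picks the feasible size nearest the window center", {
  # predictions {150, 479, 873, 1202}: only 12.6 mm feasible
  eye <- make_eye(lt = lt_for_prediction(150, 12.1))
  res <- select_icl_size(eye)
  expect_equal(res$pred_vault_12_1, 150)
  expect_equal(res$selected_size_mm, 12.6)
  expect_true(res$in_window)
  # exactly equidistant feasible predictions tie toward the smaller size
  # (a flat size response makes every size feasible at the same distance)
  flat <- model_coefficients(intercept = 400, coef_size = 0, coef_sts_h = 0,
                             coef_lt = 0, coef_sts_v = 0)
  expect_equal(select_icl_size(make_eye(), coeffs = flat)$selected_size_mm,
               12.1)
})

test_that("infeasible eyes return the boundary-nearest size, flagged", {
  # all four predictions below 300: largest size is nearest the window
  eye <- make_eye(lt = lt_for_prediction(250, 13.7))
  res <- select_icl_size(eye)
  expect_true(all(res[, 1:4] < 300))
  expect_equal(res$selected_size_mm, 13.7)
  expect_false(res$in_window)
})

test_that("an anteriorly positioned ciliary body shifts selection to the smaller feasible size", {
  # 680 um at 12.6 mm: downsizing lands at ~351 um on the same eye
  eye <- make_eye(lt = lt_for_prediction(680, 12.6),
                  anterior_ciliary_body = 1)
  res <- select_icl_size(eye, apply_feature_adjustment = TRUE)
  expect_equal(res$selected_size_mm, 12.1)
  expect_equal(round(res$selected_pred_um), 351)
  expect_true(res$in_window)
  # both 310 and 639 feasible, 12.6 nearer center: the flag flips it down
  eye2 <- make_eye(lt = lt_for_prediction(310, 12.1),
                   anterior_ciliary_body = 1)
  plain <- select_icl_size(eye2)
  adj <- select_icl_size(eye2, apply_feature_adjustment = TRUE)
  expect_equal(plain$selected_size_mm, 12.6)
  expect_false(plain$adjusted_for_feature)
  expect_equal(adj$selected_size_mm, 12.1)
  expect_true(adj$adjusted_for_feature)
  # without the feature the flag does nothing
  expect_equal(select_icl_size(make_eye(lt = lt_for_prediction(310, 12.1)),
                               apply_feature_adjustment = TRUE)$selected_size_mm,
               12.6)
})

test_that("vault classification partitions [0, Inf) at 200 and 800 um", {
  expect_equal(as.character(classify_vault(c(0, 150, 199.9, 200, 500, 800,
                                             800.1, 1150))),
               c("low", "low", "low", "normal", "normal", "normal",
                 "high", "high"))
  set.seed(7)
  v <- runif(200, 0, 1500)
  expect_false(any(is.na(classify_vault(v))))
  expect_error(classify_vault(-1), "0 um|>= 0")
})

test_that("error grouping uses strict 300 um thresholds in both directions", {
  expect_equal(as.character(assign_error_group(c(-350, -301, -300, 0, 300,
                                                 301, 350))),
               c("overestimated", "overestimated", "within", "within",
                 "within", "underestimated", "underestimated"))
  expect_error(assign_error_group(NaN), "finite")
})
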