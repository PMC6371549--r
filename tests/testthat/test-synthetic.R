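test_that("the quantile model interpolates its knots and tails linearly", {
  qm <- fit_quantile_model(-1, 0, 1)
  expect_equal(qm(c(0.25, 0.5, 0.75)), c(-1, 0, 1))
  expect_equal(qm(0.375), -0.5)
  # tails continue the adjacent segment slope (factor 1)
  expect_equal(qm(0.125), -1 + (0.125 - 0.25) * 4)
  expect_equal(qm(0.9), 1 + (0.9 - 0.75) * 4)
  # clamped beyond p = 0.001 / 0.999
  expect_equal(qm(0), qm(0.001))
  expect_equal(qm(1), qm(0.999))
  # monotone non-decreasing over the whole unit interval
  p <- seq(0, 1, by = 1e-3)
  for (q in list(c(-1, 0, 1), c(0, 8, 17), c(2, 2, 5), c(3, 3, 3))) {
    f <- fit_quantile_model(q[1], q[2], q[3])
    expect_true(all(diff(f(p)) >= 0))
  }
  expect_equal(fit_quantile_model(3, 3, 3)(c(0.1, 0.5, 0.9)), c(3, 3, 3))
  expect_error(fit_quantile_model(1, 0, 2), "q1 <= median <= q3")
})

test_that("large samples reproduce the defining quartiles", {
  qm <- fit_quantile_model(41.5, 68.6, 122.7)
  set.seed(47)
  draws <- qm(runif(1e6))
  q <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- 122.7 - 41.5
  expect_lt(max(abs(q - c(41.5, 68.6, 122.7))), 0.01 * iqr)
})

test_that("calibrated cohorts have the requested sizes and invariants", {
  co <- sample_cohort("idb", n_cases = 42, n_controls = 199, seed = 51)
  expect_equal(dim(co), c(241L, 15L))  # pair_id + 13 features + label
  expect_equal(sum(co$label == 1), 42)
  expect_equal(sum(co$label == 0), 199)
  expect_true(all(co$mag_d_vg_mvms >= 0))
  expect_true(all(co$mag_d_j_uv >= 0))
  expect_true(all(co$mag_d_sa_deg >= 0 & co$mag_d_sa_deg <= 180))
  expect_identical(co, sample_cohort("idb", 42, 199, seed = 51))
  expect_false(identical(co, sample_cohort("idb", 42, 199, seed = 52)))
  # identical CSV bytes for identical seeds
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, p1)
  write_cohort(sample_cohort("idb", 42, 199, seed = 51), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("hfdb cohorts draw from their own quartile calibration", {
  co <- sample_cohort("hfdb", seed = 53)
  expect_equal(sum(co$label == 1), 47)
  expect_equal(sum(co$label == 0), 81)
  q <- feature_quartiles("hfdb", "case")
  expect_equal(q$median[q$feature == "mag_d_sa_deg"], 31.7)
  # quartile table is internally consistent
  for (ds in c("hfdb", "idb")) {
    for (cl in c("case", "control", "total")) {
      qq <- feature_quartiles(ds, cl)
      expect_equal(qq$feature, difference_feature_names())
      expect_true(all(qq$q1 <= qq$median & qq$median <= qq$q3))
    }
  }
})

test_that("toy families deliver their designed structure", {
  # null: an arbitrary fixed scorer stays near chance
  co0 <- make_toy_cohort("null", 200, 200, seed = 55)
  a0 <- roc_auc(co0$d_qrs_dur_ms, co0$label)
  expect_gt(a0, 0.4)
  expect_lt(a0, 0.6)
  # separable: weighted LR reaches near-perfect discrimination
  co1 <- make_toy_cohort("separable", 100, 100, seed = 56)
  x1 <- as.matrix(co1[difference_feature_names()])
  m1 <- suppressWarnings(train_weighted_lr(x1, co1$label))
  expect_gt(roc_auc(lr_score(m1, x1), co1$label), 0.95)
  # the signal features are separated with a margin by construction
  expect_gt(min(co1$d_qrs_dur_ms[co1$label == 1]),
            max(co1$d_qrs_dur_ms[co1$label == 0]))
  # xor2d: linear scoring is near chance, a small network is not
  co2 <- make_toy_cohort("xor2d", 200, 200, seed = 57)
  d <- prepare_split(co2, seed = 57)
  m2 <- train_weighted_lr(rbind(d$x_train, d$x_val),
                          c(d$y_train, d$y_val))
  auc_lr <- roc_auc(lr_score(m2, d$x_test), d$y_test)
  expect_gt(auc_lr, 0.4)
  expect_lt(auc_lr, 0.6)
  # a [4 2] network can represent the xor structure: train to convergence
  # (no held-out set, so the stop rule fires only at perfection or the cap)
  aucs <- vapply(58:60, function(s) {
    nn <- train_standard_nn(c(4, 2), d$x_train, d$y_train,
                            d$x_train, d$y_train,
                            config = training_config(max_iterations = 500),
                            seed = s)
    roc_auc(nn_forward(nn$params, d$x_test), d$y_test)
  }, numeric(1))
  expect_gt(max(aucs), 0.85)
})
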