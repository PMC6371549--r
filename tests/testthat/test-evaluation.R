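test_that("the threshold sweep enumerates the hand-checked operating points", {
  scores <- c(0.8, 0.3, 0.6, 0.1)
  labels <- c(1, 1, 0, 0)
  rp <- roc_points(scores, labels)
  expect_equal(rp$threshold, c(-Inf, 0.1, 0.3, 0.6, 0.8, Inf))
  at <- function(thr) unlist(rp[rp$threshold == thr, 2:3], use.names = FALSE)
  expect_equal(at(0.8), c(0.5, 1.0))
  expect_equal(at(0.3), c(1.0, 0.5))
  # monotone in the threshold; sentinels at the corners
  expect_true(all(diff(rp$sensitivity) <= 0))
  expect_true(all(diff(rp$specificity) >= 0))
  expect_equal(at(-Inf), c(1, 0))
  expect_equal(at(Inf), c(0, 1))
  expect_error(roc_points(scores, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the pairwise Mann-Whitney count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1)), 0.0)
  expect_equal(roc_auc(c(0.8, 0.3, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(23)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)  # coarse grid forces ties
    expect_equal(roc_auc(s, y), auc_bruteforce(s, y), tolerance = 1e-12)
    # complement and monotone-transform invariances
    expect_equal(roc_auc(s, y) + roc_auc(s, 1 - y), 1, tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y), tolerance = 1e-12)
  }
})

test_that("equal-sensitivity/specificity accuracy interpolates the sweep", {
  expect_equal(acc_equal_sens_spec(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(acc_equal_sens_spec(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1)), 0)
  # the 4-sample sweep has an exact sens = spec operating point at
  # threshold 0.6 ((0.5, 0.5)); an exact crossing point takes precedence
  # over interpolation
  expect_equal(acc_equal_sens_spec(c(0.8, 0.3, 0.6, 0.1), c(1, 1, 0, 0)),
               0.5)
  # the crossing value lies between the bracketing sensitivities
  set.seed(29)
  for (i in 1:10) {
    y <- rep(c(1, 0), each = 30)
    s <- c(rnorm(30, 1), rnorm(30))
    acc <- acc_equal_sens_spec(s, y)
    expect_gte(acc, 0)
    expect_lte(acc, 1)
    rp <- roc_points(s, y)
    d <- rp$sensitivity - rp$specificity
    i0 <- which(d[-length(d)] > 0 & d[-1] <= 0)[1]
    expect_gte(acc, min(rp$sensitivity[i0 + 1], rp$specificity[i0]))
    expect_lte(acc, max(rp$sensitivity[i0], rp$specificity[i0 + 1]))
  }
})

test_that("DeLong interval brackets the AUC and the paired test is sane", {
  set.seed(37)
  y <- rep(c(1, 0), each = 50)
  s <- c(rnorm(50, 1), rnorm(50))
  ci <- auc_ci_delong(s, y)
  a <- roc_auc(s, y)
  expect_lt(ci[["low"]], a)
  expect_gt(ci[["high"]], a)
  expect_gte(ci[["low"]], 0)
  expect_lte(ci[["high"]], 1)
  # identical score vectors: null identity, p = 1
  dt <- delong_test(s, s, y)
  expect_equal(dt$p, 1)
  expect_equal(dt$auc_a, dt$auc_b)
  # an informative scorer against pure noise on enough data: small p
  noise <- runif(100)
  dt2 <- delong_test(s, noise, y)
  expect_lt(dt2$p, 0.05)
  # CI width shrinks with sample size (averaged over replicates)
  width <- function(n, seeds) {
    mean(vapply(seeds, function(sd) {
      set.seed(sd)
      yy <- rep(c(1, 0), each = n / 2)
      ss <- c(rnorm(n / 2, 1), rnorm(n / 2))
      diff(as.numeric(auc_ci_delong(ss, yy)))
    }, numeric(1)))
  }
  expect_lt(width(500, 1:5), width(50, 1:5))
})

test_that("rank-sum p-values match exact enumeration and symmetries", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(ranksum_test(c(1, 5, 7, 2), c(3, 8, 4, 9)),
               ranksum_test(c(3, 8, 4, 9), c(1, 5, 7, 2)))
})

test_that("the cohort summary reports quartiles, p-values and stars", {
  co <- sample_cohort("idb", n_cases = 60, n_controls = 120, seed = 41)
  tab <- summarize_features(co)
  expect_equal(tab$feature, difference_feature_names())
  expect_true(all(tab$case_q1 <= tab$case_median &
                    tab$case_median <= tab$case_q3))
  co2 <- co
  co2$d_qt_ms <- 5  # single-valued feature collapses its quartiles
  tab2 <- summarize_features(co2)
  row <- tab2[tab2$feature == "d_qt_ms", ]
  expect_equal(unlist(row[c("case_q1", "case_median", "case_q3")],
                      use.names = FALSE), c(5, 5, 5))
  expect_equal(row$p_value, 1)
  expect_equal(rslpnet:::significance_stars(c(0.04, 0.005, 5e-4, 0.2)),
               c("*", "**", "***", ""))
})
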