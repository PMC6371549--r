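test_that("initialization draws all parameters uniformly in [-1, 1]", {
  p <- init_network(c(5, 3), seed = 1)
  v <- rslpnet:::pack_params(p)
  expect_length(v, 13 * 5 + 5 + 5 * 3 + 3 + 3 * 1 + 1)
  expect_true(all(v >= -1 & v <= 1))
  expect_identical(rslpnet:::pack_params(init_network(c(5, 3), seed = 1)), v)
  expect_false(identical(rslpnet:::pack_params(init_network(c(5, 3), 2)), v))
  # parameter counts from shape arithmetic: arch [1] has 16
  expect_equal(rslpnet:::n_parameters(init_network(c(1), 1)), 16L)
  expect_error(init_network(c(2, 3), 1), "non-increasing")
  expect_error(init_network(c(1, 1, 1, 1), 1), "between 1 and 3")
})

test_that("total neuron counts match the published final architectures", {
  expect_equal(count_neurons(c(16, 13, 12)), 41)
  expect_equal(count_neurons(c(11, 9, 1)), 21)
})

test_that("the forward pass chains logistic sigmoids", {
  p <- init_network(c(1), seed = 3)
  p$W[[1]][] <- 0; p$b[[1]][] <- 0   # hidden pre-activation 0
  p$W[[2]][] <- 1; p$b[[2]][] <- 0   # output sees sigmoid(0) = 0.5
  x <- rnorm(13)
  expect_equal(nn_forward(p, x), 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  # all-zero parameters give 0.5 for any input and architecture
  q <- init_network(c(4, 2), seed = 4)
  for (l in seq_along(q$W)) { q$W[[l]][] <- 0; q$b[[l]][] <- 0 }
  expect_equal(nn_forward(q, matrix(rnorm(26), 2)), c(0.5, 0.5))
  # scores are strictly inside (0, 1) and monotone in the output weight
  r <- init_network(c(2), seed = 5)
  s <- nn_forward(r, matrix(rnorm(5 * 13), 5))
  expect_true(all(s > 0 & s < 1))
  r2 <- r
  r2$W[[2]] <- r$W[[2]] + 5  # hidden activations are positive
  expect_true(all(nn_forward(r2, matrix(1:13, 1)) >
                    nn_forward(r, matrix(1:13, 1))))
  expect_error(nn_forward(r, rep(NA_real_, 13)), "non-finite")
})

test_that("the weighted error is the normalized weighted sum of squares", {
  y <- c(1, 0)
  expect_equal(weighted_error(c(1, 0), y), 0)
  expect_equal(weighted_error(c(0.5, 0.5), y), 0.25)
  # 3 controls + 1 case, all scores 0: E = 4/(3*4/3 + 4) = 0.5
  y2 <- c(1, 0, 0, 0)
  expect_equal(weighted_error(c(0, 0, 0, 0), y2), 0.5)
  # invariant under positive rescaling of the class weights
  s <- runif(10)
  y3 <- rep(c(0, 1), 5)
  w <- class_weights(y3)
  w2 <- list(w_case = 7 * w$w_case, w_control = 7 * w$w_control)
  expect_equal(weighted_error(s, y3, w), weighted_error(s, y3, w2))
  expect_error(weighted_error(numeric(0), numeric(0)), "non-empty")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(7)
  for (arch in list(c(1), c(3), c(4, 2), c(3, 3, 1))) {
    p <- init_network(arch, seed = sum(arch))
    x <- matrix(rnorm(8 * 13), 8)
    y <- rep(c(1, 0), 4)
    w <- class_weights(y)
    g <- rslpnet:::pack_gradient(nn_gradient(p, x, y, w))
    fd <- fd_gradient(p, x, y, w)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-5)
  }
  # doubling both class weights leaves the gradient unchanged
  p <- init_network(c(2), seed = 9)
  x <- matrix(rnorm(6 * 13), 6)
  y <- c(1, 1, 0, 0, 0, 1)
  w <- class_weights(y)
  w2 <- list(w_case = 2 * w$w_case, w_control = 2 * w$w_control)
  expect_equal(nn_gradient(p, x, y, w), nn_gradient(p, x, y, w2))
})

test_that("a learning phase reduces training error and obeys the stop rule", {
  d <- prepare_split(make_toy_cohort("separable", 60, 60, seed = 2), seed = 2)
  p <- init_network(c(1), seed = 2)
  res <- scg_train(p, d$x_train, d$y_train, d$x_val, d$y_val)
  expect_s3_class(res, "train_result")
  expect_length(res$train_trace, res$iterations)
  expect_length(res$val_trace, res$iterations)
  # full-batch SCG never accepts an error increase
  expect_true(all(diff(res$train_trace) <= 1e-12))
  expect_lt(res$train_error, res$train_trace[1])
  # returned parameters achieve the minimum validation error observed
  # (a perfect-classification stop keeps the perfect iterate instead)
  if (res$stop_reason != "perfect-classification") {
    expect_equal(res$val_error, min(res$val_trace))
  }
  if (res$stop_reason == "validation-increase") {
    k <- res$iterations
    expect_gt(res$val_trace[k], res$val_trace[k - 1])
  }
  # zero allowed iterations returns the initialization unchanged
  res0 <- scg_train(p, d$x_train, d$y_train, d$x_val, d$y_val,
                    config = training_config(max_iterations = 0))
  expect_identical(rslpnet:::pack_params(res0$params),
                   rslpnet:::pack_params(p))
  expect_equal(res0$iterations, 0L)
})

test_that("the first-iteration exemption tolerates one early rise only", {
  # drive many short phases; whenever a validation-increase stop occurred
  # with the exemption on, the rise was never at the first comparison
  d <- prepare_split(make_toy_cohort("xor2d", 50, 50, seed = 3), seed = 3)
  stops <- 0L
  for (s in 1:10) {
    p <- init_network(c(2), seed = s)
    res <- scg_train(p, d$x_train, d$y_train, d$x_val, d$y_val,
                     config = training_config(first_iteration_exemption = TRUE))
    if (res$stop_reason == "validation-increase") {
      stops <- stops + 1L
      expect_gt(res$iterations, 2L)
      rises <- which(diff(res$val_trace) > 0)
      expect_true(all(rises %in% c(1L, res$iterations - 1L)))
    }
  }
  expect_gt(stops, 0L)
})
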