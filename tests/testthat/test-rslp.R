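test_that("candidate enumeration applies both structural constraints", {
  expect_equal(candidate_architectures(c(1)),
               structure(list(c(2L), c(1L, 1L)), attempts = 2L),
               ignore_attr = FALSE)
  c221 <- candidate_architectures(c(2, 2, 1))
  expect_equal(attr(c221, "attempts"), 4L)
  expect_equal(unclass(c221)[1:2], list(c(3L, 2L, 1L), c(2L, 2L, 2L)),
               ignore_attr = TRUE)
  c3 <- candidate_architectures(c(16, 13, 12))
  expect_equal(unclass(c3)[1:3],
               list(c(17L, 13L, 12L), c(16L, 14L, 12L), c(16L, 13L, 13L)),
               ignore_attr = TRUE)
  # every candidate is valid and exactly one neuron larger
  set.seed(31)
  for (i in 1:30) {
    L <- sample(1:3, 1)
    arch <- sort(sample(1:8, L, replace = TRUE), decreasing = TRUE)
    for (cand in candidate_architectures(arch)) {
      expect_silent(validate_architecture(cand))
      expect_equal(sum(cand), sum(arch) + 1L)
    }
  }
})

test_that("growth keeps every existing parameter and adds random ones", {
  existing <- init_network(c(2), seed = 5)
  g1 <- grow_network(existing, c(3), seed = 6)
  expect_equal(g1$W[[1]][, 1:2], existing$W[[1]])
  expect_equal(g1$b[[1]][1:2], existing$b[[1]])
  expect_equal(g1$W[[2]][1:2, ], existing$W[[2]][, 1])
  expect_true(all(abs(c(g1$W[[1]][, 3], g1$b[[1]][3], g1$W[[2]][3, ])) <= 1))
  # new trailing layer: old output weights are replaced, bias kept
  g2 <- grow_network(existing, c(2, 1), seed = 7)
  expect_equal(g2$W[[1]], existing$W[[1]])
  expect_equal(g2$b[[1]], existing$b[[1]])
  expect_equal(dim(g2$W[[2]]), c(2L, 1L))   # last hidden -> new neuron
  expect_equal(dim(g2$W[[3]]), c(1L, 1L))   # new neuron -> output
  expect_equal(g2$b[[3]], existing$b[[2]])  # output neuron keeps its bias
  expect_gt(rslpnet:::n_parameters(g2), rslpnet:::n_parameters(existing))
  expect_gt(rslpnet:::n_parameters(g1), rslpnet:::n_parameters(existing))
  expect_error(grow_network(existing, c(4)), "one-neuron")
  expect_identical(rslpnet:::pack_params(grow_network(existing, c(3), 6)),
                   rslpnet:::pack_params(g1))
})

test_that("a perfect existing network rejects all growth", {
  d <- prepare_split(make_toy_cohort("separable", 30, 30, seed = 4), seed = 4)
  existing <- init_network(c(1), seed = 4)
  cfg <- rslp_config(max_new_neuron_inits = 5)
  out <- accept_candidate(existing, 0, c(2), d$x_train, d$y_train,
                          config = cfg, seed = 1)
  expect_false(out$accepted)
  expect_equal(out$inits, 5L)
})

test_that("growth is accepted when the existing network underfits", {
  d <- prepare_split(make_toy_cohort("xor2d", 60, 60, seed = 6), seed = 6)
  existing <- init_network(c(1), seed = 1)
  res <- scg_train(existing, d$x_train, d$y_train, d$x_val, d$y_val)
  out <- accept_candidate(res$params, res$train_error, c(2),
                          d$x_train, d$y_train, seed = 2)
  expect_true(out$accepted)
  expect_lte(out$inits, 500L)
  e1 <- rslpnet:::scg_step_error(out$params, d$x_train, d$y_train,
                                 class_weights(d$y_train),
                                 training_config(max_iterations = 1))
  expect_lt(e1, res$train_error)
})

test_that("candidate learning succeeds/fails by the validation-error rule", {
  d <- prepare_split(make_toy_cohort("separable", 30, 30, seed = 8), seed = 8)
  existing <- init_network(c(1), seed = 3)
  res <- scg_train(existing, d$x_train, d$y_train, d$x_val, d$y_val)
  # worst possible existing validation error: any converged candidate wins
  win <- learn_candidate(res$params, res$train_error, 1.0, c(2),
                         d$x_train, d$y_train, d$x_val, d$y_val, seed = 4)
  expect_true(win$success)
  expect_lte(win$result$val_error, 1.0)
  # unbeatable existing validation error: rejected after the attempt cap
  cfg <- rslp_config(max_candidate_reinits = 3)
  lose <- learn_candidate(res$params, res$train_error, 0, c(2),
                          d$x_train, d$y_train, d$x_val, d$y_val,
                          config = cfg, seed = 5)
  expect_false(lose$success)
  expect_equal(lose$attempts, 3L)
})

test_that("the constructive run respects its growth invariants", {
  families <- c("separable", "xor2d")
  for (s in 1:4) {
    d <- prepare_split(make_toy_cohort(families[1 + s %% 2], 60, 60,
                                       seed = s), seed = s)
    r <- rslp_run(d$x_train, d$y_train, d$x_val, d$y_val, seed = s)
    expect_s3_class(r, "rslp_result")
    expect_true(r$history$stop_criterion %in%
                  c("all-candidates-rejected", "perfect-classification"))
    acc <- Filter(function(st) st$accepted, r$history$steps)
    archs <- lapply(acc, `[[`, "arch")
    expect_equal(archs[[1]], c(1L))
    for (a in archs) expect_silent(validate_architecture(a))
    if (length(archs) > 1) {
      for (i in 2:length(archs)) {
        expect_equal(sum(archs[[i]]), sum(archs[[i - 1]]) + 1L)
      }
    }
    # total neurons = 1 + accepted growth steps
    expect_equal(sum(r$params$arch), length(archs))
    v <- vapply(acc, `[[`, numeric(1), "val_error")
    t <- vapply(acc, `[[`, numeric(1), "train_error")
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(diff(t) < 0))
  }
})

test_that("multi-restart optimization picks the best learning AUC", {
  d <- prepare_split(make_toy_cohort("separable", 50, 50, seed = 12),
                     seed = 12)
  one <- rslp_optimize(d$x_train, d$y_train, d$x_val, d$y_val,
                       rslp_config(n_alternatives = 1), seed = 13)
  solo <- rslp_run(d$x_train, d$y_train, d$x_val, d$y_val,
                   seed = child_seed(13, "rslp-alternative-1"))
  expect_identical(rslpnet:::pack_params(one$params),
                   rslpnet:::pack_params(solo$params))
  opt <- rslp_optimize(d$x_train, d$y_train, d$x_val, d$y_val,
                       rslp_config(n_alternatives = 3), seed = 13)
  expect_equal(nrow(opt$report), 3L)
  expect_equal(max(opt$report$learning_auc),
               opt$report$learning_auc[opt$alternative])
  # separable cohort: perfect learning discrimination is attainable
  expect_equal(max(opt$report$learning_auc), 1.0)
  # tie-break prefers the smallest network among equal AUCs
  ties <- opt$report[opt$report$learning_auc == max(opt$report$learning_auc), ]
  expect_equal(opt$report$neurons[opt$alternative], min(ties$neurons))
  # end-to-end reproducibility of the master seed
  opt2 <- rslp_optimize(d$x_train, d$y_train, d$x_val, d$y_val,
                        rslp_config(n_alternatives = 3), seed = 13)
  expect_identical(rslpnet:::pack_params(opt$params),
                   rslpnet:::pack_params(opt2$params))
  expect_equal(opt$report, opt2$report)
})
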