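#' Configuration of the repeated structuring and learning procedure
#'
#' @param max_new_neuron_inits maximum random initializations of a new
#'   neuron before a candidate architecture is rejected at the
#'   one-iteration acceptance test (default 500).
#' @param max_candidate_reinits maximum learning attempts of an accepted
#'   candidate before it is rejected after repeated validation failures
#'   (default 10).
#' @param n_alternatives number of alternative networks constructed by
#'   [rslp_optimize()], of which the one with the largest learning AUC is
#'   kept (default 100).
#' @param training a [training_config()] shared by every learning phase.
#' @return list of class `rslp_config`.
#' @export
rslp_config <- function(max_new_neuron_inits = 500L,
                        max_candidate_reinits = 10L,
                        n_alternatives = 100L,
                        training = training_config()) {
  stopifnot(max_new_neuron_inits >= 1, max_candidate_reinits >= 1,
            n_alternatives >= 1)
  structure(list(max_new_neuron_inits = as.integer(max_new_neuron_inits),
                 max_candidate_reinits = as.integer(max_candidate_reinits),
                 n_alternatives = as.integer(n_alternatives),
                 training = training),
            class = "rslp_config")
}

#' Enumerate the architectures reachable by adding one neuron
#'
#' A growth attempt adds one neuron to each existing hidden layer in turn,
#' then tries to open a new trailing hidden layer of width 1.  Attempts
#' violating either structural constraint (at most three hidden layers; no
#' layer wider than its predecessor) are discarded.  For a 3-layer
#' architecture with the second layer as wide as the first and a narrower
#' third layer, exactly two of the four attempts survive.
#'
#' @param arch hidden-layer widths of the existing network.
#' @return list of candidate architectures, in the order: first-layer
#'   increment, deeper-layer increments, new-layer attempt; with attribute
#'   `attempts` giving the number of attempts tried.
#' @examples
#' candidate_architectures(c(1))        # [2] and [1 1]
#' candidate_architectures(c(2, 2, 1))  # [3 2 1] and [2 2 2]
#' @export
candidate_architectures <- function(arch) {
  arch <- validate_architecture(arch)
  L <- length(arch)
  attempts <- L + 1L
  out <- list()
  for (i in seq_len(L)) {
    grown <- arch
    grown[i] <- grown[i] + 1L
    if (i == 1L || grown[i] <= grown[i - 1L]) {
      out[[length(out) + 1L]] <- grown
    }
  }
  if (L < 3L) {
    out[[length(out) + 1L]] <- c(arch, 1L)
  }
  stopifnot(length(out) >= 1L) # cannot be empty for <= 3 layers
  attr(out, "attempts") <- attempts
  out
}

# Where does `candidate` differ from `arch`?  Returns the grown layer index,
# or L+1 when a new layer is added; error when not a one-neuron growth.
growth_layer <- function(arch, candidate) {
  if (length(candidate) == length(arch) + 1L &&
      all(candidate[seq_along(arch)] == arch) &&
      candidate[length(candidate)] == 1L) {
    return(length(arch) + 1L)
  }
  if (length(candidate) == length(arch)) {
    d <- candidate - arch
    if (sum(d == 1L) == 1L && sum(d != 0L) == 1L) return(which(d == 1L))
  }
  stop("candidate is not reachable from the existing architecture by ",
       "one-neuron growth", call. = FALSE)
}

#' Grow an existing network into a one-neuron-larger candidate
#'
#' All weights and biases of the existing neurons are copied unchanged;
#' only the parameters that exist because of the new neuron — its incoming
#' weights and bias, and the new connections feeding the downstream layer —
#' are drawn uniformly from [-1, +1].  When a new hidden layer is opened,
#' the old direct last-hidden-to-output weights can no longer exist; they
#' are discarded and the replacement connections are newly drawn (the
#' output neuron keeps its bias).
#'
#' @param existing `nn_parameters` of the existing network.
#' @param candidate target architecture, one neuron larger.
#' @param seed integer seed for the new random parameters.
#' @return `nn_parameters` for the candidate architecture.
#' @export
grow_network <- function(existing, candidate, seed = 1L) {
  candidate <- validate_architecture(candidate)
  arch <- existing$arch
  gl <- growth_layer(arch, candidate)
  with_seed(seed, {
    W <- existing$W
    b <- existing$b
    if (gl > length(arch)) {
      # new trailing hidden layer of width 1, feeding the output neuron
      h_last <- arch[length(arch)]
      out_idx <- length(W)
      out_bias <- b[[out_idx]]
      W[[out_idx]] <- matrix(stats::runif(h_last, -1, 1), nrow = h_last,
                             ncol = 1L)                  # last hidden -> new
      b[[out_idx]] <- stats::runif(1L, -1, 1)            # new neuron's bias
      W[[out_idx + 1L]] <- matrix(stats::runif(1L, -1, 1), 1L, 1L)
      b[[out_idx + 1L]] <- out_bias                      # output keeps bias
    } else {
      # widen layer gl: one new column in, one new row out
      n_in <- nrow(W[[gl]])
      W[[gl]] <- cbind(W[[gl]], stats::runif(n_in, -1, 1))
      b[[gl]] <- c(b[[gl]], stats::runif(1L, -1, 1))
      n_out <- ncol(W[[gl + 1L]])
      W[[gl + 1L]] <- rbind(W[[gl + 1L]], stats::runif(n_out, -1, 1))
    }
    structure(list(W = W, b = b, arch = candidate,
                   n_inputs = existing$n_inputs, scaler = existing$scaler),
              class = "nn_parameters")
  })
}

#' One-iteration acceptance test of a candidate architecture
#'
#' A grown candidate is acceptable only if the new neuron improves training
#' performance: after exactly one SCG iteration its training error must be
#' strictly below the existing network's training error.  Otherwise the new
#' neuron is re-initialized, up to `max_new_neuron_inits` times, after
#' which the candidate is rejected.
#'
#' @param existing `nn_parameters` of the existing (trained) network.
#' @param existing_train_error training error of the existing network.
#' @param candidate target architecture.
#' @param x_train,y_train training data (scaled) and labels.
#' @param w_train class weights of the training set.
#' @param config an [rslp_config()].
#' @param seed integer seed for the initialization stream.
#' @return list with `accepted` (logical), `params` (the grown, untrained
#'   candidate whose first iteration passed the test; NULL on rejection)
#'   and `inits` (initializations used).
#' @export
accept_candidate <- function(existing, existing_train_error, candidate,
                             x_train, y_train,
                             w_train = class_weights(y_train),
                             config = rslp_config(), seed = 1L) {
  one_iter <- training_config(max_iterations = 1L,
                              first_iteration_exemption = TRUE,
                              sigma = config$training$sigma,
                              lambda = config$training$lambda)
  for (i in seq_len(config$max_new_neuron_inits)) {
    grown <- grow_network(existing, candidate,
                          seed = child_seed(seed, paste0("init-", i)))
    e1 <- scg_step_error(grown, x_train, y_train, w_train, one_iter)
    if (e1 < existing_train_error) {
      return(list(accepted = TRUE, params = grown, inits = i))
    }
  }
  list(accepted = FALSE, params = NULL, inits = config$max_new_neuron_inits)
}

# Training error after exactly one SCG iteration from `params` (no
# validation bookkeeping; mirrors the first iteration of scg_train).
scg_step_error <- function(params, x_train, y_train, w_train, config) {
  sizes <- layer_sizes(params$arch, params$n_inputs)
  sw <- sample_weights(y_train, w_train)
  f <- function(vec) {
    cpp_nn_err_grad(vec, sizes, x_train, y_train, sw, FALSE)$error
  }
  g <- function(vec) {
    as.numeric(cpp_nn_err_grad(vec, sizes, x_train, y_train, sw, TRUE)$grad)
  }
  wv <- pack_params(params)
  eg0 <- cpp_nn_err_grad(wv, sizes, x_train, y_train, sw, TRUE)
  fw <- eg0$error
  r <- -as.numeric(eg0$grad)
  p2 <- sum(r * r)
  pnorm <- sqrt(p2)
  if (pnorm < 1e-14) return(fw)
  sigma_k <- config$sigma / pnorm
  s <- (g(wv + sigma_k * r) + r) / sigma_k
  delta <- sum(r * s) + config$lambda * p2
  if (delta <= 0) delta <- -delta + config$lambda * p2
  alpha <- p2 / delta
  fnew <- f(wv + alpha * r)
  cmp <- 2 * delta * (fw - fnew) / p2^2
  if (is.finite(fnew) && cmp >= 0) fnew else fw
}

#' Acceptance plus full learning of one candidate architecture
#'
#' Runs the one-iteration acceptance test and, when accepted, the full
#' learning phase.  The learned candidate succeeds if its (minimum)
#' validation error does not exceed the existing network's validation
#' error; on failure the candidate is regrown with a fresh random new
#' neuron (re-passing the acceptance test), and it is rejected after
#' `max_candidate_reinits` consecutive failures.
#'
#' @param existing,existing_train_error as in [accept_candidate()].
#' @param existing_val_error validation error of the existing network.
#' @param candidate target architecture.
#' @param x_train,y_train,x_val,y_val scaled data and labels.
#' @param w_train,w_val class weights.
#' @param config an [rslp_config()].
#' @param seed integer seed.
#' @return list with `success` (logical) and, on success, `result` (the
#'   [scg_train()] result of the successful attempt) plus `attempts`.
#' @export
learn_candidate <- function(existing, existing_train_error,
                            existing_val_error, candidate,
                            x_train, y_train, x_val, y_val,
                            w_train = class_weights(y_train),
                            w_val = class_weights(y_val),
                            config = rslp_config(), seed = 1L) {
  last <- NULL
  for (attempt in seq_len(config$max_candidate_reinits)) {
    acc <- accept_candidate(existing, existing_train_error, candidate,
                            x_train, y_train, w_train, config,
                            seed = child_seed(seed,
                                              paste0("attempt-", attempt)))
    if (!acc$accepted) {
      return(list(success = FALSE, result = last, attempts = attempt,
                  rejected_at = "acceptance"))
    }
    res <- scg_train(acc$params, x_train, y_train, x_val, y_val,
                     w_train, w_val, config$training)
    last <- res
    if (res$val_error <= existing_val_error) {
      return(list(success = TRUE, result = res, attempts = attempt))
    }
  }
  list(success = FALSE, result = last,
       attempts = config$max_candidate_reinits, rejected_at = "learning")
}

#' Run the repeated structuring and learning procedure once
#'
#' Starts from a one-hidden-neuron network, trains it, then alternates
#' structuring with learning: every reachable one-neuron-larger candidate
#' is grown, tested for acceptance, and learned; among the successful
#' candidates the one with the lowest validation error becomes the new
#' existing network.  The procedure stops when all candidates are rejected
#' (first stopping criterion) or when the training and validation datasets
#' are classified without error at threshold 0.5 (second stopping
#' criterion, which guards against overfitting).
#'
#' @param x_train,y_train,x_val,y_val scaled feature matrices and 0/1
#'   labels for the training and validation datasets.
#' @param config an [rslp_config()].
#' @param seed integer seed; the whole run is reproducible given the seed.
#' @param verbose print structuring decisions as they happen.
#' @return list of class `rslp_result`: `params` (final network),
#'   `train_error`, `val_error`, and `history` with per-step records
#'   (`arch`, `accepted`, error traces), `stop_criterion`
#'   (`"all-candidates-rejected"` or `"perfect-classification"`) and
#'   `total_iterations` over accepted learning phases.
#' @export
rslp_run <- function(x_train, y_train, x_val, y_val,
                     config = rslp_config(), seed = 1L, verbose = FALSE) {
  w_train <- class_weights(y_train)
  w_val <- class_weights(y_val)
  existing <- init_network(c(1L), seed = child_seed(seed, "initial"),
                           n_inputs = ncol(x_train))
  res <- scg_train(existing, x_train, y_train, x_val, y_val,
                   w_train, w_val, config$training)
  existing <- res$params
  e_train <- res$train_error
  e_val <- res$val_error
  steps <- list(list(arch = existing$arch, accepted = TRUE,
                     train_trace = res$train_trace,
                     val_trace = res$val_trace,
                     train_error = e_train, val_error = e_val,
                     iterations = res$iterations))
  total_iter <- res$iterations
  stop_criterion <- NULL
  if (res$stop_reason == "perfect-classification") {
    stop_criterion <- "perfect-classification"
  }

  cycle <- 0L
  while (is.null(stop_criterion)) {
    cycle <- cycle + 1L
    cands <- candidate_architectures(existing$arch)
    outcomes <- vector("list", length(cands))
    for (ci in seq_along(cands)) {
      outcomes[[ci]] <- learn_candidate(
        existing, e_train, e_val, cands[[ci]],
        x_train, y_train, x_val, y_val, w_train, w_val, config,
        seed = child_seed(seed, sprintf("cycle-%d-cand-%d", cycle, ci)))
      if (verbose) {
        message(sprintf("cycle %d candidate [%s]: %s", cycle,
                        paste(cands[[ci]], collapse = " "),
                        if (outcomes[[ci]]$success) "success" else "failure"))
      }
    }
    ok <- vapply(outcomes, function(o) isTRUE(o$success), logical(1))
    if (!any(ok)) {
      for (ci in seq_along(cands)) {
        res_ci <- outcomes[[ci]]$result
        steps[[length(steps) + 1L]] <-
          list(arch = cands[[ci]], accepted = FALSE,
               train_trace = if (is.null(res_ci)) numeric(0) else
                 res_ci$train_trace,
               val_trace = if (is.null(res_ci)) numeric(0) else
                 res_ci$val_trace,
               train_error = if (is.null(res_ci)) NA_real_ else
                 res_ci$train_error,
               val_error = if (is.null(res_ci)) NA_real_ else
                 res_ci$val_error,
               iterations = 0L)
      }
      stop_criterion <- "all-candidates-rejected"
      break
    }
    vals <- vapply(outcomes, function(o) {
      if (isTRUE(o$success)) o$result$val_error else Inf
    }, numeric(1))
    best <- which.min(vals)
    res <- outcomes[[best]]$result
    existing <- res$params
    e_train <- res$train_error
    e_val <- res$val_error
    steps[[length(steps) + 1L]] <-
      list(arch = existing$arch, accepted = TRUE,
           train_trace = res$train_trace, val_trace = res$val_trace,
           train_error = e_train, val_error = e_val,
           iterations = res$iterations)
    total_iter <- total_iter + res$iterations
    if (verbose) {
      message(sprintf("cycle %d upgraded to [%s] (val error %.4g)", cycle,
                      paste(existing$arch, collapse = " "), e_val))
    }
    if (all(classify(nn_forward(existing, x_train)) == y_train) &&
        all(classify(nn_forward(existing, x_val)) == y_val)) {
      stop_criterion <- "perfect-classification"
    }
  }

  structure(list(params = existing, train_error = e_train,
                 val_error = e_val,
                 history = list(steps = steps,
                                stop_criterion = stop_criterion,
                                total_iterations = total_iter)),
            class = "rslp_result")
}

#' Multi-restart optimization of the constructive procedure
#'
#' Random neuron initialization makes every run of [rslp_run()] different;
#' to reduce the chance of keeping an inefficient network due to adverse
#' initialization, `n_alternatives` alternative networks are constructed
#' with independent seed streams, the ROC of each is computed on the full
#' learning dataset (training plus validation) by sweeping the decision
#' threshold, and the network with the largest learning AUC is selected.
#' Ties are broken toward fewer total neurons, then lower validation error,
#' then lower alternative index.
#'
#' @inheritParams rslp_run
#' @return list of class `rslp_optimized`: `params` (selected network),
#'   `run` (its full `rslp_result`), `alternative` (its index) and
#'   `report` (data.frame over alternatives: learning AUC, architecture,
#'   neurons, validation error, stop criterion, iterations).
#' @export
rslp_optimize <- function(x_train, y_train, x_val, y_val,
                          config = rslp_config(), seed = 1L,
                          verbose = FALSE) {
  x_learn <- rbind(x_train, x_val)
  y_learn <- c(y_train, y_val)
  runs <- vector("list", config$n_alternatives)
  aucs <- numeric(config$n_alternatives)
  for (k in seq_len(config$n_alternatives)) {
    runs[[k]] <- rslp_run(x_train, y_train, x_val, y_val, config,
                          seed = child_seed(seed,
                                            paste0("rslp-alternative-", k)))
    aucs[k] <- roc_auc(nn_forward(runs[[k]]$params, x_learn), y_learn)
    if (verbose) {
      message(sprintf("alternative %d: [%s], learning AUC %.4f", k,
                      paste(runs[[k]]$params$arch, collapse = " "), aucs[k]))
    }
  }
  neurons <- vapply(runs, function(r) count_neurons(r$params$arch),
                    numeric(1))
  val_errs <- vapply(runs, function(r) r$val_error, numeric(1))
  ord <- order(-aucs, neurons, val_errs, seq_along(runs))
  best <- ord[1L]
  report <- data.frame(
    alternative = seq_len(config$n_alternatives),
    learning_auc = aucs,
    architecture = vapply(runs, function(r) {
      paste(r$params$arch, collapse = " ")
    }, character(1)),
    neurons = as.integer(neurons),
    val_error = val_errs,
    stop_criterion = vapply(runs, function(r) r$history$stop_criterion,
                            character(1)),
    iterations = vapply(runs, function(r) r$history$total_iterations,
                        numeric(1)))
  structure(list(params = runs[[best]]$params, run = runs[[best]],
                 alternative = best, report = report),
            class = "rslp_optimized")
}
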