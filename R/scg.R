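#' Configuration of a scaled-conjugate-gradient learning phase
#'
#' @param max_iterations safety cap on full-batch SCG iterations (default
#'   1000; the early-stopping rule normally triggers much earlier, and
#'   hitting the cap is reported in the result).  0 is allowed and returns
#'   the initial parameters untrained.
#' @param first_iteration_exemption tolerate a validation-error rise at the
#'   first comparison of a learning phase.  Freshly structured networks
#'   (existing weights plus one random neuron) often overshoot once before
#'   settling; afterwards the validation error must decrease monotonically.
#' @param sigma step size of the finite-difference approximation to the
#'   Hessian-vector product (default 1e-4).
#' @param lambda initial Levenberg-Marquardt damping (default 1e-6).
#' @return list of class `training_config`.
#' @export
training_config <- function(max_iterations = 1000L,
                            first_iteration_exemption = TRUE,
                            sigma = 1e-4, lambda = 1e-6) {
  stopifnot(max_iterations >= 0, sigma > 0, lambda > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 first_iteration_exemption = isTRUE(first_iteration_exemption),
                 sigma = sigma, lambda = lambda),
            class = "training_config")
}

#' Scaled-conjugate-gradient learning phase with validation-based early
#' stopping
#'
#' Full-batch training of a sigmoid network by Moller's scaled conjugate
#' gradient: a conjugate-direction method with a Levenberg-Marquardt
#' damping term in place of a line search.  One iteration is one pass of
#' the SCG update on the full training set (the weight update is only
#' applied when the comparison parameter accepts the step, so the training
#' error never increases).  The learning phase ends when the validation
#' error starts to increase (strict rise over the previous iteration;
#' optionally exempting the first comparison), when training and validation
#' are both perfectly classified at threshold 0.5, or at the iteration cap.
#' The parameters returned are those with the minimum validation error
#' observed during the phase.
#'
#' @param params initial `nn_parameters`.
#' @param x_train,y_train training inputs (scaled matrix) and 0/1 labels.
#' @param x_val,y_val validation inputs and labels.
#' @param w_train,w_val class weights for the two error functions; default
#'   to the inverse prevalences of each dataset.
#' @param config a [training_config()].
#' @return list of class `train_result`: `params` (minimum-validation-error
#'   iterate), `train_trace`, `val_trace` (per-iteration errors),
#'   `iterations`, `stop_reason` (one of `"validation-increase"`,
#'   `"max-iterations"`, `"perfect-classification"`, `"converged"`), and
#'   `train_error` / `val_error` of the returned parameters.
#' @export
scg_train <- function(params, x_train, y_train, x_val, y_val,
                      w_train = class_weights(y_train),
                      w_val = class_weights(y_val),
                      config = training_config()) {
  stopifnot(inherits(params, "nn_parameters"))
  if (!all(c(0, 1) %in% y_train) || !all(c(0, 1) %in% y_val)) {
    stop("training and validation sets must both contain both classes",
         call. = FALSE)
  }
  template <- params
  sizes <- layer_sizes(params$arch, params$n_inputs)
  sw_train <- sample_weights(y_train, w_train)
  sw_val <- sample_weights(y_val, w_val)
  f <- function(vec) {
    cpp_nn_err_grad(vec, sizes, x_train, y_train, sw_train, FALSE)$error
  }
  g <- function(vec) {
    as.numeric(cpp_nn_err_grad(vec, sizes, x_train, y_train, sw_train,
                               TRUE)$grad)
  }
  val_scores <- function(vec) as.numeric(cpp_nn_scores(vec, sizes, x_val))
  val_err_of <- function(s) sum(sw_val * (s - y_val)^2) / sum(sw_val)
  perfect <- function(vec, vscores) {
    all(classify(vscores) == y_val) &&
      all(classify(as.numeric(cpp_nn_scores(vec, sizes, x_train))) ==
            y_train)
  }

  wv <- pack_params(params)
  N <- length(wv)
  lambda <- config$lambda
  lambdabar <- 0
  fw <- f(wv)
  v0 <- val_err_of(val_scores(wv))
  if (!is.finite(fw) || !is.finite(v0)) {
    stop("non-finite error at the initial parameters; training aborted",
         call. = FALSE)
  }
  r <- -g(wv)
  p <- r
  success <- TRUE
  delta <- 0

  train_trace <- numeric(0)
  val_trace <- numeric(0)
  # best-by-validation over iterations actually run; the untrained initial
  # parameters are only a fallback for a zero-iteration phase
  best_vec <- wv
  best_val <- Inf
  best_train <- fw
  stop_reason <- "max-iterations"
  k <- 0L

  while (k < config$max_iterations) {
    k <- k + 1L
    p2 <- sum(p * p)
    pnorm <- sqrt(p2)
    if (pnorm < 1e-14 || lambda > 1e18) {
      k <- k - 1L
      stop_reason <- "converged"
      break
    }
    if (success) {
      sigma_k <- config$sigma / pnorm
      s <- (g(wv + sigma_k * p) + r) / sigma_k
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambdabar) * p2
    if (delta <= 0) {
      lambdabar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    fnew <- f(wv + alpha * p)
    if (!is.finite(fnew)) {
      stop("non-finite training error during SCG; training aborted",
           call. = FALSE)
    }
    cmp <- 2 * delta * (fw - fnew) / mu^2
    if (cmp >= 0) {
      wv <- wv + alpha * p
      fw <- fnew
      rnew <- -g(wv)
      lambdabar <- 0
      success <- TRUE
      if (k %% N == 0L) {
        p <- rnew
      } else {
        beta <- (sum(rnew * rnew) - sum(rnew * r)) / mu
        p <- rnew + beta * p
      }
      r <- rnew
      if (cmp >= 0.75) lambda <- lambda / 4
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (cmp < 0.25) lambda <- lambda + delta * (1 - cmp) / p2

    vs <- val_scores(wv)
    v <- val_err_of(vs)
    train_trace[k] <- fw
    val_trace[k] <- v
    if (v < best_val) {
      best_val <- v
      best_vec <- wv
      best_train <- fw
    }
    if (perfect(wv, vs)) {
      stop_reason <- "perfect-classification"
      # a perfect classifier supersedes the min-validation-error iterate
      best_vec <- wv
      best_val <- v
      best_train <- fw
      break
    }
    if (k >= 2L && val_trace[k] > val_trace[k - 1L] &&
        !(config$first_iteration_exemption && k == 2L)) {
      stop_reason <- "validation-increase"
      break
    }
  }

  if (!is.finite(best_val)) best_val <- v0  # zero-iteration phase
  out <- list(params = unpack_params(best_vec, template),
              train_trace = train_trace, val_trace = val_trace,
              iterations = k, stop_reason = stop_reason,
              train_error = best_train, val_error = best_val)
  class(out) <- "train_result"
  out
}
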