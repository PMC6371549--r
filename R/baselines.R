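#' Train a fixed-architecture network by a single learning phase
#'
#' The standard-method comparator: the architecture is fixed (typically the
#' final architecture found by the constructive procedure), all parameters
#' are initialized uniformly in [-1, 1], and exactly one learning phase is
#' applied with the same data division, class weighting, optimizer and
#' early-stopping rule as the constructive runs — no structuring.
#'
#' @param arch hidden-layer widths.
#' @param x_train,y_train,x_val,y_val scaled data and 0/1 labels.
#' @param w_train,w_val class weights (default: inverse prevalence of each
#'   dataset).
#' @param config a [training_config()].
#' @param seed integer seed for the initialization.
#' @return list with `params` (trained `nn_parameters`) and `result` (the
#'   [scg_train()] result).
#' @export
train_standard_nn <- function(arch, x_train, y_train, x_val, y_val,
                              w_train = class_weights(y_train),
                              w_val = class_weights(y_val),
                              config = training_config(), seed = 1L) {
  params <- init_network(arch, seed = child_seed(seed, "standard-init"),
                         n_inputs = ncol(x_train))
  res <- scg_train(params, x_train, y_train, x_val, y_val, w_train, w_val,
                   config)
  list(params = res$params, result = res)
}

#' Inverse-prevalence-weighted logistic regression
#'
#' The rigid comparator: a logistic discriminating function of the 13
#' (standardized) difference features, fitted by maximizing the
#' class-weighted log-likelihood with each sample weighted by the inverse
#' prevalence of its class.  Unpenalized by default; if the fit is flagged
#' as separated (non-converged or exploding coefficients), it is refitted
#' with a tiny ridge stabilizer (1e-8) and the model is marked.
#'
#' @param x numeric matrix (n x 13) of scaled features.
#' @param labels 0/1 labels.
#' @param w class weights (default: inverse prevalence of `labels`).
#' @return list of class `lr_model`: `coefficients` (13), `intercept`,
#'   `separation` flag, and `scaler` (attached by the caller, NULL here).
#' @export
train_weighted_lr <- function(x, labels, w = class_weights(labels)) {
  check_two_classes(labels)
  sw <- sample_weights(labels, w)
  df <- as.data.frame(x)
  df$.y <- labels
  # quasibinomial likelihood has the same maximizer and accepts
  # non-integer prevalence weights without complaint
  fit <- stats::glm(.y ~ ., family = stats::quasibinomial(), data = df,
                    weights = sw, control = list(maxit = 100))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0  # aliased / zero-variance columns drop out
  # numerically 0/1 fitted probabilities signal (quasi-)separation
  saturated <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  separated <- saturated || !fit$converged || any(abs(co[-1]) > 1e3) ||
    any(!is.finite(co))
  if (separated) {
    refit <- tryCatch({
      gfit <- glmnet::glmnet(as.matrix(x), labels, family = "binomial",
                             weights = sw, alpha = 0, lambda = 1e-8,
                             standardize = FALSE)
      stats::setNames(c(as.numeric(gfit$a0), as.numeric(gfit$beta)),
                      c("(Intercept)", colnames(x)))
    }, error = function(e) NULL)
    if (!is.null(refit)) {
      co <- refit
    } else {
      # cap exploded coefficients; scores saturate either way
      co[!is.finite(co)] <- 0
      co <- pmin(pmax(co, -1e3), 1e3)
    }
    warning("separation detected in the weighted logistic fit; ",
            "ridge stabilizer applied", call. = FALSE)
  }
  structure(list(coefficients = co[-1], intercept = unname(co[1]),
                 separation = separated, scaler = NULL),
            class = "lr_model")
}

#' Score samples with a fitted logistic model
#'
#' @param model an `lr_model`.
#' @param x scaled feature matrix or single feature vector (if the model
#'   carries a scaler, `x` is taken as raw features and scaled first).
#' @return numeric scores in (0, 1).
#' @export
lr_score <- function(model, x) {
  stopifnot(inherits(model, "lr_model"))
  if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(sigmoid(x %*% model$coefficients + model$intercept))
}
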