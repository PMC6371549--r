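#' Validate a hidden-layer architecture
#'
#' An architecture is the ordered vector of hidden-layer widths of a
#' 13-input, 1-output feed-forward network, e.g. `c(19, 9, 9)`.  Growth of
#' such networks is constrained to at most three hidden layers, and no
#' hidden layer may be wider than the one before it.
#'
#' @param arch integer vector of hidden-layer widths.
#' @return the architecture, invisibly, if valid; otherwise an error.
#' @export
validate_architecture <- function(arch) {
  if (length(arch) < 1L || length(arch) > 3L) {
    stop("architecture must have between 1 and 3 hidden layers",
         call. = FALSE)
  }
  if (any(arch != as.integer(arch)) || any(arch < 1)) {
    stop("hidden-layer widths must be positive integers", call. = FALSE)
  }
  if (length(arch) > 1L && any(diff(arch) > 0)) {
    stop("hidden-layer widths must be non-increasing", call. = FALSE)
  }
  invisible(as.integer(arch))
}

#' Total number of neurons of an architecture
#'
#' Hidden neurons only (the single output neuron is fixed and not counted),
#' so `c(16, 13, 12)` has 41 neurons and `c(11, 9, 1)` has 21.
#'
#' @param arch integer vector of hidden-layer widths.
#' @return integer neuron count.
#' @export
count_neurons <- function(arch) {
  sum(validate_architecture(arch))
}

# Layer sizes including input (n_inputs) and output (1).
layer_sizes <- function(arch, n_inputs = 13L) {
  c(n_inputs, as.integer(arch), 1L)
}

#' Initialize a network with uniform random weights and biases in [-1, 1]
#'
#' Every neuron (hidden and output) has a bias and incoming weights, all
#' drawn independently and uniformly from [-1, +1]; the draw is
#' deterministic given the seed.
#'
#' @param arch hidden-layer widths (see [validate_architecture()]).
#' @param seed integer seed.
#' @param n_inputs number of input features (13 difference features).
#' @return object of class `nn_parameters`: lists `W` (weight matrices,
#'   one per connection layer, rows = source units) and `b` (bias vectors),
#'   plus the architecture.
#' @export
init_network <- function(arch, seed = 1L, n_inputs = 13L) {
  arch <- validate_architecture(arch)
  sizes <- layer_sizes(arch, n_inputs)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -1, 1),
                       nrow = sizes[l], ncol = sizes[l + 1L])
      b[[l]] <- stats::runif(sizes[l + 1L], -1, 1)
    }
    structure(list(W = W, b = b, arch = arch, n_inputs = n_inputs,
                   scaler = NULL),
              class = "nn_parameters")
  })
}

# Number of free parameters (weights + biases).
n_parameters <- function(params) {
  sum(vapply(params$W, length, integer(1))) +
    sum(vapply(params$b, length, integer(1)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of a sigmoid feed-forward network
#'
#' Every neuron, hidden and output, applies the logistic sigmoid to its
#' affine pre-activation, so the single output is a score strictly inside
#' (0, 1): 0 leaning control, 1 leaning case.
#'
#' @param params `nn_parameters`.
#' @param x numeric matrix (n x 13) of (scaled) inputs, or a single
#'   13-vector.
#' @return numeric vector of n scores in (0, 1).
#' @export
nn_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("non-finite network input", call. = FALSE)
  if (ncol(x) != params$n_inputs) {
    stop("input must have ", params$n_inputs, " features", call. = FALSE)
  }
  as.numeric(cpp_nn_scores(pack_params(params),
                           layer_sizes(params$arch, params$n_inputs), x))
}

#' Inverse-prevalence-weighted normalized squared error
#'
#' The training- and validation-error function: the sum of squared
#' differences between network scores and true 0/1 labels, with each sample
#' weighted by the inverse prevalence of its class, normalized by the total
#' weight so that E lies in [0, 1] and is comparable across datasets of
#' different size and case/control disproportion.
#'
#' @param scores numeric scores in [0, 1].
#' @param labels 0/1 labels.
#' @param w class weights from [class_weights()] (defaults to the inverse
#'   prevalences of `labels` themselves).
#' @return E in [0, 1].
#' @export
weighted_error <- function(scores, labels, w = class_weights(labels)) {
  if (length(scores) == 0L || length(scores) != length(labels)) {
    stop("scores and labels must be non-empty and of equal length",
         call. = FALSE)
  }
  sw <- sample_weights(labels, w)
  sum(sw * (scores - labels)^2) / sum(sw)
}

#' Analytic gradient of the weighted error of a network
#'
#' Backpropagation of [weighted_error()] through the sigmoid layers;
#' returns the exact gradient with respect to every weight and bias.
#'
#' @param params `nn_parameters`.
#' @param x input matrix (n x 13), already scaled.
#' @param labels 0/1 labels.
#' @param w class weights (see [class_weights()]).
#' @return list with `W` and `b` mirroring the shapes of `params`.
#' @export
nn_gradient <- function(params, x, labels, w = class_weights(labels)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0L) stop("empty batch", call. = FALSE)
  if (ncol(x) != params$n_inputs) {
    stop("input must have ", params$n_inputs, " features", call. = FALSE)
  }
  eg <- cpp_nn_err_grad(pack_params(params),
                        layer_sizes(params$arch, params$n_inputs),
                        x, labels, sample_weights(labels, w), TRUE)
  unpack_params(as.numeric(eg$grad), params)[c("W", "b")]
}

# --- flat parameter vector <-> structured parameters -----------------------

pack_params <- function(params) {
  c(unlist(params$W, use.names = FALSE), unlist(params$b, use.names = FALSE))
}

unpack_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template$W)) {
    k <- length(template$W[[l]])
    out$W[[l]] <- matrix(vec[pos + seq_len(k)], nrow = nrow(template$W[[l]]))
    pos <- pos + k
  }
  for (l in seq_along(template$b)) {
    k <- length(template$b[[l]])
    out$b[[l]] <- vec[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}

pack_gradient <- function(grad) {
  c(unlist(grad$W, use.names = FALSE), unlist(grad$b, use.names = FALSE))
}

# Hard 0/1 classification at the symmetric decision threshold.
classify <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}
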