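# JSON model envelope: diff-able, language-neutral, full numeric precision.
# Matrices are stored as {dim, values} with column-major values so the
# round trip is exact and shape-unambiguous.

mat_to_json <- function(m) {
  list(dim = as.integer(dim(m)), values = as.numeric(m))
}

mat_from_json <- function(obj) {
  matrix(as.numeric(unlist(obj$values)), nrow = obj$dim[[1]],
         ncol = obj$dim[[2]])
}

scaler_to_json <- function(scaler) {
  if (is.null(scaler)) return(NULL)
  list(location = as.numeric(scaler$location),
       scale = as.numeric(scaler$scale),
       features = names(scaler$location))
}

scaler_from_json <- function(obj) {
  if (is.null(obj)) return(NULL)
  loc <- as.numeric(unlist(obj$location))
  sc <- as.numeric(unlist(obj$scale))
  names(loc) <- names(sc) <- unlist(obj$features)
  structure(list(location = loc, scale = sc), class = "feature_scaler")
}

#' Save a trained model to JSON
#'
#' Serializes a network (`nn_parameters`) or logistic model (`lr_model`)
#' together with its input scaler, the 0.5 decision threshold and metadata
#' (seed, creation time, package version).  Numeric payloads round-trip at
#' full stored precision: save, load and save again produces identical
#' bytes.
#'
#' @param model `nn_parameters` or `lr_model`.
#' @param path output path (`.json`).
#' @param seed the seed recorded in the metadata (optional).
#' @return the path, invisibly.
#' @export
save_model <- function(model, path, seed = NULL) {
  if (inherits(model, "nn_parameters")) {
    doc <- list(model_type = "nn",
                architecture = as.integer(model$arch),
                n_inputs = as.integer(model$n_inputs),
                weights = lapply(model$W, mat_to_json),
                biases = lapply(model$b, as.numeric),
                scaler = scaler_to_json(model$scaler),
                decision_threshold = 0.5)
  } else if (inherits(model, "lr_model")) {
    doc <- list(model_type = "lr",
                coefficients = as.numeric(model$coefficients),
                coefficient_names = names(model$coefficients),
                intercept = model$intercept,
                separation = model$separation,
                scaler = scaler_to_json(model$scaler),
                decision_threshold = 0.5)
  } else {
    stop("model must be `nn_parameters` or `lr_model`", call. = FALSE)
  }
  doc$metadata <- list(seed = seed,
                       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       software = paste0("rslpnet ",
                                         as.character(utils::packageVersion(
                                           "rslpnet"))))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Validates the architecture constraints on load (a stored network that
#' violates the non-increasing-width or three-layer rule is rejected).
#'
#' @param path path to the model JSON.
#' @return `nn_parameters` or `lr_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$model_type)) {
    stop("not a model document: missing `model_type`", call. = FALSE)
  }
  if (doc$model_type == "nn") {
    arch <- validate_architecture(as.integer(unlist(doc$architecture)))
    params <- structure(
      list(W = lapply(doc$weights, mat_from_json),
           b = lapply(doc$biases, function(v) as.numeric(unlist(v))),
           arch = arch, n_inputs = as.integer(doc$n_inputs),
           scaler = scaler_from_json(doc$scaler)),
      class = "nn_parameters")
    sizes <- layer_sizes(arch, params$n_inputs)
    for (l in seq_along(params$W)) {
      if (!identical(dim(params$W[[l]]), c(sizes[l], sizes[l + 1L])) ||
          length(params$b[[l]]) != sizes[l + 1L]) {
        stop("stored weight shapes are inconsistent with the architecture",
             call. = FALSE)
      }
    }
    attr(params, "metadata") <- doc$metadata
    params
  } else if (doc$model_type == "lr") {
    co <- as.numeric(unlist(doc$coefficients))
    names(co) <- unlist(doc$coefficient_names)
    model <- structure(list(coefficients = co, intercept = doc$intercept,
                            separation = isTRUE(doc$separation),
                            scaler = scaler_from_json(doc$scaler)),
                       class = "lr_model")
    attr(model, "metadata") <- doc$metadata
    model
  } else {
    stop("unknown model_type: ", doc$model_type, call. = FALSE)
  }
}

#' Score a cohort with any saved model
#'
#' Applies the model's own scaler to the raw difference features and
#' returns the (0, 1) classification scores.
#'
#' @param model `nn_parameters` or `lr_model` (with an attached scaler).
#' @param cohort labeled cohort data.frame, or a raw feature matrix.
#' @return numeric scores.
#' @export
model_scores <- function(model, cohort) {
  x <- if (is.data.frame(cohort)) cohort_matrix(cohort) else cohort
  if (inherits(model, "nn_parameters")) {
    if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
    nn_forward(model, x)
  } else if (inherits(model, "lr_model")) {
    lr_score(model, x)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
}
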