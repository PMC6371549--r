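#' Read a labeled difference-feature cohort from CSV
#'
#' Schema: `pair_id`, the 13 difference-feature columns in the order of
#' [difference_feature_names()], and `label` (0 = control, 1 = case).
#'
#' @param path CSV file path.
#' @return data.frame cohort.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  df[c("pair_id", difference_feature_names(), "label")]
}

#' Write a labeled cohort to CSV
#'
#' @param cohort data.frame cohort.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[c("pair_id", difference_feature_names(), "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  need <- c("pair_id", difference_feature_names(), "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$label %in% c(0, 1))) {
    stop("`label` must be 0 (control) or 1 (case)", call. = FALSE)
  }
  x <- as.matrix(df[difference_feature_names()])
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  invisible(df)
}

# Feature matrix (n x 13) of a cohort data.frame.
cohort_matrix <- function(cohort) {
  as.matrix(cohort[difference_feature_names()])
}

#' Stratified, seeded partition of a cohort into learning/testing and
#' training/validation parts
#'
#' The cohort is first split into a learning and a testing dataset
#' (`learning_fraction` of each class to learning), then the learning part
#' is split into training and validation datasets (`validation_fraction` of
#' the learning part to validation).  With `stratified = TRUE` (default)
#' the split is performed per class, so per-class counts match the exact
#' fractional counts to within rounding; per-class part sizes are rounded
#' to the nearest integer and the remainder goes to the larger part.
#'
#' @param cohort data.frame cohort (see [read_cohort()]).
#' @param learning_fraction fraction of samples assigned to the learning
#'   dataset (default 0.5, the equal random split used for clinical serial
#'   ECG databases).
#' @param validation_fraction fraction of the *learning* dataset held out
#'   for validation-based early stopping (default 0.2).
#' @param stratified split per class (default TRUE).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list of class `cohort_split` with data.frames `training`,
#'   `validation`, `testing`.
#' @export
split_cohort <- function(cohort, learning_fraction = 0.5,
                         validation_fraction = 0.2, stratified = TRUE,
                         seed = 1L) {
  validate_cohort(cohort)
  stopifnot(learning_fraction > 0, learning_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  n_case <- sum(cohort$label == 1)
  n_ctrl <- sum(cohort$label == 0)
  if (n_case < 2 || n_ctrl < 2) {
    stop("need at least 2 cases and 2 controls to split", call. = FALSE)
  }
  idx_learn <- with_seed(child_seed(seed, "split-learning"),
                         draw_part(cohort$label, learning_fraction,
                                   stratified))
  learning <- cohort[idx_learn, , drop = FALSE]
  testing <- cohort[-idx_learn, , drop = FALSE]
  idx_val <- with_seed(child_seed(seed, "split-validation"),
                       draw_part(learning$label, validation_fraction,
                                 stratified))
  out <- list(training = learning[-idx_val, , drop = FALSE],
              validation = learning[idx_val, , drop = FALSE],
              testing = testing)
  for (part in names(out)) {
    if (!all(c(0, 1) %in% out[[part]]$label)) {
      stop("split produced a ", part,
           " set without both classes; use more samples or other fractions",
           call. = FALSE)
    }
  }
  structure(out, class = "cohort_split")
}

# Indices of the selected part: `fraction` of each class (stratified) or of
# the whole (not).  Nearest-integer rounding; sizes are clamped so both
# parts keep at least one sample per stratum.
draw_part <- function(labels, fraction, stratified) {
  pick <- function(idx) {
    k <- round(length(idx) * fraction)
    k <- min(length(idx) - 1L, max(1L, k))
    if (k < 1L) {
      stop("a stratum is too small to split; need >= 2 samples per class",
           call. = FALSE)
    }
    sort(sample(idx, k))
  }
  if (stratified) {
    sort(c(pick(which(labels == 1)), pick(which(labels == 0))))
  } else {
    pick(seq_along(labels))
  }
}

#' Inverse-prevalence class weights
#'
#' Each class is weighted by the inverse of its prevalence in the dataset,
#' so that the total weighted mass contributed by cases equals that of
#' controls (each equals the sample size N); this compensates the typical
#' clinical disproportion between controls and cases in the error function.
#'
#' @param labels 0/1 label vector.
#' @return list with `w_case`, `w_control`, and `n` (total count).
#' @examples
#' class_weights(c(rep(1, 24), rep(0, 40)))  # w_case = 64/24, w_control = 1.6
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  n_case <- sum(labels == 1)
  n_ctrl <- sum(labels == 0)
  if (n_case == 0 || n_ctrl == 0) {
    stop("both classes must be present to compute inverse-prevalence weights",
         call. = FALSE)
  }
  list(w_case = n / n_case, w_control = n / n_ctrl, n = n)
}

# Per-sample weight vector for a 0/1 label vector.
sample_weights <- function(labels, w) {
  ifelse(labels == 1, w$w_case, w$w_control)
}

#' Fit a per-feature standardizing scaler on a training set
#'
#' Location = training mean, scale = training population standard deviation
#' (denominator n).  Constant features get scale 1 with a warning.  The
#' difference features span several orders of magnitude (microvolt
#' amplitudes vs percent units); with initial network weights in [-1, 1]
#' and sigmoid units, unscaled inputs would saturate the first layer, so
#' every model stores its scaler and applies it at inference.
#'
#' @param x numeric matrix (n x 13) of training-set features, or a cohort
#'   data.frame.
#' @return object of class `feature_scaler` with `location` and `scale`.
#' @export
fit_scaler <- function(x) {
  if (is.data.frame(x)) x <- cohort_matrix(x)
  stopifnot(is.matrix(x), nrow(x) >= 1)
  location <- colMeans(x)
  n <- nrow(x)
  sc <- sqrt(colMeans(sweep(x, 2, location)^2))
  if (any(sc == 0)) {
    warning("zero-variance feature(s): ",
            paste(colnames(x)[sc == 0], collapse = ", "),
            "; scale forced to 1", call. = FALSE)
    sc[sc == 0] <- 1
  }
  structure(list(location = location, scale = sc), class = "feature_scaler")
}

#' Apply (or invert) a fitted scaler
#'
#' @param scaler a `feature_scaler`.
#' @param x numeric matrix or vector of raw features.
#' @param invert if TRUE, map scaled values back to the original units.
#' @return matrix (or vector) of the same shape.
#' @export
apply_scaler <- function(scaler, x, invert = FALSE) {
  stopifnot(inherits(scaler, "feature_scaler"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(scaler$location)) {
    stop("feature dimensionality does not match the scaler", call. = FALSE)
  }
  out <- if (invert) {
    sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$location, "+")
  } else {
    sweep(sweep(x, 2, scaler$location), 2, scaler$scale, "/")
  }
  if (vec) out[1, ] else out
}
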