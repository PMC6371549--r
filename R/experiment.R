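#' Run the full comparison experiment on one labeled cohort
#'
#' Reproduces the complete study design on a cohort: split into
#' learning/testing and training/validation parts, standardize features on
#' the training set, construct the network by the multi-restart
#' constructive procedure, train the fixed-architecture comparator on the
#' final architecture, fit the weighted logistic regression, and evaluate
#' all three on the learning and testing datasets (AUC, DeLong 95% CI,
#' accuracy at equal sensitivity/specificity) with paired DeLong
#' comparisons on the testing scores.  Fully reproducible given the seed.
#'
#' @param cohort labeled cohort data.frame, or a path to a cohort CSV.
#' @param config an [rslp_config()].
#' @param learning_fraction,validation_fraction split fractions (defaults
#'   0.5 and 0.2).
#' @param seed master integer seed.
#' @param verbose narrate progress.
#' @return list of class `rslp_experiment`: `models` (the three fitted
#'   models, each carrying the training-set scaler), `performance`
#'   (data.frame: model x dataset with auc, ci, acc), `comparisons`
#'   (paired DeLong p-values on the testing set), `split`, `seed`, and the
#'   constructive `report`.
#' @export
run_experiment <- function(cohort, config = rslp_config(),
                           learning_fraction = 0.5,
                           validation_fraction = 0.2, seed = 1L,
                           verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  split <- split_cohort(cohort, learning_fraction, validation_fraction,
                        stratified = TRUE,
                        seed = child_seed(seed, "split"))
  scaler <- fit_scaler(split$training)
  x_tr <- apply_scaler(scaler, cohort_matrix(split$training))
  x_val <- apply_scaler(scaler, cohort_matrix(split$validation))
  y_tr <- split$training$label
  y_val <- split$validation$label

  opt <- rslp_optimize(x_tr, y_tr, x_val, y_val, config,
                       seed = child_seed(seed, "rslp"), verbose = verbose)
  nn_rslp <- opt$params
  nn_rslp$scaler <- scaler

  sm <- train_standard_nn(nn_rslp$arch, x_tr, y_tr, x_val, y_val,
                          config = config$training,
                          seed = child_seed(seed, "standard"))
  nn_sm <- sm$params
  nn_sm$scaler <- scaler

  x_learn <- rbind(x_tr, x_val)
  y_learn <- c(y_tr, y_val)
  lr <- train_weighted_lr(x_learn, y_learn)
  lr$scaler <- scaler

  models <- list(nn_rslp = nn_rslp, nn_sm = nn_sm, lr = lr)
  datasets <- list(
    learning = rbind(split$training, split$validation),
    testing = split$testing)
  perf <- do.call(rbind, lapply(names(models), function(m) {
    do.call(rbind, lapply(names(datasets), function(d) {
      s <- model_scores(models[[m]], datasets[[d]])
      y <- datasets[[d]]$label
      ci <- auc_ci_delong(s, y)
      data.frame(model = m, dataset = d, auc = roc_auc(s, y),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 acc_eq = acc_equal_sens_spec(s, y),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(perf) <- NULL

  y_test <- datasets$testing$label
  s_rslp <- model_scores(nn_rslp, datasets$testing)
  s_sm <- model_scores(nn_sm, datasets$testing)
  s_lr <- model_scores(lr, datasets$testing)
  comparisons <- data.frame(
    comparison = c("nn_rslp_vs_nn_sm", "nn_rslp_vs_lr"),
    p = c(delong_test(s_rslp, s_sm, y_test)$p,
          delong_test(s_rslp, s_lr, y_test)$p),
    stringsAsFactors = FALSE)

  structure(list(models = models, performance = perf,
                 comparisons = comparisons, split = split,
                 report = opt$report, alternative = opt$alternative,
                 history = opt$run$history, seed = seed),
            class = "rslp_experiment")
}

#' Write an experiment report to JSON
#'
#' Performance table, paired comparisons, selected architecture, growth
#' summary and the seed, as a single diff-able JSON document.
#'
#' @param experiment an `rslp_experiment`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_experiment_report <- function(experiment, path) {
  stopifnot(inherits(experiment, "rslp_experiment"))
  doc <- list(
    architecture = as.integer(experiment$models$nn_rslp$arch),
    performance = experiment$performance,
    comparisons = experiment$comparisons,
    alternatives = experiment$report,
    stop_criterion = experiment$history$stop_criterion,
    total_iterations = experiment$history$total_iterations,
    seed = experiment$seed,
    software = paste0("rslpnet ",
                      as.character(utils::packageVersion("rslpnet"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, dataframe = "rows"), path)
  invisible(path)
}

#' @export
print.rslp_experiment <- function(x, ...) {
  cat("Constructive serial-ECG classification experiment\n")
  cat("  final architecture: [",
      paste(x$models$nn_rslp$arch, collapse = " "), "]\n", sep = "")
  cat("  stop criterion:", x$history$stop_criterion, "\n")
  cat("  performance:\n")
  perf <- x$performance
  perf$auc <- sprintf("%.3f", perf$auc)
  perf$ci <- sprintf("[%.3f, %.3f]", perf$ci_low, perf$ci_high)
  perf$acc_eq <- sprintf("%.3f", perf$acc_eq)
  print(perf[c("model", "dataset", "auc", "ci", "acc_eq")],
        row.names = FALSE)
  cat("  paired DeLong (testing): ",
      paste(sprintf("%s p=%.3g", x$comparisons$comparison,
                    x$comparisons$p), collapse = "; "), "\n", sep = "")
  invisible(x)
}
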