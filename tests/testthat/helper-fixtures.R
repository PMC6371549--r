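# Shared fixtures built in code.

# A plausible per-ECG feature record; override any field.
make_ecg <- function(...) {
  args <- list(qrs_dur = 100, qt = 400, qrs_max = 1500, t_max = 500,
               qrs_intg = 50, t_intg = 60, qrs_cmplx = 2, t_cmplx = 3,
               vg = c(30, 40, 0), sa = 60, hr = 70, j = c(20, 10, 5),
               t_sym = 40)
  args[names(list(...))] <- list(...)
  do.call(ecg_features, args)
}

# Scaled training/validation/testing matrices from a cohort.
prepare_split <- function(cohort, seed = 1L) {
  sp <- split_cohort(cohort, 0.5, 0.2, seed = seed)
  sc <- fit_scaler(sp$training)
  xm <- function(part) apply_scaler(sc, as.matrix(part[difference_feature_names()]))
  list(x_train = xm(sp$training), y_train = sp$training$label,
       x_val = xm(sp$validation), y_val = sp$validation$label,
       x_test = xm(sp$testing), y_test = sp$testing$label,
       scaler = sc, split = sp)
}

# Brute-force pairwise AUC oracle (independent of the rank-based code path).
auc_bruteforce <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Central finite-difference gradient of the weighted error.
fd_gradient <- function(params, x, y, w, h = 1e-6) {
  wv <- rslpnet:::pack_params(params)
  f <- function(v) {
    weighted_error(nn_forward(rslpnet:::unpack_params(v, params), x), y, w)
  }
  vapply(seq_along(wv), function(i) {
    e <- rep(0, length(wv)); e[i] <- h
    (f(wv + e) - f(wv - e)) / (2 * h)
  }, numeric(1))
}
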