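#' Reference per-feature quartiles of the two clinical serial-ECG cohorts
#'
#' The bundled table of per-feature, per-class 25th/50th/75th percentiles of
#' the 13 difference features in the heart-failure (`"hfdb"`) and ischemia
#' (`"idb"`) serial-ECG populations.  These marginal quartiles, together
#' with the printed case/control counts, are all that is published about
#' the feature distributions; the generator emulates cohorts by matching
#' them exactly (see [fit_quantile_model()]).
#'
#' @param dataset `"hfdb"` or `"idb"`.
#' @param class `"case"`, `"control"` or `"total"`.
#' @return data.frame with `feature`, `q1`, `median`, `q3` in the canonical
#'   feature order.
#' @export
feature_quartiles <- function(dataset = c("hfdb", "idb"),
                              class = c("case", "control", "total")) {
  dataset <- match.arg(dataset)
  class <- match.arg(class)
  path <- system.file("extdata", "reference_quartiles.csv",
                      package = "rslpnet", mustWork = TRUE)
  q <- utils::read.csv(path, stringsAsFactors = FALSE)
  q <- q[q$dataset == dataset & q$class == class, ]
  q <- q[match(difference_feature_names(), q$feature), ]
  rownames(q) <- NULL
  q[c("feature", "q1", "median", "q3")]
}

#' Fit a piecewise-linear quantile model to three quartiles
#'
#' Builds an inverse CDF that passes exactly through (0.25, q1),
#' (0.5, median) and (0.75, q3), linear between the knots.  The tails
#' continue the adjacent inter-quartile segment's slope, scaled by
#' `tail_factor`, anchored at p = 0.25 and p = 0.75; draw probabilities are
#' clamped to [0.001, 0.999] so the support stays bounded.  With q1 = q3
#' the model degenerates to a constant.
#'
#' @param q1,median,q3 the quartiles to match (must be non-decreasing).
#' @param tail_factor positive multiplier on the tail slopes (default 1:
#'   tails continue the quartile-segment slopes).
#' @return function mapping probabilities in \[0, 1\] to quantiles.
#' @examples
#' qm <- fit_quantile_model(-1, 0, 1)
#' qm(c(0.25, 0.375, 0.5, 0.75))  # -1, -0.5, 0, 1
#' @export
fit_quantile_model <- function(q1, median, q3, tail_factor = 1) {
  if (!(q1 <= median && median <= q3)) {
    stop("quartiles must satisfy q1 <= median <= q3", call. = FALSE)
  }
  stopifnot(tail_factor > 0)
  s_lo <- (median - q1) / 0.25 * tail_factor
  s_hi <- (q3 - median) / 0.25 * tail_factor
  function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    p <- pmin(pmax(p, 0.001), 0.999)
    ifelse(p < 0.25, q1 + (p - 0.25) * s_lo,
           ifelse(p <= 0.5, q1 + (p - 0.25) / 0.25 * (median - q1),
                  ifelse(p <= 0.75, median + (p - 0.5) / 0.25 * (q3 - median),
                         q3 + (p - 0.75) * s_hi)))
  }
}

# Upper clip bounds for physically bounded features (spatial-angle
# difference cannot exceed 180 degrees); magnitude features are clipped at 0.
FEATURE_UPPER_CLIP <- c(mag_d_sa_deg = 180)

#' Generate a labeled cohort matching reference quartiles
#'
#' Draws each of the 13 difference features independently from the
#' class-specific piecewise-linear quantile model fitted to the reference
#' quartiles of the chosen population.  Only marginal quartiles are
#' published, so no inter-feature correlation is imposed.  Physically
#' non-negative features (the ventricular-gradient, spatial-angle and
#' J-vector difference magnitudes) are clipped at 0 (and the angle at 180);
#' clip rates above 5% trigger a warning.
#'
#' @param spec `"hfdb"` or `"idb"`, or a data.frame of per-class quartiles
#'   with columns `class`, `feature`, `q1`, `median`, `q3`.
#' @param n_cases,n_controls class sizes; defaults are the full printed
#'   database counts (HFDB 47/81, IDB 84/398).
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param tail_factor tail-slope multiplier of the quantile models.
#' @return labeled cohort data.frame (see [read_cohort()] for the schema).
#' @export
sample_cohort <- function(spec = c("hfdb", "idb"), n_cases = NULL,
                          n_controls = NULL, seed = 1L, tail_factor = 1) {
  if (is.character(spec)) {
    spec <- match.arg(spec)
    defaults <- list(hfdb = c(cases = 47L, controls = 81L),
                     idb = c(cases = 84L, controls = 398L))[[spec]]
    if (is.null(n_cases)) n_cases <- defaults[["cases"]]
    if (is.null(n_controls)) n_controls <- defaults[["controls"]]
    quart <- rbind(cbind(class = "case", feature_quartiles(spec, "case")),
                   cbind(class = "control",
                         feature_quartiles(spec, "control")))
  } else {
    quart <- spec
    if (is.null(n_cases) || is.null(n_controls)) {
      stop("n_cases and n_controls are required with a custom quartile spec",
           call. = FALSE)
    }
  }
  stopifnot(n_cases >= 1, n_controls >= 1)
  feats <- difference_feature_names()
  draw_class <- function(cls, n, stream) {
    with_seed(child_seed(seed, stream), {
      cols <- lapply(feats, function(f) {
        row <- quart[quart$class == cls & quart$feature == f, ]
        if (nrow(row) != 1L) {
          stop("quartile spec must have exactly one row per class/feature",
               call. = FALSE)
        }
        qm <- fit_quantile_model(row$q1, row$median, row$q3, tail_factor)
        qm(stats::runif(n))
      })
      names(cols) <- feats
      as.data.frame(cols)
    })
  }
  x_case <- draw_class("case", n_cases, "generator-cases")
  x_ctrl <- draw_class("control", n_controls, "generator-controls")
  out <- rbind(x_case, x_ctrl)
  label <- c(rep(1L, n_cases), rep(0L, n_controls))
  # clip physically bounded features and report heavy clipping
  n_clipped <- 0L
  for (idx in MAGNITUDE_FEATURES) {
    f <- feats[idx]
    lo <- out[[f]] < 0
    n_clipped <- n_clipped + sum(lo)
    out[[f]][lo] <- 0
    if (f %in% names(FEATURE_UPPER_CLIP)) {
      hi <- out[[f]] > FEATURE_UPPER_CLIP[[f]]
      n_clipped <- n_clipped + sum(hi)
      out[[f]][hi] <- FEATURE_UPPER_CLIP[[f]]
    }
  }
  clip_rate <- n_clipped / (nrow(out) * length(MAGNITUDE_FEATURES))
  if (clip_rate > 0.05) {
    warning(sprintf("%.1f%% of magnitude-feature draws were clipped; ",
                    100 * clip_rate),
            "check the quartile spec or tail_factor", call. = FALSE)
  }
  cbind(data.frame(pair_id = sprintf("pair_%04d", seq_len(nrow(out)))),
        out, data.frame(label = label))
}

#' Parametric toy cohorts for exercising the training algorithms
#'
#' Three synthetic 13-feature families with known structure:
#' \describe{
#'   \item{`separable`}{cases and controls offset by +2/-2 noise-SD units
#'     along features 1 and 9; the noise on these two signal features is
#'     truncated at 1.5 SD so the classes are linearly separable by
#'     construction, with a guaranteed margin (any sensible classifier can
#'     reach perfect discrimination).}
#'   \item{`xor2d`}{class is the exclusive-or of the signs of features 1
#'     and 10, so no linear discriminant works, but a small network does.}
#'   \item{`null`}{identical distributions in both classes; any scorer has
#'     expected AUC 0.5.}
#' }
#' All other features carry pure noise.  These cohorts are abstract
#' covariate patterns for algorithm testing; they deliberately ignore the
#' sign conventions of the physiologic magnitude features.
#'
#' @param family `"separable"`, `"xor2d"` or `"null"`.
#' @param n_cases,n_controls class sizes.
#' @param noise_sd standard deviation of the feature noise (default 1).
#' @param seed integer seed.
#' @return labeled cohort data.frame in the standard schema.
#' @export
make_toy_cohort <- function(family = c("separable", "xor2d", "null"),
                            n_cases = 100L, n_controls = 100L,
                            noise_sd = 1, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_cases >= 1, n_controls >= 1, noise_sd > 0)
  n <- n_cases + n_controls
  feats <- difference_feature_names()
  with_seed(child_seed(seed, paste0("toy-", family)), {
    x <- matrix(stats::rnorm(n * 13L, sd = noise_sd), nrow = n)
    colnames(x) <- feats
    label <- c(rep(1L, n_cases), rep(0L, n_controls))
    if (family == "separable") {
      shift <- ifelse(label == 1, 2 * noise_sd, -2 * noise_sd)
      # truncated noise on the signal features guarantees a margin
      trunc_noise <- function(n) {
        noise_sd * stats::qnorm(stats::runif(n, stats::pnorm(-1.5),
                                             stats::pnorm(1.5)))
      }
      x[, 1L] <- trunc_noise(n) + shift
      x[, 9L] <- trunc_noise(n) + shift
    } else if (family == "xor2d") {
      # place the two signal features in the quadrants dictated by the label
      s1 <- sample(c(-1, 1), n, replace = TRUE)
      s2 <- ifelse(xor(s1 > 0, label == 1), 1, -1)
      x[, 1L] <- s1 * (abs(x[, 1L]) + noise_sd)
      x[, 10L] <- s2 * (abs(x[, 10L]) + noise_sd)
    }
    cbind(data.frame(pair_id = sprintf("pair_%04d", seq_len(n))),
          as.data.frame(x), data.frame(label = label))
  })
}
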