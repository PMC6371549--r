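#' Names of the 13 serial difference features
#'
#' The canonical (fixed) ordering of the difference features computed from a
#' baseline/follow-up ECG pair: QRS duration, QT interval, maximal QRS- and
#' T-vector magnitudes, QRS- and T-integral vector magnitudes, QRS and
#' T-wave complexity, magnitude of the ventricular-gradient difference
#' vector, magnitude of the QRS-T spatial-angle difference, heart rate,
#' magnitude of the J-vector difference vector, and T-wave symmetry.
#' Features 9, 10 and 12 are difference-vector (or absolute) magnitudes and
#' therefore non-negative; pathological "pseudo-normalization" (a change
#' back toward normal values) would otherwise cancel in a signed difference.
#'
#' @return character vector of length 13, in the canonical order.
#' @export
difference_feature_names <- function() {
  c("d_qrs_dur_ms", "d_qt_ms", "d_qrs_max_uv", "d_t_max_uv",
    "d_qrs_intg_mvms", "d_t_intg_mvms", "d_qrs_cmplx_pct", "d_t_cmplx_pct",
    "mag_d_vg_mvms", "mag_d_sa_deg", "d_hr_bpm", "mag_d_j_uv",
    "d_t_sym_pct")
}

# indices of the magnitude-valued (non-negative) difference features
MAGNITUDE_FEATURES <- c(9L, 10L, 12L)

#' Construct a per-ECG vectorcardiographic feature set
#'
#' Holds the 13 features measured on one averaged-beat vectorcardiogram
#' (VCG): scalar durations, amplitudes, integral magnitudes, complexity and
#' symmetry percentages, heart rate, the QRS-T spatial angle, and the full
#' 3-D ventricular-gradient and J vectors.  VG and J are stored as vectors
#' (not magnitudes) because serial comparison needs the magnitude of their
#' *difference vector*; the spatial angle is a scalar in [0, 180] degrees,
#' so its serial difference is a plain absolute difference.
#'
#' @param qrs_dur QRS duration, ms (> 0).
#' @param qt QT interval, ms (> 0).
#' @param qrs_max maximal QRS-vector magnitude, uV (>= 0).
#' @param t_max maximal T-vector magnitude, uV (>= 0).
#' @param qrs_intg QRS-integral vector magnitude, mV·ms (>= 0).
#' @param t_intg T-integral vector magnitude, mV·ms (>= 0).
#' @param qrs_cmplx QRS complexity, percent.
#' @param t_cmplx T-wave complexity, percent.
#' @param vg ventricular-gradient vector, length-3 numeric, mV·ms.
#' @param sa QRS-T spatial angle, degrees in [0, 180].
#' @param hr heart rate, bpm (> 0).
#' @param j J-point vector, length-3 numeric, uV.
#' @param t_sym T-wave symmetry, percent.
#' @return an object of class `ecg_features`.
#' @export
ecg_features <- function(qrs_dur, qt, qrs_max, t_max, qrs_intg, t_intg,
                         qrs_cmplx, t_cmplx, vg, sa, hr, j, t_sym) {
  if (length(vg) != 3L || length(j) != 3L) {
    stop("`vg` and `j` must be 3-component vectors", call. = FALSE)
  }
  scalars <- c(qrs_dur = qrs_dur, qt = qt, qrs_max = qrs_max, t_max = t_max,
               qrs_intg = qrs_intg, t_intg = t_intg, qrs_cmplx = qrs_cmplx,
               t_cmplx = t_cmplx, sa = sa, hr = hr, t_sym = t_sym)
  if (!all(is.finite(c(scalars, vg, j)))) {
    stop("all ECG features must be finite", call. = FALSE)
  }
  if (qrs_dur <= 0 || qt <= 0 || hr <= 0) {
    stop("qrs_dur, qt and hr must be positive", call. = FALSE)
  }
  if (any(c(qrs_max, t_max, qrs_intg, t_intg) < 0)) {
    stop("magnitude features must be non-negative", call. = FALSE)
  }
  if (sa < 0 || sa > 180) {
    stop("spatial angle must lie in [0, 180] degrees", call. = FALSE)
  }
  structure(list(qrs_dur = qrs_dur, qt = qt, qrs_max = qrs_max,
                 t_max = t_max, qrs_intg = qrs_intg, t_intg = t_intg,
                 qrs_cmplx = qrs_cmplx, t_cmplx = t_cmplx,
                 vg = as.numeric(vg), sa = sa, hr = hr, j = as.numeric(j),
                 t_sym = t_sym),
            class = "ecg_features")
}

#' Compute the 13 serial difference features for one ECG pair
#'
#' Subtracts the baseline-ECG features from the follow-up-ECG features.
#' Ten features are signed scalar differences (follow-up minus baseline);
#' the ventricular-gradient and J-vector features are the Euclidean norms of
#' the 3-D difference vectors, and the spatial-angle feature is the absolute
#' scalar angle difference — the magnitudes guard against
#' pseudo-normalization, where a pathological change moves a feature back
#' toward normal values and a signed difference would understate it.
#'
#' @param bl baseline `ecg_features`.
#' @param fu follow-up `ecg_features`.
#' @return named numeric vector of length 13 in the canonical order of
#'   [difference_feature_names()].
#' @examples
#' bl <- ecg_features(100, 400, 1500, 500, 50, 60, 2, 3,
#'                    vg = c(1, 0, 0), sa = 144, hr = 70, j = c(10, 0, 0),
#'                    t_sym = 40)
#' fu <- ecg_features(100, 400, 1500, 500, 50, 60, 2, 3,
#'                    vg = c(0, 1, 0), sa = 100, hr = 70, j = c(10, 0, 0),
#'                    t_sym = 40)
#' compute_difference_features(bl, fu)
#' @export
compute_difference_features <- function(bl, fu) {
  stopifnot(inherits(bl, "ecg_features"), inherits(fu, "ecg_features"))
  out <- c(fu$qrs_dur - bl$qrs_dur,
           fu$qt - bl$qt,
           fu$qrs_max - bl$qrs_max,
           fu$t_max - bl$t_max,
           fu$qrs_intg - bl$qrs_intg,
           fu$t_intg - bl$t_intg,
           fu$qrs_cmplx - bl$qrs_cmplx,
           fu$t_cmplx - bl$t_cmplx,
           sqrt(sum((fu$vg - bl$vg)^2)),
           abs(fu$sa - bl$sa),
           fu$hr - bl$hr,
           sqrt(sum((fu$j - bl$j)^2)),
           fu$t_sym - bl$t_sym)
  names(out) <- difference_feature_names()
  out
}

#' Read per-ECG VCG feature records from CSV
#'
#' One row per ECG with columns `ecg_id, qrs_dur_ms, qt_ms, qrs_max_uv,
#' t_max_uv, qrs_intg_mvms, t_intg_mvms, qrs_cmplx_pct, t_cmplx_pct,
#' vg_x_mvms, vg_y_mvms, vg_z_mvms, sa_deg, hr_bpm, j_x_uv, j_y_uv, j_z_uv,
#' t_sym_pct`.
#'
#' @param path CSV file path.
#' @return data.frame with one row per ECG.
#' @export
read_ecg_features <- function(path) {
  cols <- c("ecg_id", "qrs_dur_ms", "qt_ms", "qrs_max_uv", "t_max_uv",
            "qrs_intg_mvms", "t_intg_mvms", "qrs_cmplx_pct", "t_cmplx_pct",
            "vg_x_mvms", "vg_y_mvms", "vg_z_mvms", "sa_deg", "hr_bpm",
            "j_x_uv", "j_y_uv", "j_z_uv", "t_sym_pct")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("ECG feature CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[cols]
}

# Turn one row of a per-ECG feature table into an ecg_features object.
row_to_ecg_features <- function(row) {
  ecg_features(qrs_dur = row$qrs_dur_ms, qt = row$qt_ms,
               qrs_max = row$qrs_max_uv, t_max = row$t_max_uv,
               qrs_intg = row$qrs_intg_mvms, t_intg = row$t_intg_mvms,
               qrs_cmplx = row$qrs_cmplx_pct, t_cmplx = row$t_cmplx_pct,
               vg = c(row$vg_x_mvms, row$vg_y_mvms, row$vg_z_mvms),
               sa = row$sa_deg, hr = row$hr_bpm,
               j = c(row$j_x_uv, row$j_y_uv, row$j_z_uv),
               t_sym = row$t_sym_pct)
}

#' Compute difference features for a table of baseline/follow-up ECG pairs
#'
#' @param bl,fu data.frames in the [read_ecg_features()] schema, matched by
#'   `ecg_id` position (row i of `bl` pairs with row i of `fu`).
#' @param pair_id optional identifiers for the resulting pairs; defaults to
#'   the baseline `ecg_id`.
#' @return data.frame with `pair_id` and the 13 difference-feature columns.
#' @export
compute_difference_table <- function(bl, fu, pair_id = NULL) {
  if (nrow(bl) != nrow(fu)) {
    stop("baseline and follow-up tables must have the same number of rows",
         call. = FALSE)
  }
  if (is.null(pair_id)) pair_id <- bl$ecg_id
  rows <- lapply(seq_len(nrow(bl)), function(i) {
    compute_difference_features(row_to_ecg_features(bl[i, ]),
                                row_to_ecg_features(fu[i, ]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(pair_id = pair_id, stringsAsFactors = FALSE), out)
}
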