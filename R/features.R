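# Subject-level feature extraction: eight sample quantiles of each beat
# variable's distribution (144 numeric features) plus T-wave-type
# proportions, assembled into the classification feature matrix.

#' Sample quantile by linear interpolation of order statistics
#'
#' The order-statistic quantile with linear interpolation between closest
#' ranks: on the sorted vector, position `h = (n - 1) * p / 100 + 1`,
#' interpolating linearly between `floor(h)` and `ceiling(h)` (the common
#' "type 7" convention). Quantiles of the beat distributions are used
#' instead of means because diseased subjects' distributions are typically
#' skewed, heavy-tailed or multimodal -- differences that live in the tails.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param p Percentile(s) in (0, 100).
#' @return Quantile value(s); `NA` if no finite values remain.
#' @examples
#' sample_quantile(1:100, 25)   # 25.75
#' sample_quantile(c(1, 2), 50) # 1.5
#' @export
sample_quantile <- function(values, p) {
  if (any(p <= 0 | p >= 100)) stop_ecg("percentiles must lie in (0, 100)")
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (n == 0) return(rep(NA_real_, length(p)))
  if (n == 1) return(rep(x, length(p)))
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# display names of the 144 quantile features, e.g. "QT-int_p95"
quantile_feature_names <- function() {
  as.vector(t(outer(feature_display_names[c(span_vars, amp_vars, slope_vars)],
                    feature_percentiles,
                    function(v, p) paste0(v, "_p", p))))
}

ttype_feature_names <- function() paste0("Ttype_", ttype_levels)

#' Summarize one subject's beats into a feature vector
#'
#' Pools the subject's beats (across records) and computes, for each of the
#' 18 numeric measurement variables, the eight [sample_quantile()]s at
#' [feature_percentiles] -- 144 features -- plus the proportions of the six
#' T-wave types and the modal type. Each variable uses its own non-missing
#' beats. Subjects with fewer than `min_beats` usable beats are flagged
#' rather than summarized.
#'
#' @param beats Beat-table rows of one subject (RR-corrected).
#' @param min_beats Minimum number of beats required.
#' @param stat `"quantile"` for the 144 quantile features or `"mean"` for
#'   the 18 per-variable beat means (the comparison arm).
#' @return A `feature_vector`: list with `subject_id`, `label`, `features`
#'   (named numeric), `ttype_props`, `ttype_mode`, `n_beats`, and
#'   `flagged` (`TRUE` with a `flag_reason` when the subject is unusable).
#' @export
summarize_subject <- function(beats, min_beats = 30, stat = "quantile") {
  stat <- match.arg(stat, c("quantile", "mean"))
  out <- list(subject_id = beats$subject_id[1], label = beats$label[1],
              n_beats = nrow(beats), flagged = FALSE, flag_reason = NA)
  if (nrow(beats) < min_beats) {
    out$flagged <- TRUE
    out$flag_reason <- sprintf("only %d beats (min %d)", nrow(beats), min_beats)
    return(structure(out, class = "feature_vector"))
  }
  vars <- c(span_vars, amp_vars, slope_vars)
  if (stat == "quantile") {
    feats <- unlist(lapply(vars, function(v)
      stats::setNames(sample_quantile(beats[[v]], feature_percentiles),
                      paste0(feature_display_names[[v]], "_p",
                             feature_percentiles))))
  } else {
    feats <- stats::setNames(
      vapply(vars, function(v) mean(beats[[v]], na.rm = TRUE), 0),
      paste0(feature_display_names[vars], "_mean"))
    feats[is.nan(feats)] <- NA_real_
  }
  tt <- factor(beats$T_type, levels = ttype_levels)
  props <- as.vector(table(tt)) / max(1, sum(!is.na(tt)))
  out$features <- feats
  out$ttype_props <- stats::setNames(props, ttype_feature_names())
  out$ttype_mode <- ttype_levels[which.max(props)]
  structure(out, class = "feature_vector")
}

#' Build the subject-by-feature classification matrix
#'
#' Summarizes every subject of a cohort (or beat table) with
#' [summarize_subject()] and stacks the results: 144 quantile features (or
#' 18 mean features) plus the six T-type proportion columns. Sporadic
#' missing entries are imputed by the column median (an imputation mask is
#' recorded); features missing for every subject are dropped with a
#' warning. The builder itself is deterministic.
#'
#' @param x A `synthetic_cohort` or a beat table data frame.
#' @param stat `"quantile"` or `"mean"` (see [summarize_subject()]).
#' @param min_beats Minimum usable beats per subject.
#' @param impute Impute missing entries by column medians (default `TRUE`;
#'   [classify_cohort()] instead imputes with training-set medians).
#' @return List with `x` (numeric matrix, subjects x features), `y`
#'   (factor healthy/disease), `ttype_cols` (names of the T-type columns,
#'   excluded from PCA), `imputed` (logical mask), `flagged` (data frame
#'   of excluded subjects).
#' @export
build_feature_matrix <- function(x, stat = "quantile", min_beats = 30,
                                 impute = TRUE) {
  beats <- if (inherits(x, "synthetic_cohort")) x$beats else x
  subjects <- split(beats, beats$subject_id)
  fvs <- lapply(subjects, summarize_subject, min_beats = min_beats,
                stat = stat)
  flagged <- do.call(rbind, lapply(fvs[vapply(fvs, `[[`, TRUE, "flagged")],
    function(f) data.frame(subject_id = f$subject_id,
                           reason = f$flag_reason)))
  fvs <- fvs[!vapply(fvs, `[[`, TRUE, "flagged")]
  if (length(fvs) < 2) stop_ecg("fewer than 2 usable subjects")
  mat <- do.call(rbind, lapply(fvs, function(f)
    c(f$features, f$ttype_props)))
  rownames(mat) <- vapply(fvs, `[[`, "", "subject_id")
  y <- factor(vapply(fvs, `[[`, "", "label"),
              levels = c("healthy", "disease"))
  if (nlevels(droplevels(y)) < 2)
    stop_ecg("both classes must be present among usable subjects")
  all_na <- apply(mat, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    warning("dropping features absent for all subjects: ",
            paste(colnames(mat)[all_na], collapse = ", "))
    mat <- mat[, !all_na, drop = FALSE]
  }
  imputed <- is.na(mat)
  if (impute && any(imputed)) {
    med <- apply(mat, 2, median, na.rm = TRUE)
    for (j in which(colSums(imputed) > 0))
      mat[imputed[, j], j] <- med[j]
  }
  list(x = mat, y = y,
       ttype_cols = intersect(ttype_feature_names(), colnames(mat)),
       imputed = imputed,
       flagged = flagged %||%
         data.frame(subject_id = character(0), reason = character(0)))
}
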