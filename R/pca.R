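# Principal-component reduction of the standardized quantile features, with
# top-loading reports used to rank candidate biomarkers.

#' Fit a PCA on standardized features
#'
#' Columns are centered and scaled to unit variance using the training rows
#' (equivalently, PCA of the correlation matrix) -- required because spans
#' (s), amplitudes (mV) and slopes (mV/s) live on different scales.
#' Zero-variance columns are dropped with a warning before scaling. Each
#' loading column is oriented so that its largest-magnitude entry is
#' positive, making signs deterministic. T-wave-type columns are expected
#' to be excluded by the caller (they bypass PCA and rejoin at
#' classification).
#'
#' @param x Numeric matrix, subjects x features (no T-type columns).
#' @return An `ecg_pca` model: `feature_names`, `center`, `scale`,
#'   `loadings` (orthonormal), `sdev`, `explained_ratio`, and
#'   `n_components_kept` (initialized to all; see [select_components()]).
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_ecg("PCA needs at least 2 rows")
  sds <- apply(x, 2, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning("dropping zero-variance features: ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pc$sdev^2
  structure(list(feature_names = colnames(x),
                 center = pc$center, scale = pc$scale,
                 loadings = rot, sdev = pc$sdev,
                 explained_ratio = ev / sum(ev),
                 n_components_kept = ncol(rot)),
            class = "ecg_pca")
}

#' Choose the number of retained components
#'
#' Either a fixed count `k` (default 8, a compact set capturing the bulk of
#' the correlated quantile features) or the smallest number of components
#' whose cumulative explained-variance ratio reaches `threshold`; at least
#' one component is always kept.
#'
#' @param model An `ecg_pca` model.
#' @param k Fixed number of components, or `NULL` to use `threshold`.
#' @param threshold Cumulative explained-variance target in (0, 1].
#' @return The model with `n_components_kept` set.
#' @export
select_components <- function(model, k = 8, threshold = NULL) {
  n_avail <- ncol(model$loadings)
  if (!is.null(threshold)) {
    k <- which(cumsum(model$explained_ratio) >= threshold)[1]
    if (is.na(k)) k <- n_avail
    k <- max(1L, k)
  } else {
    if (k > n_avail)
      stop_ecg("requested ", k, " components but only ", n_avail,
               " are available")
    k <- max(1L, as.integer(k))
  }
  model$n_components_kept <- k
  model
}

#' Top-loading features per component (biomarker report)
#'
#' For each kept component, the `k_vars` features with the largest absolute
#' loading, in decreasing order (ties broken by feature name). Features
#' recurring across components -- and especially those also picked by the
#' stepwise discriminant selection -- are the pipeline's biomarker
#' candidates.
#'
#' @param model An `ecg_pca` model.
#' @param k_vars Number of features to list per component.
#' @return Named list of data frames (`feature`, `loading`).
#' @export
top_loadings <- function(model, k_vars = 5) {
  k <- model$n_components_kept
  lapply(stats::setNames(seq_len(k), paste0("PC", seq_len(k))), function(j) {
    l <- model$loadings[, j]
    ord <- order(-abs(l), names(l))[seq_len(min(k_vars, length(l)))]
    data.frame(feature = names(l)[ord], loading = unname(l[ord]),
               stringsAsFactors = FALSE)
  })
}

#' Project data onto the kept components
#'
#' Standardizes `newdata` with the *training* centers and scales (test rows
#' never update them) and projects onto the kept loadings.
#'
#' @param object An `ecg_pca` model.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return Scores matrix, rows x kept components.
#' @export
predict.ecg_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  z %*% object$loadings[, seq_len(object$n_components_kept), drop = FALSE]
}

#' @export
print.ecg_pca <- function(x, ...) {
  k <- x$n_components_kept
  cat("PCA of", length(x$feature_names), "standardized features;",
      k, "component(s) kept\n")
  cat(sprintf("cumulative explained variance: %.2f%%\n",
              100 * sum(x$explained_ratio[seq_len(k)])))
  invisible(x)
}

#' Format a top-loading report
#'
#' Text report mirroring the usual biomarker table: one line per component
#' with its contribution (% of variance) and top features.
#'
#' @param model An `ecg_pca` model.
#' @param k_vars Features listed per component.
#' @return Character vector of report lines, invisibly printed.
#' @export
pca_report <- function(model, k_vars = 5) {
  tl <- top_loadings(model, k_vars)
  k <- model$n_components_kept
  lines <- c(sprintf("Principal components (total contribution %.2f%%)",
                     100 * sum(model$explained_ratio[seq_len(k)])),
             vapply(seq_len(k), function(j)
               sprintf("PC%d (%.2f%%): %s", j,
                       100 * model$explained_ratio[j],
                       paste(tl[[j]]$feature, collapse = ", ")), ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
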