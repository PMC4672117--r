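# Stepwise discriminant analysis with a generalized squared distance:
# forward selection with backward elimination on the partial F statistic
# derived from Wilks' lambda, Box's M homogeneity test to choose pooled vs
# per-class covariances, and classification by minimal D^2 = Mahalanobis
# distance + log-determinant term (equal priors, so no prior offset).

# Within- and total-group SSCP matrices for the full feature set.
sscp_matrices <- function(x, y) {
  x <- as.matrix(x)
  tot <- crossprod(scale(x, center = TRUE, scale = FALSE))
  within <- Reduce(`+`, lapply(levels(y), function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    crossprod(scale(xc, center = TRUE, scale = FALSE))
  }))
  list(W = within, T = tot)
}

# Wilks' lambda of a variable subset from precomputed SSCP matrices.
wilks_lambda <- function(sscp, vars) {
  if (!length(vars)) return(1)
  dw <- det(sscp$W[vars, vars, drop = FALSE])
  dt <- det(sscp$T[vars, vars, drop = FALSE])
  if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
  max(0, dw / dt)
}

#' Stepwise variable selection for discriminant analysis
#'
#' Forward selection with backward elimination on the partial F statistic
#' derived from Wilks' lambda. With `p` variables already selected and `g`
#' classes, the F-to-enter of a candidate `v` is
#' `F = ((n - g - p) / (g - 1)) * (Lambda(S) / Lambda(S + v) - 1)` on
#' `(g - 1, n - g - p)` degrees of freedom; the F-to-remove of a selected
#' variable is its F-to-enter given the others. At each step the most
#' significant candidate with p-value below `slentry` enters, then any
#' selected variable whose p-value exceeds `slstay` is removed (worst
#' first). Stops when no entry or removal occurs. Deterministic given the
#' data; exactly collinear candidates never enter (their partial F is 0).
#'
#' @param x Numeric feature matrix.
#' @param y Class factor (2 or more levels).
#' @param slentry,slstay Significance levels to enter / to stay, in (0, 1).
#' @param max_vars Cap on the number of selected variables (defaults to
#'   keeping the error degrees of freedom positive).
#' @return Character vector of selected feature names in entry order
#'   (possibly empty, with a warning).
#' @export
stepwise_select <- function(x, y, slentry = 0.15, slstay = 0.15,
                            max_vars = NULL) {
  x <- as.matrix(x); y <- droplevels(as.factor(y))
  g <- nlevels(y); n <- nrow(x)
  if (g < 2) stop_ecg("need at least 2 classes")
  if (any(!is.finite(slentry), !is.finite(slstay)) ||
      slentry <= 0 || slentry >= 1 || slstay <= 0 || slstay >= 1)
    stop_ecg("slentry and slstay must lie in (0, 1)")
  max_vars <- max_vars %||% (n - g - 2L)
  sscp <- sscp_matrices(x, y)
  vars <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(sscp$W) <- rownames(sscp$W) <- vars
  colnames(sscp$T) <- rownames(sscp$T) <- vars

  selected <- character(0)
  partial_f <- function(v, base) {
    # F for v given base (v not in base)
    p <- length(base)
    df2 <- n - g - p
    if (df2 < 1) return(c(f = NA, p = NA))
    l0 <- wilks_lambda(sscp, base)
    l1 <- wilks_lambda(sscp, c(base, v))
    if (!is.finite(l0) || !is.finite(l1) || l1 <= 0)
      return(c(f = 0, p = 1))
    f <- (df2 / (g - 1)) * (l0 / l1 - 1)
    f <- max(0, f)
    c(f = f, p = pf(f, g - 1, df2, lower.tail = FALSE))
  }

  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 10L * max(1L, max_vars)) break   # cycle guard
    changed <- FALSE
    # removal first: worst currently-selected variable
    if (length(selected) > 1) {
      pr <- vapply(selected, function(v)
        partial_f(v, setdiff(selected, v))["p"], 0)
      worst <- which.max(pr)
      if (is.finite(pr[worst]) && pr[worst] > slstay) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    # entry
    if (!changed && length(selected) < max_vars) {
      cand <- setdiff(vars, selected)
      if (length(cand)) {
        pe <- vapply(cand, function(v) partial_f(v, selected)["p"], 0)
        fe <- vapply(cand, function(v) partial_f(v, selected)["f"], 0)
        ok <- is.finite(pe) & pe < slentry
        if (any(ok)) {
          best <- cand[ok][which.max(fe[ok])]
          selected <- c(selected, best)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (!length(selected))
    warning("stepwise selection: no variable met the entry criterion")
  selected
}

#' Box's M test of covariance homogeneity
#'
#' Tests equality of the class covariance matrices with Box's M statistic
#' and its chi-square approximation. The discriminant uses the pooled
#' covariance when homogeneity is not rejected and per-class covariances
#' (adding the log-determinant term to the distance) when it is.
#'
#' @param x Numeric feature matrix.
#' @param y Class factor.
#' @param ridge Relative ridge added to near-singular class covariances
#'   (times `trace/dim`) before taking log-determinants.
#' @return List with `statistic` (the corrected chi-square), `df`,
#'   `p_value`, and `m` (the uncorrected statistic).
#' @export
box_m_test <- function(x, y, ridge = 1e-8) {
  x <- as.matrix(x); y <- droplevels(as.factor(y))
  g <- nlevels(y); p <- ncol(x); n <- nrow(x)
  ns <- table(y)
  if (any(ns <= p))
    stop_ecg("each class needs more observations than features for Box's M")
  covs <- lapply(levels(y), function(cl)
    regularize_cov(cov(x[y == cl, , drop = FALSE]), ridge))
  pooled <- Reduce(`+`, Map(function(S, nt) (nt - 1) * S, covs, as.list(ns))) /
    (n - g)
  logdet <- function(S) determinant(S, logarithm = TRUE)$modulus[1]
  m <- (n - g) * logdet(pooled) -
    sum((ns - 1) * vapply(covs, logdet, 0))
  c1 <- (sum(1 / (ns - 1)) - 1 / (n - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  stat <- m * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(statistic = unname(stat), df = df,
       p_value = unname(pchisq(stat, df, lower.tail = FALSE)), m = unname(m))
}

regularize_cov <- function(S, ridge = 1e-8) {
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) S <- S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S))
  S
}

#' Generalized squared distance to a class
#'
#' `D^2 = (x - m)' S^-1 (x - m) + g1`, the squared Mahalanobis distance
#' plus, in per-class-covariance mode, the log-determinant term
#' `g1 = ln|S|`. Under the equal-prior assumption there is no prior-based
#' offset, and classification assigns a sample to the class minimizing
#' `D^2`.
#'
#' @param x Numeric vector (one sample) or matrix (rows = samples).
#' @param class_mean Class mean vector.
#' @param class_cov Covariance matrix (pooled or per-class).
#' @param per_class If `TRUE`, add `ln|class_cov|`.
#' @return Numeric vector of squared distances.
#' @export
generalized_distance <- function(x, class_mean, class_cov,
                                 per_class = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  d <- sweep(x, 2, class_mean)
  ch <- tryCatch(chol(class_cov), error = function(e)
    stop_ecg("class covariance is singular on features: ",
             paste(colnames(class_cov) %||% seq_len(ncol(class_cov)),
                   collapse = ", ")))
  z <- backsolve(ch, t(d), transpose = TRUE)
  d2 <- colSums(z^2)
  if (per_class) d2 <- d2 + 2 * sum(log(diag(ch)))
  d2
}

#' Train a stepwise discriminant classifier
#'
#' The full discriminant stage: optional stepwise variable selection
#' ([stepwise_select()]), Box's M homogeneity test ([box_m_test()]) on the
#' selected features to pick pooled vs per-class covariance mode, then the
#' class statistics of the generalized-distance rule. T-type proportion
#' columns compete in the selection like any other feature.
#'
#' @param x Numeric training matrix (subjects x features).
#' @param y Factor with levels `healthy`, `disease`.
#' @param stepwise Run variable selection (default) or use all columns.
#' @param slentry,slstay Stepwise significance levels.
#' @param homogeneity_alpha Box's M threshold below which per-class
#'   covariances are used.
#' @param ridge Relative ridge for near-singular covariances.
#' @return An `ecg_sda` model.
#' @export
train_sda <- function(x, y, stepwise = TRUE, slentry = 0.15, slstay = 0.15,
                      homogeneity_alpha = 0.10, ridge = 1e-8) {
  x <- as.matrix(x); y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop_ecg("train_sda expects exactly 2 classes")
  selected <- if (stepwise) {
    s <- stepwise_select(x, y, slentry, slstay)
    if (!length(s)) colnames(x) else s   # degenerate fallback: all features
  } else colnames(x)
  xs <- x[, selected, drop = FALSE]
  ns <- table(y); p <- length(selected)
  hom_p <- if (all(ns > p)) box_m_test(xs, y, ridge)$p_value else NA_real_
  cov_mode <- if (!is.na(hom_p) && hom_p < homogeneity_alpha)
    "per_class" else "pooled"
  class_means <- lapply(levels(y), function(cl)
    colMeans(xs[y == cl, , drop = FALSE]))
  names(class_means) <- levels(y)
  per_covs <- lapply(levels(y), function(cl)
    regularize_cov(cov(xs[y == cl, , drop = FALSE]), ridge))
  names(per_covs) <- levels(y)
  pooled <- regularize_cov(
    Reduce(`+`, Map(function(S, nt) (nt - 1) * S, per_covs, as.list(ns))) /
      (nrow(xs) - 2), ridge)
  covs <- if (cov_mode == "pooled")
    stats::setNames(list(pooled, pooled), levels(y)) else per_covs
  g1 <- if (cov_mode == "per_class")
    vapply(covs, function(S) determinant(S, TRUE)$modulus[1], 0)
  else stats::setNames(c(0, 0), levels(y))
  structure(list(selected_features = selected,
                 class_levels = levels(y),
                 class_means = class_means,
                 cov_mode = cov_mode, covariances = covs,
                 g1 = g1, homogeneity_pvalue = hom_p,
                 slentry = slentry, slstay = slstay,
                 n_train = as.vector(ns)),
            class = "ecg_sda")
}

#' @export
print.ecg_sda <- function(x, ...) {
  cat("Stepwise discriminant model (", x$cov_mode, " covariance)\n",
      sep = "")
  cat("  homogeneity p-value:", format(x$homogeneity_pvalue, digits = 4), "\n")
  cat("  selected features (", length(x$selected_features), "): ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify samples with a trained discriminant model
#'
#' @param object An `ecg_sda` model.
#' @param newdata Numeric matrix containing the model's selected features.
#' @param type `"class"` for predicted labels or `"distance"` for the
#'   per-class generalized squared distances.
#' @param ... Unused.
#' @return Factor of predicted classes, or a distance matrix.
#' @export
predict.ecg_sda <- function(object, newdata, type = c("class", "distance"),
                            ...) {
  type <- match.arg(type)
  nd <- as.matrix(newdata)[, object$selected_features, drop = FALSE]
  per <- object$cov_mode == "per_class"
  d2 <- vapply(object$class_levels, function(cl)
    generalized_distance(nd, object$class_means[[cl]],
                         object$covariances[[cl]], per_class = per),
    numeric(nrow(nd)))
  d2 <- matrix(d2, nrow = nrow(nd),
               dimnames = list(rownames(nd), object$class_levels))
  if (type == "distance") return(d2)
  factor(object$class_levels[max.col(-d2, ties.method = "first")],
         levels = object$class_levels)
}
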