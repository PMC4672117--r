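# Structured-text (JSON) serialization of fitted models and reports, so
# pipeline stages can be run, stored and resumed from the command line.

#' Serialize and restore fitted pipeline objects
#'
#' Writes discriminant models, correction models and classification
#' reports as JSON and reads them back. Round trips preserve every numeric
#' field to full double precision.
#'
#' @param model An `ecg_sda` / `correction_model` object (or a named list
#'   of `correction_model`s) / `classification_report`.
#' @param path File path.
#' @return The read functions return the restored object; write functions
#'   return `path` invisibly.
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_sda_model <- function(model, path) {
  if (!inherits(model, "ecg_sda")) stop_ecg("not an ecg_sda model")
  out <- list(type = "ecg_sda",
              selected_features = model$selected_features,
              class_levels = model$class_levels,
              class_means = model$class_means,
              cov_mode = model$cov_mode,
              covariances = lapply(model$covariances, unclass),
              g1 = as.list(model$g1),
              homogeneity_pvalue = model$homogeneity_pvalue,
              slentry = model$slentry, slstay = model$slstay,
              n_train = model$n_train)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname serialization
#' @export
read_sda_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "ecg_sda")) stop_ecg("not a serialized ecg_sda model")
  fix_cov <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(j$selected_features, j$selected_features)
    m
  }
  structure(list(selected_features = j$selected_features,
                 class_levels = j$class_levels,
                 class_means = lapply(j$class_means, function(v)
                   stats::setNames(unlist(v), j$selected_features)),
                 cov_mode = j$cov_mode,
                 covariances = lapply(j$covariances, fix_cov),
                 g1 = stats::setNames(unlist(j$g1), j$class_levels),
                 homogeneity_pvalue = j$homogeneity_pvalue,
                 slentry = j$slentry, slstay = j$slstay,
                 n_train = j$n_train),
            class = "ecg_sda")
}

#' @rdname serialization
#' @export
write_correction_models <- function(model, path) {
  models <- if (inherits(model, "correction_model")) list(model) else model
  out <- lapply(models, function(m)
    list(variable = m$variable, alpha = m$alpha, beta = m$beta,
         r_square = m$r_square, n_beats = m$n_beats,
         grid = m$grid, r_square_grid = m$r_square_grid))
  jsonlite::write_json(list(type = "correction_models", models = out),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname serialization
#' @export
read_correction_models <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "correction_models"))
    stop_ecg("not a serialized correction-model file")
  models <- lapply(j$models, function(m) {
    m$grid <- as.numeric(unlist(m$grid))
    m$r_square_grid <- as.numeric(unlist(m$r_square_grid))
    for (f in c("alpha", "beta", "r_square"))
      m[[f]] <- as.numeric(m[[f]])
    m$n_beats <- as.integer(m$n_beats)
    structure(m, class = "correction_model")
  })
  stats::setNames(models, vapply(models, function(m)
    as.character(m$variable %||% NA), ""))
}

#' @rdname serialization
#' @export
write_report <- function(model, path) {
  if (!inherits(model, "classification_report"))
    stop_ecg("not a classification_report")
  out <- list(type = "classification_report",
              confusion = as.vector(model$confusion),
              confusion_dimnames = dimnames(model$confusion),
              sensitivity = model$sensitivity,
              specificity = model$specificity,
              accuracy = model$accuracy,
              method = model$method, feature_set = model$feature_set)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname serialization
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "classification_report"))
    stop_ecg("not a serialized classification report")
  conf <- array(unlist(j$confusion), dim = c(2, 2),
                dimnames = j$confusion_dimnames)
  structure(list(confusion = as.table(conf),
                 sensitivity = j$sensitivity,
                 specificity = j$specificity,
                 accuracy = j$accuracy,
                 method = j$method %||% NA,
                 feature_set = j$feature_set %||% NA),
            class = "classification_report")
}
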