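# Heart-rate (RR) correction of time-span measurements. Each span y is
# modelled as y = beta * RR^alpha + error on healthy beats; alpha is picked
# from a discrete grid by R-square and the span is corrected as y / RR^alpha,
# generalizing Bazett's QTc = QT / sqrt(RR).

#' Default grid of candidate RR exponents
#' @return Numeric vector 0, 0.1, ..., 1.
#' @export
alpha_grid <- function() seq(0, 1, by = 0.1)

#' Fit the power-law RR dependence of a time span
#'
#' For each candidate exponent `alpha` on the grid, fits the no-intercept
#' least-squares model `y = beta * RR^alpha` and scores it by
#' `R^2 = 1 - SSE/SST` with SST taken about the mean of `y` (so models are
#' comparable across exponents; note `alpha = 0` then scores exactly 0).
#' Returns the grid exponent maximizing R-square, ties broken toward the
#' smaller (more parsimonious) exponent. Intended to be fit on healthy
#' subjects' beats.
#'
#' @param y Span values (seconds), one per beat.
#' @param rr Matching RR intervals (seconds), all positive.
#' @param grid Candidate exponents; default [alpha_grid()].
#' @param variable Optional variable name stored in the model.
#' @return A `correction_model`: list with `variable`, `alpha`, `beta`,
#'   `r_square`, `n_beats`, and the full `grid` / `r_square_grid` scanned.
#' @examples
#' rr <- seq(0.6, 1.4, length.out = 200)
#' m <- fit_power_exponent(0.4 * sqrt(rr), rr)
#' c(m$alpha, m$beta, m$r_square)   # 0.5, 0.4, 1
#' @export
fit_power_exponent <- function(y, rr, grid = alpha_grid(), variable = NA) {
  keep <- is.finite(y) & is.finite(rr)
  y <- y[keep]; rr <- rr[keep]
  if (length(y) < 10) stop_ecg("need at least 10 paired finite beats")
  if (any(rr <= 0)) stop_ecg("all RR intervals must be positive")
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    stop_ecg("span is constant (SST = 0): no RR trend to fit; use alpha = 0")
  grid <- sort(grid)
  fit_one <- function(a) {
    x <- rr^a
    beta <- sum(x * y) / sum(x * x)
    sse <- sum((y - beta * x)^2)
    c(beta = beta, r2 = 1 - sse / sst)
  }
  fits <- vapply(grid, fit_one, c(beta = 0, r2 = 0))
  best <- which.max(fits["r2", ])   # ties: first index = smallest alpha
  structure(list(variable = variable, alpha = grid[best],
                 beta = unname(fits["beta", best]),
                 r_square = unname(fits["r2", best]),
                 n_beats = length(y),
                 grid = grid, r_square_grid = unname(fits["r2", ])),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("RR correction model%s: y = %.4g * RR^%.1f  (R2 = %.4f, n = %d)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$beta, x$alpha, x$r_square, x$n_beats))
  invisible(x)
}

#' Correct a span for its RR dependence
#'
#' `y_c = y / RR^alpha`; with `alpha = 0.5` and `y = QT` this is Bazett's
#' formula. Beats with absent RR (the last beat of a record) yield `NA`.
#'
#' @param y Span value(s), seconds.
#' @param rr RR interval(s), seconds, positive.
#' @param alpha Correction exponent.
#' @return Corrected value(s).
#' @export
apply_correction <- function(y, rr, alpha) {
  if (any(rr <= 0, na.rm = TRUE)) stop_ecg("RR must be positive")
  y / rr^alpha
}

#' Reference correction exponents for the five adjusted spans
#'
#' The standard exponents used by the pipeline when not refitting: QT 0.5
#' (Bazett), PR 0.2, P span 0.1, T span 0.5; the QRS span is not adjusted
#' (exponent 0) because its correlation with RR is negligible.
#'
#' @return Named numeric vector of exponents.
#' @export
default_corrections <- function()
  c(QT = 0.5, PR = 0.2, Pspan = 0.1, Tspan = 0.5, QRSspan = 0)

#' Fit correction models for all spans on healthy beats
#'
#' Runs [fit_power_exponent()] per span variable on the healthy subjects'
#' beats of a beat table.
#'
#' @param beats Beat table (see [write_beat_table()]).
#' @param variables Span variables to fit.
#' @param grid Candidate exponents.
#' @return Named list of `correction_model`s.
#' @export
fit_corrections <- function(beats, variables = c("PR", "QT", "Pspan",
                                                 "QRSspan", "Tspan"),
                            grid = alpha_grid()) {
  h <- beats[beats$label == "healthy", ]
  if (!nrow(h)) stop_ecg("no healthy beats to fit corrections on")
  stats::setNames(
    lapply(variables, function(v)
      fit_power_exponent(h[[v]], h$RR, grid = grid, variable = v)),
    variables)
}

#' Apply RR corrections to a beat table
#'
#' Divides each adjustable span column by `RR^alpha`. RR itself is never
#' corrected. Exponents default to [default_corrections()]; pass the
#' `alpha` entries of [fit_corrections()] models to use refitted values.
#'
#' @param beats Beat table.
#' @param alphas Named vector of exponents per span column.
#' @return The beat table with corrected span columns.
#' @export
adjust_beat_table <- function(beats, alphas = default_corrections()) {
  for (v in names(alphas)) {
    if (!v %in% names(beats)) next
    if (alphas[[v]] != 0)
      beats[[v]] <- apply_correction(beats[[v]], beats$RR, alphas[[v]])
  }
  beats
}
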