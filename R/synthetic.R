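# Synthetic cohort generator: per-beat measurement tables with power-law RR
# dependence and a healthy-vs-diseased mixture structure, plus piecewise-
# linear single-beat waveforms with exactly known ground truth.

#' Specify the generative law of one subject group
#'
#' Defines how per-beat measurements are drawn for one group of synthetic
#' subjects. Time spans follow the power law `span = beta * RR^alpha *
#' exp(eps)` with multiplicative lognormal noise (`eps ~ N(0, noise_cv)`),
#' which keeps spans positive and matches the ratio form of the RR
#' corrections. Amplitudes are lognormal around their group mean; slopes are
#' Gaussian around theirs. A fraction `abnormal_fraction` of beats is drawn
#' from an abnormal mixture component: those beats receive the location
#' shifts in `abnormal_shift` and a four-fold noise-variance inflation,
#' producing the heavy-tailed / multimodal beat distributions seen in
#' diseased subjects while most beats stay normal. Between-subject
#' physiological heterogeneity is a per-subject lognormal scale factor
#' (`subject_cv`) on span betas and amplitude means and an additive offset
#' on slope means.
#'
#' @param label `"healthy"` or `"disease"`.
#' @param n_subjects,beats_per_subject Cohort dimensions.
#' @param rr_mean,rr_sd RR interval distribution (seconds); RR is truncated
#'   below at 0.3 s.
#' @param span_betas,span_alphas Named vectors (PR, QT, Pspan, QRSspan,
#'   Tspan): power-law scale (seconds) and exponent per time span.
#' @param amp_means Named vector (P_amp, R_amp, T_amp), millivolts.
#' @param slope_means Named vector over the nine waveform segments
#'   (`Up-P`, `Down-P`, `PR`, `Up-R`, `Down-R`, `ST`, `Up-T`, `Down-T`,
#'   `TP`), mV/s.
#' @param noise_cv Within-subject coefficient of variation of beat noise.
#' @param subject_cv Between-subject coefficient of variation.
#' @param abnormal_fraction Expected proportion of beats drawn from the
#'   abnormal component, in `[0, 1]`.
#' @param abnormal_dispersion Between-subject heterogeneity of the abnormal
#'   fraction: 0 gives every subject exactly `abnormal_fraction`; a value
#'   `s > 0` draws each subject's fraction from a Beta distribution with
#'   mean `abnormal_fraction` and concentration `s` (small `s` = strongly
#'   heterogeneous disease expression, so some diseased subjects have
#'   almost no abnormal beats).
#' @param abnormal_shift Named numeric vector of location shifts applied to
#'   abnormal beats; names are beat-table variables (spans, `P_amp` etc.,
#'   or `slope_*` columns), units those of the variable.
#' @param ttype_probs Probabilities of the six T-wave types
#'   (see [ttype_levels]); must sum to 1.
#' @return A `group_spec` object.
#' @seealso [healthy_spec()], [disease_spec()], [simulate_beat_table()]
#' @export
group_spec <- function(label = c("healthy", "disease"),
                       n_subjects = 25L,
                       beats_per_subject = 100L,
                       rr_mean = 1.0, rr_sd = 0.1,
                       span_betas = c(PR = 0.16, QT = 0.40, Pspan = 0.10,
                                      QRSspan = 0.09, Tspan = 0.18),
                       span_alphas = c(PR = 0.2, QT = 0.5, Pspan = 0.1,
                                       QRSspan = 0, Tspan = 0.5),
                       amp_means = c(P_amp = 0.15, R_amp = 1.2, T_amp = 0.35),
                       slope_means = c("Up-P" = 3, "Down-P" = -3, "PR" = 0,
                                       "Up-R" = 80, "Down-R" = -90, "ST" = 0.5,
                                       "Up-T" = 3.5, "Down-T" = -4.5, "TP" = 0),
                       noise_cv = 0.05,
                       subject_cv = 0.08,
                       abnormal_fraction = 0,
                       abnormal_dispersion = 0,
                       abnormal_shift = numeric(0),
                       ttype_probs = c(0.85, 0.03, 0.03, 0.03, 0.03, 0.03)) {
  label <- match.arg(label)
  if (!is.numeric(n_subjects) || n_subjects < 1 ||
      !is.numeric(beats_per_subject) || beats_per_subject < 1)
    stop_ecg("n_subjects and beats_per_subject must be positive integers")
  if (!is.finite(rr_mean) || rr_mean <= 0)
    stop_ecg("rr_mean must be positive")
  if (!is.finite(abnormal_fraction) || abnormal_fraction < 0 ||
      abnormal_fraction > 1)
    stop_ecg("abnormal_fraction must lie in [0, 1]")
  if (!is.finite(abnormal_dispersion) || abnormal_dispersion < 0)
    stop_ecg("abnormal_dispersion must be nonnegative")
  check_prob_vector(ttype_probs, 6L, "ttype_probs")
  bad <- setdiff(names(span_alphas), c("PR", "QT", "Pspan", "QRSspan", "Tspan"))
  if (length(bad))
    stop_ecg("span_alphas has unknown variables: ", paste(bad, collapse = ", "))
  shift_names <- names(abnormal_shift)
  known <- c(names(span_betas), names(amp_means),
             paste0("slope_", gsub("-", "_", names(slope_means))),
             names(slope_means))
  if (length(abnormal_shift) && !all(shift_names %in% known))
    stop_ecg("abnormal_shift names must be beat-table variables; unknown: ",
             paste(setdiff(shift_names, known), collapse = ", "))
  structure(list(label = label,
                 n_subjects = as.integer(n_subjects),
                 beats_per_subject = as.integer(beats_per_subject),
                 rr_mean = rr_mean, rr_sd = rr_sd,
                 span_betas = span_betas, span_alphas = span_alphas,
                 amp_means = amp_means, slope_means = slope_means,
                 noise_cv = noise_cv, subject_cv = subject_cv,
                 abnormal_fraction = abnormal_fraction,
                 abnormal_dispersion = abnormal_dispersion,
                 abnormal_shift = abnormal_shift,
                 ttype_probs = ttype_probs),
            class = "group_spec")
}

#' Default group specifications for a synthetic study cohort
#'
#' `healthy_spec()` draws every beat from the normal component with a
#' dominant normal T-wave type. `disease_spec()` keeps most beats normal
#' but draws 15% (on average; the fraction varies between subjects,
#' `abnormal_dispersion = 4`) from an abnormal component with diffuse
#' moderate shifts across most measurements -- prolonged QT/PR/T span,
#' reduced P/R/T amplitudes, T- and R-wave slopes pulled toward zero or
#' reversed -- plus a more dispersed T-type distribution: the beat-level
#' picture of a heterogeneous disease group whose signal is spread over
#' many correlated variables rather than one dominant marker. Group sizes
#' default to 52 healthy and 194 diseased subjects (a 26+26 / 98+96
#' train-test study design).
#'
#' @param n_subjects,beats_per_subject Cohort dimensions.
#' @param ... Further arguments passed to [group_spec()] to override
#'   defaults.
#' @return A `group_spec` object.
#' @export
healthy_spec <- function(n_subjects = 52L, beats_per_subject = 200L, ...) {
  group_spec(label = "healthy", n_subjects = n_subjects,
             beats_per_subject = beats_per_subject, ...)
}

#' @rdname healthy_spec
#' @export
disease_spec <- function(n_subjects = 194L, beats_per_subject = 200L, ...) {
  defaults <- list(
    label = "disease",
    n_subjects = n_subjects, beats_per_subject = beats_per_subject,
    rr_sd = 0.15,
    abnormal_fraction = 0.15,
    abnormal_dispersion = 4,
    abnormal_shift = c(QT = 0.06, PR = 0.04, Pspan = 0.012, Tspan = 0.035,
                       QRSspan = 0.02, T_amp = -0.35, P_amp = -0.07,
                       R_amp = -0.4,
                       slope_Up_P = -1.2, slope_Down_P = 1.2,
                       slope_Up_R = -20, slope_Down_R = 25,
                       slope_ST = 1.5, slope_Up_T = -2.5,
                       slope_Down_T = 3, slope_TP = 0.8),
    ttype_probs = c(0.72, 0.08, 0.05, 0.05, 0.05, 0.05))
  do.call(group_spec, modifyList(defaults, list(...)))
}

#' Draw RR intervals from a truncated normal distribution
#'
#' RR intervals are normal with the given mean and standard deviation,
#' truncated below (default 0.3 s) to exclude physiologically impossible
#' beat periods. Sampling is by inverse-CDF, so it consumes exactly `n`
#' uniforms from the RNG stream.
#'
#' @param n Number of beats.
#' @param mean,sd Normal parameters in seconds.
#' @param lower Truncation bound in seconds.
#' @return Numeric vector of RR intervals (seconds).
#' @export
simulate_rr <- function(n, mean = 1.0, sd = 0.1, lower = 0.3) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(p0 + runif(n) * (1 - p0))
}

#' Simulate a per-beat measurement table for a two-group cohort
#'
#' Generates a synthetic cohort of healthy and diseased subjects with one
#' record per subject, drawing each beat's spans, amplitudes, slopes and
#' T-wave type from the generative laws in the two [group_spec()]s. Fully
#' reproducible from `seed`.
#'
#' @param healthy,disease [group_spec()] objects (labels must match).
#' @param seed Integer RNG seed.
#' @return A `synthetic_cohort` object: list with `beats` (the beat table,
#'   one row per beat, columns `subject_id`, `record_id`, `label`,
#'   `beat_index`, the 18 measurement variables and `T_type`), `truth`
#'   (the two specs) and `seed`.
#' @examples
#' co <- simulate_beat_table(healthy_spec(n_subjects = 3, beats_per_subject = 20),
#'                           disease_spec(n_subjects = 3, beats_per_subject = 20),
#'                           seed = 1)
#' table(co$beats$label) / 20
#' @export
simulate_beat_table <- function(healthy = healthy_spec(),
                                disease = disease_spec(),
                                seed = 1L) {
  if (!inherits(healthy, "group_spec") || !inherits(disease, "group_spec"))
    stop_ecg("healthy and disease must be group_spec objects")
  if (healthy$label != "healthy" || disease$label != "disease")
    stop_ecg("specs must carry labels 'healthy' and 'disease' respectively")
  set.seed(as.integer(seed))
  beats <- rbind(simulate_group(healthy, id_prefix = "H"),
                 simulate_group(disease, id_prefix = "D"))
  rownames(beats) <- NULL
  structure(list(beats = beats,
                 truth = list(healthy = healthy, disease = disease),
                 seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# One group's beats; assumes the RNG is already seeded.
simulate_group <- function(spec, id_prefix) {
  nb <- spec$beats_per_subject
  shift_of <- function(var) {
    s <- spec$abnormal_shift
    # slope shifts may be named either by segment or by table column
    for (nm in unique(c(var, sub("^slope_", "", gsub("_", "-", var)))))
      if (nm %in% names(s)) return(unname(s[[nm]]))
    0
  }
  one_subject <- function(i) {
    subj_scale <- exp(rnorm(1, 0, spec$subject_cv))
    rr <- simulate_rr(nb, spec$rr_mean, spec$rr_sd)
    frac <- spec$abnormal_fraction
    if (spec$abnormal_dispersion > 0 && frac > 0 && frac < 1)
      frac <- stats::rbeta(1, frac * spec$abnormal_dispersion,
                           (1 - frac) * spec$abnormal_dispersion)
    abn <- runif(nb) < frac
    cv <- spec$noise_cv * ifelse(abn, 2, 1)   # variance inflation x4
    row <- data.frame(subject_id = sprintf("%s%03d", id_prefix, i),
                      record_id = "r1", label = spec$label,
                      beat_index = seq_len(nb), RR = rr,
                      stringsAsFactors = FALSE)
    for (v in names(spec$span_betas)) {
      if (v == "RR") next
      a <- spec$span_alphas[[v]] %||% 0
      row[[v]] <- spec$span_betas[[v]] * subj_scale * rr^a *
        exp(rnorm(nb, 0, cv)) + abn * shift_of(v)
    }
    for (v in amp_vars)
      row[[v]] <- spec$amp_means[[v]] * subj_scale * exp(rnorm(nb, 0, cv)) +
        abn * shift_of(v)
    for (k in seq_along(slope_segments)) {
      seg <- slope_segments[k]; col <- slope_vars[k]
      m <- spec$slope_means[[seg]]
      scale_k <- abs(m) + 1      # additive noise floor of 1 mV/s
      subj_off <- rnorm(1, 0, spec$subject_cv * scale_k)
      row[[col]] <- m + subj_off + rnorm(nb, 0, cv * scale_k) +
        abn * shift_of(col)
    }
    row$T_type <- ttype_levels[sample.int(6L, nb, replace = TRUE,
                                          prob = spec$ttype_probs)]
    row
  }
  out <- do.call(rbind, lapply(seq_len(spec$n_subjects), one_subject))
  out[, beat_table_cols]
}

#' Simulate a piecewise-linear ECG waveform with known ground truth
#'
#' Builds a sampled single-lead trace of identical beats whose fiducial
#' spans, baseline-referenced amplitudes and segment slopes are known
#' exactly (up to sampling-grid rounding): each wave rises linearly from the
#' baseline to its peak and falls back linearly, and the PR, ST and TP
#' segments sit flat on the baseline. Intended as a measurement fixture,
#' not as physiologically realistic morphology.
#'
#' @param params Named list of beat geometry: `rr`, `pr`, `qt`, `p_span`,
#'   `qrs_span`, `t_span` (seconds; `pr > p_span` and
#'   `qt > qrs_span + t_span` must hold), `p_amp`, `r_amp`, `t_amp` (mV,
#'   signed, relative to baseline), `baseline` (mV), optional `t_type`
#'   (default `"Normal"`) and peak position fractions `p_frac`, `r_frac`,
#'   `t_frac` (default 0.5).
#' @param fs Sampling frequency in Hz, at least 250.
#' @param n_beats Number of identical beats to emit (at least 2, so that
#'   RR- and TP-dependent measurements are defined for the first beat).
#' @return List with `signal` (mV), `fs`, `fiducials` (list of
#'   [fiducial_beat()]), and `truth`: the measurements implied by the
#'   snapped sample grid, named as in the beat table.
#' @export
simulate_waveform <- function(params, fs = 1000, n_beats = 2L) {
  if (fs < 250) stop_ecg("fs must be at least 250 Hz")
  p <- modifyList(list(baseline = 0, t_type = "Normal",
                       p_frac = 0.5, r_frac = 0.5, t_frac = 0.5), params)
  need <- c("rr", "pr", "qt", "p_span", "qrs_span", "t_span",
            "p_amp", "r_amp", "t_amp")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop_ecg("params missing: ", paste(missing, collapse = ", "))
  spans <- unlist(p[c("pr", "qt", "p_span", "qrs_span", "t_span")])
  if (any(spans <= 0)) stop_ecg("spans must be positive")
  if (p$pr <= p$p_span)
    stop_ecg("PR interval must exceed the P-wave span")
  if (p$qt <= p$qrs_span + p$t_span)
    stop_ecg("QT interval must exceed QRS span plus T span")
  lead_in <- 0.05
  if (lead_in + p$pr + p$qt > p$rr)
    stop_ecg("beat spans exceed the RR interval")

  snap <- function(t) as.integer(round(t * fs))   # 0-based sample index
  beat_samples <- function(offset) {
    p_on   <- snap(offset + lead_in)
    p_off  <- snap(offset + lead_in + p$p_span)
    p_peak <- snap(offset + lead_in + p$p_frac * p$p_span)
    qrs_on  <- snap(offset + lead_in + p$pr)
    qrs_off <- snap(offset + lead_in + p$pr + p$qrs_span)
    r_peak  <- snap(offset + lead_in + p$pr + p$r_frac * p$qrs_span)
    t_off  <- snap(offset + lead_in + p$pr + p$qt)
    t_on   <- snap(offset + lead_in + p$pr + p$qt - p$t_span)
    t_peak <- snap(offset + lead_in + p$pr + p$qt - p$t_span +
                     p$t_frac * p$t_span)
    fiducial_beat(p_on = p_on, p_peak = p_peak, p_off = p_off,
                  qrs_on = qrs_on, r_peak = r_peak, qrs_off = qrs_off,
                  t_on = t_on, t_peak = t_peak, t_off = t_off,
                  t_type = p$t_type, fs = fs)
  }
  fiducials <- lapply((seq_len(n_beats) - 1) * p$rr, beat_samples)

  n_samp <- snap((n_beats - 1) * p$rr + lead_in + p$pr + p$qt + 0.05) + 1L
  # breakpoints: (0-based sample, value); flat baseline elsewhere
  bp_x <- c(0L); bp_y <- c(p$baseline)
  for (fb in fiducials) {
    bp_x <- c(bp_x, fb$p_on, fb$p_peak, fb$p_off,
              fb$qrs_on, fb$r_peak, fb$qrs_off,
              fb$t_on, fb$t_peak, fb$t_off)
    bp_y <- c(bp_y, p$baseline, p$baseline + p$p_amp, p$baseline,
              p$baseline, p$baseline + p$r_amp, p$baseline,
              p$baseline, p$baseline + p$t_amp, p$baseline)
  }
  bp_x <- c(bp_x, n_samp - 1L); bp_y <- c(bp_y, p$baseline)
  signal <- stats::approx(bp_x, bp_y, xout = 0:(n_samp - 1L),
                          method = "linear", ties = "ordered")$y

  fb <- fiducials[[1]]; nb <- fiducials[[2]]
  tdiff <- function(a, b) (b - a) / fs
  slope <- function(amp, n_rise) if (n_rise == 0) NA_real_ else amp / (n_rise / fs)
  truth <- c(
    RR = tdiff(fb$r_peak, nb$r_peak),
    PR = tdiff(fb$p_on, fb$qrs_on),
    QT = tdiff(fb$qrs_on, fb$t_off),
    Pspan = tdiff(fb$p_on, fb$p_off),
    QRSspan = tdiff(fb$qrs_on, fb$qrs_off),
    Tspan = tdiff(fb$t_on, fb$t_off),
    P_amp = p$p_amp, R_amp = p$r_amp, T_amp = p$t_amp,
    slope_Up_P = slope(p$p_amp, fb$p_peak - fb$p_on),
    slope_Down_P = slope(-p$p_amp, fb$p_off - fb$p_peak),
    slope_PR = 0,
    slope_Up_R = slope(p$r_amp, fb$r_peak - fb$qrs_on),
    slope_Down_R = slope(-p$r_amp, fb$qrs_off - fb$r_peak),
    slope_ST = 0,
    slope_Up_T = slope(p$t_amp, fb$t_peak - fb$t_on),
    slope_Down_T = slope(-p$t_amp, fb$t_off - fb$t_peak),
    slope_TP = 0)
  list(signal = signal, fs = fs, fiducials = fiducials,
       baseline = p$baseline, truth = truth)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_by <- table(unique(x$beats[, c("subject_id", "label")])$label)
  cat("Synthetic ECG cohort (seed ", x$seed, ")\n", sep = "")
  cat("  subjects: ", paste(sprintf("%s = %d", names(n_by), n_by),
                            collapse = ", "), "\n", sep = "")
  cat("  beats:    ", nrow(x$beats), "\n", sep = "")
  invisible(x)
}
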