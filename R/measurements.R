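# Per-beat waveform measurements: time spans, baseline, amplitudes, slopes.
# All windows are inclusive of both endpoint samples; indices are 0-based
# as in the fiducial annotations, so sample k is signal[k + 1].

#' Six time-span measurements of one beat
#'
#' RR is measured to the next beat's R peak; PR from P onset to QRS onset;
#' QT from QRS onset to T offset; the P, QRS and T spans between the
#' respective onsets and offsets. A span whose fiducials are absent is
#' `NA` -- in particular RR and the TP segment for the last beat of a
#' record.
#'
#' @param beat A [fiducial_beat()].
#' @param next_beat The following beat, or `NULL` for the last beat.
#' @return Named numeric vector `RR, PR, QT, Pspan, QRSspan, Tspan`
#'   (seconds).
#' @export
time_spans <- function(beat, next_beat = NULL) {
  fs <- beat$fs
  d <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(NA_real_)
    (b - a) / fs
  }
  c(RR = if (is.null(next_beat)) NA_real_ else d(beat$r_peak, next_beat$r_peak),
    PR = d(beat$p_on, beat$qrs_on),
    QT = d(beat$qrs_on, beat$t_off),
    Pspan = d(beat$p_on, beat$p_off),
    QRSspan = d(beat$qrs_on, beat$qrs_off),
    Tspan = d(beat$t_on, beat$t_off))
}

# inclusive window of 0-based samples [a, b] as signal values; NULL if absent
window_samples <- function(signal, a, b) {
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b) || b < a) return(NULL)
  lo <- max(0, a); hi <- min(length(signal) - 1, b)
  if (hi < lo) return(NULL)
  signal[(lo:hi) + 1]
}

#' Estimate the isoelectric baseline of one beat
#'
#' The baseline is the arithmetic mean of all signal samples pooled across
#' the PR segment (P offset to QRS onset), the ST segment (QRS offset to
#' T onset) and the TP segment (T offset to the next beat's P onset).
#' Segments whose fiducials are absent contribute nothing; the mean is over
#' the remaining segments' samples, and the baseline is `NA` only when all
#' three are unavailable.
#'
#' @param signal Numeric signal vector (mV).
#' @param beat,next_beat [fiducial_beat()]s; `next_beat` may be `NULL`.
#' @return Baseline in mV, or `NA`.
#' @export
estimate_baseline <- function(signal, beat, next_beat = NULL) {
  segs <- list(window_samples(signal, beat$p_off, beat$qrs_on),
               window_samples(signal, beat$qrs_off, beat$t_on),
               if (!is.null(next_beat))
                 window_samples(signal, beat$t_off, next_beat$p_on))
  pooled <- unlist(segs)
  if (!length(pooled)) return(NA_real_)
  mean(pooled)
}

#' Baseline-referenced amplitude of a wave
#'
#' Subtracts the baseline from the maximum and the minimum of the wave
#' window and returns whichever has the larger absolute value, keeping its
#' sign; ties go to the positive deviation. A flat wave at the baseline
#' therefore has amplitude 0, and an inverted wave a negative amplitude.
#'
#' @param signal Numeric signal vector (mV).
#' @param wave_on,wave_off 0-based window bounds (inclusive).
#' @param baseline Baseline in mV.
#' @return Signed amplitude in mV, or `NA`.
#' @export
wave_amplitude <- function(signal, wave_on, wave_off, baseline) {
  w <- window_samples(signal, wave_on, wave_off)
  if (is.null(w) || is.na(baseline)) return(NA_real_)
  a <- max(w) - baseline
  b <- min(w) - baseline
  if (abs(a) >= abs(b)) a else b
}

#' Least-squares slope of a waveform segment
#'
#' Ordinary-least-squares slope (intercept included) of signal values on
#' time in seconds, so the unit is mV/s regardless of sampling rate.
#'
#' @param times Sample times in seconds.
#' @param values Signal values in mV.
#' @return Slope in mV/s; `NA` with fewer than two distinct time points.
#' @export
segment_slope <- function(times, values) {
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 2) return(NA_real_)
  tc <- times - mean(times)
  stt <- sum(tc^2)
  if (stt == 0) return(NA_real_)
  sum(tc * values) / stt
}

segment_slope_idx <- function(signal, a, b, fs) {
  w <- window_samples(signal, a, b)
  if (is.null(w)) return(NA_real_)
  n0 <- max(0, a)
  segment_slope((n0:(n0 + length(w) - 1)) / fs, w)
}

#' Measure all features of one beat
#'
#' Assembles the full per-beat measurement row: the six [time_spans()], the
#' [estimate_baseline()] estimate, the three [wave_amplitude()]s over the
#' P, QRS and T windows, the nine [segment_slope()]s over the Table-style
#' waveform segments (Up-P, Down-P, PR, Up-R, Down-R, ST, Up-T, Down-T,
#' and TP into the next beat) and the T-wave type. Any measurement whose
#' fiducials are missing is `NA`; a beat never fails wholesale.
#'
#' @param signal Numeric signal vector (mV).
#' @param beat,next_beat [fiducial_beat()]s; `next_beat` may be `NULL`
#'   (last beat of a record), which leaves RR, the TP slope and the TP
#'   baseline segment undefined.
#' @return Named list with the 18 measurement variables, `baseline`, and
#'   `T_type`.
#' @export
measure_beat <- function(signal, beat, next_beat = NULL) {
  fs <- beat$fs
  spans <- time_spans(beat, next_beat)
  baseline <- estimate_baseline(signal, beat, next_beat)
  amp <- function(a, b) wave_amplitude(signal, a, b, baseline)
  sl <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(NA_real_)
    segment_slope_idx(signal, a, b, fs)
  }
  next_p_on <- if (is.null(next_beat)) NA else next_beat$p_on
  c(as.list(spans),
    list(baseline = baseline,
         P_amp = amp(beat$p_on, beat$p_off),
         R_amp = amp(beat$qrs_on, beat$qrs_off),
         T_amp = amp(beat$t_on, beat$t_off),
         slope_Up_P = sl(beat$p_on, beat$p_peak),
         slope_Down_P = sl(beat$p_peak, beat$p_off),
         slope_PR = sl(beat$p_off, beat$qrs_on),
         slope_Up_R = sl(beat$qrs_on, beat$r_peak),
         slope_Down_R = sl(beat$r_peak, beat$qrs_off),
         slope_ST = sl(beat$qrs_off, beat$t_on),
         slope_Up_T = sl(beat$t_on, beat$t_peak),
         slope_Down_T = sl(beat$t_peak, beat$t_off),
         slope_TP = sl(beat$t_off, next_p_on),
         T_type = beat$t_type))
}

#' Measure every beat of a delineated record
#'
#' Applies [measure_beat()] to each consecutive beat pair of a record and
#' returns rows in the beat-table schema (see [write_beat_table()]).
#'
#' @param signal Numeric signal vector (mV).
#' @param fiducials List of [fiducial_beat()]s in temporal order (e.g.
#'   from [read_annotations()]).
#' @param subject_id,record_id,label Identifier columns for the rows.
#' @return Data frame in the beat-table schema, one row per beat.
#' @export
measure_record <- function(signal, fiducials, subject_id = "S1",
                           record_id = "r1", label = "healthy") {
  if (!length(fiducials))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(beat_table_cols))),
      beat_table_cols))
  rows <- lapply(seq_along(fiducials), function(i) {
    nb <- if (i < length(fiducials)) fiducials[[i + 1]] else NULL
    m <- measure_beat(signal, fiducials[[i]], nb)
    m$baseline <- NULL
    data.frame(subject_id = subject_id, record_id = record_id,
               label = label, beat_index = i,
               m[span_vars], m[amp_vars], m[slope_vars],
               T_type = if (is.na(m$T_type)) NA_character_ else m$T_type,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- beat_table_cols
  out
}
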