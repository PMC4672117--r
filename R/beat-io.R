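# Data model and I/O for delineated ECG beats: fiducial-point containers,
# a minimal WFDB-style header/format-16 signal reader and writer, an
# rdann-style text annotation reader following ECGPUWAVE conventions, and
# the comma-delimited beat-table interchange format.

#' Fiducial points of one delineated heartbeat
#'
#' Holds the 0-based sample indices of the nine fiducial points of a beat
#' (onset, peak and offset of the P wave, QRS complex and T wave) plus the
#' 6-category T-wave morphology type. A wave the delineator did not find is
#' represented by `NA` indices, never by zeros. Present indices must be
#' strictly increasing in anatomical order.
#'
#' @param p_on,p_peak,p_off,qrs_on,r_peak,qrs_off,t_on,t_peak,t_off
#'   0-based sample indices (`NA` if absent).
#' @param t_type One of [ttype_levels], or `NA`.
#' @param fs Sampling frequency in Hz.
#' @return A `fiducial_beat` object.
#' @export
fiducial_beat <- function(p_on = NA, p_peak = NA, p_off = NA,
                          qrs_on = NA, r_peak = NA, qrs_off = NA,
                          t_on = NA, t_peak = NA, t_off = NA,
                          t_type = NA, fs = 1000) {
  idx <- c(p_on = p_on, p_peak = p_peak, p_off = p_off,
           qrs_on = qrs_on, r_peak = r_peak, qrs_off = qrs_off,
           t_on = t_on, t_peak = t_peak, t_off = t_off)
  present <- idx[!is.na(idx)]
  if (length(present) > 1 && any(diff(present) <= 0))
    stop_ecg("fiducial indices must be strictly increasing in beat order")
  if (!is.na(t_type) && !t_type %in% ttype_levels)
    stop_ecg("t_type must be one of: ", paste(ttype_levels, collapse = ", "))
  structure(c(as.list(idx), list(t_type = t_type, fs = fs)),
            class = "fiducial_beat")
}

#' @export
print.fiducial_beat <- function(x, ...) {
  idx <- unlist(x[c("p_on", "p_peak", "p_off", "qrs_on", "r_peak",
                    "qrs_off", "t_on", "t_peak", "t_off")])
  cat("Heartbeat fiducials (fs ", x$fs, " Hz, T type ",
      x$t_type %||% NA, ")\n", sep = "")
  print(idx)
  invisible(x)
}

# ---- WFDB-style signal files ---------------------------------------------

#' Read one lead from a WFDB-style record
#'
#' Parses a WFDB header (`.hea`) and the associated binary signal file and
#' returns the requested lead in physical units (mV). Only signal format 16
#' (16-bit little-endian two's complement, interleaved channels) is
#' supported; physical values are `(adc - baseline) / gain`.
#'
#' @param header_path Path to the `.hea` file.
#' @param lead Lead (signal description) name to extract.
#' @return List with `signal` (numeric, mV), `fs` (Hz), `lead`, and
#'   `record` name.
#' @export
read_wfdb_record <- function(header_path, lead) {
  if (!file.exists(header_path)) stop_ecg("header not found: ", header_path)
  lines <- trimws(readLines(header_path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rec <- strsplit(lines[1], "\\s+")[[1]]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  sig_lines <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    gain_field <- sub("/.*", "", f[3])
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    else if (length(f) >= 5) as.numeric(f[5]) else 0
    gain <- as.numeric(sub("\\(.*", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
            else paste0("sig", seq_along(sig_lines))
    list(file = f[1], format = as.integer(sub("[x:+].*", "", f[2])),
         gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  descs <- vapply(sigs, `[[`, "", "desc")
  k <- match(lead, descs)
  if (is.na(k))
    stop_ecg("lead '", lead, "' not found; available leads: ",
             paste(descs, collapse = ", "))
  if (sigs[[k]]$format != 16)
    stop_ecg("unsupported WFDB signal format ", sigs[[k]]$format,
             " (only format 16 is supported)")
  dat_path <- file.path(dirname(header_path), sigs[[k]]$file)
  if (!file.exists(dat_path)) stop_ecg("signal file not found: ", dat_path)
  raw_n <- file.size(dat_path) / 2
  adc <- readBin(dat_path, "integer", n = raw_n, size = 2,
                 endian = "little", signed = TRUE)
  channel <- adc[seq(k, length(adc), by = n_sig)]
  list(signal = (channel - sigs[[k]]$baseline) / sigs[[k]]$gain,
       fs = fs, lead = lead, record = rec[1])
}

#' Write a single-lead WFDB-style record
#'
#' Companion writer for [read_wfdb_record()]: emits a `.hea` header and a
#' format-16 binary signal file. Samples are quantized to integers with the
#' given gain, so the round trip is exact to within `1/(2*gain)` mV.
#'
#' @param signal Numeric vector in mV.
#' @param fs Sampling frequency in Hz.
#' @param path_base Path without extension; `.hea` and `.dat` are appended.
#' @param lead Lead description written to the header.
#' @param gain ADC units per mV.
#' @return `path_base`, invisibly.
#' @export
write_wfdb_record <- function(signal, fs, path_base, lead = "i", gain = 200) {
  record <- basename(path_base)
  adc <- as.integer(round(signal * gain))
  if (any(abs(adc) > 32767)) stop_ecg("signal exceeds 16-bit ADC range")
  writeLines(c(sprintf("%s 1 %g %d", record, fs, length(adc)),
               sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
                       record, as.integer(gain), adc[1], lead)),
             paste0(path_base, ".hea"))
  writeBin(adc, paste0(path_base, ".dat"), size = 2, endian = "little")
  invisible(path_base)
}

# ---- annotation streams --------------------------------------------------

# ECGPUWAVE-style annotation conventions in rdann text dumps:
#   symbol '(' = wave onset, ')' = wave offset, 'p'/'t' = P/T peak,
#   a beat label (e.g. 'N') at the R peak; `num` disambiguates the wave
#   (0 = P, 1 = QRS, 2 = T); `subtype` on 't' carries the T-type code 0-5.

#' Read per-beat fiducials from an rdann-style annotation file
#'
#' Parses a whitespace-delimited annotation dump (the output format of
#' WFDB's `rdann`, with or without the leading elapsed-time column) into
#' per-beat [fiducial_beat()] objects. Wave boundary events use `(` / `)`
#' symbols with peaks marked `p`, `t`, or a beat label at the R peak; the
#' `num` field, when present, names the wave (0 = P, 1 = QRS, 2 = T) and
#' the `subtype` of the T peak carries the 6-category T-type code (0-5).
#' P and T waves are paired with the QRS they precede / follow. Beats whose
#' events cannot be assembled into monotone fiducials are returned in a
#' separate rejects table rather than raising an error.
#'
#' @param ann_path Path to the annotation text file. Columns are
#'   `[time] sample symbol subtype chan num`; a first field containing
#'   `:` is treated as the elapsed-time column and skipped.
#' @param fs Sampling frequency of the underlying record (Hz).
#' @return List with `beats` (list of `fiducial_beat`) and `rejects`
#'   (data frame with `r_peak` and `reason`).
#' @export
read_annotations <- function(ann_path, fs = 1000) {
  if (!file.exists(ann_path)) stop_ecg("annotation file not found: ", ann_path)
  lines <- readLines(ann_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list(beats = list(),
                                  rejects = empty_rejects()))
  fields <- strsplit(lines, "\\s+")
  ev <- do.call(rbind, lapply(fields, function(f) {
    if (grepl("[:.]", f[1])) f <- f[-1]   # drop elapsed-time column
    data.frame(sample = as.numeric(f[1]), symbol = f[2],
               subtype = if (length(f) >= 3) as.integer(f[3]) else 0L,
               num = if (length(f) >= 5) as.integer(f[5]) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  # events are consumed in file (stream) order: a delineator emits them
  # ordered, and out-of-order indices must surface as rejected beats rather
  # than be silently re-sorted away

  # assemble (onset, peak, offset) wave triples
  waves <- list(); open <- NULL
  peak_syms <- function(s) s %in% c("p", "t") | grepl("^[A-Za-z/]$", s)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$symbol == "(") {
      open <- list(on = e$sample, num = e$num, peak = NA, peak_sym = NA,
                   subtype = NA)
    } else if (e$symbol == ")") {
      if (!is.null(open)) {
        open$off <- e$sample
        if (is.na(open$num)) open$num <- e$num
        waves[[length(waves) + 1L]] <- open
      }
      open <- NULL
    } else if (peak_syms(e$symbol)) {
      if (!is.null(open) && is.na(open$peak)) {
        open$peak <- e$sample; open$peak_sym <- e$symbol
        open$subtype <- e$subtype
        if (is.na(open$num)) open$num <- e$num
      } else {
        # bare peak without surrounding parens: degenerate one-point wave
        waves[[length(waves) + 1L]] <- list(on = NA, off = NA,
                                            peak = e$sample,
                                            peak_sym = e$symbol,
                                            num = e$num, subtype = e$subtype)
      }
    }
  }

  wave_kind <- vapply(waves, function(w) {
    if (!is.na(w$num)) return(c("P", "QRS", "T")[w$num + 1L])
    if (identical(w$peak_sym, "p")) return("P")
    if (identical(w$peak_sym, "t")) return("T")
    "QRS"
  }, "")

  qrs_idx <- which(wave_kind == "QRS")
  beats <- list(); rejects <- empty_rejects()
  for (j in seq_along(qrs_idx)) {
    qi <- qrs_idx[j]
    q <- waves[[qi]]
    lo <- if (j > 1) qrs_idx[j - 1] else 0L
    hi <- if (j < length(qrs_idx)) qrs_idx[j + 1] else length(waves) + 1L
    p_i <- which(wave_kind == "P" & seq_along(waves) > lo &
                   seq_along(waves) < qi)
    t_i <- which(wave_kind == "T" & seq_along(waves) > qi &
                   seq_along(waves) < hi)
    pw <- if (length(p_i)) waves[[max(p_i)]] else NULL
    tw <- if (length(t_i)) waves[[min(t_i)]] else NULL
    t_type <- if (!is.null(tw) && !is.na(tw$subtype) &&
                  tw$subtype %in% 0:5) ttype_levels[tw$subtype + 1L] else NA
    fb <- tryCatch(
      fiducial_beat(p_on = if (is.null(pw)) NA else pw$on,
                    p_peak = if (is.null(pw)) NA else pw$peak,
                    p_off = if (is.null(pw)) NA else pw$off,
                    qrs_on = q$on, r_peak = q$peak, qrs_off = q$off,
                    t_on = if (is.null(tw)) NA else tw$on,
                    t_peak = if (is.null(tw)) NA else tw$peak,
                    t_off = if (is.null(tw)) NA else tw$off,
                    t_type = t_type, fs = fs),
      error = function(e) e)
    if (inherits(fb, "error")) {
      rejects <- rbind(rejects,
                       data.frame(r_peak = q$peak,
                                  reason = "non-monotone fiducials",
                                  stringsAsFactors = FALSE))
    } else {
      beats[[length(beats) + 1L]] <- fb
    }
  }
  list(beats = beats, rejects = rejects)
}

empty_rejects <- function()
  data.frame(r_peak = numeric(0), reason = character(0),
             stringsAsFactors = FALSE)

#' Write fiducial beats as an rdann-style annotation file
#'
#' Inverse of [read_annotations()] for synthetic fixtures: emits one line
#' per annotation event with columns `sample symbol subtype chan num`.
#'
#' @param fiducials List of [fiducial_beat()] objects.
#' @param path Output file path.
#' @param beat_symbol Beat label placed at each R peak.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(fiducials, path, beat_symbol = "N") {
  rows <- character(0)
  line <- function(sample, symbol, subtype = 0L, num = 0L)
    sprintf("%10d %5s %5d %5d %5d", as.integer(sample), symbol,
            as.integer(subtype), 0L, as.integer(num))
  for (fb in fiducials) {
    if (!is.na(fb$p_on)) rows <- c(rows, line(fb$p_on, "("))
    if (!is.na(fb$p_peak)) rows <- c(rows, line(fb$p_peak, "p"))
    if (!is.na(fb$p_off)) rows <- c(rows, line(fb$p_off, ")"))
    if (!is.na(fb$qrs_on)) rows <- c(rows, line(fb$qrs_on, "(", num = 1L))
    if (!is.na(fb$r_peak)) rows <- c(rows, line(fb$r_peak, beat_symbol,
                                                num = 1L))
    if (!is.na(fb$qrs_off)) rows <- c(rows, line(fb$qrs_off, ")", num = 1L))
    tt <- if (is.na(fb$t_type)) 0L else match(fb$t_type, ttype_levels) - 1L
    if (!is.na(fb$t_on)) rows <- c(rows, line(fb$t_on, "(", num = 2L))
    if (!is.na(fb$t_peak)) rows <- c(rows, line(fb$t_peak, "t",
                                                subtype = tt, num = 2L))
    if (!is.na(fb$t_off)) rows <- c(rows, line(fb$t_off, ")", num = 2L))
  }
  writeLines(rows, path)
  invisible(path)
}

# ---- beat-table interchange ----------------------------------------------

#' Read and write per-beat measurement tables
#'
#' The beat table is the pipeline's tabular interchange format: one row per
#' beat, comma-delimited with a header, `.` decimal separator, UTF-8, in a
#' fixed column order (`subject_id`, `record_id`, `label`, `beat_index`,
#' six time spans in seconds, three amplitudes in mV, nine slopes in mV/s,
#' `T_type`). The round trip is lossless for finite values.
#'
#' @param table Data frame with (at least) the schema columns.
#' @param path File path.
#' @return `write_beat_table()` returns `path` invisibly;
#'   `read_beat_table()` returns the table with `T_type` as a factor over
#'   [ttype_levels].
#' @export
write_beat_table <- function(table, path) {
  missing <- setdiff(beat_table_cols, names(table))
  if (length(missing))
    stop_ecg("beat table missing columns: ", paste(missing, collapse = ", "))
  write.csv(table[, beat_table_cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) stop_ecg("beat table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(beat_table_cols, names(tab))
  if (length(missing))
    stop_ecg("beat table at ", path, " missing columns: ",
             paste(missing, collapse = ", "))
  tab$T_type <- as.character(tab$T_type)
  tab[, beat_table_cols]
}
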