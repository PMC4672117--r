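# Shared fixtures, all built in code at test time.

# A small two-group cohort for pipeline-level tests.
small_cohort <- function(nh = 6, nd = 8, nb = 60, seed = 42) {
  simulate_beat_table(healthy_spec(n_subjects = nh, beats_per_subject = nb),
                      disease_spec(n_subjects = nd, beats_per_subject = nb),
                      seed = seed)
}

# Default geometry for waveform fixtures; override fields as needed.
beat_params <- function(...) {
  modifyList(list(rr = 1.0, pr = 0.16, qt = 0.40, p_span = 0.10,
                  qrs_span = 0.09, t_span = 0.18, p_amp = 0.15,
                  r_amp = 1.2, t_amp = 0.35, baseline = 0.1),
             list(...))
}

# Random valid beat geometry for property tests.
random_beat_params <- function() {
  p_span <- runif(1, 0.06, 0.12)
  qrs_span <- runif(1, 0.06, 0.12)
  t_span <- runif(1, 0.12, 0.22)
  list(rr = runif(1, 0.8, 1.2),
       pr = p_span + runif(1, 0.03, 0.08),
       qt = qrs_span + t_span + runif(1, 0.04, 0.12),
       p_span = p_span, qrs_span = qrs_span, t_span = t_span,
       p_amp = runif(1, 0.05, 0.3) * sample(c(-1, 1), 1),
       r_amp = runif(1, 0.5, 2) * sample(c(-1, 1), 1),
       t_amp = runif(1, 0.1, 0.6) * sample(c(-1, 1), 1),
       baseline = runif(1, -0.2, 0.2),
       p_frac = runif(1, 0.3, 0.7), r_frac = runif(1, 0.3, 0.7),
       t_frac = runif(1, 0.3, 0.7))
}

# rdann-style annotation fixture: three clean beats at fs = 1000.
write_three_beat_ann <- function(path) {
  wf <- simulate_waveform(beat_params(), fs = 1000, n_beats = 3)
  write_annotations(wf$fiducials, path)
  wf
}
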