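# Synthetic cohort generator: determinism, validation, and the generative
# law (power-law RR dependence, abnormal mixture component).

test_that("equal seeds give bitwise-identical cohorts, unequal seeds differ", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a, b)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$beats, c$beats))
})

test_that("invalid group specifications are rejected", {
  expect_error(group_spec(n_subjects = 0), "positive")
  expect_error(group_spec(rr_mean = -1), "positive")
  expect_error(group_spec(abnormal_fraction = 1.5), "0, 1")
  expect_error(group_spec(ttype_probs = rep(0.2, 6)), "sum")
  expect_error(group_spec(ttype_probs = c(0.6, 0.6, -0.2, 0, 0, 0)), "sum")
  expect_error(group_spec(abnormal_shift = c(bogus = 1)), "unknown")
  expect_error(simulate_beat_table(healthy_spec(2, 10), healthy_spec(2, 10)),
               "labels")
})

test_that("identical generative laws give two statistically identical groups", {
  h <- healthy_spec(n_subjects = 4, beats_per_subject = 200,
                    subject_cv = 0)
  d <- do.call(group_spec, modifyList(unclass(h)[
    setdiff(names(unclass(h)), c("label", "n_subjects"))],
    list(label = "disease", n_subjects = 4)))
  co <- simulate_beat_table(h, d, seed = 1)
  qt_h <- co$beats$QT[co$beats$label == "healthy"]
  qt_d <- co$beats$QT[co$beats$label == "disease"]
  # same law: a rank test should not reject at any strict level
  expect_gt(suppressWarnings(wilcox.test(qt_h, qt_d)$p.value), 0.001)
})

test_that("generated span means converge to beta * E[RR^alpha * exp(eps)]", {
  spec <- healthy_spec(n_subjects = 1, beats_per_subject = 10000,
                       subject_cv = 0)
  co <- simulate_beat_table(
    spec, disease_spec(n_subjects = 1, beats_per_subject = 10,
                       subject_cv = 0), seed = 11)
  b <- co$beats[co$beats$label == "healthy", ]
  for (v in c("PR", "QT", "Tspan")) {
    a <- spec$span_alphas[[v]]
    expected <- spec$span_betas[[v]] * mean(b$RR^a) *
      exp(spec$noise_cv^2 / 2)
    se <- sd(b[[v]]) / sqrt(nrow(b))
    expect_lt(abs(mean(b[[v]]) - expected), 3 * se)
  }
})

test_that("abnormal mixture shifts the upper tail and fattens it", {
  set.seed(17)
  base <- list(n_subjects = 2, beats_per_subject = 150, subject_cv = 0)
  p95_gap <- replicate(100, {
    seed <- sample.int(1e6, 1)
    co <- simulate_beat_table(
      do.call(healthy_spec, base),
      do.call(disease_spec, c(base, list(abnormal_fraction = 0.15,
                                         abnormal_dispersion = 0,
                                         abnormal_shift = c(QT = 0.08)))),
      seed = seed)
    q <- tapply(co$beats$QT, co$beats$label, sample_quantile, p = 95)
    q[["disease"]] > q[["healthy"]]
  })
  expect_gte(sum(p95_gap), 95)

  set.seed(5)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
  excess <- replicate(100, {
    seed <- sample.int(1e6, 1)
    co0 <- simulate_beat_table(
      do.call(healthy_spec, base),
      do.call(disease_spec, c(base, list(abnormal_fraction = 0,
                                         abnormal_dispersion = 0))),
      seed = seed)
    co1 <- simulate_beat_table(
      do.call(healthy_spec, base),
      do.call(disease_spec, c(base, list(abnormal_fraction = 0.1,
                                         abnormal_dispersion = 0,
                                         abnormal_shift = c(QT = 0.1)))),
      seed = seed)
    kurt(co1$beats$QT[co1$beats$label == "disease"]) >
      kurt(co0$beats$QT[co0$beats$label == "disease"])
  })
  # one-sided sign test at 0.01 on 100 replications
  expect_lt(binom.test(sum(excess), 100, alternative = "greater")$p.value,
            0.01)
})

test_that("waveform fixtures reproduce requested slopes and amplitudes", {
  wf <- simulate_waveform(beat_params(qrs_span = 0.04, r_amp = 0.2,
                                      r_frac = 1 / 2), fs = 1000)
  # Up-R rise of 0.2 mV over 0.02 s -> 10 mV/s; check via measurement
  m <- measure_beat(wf$signal, wf$fiducials[[1]], wf$fiducials[[2]])
  expect_equal(m$slope_Up_R, wf$truth[["slope_Up_R"]], tolerance = 1e-6)
  expect_equal(m$R_amp, 0.2, tolerance = 1e-9)
  expect_equal(m$P_amp, 0.15, tolerance = 1e-9)

  flat <- simulate_waveform(beat_params(p_amp = 0, r_amp = 0, t_amp = 0),
                            fs = 500)
  mf <- measure_beat(flat$signal, flat$fiducials[[1]], flat$fiducials[[2]])
  expect_equal(unlist(mf[grep("slope", names(mf))]),
               setNames(rep(0, 9), grep("slope", names(mf), value = TRUE)),
               tolerance = 1e-9)
  expect_equal(unname(unlist(mf[c("P_amp", "R_amp", "T_amp")])), rep(0, 3),
               tolerance = 1e-12)
})

test_that("waveform validation rejects impossible geometry", {
  expect_error(simulate_waveform(beat_params(rr = 0.4)), "RR")
  expect_error(simulate_waveform(beat_params(pr = 0.05)), "P-wave")
  expect_error(simulate_waveform(beat_params(qt = 0.2)), "QT")
  expect_error(simulate_waveform(beat_params(), fs = 100), "250")
})
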