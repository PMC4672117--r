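# Beat I/O: fiducial containers, WFDB-style signal files, rdann-style
# annotation parsing, and the beat-table interchange format.

test_that("fiducial monotonicity is enforced at construction", {
  expect_error(fiducial_beat(p_on = 100, p_peak = 90), "increasing")
  fb <- fiducial_beat(qrs_on = 100, r_peak = 140, qrs_off = 180)
  expect_true(is.na(fb$p_on))
  expect_error(fiducial_beat(r_peak = 10, t_type = "Weird"), "t_type")
})

test_that("WFDB writer/reader round-trips within format quantization", {
  wf <- simulate_waveform(beat_params(), fs = 1000, n_beats = 2)
  base <- file.path(withr::local_tempdir(), "rec")
  write_wfdb_record(wf$signal, wf$fs, base, lead = "i", gain = 200)
  rt <- read_wfdb_record(paste0(base, ".hea"), "i")
  expect_equal(rt$fs, 1000)
  expect_lt(max(abs(rt$signal - wf$signal)), 1 / (2 * 200) + 1e-12)
  expect_error(read_wfdb_record(paste0(base, ".hea"), "xyz"),
               "available leads: i")
})

test_that("multi-lead files return the requested channel", {
  td <- withr::local_tempdir()
  s1 <- sin(seq(0, 2 * pi, length.out = 100))
  s2 <- cos(seq(0, 2 * pi, length.out = 100))
  adc <- as.integer(round(rbind(s1, s2) * 200))  # interleaved two channels
  writeBin(as.vector(adc), file.path(td, "two.dat"), size = 2,
           endian = "little")
  writeLines(c("two 2 500 100",
               "two.dat 16 200(0)/mV 16 0 0 0 0 i",
               "two.dat 16 200(0)/mV 16 0 0 0 0 ii"),
             file.path(td, "two.hea"))
  rt <- read_wfdb_record(file.path(td, "two.hea"), "ii")
  expect_lt(max(abs(rt$signal - s2)), 1 / 400 + 1e-12)
})

test_that("annotation fixtures round-trip into per-beat fiducials", {
  path <- file.path(withr::local_tempdir(), "rec.ann")
  wf <- write_three_beat_ann(path)
  got <- read_annotations(path, fs = 1000)
  expect_length(got$beats, 3)
  expect_identical(nrow(got$rejects), 0L)
  for (i in 1:3)
    for (f in c("p_on", "p_peak", "p_off", "qrs_on", "r_peak", "qrs_off",
                "t_on", "t_peak", "t_off"))
      expect_equal(got$beats[[i]][[f]], wf$fiducials[[i]][[f]])
  expect_equal(got$beats[[1]]$t_type, "Normal")
})

test_that("beats with missing waves parse with absent fields, not errors", {
  path <- file.path(withr::local_tempdir(), "nop.ann")
  fb1 <- fiducial_beat(qrs_on = 100, r_peak = 140, qrs_off = 180,
                       t_on = 280, t_peak = 350, t_off = 430,
                       t_type = "Inverted")
  fb2 <- fiducial_beat(p_on = 900, p_peak = 950, p_off = 1000,
                       qrs_on = 1060, r_peak = 1100, qrs_off = 1140,
                       t_on = 1240, t_peak = 1310, t_off = 1390)
  write_annotations(list(fb1, fb2), path)
  got <- read_annotations(path)
  expect_length(got$beats, 2)
  expect_true(is.na(got$beats[[1]]$p_on))
  expect_equal(got$beats[[1]]$t_type, "Inverted")
  expect_equal(got$beats[[2]]$p_on, 900)
})

test_that("non-monotone beats land in the rejects list with a reason", {
  path <- file.path(withr::local_tempdir(), "bad.ann")
  writeLines(c("100 (  0 0 1", "140 N  0 0 1", "180 )  0 0 1",
               "430 (  0 0 2", "350 t  0 0 2", "280 )  0 0 2"), path)
  # T offset annotated before T onset: events sort to t_off < t_on
  got <- read_annotations(path)
  expect_length(got$beats, 0)
  expect_identical(got$rejects$reason, "non-monotone fiducials")
})

test_that("rdann dumps with an elapsed-time column parse identically", {
  td <- withr::local_tempdir()
  plain <- file.path(td, "a.ann"); timed <- file.path(td, "b.ann")
  wf <- write_three_beat_ann(plain)
  lines <- readLines(plain)
  writeLines(paste("0:00.123", lines), timed)
  a <- read_annotations(plain); b <- read_annotations(timed)
  expect_identical(a$beats, b$beats)
})

test_that("beat tables round-trip losslessly and check their schema", {
  co <- small_cohort(nh = 2, nd = 2, nb = 15)
  path <- file.path(withr::local_tempdir(), "beats.csv")
  write_beat_table(co$beats, path)
  rt <- read_beat_table(path)
  expect_equal(rt, co$beats, tolerance = 1e-12)

  empty <- co$beats[0, ]
  write_beat_table(empty, path)
  expect_identical(nrow(read_beat_table(path)), 0L)

  broken <- co$beats[, setdiff(names(co$beats), "RR")]
  expect_error(write_beat_table(broken, path), "RR")
  write.csv(broken, path, row.names = FALSE)
  expect_error(read_beat_table(path), "RR")
})

test_that("readers are total over the synthetic writer's output", {
  set.seed(31)
  for (i in 1:5) {
    params <- random_beat_params()
    wf <- simulate_waveform(params, fs = 500, n_beats = 3)
    td <- withr::local_tempdir()
    write_annotations(wf$fiducials, file.path(td, "r.ann"))
    got <- read_annotations(file.path(td, "r.ann"), fs = 500)
    expect_length(got$beats, 3)
    co <- small_cohort(nh = 2, nd = 2, nb = 10, seed = i)
    write_beat_table(co$beats, file.path(td, "b.csv"))
    expect_silent(read_beat_table(file.path(td, "b.csv")))
  }
})
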