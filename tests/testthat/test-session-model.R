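# Domain types and on-disk formats: field mapping, closed vocabularies,
# overlap validation, and lossless round trips.

test_that("epoch CSV maps fields, round-trips, and handles the empty case", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,stimulus,context,onset_s,offset_s,motif_bounds,source",
    "1,BOS,solitary,10.0,12.1,10.0:10.7;11.0:11.7,playback"
  ), path)
  ep <- read_epoch_table(path)
  expect_equal(nrow(ep), 1L)
  expect_equal(nrow(ep$motif_bounds[[1]]), 2L)
  expect_equal(unname(ep$motif_bounds[[1]][2, ]), c(11.0, 11.7))
  expect_identical(ep$source, "playback")

  # header-only file -> empty table
  writeLines("trial_id,stimulus,context,onset_s,offset_s,motif_bounds,source",
             path)
  expect_equal(nrow(read_epoch_table(path)), 0L)

  # full write/read round trip on a richer table
  ep2 <- tiny_epochs()
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_epoch_table(ep2, path2)
  back <- read_epoch_table(path2)
  expect_equal(back$onset_s, ep2$onset_s, tolerance = 1e-9)
  expect_equal(back$offset_s, ep2$offset_s, tolerance = 1e-9)
  for (i in seq_len(nrow(ep2)))
    expect_equal(back$motif_bounds[[i]], ep2$motif_bounds[[i]],
                 tolerance = 1e-9)
})

test_that("unknown labels are parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trial_id,stimulus,context,onset_s,offset_s,motif_bounds,source",
    "1,SONG,solitary,10,12,10:12,playback"
  ), path)
  expect_error(read_epoch_table(path), "line 2.*SONG")
  writeLines(c(
    "trial_id,stimulus,context,onset_s,offset_s,motif_bounds,source",
    "1,WN,solitary,10,12,10:12,playback",
    "2,WN,alone,20,22,20:22,playback"
  ), path)
  expect_error(read_epoch_table(path), "line 3.*alone")
})

test_that("epoch validation enforces ordering, nesting and the WN rule", {
  expect_error(
    epoch_table(1, "BOS", "solitary", 10, 9, list(matrix(c(10, 9), ncol = 2)),
                "playback"),
    "onset_s < offset_s")
  # overlapping epochs
  expect_error(
    epoch_table(1:2, c("WN", "WN"), "solitary", c(10, 11), c(12, 13),
                list(matrix(c(10, 12), ncol = 2), matrix(c(11, 13), ncol = 2)),
                "playback"),
    "overlap")
  # WN must span the whole stimulus with exactly one bound
  expect_error(
    epoch_table(1, "WN", "solitary", 10, 12,
                list(matrix(c(10, 11), ncol = 2)), "playback"),
    "WN")
  # motif bounds must not overlap each other
  expect_error(
    epoch_table(1, "BOS", "solitary", 10, 12,
                list(matrix(c(10, 11, 10.5, 11.5), ncol = 2, byrow = TRUE)),
                "playback"),
    "overlap")
})

test_that("random non-overlapping interval sets validate; overlaps reject", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    gaps <- runif(n, 0.5, 3)
    durs <- runif(n, 0.5, 2)
    onsets <- 5 + cumsum(gaps + durs) - durs
    ep <- epoch_table(seq_len(n), "WN", "solitary", onsets, onsets + durs,
                      lapply(seq_len(n), function(i)
                        matrix(c(onsets[i], onsets[i] + durs[i]), ncol = 2)),
                      "playback")
    expect_s3_class(ep, "epoch_table")
    # perturb one onset into its predecessor to force an overlap
    k <- sample(2:n, 1)
    bad_on <- onsets; bad_on[k] <- onsets[k - 1] + durs[k - 1] / 2
    expect_error(
      epoch_table(seq_len(n), "WN", "solitary", bad_on, bad_on + durs,
                  lapply(seq_len(n), function(i)
                    matrix(c(bad_on[i], bad_on[i] + durs[i]), ncol = 2)),
                  "playback"),
      "overlap")
  }
})

test_that("spike table sorts, splits units, rejects negative times", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,spike_time_s", "u1,0.5", "u1,0.2", "u2,1.0"), path)
  trains <- read_spike_table(path, session_duration_s = 10)
  expect_length(trains, 2L)
  expect_equal(trains$u1$spike_times_s, c(0.2, 0.5))
  writeLines(c("unit_id,spike_time_s", "u1,-1.0"), path)
  expect_error(read_spike_table(path), "negative")
})

test_that("spike and waveform tables round-trip", {
  dur <- 100
  trains <- list(u1 = poisson_train(5, dur, 1, "u1"),
                 u2 = poisson_train(2, dur, 2, "u2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(trains, path)
  back <- read_spike_table(path, session_duration_s = dur)
  expect_equal(back$u1$spike_times_s, trains$u1$spike_times_s,
               tolerance = 1e-9)
  expect_equal(back$u2$spike_times_s, trains$u2$spike_times_s,
               tolerance = 1e-9)

  wfs <- list(u1 = waveform("u1", sin(seq(0, 3, length.out = 60)), 30000))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_waveform_table(wfs, path2)
  back2 <- read_waveform_table(path2)
  expect_equal(back2$u1$samples, wfs$u1$samples, tolerance = 1e-7)
  expect_equal(back2$u1$sampling_rate_hz, 30000)
})

test_that("metrics table: cardinality, header-only empty case, round trip", {
  m <- expand.grid(stimulus = ncm_stimuli(),
                   context = c("solitary", "social"),
                   stringsAsFactors = FALSE)
  set.seed(4)
  m <- cbind(unit_id = "u1", unit_class = "BS", m, n_trials = 20L,
             mean_fr_hz = runif(8, 5, 30), mean_blfr_hz = runif(8, 2, 12),
             z = rnorm(8), rs = rnorm(8, 5), ssa_ratio = runif(8),
             offset_ratio = runif(8, 0, 3), offset_z = rnorm(8),
             responsive = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(m, path)
  back <- read_metrics_table(path)
  expect_equal(nrow(back), 8L) # 1 unit x 4 stimuli x 2 contexts
  for (cn in c("mean_fr_hz", "mean_blfr_hz", "z", "rs", "ssa_ratio",
               "offset_ratio", "offset_z"))
    expect_equal(back[[cn]], m[[cn]], tolerance = 1e-9)

  empty <- m[0, , drop = FALSE]
  write_metrics_table(empty, path)
  expect_equal(nrow(read_metrics_table(path)), 0L)
  expect_equal(length(readLines(path)), 1L) # header only
})

test_that("LFP binary round-trips to float32 precision", {
  set.seed(9)
  lfp <- lfp_recording(matrix(rnorm(4000), ncol = 4), 500)
  base <- withr::local_tempfile()
  write_lfp(lfp, base)
  back <- read_lfp(base)
  expect_equal(back$channels, lfp$channels)
  expect_equal(back$sampling_rate_hz, 500)
  # 32-bit storage: relative error bounded by float32 epsilon
  expect_lt(max(abs(back$signal - lfp$signal)), 1e-6)
})

test_that("session round-trips through a directory", {
  cfg <- one_unit_config(baseline = 8, gain = 2, n_trials = 5, seed = 3)
  s <- generate_session(cfg, "sess1")
  dir <- withr::local_tempdir()
  write_session(s, dir)
  back <- read_session(dir)
  expect_equal(back$session_id, "sess1")
  expect_equal(back$epochs$onset_s, s$epochs$onset_s, tolerance = 1e-9)
  expect_equal(back$spike_trains$u1$spike_times_s,
               s$spike_trains$u1$spike_times_s, tolerance = 1e-9)
  expect_equal(back$waveforms$u1$samples, s$waveforms$u1$samples,
               tolerance = 1e-7)
})

test_that("session constructor enforces waveform/train matching", {
  ep <- tiny_epochs()
  tr <- list(poisson_train(5, 100, 1, "u1"))
  wf <- list(waveform("u9", c(-(1:5), 3:1, 0, 0), 30000))
  expect_error(ncm_session("s", ep, tr, wf), "u9")
})
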