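# Response statistics: frozen direct-formula values, degenerate-input
# contracts, invariance properties, and oracle equivalence on random
# series.

test_that("peak_to_peak_width measures trough-to-peak time", {
  s <- rep(0, 60); s[30] <- -1; s[45] <- 0.5
  expect_equal(peak_to_peak_width(waveform("u", s, 30000)), 0.5)
  # symmetric single negative lobe: no positive peak after trough
  lobe <- -exp(-((1:100) - 50)^2 / 50)
  expect_error(peak_to_peak_width(waveform("u", lobe, 30000)), "shape")
  # generator round trip at the decision boundary
  u <- unit_sim_params("u", c(solitary = 5), flat_gains(1, "solitary"),
                       waveform_width_ms = 0.43)
  w <- generate_waveform(u, seed = 8)
  expect_equal(peak_to_peak_width(w), 0.43, tolerance = (1000 / 30000) / 0.43)
})

test_that("classify_unit applies the 0.43 ms rule with equality -> NS", {
  expect_identical(classify_unit(0.50), "BS")
  expect_identical(classify_unit(0.30), "NS")
  expect_identical(classify_unit(0.43), "NS")
})

test_that("motif_rate uses the half-open window", {
  tr <- spike_train("u", c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5), 10)
  expect_equal(motif_rate(tr, c(1.0, 1.5)), 5 / 0.5) # 1.5 excluded
  expect_equal(motif_rate(tr, c(5, 6)), 0)
  expect_error(motif_rate(tr, c(2, 2)), "window")
})

test_that("playback baseline is [onset-2, onset-1) with a 1 s buffer", {
  tr <- spike_train("u", c(8.1, 8.5, 8.9), 100)
  expect_equal(baseline_rate_playback(tr, list(onset_s = 10)), 3)
  # spikes only inside the buffer second do not count
  tr2 <- spike_train("u", c(9.2, 9.5, 9.8), 100)
  expect_equal(baseline_rate_playback(tr2, list(onset_s = 10)), 0)
  expect_error(baseline_rate_playback(tr, list(onset_s = 1.5)), "before")
})

test_that("vocal baseline pools flanks with 1.5 s buffers", {
  bout <- epoch_table(1, "BOS", "directed", 20, 22,
                      list(matrix(c(20, 20.8, 21, 21.8), ncol = 2,
                                  byrow = TRUE)),
                      "vocalization")
  # spikes only within 1.5 s of the bout edges -> excluded
  tr <- spike_train("u", c(19.0, 18.6, 22.5, 23.0), 100)
  expect_equal(baseline_rate_vocal(tr, bout), 0)
  # spikes in the flanks count; pooled over 2 x window_s
  tr2 <- spike_train("u", c(17.6, 17.9, 23.4, 24.2), 100)
  expect_equal(baseline_rate_vocal(tr2, bout), 4 / 2)
  # single-motif bout: first = last motif
  bout1 <- epoch_table(1, "BOS", "directed", 20, 21,
                       list(matrix(c(20, 20.8), ncol = 2)), "vocalization")
  # pre window [17.5, 18.5): 17.6, 17.9; post [22.3, 23.3): none -> 2 / 2 s
  expect_equal(baseline_rate_vocal(tr2, bout1), 1)
  # uniform Poisson train recovers its rate
  tr3 <- poisson_train(10, 1000, seed = 15)
  bouts <- lapply(seq(50, 900, by = 50), function(on)
    epoch_table(1, "BOS", "directed", on, on + 2,
                list(matrix(c(on, on + 2), ncol = 2)), "vocalization"))
  rates <- vapply(bouts, function(b) baseline_rate_vocal(tr3, b), numeric(1))
  expect_equal(mean(rates), 10, tolerance = 0.2)
})

test_that("z_score matches the frozen direct-formula value", {
  # (11 - 6) / sqrt(2 + 2 - 2*(-2)) = 5 / sqrt(8)
  ser <- make_series(c(10, 12), c(7, 5))
  expect_equal(z_score(ser), 5 / sqrt(8), tolerance = 1e-12)
  # identical series -> 0/0 defined as 0
  expect_equal(z_score(make_series(c(4, 4, 4), c(4, 4, 4))), 0)
  # translation invariance
  set.seed(1)
  fr <- rnorm(20, 10); bl <- rnorm(20, 5)
  expect_equal(z_score(make_series(fr, bl)),
               z_score(make_series(fr + 7.3, bl + 7.3)), tolerance = 1e-12)
  # nonzero numerator over zero denominator -> undefined
  expect_true(is.na(z_score(make_series(c(5, 6), c(1, 2)))))
  expect_error(z_score(make_series(4, 1)), "at least 2")
  # the no-radical variant divides by the raw variance sum
  expect_equal(z_score(ser, sqrt_denominator = FALSE), 5 / 8,
               tolerance = 1e-12)
})

test_that("response_strength is the mean paired difference", {
  expect_equal(response_strength(make_series(c(10, 12), c(7, 5))), 5)
  expect_equal(response_strength(make_series(c(3, 3), c(3, 3))), 0)
  expect_equal(response_strength(make_series(4, 1)), 3)
})

test_that("d_prime matches the frozen value and is antisymmetric", {
  a <- make_series(c(5, 5, 7, 7), c(0, 0, 0, 0))
  b <- make_series(c(1, 1, 3, 3), c(0, 0, 0, 0))
  # RS 6 vs 2, both variances 4/3: 2*4/sqrt(8/3)
  expect_equal(d_prime(a, b), 8 / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(d_prime(a, a), 0)
  expect_equal(d_prime(b, a), -d_prime(a, b), tolerance = 1e-12)
  # zero variances with differing RS -> undefined
  expect_true(is.na(d_prime(make_series(c(5, 5), c(0, 0)),
                            make_series(c(1, 1), c(0, 0)))))
})

test_that("d_prime antisymmetry and zero diagonal on random series", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    a <- make_series(rnorm(n, 10, 3), rnorm(n, 5, 2))
    b <- make_series(rnorm(n, 8, 3), rnorm(n, 5, 2))
    expect_equal(d_prime(a, b), -d_prime(b, a), tolerance = 1e-12)
    expect_equal(d_prime(a, a), 0)
  }
})

test_that("ssa_ratio takes last-five over first-five presentation rates", {
  expect_equal(ssa_ratio(make_series(c(rep(10, 5), rep(5, 5)),
                                     rep(0, 10))), 0.5)
  expect_equal(ssa_ratio(make_series(rep(7, 12), rep(0, 12))), 1.0)
  expect_error(ssa_ratio(make_series(rep(7, 9), rep(0, 9))), "10")
  expect_true(is.na(ssa_ratio(make_series(c(rep(0, 5), rep(5, 5)),
                                          rep(0, 10)))))
  # motif-level entries are averaged within each presentation first
  fr <- c(rbind(c(rep(10, 5), rep(5, 5)), c(rep(14, 5), rep(7, 5))))
  idx <- rep(1:10, each = 2)
  expect_equal(ssa_ratio(make_series(fr, rep(0, 20), idx)), 0.5)
})

test_that("the 0.6 SSA threshold separates adapting from retained units", {
  mk <- function(ssa_values, responsive = TRUE) {
    data.frame(unit_id = "u", unit_class = "BS",
               stimulus = ncm_stimuli(), context = "solitary",
               n_trials = 20L, mean_fr_hz = 10, mean_blfr_hz = 5, z = 1,
               rs = 5, ssa_ratio = ssa_values, offset_ratio = 1,
               offset_z = 0, responsive = responsive)
  }
  # one stimulus above threshold suffices
  expect_equal(attr(select_analysis_units(mk(c(0.9, 0.2, 0.1, 0.1))),
                    "retained_units"), "u")
  # all at or below threshold -> excluded (0.6 itself is not > 0.6)
  expect_length(attr(select_analysis_units(mk(c(0.6, 0.5, 0.2, 0.1))),
                     "retained_units"), 0)
  # non-responsive excluded regardless of SSA
  expect_length(attr(select_analysis_units(mk(c(0.95, 0.9, 0.9, 0.9),
                                              responsive = FALSE)),
                     "retained_units"), 0)
})

test_that("offset_ratio and offset_z behave per contract", {
  tr <- spike_train("u", 12 + c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 100)
  expect_equal(offset_ratio(tr, 12, blfr_hz = 3), 2.0)
  expect_equal(offset_ratio(tr, 12, blfr_hz = 6), 1.0)
  expect_true(is.na(offset_ratio(tr, 12, blfr_hz = 0)))
  # offset rates equal to baselines -> zero Z
  expect_equal(offset_z(make_series(c(3, 5, 4), c(3, 5, 4))), 0)
  # perfectly correlated shift: denominator collapses, numerator does not
  expect_true(is.na(offset_z(make_series(c(6, 8), c(3, 5)))))
  # swapping series roles flips the sign
  a <- make_series(c(6, 9, 7), c(3, 4, 5))
  b <- make_series(c(3, 4, 5), c(6, 9, 7))
  expect_equal(offset_z(a), -offset_z(b), tolerance = 1e-12)
})

test_that("programmed offset gain is recovered by the offset ratio", {
  cfg <- one_unit_config(baseline = 10, gain = 1, offset_gain = 2,
                         n_trials = 13, contexts = "solitary", seed = 6)
  s <- generate_session(cfg)
  ratios <- vapply(ncm_stimuli(), function(st) {
    off <- build_offset_series(s$spike_trains$u1, s$epochs, st, "solitary")
    mean_offset_ratio(off)
  }, numeric(1))
  # ~50 presentations pooled across stimuli at 10 Hz baseline
  expect_equal(mean(ratios), 2.0, tolerance = 0.15)
})

test_that("is_responsive flags forced separation and calibrates near alpha", {
  set.seed(33)
  fr <- rnorm(20, 15, 1); bl <- fr - 10 + rnorm(20, 0, 0.5)
  expect_true(is_responsive(fr, bl))
  expect_false(is_responsive(rep(3, 10), rep(3, 10))) # all-zero differences
  expect_error(is_responsive(5, 3), "at least 2")
  # type-I calibration: null units flagged at ~5%
  set.seed(34)
  flags <- vapply(1:1000, function(i)
    is_responsive(rnorm(20, 10, 2), rnorm(20, 10, 2)), logical(1))
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.07)
})

test_that("increasing evoked gain increases estimated Z and RS", {
  med_stats <- function(gain) {
    vals <- vapply(1:8, function(r) {
      cfg <- one_unit_config(baseline = 10, gain = gain, n_trials = 10,
                             contexts = "solitary", seed = 100 + r)
      s <- generate_session(cfg)
      ser <- build_response_series(s$spike_trains$u1, s$epochs, "BOS",
                                   "solitary")
      c(z_score(ser), response_strength(ser))
    }, numeric(2))
    apply(vals, 1, median)
  }
  lo <- med_stats(1.5); hi <- med_stats(3)
  expect_gt(hi[1], lo[1]) # Z
  expect_gt(hi[2], lo[2]) # RS
})

test_that("metric implementations agree with independent oracles", {
  # direct-sum re-implementations, coded without var/cov
  oracle_rs <- function(fr, bl) sum(fr - bl) / length(fr)
  oracle_var <- function(x) {
    m <- sum(x) / length(x); sum((x - m)^2) / (length(x) - 1)
  }
  oracle_cov <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) / (length(x) - 1)
  }
  oracle_z <- function(fr, bl) {
    (sum(fr) / length(fr) - sum(bl) / length(bl)) /
      sqrt(oracle_var(fr) + oracle_var(bl) - 2 * oracle_cov(fr, bl))
  }
  oracle_d <- function(fa, ba, fb, bb) {
    2 * (oracle_rs(fa, ba) - oracle_rs(fb, bb)) /
      sqrt(oracle_var(fa - ba) + oracle_var(fb - bb))
  }
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    fr <- rnorm(n, 12, 4); bl <- rnorm(n, 6, 2)
    fr2 <- rnorm(n, 9, 4); bl2 <- rnorm(n, 6, 2)
    expect_equal(z_score(make_series(fr, bl)), oracle_z(fr, bl),
                 tolerance = 1e-12)
    expect_equal(response_strength(make_series(fr, bl)), oracle_rs(fr, bl),
                 tolerance = 1e-12)
    expect_equal(d_prime(make_series(fr, bl), make_series(fr2, bl2)),
                 oracle_d(fr, bl, fr2, bl2), tolerance = 1e-12)
  }
})
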