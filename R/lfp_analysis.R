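# LFP branch: preprocessing (mains notch then common average reference),
# before/during/after envelope segmentation, Welch power spectral density
# restricted to 0-50 Hz with channel averaging, and the two trial-label
# permutation procedures with sign-directed p-values.

# Second-order IIR notch (RBJ biquad). Only the >= 20 dB attenuation at the
# notch frequency is normative; the filter family is an implementation
# choice. Applied causally with zero initial conditions via a vectorized
# MA pass plus a recursive AR pass.
notch_filter <- function(x, fs, f0 = 60, q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  b <- b / a[1]; a <- a / a[1]
  n <- length(x)
  v <- b[1] * x +
    b[2] * c(0, x[-n]) +
    b[3] * c(0, 0, x[-c(n - 1, n)])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

#' Preprocess an LFP recording
#'
#' Applies a 60 Hz notch filter to every channel, then a common average
#' reference (CAR): the per-sample cross-channel mean is subtracted from
#' each channel, removing shared artifact. With a single channel the CAR
#' step is skipped with a warning.
#'
#' @param lfp An [lfp_recording()].
#' @param line_hz Notch frequency (default 60).
#' @param q Notch quality factor (default 30; gives >= 20 dB attenuation at
#'   the line frequency and < 1 dB in the 0--50 Hz analysis band).
#' @return A preprocessed [lfp_recording()].
#' @export
preprocess_lfp <- function(lfp, line_hz = 60, q = 30) {
  sig <- lfp$signal
  for (ci in seq_len(ncol(sig)))
    sig[, ci] <- notch_filter(sig[, ci], lfp$sampling_rate_hz, line_hz, q)
  if (ncol(sig) >= 2) {
    sig <- sig - rowMeans(sig)
  } else {
    warning("single channel: common average reference skipped")
  }
  lfp_recording(sig, lfp$sampling_rate_hz, lfp$channels)
}

#' Extract before/during/after envelopes around one stimulus
#'
#' `before` is the 2 s segment ending 0.5 s before onset, `during` spans the
#' stimulus, and `after` is the 2 s segment starting 0.5 s after offset.
#' Epochs without 2.5 s of recording on both sides raise a condition of
#' class `ncmephys_pad_error` so callers can drop the trial with a logged
#' reason.
#'
#' @param lfp An [lfp_recording()].
#' @param epoch One epoch-table row.
#' @param flank_s Flank duration (default 2 s).
#' @param buffer_s Buffer between flank and stimulus (default 0.5 s).
#' @return List with `before`, `during`, `after` signal matrices.
#' @export
extract_envelopes <- function(lfp, epoch, flank_s = 2, buffer_s = 0.5) {
  fs <- lfp$sampling_rate_hz
  n <- nrow(lfp$signal)
  cut <- function(start_s, end_s) {
    i0 <- floor(start_s * fs) + 1
    i1 <- floor(end_s * fs)
    if (i0 < 1 || i1 > n)
      stop(structure(
        class = c("ncmephys_pad_error", "error", "condition"),
        list(message = sprintf(
          "epoch at %.3f s lacks %.1f s padding in the recording",
          epoch$onset_s, flank_s + buffer_s), call = NULL)))
    lfp$signal[i0:i1, , drop = FALSE]
  }
  list(
    before = cut(epoch$onset_s - buffer_s - flank_s, epoch$onset_s - buffer_s),
    during = cut(epoch$onset_s, epoch$offset_s),
    after = cut(epoch$offset_s + buffer_s, epoch$offset_s + buffer_s + flank_s)
  )
}

#' Welch power spectral density, channel-averaged, 0--50 Hz
#'
#' Hann-windowed segments of `seg_s` seconds with 50% overlap, mean-averaged
#' periodograms (one-sided density scaling), restricted to frequencies up to
#' `fmax`. Matrix input is treated as channels in columns and the PSD is
#' averaged across channels before any statistics.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 1, about 1 Hz bins).
#' @param overlap Fractional overlap (default 0.5).
#' @param fmax Upper analysis frequency (default 50 Hz).
#' @return List with `frequency_hz` and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 1, overlap = 0.5, fmax = 50) {
  x <- as.matrix(x)
  L <- round(seg_s * fs)
  if (nrow(x) < L)
    stop("segment shorter than one Welch window")
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, nrow(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (ci in seq_len(ncol(x))) {
    for (s0 in starts) {
      seg <- x[s0:(s0 + L - 1), ci]
      seg <- (seg - mean(seg)) * w
      p <- Mod(stats::fft(seg)[1:nf])^2 * scale
      if (nf > 2) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] # one-sided doubling
      if (L %% 2 == 1) p[nf] <- 2 * p[nf]
      acc <- acc + p
    }
  }
  pow <- acc / (length(starts) * ncol(x))
  freq <- (0:(nf - 1)) * fs / L
  keep <- freq <= fmax
  list(frequency_hz = freq[keep], power = pow[keep])
}

#' Per-trial channel-averaged PSD matrices for one envelope
#'
#' Computes the Welch PSD of the requested envelope for every epoch in
#' `epochs`, returning a trials-by-frequency matrix. Trials lacking padding
#' are dropped; their count is recorded in `attr(, "n_dropped")`.
#'
#' @param lfp A (preprocessed) [lfp_recording()].
#' @param epochs Epoch-table rows to analyze.
#' @param envelope One of `"before"`, `"during"`, `"after"`.
#' @inheritParams welch_psd
#' @return Matrix with `attr(, "frequency_hz")` and `attr(, "n_dropped")`.
#' @export
trial_psd_matrix <- function(lfp, epochs, envelope = c("during", "before",
                                                       "after"),
                             seg_s = 1, overlap = 0.5, fmax = 50) {
  envelope <- match.arg(envelope)
  rows <- list(); freq <- NULL; dropped <- 0L
  for (i in seq_len(nrow(epochs))) {
    env <- tryCatch(extract_envelopes(lfp, epochs[i, ]),
                    ncmephys_pad_error = function(e) NULL)
    if (is.null(env)) { dropped <- dropped + 1L; next }
    psd <- welch_psd(env[[envelope]], lfp$sampling_rate_hz, seg_s, overlap,
                     fmax)
    freq <- psd$frequency_hz
    rows[[length(rows) + 1L]] <- psd$power
  }
  out <- do.call(rbind, rows)
  attr(out, "frequency_hz") <- freq
  attr(out, "n_dropped") <- dropped
  out
}

# Shared permutation machinery: per-frequency mean difference of
# log10-power between two trial groups, null built by relabeling trials,
# sign-directed p-values. One seeded RNG stream per comparison; the same
# label permutations are reused across the frequency grid of one call.
perm_mean_diff_test <- function(a, b, frequencies, n_perm, seed, alpha,
                                log_transform = TRUE) {
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("permutation test needs at least 3 trials per group")
  if (log_transform) {
    floor_eps <- .Machine$double.xmin
    a <- log10(pmax(a, floor_eps))
    b <- log10(pmax(b, floor_eps))
  }
  na <- nrow(a); nb <- nrow(b)
  pooled <- rbind(a, b)
  stat <- colMeans(a) - colMeans(b)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(na + nb, na)
      colMeans(pooled[idx, , drop = FALSE]) -
        colMeans(pooled[-idx, , drop = FALSE])
    }, numeric(length(stat)))
  })
  perm_stats <- matrix(perm_stats, nrow = length(stat)) # freq x n_perm
  p <- vapply(seq_along(stat), function(j) {
    if (stat[j] > 0) mean(perm_stats[j, ] >= stat[j])
    else if (stat[j] < 0) mean(perm_stats[j, ] <= stat[j])
    else 1
  }, numeric(1))
  data.frame(
    frequency_hz = frequencies,
    stat = unname(stat),
    p_value = p,
    n_permutations = n_perm,
    # the sign-directed p is one tail of a two-sided test, so the flag
    # compares it to alpha/2 to control the two-sided error at alpha
    significant = p < alpha / 2
  )
}

#' Stimulus-vs-baseline LFP permutation test
#'
#' Per frequency, independently: the empirical statistic is the mean
#' difference of log10 power between stimulus-envelope and baseline-envelope
#' trials; the null is simulated by scrambling the trial-level
#' stimulus/baseline labels `n_perm` times (default 2500). The p-value is
#' sign-directed: the fraction of permuted statistics at least as large as a
#' positive empirical statistic, or at least as small as a negative one.
#' Because that is a single tail, the `significant` flag compares p to
#' `alpha / 2`, which controls the two-sided error at `alpha`.
#'
#' @param psd_stim,psd_base Trials-by-frequency power matrices on a common
#'   grid (>= 3 trials each).
#' @param frequencies Frequency grid; defaults to the `frequency_hz`
#'   attribute of `psd_stim`.
#' @param n_perm Number of permutations (default 2500).
#' @param seed Integer seed for the comparison's RNG stream.
#' @param alpha Significance level (default 0.01).
#' @return Data frame `frequency_hz, stat, p_value, n_permutations,
#'   significant`. A reported p of 0 means "< 1 / n_perm".
#' @export
permutation_test_stimulus <- function(psd_stim, psd_base, frequencies = NULL,
                                      n_perm = 2500, seed = 1, alpha = 0.01) {
  if (is.null(frequencies)) frequencies <- attr(psd_stim, "frequency_hz")
  perm_mean_diff_test(psd_stim, psd_base, frequencies, n_perm, seed, alpha,
                      log_transform = TRUE)
}

#' Context LFP permutation test on baseline-subtracted power
#'
#' Inputs are per-trial baseline-subtracted log10 PSDs (stimulus minus
#' baseline envelope) for the two social conditions; condition labels are
#' permuted. Same sign-directed p convention as
#' [permutation_test_stimulus()].
#'
#' @param bsub_ctx1,bsub_ctx2 Trials-by-frequency baseline-subtracted
#'   log-power matrices (>= 3 trials each).
#' @inheritParams permutation_test_stimulus
#' @export
permutation_test_context <- function(bsub_ctx1, bsub_ctx2, frequencies = NULL,
                                     n_perm = 2500, seed = 1, alpha = 0.01) {
  if (is.null(frequencies)) frequencies <- attr(bsub_ctx1, "frequency_hz")
  perm_mean_diff_test(bsub_ctx1, bsub_ctx2, frequencies, n_perm, seed, alpha,
                      log_transform = FALSE)
}

#' Per-trial baseline-subtracted log-power matrix
#'
#' For each epoch: log10 PSD of the during envelope minus log10 PSD of the
#' chosen baseline envelope (channel-averaged before the log).
#'
#' @param lfp A (preprocessed) [lfp_recording()].
#' @param epochs Epoch-table rows.
#' @param baseline `"before"` (default) or `"after"`.
#' @inheritParams welch_psd
#' @return Matrix with `frequency_hz` / `n_dropped` attributes.
#' @export
baseline_subtracted_psd <- function(lfp, epochs, baseline = c("before",
                                                              "after"),
                                    seg_s = 1, overlap = 0.5, fmax = 50) {
  baseline <- match.arg(baseline)
  during <- trial_psd_matrix(lfp, epochs, "during", seg_s, overlap, fmax)
  base <- trial_psd_matrix(lfp, epochs, baseline, seg_s, overlap, fmax)
  floor_eps <- .Machine$double.xmin
  out <- log10(pmax(during, floor_eps)) - log10(pmax(base, floor_eps))
  attr(out, "frequency_hz") <- attr(during, "frequency_hz")
  attr(out, "n_dropped") <- attr(during, "n_dropped")
  out
}

#' Run all stimulus-vs-baseline LFP tests for a session
#'
#' Preprocesses the LFP, then for every stimulus x context cell with enough
#' trials runs the stimulus-vs-baseline permutation test against the chosen
#' baseline envelope.
#'
#' @param session An [ncm_session()] with an LFP.
#' @param baseline `"before"` (default) or `"after"`.
#' @param n_perm Permutations per comparison (default 2500).
#' @param alpha Significance level (default 0.01).
#' @param seed Master seed; each comparison derives its own stream.
#' @return Data frame `comparison, stimulus, context, frequency_hz, stat, p,
#'   significant` plus a `n_dropped` attribute.
#' @export
lfp_stimulus_tests <- function(session, baseline = "before", n_perm = 2500,
                               alpha = 0.01, seed = 1) {
  stopifnot(!is.null(session$lfp))
  lfp <- preprocess_lfp(session$lfp)
  epochs <- session$epochs
  out <- list(); dropped <- 0L
  for (ctx in intersect(ncm_contexts(), unique(epochs$context))) {
    for (st in intersect(ncm_stimuli(), unique(epochs$stimulus))) {
      ep <- epochs[epochs$stimulus == st & epochs$context == ctx &
                     epochs$source == "playback", , drop = FALSE]
      if (nrow(ep) < 3) next
      during <- trial_psd_matrix(lfp, ep, "during")
      base <- trial_psd_matrix(lfp, ep, baseline)
      dropped <- dropped + attr(during, "n_dropped")
      if (is.null(during) || is.null(base) || nrow(during) < 3 ||
          nrow(base) < 3) next
      res <- permutation_test_stimulus(
        during, base, attr(during, "frequency_hz"), n_perm,
        seed = derive_seed(seed, paste("lfp-stim", st, ctx)), alpha = alpha)
      res$comparison <- paste0("stimulus_vs_", baseline)
      res$stimulus <- st
      res$context <- ctx
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_dropped") <- dropped
  res
}
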