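# Synthetic-session generator: block-randomized playback schedules,
# inhomogeneous-Poisson spike trains with trial-level adaptation and offset
# responses, biphasic waveform templates, and 1/f LFP with stimulus-locked
# band-power effects. The generator is context-agnostic machinery; context
# effects enter only through the per-context parameter maps.

#' Simulation parameters for one unit
#'
#' @param unit_id Unit identifier.
#' @param baseline_rate_hz Named numeric: baseline rate per context.
#' @param evoked_gain Named list per context of named numeric per stimulus:
#'   multiplicative gain on baseline during motif windows.
#' @param offset_gain Named numeric per context: gain on baseline during the
#'   1 s post-offset window (default 1 = no offset response).
#' @param adaptation_floor Asymptotic fraction of the initial evoked rate
#'   across repeated presentations, in (0, 1]; 1 disables adaptation.
#' @param adaptation_tau_trials Trial-constant of the exponential decay.
#' @param unit_class `"BS"` or `"NS"`; sets the default waveform width
#'   (0.60 ms / 0.30 ms) when `waveform_width_ms` is not given.
#' @param waveform_width_ms Trough-to-peak width of the generated template.
#' @return An object of class `unit_sim_params`.
#' @export
unit_sim_params <- function(unit_id, baseline_rate_hz, evoked_gain,
                            offset_gain = NULL, adaptation_floor = 1,
                            adaptation_tau_trials = 10,
                            unit_class = c("BS", "NS"),
                            waveform_width_ms = NULL) {
  unit_class <- match.arg(unit_class)
  if (any(baseline_rate_hz < 0)) stop("baseline rates must be >= 0")
  if (adaptation_floor <= 0 || adaptation_floor > 1)
    stop("adaptation_floor must lie in (0, 1]")
  if (adaptation_tau_trials <= 0) stop("adaptation_tau_trials must be > 0")
  for (ctx in names(evoked_gain))
    if (any(unlist(evoked_gain[[ctx]]) < 0)) stop("gains must be >= 0")
  if (is.null(offset_gain))
    offset_gain <- stats::setNames(rep(1, length(baseline_rate_hz)),
                                   names(baseline_rate_hz))
  if (is.null(waveform_width_ms))
    waveform_width_ms <- if (unit_class == "BS") 0.60 else 0.30
  structure(
    list(unit_id = as.character(unit_id),
         unit_class = unit_class,
         baseline_rate_hz = baseline_rate_hz,
         evoked_gain = evoked_gain,
         offset_gain = offset_gain,
         adaptation_floor = adaptation_floor,
         adaptation_tau_trials = adaptation_tau_trials,
         waveform_width_ms = waveform_width_ms),
    class = "unit_sim_params"
  )
}

#' Simulation parameters for the LFP channel bank
#'
#' @param n_channels Number of channels (default 4).
#' @param sampling_rate_hz LFP sampling rate (default 500 Hz).
#' @param noise_spectrum_exponent Exponent alpha of the 1/f^alpha background.
#' @param line_hz Mains interference frequency (default 60 Hz).
#' @param band_effects Data frame with columns `stimulus, context,
#'   center_hz, bandwidth_hz, power_gain`: in-band power is multiplied by
#'   `power_gain` (>= 1) while a matching stimulus plays. The band must stay
#'   within the 0--50 Hz analysis range.
#' @return An object of class `lfp_sim_params`.
#' @export
lfp_sim_params <- function(n_channels = 4, sampling_rate_hz = 500,
                           noise_spectrum_exponent = 1, line_hz = 60,
                           band_effects = NULL) {
  if (!is.null(band_effects) && nrow(band_effects) > 0) {
    if (any(band_effects$center_hz + band_effects$bandwidth_hz / 2 > 50))
      stop("band effects must lie within the 0-50 Hz analysis range")
    if (any(band_effects$power_gain < 1))
      stop("power_gain must be >= 1")
  }
  structure(
    list(n_channels = as.integer(n_channels),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         noise_spectrum_exponent = noise_spectrum_exponent,
         line_hz = line_hz, band_effects = band_effects),
    class = "lfp_sim_params"
  )
}

#' Session-level simulation configuration
#'
#' Defaults emulate a playback experiment: the four stimulus classes
#' delivered in randomized blocks, 25--50 blocks per context, the solitary
#' block before the social block, 2 s stimuli of three motifs, and an
#' inter-trial gap wide enough that baseline and offset windows (and the
#' 2.5 s LFP flanks) never touch an adjacent stimulus.
#'
#' @param units List of [unit_sim_params()].
#' @param n_trials_per_stimulus Blocks per context (>= 5; adaptation
#'   quantification additionally needs >= 10).
#' @param stimulus_duration_s Stimulus length (default 2 s).
#' @param motifs_per_song Motifs per song stimulus (default 3).
#' @param inter_trial_interval_s Gap between stimulus offset and the next
#'   onset; must be >= 4.5 s, default 6 s.
#' @param contexts Context labels in presentation order
#'   (default solitary then social).
#' @param lfp Optional [lfp_sim_params()].
#' @param seed Master seed; every unit/channel derives its own stream.
#' @return An object of class `session_sim_config`.
#' @export
session_sim_config <- function(units, n_trials_per_stimulus = 25,
                               stimulus_duration_s = 2, motifs_per_song = 3,
                               inter_trial_interval_s = 6,
                               contexts = c("solitary", "social"),
                               lfp = NULL, seed = 1) {
  if (inter_trial_interval_s < 4.5)
    stop("inter_trial_interval_s must be >= 4.5 s so baseline and offset ",
         "windows never overlap adjacent stimuli")
  if (n_trials_per_stimulus < 5)
    stop("n_trials_per_stimulus must be >= 5")
  if (!all(contexts %in% ncm_contexts()))
    stop("unknown context label")
  structure(
    list(units = units, n_trials_per_stimulus = n_trials_per_stimulus,
         stimulus_duration_s = stimulus_duration_s,
         motifs_per_song = motifs_per_song,
         inter_trial_interval_s = inter_trial_interval_s,
         contexts = contexts, lfp = lfp, seed = seed,
         lead_in_s = 5),
    class = "session_sim_config"
  )
}

#' Generate a block-randomized epoch schedule
#'
#' Within each context, `n_trials_per_stimulus` blocks of the four stimuli
#' in random order; contexts follow the configured order (solitary before
#' social). Motif bounds split song stimuli into equal motifs with 100 ms
#' gaps; white noise gets a single whole-stimulus bound.
#'
#' @param config A [session_sim_config()].
#' @return An [epoch_table()].
#' @export
generate_epochs <- function(config) {
  stimuli <- ncm_stimuli()
  ord <- with_seed(derive_seed(config$seed, "epochs"), {
    unlist(lapply(config$contexts, function(ctx)
      unlist(lapply(seq_len(config$n_trials_per_stimulus), function(b)
        sample(stimuli)))))
  })
  ctx_col <- rep(config$contexts,
                 each = config$n_trials_per_stimulus * length(stimuli))
  n <- length(ord)
  dur <- config$stimulus_duration_s
  step <- dur + config$inter_trial_interval_s
  onsets <- config$lead_in_s + (seq_len(n) - 1) * step
  bounds <- lapply(seq_len(n), function(i) {
    if (ord[i] == "WN") {
      matrix(c(onsets[i], onsets[i] + dur), ncol = 2)
    } else {
      m <- config$motifs_per_song
      slot <- dur / m
      starts <- onsets[i] + (seq_len(m) - 1) * slot
      cbind(starts, starts + slot - 0.1)
    }
  })
  epoch_table(seq_len(n), ord, ctx_col, onsets, onsets + dur, bounds,
              rep("playback", n))
}

# Piecewise-constant firing-rate profile for one unit over a session.
# Returns a data.frame of consecutive segments (start, end, rate).
rate_profile <- function(unit, epochs, duration_s) {
  ctx_of_epoch <- epochs$context
  # context boundaries: switch halfway through the gap between blocks
  bk <- c(0)
  ctx_seq <- character(0)
  if (nrow(epochs) > 0) {
    switches <- which(ctx_of_epoch[-1] != ctx_of_epoch[-nrow(epochs)])
    cuts <- vapply(switches, function(i)
      (epochs$offset_s[i] + epochs$onset_s[i + 1]) / 2, numeric(1))
    bk <- c(0, cuts)
    ctx_seq <- ctx_of_epoch[c(1, switches + 1)]
  } else {
    ctx_seq <- names(unit$baseline_rate_hz)[1]
  }
  base_of <- function(ctx) unname(unit$baseline_rate_hz[ctx])
  # overrides: motif windows (evoked + adaptation) and offset windows
  ov_start <- numeric(0); ov_end <- numeric(0); ov_rate <- numeric(0)
  if (nrow(epochs) > 0) {
    pres_idx <- stats::ave(seq_len(nrow(epochs)),
                           epochs$stimulus, epochs$context,
                           FUN = seq_along)
    for (i in seq_len(nrow(epochs))) {
      ctx <- epochs$context[i]; st <- epochs$stimulus[i]
      b <- base_of(ctx)
      if (is.na(b))
        stop("unit '", unit$unit_id, "' has no baseline rate for context '",
             ctx, "'")
      eg <- unit$evoked_gain[[ctx]]
      gain <- if (is.null(eg)) 1 else (eg[[st]] %||% 1)
      k <- pres_idx[i] - 1 # first presentation adapts not at all
      adapt <- unit$adaptation_floor +
        (1 - unit$adaptation_floor) * exp(-k / unit$adaptation_tau_trials)
      m <- epochs$motif_bounds[[i]]
      ov_start <- c(ov_start, m[, 1]); ov_end <- c(ov_end, m[, 2])
      ov_rate <- c(ov_rate, rep(b * gain * adapt, nrow(m)))
      og <- unname(unit$offset_gain[ctx])
      if (is.na(og)) og <- 1
      ov_start <- c(ov_start, epochs$offset_s[i])
      ov_end <- c(ov_end, epochs$offset_s[i] + 1)
      ov_rate <- c(ov_rate, b * og)
    }
  }
  brk <- sort(unique(c(0, duration_s, bk, ov_start, ov_end)))
  brk <- brk[brk >= 0 & brk <= duration_s]
  seg_start <- brk[-length(brk)]
  seg_end <- brk[-1]
  mid <- (seg_start + seg_end) / 2
  ctx_idx <- findInterval(mid, bk)
  rate <- vapply(ctx_seq[pmax(ctx_idx, 1)], base_of, numeric(1))
  if (length(ov_start) > 0) {
    o <- order(ov_start)
    ov_start <- ov_start[o]; ov_end <- ov_end[o]; ov_rate <- ov_rate[o]
    j <- findInterval(mid, ov_start)
    hit <- j >= 1 & mid < c(ov_end, Inf)[pmax(j, 1)]
    rate[hit] <- ov_rate[j[hit]]
  }
  data.frame(start = seg_start, end = seg_end, rate = unname(rate))
}

#' Simulate a spike train by Poisson thinning
#'
#' The rate function is piecewise constant: the context's baseline outside
#' stimuli; `baseline x evoked_gain x adaptation` inside motif windows of
#' the k-th presentation of a stimulus, where adaptation decays from 1 to
#' `adaptation_floor` as `floor + (1 - floor) exp(-k / tau)` (k = 0 for the
#' first presentation, counted per stimulus within each context); and
#' `baseline x offset_gain` in the second after stimulus offset. Events are
#' drawn by thinning a homogeneous Poisson process at the peak rate.
#'
#' @param unit A [unit_sim_params()].
#' @param epochs An [epoch_table()] within `[0, duration_s]`.
#' @param duration_s Session duration.
#' @param seed Integer seed for this unit's stream.
#' @return A [spike_train()].
#' @export
generate_spike_train <- function(unit, epochs, duration_s, seed) {
  prof <- rate_profile(unit, epochs, duration_s)
  lam_max <- max(prof$rate)
  times <- with_seed(seed, {
    if (lam_max <= 0) numeric(0) else {
      n <- stats::rpois(1, lam_max * duration_s)
      cand <- sort(stats::runif(n, 0, duration_s))
      seg <- findInterval(cand, prof$start)
      keep <- stats::runif(n) < prof$rate[seg] / lam_max
      cand[keep]
    }
  })
  spike_train(unit$unit_id, times, duration_s)
}

#' Generate a biphasic waveform template
#'
#' Negative Gaussian trough followed by a positive peak whose trough-to-peak
#' interval equals the unit's programmed width to within one sample, plus a
#' small seeded noise floor.
#'
#' @param unit A [unit_sim_params()].
#' @param seed Integer seed.
#' @param sampling_rate_hz Template sampling rate (default 30 kHz).
#' @return A [waveform()].
#' @export
generate_waveform <- function(unit, seed, sampling_rate_hz = 30000) {
  w <- unit$waveform_width_ms
  if (w <= 0) stop("waveform width must be positive")
  if (w < 2000 / sampling_rate_hz)
    stop("waveform width not resolvable at this sampling rate")
  dur_ms <- max(3, w * 2 + 2)
  t <- seq(0, dur_ms, by = 1000 / sampling_rate_hz)
  t0 <- 1.0
  s1 <- w / 5; s2 <- w / 3
  shape <- -exp(-(t - t0)^2 / (2 * s1^2)) +
    0.5 * exp(-(t - t0 - w)^2 / (2 * s2^2))
  noise <- with_seed(seed, stats::rnorm(length(t), sd = 0.004))
  waveform(unit$unit_id, shape + noise, sampling_rate_hz)
}

#' Generate a multichannel LFP recording
#'
#' Per channel: 1/f^alpha Gaussian background (unit variance), a mains
#' sinusoid at `line_hz`, and band-limited components added inside matching
#' stimulus envelopes so that in-band power is multiplied by exactly
#' `power_gain` while the stimulus plays. Each channel has its own RNG
#' stream derived from the seed and channel name.
#'
#' @param params An [lfp_sim_params()].
#' @param epochs An [epoch_table()].
#' @param duration_s Recording duration.
#' @param seed Integer seed.
#' @return An [lfp_recording()].
#' @export
generate_lfp <- function(params, epochs, duration_s, seed) {
  fs <- params$sampling_rate_hz
  n <- round(duration_s * fs)
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs) # absolute frequency of each FFT bin
  alpha <- params$noise_spectrum_exponent
  h <- ifelse(freqs <= 0, 0, pmax(freqs, 0.5)^(-alpha / 2))
  tt <- (seq_len(n) - 1) / fs
  chans <- paste0("ch", seq_len(params$n_channels))
  shape_noise <- function(mask) {
    x <- stats::rnorm(n)
    Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  }
  sig <- matrix(0, nrow = n, ncol = params$n_channels,
                dimnames = list(NULL, chans))
  for (ci in seq_along(chans)) {
    sig[, ci] <- with_seed(derive_seed(seed, paste0("lfp:", chans[ci])), {
      bg <- shape_noise(h)
      s <- stats::sd(bg)
      bg <- bg / s
      phase <- stats::runif(1, 0, 2 * pi)
      x <- bg + 0.5 * sin(2 * pi * params$line_hz * tt + phase)
      be <- params$band_effects
      if (!is.null(be) && nrow(be) > 0) {
        for (k in seq_len(nrow(be))) {
          lo <- be$center_hz[k] - be$bandwidth_hz[k] / 2
          hi <- be$center_hz[k] + be$bandwidth_hz[k] / 2
          mask <- h * (freqs >= lo & freqs <= hi)
          comp <- shape_noise(mask) / s # same spectral density as background
          env <- rep(0, n)
          sel <- which(epochs$stimulus == be$stimulus[k] &
                         epochs$context == be$context[k])
          for (i in sel) {
            i0 <- max(1, floor(epochs$onset_s[i] * fs) + 1)
            i1 <- min(n, ceiling(epochs$offset_s[i] * fs))
            env[i0:i1] <- sqrt(be$power_gain[k] - 1)
          }
          x <- x + env * comp
        }
      }
      x
    })
  }
  lfp_recording(sig, fs, chans)
}

#' Generate a complete synthetic session
#'
#' Epoch schedule, one spike train and one waveform per unit (each on its
#' own RNG stream), and optionally the LFP bank. Identical configuration and
#' seed give byte-identical session files.
#'
#' @param config A [session_sim_config()].
#' @param session_id Session identifier.
#' @return An [ncm_session()].
#' @export
generate_session <- function(config, session_id = "synthetic") {
  epochs <- generate_epochs(config)
  duration <- max(epochs$offset_s) + config$inter_trial_interval_s
  trains <- lapply(config$units, function(u)
    generate_spike_train(u, epochs, duration,
                         derive_seed(config$seed, paste0("unit:", u$unit_id))))
  waveforms <- lapply(config$units, function(u)
    generate_waveform(u, derive_seed(config$seed, paste0("wf:", u$unit_id))))
  lfp <- if (!is.null(config$lfp))
    generate_lfp(config$lfp, epochs, duration,
                 derive_seed(config$seed, "lfp")) else NULL
  ncm_session(session_id, epochs, trains, waveforms, lfp,
              metadata = list(generator = "ncmephys-synth",
                              seed = config$seed))
}

#' Simulate a solitary-vs-social population of units
#'
#' Builds a session whose social parameterization encodes the audience
#' effect on synthetic ground truth: per-unit baseline rates are multiplied
#' by a lognormal factor whose population mean is `social_baseline_factor`
#' (the reported group-level baseline shift is a ratio of means; dispersion
#' `sdlog` reflects the large cross-unit variability of baseline modulation
#' seen in awake recordings, where group-level baseline shifts are not
#' reliably significant). The baseline elevation adds into the evoked
#' window rather than scaling it: the social evoked rate is the social
#' baseline plus the solitary evoked increment compressed by
#' `selectivity_compression` (0.5 halves the response strength and the
#' gain contrast between stimuli). Normalized responses (Z) and selectivity
#' (d-prime) therefore drop for every unit in the social condition while
#' absolute evoked rates change with no fixed sign.
#'
#' @param n_units Number of units.
#' @param n_trials Trials per stimulus per context.
#' @param seed Master seed.
#' @param baseline_median_hz Median solitary baseline (default 10 Hz).
#' @param baseline_sdlog Cross-unit spread of solitary baselines (0.3).
#' @param bos_gain,other_gain Solitary evoked gains (3.0 and 1.5).
#' @param social_baseline_factor Mean social baseline multiplier (1.3).
#' @param sdlog Cross-unit dispersion of the social multiplier (0.8).
#' @param selectivity_compression Fraction of the gain-above-1 retained in
#'   the social condition (0.5).
#' @param prop_bs Proportion of broad-spiking units (0.7).
#' @return A [session_sim_config()]; pass to [generate_session()].
#' @export
simulate_population_config <- function(n_units = 30, n_trials = 25, seed = 1,
                                       baseline_median_hz = 10,
                                       baseline_sdlog = 0.3,
                                       bos_gain = 3, other_gain = 1.5,
                                       social_baseline_factor = 1.3,
                                       sdlog = 0.8,
                                       selectivity_compression = 0.5,
                                       prop_bs = 0.7) {
  draws <- with_seed(derive_seed(seed, "population"), list(
    b = stats::rlnorm(n_units, log(baseline_median_hz), baseline_sdlog),
    # lognormal with mean social_baseline_factor: E[m] = exp(mu + s^2/2)
    m = stats::rlnorm(n_units, log(social_baseline_factor) - sdlog^2 / 2,
                      sdlog),
    bs = stats::runif(n_units) < prop_bs
  ))
  gains_sol <- c(BOS = bos_gain, BOS_REV = other_gain, CON = other_gain,
                 WN = other_gain)
  units <- lapply(seq_len(n_units), function(i) {
    m <- draws$m[i]
    # social evoked rate = social baseline + compressed solitary increment:
    # rate_soc = m*b + b*(g - 1)*compression, expressed as a gain on the
    # social baseline m*b
    gains_soc <- 1 + (gains_sol - 1) * selectivity_compression / m
    unit_sim_params(
      unit_id = sprintf("u%03d", i),
      baseline_rate_hz = c(solitary = draws$b[i],
                           social = draws$b[i] * m),
      evoked_gain = list(solitary = as.list(gains_sol),
                         social = as.list(gains_soc)),
      offset_gain = c(solitary = 1.5, social = 1.5),
      unit_class = if (draws$bs[i]) "BS" else "NS"
    )
  })
  session_sim_config(units, n_trials_per_stimulus = n_trials, seed = seed)
}
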