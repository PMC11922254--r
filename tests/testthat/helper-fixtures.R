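# Shared fixture builders. Everything is generated in code; no stored data.

# A small hand-built epoch table: two song trials and one WN trial,
# solitary playback.
tiny_epochs <- function() {
  epoch_table(
    trial_id = 1:3,
    stimulus = c("BOS", "CON", "WN"),
    context = "solitary",
    onset_s = c(10, 20, 30),
    offset_s = c(12, 22, 32),
    motif_bounds = list(
      matrix(c(10, 10.7, 11, 11.7), ncol = 2, byrow = TRUE),
      matrix(c(20, 20.9, 21, 21.9), ncol = 2, byrow = TRUE),
      matrix(c(30, 32), ncol = 2)
    ),
    source = "playback"
  )
}

# Deterministic response series from explicit rate vectors.
make_series <- function(fr, blfr, idx = seq_along(fr), stimulus = "BOS",
                        context = "solitary") {
  trial_response_series("u", stimulus, context, fr, blfr, idx)
}

# Default gain maps used by several synthetic-unit fixtures.
flat_gains <- function(g, contexts = c("solitary", "social")) {
  gl <- as.list(stats::setNames(rep(g, 4), ncm_stimuli()))
  stats::setNames(lapply(contexts, function(...) gl), contexts)
}

# One-unit config with uniform evoked gain; handy for rate-recovery tests.
one_unit_config <- function(baseline = 10, gain = 1, offset_gain = 1,
                            floor = 1, tau = 10, n_trials = 12, seed = 1,
                            contexts = c("solitary", "social"), ...) {
  u <- unit_sim_params(
    "u1",
    baseline_rate_hz = stats::setNames(rep(baseline, length(contexts)),
                                       contexts),
    evoked_gain = flat_gains(gain, contexts),
    offset_gain = stats::setNames(rep(offset_gain, length(contexts)),
                                  contexts),
    adaptation_floor = floor, adaptation_tau_trials = tau
  )
  session_sim_config(list(u), n_trials_per_stimulus = n_trials,
                     contexts = contexts, seed = seed, ...)
}

# Uniform-rate Poisson spike train over [0, dur).
poisson_train <- function(rate, dur, seed, unit_id = "u") {
  set.seed(seed)
  n <- rpois(1, rate * dur)
  spike_train(unit_id, sort(runif(n, 0, dur)), dur)
}
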