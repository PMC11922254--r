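# Per-unit spike-derived statistics: firing-rate windows, baseline
# conventions, baseline-normalized Z-scores, response strength, d-prime
# selectivity, stimulus-specific adaptation, offset responses,
# responsiveness testing and waveform-based unit classification.
#
# Degenerate 0/0 statistics return NA_real_ (a typed "undefined", never a
# silent NaN); downstream comparisons drop them pairwise with logged counts.

#' Trough-to-peak width of a mean waveform
#'
#' Time from the global minimum (trough) to the subsequent global maximum
#' (peak), in milliseconds. A waveform with no positive deflection after its
#' trough (e.g. a symmetric single lobe) raises a shape error.
#'
#' @param w A [waveform()].
#' @return Width in ms.
#' @export
peak_to_peak_width <- function(w) {
  s <- w$samples
  i_min <- which.min(s)
  if (i_min >= length(s))
    stop("waveform shape error: trough is the last sample")
  after <- s[(i_min + 1):length(s)]
  i_max <- i_min + which.max(after)
  if (s[i_min] >= 0 || s[i_max] <= 0)
    stop("waveform shape error: no positive peak after the trough")
  (i_max - i_min) / w$sampling_rate_hz * 1000
}

#' Classify a unit as broad- or narrow-spiking
#'
#' Broad-spiking (BS, putative excitatory) if the trough-to-peak width
#' strictly exceeds the threshold, narrow-spiking (NS, putative inhibitory)
#' otherwise. The classification rule leaves exact equality unassigned
#' (BS is defined by `> threshold`, NS by `< threshold`); equality is
#' resolved to NS by the strict-greater reading of the BS rule.
#'
#' @param width_ms Trough-to-peak width in ms.
#' @param threshold_ms Decision boundary, default 0.43 ms.
#' @return `"BS"` or `"NS"`.
#' @export
classify_unit <- function(width_ms, threshold_ms = 0.43) {
  stopifnot(width_ms > 0)
  if (width_ms > threshold_ms) "BS" else "NS"
}

#' Firing rate in a half-open window
#'
#' Spike count in `[start, end)` divided by the window duration. This is the
#' per-motif evoked rate for songs and the whole-stimulus rate for white
#' noise (whose single motif bound spans the entire playback).
#'
#' @param train A [spike_train()].
#' @param window Numeric `c(start_s, end_s)`.
#' @return Rate in Hz.
#' @export
motif_rate <- function(train, window) {
  if (window[2] <= window[1]) stop("zero-length or inverted window")
  count_in_window(train$spike_times_s, window[1], window[2]) /
    (window[2] - window[1])
}

#' Playback baseline firing rate
#'
#' Rate over one second starting two seconds before stimulus onset, i.e.
#' `[onset - 2, onset - 1)`. The remaining second before onset is a buffer
#' ensuring baseline and playback never overlap.
#'
#' @param train A [spike_train()].
#' @param epoch One epoch-table row (or a list with `onset_s`).
#' @return Rate in Hz.
#' @export
baseline_rate_playback <- function(train, epoch) {
  onset <- epoch$onset_s
  if (onset < 2) stop("baseline window extends before session start")
  motif_rate(train, c(onset - 2, onset - 1))
}

#' Vocalization-bout baseline firing rate
#'
#' For singing bouts the baseline is pooled over two windows flanking the
#' bout: `window_s` seconds ending 1.5 s before the first motif and
#' `window_s` seconds starting 1.5 s after the last motif. A single-motif
#' bout is the degenerate case first = last.
#'
#' @param train A [spike_train()].
#' @param bout Epoch-table rows forming one bout.
#' @param window_s Flanking window duration in seconds (default 1).
#' @return Pooled rate in Hz.
#' @export
baseline_rate_vocal <- function(train, bout, window_s = 1) {
  if (nrow(bout) < 1) stop("empty bout")
  first_start <- min(vapply(bout$motif_bounds, function(m) min(m[, 1]),
                            numeric(1)))
  last_end <- max(vapply(bout$motif_bounds, function(m) max(m[, 2]),
                         numeric(1)))
  pre <- c(first_start - 1.5 - window_s, first_start - 1.5)
  post <- c(last_end + 1.5, last_end + 1.5 + window_s)
  if (pre[1] < 0 || post[2] > train$session_duration_s)
    stop("vocal baseline windows fall outside the session")
  n <- count_in_window(train$spike_times_s, pre[1], pre[2]) +
    count_in_window(train$spike_times_s, post[1], post[2])
  n / (2 * window_s)
}

#' Paired per-presentation response series
#'
#' The container for all rate symbols: per-presentation evoked rates `FR_i`
#' (one per motif for songs, whole-stimulus for WN) paired with their
#' trial's baseline rate `BLFR_i`. Pairing is preserved so covariances are
#' meaningful; `presentation_index` records which presentation each entry
#' came from (several motifs of one trial share an index).
#'
#' @param unit_id,stimulus,context Identifiers.
#' @param fr_hz,blfr_hz Equal-length paired rate vectors.
#' @param presentation_index Integer presentation index per entry.
#' @return An object of class `trial_response_series`.
#' @export
trial_response_series <- function(unit_id, stimulus, context, fr_hz, blfr_hz,
                                  presentation_index = seq_along(fr_hz)) {
  fr_hz <- as.numeric(fr_hz); blfr_hz <- as.numeric(blfr_hz)
  if (length(fr_hz) < 1 || length(fr_hz) != length(blfr_hz) ||
      length(fr_hz) != length(presentation_index))
    stop("fr_hz, blfr_hz and presentation_index must have equal length >= 1")
  structure(
    list(unit_id = unit_id, stimulus = stimulus, context = context,
         fr_hz = fr_hz, blfr_hz = blfr_hz,
         presentation_index = as.integer(presentation_index)),
    class = "trial_response_series"
  )
}

#' Build the evoked response series for one unit x stimulus x context
#'
#' Each motif contributes one evoked rate; its paired baseline is the
#' trial's playback baseline repeated per motif, preserving pairing for the
#' covariance term of the Z-score.
#'
#' @param train A [spike_train()].
#' @param epochs An [epoch_table()]; only playback rows of the requested
#'   stimulus and context are used.
#' @param stimulus,context Labels selecting the cell.
#' @return A [trial_response_series()], or `NULL` if no matching epochs.
#' @export
build_response_series <- function(train, epochs, stimulus, context) {
  sel <- epochs$stimulus == stimulus & epochs$context == context &
    epochs$source == "playback"
  ep <- epochs[sel, , drop = FALSE]
  if (nrow(ep) == 0) return(NULL)
  fr <- numeric(0); bl <- numeric(0); idx <- integer(0)
  for (i in seq_len(nrow(ep))) {
    m <- ep$motif_bounds[[i]]
    rates <- vapply(seq_len(nrow(m)), function(j)
      motif_rate(train, m[j, ]), numeric(1))
    b <- baseline_rate_playback(train, ep[i, ])
    fr <- c(fr, rates)
    bl <- c(bl, rep(b, length(rates)))
    idx <- c(idx, rep(i, length(rates)))
  }
  trial_response_series(train$unit_id, stimulus, context, fr, bl, idx)
}

#' Offset-response series for one unit x stimulus x context
#'
#' Per presentation: the firing rate in the one-second window after the end
#' of the last motif, paired with that trial's playback baseline.
#'
#' @inheritParams build_response_series
#' @param window_s Offset window duration (default 1 s).
#' @return A [trial_response_series()] of offset rates, or `NULL`.
#' @export
build_offset_series <- function(train, epochs, stimulus, context,
                                window_s = 1) {
  sel <- epochs$stimulus == stimulus & epochs$context == context &
    epochs$source == "playback"
  ep <- epochs[sel, , drop = FALSE]
  if (nrow(ep) == 0) return(NULL)
  ends <- vapply(ep$motif_bounds, function(m) max(m[, 2]), numeric(1))
  fr <- vapply(seq_len(nrow(ep)), function(i)
    motif_rate(train, c(ends[i], ends[i] + window_s)), numeric(1))
  bl <- vapply(seq_len(nrow(ep)), function(i)
    baseline_rate_playback(train, ep[i, ]), numeric(1))
  trial_response_series(train$unit_id, stimulus, context, fr, bl,
                        seq_len(nrow(ep)))
}

#' Baseline-normalized response Z-score
#'
#' \deqn{Z = \frac{\overline{FR} - \overline{BLFR}}
#'   {\sqrt{var(FR) + var(BLFR) - 2\,cov(FR, BLFR)}}}
#' with sample (N-1) variances and covariance across paired presentations.
#' The denominator equals the standard deviation of the paired differences,
#' so Z is invariant to shifting both series by a constant. A 0/0 is defined
#' as 0; a nonzero numerator over a zero denominator is undefined and
#' returned as `NA`.
#'
#' @param series A [trial_response_series()] with at least 2 entries.
#' @param sqrt_denominator If `FALSE`, divide by the raw variance sum
#'   instead of its square root (replicates the formula exactly as sometimes
#'   rendered without the radical; the default follows the standard
#'   definition the statistic names).
#' @return Unitless Z, or `NA` if undefined.
#' @export
z_score <- function(series, sqrt_denominator = TRUE) {
  fr <- series$fr_hz; bl <- series$blfr_hz
  if (length(fr) < 2) stop("z_score needs at least 2 paired presentations")
  num <- mean(fr) - mean(bl)
  den2 <- stats::var(fr) + stats::var(bl) - 2 * stats::cov(fr, bl)
  den2 <- max(den2, 0) # exact value is var(fr - bl) >= 0; guard rounding
  den <- if (sqrt_denominator) sqrt(den2) else den2
  if (den == 0) {
    if (num == 0) 0 else NA_real_
  } else {
    num / den
  }
}

#' Response strength
#'
#' Mean paired difference `FR_i - BLFR_i` across presentations, in Hz.
#'
#' @param series A [trial_response_series()].
#' @return RS in Hz.
#' @export
response_strength <- function(series) {
  mean(series$fr_hz - series$blfr_hz)
}

#' d-prime selectivity between two stimuli
#'
#' \deqn{d'_{A-B} = \frac{2\,(RS_A - RS_B)}{\sqrt{var_A + var_B}}}
#' where `RS` is the response strength and `var` the sample variance of the
#' per-presentation paired differences `FR_i - BLFR_i`. Antisymmetric, zero
#' on the diagonal. If both variances are zero the statistic is 0 when the
#' response strengths agree and undefined (`NA`) otherwise.
#'
#' @param series_a,series_b Two [trial_response_series()] with >= 2 entries.
#' @return Unitless d-prime, or `NA` if undefined.
#' @export
d_prime <- function(series_a, series_b) {
  da <- series_a$fr_hz - series_a$blfr_hz
  db <- series_b$fr_hz - series_b$blfr_hz
  if (length(da) < 2 || length(db) < 2)
    stop("d_prime needs at least 2 presentations per series")
  num <- 2 * (mean(da) - mean(db))
  den <- sqrt(stats::var(da) + stats::var(db))
  if (den == 0) {
    if (num == 0) 0 else NA_real_
  } else {
    num / den
  }
}

# Mean evoked rate per presentation (motifs of one presentation averaged).
per_presentation_rates <- function(series) {
  as.numeric(tapply(series$fr_hz, series$presentation_index, mean))
}

#' Stimulus-specific adaptation ratio
#'
#' Ratio of the mean of the last five to the mean of the first five
#' per-presentation firing rates for a stimulus. A declining response gives
#' a ratio below 1; values under the (arbitrary) 0.6 threshold mark a high
#' degree of adaptation and flag the unit for exclusion from cross-context
#' comparisons (order-effect control). For motif-level series the rates are
#' first averaged within each presentation, since adaptation is defined
#' across repeated presentations.
#'
#' @param series A [trial_response_series()] with >= 10 presentations.
#' @return Unitless ratio; `NA` if the first-five mean is zero.
#' @export
ssa_ratio <- function(series) {
  r <- per_presentation_rates(series)
  n <- length(r)
  if (n < 10)
    stop("ssa_ratio needs at least 10 presentations (first and last five)")
  first5 <- mean(r[1:5])
  last5 <- mean(r[(n - 4):n])
  if (first5 == 0) return(NA_real_)
  last5 / first5
}

#' Offset ratio for one presentation
#'
#' Firing rate in the one-second window after the end of the last motif,
#' divided by the baseline rate. Undefined (`NA`) when the baseline is zero.
#'
#' @param train A [spike_train()].
#' @param last_motif_end_s End of the last motif, seconds.
#' @param blfr_hz Baseline rate in Hz.
#' @param window_s Offset window duration (default 1 s).
#' @return Unitless ratio, or `NA`.
#' @export
offset_ratio <- function(train, last_motif_end_s, blfr_hz, window_s = 1) {
  if (blfr_hz == 0) return(NA_real_)
  motif_rate(train, c(last_motif_end_s, last_motif_end_s + window_s)) /
    blfr_hz
}

#' Unit-level offset ratio across presentations
#'
#' Ratio of the mean offset-window rate to the mean baseline rate over all
#' presentations (ratio of means: robust to single trials with an empty
#' baseline window, unlike a mean of per-trial ratios).
#'
#' @param offset_series A [trial_response_series()] from
#'   [build_offset_series()].
#' @return Unitless ratio, or `NA` when the mean baseline is zero.
#' @export
mean_offset_ratio <- function(offset_series) {
  mb <- mean(offset_series$blfr_hz)
  if (mb == 0) return(NA_real_)
  mean(offset_series$fr_hz) / mb
}

#' Offset-response Z-score
#'
#' The response Z-score applied to per-presentation offset-window rates
#' paired with their trial baselines (the offset statistic is given no
#' separate formula of its own; the standard Z form is reused).
#'
#' @param offset_series A [trial_response_series()] of offset rates.
#' @inheritParams z_score
#' @return Unitless Z, or `NA` if undefined.
#' @export
offset_z <- function(offset_series, sqrt_denominator = TRUE) {
  z_score(offset_series, sqrt_denominator = sqrt_denominator)
}

#' Auditory responsiveness test
#'
#' Paired two-tailed t-test comparing evoked and baseline rates pooled over
#' all stimulus playbacks; responsive iff p < alpha. When the paired
#' differences have zero variance the t statistic is undefined: all-zero
#' differences are non-responsive, constant nonzero differences are treated
#' as responsive (infinite separation).
#'
#' @param fr_hz,blfr_hz Paired pooled rate vectors (>= 2 pairs).
#' @param alpha Significance level, default 0.05.
#' @return Logical.
#' @export
is_responsive <- function(fr_hz, blfr_hz, alpha = 0.05) {
  if (length(fr_hz) < 2 || length(fr_hz) != length(blfr_hz))
    stop("is_responsive needs at least 2 paired rates")
  d <- fr_hz - blfr_hz
  if (stats::sd(d) == 0) return(any(d != 0))
  stats::t.test(fr_hz, blfr_hz, paired = TRUE)$p.value < alpha
}

#' Compute the full per-unit metrics table for a session
#'
#' For every unit x stimulus x context cell with playback trials: mean
#' evoked and baseline rates, Z, response strength, SSA ratio (when >= 10
#' presentations), offset ratio and offset Z. Per unit: BS/NS class from the
#' mean waveform and the pooled responsiveness flag. The pairwise d-prime
#' matrix per context is returned alongside.
#'
#' @param session An [ncm_session()].
#' @param alpha Responsiveness significance level (default 0.05).
#' @param width_threshold_ms BS/NS decision boundary (default 0.43).
#' @return A list with `metrics` (data frame, one row per cell), `d_prime`
#'   (data frame `unit_id, context, stim_a, stim_b, d_prime`), and
#'   `n_undefined` (count of NA-valued statistics).
#' @export
compute_unit_metrics <- function(session, alpha = 0.05,
                                 width_threshold_ms = 0.43) {
  epochs <- session$epochs
  stimuli <- intersect(ncm_stimuli(), unique(epochs$stimulus))
  contexts <- intersect(ncm_contexts(), unique(epochs$context))
  rows <- list(); drows <- list()
  for (train in session$spike_trains) {
    uid <- train$unit_id
    wf <- session$waveforms[[uid]]
    uclass <- if (!is.null(wf))
      classify_unit(peak_to_peak_width(wf), width_threshold_ms)
    else NA_character_
    pooled_fr <- numeric(0); pooled_bl <- numeric(0)
    series_by_cell <- list()
    for (ctx in contexts) for (st in stimuli) {
      ser <- build_response_series(train, epochs, st, ctx)
      if (is.null(ser)) next
      series_by_cell[[paste(ctx, st)]] <- ser
      pooled_fr <- c(pooled_fr, ser$fr_hz)
      pooled_bl <- c(pooled_bl, ser$blfr_hz)
    }
    responsive <- if (length(pooled_fr) >= 2)
      is_responsive(pooled_fr, pooled_bl, alpha) else NA
    for (ctx in contexts) {
      cell_series <- list()
      for (st in stimuli) {
        ser <- series_by_cell[[paste(ctx, st)]]
        if (is.null(ser)) next
        cell_series[[st]] <- ser
        off <- build_offset_series(train, epochs, st, ctx)
        n_pres <- length(unique(ser$presentation_index))
        ssa <- if (n_pres >= 10) ssa_ratio(ser) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, unit_class = uclass, stimulus = st, context = ctx,
          n_trials = n_pres,
          mean_fr_hz = mean(ser$fr_hz), mean_blfr_hz = mean(ser$blfr_hz),
          z = if (length(ser$fr_hz) >= 2) z_score(ser) else NA_real_,
          rs = response_strength(ser),
          ssa_ratio = ssa,
          offset_ratio = mean_offset_ratio(off),
          offset_z = if (length(off$fr_hz) >= 2) offset_z(off) else NA_real_,
          responsive = responsive,
          stringsAsFactors = FALSE
        )
      }
      sts <- names(cell_series)
      if (length(sts) >= 2) {
        for (a in sts) for (b in sts) {
          dp <- d_prime(cell_series[[a]], cell_series[[b]])
          drows[[length(drows) + 1L]] <- data.frame(
            unit_id = uid, context = ctx, stim_a = a, stim_b = b,
            d_prime = dp, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  metrics <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(metrics_columns()))),
      metrics_columns())
  dmat <- if (length(drows) > 0) do.call(rbind, drows) else
    data.frame(unit_id = character(0), context = character(0),
               stim_a = character(0), stim_b = character(0),
               d_prime = numeric(0))
  n_undef <- sum(is.na(metrics$z)) + sum(is.na(metrics$offset_z)) +
    sum(is.na(metrics$offset_ratio)) + sum(is.na(dmat$d_prime))
  list(metrics = metrics, d_prime = dmat, n_undefined = n_undef)
}

#' Filter units for cross-context analysis
#'
#' Retains units that are auditory-responsive AND have an SSA ratio above
#' the threshold for at least one stimulus (in any context) -- the
#' order-effect control excluding strongly adapting units.
#'
#' @param metrics The metrics data frame from [compute_unit_metrics()].
#' @param ssa_threshold SSA exclusion boundary, default 0.6.
#' @return The metrics rows of retained units; retained ids in
#'   `attr(, "retained_units")`.
#' @export
select_analysis_units <- function(metrics, ssa_threshold = 0.6) {
  keep_ids <- character(0)
  for (uid in unique(metrics$unit_id)) {
    rowsu <- metrics[metrics$unit_id == uid, , drop = FALSE]
    resp <- isTRUE(rowsu$responsive[1])
    ssa <- rowsu$ssa_ratio[!is.na(rowsu$ssa_ratio)]
    if (resp && length(ssa) > 0 && max(ssa) > ssa_threshold)
      keep_ids <- c(keep_ids, uid)
  }
  out <- metrics[metrics$unit_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_units") <- keep_ids
  out
}

#' Subsample playback trials to match a singing-motif count
#'
#' For behavioral-context comparisons the playback condition is thinned to
#' the number of sung motifs by seeded uniform subsampling, matching the
#' variance structure across conditions.
#'
#' @param epochs An [epoch_table()] of playback rows.
#' @param n_motifs Number of sung motifs to match.
#' @param seed Integer seed.
#' @return The subsampled epoch rows, onset-ordered.
#' @export
subsample_playback_trials <- function(epochs, n_motifs, seed) {
  pb <- epochs[epochs$source == "playback", , drop = FALSE]
  if (n_motifs >= nrow(pb)) return(pb)
  idx <- with_seed(seed, sample.int(nrow(pb), n_motifs))
  out <- pb[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
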