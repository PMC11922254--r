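# Pipeline orchestration: synth -> metrics -> lfp -> compare in one
# reproducible run. A single JSON run-config is the source of truth; the
# resolved config is echoed into the output directory, and the run log
# records seeds and every exclusion with counts.

#' Serialize and load synthetic-session configurations
#'
#' `synth_config_to_json` / `synth_config_from_json` mirror
#' [session_sim_config()] field-for-field so schedules are scriptable from
#' any language.
#'
#' @param config A [session_sim_config()].
#' @param path JSON file path.
#' @export
synth_config_to_json <- function(config, path) {
  ser <- list(
    n_trials_per_stimulus = config$n_trials_per_stimulus,
    stimulus_duration_s = config$stimulus_duration_s,
    motifs_per_song = config$motifs_per_song,
    inter_trial_interval_s = config$inter_trial_interval_s,
    contexts = config$contexts,
    seed = config$seed,
    units = lapply(config$units, function(u)
      list(unit_id = u$unit_id, unit_class = u$unit_class,
           baseline_rate_hz = as.list(u$baseline_rate_hz),
           evoked_gain = u$evoked_gain,
           offset_gain = as.list(u$offset_gain),
           adaptation_floor = u$adaptation_floor,
           adaptation_tau_trials = u$adaptation_tau_trials,
           waveform_width_ms = u$waveform_width_ms)),
    lfp = if (is.null(config$lfp)) NULL else list(
      n_channels = config$lfp$n_channels,
      sampling_rate_hz = config$lfp$sampling_rate_hz,
      noise_spectrum_exponent = config$lfp$noise_spectrum_exponent,
      line_hz = config$lfp$line_hz,
      band_effects = config$lfp$band_effects)
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname synth_config_to_json
#' @export
synth_config_from_json <- function(path) {
  j <- jsonlite::read_json(path) # plain nested lists
  units <- lapply(j$units, function(u)
    unit_sim_params(
      unit_id = u$unit_id,
      baseline_rate_hz = unlist(u$baseline_rate_hz),
      evoked_gain = u$evoked_gain,
      offset_gain = unlist(u$offset_gain),
      adaptation_floor = u$adaptation_floor,
      adaptation_tau_trials = u$adaptation_tau_trials,
      unit_class = u$unit_class,
      waveform_width_ms = u$waveform_width_ms))
  lfp <- NULL
  if (!is.null(j$lfp) && length(j$lfp) > 0) {
    be <- j$lfp$band_effects
    if (!is.null(be) && length(be) > 0)
      be <- do.call(rbind, lapply(be, as.data.frame))
    else be <- NULL
    lfp <- lfp_sim_params(j$lfp$n_channels, j$lfp$sampling_rate_hz,
                          j$lfp$noise_spectrum_exponent, j$lfp$line_hz, be)
  }
  session_sim_config(units, j$n_trials_per_stimulus, j$stimulus_duration_s,
                     j$motifs_per_song, j$inter_trial_interval_s,
                     unlist(j$contexts), lfp, j$seed)
}

#' Assemble a run configuration
#'
#' Every analysis threshold is surfaced with its published default: SSA
#' exclusion 0.6, BS/NS width 0.43 ms, responsiveness and comparison alpha
#' 0.05, LFP alpha 0.01 with 2500 permutations.
#'
#' @param session_dir Existing session directory to analyze, or `NULL` to
#'   synthesize one from `synth_config`.
#' @param synth_config A [session_sim_config()] (used when `session_dir` is
#'   `NULL`).
#' @param seed Master analysis seed.
#' @param ssa_threshold,width_threshold_ms,alpha,lfp_alpha,n_perm,lfp_baseline
#'   Analysis parameters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(session_dir = NULL, synth_config = NULL, seed = 1,
                       ssa_threshold = 0.6, width_threshold_ms = 0.43,
                       alpha = 0.05, lfp_alpha = 0.01, n_perm = 2500,
                       lfp_baseline = "before") {
  if (is.null(session_dir) && is.null(synth_config))
    stop("either session_dir or synth_config is required")
  structure(list(session_dir = session_dir, synth_config = synth_config,
                 seed = seed, ssa_threshold = ssa_threshold,
                 width_threshold_ms = width_threshold_ms, alpha = alpha,
                 lfp_alpha = lfp_alpha, n_perm = n_perm,
                 lfp_baseline = lfp_baseline),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) synthesize or load the session; (2) per-unit metrics ->
#' `metrics.csv`; (3) LFP stimulus-vs-baseline permutation tests ->
#' `lfp_results.csv` (if an LFP is present); (4) SSA/responsiveness
#' filtering and cross-context comparisons -> `comparisons.csv` (if two
#' contexts are present); (5) `run_log.json` with seeds, unit counts by
#' class and inclusion status, and every exclusion count. Any stage failure
#' aborts with a stage-tagged error. Identical config and seed give
#' byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the metrics, comparisons, LFP results and
#'   the run log.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  session <- stage("synth", {
    if (!is.null(config$session_dir)) {
      read_session(config$session_dir)
    } else {
      s <- generate_session(config$synth_config)
      write_session(s, file.path(out_dir, "session"))
      s
    }
  })
  um <- stage("metrics", {
    res <- compute_unit_metrics(session, alpha = config$alpha,
                                width_threshold_ms = config$width_threshold_ms)
    write_metrics_table(res$metrics, file.path(out_dir, "metrics.csv"))
    res
  })
  lfp_res <- NULL
  if (!is.null(session$lfp)) {
    lfp_res <- stage("lfp", {
      r <- lfp_stimulus_tests(session, baseline = config$lfp_baseline,
                              n_perm = config$n_perm,
                              alpha = config$lfp_alpha, seed = config$seed)
      out <- r[, c("comparison", "stimulus", "context", "frequency_hz",
                   "stat", "p_value", "significant")]
      names(out) <- c("comparison", "stimulus", "context", "frequency_hz",
                      "stat", "p", "significant")
      out$stat <- sprintf("%.12g", out$stat)
      out$p <- sprintf("%.12g", out$p)
      utils::write.csv(out, file.path(out_dir, "lfp_results.csv"),
                       row.names = FALSE, quote = FALSE)
      r
    })
  }
  contexts <- intersect(ncm_contexts(), unique(session$epochs$context))
  comparisons <- NULL
  selected <- stage("filter", {
    select_analysis_units(um$metrics, config$ssa_threshold)
  })
  if (length(contexts) >= 2) {
    comparisons <- stage("compare", {
      keep <- attr(selected, "retained_units")
      filtered <- list(
        metrics = selected,
        d_prime = um$d_prime[um$d_prime$unit_id %in% keep, , drop = FALSE])
      cmp <- compare_contexts(filtered, contexts[1], contexts[2],
                              alpha = config$alpha)
      out <- cmp
      for (cn in c("statistic", "p_raw", "p_adjusted"))
        out[[cn]] <- sprintf("%.12g", out[[cn]])
      utils::write.csv(out, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE, quote = FALSE)
      cmp
    })
  }
  n_units <- length(session$spike_trains)
  classes <- table(um$metrics$unit_class[!duplicated(um$metrics$unit_id)])
  log <- list(
    package_version = as.character(utils::packageVersion("ncmephys")),
    seed = config$seed,
    thresholds = config[c("ssa_threshold", "width_threshold_ms", "alpha",
                          "lfp_alpha", "n_perm", "lfp_baseline")],
    n_units = n_units,
    n_units_by_class = as.list(classes),
    n_units_retained = length(attr(selected, "retained_units")),
    n_units_excluded = n_units - length(attr(selected, "retained_units")),
    n_undefined_statistics = um$n_undefined,
    n_lfp_trials_dropped = if (is.null(lfp_res)) 0L
      else attr(lfp_res, "n_dropped") %||% 0L,
    contexts = contexts
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(session = session, metrics = um, lfp = lfp_res,
                 comparisons = comparisons, log = log))
}
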