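# Cross-context comparisons of unit metrics: paired Wilcoxon signed-rank
# tests (the nonparametric path, used because rate metrics rarely satisfy
# normality/homoscedasticity) with an in-repo step-down Holm-Bonferroni
# correction across stimuli.

#' Paired Wilcoxon signed-rank test between contexts
#'
#' Two-sided signed-rank test on paired per-unit values. `NA` pairs
#' (undefined statistics) are dropped pairwise and zero differences are
#' dropped by the Wilcoxon convention; both counts are recorded as
#' attributes. The null distribution is exact for n <= 25 without ties,
#' and a continuity-corrected normal approximation otherwise. If every
#' difference is zero the test is degenerate and p = 1 with a warning.
#'
#' @param values_ctx1,values_ctx2 Paired per-unit values.
#' @return List with `statistic` (V), `p_value`, `n_pairs` (used),
#'   `n_dropped_na`, `n_dropped_zero`.
#' @export
paired_context_test <- function(values_ctx1, values_ctx2) {
  stopifnot(length(values_ctx1) == length(values_ctx2))
  ok <- !is.na(values_ctx1) & !is.na(values_ctx2)
  n_na <- sum(!ok)
  d <- values_ctx1[ok] - values_ctx2[ok]
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(list(statistic = 0, p_value = 1, n_pairs = 0,
                n_dropped_na = n_na, n_dropped_zero = n_zero))
  }
  exact <- n <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n_pairs = n,
       n_dropped_na = n_na, n_dropped_zero = n_zero)
}

#' Holm-Bonferroni step-down correction
#'
#' Sort p ascending; the i-th smallest is multiplied by (m - i + 1) and
#' running maxima enforce monotonicity, capped at 1. Rejection uses the
#' adjusted values against `alpha`. Controls family-wise error at least as
#' powerfully as plain Bonferroni.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame `p_raw, p_adjusted, reject` in input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * p_values[o]))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  data.frame(p_raw = p_values, p_adjusted = adj, reject = adj < alpha)
}

#' Compare unit metrics between two contexts
#'
#' For each response metric (Z, offset Z, evoked rate, baseline rate, offset
#' ratio, d-prime relative to BOS): one pooled signed-rank test (the metric
#' averaged across stimuli within each unit, one paired value per unit; no
#' correction) plus per-stimulus tests corrected with Holm-Bonferroni across
#' stimuli. d-prime uses the BOS row of the selectivity matrix (BOS versus
#' each other stimulus). The SSA-based unit filter is expected to have been
#' applied upstream. A comparison with fewer than `min_units` common units
#' is skipped with a message.
#'
#' @param unit_metrics Result of [compute_unit_metrics()] (a list with
#'   `metrics` and `d_prime`), typically after [select_analysis_units()].
#' @param ctx1,ctx2 Context labels to compare.
#' @param alpha Significance level (default 0.05).
#' @param min_units Minimum common units per comparison (default 5).
#' @return Data frame `metric, scope, n_units, statistic, p_raw,
#'   p_adjusted, significant`.
#' @export
compare_contexts <- function(unit_metrics, ctx1, ctx2, alpha = 0.05,
                             min_units = 5) {
  metrics <- unit_metrics$metrics
  dmat <- unit_metrics$d_prime
  value_cols <- c(z = "z", offset_z = "offset_z", fr = "mean_fr_hz",
                  blfr = "mean_blfr_hz", offset_ratio = "offset_ratio")
  out <- list()
  add_row <- function(metric, scope, res, p_adj = NA_real_,
                      signif = NA) {
    out[[length(out) + 1L]] <<- data.frame(
      metric = metric, scope = scope, n_units = res$n_pairs,
      statistic = res$statistic, p_raw = res$p_value, p_adjusted = p_adj,
      significant = signif, stringsAsFactors = FALSE)
  }
  paired_values <- function(df, col, by) {
    # by: columns identifying a pairing unit (e.g. unit_id + stimulus)
    key <- do.call(paste, c(df[by], sep = "\r"))
    v1 <- df[[col]][df$context == ctx1]
    k1 <- key[df$context == ctx1]
    v2 <- df[[col]][df$context == ctx2]
    k2 <- key[df$context == ctx2]
    common <- intersect(k1, k2)
    list(x = v1[match(common, k1)], y = v2[match(common, k2)])
  }
  run_metric <- function(metric, df, col, stim_col) {
    # pooled scope: average the metric across stimuli within each unit,
    # then pair units across contexts (one value per unit avoids
    # pseudo-replication from correlated per-stimulus values)
    agg <- stats::aggregate(df[[col]],
                            by = list(unit_id = df$unit_id,
                                      context = df$context),
                            FUN = mean, na.rm = TRUE)
    names(agg)[3] <- col
    pooled <- paired_values(agg, col, "unit_id")
    if (length(pooled$x) >= min_units) {
      res <- paired_context_test(pooled$x, pooled$y)
      add_row(metric, "pooled", res, NA_real_, res$p_value < alpha)
    } else {
      message("skipping pooled ", metric, " comparison: fewer than ",
              min_units, " common pairs")
      return(invisible(NULL))
    }
    stims <- sort(unique(df[[stim_col]]))
    per <- list()
    for (st in stims) {
      sub <- df[df[[stim_col]] == st, , drop = FALSE]
      pv <- paired_values(sub, col, "unit_id")
      if (length(pv$x) < min_units) next
      per[[st]] <- paired_context_test(pv$x, pv$y)
    }
    if (length(per) > 0) {
      hb <- holm_bonferroni(vapply(per, function(r) r$p_value, numeric(1)),
                            alpha)
      for (i in seq_along(per))
        add_row(metric, names(per)[i], per[[i]], hb$p_adjusted[i],
                hb$reject[i])
    }
  }
  for (metric in names(value_cols))
    run_metric(metric, metrics, value_cols[[metric]], "stimulus")
  bos_row <- dmat[dmat$stim_a == "BOS" & dmat$stim_b != "BOS", , drop = FALSE]
  if (nrow(bos_row) > 0)
    run_metric("d_prime", bos_row, "d_prime", "stim_b")
  if (length(out) == 0)
    return(data.frame(metric = character(0), scope = character(0),
                      n_units = integer(0), statistic = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
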