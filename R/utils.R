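# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Each simulated unit, LFP channel and permutation comparison draws from its
#' own RNG stream so that adding or removing one object never perturbs the
#' others. The child seed is a deterministic 31-bit hash of the master seed
#' and the key.
#'
#' @param seed Integer master seed.
#' @param key Character key naming the stream (e.g. `"unit:u01"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 33 + b) %% m
  }
  as.integer(h)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Spike count in the half-open window [start, end). Spike trains are sorted
# on construction, so two binary searches suffice: findInterval with
# left.open counts the times strictly below a cut.
count_in_window <- function(times, start, end) {
  findInterval(end, times, left.open = TRUE) -
    findInterval(start, times, left.open = TRUE)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg),
       call. = FALSE)
}
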