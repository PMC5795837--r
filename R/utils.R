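# Internal helpers shared across modules.

EARTH_RADIUS_M <- 6371008.8
KMH_PER_MS <- 3.6

#' @keywords internal
kmh_to_ms <- function(kmh) kmh / KMH_PER_MS

#' @keywords internal
ms_to_kmh <- function(ms) ms * KMH_PER_MS

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Condition constructors so the CLI can map failures to exit codes
# (2 = bad input, 3 = bad config).
input_error <- function(msg) {
  stop(structure(class = c("ebt_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

config_error <- function(msg) {
  stop(structure(class = c("ebt_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
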