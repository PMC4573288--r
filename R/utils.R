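# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation functions are pure in (inputs, seed).
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific RNG seed from a root seed
#'
#' Each pipeline stage draws from its own substream, derived deterministically
#' from the root seed and the stage name, so adding or reordering stages never
#' perturbs the draws of other stages. The result is always a non-negative
#' integer below 2^31 - 1.
#'
#' @param seed root integer seed.
#' @param stage character scalar naming the stage (e.g. `"simulate"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1000003 + h * 97 + 17) %% 2147483647)
}

# Consistent numeric formatting for table writers (deterministic output).
#' @keywords internal
#' @noRd
fmt_num <- function(x, digits = 10) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("invalid value for '%s': must be a number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# Filtering stages report what they did: input count, output count, rule.
#' @keywords internal
#' @noRd
log_filter <- function(stage, n_in, n_out, rule) {
  message(sprintf("[%s] %d -> %d (%s)", stage, n_in, n_out, rule))
}
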