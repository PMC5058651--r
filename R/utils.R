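#' Round half away from zero
#'
#' Commercial rounding to a fixed number of decimals.  Base [round()] uses
#' round-half-to-even; cohort percentages here are reported with half-up
#' rounding (so 62.45 -> 62.5), matching how clinical frequencies are
#' conventionally printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 0.25), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a generator-specific substream seed from the master seed, kept
# inside 32-bit integer range.  Each generator owns one fixed offset so
# enlarging one generator's output never shifts another's stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset * 10007) %% 2147483647L)
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
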