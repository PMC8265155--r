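# Internal helpers: condition constructors, seeded RNG scoping, pair keys.

multisep_error <- function(message, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "multisep_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_degenerate <- function(msg, ...) stop(multisep_error(msg, "degenerate_gene_error", ...))
stop_insufficient <- function(msg, ...) stop(multisep_error(msg, "insufficient_data_error", ...))
stop_tissue_too_small <- function(msg, ...) stop(multisep_error(msg, "tissue_too_small_error", ...))
stop_not_testable <- function(msg, ...) stop(multisep_error(msg, "not_testable_error", ...))
stop_not_predictable <- function(msg, ...) stop(multisep_error(msg, "not_predictable_error", ...))
stop_config <- function(msg, ...) stop(multisep_error(msg, "config_error", ...))
stop_usage <- function(msg, ...) stop(multisep_error(msg, "usage_error", ...))
stop_value <- function(msg, ...) stop(multisep_error(msg, "value_error", ...))
stop_empty_gold <- function(msg, ...) stop(multisep_error(msg, "empty_gold_standard_error", ...))

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards, so seeded package internals
#' never perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed fan-out: one user-visible seed per invocation, derived
# per-task seeds via a fixed multiplicative hash (kept inside 32-bit range).
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Canonical unordered-pair key: symmetric, excludes self-pairs upstream.
pair_key <- function(a, b) {
  swap <- a > b
  ifelse(swap, paste(b, a, sep = "\r"), paste(a, b, sep = "\r"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
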