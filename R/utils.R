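#' @keywords internal
"_PACKAGE"

#' AAMI heartbeat class symbols
#'
#' The five consolidated heartbeat classes: normal (N), supraventricular
#' ectopic (S), ventricular ectopic (V), fusion (F) and unclassifiable (Q).
#' Integer label codes used throughout the package are 0:4 in this order.
#'
#' @export
AAMI_CLASSES <- c("N", "S", "V", "F", "Q")

# Validation helper: stop with a classed condition so callers (and the CLI)
# can distinguish validation errors from I/O or numerical failures.
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("ecgwolf_validation_error", "error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("ecgwolf_io_error", "error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("ecgwolf_config_error", "error")))
}

# Leveled logging. Silenced unless options(ecgwolf.verbose = TRUE).
log_msg <- function(..., level = "INFO") {
  if (isTRUE(getOption("ecgwolf.verbose", FALSE))) {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%H:%M:%S"), paste0(...)))
  }
  invisible(NULL)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions never perturb user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a stage seed from one global seed; keeps the
# result inside 32-bit integer range.
derive_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 1009 + 7919 * stage_index) %%
               .Machine$integer.max)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min &&
    x == floor(x)
}

clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)
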