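# internal helpers shared across modules

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ednaIBCH_error", "error")))
}
abort_validation <- function(msg) abort(msg, "ednaIBCH_validation_error")
abort_format     <- function(msg) abort(msg, "ednaIBCH_format_error")
abort_config     <- function(msg) abort(msg, "ednaIBCH_config_error")

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (0.5 -> 1), the convention
#' used when mapping continuous index predictions onto integer score categories.
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage seeds its RNG from a deterministic function of the global
#' seed and the stage name, so a stage re-run in isolation matches the full run.
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed below 2^31
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
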