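#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' stochastic stage draws its own seed from the master seed plus a fixed
#' per-stage offset, so stages are reproducible independently of one another.
#'
#' @param seed master integer seed.
#' @param stage character stage name (hashed to a fixed offset).
#' @return an integer seed below 2^31.
#' @export
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  off <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + off) %% 2147483629)
}

# machine-readable warning/notes channel: JSON lines on stderr
log_note <- function(event, ...) {
  rec <- c(list(event = event), list(...))
  message(jsonlite::toJSON(rec, auto_unbox = TRUE))
  invisible(rec)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
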