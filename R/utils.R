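#' @keywords internal
"_PACKAGE"

## Error constructors: every user-facing failure carries a class so the CLI can
## map it to an exit diagnostic and tests can assert on the failure mode.

ct_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "corotrack_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ct_format_error     <- function(msg) ct_error(msg, "corotrack_format_error")
ct_input_error      <- function(msg) ct_error(msg, "corotrack_input_error")
ct_validation_error <- function(msg) ct_error(msg, "corotrack_validation_error")
ct_parameter_error  <- function(msg) ct_error(msg, "corotrack_parameter_error")
ct_detection_error  <- function(msg) ct_error(msg, "corotrack_detection_error")
ct_degenerate_error <- function(msg) ct_error(msg, "corotrack_degenerate_error")
ct_scale_error      <- function(msg) ct_error(msg, "corotrack_scale_error")
ct_bank_error       <- function(msg) ct_error(msg, "corotrack_bank_error")
ct_generation_error <- function(msg) ct_error(msg, "corotrack_generation_error")

ct_log <- function(..., level = "INFO") {
  message(sprintf("[corotrack %s] %s", level, paste0(...)))
}

ct_warn <- function(...) ct_log(..., level = "WARN")

#' Run an expression with a local, restorable RNG state
#'
#' Used by the simulator so that generation is bit-reproducible under its
#' configured seed without disturbing the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_count <- function(x) {
  is_scalar_number(x) && x >= 0 && x == as.integer(x)
}

#' Clip values to an interval
#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)
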