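# Structured error conditions.  Stage failures carry a class so callers
# (and the run_full_analysis driver) can map them to exit codes:
# input 2, config 3, internal invariant 4.

agg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(class = c(class, "aggscape_error", "error", "condition"),
                 list(message = msg, call = call)))
}

input_error     <- function(msg) agg_stop(msg, "aggscape_input_error")
format_error    <- function(msg) agg_stop(msg, c("aggscape_format_error",
                                                 "aggscape_input_error"))
parameter_error <- function(msg) agg_stop(msg, c("aggscape_parameter_error",
                                                 "aggscape_config_error"))
config_error    <- function(msg) agg_stop(msg, "aggscape_config_error")
internal_error  <- function(msg) agg_stop(msg, "aggscape_internal_error")

#' Exit code associated with an aggscape condition
#'
#' Maps the package's condition classes onto the stable numeric contract
#' used by batch drivers: 0 success, 2 input error, 3 configuration error,
#' 4 internal invariant violation, 1 anything else.
#'
#' @param cond A condition object (or `NULL` for success).
#' @return Integer exit code.
#' @export
exit_code_for <- function(cond) {
  if (is.null(cond)) return(0L)
  if (inherits(cond, "aggscape_internal_error")) return(4L)
  if (inherits(cond, "aggscape_config_error"))   return(3L)
  if (inherits(cond, "aggscape_input_error"))    return(2L)
  1L
}
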