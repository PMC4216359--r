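# shared input-validation helpers

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}
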