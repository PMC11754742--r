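# Classed error conditions so callers and tests can dispatch on failure mode.

stop_editpause <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("editpause_", class), "editpause_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
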