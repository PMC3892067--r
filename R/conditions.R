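# Classed conditions so callers can distinguish invalid input from
# degenerate statistics, parse failures and integrator breakdowns.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tipigtow_invalid_input", "tipigtow_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tipigtow_degenerate_variance", "tipigtow_error")))
}

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tipigtow_parse_error", "tipigtow_error")))
}

stop_simulation <- function(msg, last_good_time = NA_real_, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      last_good_time = last_good_time,
                      class = c("tipigtow_simulation_error", "tipigtow_error")))
}

stop_no_baseline <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tipigtow_no_viable_baseline", "tipigtow_error")))
}

stop_unmapped <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("tipigtow_unmapped_gene", "tipigtow_error")))
}
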