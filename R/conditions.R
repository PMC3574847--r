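# Classed conditions so callers can distinguish failure modes programmatically.

hc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "haploclone_error"), call = call))
}

hc_input_error     <- function(msg) hc_stop(msg, "hc_input_error")
hc_alignment_error <- function(msg) hc_stop(msg, "hc_alignment_error")
hc_logic_error     <- function(msg) hc_stop(msg, "hc_logic_error")
hc_undefined_error <- function(msg) hc_stop(msg, "hc_undefined_statistic")
hc_analysis_error  <- function(msg) hc_stop(msg, "hc_analysis_error")
hc_pipeline_error  <- function(msg) hc_stop(msg, "hc_pipeline_error")
hc_parameter_error <- function(msg) hc_stop(msg, "hc_parameter_error")
hc_no_test_error   <- function(msg) hc_stop(msg, "hc_no_test")

# locale-independent string ordering used everywhere a deterministic
# lexicographic tie-break is required
lex_order <- function(...) order(..., method = "radix")
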