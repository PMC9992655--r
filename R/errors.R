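# Typed error conditions so callers and tests can branch on failure mode
# rather than on message text.

oda_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "oda_error"), call = call))
}

no_signal_error <- function(msg = "image has no signal (constant after mean subtraction)") {
  oda_error(msg, "oda_no_signal")
}

lattice_not_found_error <- function(msg) {
  oda_error(msg, "oda_lattice_not_found")
}

undefined_error <- function(msg) {
  oda_error(msg, "oda_undefined")
}

ill_conditioned_error <- function(msg) {
  oda_error(msg, "oda_ill_conditioned")
}

io_error <- function(msg) {
  oda_error(msg, "oda_io_error")
}

config_error <- function(msg) {
  oda_error(msg, "oda_config_error")
}
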