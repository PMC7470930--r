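# Typed condition helpers. Every user-facing failure is classed so callers
# (and tests) can distinguish validation, geometry and I/O problems.

stop_spinemorph <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "spinemorph_error"), call = call))
}

stop_validation <- function(message) stop_spinemorph(message, "spinemorph_validation_error")
stop_geometry   <- function(message) stop_spinemorph(message, "spinemorph_geometry_error")
stop_io         <- function(message) stop_spinemorph(message, "spinemorph_io_error")
stop_stat       <- function(message) stop_spinemorph(message, "spinemorph_stat_error")

# round half up at `digits` decimals; base round() rounds half to even, which
# does not reproduce conventionally reported percentages such as 27.3.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
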