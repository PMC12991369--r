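# Internal helpers shared across modules.

# Nearest-integer rounding with ties resolved half-up (x.5 -> x + 1).
# base::round() rounds half-to-even, which would make expected insertion
# counts depend on parity; a fixed half-up rule keeps results reproducible.
round_half_up <- function(x) floor(x + 0.5)

# Integer-valued check that tolerates doubles read from text files.
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
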