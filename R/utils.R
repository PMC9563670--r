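# round half away from zero (printed-table convention), to `digits` decimals
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
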