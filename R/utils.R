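# deterministic substream seeds below 2^31, derived from a single study seed
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' @keywords internal
"_PACKAGE"
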