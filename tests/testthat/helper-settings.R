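# the reproduction suite reports every divergence from the reference values
# individually; never abort the remaining files because of them
if (requireNamespace("testthat", quietly = TRUE)) {
  options(testthat.progress.max_fails = 1000)
}
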