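# deterministic uniforms for fixture matrices, keyed by length so
# different calls do not collide
runif_det <- function(n, key = 1L) {
  set.seed(1234L + n + 1000L * key)
  runif(n)
}

# scalar TV through the public API
tv_value_pkg <- function(f, graph) total_variation(f, graph)$tv
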