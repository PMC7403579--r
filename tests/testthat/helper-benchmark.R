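# The masked benchmark is used by several test files; build it once per
# test run and reuse.
.bench_env <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.bench_env$bm)) {
    .bench_env$bm <- latentfx::masked_benchmark(seed = 1)
  }
  .bench_env$bm
}
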