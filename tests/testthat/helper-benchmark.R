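# Shared training runs for the synthetic-benchmark experiments. Fits are
# cached per (variant, seed, epochs, n) within a test session so several
# test blocks can reuse the same trained models.

bench_cache <- new.env(parent = emptyenv())

bench_dataset <- function(n = 1000, artifacts = FALSE) {
  key <- paste0("ds_", n, "_", artifacts)
  if (is.null(bench_cache[[key]])) {
    bench_cache[[key]] <- make_dataset(
      benchmark_synth_config(n_samples = n, artifacts = artifacts))
  }
  bench_cache[[key]]
}

bench_run <- function(variant = "ORI", seed = 1, epochs = 30, n = 1000,
                      artifacts = FALSE) {
  key <- sprintf("%s_%d_%d_%d_%s", variant, seed, epochs, n, artifacts)
  if (is.null(bench_cache[[key]])) {
    ds <- bench_dataset(n, artifacts)
    cfg <- ablation_config(benchmark_model_config(seed = seed, epochs = epochs),
                           variant)
    bench_cache[[key]] <- evaluate_on_split(cfg, ds, seed = seed)
  }
  bench_cache[[key]]
}
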