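# A cheap injectable trainer: classify by thresholding seizure-band power at
# the midpoint of the class means seen in training. Exercises the protocol
# plumbing without fitting the network.
bp_trainer <- function(fs = 32, lo = 3, hi = 8) {
  function(x_train, y_train, x_test, seed) {
    bp <- band_power(x_train, fs, lo, hi)
    thr <- (mean(bp[y_train == 1]) + mean(bp[y_train == 0])) / 2
    as.integer(band_power(x_test, fs, lo, hi) > thr)
  }
}

proto_dataset <- function(n = 100, seed = 8) {
  make_dataset(synth_config(n_samples = n, segment_length = 32,
                            sampling_rate = 32, prevalence = 0.3, snr = 6,
                            band = c(3, 8), rhythms = list(), seed = seed))
}
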