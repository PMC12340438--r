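# Seedable synthetic EEG generator. Non-seizure segments are 1/f^beta
# ("pink") background noise plus optional ongoing rhythms; seizure segments
# add band-limited oscillatory bursts and sparse high-amplitude spike
# transients, emulating the slow-wave rhythm and spike morphology that the
# network's mechanisms are designed to exploit.

#' Synthetic dataset configuration
#'
#' @param n_samples Total number of segments.
#' @param segment_length Samples per segment `L`. Default 1228.
#' @param sampling_rate Hz. Default 256.
#' @param prevalence Fraction of seizure segments, allocated exactly
#'   (`round(n * prevalence)` positives). Default 0.0977 (~711/7280).
#' @param beta Background spectral exponent (`1/f^beta`); 1 = pink,
#'   0 = white.
#' @param highpass_hz High-pass cutoff emulating the acquisition hardware
#'   filter: spectral content strictly below this frequency (and the DC
#'   component) is removed from the background. Default 0.5 Hz.
#' @param rhythms List of `c(frequency_hz, amplitude)` pairs of ongoing
#'   background oscillations. Default: a 10 Hz rhythm at amplitude 0.5.
#' @param band Seizure oscillation band `c(lo_hz, hi_hz)`. Default 3-8 Hz.
#' @param burst_rate Expected seizure bursts per second. Default 1.
#' @param spike_amplitude Peak amplitude of spike transients, in units of
#'   the (unit) background standard deviation. Default 4.
#' @param spike_rate Expected spikes per second in seizure segments.
#'   Default 1.
#' @param artifact_rate Expected broadband (EMG-like) artifact bursts per
#'   second, affecting both classes. Default 0 (no artifacts).
#' @param artifact_amplitude Artifact burst amplitude in background-sd
#'   units. Default 3.
#' @param artifact_band Frequency band of artifact noise, Hz. Default
#'   c(20, 60) (clipped to Nyquist).
#' @param snr Amplitude of seizure-band bursts relative to the unit
#'   background standard deviation. Default 3 (a strongly expressed,
#'   learnable signature).
#' @param seed RNG seed recorded in the manifest.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_samples = 1000,
                         segment_length = 1228,
                         sampling_rate = 256,
                         prevalence = 0.0977,
                         beta = 1,
                         highpass_hz = 0.5,
                         rhythms = list(c(10, 0.5)),
                         band = c(3, 8),
                         burst_rate = 1,
                         spike_amplitude = 4,
                         spike_rate = 1,
                         artifact_rate = 0,
                         artifact_amplitude = 3,
                         artifact_band = c(20, 60),
                         snr = 3,
                         seed = 1L) {
  if (segment_length < 2) stop("`segment_length` must be >= 2.", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly in (0, 1).", call. = FALSE)
  }
  nyq <- sampling_rate / 2
  if (band[2] <= band[1] || band[2] > nyq) {
    stop(sprintf("Seizure band must be increasing and below Nyquist (%g Hz).", nyq),
         call. = FALSE)
  }
  for (r in rhythms) {
    if (r[1] > nyq) stop(sprintf("Rhythm at %g Hz is above Nyquist.", r[1]), call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), segment_length = as.integer(segment_length),
    sampling_rate = sampling_rate, prevalence = prevalence, beta = beta,
    highpass_hz = highpass_hz, rhythms = rhythms, band = band, burst_rate = burst_rate,
    spike_amplitude = spike_amplitude, spike_rate = spike_rate,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    artifact_band = artifact_band, snr = snr, seed = as.integer(seed)
  ), class = "synth_config")
}

# One batch of background segments drawn from the *current* RNG stream.
draw_background <- function(n, cfg) {
  L <- cfg$segment_length
  N <- L %/% 2L + 1L
  tt <- (seq_len(L) - 1L) / cfg$sampling_rate
  out <- matrix(0, n, L)
  for (i in seq_len(n)) {
    w <- stats::rnorm(L)
    F <- rfft_forward(matrix(w, 1))
    shape <- c(0, seq_len(N - 1L)^(-cfg$beta / 2))   # DC removed: zero mean
    freqs <- (seq_len(N) - 1L) * cfg$sampling_rate / L
    shape[freqs < cfg$highpass_hz] <- 0              # acquisition high-pass
    x <- irfft_backward(F * matrix(shape, 1), L)
    x <- x / stats::sd(x)                             # unit background scale
    for (r in cfg$rhythms) {
      x <- x + r[2] * sin(2 * pi * r[1] * tt + stats::runif(1, 0, 2 * pi))
    }
    if ((cfg$artifact_rate %||% 0) > 0) {
      x <- x + draw_artifacts(cfg)
    }
    out[i, ] <- x - mean(x)
  }
  out
}

# Broadband (EMG-like) artifact bursts: band-limited noise under a raised
# cosine envelope, present in both classes. Drawn from the current RNG
# stream.
draw_artifacts <- function(cfg) {
  L <- cfg$segment_length
  fs <- cfg$sampling_rate
  dur_s <- L / fs
  out <- numeric(L)
  n_art <- stats::rpois(1, cfg$artifact_rate * dur_s)
  if (n_art == 0) return(out)
  N <- L %/% 2L + 1L
  freqs <- (seq_len(N) - 1L) * fs / L
  lo <- cfg$artifact_band[1]
  hi <- min(cfg$artifact_band[2], fs / 2)
  bandmask <- as.numeric(freqs >= lo & freqs <= hi)
  tt <- (seq_len(L) - 1L) / fs
  for (j in seq_len(n_art)) {
    noise <- irfft_backward(rfft_forward(matrix(stats::rnorm(L), 1)) *
                              matrix(bandmask, 1), L)[1, ]
    noise <- noise / max(stats::sd(noise), 1e-12)
    center <- stats::runif(1, 0, dur_s)
    width <- stats::runif(1, 0.1, 0.3)
    rel <- (tt - center) / width
    env <- ifelse(abs(rel) <= 0.5, cos(pi * rel)^2, 0)
    out <- out + cfg$artifact_amplitude * stats::runif(1, 0.8, 1.2) * env * noise
  }
  out
}

# Add the seizure signature (bursts + spikes) to one background segment,
# drawing from the current RNG stream.
add_seizure_signature <- function(x, cfg) {
  L <- cfg$segment_length
  fs <- cfg$sampling_rate
  dur_s <- L / fs
  tt <- (seq_len(L) - 1L) / fs
  # a seizure window overlaps a discharge by definition: at least one burst
  # (unless bursts are disabled outright)
  n_burst <- if (cfg$burst_rate > 0) {
    max(1L, stats::rpois(1, cfg$burst_rate * dur_s))
  } else 0L
  for (j in seq_len(n_burst)) {
    f <- stats::runif(1, cfg$band[1], cfg$band[2])
    width <- stats::runif(1, 0.3, 0.7)               # burst duration, seconds
    center <- stats::runif(1, 0.2 * dur_s, 0.8 * dur_s)
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- cfg$snr * stats::runif(1, 0.8, 1.2)
    rel <- (tt - center) / width
    env <- ifelse(abs(rel) <= 0.5, cos(pi * rel)^2, 0)
    x <- x + amp * env * sin(2 * pi * f * tt + phase)
  }
  n_spike <- stats::rpois(1, cfg$spike_rate * dur_s)
  for (j in seq_len(n_spike)) {
    center <- stats::runif(1, 0, dur_s)
    width <- 0.02 * stats::runif(1, 0.8, 1.2)        # ~20 ms half-width
    amp <- cfg$spike_amplitude * stats::runif(1, 0.8, 1.2)
    rel <- (tt - center) / width
    x <- x + amp * rel * exp(0.5 - rel^2 / 2)        # biphasic transient
  }
  x
}

#' Generate non-seizure background segments
#'
#' `1/f^beta` noise (unit standard deviation, exactly zero DC component)
#' plus the configured ongoing rhythms at random phase.
#'
#' @param n Number of segments.
#' @param cfg A [synth_config()].
#' @param seed RNG seed; identical seeds give bitwise-identical output.
#' @return Matrix `n x L`.
#' @export
generate_background <- function(n, cfg, seed = cfg$seed) {
  set.seed(seed)
  draw_background(n, cfg)
}

#' Generate seizure segments
#'
#' Background noise (drawn exactly as [generate_background()] would from the
#' same seed) plus band-limited oscillatory bursts and sparse spike
#' transients. With `burst_rate = 0` and `spike_amplitude = 0` the output is
#' distributionally (and, spike-rate permitting, bitwise) the background.
#'
#' @inheritParams generate_background
#' @return Matrix `n x L`.
#' @export
generate_seizure <- function(n, cfg, seed = cfg$seed) {
  set.seed(seed)
  out <- draw_background(n, cfg)
  if (cfg$burst_rate == 0 && cfg$spike_amplitude == 0 && cfg$spike_rate == 0) {
    return(out)
  }
  for (i in seq_len(n)) out[i, ] <- add_seizure_signature(out[i, ], cfg)
  out
}

#' Generate a labeled synthetic dataset
#'
#' Allocates `round(n * prevalence)` seizure segments exactly, generates both
#' classes, and shuffles them. The manifest (the config itself) fully
#' determines the dataset: regeneration is bitwise-identical.
#'
#' @param cfg A [synth_config()].
#' @return List of class `eeg_dataset`: `segments` (`n x L`), `labels`
#'   (binary, 1 = seizure), `manifest` (the config).
#' @examples
#' ds <- make_dataset(synth_config(n_samples = 20, segment_length = 64,
#'                                 prevalence = 0.25, seed = 3))
#' table(ds$labels)
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_samples
  n_pos <- round(n * cfg$prevalence)
  if (n_pos < 1) {
    stop("`prevalence * n_samples` must be at least 1.", call. = FALSE)
  }
  n_neg <- n - n_pos
  pos <- generate_seizure(n_pos, cfg, seed = cfg$seed)
  neg <- generate_background(n_neg, cfg, seed = cfg$seed + 1L)
  segments <- rbind(pos, neg)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  set.seed(cfg$seed + 2L)
  ord <- sample.int(n)
  structure(list(segments = segments[ord, , drop = FALSE],
                 labels = labels[ord], manifest = cfg),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d segments x %d samples @ %g Hz | %d seizure (%.1f%%)\n",
              nrow(x$segments), ncol(x$segments), x$manifest$sampling_rate,
              sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

#' Mean band power of each segment
#'
#' Average squared one-sided spectral amplitude over the bins inside
#' `[lo_hz, hi_hz]`. Used e.g. by the benchmark's power-threshold reference
#' classifier.
#'
#' @param x Segments (`eeg_batch`, `eeg_dataset` or matrix).
#' @param sampling_rate Hz.
#' @param lo_hz,hi_hz Band edges.
#' @return Numeric vector, one value per segment.
#' @export
band_power <- function(x, sampling_rate, lo_hz, hi_hz) {
  if (inherits(x, "eeg_dataset")) x <- x$segments
  x <- as_segment_matrix(x)
  L <- ncol(x)
  A2 <- amplitude_spectrum(rfft_forward(x))^2
  freqs <- (seq_len(ncol(A2)) - 1L) * sampling_rate / L
  sel <- freqs >= lo_hz & freqs <= hi_hz
  if (!any(sel)) stop("No frequency bins inside the requested band.", call. = FALSE)
  rowMeans(A2[, sel, drop = FALSE])
}
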