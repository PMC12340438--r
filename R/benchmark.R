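# The bundled desk-scale benchmark: a fixed synthetic study configuration
# used by the package's acceptance experiments. Sizes are chosen for CPU
# training in R; all scale-free protocol conditions (prevalence, band,
# split ratio, stratification) follow the reference protocol. Rationale for
# each choice is in the methods vignette.

#' Benchmark generator configuration
#'
#' Segments of 128 samples at 128 Hz, 10% seizure prevalence, 3-8 Hz
#' seizure band at high snr over high-passed pink noise, no background
#' rhythm distractor. With `artifacts = TRUE`, class-neutral 10-16 Hz
#' artifact bursts are added to both classes: a noise band that
#' window-mean pooling cannot remove but spectral masking can, used by the
#' ablation experiment so the frequency-selection stage has a measurable
#' role.
#'
#' @param n_samples Number of segments. Default 1000.
#' @param seed Generator seed. Default 11.
#' @param artifacts Add the 10-16 Hz artifact bursts. Default `FALSE`.
#' @return A [synth_config()].
#' @export
benchmark_synth_config <- function(n_samples = 1000, seed = 11L,
                                   artifacts = FALSE) {
  synth_config(n_samples = n_samples, segment_length = 128,
               sampling_rate = 128, prevalence = 0.1, band = c(3, 8),
               snr = 6, highpass_hz = 1.5, rhythms = list(),
               artifact_rate = if (artifacts) 1 else 0,
               artifact_amplitude = 4, artifact_band = c(10, 16),
               seed = seed)
}

#' Benchmark model configuration
#'
#' A scaled-down instance of the architecture (scales [32, 16, 8], embedding
#' width 16, 4 heads, DFS hidden width 32) in its literal form: no mask
#' renormalization, no attention rescaling, plain Adam at 2e-3 for 30
#' epochs.
#'
#' @param seed Initialization/training seed.
#' @param epochs Training epochs. Default 30.
#' @param ... Further [model_config()] overrides.
#' @return A [model_config()].
#' @export
benchmark_model_config <- function(seed = 1L, epochs = 30, ...) {
  args <- list(segment_length = 128, sampling_rate = 128,
               scales = c(32, 16, 8), embed_dim = 16, n_heads = 4,
               dfs_hidden = 32, kernel_size = 15, tau = 1.0,
               learning_rate = 2e-3,
               batch_size = 32, epochs = epochs, seed = as.integer(seed))
  do.call(model_config, utils::modifyList(args, list(...)))
}

#' In-band vs out-of-band weight of the learned spectral mask
#'
#' Runs the deterministic spectral-selection stage over the given segments
#' and compares the mean mask weight inside a frequency band with the mean
#' weight outside it.
#'
#' @param model A trained `seizenet_model` (or `seizenet_fit`).
#' @param segments Segment matrix (typically the seizure segments, whose
#'   discharge band the mask is expected to accentuate).
#' @param band `c(lo_hz, hi_hz)`.
#' @return List: `ratio` (in/out mean-weight ratio), `in_band`, `out_band`.
#' @export
band_mask_ratio <- function(model, segments, band) {
  if (inherits(model, "seizenet_fit")) model <- model$model
  prof <- dfs_mask_profile(model, segments)
  sel <- prof$frequency_hz >= band[1] & prof$frequency_hz <= band[2]
  inw <- mean(prof$mean_weight[sel])
  outw <- mean(prof$mean_weight[!sel])
  list(ratio = inw / outw, in_band = inw, out_band = outw)
}
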