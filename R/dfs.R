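#' Parameters of the dynamic frequency selection (DFS) stage
#'
#' The DFS stage scores each of the `N = floor(L/2) + 1` one-sided frequency
#' bins of a segment with a two-layer perceptron applied to the amplitude
#' spectrum, converts the scores into a probabilistic spectral mask via the
#' Gumbel-SoftMax relaxation at temperature `tau`, scales the complex
#' spectrum by the mask, and transforms back to the time domain.
#'
#' @param n_bins Number of one-sided frequency bins `N`.
#' @param hidden_dim Hidden width of the scoring perceptron. Default 64.
#' @param tau Gumbel-SoftMax temperature (> 0). Small values sharpen the mask
#'   towards a near one-hot band selection, large values flatten it. Default 1.
#' @param init_sd Standard deviation of the Gaussian weight initialization
#'   (`"random"` scheme).
#' @param init `"amplitude"` (default) starts the scorer as a nonnegative
#'   low-rank smoothing of its amplitude input, so the initial mask
#'   concentrates on amplitude-salient frequencies and training refines that
#'   anchor; `"random"` is a plain Gaussian initialization.
#' @return List of class `dfs_params` with weights `W1` (`hidden_dim x N`),
#'   `b1`, `W2` (`N x hidden_dim`), `b2`, and the fixed `tau`.
#' @export
dfs_params <- function(n_bins, hidden_dim = 64, tau = 1.0, init_sd = NULL,
                       init = c("amplitude", "random")) {
  if (tau <= 0) stop("`tau` must be positive.", call. = FALSE)
  init <- match.arg(init)
  if (is.null(init_sd)) init_sd <- 1 / sqrt(n_bins)
  if (init == "amplitude") {
    # S = W2 relu(W1 A) with W2 = c t(W1) and W1 ~ N(0, 1/H): in expectation
    # S ~ (c/2) A plus zero-mean crosstalk, so the initial logits (and hence
    # the initial mask) follow the amplitude spectrum of the input at
    # order-one logit scale for unit-variance signals. Training refines this
    # amplitude anchor instead of starting from an arbitrary projection.
    R <- rnorm_mat(hidden_dim, n_bins, 1 / sqrt(hidden_dim))
    W1 <- R
    W2 <- t(R) * (16 / n_bins)
  } else {
    W1 <- rnorm_mat(hidden_dim, n_bins, init_sd)
    W2 <- rnorm_mat(n_bins, hidden_dim, 1 / sqrt(hidden_dim))
  }
  structure(list(
    W1 = W1,
    b1 = numeric(hidden_dim),
    W2 = W2,
    b2 = numeric(n_bins),
    tau = tau,
    hidden_dim = hidden_dim,
    n_bins = n_bins
  ), class = "dfs_params")
}

#' Score frequency bins with the two-layer perceptron
#'
#' `S = W2 %*% relu(W1 %*% A + b1) + b2`, applied per batch row.
#'
#' @param A Real amplitude matrix `B x N`.
#' @param p A [dfs_params()] object.
#' @return Real logit matrix `B x N`.
#' @export
score_frequencies <- function(A, p) {
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  if (ncol(A) != ncol(p$W1)) {
    stop(sprintf("Amplitude has %d bins but scorer expects %d.",
                 ncol(A), ncol(p$W1)), call. = FALSE)
  }
  Z1 <- sweep(A %*% t(p$W1), 2, p$b1, "+")
  sweep(relu(Z1) %*% t(p$W2), 2, p$b2, "+")
}

#' Gumbel-SoftMax frequency weights
#'
#' Converts per-bin logits into a probabilistic spectral mask:
#' `w[b, k] = exp((s[b, k] + g[k]) / tau) / sum_j exp((s[b, j] + g[j]) / tau)`
#' where `g ~ Gumbel(0, 1)`. Rows sum to 1; the map is differentiable in `S`,
#' so gradients flow through the (relaxed) discrete selection.
#'
#' @param S Logit matrix `B x N`.
#' @param tau Positive temperature.
#' @param noise One of `"sample"` (draw fresh Gumbel noise from the current
#'   RNG stream), `"none"` (deterministic: plain tempered softmax, used at
#'   inference), or a fixed numeric matrix/vector of noise to inject.
#' @param shared Logical; if `TRUE` one noise vector of length `N` is shared
#'   by every batch row (the literal per-frequency reading), otherwise noise
#'   is drawn independently per row. Default `FALSE`.
#' @return Mask matrix `B x N`, rows summing to 1, entries in (0, 1).
#' @export
gumbel_softmax_weights <- function(S, tau = 1.0, noise = "none", shared = FALSE) {
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("`tau` must be a positive scalar.", call. = FALSE)
  }
  g <- gumbel_noise_like(S, noise, shared)
  row_softmax((S + g) / tau)
}

gumbel_noise_like <- function(S, noise, shared) {
  if (is.character(noise)) {
    if (noise == "none") return(matrix(0, nrow(S), ncol(S)))
    if (noise == "sample") {
      if (shared) {
        g <- rgumbel(ncol(S))
        return(matrix(g, nrow(S), ncol(S), byrow = TRUE))
      }
      return(matrix(rgumbel(length(S)), nrow(S), ncol(S)))
    }
    stop("`noise` must be \"sample\", \"none\", or a numeric array.", call. = FALSE)
  }
  if (is.vector(noise)) noise <- matrix(noise, nrow(S), ncol(S), byrow = TRUE)
  if (!all(dim(noise) == dim(S))) stop("Fixed noise shape mismatch.", call. = FALSE)
  noise
}

#' Apply a spectral mask to complex coefficients
#'
#' Elementwise product `F * W` with a real nonnegative mask, so the phase of
#' every retained coefficient is unchanged.
#'
#' @param F Complex matrix `B x N`.
#' @param W Real mask of the same shape.
#' @return Complex matrix `B x N`.
#' @export
spectral_filter <- function(F, W) {
  if (is.vector(F)) F <- matrix(F, nrow = 1)
  if (is.vector(W)) W <- matrix(W, nrow = 1)
  if (!all(dim(F) == dim(W))) stop("Mask and spectrum shapes differ.", call. = FALSE)
  F * W
}

#' Dynamic frequency selection forward pass
#'
#' Runs the full DFS pipeline on a batch: one-sided FFT, amplitude scoring,
#' Gumbel-SoftMax mask, complex spectral filtering, inverse FFT. The returned
#' state retains the spectrum and mask for interpretability export and for
#' the analytic backward pass.
#'
#' @param x An [eeg_batch()] or numeric matrix `B x L`.
#' @param p A [dfs_params()] object sized for `N = floor(L/2) + 1` bins.
#' @param noise Passed to [gumbel_softmax_weights()]; default `"none"`.
#' @param shared_noise Share one Gumbel draw across the batch.
#' @param mask_gain Optional multiplier applied to the mask (e.g. `N` to
#'   compensate the softmax's ~1/N attenuation). Default 1 (literal mask).
#' @return List with `filtered` (`B x L` real) and `state`, a list of class
#'   `spectral_state` holding `coefficients`, `amplitude`, `logits`, `mask`,
#'   `n_bins`, plus a `cache` for the backward pass.
#' @export
dfs_forward <- function(x, p, noise = "none", shared_noise = FALSE, mask_gain = 1) {
  x <- as_segment_matrix(x)
  L <- ncol(x)
  N <- L %/% 2L + 1L
  if (N != p$n_bins) {
    stop(sprintf("DFS params built for %d bins; input has %d.", p$n_bins, N),
         call. = FALSE)
  }
  F <- rfft_forward(x)
  A <- amplitude_spectrum(F)
  Z1 <- sweep(A %*% t(p$W1), 2, p$b1, "+")
  R1 <- relu(Z1)
  S <- sweep(R1 %*% t(p$W2), 2, p$b2, "+")
  g <- gumbel_noise_like(S, noise, shared_noise)
  W <- row_softmax((S + g) / p$tau)
  Wg <- W * mask_gain
  Ft <- spectral_filter(F, Wg)
  xt <- irfft_backward(Ft, L)
  state <- structure(list(
    coefficients = F, amplitude = A, logits = S, mask = W, n_bins = N,
    cache = list(Z1 = Z1, R1 = R1, A = A, W = W, mask_gain = mask_gain, L = L)
  ), class = "spectral_state")
  list(filtered = xt, state = state)
}

# Backward pass of dfs_forward with respect to the scorer parameters.
# grad_x: upstream gradient on the filtered time-domain output (B x L).
# Returns gradients for W1, b1, W2, b2 (input gradient is not needed: x is
# data, and the amplitude path terminates at the input).
dfs_backward <- function(grad_x, p, state) {
  cc <- state$cache
  adj <- irfft_adjoint(grad_x)
  F <- state$coefficients
  # F~ = F * (W * gain): dW = gain * (Re F dRe + Im F dIm)
  dW <- cc$mask_gain * (Re(F) * adj$re + Im(F) * adj$im)
  dZw <- row_softmax_vjp(cc$W, dW)           # pre-softmax (S + g)/tau
  dS <- dZw / p$tau
  dW2 <- crossprod(dS, cc$R1)
  db2 <- colSums(dS)
  dR1 <- dS %*% p$W2
  dZ1 <- dR1 * (cc$Z1 > 0)
  dW1 <- crossprod(dZ1, cc$A)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Export a learned spectral mask for interpretability
#'
#' Averages per-segment masks over a dataset and writes (or returns) a table
#' mapping each frequency bin to its mean selection weight.
#'
#' @param mask Mask matrix `B x N` (e.g. `state$mask` from [dfs_forward()],
#'   or the mask field of a fitted model's [dfs_mask_profile()]).
#' @param sampling_rate Hz, used to convert bin index to frequency.
#' @param segment_length Segment length `L` (bin `k` maps to `k * fs / L` Hz).
#' @param file Optional path; when given, a CSV with columns
#'   `bin_index,frequency_hz,mean_weight` is written.
#' @return A tibble with columns `bin_index` (0-based), `frequency_hz`,
#'   `mean_weight`, invisibly when `file` is given.
#' @export
export_mask <- function(mask, sampling_rate, segment_length, file = NULL) {
  if (is.vector(mask)) mask <- matrix(mask, nrow = 1)
  out <- tibble::tibble(
    bin_index = seq_len(ncol(mask)) - 1L,
    frequency_hz = (seq_len(ncol(mask)) - 1L) * sampling_rate / segment_length,
    mean_weight = colMeans(mask)
  )
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
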