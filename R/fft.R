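#' One-sided (real-input) discrete Fourier transform of a segment batch
#'
#' Computes the complex one-sided spectrum of each row of a real segment
#' matrix. For segments of length `L` the spectrum has
#' `N = floor(L / 2) + 1` unique frequency bins; bin `k` (0-based)
#' corresponds to `k * fs / L` Hz.
#'
#' @param x An [eeg_batch()] or numeric matrix `B x L`.
#' @return Complex matrix `B x N`.
#' @seealso [irfft_backward()] for the inverse, [amplitude_spectrum()].
#' @examples
#' x <- matrix(sin(2 * pi * 4 * (0:63) / 64), 1)
#' F <- rfft_forward(x)
#' which.max(Mod(F)) - 1  # bin 4
#' @export
rfft_forward <- function(x) {
  x <- as_segment_matrix(x)
  L <- ncol(x)
  N <- L %/% 2L + 1L
  full <- t(stats::mvfft(t(x)))       # B x L complex, rows transformed
  full[, seq_len(N), drop = FALSE]
}

#' Inverse of the one-sided transform
#'
#' Reconstructs real time-domain segments of length `L` from a one-sided
#' spectrum by Hermitian symmetrization. The imaginary parts of the DC bin
#' (and, for even `L`, the Nyquist bin) do not contribute: for a spectrum
#' obtained from real input they are zero anyway.
#'
#' @param F Complex (or numeric) matrix `B x N` with `N = floor(L/2) + 1`.
#' @param L Target segment length.
#' @return Real matrix `B x L`.
#' @export
irfft_backward <- function(F, L) {
  if (is.vector(F)) F <- matrix(F, nrow = 1)
  N <- ncol(F)
  if (N != L %/% 2L + 1L) {
    stop(sprintf("Spectrum has %d bins but length %d requires %d.",
                 N, L, L %/% 2L + 1L), call. = FALSE)
  }
  full <- matrix(0 + 0i, nrow(F), L)
  full[, seq_len(N)] <- F
  if (L > 2) {
    hi <- if (L %% 2L == 0L) (N - 1L) else N     # last bin to mirror
    full[, L + 2L - (2:hi)] <- Conj(F[, 2:hi, drop = FALSE])
  }
  Re(t(stats::mvfft(t(full), inverse = TRUE))) / L
}

# Weights of each one-sided bin in the real reconstruction: 1 for DC and
# (even L) Nyquist, 2 for all mirrored interior bins. Used by the adjoint.
rfft_bin_weights <- function(L) {
  N <- L %/% 2L + 1L
  w <- rep(2, N)
  w[1] <- 1
  if (L %% 2L == 0L) w[N] <- 1
  w
}

# Adjoint of irfft_backward with respect to the (Re, Im) parts of the
# one-sided spectrum: for real upstream gradient g (B x L),
#   d/dRe_k = (w_k / L) Re(rfft(g)),  d/dIm_k = (w_k / L) Im(rfft(g)).
irfft_adjoint <- function(grad_x) {
  L <- ncol(grad_x)
  G <- rfft_forward(grad_x)
  w <- rfft_bin_weights(L)
  list(re = sweep(Re(G), 2, w / L, "*"),
       im = sweep(Im(G), 2, w / L, "*"))
}

#' Amplitude spectrum
#'
#' Elementwise modulus of complex spectral coefficients.
#'
#' @param F Complex matrix (or vector).
#' @return Nonnegative real array of the same shape.
#' @export
amplitude_spectrum <- function(F) {
  Mod(F)
}
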