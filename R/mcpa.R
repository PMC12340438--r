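# Phase-aware fusion: key-waveform attention via a hybrid learnable/impulse
# template, per-scale alignment of the enhanced signal, a small phase-offset
# network, sigmoid gating, and the classification head.

#' Impulse kernel (1 at the center position, 0 elsewhere)
#'
#' @param k Odd kernel size.
#' @return Numeric vector of length `k`.
#' @export
impulse_kernel <- function(k) {
  k0 <- numeric(k)
  k0[(k %/% 2L) + 1L] <- 1
  k0
}

#' Hybrid waveform template
#'
#' Blends a trainable base pattern with a fixed center impulse,
#' `K = alpha * tanh(W_b) + (1 - alpha) * K0`, then energy-normalizes with a
#' softmax so the template has unit mass and strictly positive entries.
#' `alpha` is clamped to [0, 1] at use.
#'
#' @param W_b Trainable base template (length `k`).
#' @param K0 Fixed impulse kernel (length `k`); default [impulse_kernel()].
#' @param alpha Mixing coefficient in [0, 1] (0 = pure impulse prior,
#'   1 = pure learned template).
#' @return Normalized kernel of length `k` summing to 1.
#' @examples
#' hybrid_kernel(numeric(3), alpha = 0)  # softmax of (0, 1, 0)
#' @export
hybrid_kernel <- function(W_b, K0 = impulse_kernel(length(W_b)), alpha = 0.5) {
  if (length(W_b) != length(K0)) stop("`W_b` and `K0` lengths differ.", call. = FALSE)
  a <- clamp01(alpha)
  vec_softmax(a * tanh(W_b) + (1 - a) * K0)
}

#' Sliding waveform similarity (replicate-padded correlation)
#'
#' Pads each segment by `p = floor(k/2)` edge values on both ends, then
#' slides the unit-mass template across it, producing one similarity score
#' per original position (output length equals input length).
#'
#' @param x Numeric matrix `B x L` or [eeg_batch()].
#' @param kernel Template of odd length `k`.
#' @return Matrix `B x L` of similarity scores.
#' @export
waveform_similarity <- function(x, kernel) {
  x <- as_segment_matrix(x)
  k <- length(kernel)
  if (k %% 2L == 0L) stop("Kernel length must be odd.", call. = FALSE)
  p <- k %/% 2L
  L <- ncol(x)
  xp <- cbind(x[, rep(1L, p), drop = FALSE], x, x[, rep(L, p), drop = FALSE])
  S <- matrix(0, nrow(x), L)
  for (j in seq_len(k)) {
    S <- S + kernel[j] * xp[, j:(j + L - 1L), drop = FALSE]
  }
  S
}

#' Key-waveform attention
#'
#' Softmax-normalizes similarity scores along the time axis and rescales the
#' signal with them, concentrating mass on template-matching positions.
#'
#' @param x Numeric matrix `B x L` or [eeg_batch()].
#' @param S Similarity scores `B x L` (e.g. from [waveform_similarity()]).
#' @param scale_preserving Multiply attention by `L` so a flat attention maps
#'   the signal to itself instead of `x / L`. Default `FALSE` (literal form).
#' @return List with `enhanced` (`B x L`) and `attention` (`B x L`, rows
#'   summing to 1 before any `scale_preserving` gain).
#' @export
waveform_attention <- function(x, S, scale_preserving = FALSE) {
  x <- as_segment_matrix(x)
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  if (!all(dim(S) == dim(x))) stop("`S` and `x` shapes differ.", call. = FALSE)
  A <- row_softmax(S)
  gain <- if (scale_preserving) ncol(x) else 1
  list(enhanced = x * A * gain, attention = A)
}

#' Align the enhanced signal to a resolution branch
#'
#' Average-pools the enhanced time-domain signal to length `s` and embeds
#' each pooled scalar into `D` dimensions with a per-scale affine map, making
#' it elementwise comparable with that branch's attended features.
#'
#' @param x_enh Enhanced signal `B x L`.
#' @param s Target scale length (must divide `L` unless interpolation is on).
#' @param w,b0 Affine embedding (length-`D` weight and bias).
#' @param allow_interpolation See [pool_matrix()].
#' @return Array `B x s x D`.
#' @export
align_to_scale <- function(x_enh, s, w, b0, allow_interpolation = FALSE) {
  x_enh <- as_segment_matrix(x_enh)
  P <- x_enh %*% pool_matrix(ncol(x_enh), s, allow_interpolation)
  scale_embed(P, w, b0)
}

#' Phase-offset network parameters
#'
#' @param embed_dim Latent width `D`; the hidden layer has width `D / 2`.
#' @return List of class `phase_params` with `W1` (`D x D/2`), `b1`, `W2`
#'   (length `D/2`), `b2` (scalar).
#' @export
phase_params <- function(embed_dim) {
  d2 <- max(1L, embed_dim %/% 2L)
  structure(list(
    W1 = rnorm_mat(embed_dim, d2, 1 / sqrt(embed_dim)),
    b1 = numeric(d2),
    W2 = stats::rnorm(d2, sd = 1 / sqrt(d2)),
    b2 = 0,
    embed_dim = embed_dim
  ), class = "phase_params")
}

#' Signed per-timestep phase offset between two feature streams
#'
#' A small bottleneck network applied to the feature difference:
#' `dP = W2 . tanh((A - X) W1 + b1) + b2`, one scalar per timestep.
#'
#' @param A_feat,X_feat Arrays `B x s x D`.
#' @param p A [phase_params()] object.
#' @return Matrix `B x s` of signed offsets.
#' @export
phase_difference <- function(A_feat, X_feat, p) {
  if (!all(dim(A_feat) == dim(X_feat))) stop("Feature shapes differ.", call. = FALSE)
  d <- dim(A_feat)
  Dm <- matrix(A_feat - X_feat, d[1] * d[2], d[3])
  T1 <- tanh(sweep(Dm %*% p$W1, 2, p$b1, "+"))
  matrix(drop(T1 %*% p$W2) + p$b2, d[1], d[2])
}

#' Phase-gated convex fusion of two feature streams
#'
#' `Gamma = sigmoid(dP)` (broadcast over the feature axis) blends the
#' attended features with the aligned enhanced signal:
#' `F = Gamma * A + (1 - Gamma) * X`. Every output entry lies between the two
#' corresponding inputs.
#'
#' @param A_feat,X_feat Arrays `B x s x D`.
#' @param dP Phase offsets `B x s` (from [phase_difference()]).
#' @return List with `fused` (`B x s x D`) and `gate` (`B x s`, in (0, 1)).
#' @export
phase_gate_fuse <- function(A_feat, X_feat, dP) {
  if (is.vector(dP)) dP <- matrix(dP, nrow = dim(A_feat)[1])
  G <- sigmoid(dP)
  d <- dim(A_feat)
  Garr <- array(rep(G, d[3]), dim = d)
  list(fused = Garr * A_feat + (1 - Garr) * X_feat, gate = G)
}

#' Classification head
#'
#' Reduces each scale's fused features over time (mean by default, or
#' flattening), concatenates the per-scale summaries, and applies an affine
#' map followed by a two-class softmax.
#'
#' @param feats List of arrays `B x s_i x D` (one per scale).
#' @param W_y Weight matrix (`n_features x 2`).
#' @param b_y Bias vector (length 2).
#' @param reduction `"mean"` (temporal mean per scale) or `"flatten"`.
#' @return List with `prob` (`B x 2`, rows summing to 1) and `features`
#'   (`B x n_features`, the reduced concatenation).
#' @export
classify_head <- function(feats, W_y, b_y, reduction = "mean") {
  M <- do.call(cbind, lapply(feats, reduce_scale_features, reduction = reduction))
  if (ncol(M) != nrow(W_y)) {
    stop(sprintf("Head expects %d features, got %d.", nrow(W_y), ncol(M)), call. = FALSE)
  }
  logits <- sweep(M %*% W_y, 2, b_y, "+")
  list(prob = row_softmax(logits), features = M, logits = logits)
}

reduce_scale_features <- function(Fi, reduction) {
  d <- dim(Fi)
  if (reduction == "mean") {
    # temporal mean per sample: rowsum over the flattened (b, t) axis
    M <- rowsum(matrix(Fi, d[1] * d[2], d[3]), rep(seq_len(d[1]), times = d[2]),
                reorder = TRUE) / d[2]
    dimnames(M) <- NULL
    M
  } else if (reduction == "flatten") {
    matrix(Fi, d[1], d[2] * d[3])
  } else {
    stop("`reduction` must be \"mean\" or \"flatten\".", call. = FALSE)
  }
}
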