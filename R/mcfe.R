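# Multi-scale feature extraction: adaptive average pooling to a preset scale
# list, per-scale affine embedding of scalar timesteps into D dimensions, and
# multi-head self-attention whose per-head score sharpness is governed by a
# learnable log-temperature.

#' Build the pooling operator mapping length L to target length s
#'
#' Exact non-overlapping window averaging when `L` is divisible by `s`
#' (kernel `k = L / s`). Non-divisible targets are rejected unless
#' `allow_interpolation = TRUE`, in which case fractional windows
#' (`floor((t-1) L / s) .. ceiling(t L / s)`, averaged) are used.
#'
#' @param L Input length.
#' @param s Target length.
#' @param allow_interpolation Permit fractional windows for non-divisible `s`.
#' @return `L x s` matrix `P` such that `x %*% P` pools each row of `x`.
#' @keywords internal
pool_matrix <- function(L, s, allow_interpolation = FALSE) {
  if (s < 1 || s > L) stop(sprintf("Scale %d outside [1, %d].", s, L), call. = FALSE)
  PM <- matrix(0, L, s)
  if (L %% s == 0L) {
    k <- L %/% s
    for (t in seq_len(s)) PM[((t - 1L) * k + 1L):(t * k), t] <- 1 / k
  } else if (allow_interpolation) {
    for (t in seq_len(s)) {
      a <- floor((t - 1) * L / s) + 1L
      b <- ceiling(t * L / s)
      PM[a:b, t] <- 1 / (b - a + 1L)
    }
  } else {
    stop(sprintf(
      "Scale %d does not divide length %d; set `allow_interpolation = TRUE` to pool with fractional windows.",
      s, L), call. = FALSE)
  }
  PM
}

#' Pool a segment batch to multiple temporal resolutions
#'
#' @param x Numeric matrix `B x L` or [eeg_batch()].
#' @param scales Integer vector of target lengths `s_i`; each must divide `L`
#'   unless `allow_interpolation = TRUE`.
#' @param allow_interpolation See [pool_matrix()].
#' @return List of matrices `B x s_i`, one per scale.
#' @examples
#' multiscale_pool(matrix(1:4, 1), scales = 2)[[1]]  # window means 1.5, 3.5
#' @export
multiscale_pool <- function(x, scales, allow_interpolation = FALSE) {
  x <- as_segment_matrix(x)
  L <- ncol(x)
  lapply(scales, function(s) x %*% pool_matrix(L, s, allow_interpolation))
}

#' Embed pooled scalars into a D-dimensional latent space
#'
#' Resolution-specific affine map: `H[b, t, ] = P[b, t] * w + b0`.
#'
#' @param P Pooled matrix `B x s`.
#' @param w Weight vector of length `D`.
#' @param b0 Bias vector of length `D`.
#' @return Array `B x s x D`.
#' @export
scale_embed <- function(P, w, b0) {
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  arr <- outer(P, w)                       # B x s x D
  sweep(arr, 3, b0, "+")
}

#' Attention parameters shared across scales
#'
#' QKV projection `W_qkv` (`D x 3D`) and output projection are shared across
#' resolution branches; each of the `n_heads` heads carries a learnable
#' log-temperature `lambda_h` initialized to `log(D / n_heads)`, so the
#' initial temperature equals the head dimension (e.g. 16 for D = 64, H = 4).
#'
#' @param embed_dim Latent width `D` (divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @return List of class `attention_params`.
#' @export
attention_params <- function(embed_dim, n_heads) {
  if (embed_dim %% n_heads != 0) {
    stop("`embed_dim` must be divisible by `n_heads`.", call. = FALSE)
  }
  structure(list(
    W_qkv = rnorm_mat(embed_dim, 3L * embed_dim, 1 / sqrt(embed_dim)),
    lambda = rep(log(embed_dim / n_heads), n_heads),
    W_o = rnorm_mat(embed_dim, embed_dim, 1 / sqrt(embed_dim)),
    b_o = numeric(embed_dim),
    embed_dim = embed_dim,
    n_heads = n_heads
  ), class = "attention_params")
}

# Extract sample b of a (B, s, D) array as an s x D matrix.
slice_sd <- function(arr, b) {
  d <- dim(arr)
  matrix(arr[b, , ], d[2], d[3])
}

# Forward pass with cache. H_arr: (B, s, D).
attn_forward <- function(H_arr, ap) {
  d <- dim(H_arr)
  B <- d[1]; s <- d[2]; D <- d[3]
  nh <- ap$n_heads
  dh <- D %/% nh
  tau_h <- exp(ap$lambda)
  out <- array(0, dim = c(B, s, D))
  QKV <- vector("list", B)
  AL <- vector("list", B)
  CT <- vector("list", B)
  for (b in seq_len(B)) {
    M <- slice_sd(H_arr, b)
    qkv <- M %*% ap$W_qkv                  # s x 3D
    Cb <- matrix(0, s, D)
    ALb <- vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[, idx, drop = FALSE]
      K <- qkv[, D + idx, drop = FALSE]
      V <- qkv[, 2L * D + idx, drop = FALSE]
      Sc <- tcrossprod(Q, K) / tau_h[h]
      Al <- row_softmax(Sc)
      Cb[, idx] <- Al %*% V
      ALb[[h]] <- Al
    }
    Ob <- sweep(Cb %*% ap$W_o, 2, ap$b_o, "+")
    check_finite(Ob, "tempered attention output")
    out[b, , ] <- Ob
    QKV[[b]] <- qkv
    AL[[b]] <- ALb
    CT[[b]] <- Cb
  }
  list(out = out, cache = list(QKV = QKV, AL = AL, CT = CT))
}

# Backward pass. dOut: (B, s, D). Returns gradients and dH (input gradient).
attn_backward <- function(dOut, ap, H_arr, cache) {
  d <- dim(H_arr)
  B <- d[1]; s <- d[2]; D <- d[3]
  nh <- ap$n_heads
  dh <- D %/% nh
  tau_h <- exp(ap$lambda)
  dH <- array(0, dim = c(B, s, D))
  dW_qkv <- matrix(0, D, 3L * D)
  dW_o <- matrix(0, D, D)
  db_o <- numeric(D)
  dlambda <- numeric(nh)
  for (b in seq_len(B)) {
    dOb <- slice_sd(dOut, b)
    Cb <- cache$CT[[b]]
    qkv <- cache$QKV[[b]]
    db_o <- db_o + colSums(dOb)
    dW_o <- dW_o + crossprod(Cb, dOb)
    dCb <- tcrossprod(dOb, ap$W_o)
    dqkv <- matrix(0, s, 3L * D)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[, idx, drop = FALSE]
      K <- qkv[, D + idx, drop = FALSE]
      V <- qkv[, 2L * D + idx, drop = FALSE]
      Al <- cache$AL[[b]][[h]]
      dC <- dCb[, idx, drop = FALSE]
      dAl <- tcrossprod(dC, V)
      dV <- crossprod(Al, dC)
      dSc <- row_softmax_vjp(Al, dAl)
      Sc <- tcrossprod(Q, K) / tau_h[h]
      dlambda[h] <- dlambda[h] - sum(dSc * Sc)
      dQ <- (dSc %*% K) / tau_h[h]
      dK <- crossprod(dSc, Q) / tau_h[h]
      dqkv[, idx] <- dQ
      dqkv[, D + idx] <- dK
      dqkv[, 2L * D + idx] <- dV
    }
    M <- slice_sd(H_arr, b)
    dW_qkv <- dW_qkv + crossprod(M, dqkv)
    dH[b, , ] <- tcrossprod(dqkv, ap$W_qkv)
  }
  list(dH = dH, W_qkv = dW_qkv, lambda = dlambda, W_o = dW_o, b_o = db_o)
}

#' Temperature-controlled multi-head self-attention
#'
#' Within one resolution branch, queries/keys/values are linear projections of
#' the embedded sequence; per head `h` the score matrix is
#' `Q K' / tau_h` with `tau_h = exp(lambda_h)`, softmax-normalized over keys,
#' then used to aggregate values; head contexts are concatenated and passed
#' through the output projection. No positional encoding, residual path, or
#' normalization layer is applied.
#'
#' @param H Array `B x s x D` of embedded features (a matrix `s x D` is
#'   treated as one sample).
#' @param params An [attention_params()] object.
#' @return Array `B x s x D` of attended features.
#' @export
tempered_attention <- function(H, params) {
  if (is.matrix(H)) H <- array(H, dim = c(1, nrow(H), ncol(H)))
  if (dim(H)[3] != params$embed_dim) {
    stop("Feature width does not match `params$embed_dim`.", call. = FALSE)
  }
  attn_forward(H, params)$out
}

#' Multi-scale feature extraction forward pass
#'
#' Pools the input to each configured scale, embeds, and attends. This is the
#' standalone (inference) surface; the trainer uses the cached internal
#' version.
#'
#' @param x Numeric matrix `B x L` or [eeg_batch()].
#' @param scales Integer scale list (default `c(1228, 614, 307)`).
#' @param embed List with per-scale weight vectors `w[[i]]`, biases `b[[i]]`.
#' @param attn An [attention_params()] object shared across scales.
#' @param allow_interpolation See [pool_matrix()].
#' @return List with one element per scale: list(`pooled`, `embedded`,
#'   `attended`) of shapes `B x s_i`, `B x s_i x D`, `B x s_i x D`.
#' @export
mcfe_forward <- function(x, scales, embed, attn, allow_interpolation = FALSE) {
  x <- as_segment_matrix(x)
  pooled <- multiscale_pool(x, scales, allow_interpolation)
  lapply(seq_along(scales), function(i) {
    Hm <- scale_embed(pooled[[i]], embed$w[[i]], embed$b[[i]])
    list(pooled = pooled[[i]], embedded = Hm, attended = attn_forward(Hm, attn)$out)
  })
}
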