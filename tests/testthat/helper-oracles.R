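# Independent brute-force oracles used to validate the vectorized
# implementations. These are deliberately naive (explicit loops) and never
# share code with the package internals they check.

# Naive multi-head attention: per sample, per head, per query position,
# explicit weighted sum of value rows.
naive_attention <- function(H_arr, W_qkv, lambda, W_o, b_o, n_heads) {
  d <- dim(H_arr)
  B <- d[1]; s <- d[2]; D <- d[3]
  dh <- D / n_heads
  out <- array(0, dim = c(B, s, D))
  for (b in seq_len(B)) {
    M <- matrix(H_arr[b, , ], s, D)
    qkv <- M %*% W_qkv
    Cfull <- matrix(0, s, D)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      Q <- qkv[, idx, drop = FALSE]
      K <- qkv[, D + idx, drop = FALSE]
      V <- qkv[, 2 * D + idx, drop = FALSE]
      tau <- exp(lambda[h])
      for (t in seq_len(s)) {
        sc <- numeric(s)
        for (u in seq_len(s)) sc[u] <- sum(Q[t, ] * K[u, ]) / tau
        w <- exp(sc - max(sc)); w <- w / sum(w)
        acc <- numeric(dh)
        for (u in seq_len(s)) acc <- acc + w[u] * V[u, ]
        Cfull[t, idx] <- acc
      }
    }
    out[b, , ] <- Cfull %*% W_o + matrix(b_o, s, D, byrow = TRUE)
  }
  out
}

# Naive replicate-padded sliding correlation, one dot product per position.
naive_sliding_correlation <- function(x, kernel) {
  k <- length(kernel)
  p <- k %/% 2
  L <- length(x)
  xp <- c(rep(x[1], p), x, rep(x[L], p))
  out <- numeric(L)
  for (t in seq_len(L)) out[t] <- sum(xp[t:(t + k - 1)] * kernel)
  out
}

# Welch-style band power oracle independent of the package's FFT path.
oracle_band_power <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0, plot = FALSE,
                          detrend = FALSE, fast = FALSE)
  sel <- sp$freq >= lo & sp$freq <= hi
  mean(sp$spec[sel])
}
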