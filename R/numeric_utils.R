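# Shared numerical primitives. All softmaxes are shifted by the row max for
# overflow safety; gradients use the standard Jacobian-vector products.

row_softmax <- function(z) {
  rm <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - rm)
  e / rowSums(e)
}

# VJP of row_softmax: given output p and upstream dp, returns dz.
row_softmax_vjp <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

vec_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

vec_softmax_vjp <- function(p, dp) {
  p * (dp - sum(dp * p))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) pmax(z, 0)

# Draw Gumbel(0, 1) noise of the given shape from the current RNG stream.
rgumbel <- function(n) {
  -log(-log(stats::runif(n)))
}

clamp01 <- function(x) min(max(x, 0), 1)

# Gaussian init helper.
rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("Non-finite activations in %s.", what), call. = FALSE)
  }
  invisible(x)
}
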