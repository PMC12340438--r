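# Small fixture builders shared across test files. All randomness is drawn
# under explicit seeds so failures reproduce exactly.

tiny_model_config <- function(...) {
  defaults <- list(segment_length = 32, sampling_rate = 32,
                   scales = c(32, 16, 8), embed_dim = 8, n_heads = 2,
                   dfs_hidden = 5, kernel_size = 5, epochs = 2,
                   batch_size = 8, seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

tiny_batch <- function(B = 3, L = 32, seed = 99) {
  set.seed(seed)
  matrix(rnorm(B * L), B, L)
}

# Numerically differentiate a scalar loss with respect to one parameter entry.
fd_grad <- function(model, x, y, name, j, eps = 1e-5) {
  loss_at <- function(v) {
    m <- model
    m$params[[name]][j] <- v
    fw <- seizenet:::model_forward(m, x, training = FALSE)
    seizenet:::cross_entropy(fw$prob, y)
  }
  p0 <- model$params[[name]][j]
  (loss_at(p0 + eps) - loss_at(p0 - eps)) / (2 * eps)
}
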