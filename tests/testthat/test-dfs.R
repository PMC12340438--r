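test_that("frequency scorer implements the two-layer perceptron exactly", {
  # hand-computed: W1 = [1, 1], b1 = 0, W2 = [1, -1]', b2 = 0, A = [1, 2]
  p <- structure(list(W1 = matrix(c(1, 1), 1, 2), b1 = 0,
                      W2 = matrix(c(1, -1), 2, 1), b2 = c(0, 0),
                      tau = 1, n_bins = 2), class = "dfs_params")
  expect_equal(score_frequencies(c(1, 2), p), matrix(c(3, -3), 1, 2))

  # zero weights collapse to the output bias for any amplitude
  p0 <- dfs_params(4, hidden_dim = 3)
  p0$W1[] <- 0; p0$W2[] <- 0; p0$b2 <- c(1, 2, 3, 4)
  expect_equal(score_frequencies(matrix(rnorm(8), 2, 4), p0),
               matrix(c(1, 2, 3, 4), 2, 4, byrow = TRUE))

  # negative hidden bias + zero input: ReLU dead zone leaves only b2
  pn <- dfs_params(4, hidden_dim = 3)
  pn$b1[] <- -1; pn$b2 <- rep(0.5, 4)
  expect_equal(score_frequencies(matrix(0, 1, 4), pn), matrix(0.5, 1, 4))
})

test_that("Gumbel-SoftMax weights normalize, reduce to softmax, and sharpen", {
  set.seed(10)
  S <- matrix(rnorm(5 * 8, sd = 2), 5, 8)
  # noise-free reduction to plain softmax
  W <- gumbel_softmax_weights(S, tau = 1, noise = "none")
  expect_equal(W, seizenet:::row_softmax(S), tolerance = 1e-12)
  expect_equal(rowSums(W), rep(1, 5), tolerance = 1e-6)
  expect_true(all(W > 0 & W < 1))
  # equal logits give uniform weights
  expect_equal(gumbel_softmax_weights(matrix(2, 1, 6), noise = "none")[1, ],
               rep(1 / 6, 6))
  # with fixed noise and tau -> 0+, rows approach one-hot at argmax(S + g)
  g <- matrix(rnorm(40), 5, 8)
  Wc <- gumbel_softmax_weights(S, tau = 1e-4, noise = g)
  for (b in 1:5) {
    expect_equal(which.max(Wc[b, ]), which.max(S[b, ] + g[b, ]))
    expect_gt(max(Wc[b, ]), 1 - 1e-8)
  }
  expect_error(gumbel_softmax_weights(S, tau = 0), "positive")
})

test_that("mask rows sum to 1 and peak weight is non-increasing in tau", {
  set.seed(11)
  S <- matrix(rnorm(3 * 10), 3, 10)
  g <- matrix(seizenet:::rgumbel(30), 3, 10)
  peaks <- sapply(c(0.1, 0.5, 1, 2), function(tau) {
    W <- gumbel_softmax_weights(S, tau = tau, noise = g)
    expect_equal(rowSums(W), rep(1, 3), tolerance = 1e-6)
    max(W)
  })
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("spectral filtering scales coefficients without touching phase", {
  set.seed(12)
  F <- matrix(complex(real = rnorm(8), imaginary = rnorm(8)), 2, 4)
  expect_equal(spectral_filter(F, matrix(1, 2, 4)), F)
  W <- matrix(0, 2, 4); W[, 3] <- 1
  Ft <- spectral_filter(F, W)
  expect_true(all(Ft[, -3] == 0))
  expect_equal(Ft[, 3], F[, 3])
  Wr <- matrix(runif(8, 0.1, 2), 2, 4)
  expect_equal(Arg(spectral_filter(F, Wr)), Arg(F), tolerance = 1e-12)
})

test_that("DFS forward preserves length and supports an all-pass mode", {
  set.seed(13)
  x <- matrix(rnorm(2 * 1228), 2, 1228)
  p <- dfs_params(615, hidden_dim = 4)
  out <- dfs_forward(x, p, noise = "none")
  expect_equal(dim(out$filtered), c(2L, 1228L))
  expect_equal(out$state$n_bins, 615L)
  expect_equal(rowSums(out$state$mask), rep(1, 2), tolerance = 1e-6)

  # frozen scorer (zero weights) + mask_gain = N gives a uniform all-pass
  # mask of exactly 1, so the stage reduces to the identity
  p0 <- dfs_params(9, hidden_dim = 3)
  p0$W1[] <- 0; p0$W2[] <- 0
  xs <- matrix(rnorm(3 * 16), 3, 16)
  bypass <- dfs_forward(xs, p0, noise = "none", mask_gain = 9)
  expect_equal(bypass$filtered, xs, tolerance = 1e-8)

  # a pure sinusoid is an eigenfunction of its own one-hot band filter
  L <- 32
  tt <- 0:(L - 1)
  xsin <- matrix(sin(2 * pi * 4 * tt / L), 1, L)
  Fs <- rfft_forward(xsin)
  W <- matrix(0, 1, 17); W[1, 5] <- 1    # bin 4 (0-based)
  back <- irfft_backward(spectral_filter(Fs, W), L)
  expect_equal(back, xsin, tolerance = 1e-8)
})

test_that("analytic DFS gradients match finite differences", {
  set.seed(14)
  x <- matrix(rnorm(2 * 16), 2, 16)
  p <- dfs_params(9, hidden_dim = 4)
  g_up <- matrix(rnorm(32), 2, 16)           # arbitrary upstream gradient
  fw <- dfs_forward(x, p, noise = "none")
  gr <- seizenet:::dfs_backward(g_up, p, fw$state)
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (j in sample(length(p[[nm]]), 3)) {
      pp <- p; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- p; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- sum(g_up * (dfs_forward(x, pp, noise = "none")$filtered -
                         dfs_forward(x, pm, noise = "none")$filtered)) / (2 * eps)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                   label = sprintf("dfs grad %s[%d]", nm, j))
    }
  }
})

test_that("mask export maps bins to frequencies and averages weights", {
  mask <- rbind(c(0.2, 0.3, 0.5), c(0.4, 0.1, 0.5))
  tab <- export_mask(mask, sampling_rate = 30, segment_length = 6)
  expect_equal(tab$bin_index, 0:2)
  expect_equal(tab$frequency_hz, c(0, 5, 10))
  expect_equal(tab$mean_weight, c(0.3, 0.2, 0.5))
  f <- tempfile(fileext = ".csv")
  export_mask(mask, 30, 6, file = f)
  expect_equal(utils::read.csv(f)$mean_weight, c(0.3, 0.2, 0.5))
})
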