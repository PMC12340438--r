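test_that("hybrid kernel blends template and impulse, then normalizes", {
  # alpha = 0, k = 3: softmax of the bare impulse (0, 1, 0)
  got <- hybrid_kernel(c(5, -2, 7), alpha = 0)
  e <- exp(c(0, 1, 0)); e <- e / sum(e)
  expect_equal(got, e, tolerance = 1e-4)
  expect_equal(round(got, 4), c(0.2119, 0.5762, 0.2119), tolerance = 1e-3)
  # alpha = 1: the impulse no longer matters
  W_b <- rnorm(5)
  expect_equal(hybrid_kernel(W_b, impulse_kernel(5), alpha = 1),
               hybrid_kernel(W_b, rev(impulse_kernel(5)) * 0, alpha = 1))
  # normalization holds across many random draws
  set.seed(30)
  for (i in 1:1000) {
    k <- hybrid_kernel(rnorm(7, sd = 2), alpha = runif(1))
    expect_true(abs(sum(k) - 1) < 1e-9 && all(k > 0))
  }
})

test_that("waveform similarity is a replicate-padded unit-mass correlation", {
  set.seed(31)
  # p = floor(k/2): kernel 15 needs 7 pad values; output length is preserved
  x <- matrix(rnorm(40), 2, 20)
  k15 <- rep(1 / 15, 15)
  expect_equal(dim(waveform_similarity(x, k15)), c(2L, 20L))
  # constant signal with a sum-1 kernel gives the constant everywhere
  expect_equal(waveform_similarity(matrix(4, 1, 10), rep(0.2, 5)),
               matrix(4, 1, 10))
  # exact center impulse is the identity
  expect_equal(waveform_similarity(x, impulse_kernel(5)), x)
  expect_error(waveform_similarity(x, rep(0.25, 4)), "odd")
})

test_that("sliding correlation matches the per-position dot-product oracle", {
  set.seed(32)
  for (rep in 1:5) {
    x <- rnorm(32)
    kern <- rnorm(5)
    got <- waveform_similarity(matrix(x, 1), kern)[1, ]
    expect_equal(got, naive_sliding_correlation(x, kern), tolerance = 1e-6)
  }
})

test_that("waveform attention normalizes over time and rescales the signal", {
  set.seed(33)
  x <- matrix(rnorm(2 * 12), 2, 12)
  # uniform scores: attention 1/L, enhanced = x / L
  wa <- waveform_attention(x, matrix(1, 2, 12))
  expect_equal(wa$attention, matrix(1 / 12, 2, 12))
  expect_equal(wa$enhanced, x / 12)
  # a dominant spike takes almost all the mass
  S <- matrix(0, 1, 12); S[1, 5] <- 50
  wa2 <- waveform_attention(x[1, , drop = FALSE], S)
  expect_gt(wa2$attention[1, 5], 1 - 1e-12)
  # rows always sum to 1
  wa3 <- waveform_attention(x, matrix(rnorm(24, sd = 3), 2, 12))
  expect_equal(rowSums(wa3$attention), c(1, 1), tolerance = 1e-6)
  # scale-preserving mode multiplies by L
  wa4 <- waveform_attention(x, matrix(1, 2, 12), scale_preserving = TRUE)
  expect_equal(wa4$enhanced, x)
})

test_that("alignment pools and embeds the enhanced signal per scale", {
  set.seed(34)
  x <- matrix(rnorm(2 * 12), 2, 12)
  D <- 4
  # identity alignment: s = L, weight e1, zero bias
  out <- align_to_scale(x, 12, c(1, 0, 0, 0), numeric(4))
  expect_equal(out[, , 1], x)
  expect_true(all(out[, , 2:4] == 0))
  # constant input embeds identically at every position
  outc <- align_to_scale(matrix(2, 1, 12), 4, rnorm(4), rnorm(4))
  for (d in 1:4) expect_equal(length(unique(round(outc[1, , d], 12))), 1L)
  # contract: shape (B, s, D) for each scale
  for (s in c(12, 6, 3)) {
    expect_equal(dim(align_to_scale(x, s, rnorm(D), rnorm(D))), c(2L, s, D))
  }
})

test_that("phase-offset network follows its closed form and bound", {
  # A = X: offset collapses to the output bias
  p <- phase_params(4)
  p$b1[] <- 0; p$b2 <- 0.7
  A <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  expect_equal(phase_difference(A, A, p), matrix(0.7, 2, 3))
  # hand case: D = 2, W1 = [1, 0]', W2 = 2, difference (0.5, 9)
  p2 <- structure(list(W1 = matrix(c(1, 0), 2, 1), b1 = 0, W2 = 2, b2 = 0,
                       embed_dim = 2), class = "phase_params")
  A2 <- array(c(0.5, 9), dim = c(1, 1, 2))
  X2 <- array(0, dim = c(1, 1, 2))
  expect_equal(phase_difference(A2, X2, p2)[1, 1], 2 * tanh(0.5),
               tolerance = 1e-10)
  expect_equal(2 * tanh(0.5), 0.9242, tolerance = 1e-4)
  # tanh bound: |dP - b2| <= sum(|W2|)
  set.seed(35)
  p3 <- phase_params(6)
  A3 <- array(rnorm(60, sd = 10), dim = c(2, 5, 6))
  X3 <- array(rnorm(60, sd = 10), dim = c(2, 5, 6))
  dP <- phase_difference(A3, X3, p3)
  expect_true(all(abs(dP - p3$b2) <= sum(abs(p3$W2)) + 1e-12))
})

test_that("phase gate is a convex blend saturating at its two inputs", {
  set.seed(36)
  A <- array(rnorm(24), dim = c(2, 3, 4))
  X <- array(rnorm(24), dim = c(2, 3, 4))
  # dP = 0: exact average
  fg <- phase_gate_fuse(A, X, matrix(0, 2, 3))
  expect_equal(fg$fused, (A + X) / 2)
  expect_equal(fg$gate, matrix(0.5, 2, 3))
  # saturation
  expect_equal(phase_gate_fuse(A, X, matrix(100, 2, 3))$fused, A, tolerance = 1e-8)
  expect_equal(phase_gate_fuse(A, X, matrix(-100, 2, 3))$fused, X, tolerance = 1e-8)
  # convexity for random gates
  fg2 <- phase_gate_fuse(A, X, matrix(rnorm(6), 2, 3))
  lo <- pmin(A, X); hi <- pmax(A, X)
  expect_true(all(fg2$fused >= lo - 1e-12 & fg2$fused <= hi + 1e-12))
  expect_true(all(fg2$gate > 0 & fg2$gate < 1))
})

test_that("classification head reduces, concatenates, and normalizes", {
  set.seed(37)
  feats <- list(array(rnorm(2 * 4 * 3), dim = c(2, 4, 3)),
                array(rnorm(2 * 2 * 3), dim = c(2, 2, 3)))
  # zero map: uniform class probabilities
  out0 <- classify_head(feats, matrix(0, 6, 2), c(0, 0))
  expect_equal(out0$prob, matrix(0.5, 2, 2))
  # bias-only head realizes any fixed logits: [2, 0] -> ~[0.8808, 0.1192]
  out1 <- classify_head(feats, matrix(0, 6, 2), c(2, 0))
  expect_equal(out1$prob[1, ], exp(c(2, 0)) / sum(exp(c(2, 0))))
  expect_equal(round(out1$prob[1, ], 4), c(0.8808, 0.1192), tolerance = 1e-3)
  # probability rows for random parameters
  out2 <- classify_head(feats, matrix(rnorm(12), 6, 2), rnorm(2))
  expect_equal(rowSums(out2$prob), c(1, 1), tolerance = 1e-9)
  # the mean reduction averages over time
  expect_equal(out2$features[, 1:3],
               t(sapply(1:2, function(b) colMeans(matrix(feats[[1]][b, , ], 4, 3)))))
  # flatten reduction keeps every timestep
  outf <- classify_head(feats, matrix(0, 4 * 3 + 2 * 3, 2), c(0, 0),
                        reduction = "flatten")
  expect_equal(ncol(outf$features), 18L)
})
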