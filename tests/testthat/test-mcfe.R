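test_that("multiscale pooling computes non-overlapping window means", {
  expect_equal(multiscale_pool(matrix(1:4, 1), scales = 2)[[1]],
               matrix(c(1.5, 3.5), 1))
  # target length equal to input is the identity
  x <- matrix(rnorm(12), 2, 6)
  expect_equal(multiscale_pool(x, scales = 6)[[1]], x)
  # constants are preserved at every scale
  xc <- matrix(2.5, 1, 12)
  for (P in multiscale_pool(xc, scales = c(12, 6, 3))) {
    expect_true(all(abs(P - 2.5) < 1e-12))
  }
  # reference geometry: L = 1228 with scales [1228, 614, 307] gives
  # kernels [1, 2, 4] (each pooling matrix column carries k entries of 1/k)
  for (cfg in list(c(1228, 1), c(614, 2), c(307, 4))) {
    PM <- seizenet:::pool_matrix(1228, cfg[1])
    expect_equal(colSums(PM != 0), rep(cfg[2], cfg[1]), ignore_attr = TRUE)
    expect_equal(unique(PM[PM != 0]), 1 / cfg[2])
  }
  expect_error(multiscale_pool(matrix(1:10, 1), scales = 3), "divide")
})

test_that("fractional-window pooling handles non-divisible scales when enabled", {
  PM <- seizenet:::pool_matrix(10, 4, allow_interpolation = TRUE)
  expect_equal(colSums(PM), rep(1, 4))          # each window averages to mass 1
  x <- matrix(rep(3, 10), 1)
  expect_equal((x %*% PM)[1, ], rep(3, 4))      # constants preserved
})

test_that("scale embedding is the scalar-to-vector affine map", {
  P <- matrix(c(1, 2, 3, 4), 2, 2)
  w <- c(1, -1, 0)
  b0 <- c(0, 0, 5)
  H <- scale_embed(P, w, b0)
  expect_equal(dim(H), c(2L, 2L, 3L))
  expect_equal(H[1, 2, ], c(3, -3, 5))
  # zero weights collapse every position onto the bias
  H0 <- scale_embed(P, c(0, 0, 0), c(1, 2, 3))
  expect_true(all(aperm(H0, c(3, 1, 2)) == c(1, 2, 3)))
  # affine map: embed(aP) - embed(0) = a (embed(P) - embed(0))
  Ha <- scale_embed(3 * P, w, b0)
  Hz <- scale_embed(0 * P, w, b0)
  expect_equal(Ha - Hz, 3 * (H - Hz), tolerance = 1e-12)
})

test_that("head temperatures initialize to D/H (16 for D=64, H=4)", {
  ap <- attention_params(64, 4)
  expect_equal(exp(ap$lambda), rep(16, 4))
  expect_equal(exp(attention_params(8, 2)$lambda), rep(4, 2))
  expect_error(attention_params(10, 4), "divisible")
})

test_that("attention with a single key reduces to the projected value", {
  set.seed(20)
  ap <- attention_params(4, 2)
  H <- array(rnorm(4), dim = c(1, 1, 4))
  out <- tempered_attention(H, ap)
  qkv <- matrix(H[1, , ], 1, 4) %*% ap$W_qkv
  V <- qkv[, 9:12, drop = FALSE]
  expect_equal(matrix(out[1, , ], 1, 4), V %*% ap$W_o + matrix(ap$b_o, 1, 4))
})

test_that("very high temperature flattens attention to the value mean", {
  set.seed(21)
  ap <- attention_params(4, 1)
  ap$lambda <- 30                                # tau astronomically large
  s <- 6
  H <- array(rnorm(s * 4), dim = c(1, s, 4))
  out <- tempered_attention(H, ap)
  qkv <- matrix(H[1, , ], s, 4) %*% ap$W_qkv
  Vmean <- colMeans(qkv[, 9:12, drop = FALSE])
  expected <- matrix(Vmean, s, 4, byrow = TRUE) %*% ap$W_o +
    matrix(ap$b_o, s, 4, byrow = TRUE)
  expect_equal(out[1, , ], expected, tolerance = 1e-8)
})

test_that("vectorized attention matches the naive loop oracle", {
  set.seed(22)
  for (case in list(c(B = 1, s = 4, D = 4, H = 1), c(B = 3, s = 16, D = 8, H = 2),
                    c(B = 2, s = 7, D = 6, H = 3))) {
    ap <- attention_params(case["D"], case["H"])
    ap$lambda <- ap$lambda + rnorm(case["H"], sd = 0.3)
    Hm <- array(rnorm(prod(case[1:3])), dim = case[1:3])
    got <- tempered_attention(Hm, ap)
    want <- naive_attention(Hm, ap$W_qkv, ap$lambda, ap$W_o, ap$b_o, case["H"])
    expect_equal(got, want, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("attention weights are probability rows", {
  set.seed(23)
  ap <- attention_params(8, 2)
  H <- array(rnorm(2 * 10 * 8, sd = 2), dim = c(2, 10, 8))
  cache <- seizenet:::attn_forward(H, ap)$cache
  for (b in 1:2) for (h in 1:2) {
    Al <- cache$AL[[b]][[h]]
    expect_equal(rowSums(Al), rep(1, 10), tolerance = 1e-6)
    expect_true(all(Al >= 0 & Al <= 1))
  }
})

test_that("attention-row entropy is non-decreasing in the head temperature", {
  set.seed(24)
  D <- 4; s <- 8
  H <- array(rnorm(s * D, sd = 2), dim = c(1, s, D))
  ent <- sapply(c(-2, -1, 0, 1, 2), function(lam) {
    ap <- attention_params(D, 1)
    ap$lambda <- lam
    Al <- seizenet:::attn_forward(H, ap)$cache$AL[[1]][[1]]
    mean(apply(Al, 1, function(p) -sum(p * log(p + 1e-300))))
  })
  expect_true(all(diff(ent) >= -1e-10))
})

test_that("batch permutation permutes attention outputs identically", {
  set.seed(25)
  ap <- attention_params(6, 2)
  H <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  out <- tempered_attention(H, ap)
  perm <- c(3, 1, 4, 2)
  out_p <- tempered_attention(H[perm, , , drop = FALSE], ap)
  expect_equal(out_p, out[perm, , , drop = FALSE])
})

test_that("mcfe forward yields attended features at every scale, deterministically", {
  set.seed(26)
  x <- matrix(rnorm(2 * 24), 2, 24)
  scales <- c(24, 12, 6)
  D <- 8
  embed <- list(w = replicate(3, rnorm(D), simplify = FALSE),
                b = replicate(3, rnorm(D), simplify = FALSE))
  ap <- attention_params(D, 2)
  out1 <- mcfe_forward(x, scales, embed, ap)
  out2 <- mcfe_forward(x, scales, embed, ap)
  expect_identical(out1, out2)                   # no stochastic op
  for (i in seq_along(scales)) {
    expect_equal(dim(out1[[i]]$attended), c(2L, scales[i], D))
    expect_true(all(is.finite(out1[[i]]$attended)))
  }
})
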