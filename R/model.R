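# Full network assembly: dynamic frequency selection -> multi-scale
# temperature-controlled attention -> phase-aware gated fusion -> softmax
# head, with ablation variants and an analytic end-to-end backward pass.

#' Model configuration
#'
#' Collects every architectural and training hyperparameter. Defaults follow
#' the reference configuration: input length 1228 at 256 Hz, scale list
#' [1228, 614, 307], embedding width 64, 4 attention heads, DFS hidden width
#' 64 at temperature 1.0, waveform kernel size 15 with initial mixing
#' coefficient 0.5.
#'
#' @param segment_length Input length `L`.
#' @param sampling_rate Hz (metadata for mask export).
#' @param scales Integer scale list; each must divide `L` unless
#'   `allow_interpolation`.
#' @param embed_dim Latent width `D` (divisible by `n_heads`).
#' @param n_heads Attention heads `H`.
#' @param dfs_hidden Hidden width of the DFS scoring perceptron.
#' @param tau DFS Gumbel-SoftMax temperature (fixed, not learned).
#' @param kernel_size Waveform template length (odd).
#' @param alpha_init Initial template mixing coefficient in [0, 1].
#' @param use_dfs,use_mcfe,use_mcpa Ablation flags. All `TRUE` is the full
#'   model; exactly one `FALSE` gives the AB1 (no spectral selection), AB2
#'   (single full-resolution branch, no multi-scale fusion), or AB3 (no
#'   phase-aware fusion) variant.
#' @param mcpa_input `"dfs"` (waveform attention consumes the DFS output;
#'   default) or `"raw"`.
#' @param head_reduction `"mean"` or `"flatten"` temporal reduction before
#'   the head.
#' @param mask_gain Multiplier on the spectral mask (1 = literal softmax
#'   mask; `n_bins` restores input energy scale).
#' @param scale_preserving Rescale waveform attention by `L` (off = literal).
#' @param shared_noise Share one Gumbel draw across the batch rows.
#' @param allow_interpolation Permit non-divisible scales via fractional
#'   pooling windows.
#' @param learning_rate,batch_size,epochs,optimizer Training defaults
#'   (Adam, 1e-3, 32, 30).
#' @param weight_decay Decoupled L2 weight decay applied by the optimizer.
#'   Default 0. A small positive value keeps the spectral-mask logits
#'   bounded, so the Gumbel noise keeps exploring instead of freezing onto
#'   near one-hot per-sample masks.
#' @param class_weights `FALSE` (plain cross-entropy) or `TRUE`
#'   (inverse-frequency weights for the imbalanced seizure class).
#' @param positive_class Label treated as positive by reported metrics.
#' @param seed Seed used for parameter initialization.
#' @return List of class `model_config`.
#' @export
model_config <- function(segment_length = 1228,
                         sampling_rate = 256,
                         scales = c(1228, 614, 307),
                         embed_dim = 64,
                         n_heads = 4,
                         dfs_hidden = 64,
                         tau = 1.0,
                         kernel_size = 15,
                         alpha_init = 0.5,
                         use_dfs = TRUE,
                         use_mcfe = TRUE,
                         use_mcpa = TRUE,
                         mcpa_input = c("dfs", "raw"),
                         head_reduction = c("mean", "flatten"),
                         mask_gain = 1,
                         scale_preserving = FALSE,
                         shared_noise = FALSE,
                         allow_interpolation = FALSE,
                         learning_rate = 1e-3,
                         weight_decay = 0,
                         batch_size = 32,
                         epochs = 30,
                         optimizer = "adam",
                         class_weights = FALSE,
                         positive_class = 1,
                         seed = 1L) {
  mcpa_input <- match.arg(mcpa_input)
  head_reduction <- match.arg(head_reduction)
  if (tau <= 0) stop("`tau` must be positive.", call. = FALSE)
  if (kernel_size %% 2L == 0L) stop("`kernel_size` must be odd.", call. = FALSE)
  if (embed_dim %% n_heads != 0) {
    stop("`embed_dim` must be divisible by `n_heads`.", call. = FALSE)
  }
  if (length(scales) < 1) stop("At least one scale is required.", call. = FALSE)
  if (sum(!c(use_dfs, use_mcfe, use_mcpa)) > 1) {
    stop("At most one module may be ablated at a time (AB1/AB2/AB3).", call. = FALSE)
  }
  if (!allow_interpolation) {
    bad <- scales[segment_length %% scales != 0]
    if (length(bad) > 0) {
      stop(sprintf("Scale(s) %s do not divide segment length %d.",
                   paste(bad, collapse = ", "), segment_length), call. = FALSE)
    }
  }
  cfg <- list(
    segment_length = as.integer(segment_length), sampling_rate = sampling_rate,
    scales = as.integer(scales), embed_dim = as.integer(embed_dim),
    n_heads = as.integer(n_heads), dfs_hidden = as.integer(dfs_hidden),
    tau = tau, kernel_size = as.integer(kernel_size), alpha_init = alpha_init,
    use_dfs = use_dfs, use_mcfe = use_mcfe, use_mcpa = use_mcpa,
    mcpa_input = mcpa_input, head_reduction = head_reduction,
    mask_gain = mask_gain, scale_preserving = scale_preserving,
    shared_noise = shared_noise, allow_interpolation = allow_interpolation,
    learning_rate = learning_rate, weight_decay = weight_decay,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), optimizer = optimizer,
    class_weights = class_weights, positive_class = as.integer(positive_class),
    seed = as.integer(seed)
  )
  structure(cfg, class = "model_config")
}

#' Stable hash of a configuration
#'
#' @param config A [model_config()] (or any list).
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(config[sort(names(config))])
}

# Effective scale list after ablation: AB2 collapses to one full-resolution
# branch.
effective_scales <- function(config) {
  if (config$use_mcfe) config$scales else config$segment_length
}

#' Build a model from a configuration
#'
#' Initializes every parameter group from `config$seed`. Ablation variants
#' drop the corresponding parameter groups entirely, so an ablated model
#' always has strictly fewer parameters than the full model.
#'
#' @param config A [model_config()].
#' @return Object of class `seizenet_model`: list with `config`, `params`
#'   (flat named list of numeric arrays), and cached pooling operators.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  L <- config$segment_length
  D <- config$embed_dim
  scales <- effective_scales(config)
  params <- list()
  if (config$use_dfs) {
    dp <- dfs_params(L %/% 2L + 1L, hidden_dim = config$dfs_hidden, tau = config$tau)
    params$dfs_W1 <- dp$W1; params$dfs_b1 <- dp$b1
    params$dfs_W2 <- dp$W2; params$dfs_b2 <- dp$b2
  }
  for (i in seq_along(scales)) {
    params[[paste0("emb_w_", i)]] <- stats::rnorm(D, sd = 0.5)
    params[[paste0("emb_b_", i)]] <- numeric(D)
  }
  ap <- attention_params(D, config$n_heads)
  params$attn_W_qkv <- ap$W_qkv; params$attn_lambda <- ap$lambda
  params$attn_W_o <- ap$W_o; params$attn_b_o <- ap$b_o
  use_fusion <- config$use_mcpa && config$use_mcfe
  if (use_fusion) {
    params$mcpa_W_b <- stats::rnorm(config$kernel_size)
    params$mcpa_alpha <- config$alpha_init
    for (i in seq_along(scales)) {
      params[[paste0("align_w_", i)]] <- stats::rnorm(D, sd = 0.5)
      params[[paste0("align_b_", i)]] <- numeric(D)
    }
    pp <- phase_params(D)
    params$ph_W1 <- pp$W1; params$ph_b1 <- pp$b1
    params$ph_W2 <- pp$W2; params$ph_b2 <- pp$b2
  }
  n_features <- if (config$head_reduction == "mean") {
    length(scales) * D
  } else {
    sum(scales) * D
  }
  params$head_W_y <- rnorm_mat(n_features, 2L, 1 / sqrt(n_features))
  params$head_b_y <- numeric(2L)
  pool <- lapply(scales, function(s) pool_matrix(L, s, config$allow_interpolation))
  structure(list(config = config, params = params, pool = pool,
                 scales = scales, use_fusion = use_fusion),
            class = "seizenet_model")
}

#' Number of trainable parameters
#' @param model A `seizenet_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.seizenet_model <- function(x, ...) {
  cfg <- x$config
  variant <- if (!cfg$use_dfs) "AB1 (no spectral selection)"
  else if (!cfg$use_mcfe) "AB2 (single branch)"
  else if (!cfg$use_mcpa) "AB3 (no phase fusion)"
  else "full"
  cat(sprintf("<seizenet_model> %s | L=%d, scales=[%s], D=%d, H=%d | %d parameters\n",
              variant, cfg$segment_length, paste(x$scales, collapse = ", "),
              cfg$embed_dim, cfg$n_heads, n_params(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Forward pass (with cache for training).

model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  pr <- model$params
  x <- as_segment_matrix(x)
  if (ncol(x) != cfg$segment_length) {
    stop(sprintf("Input length %d does not match configured %d.",
                 ncol(x), cfg$segment_length), call. = FALSE)
  }
  B <- nrow(x)
  D <- cfg$embed_dim
  scales <- model$scales
  cache <- list(x = x)

  # --- dynamic frequency selection -----------------------------------------
  if (cfg$use_dfs) {
    dp <- structure(list(W1 = pr$dfs_W1, b1 = pr$dfs_b1, W2 = pr$dfs_W2,
                         b2 = pr$dfs_b2, tau = cfg$tau,
                         n_bins = cfg$segment_length %/% 2L + 1L),
                    class = "dfs_params")
    noise <- if (training) "sample" else "none"
    dfs <- dfs_forward(x, dp, noise = noise, shared_noise = cfg$shared_noise,
                       mask_gain = cfg$mask_gain)
    xt <- dfs$filtered
    cache$dfs_state <- dfs$state
    cache$dfs_params <- dp
  } else {
    xt <- x
  }
  cache$xt <- xt

  # --- multi-scale embedding + tempered attention --------------------------
  attn <- structure(list(W_qkv = pr$attn_W_qkv, lambda = pr$attn_lambda,
                         W_o = pr$attn_W_o, b_o = pr$attn_b_o,
                         embed_dim = D, n_heads = cfg$n_heads),
                    class = "attention_params")
  cache$attn <- attn
  cache$P <- cache$Hemb <- cache$A <- cache$attn_cache <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    P <- xt %*% model$pool[[i]]
    Hm <- scale_embed(P, pr[[paste0("emb_w_", i)]], pr[[paste0("emb_b_", i)]])
    af <- attn_forward(Hm, attn)
    cache$P[[i]] <- P; cache$Hemb[[i]] <- Hm
    cache$A[[i]] <- af$out; cache$attn_cache[[i]] <- af$cache
  }

  # --- phase-aware fusion ---------------------------------------------------
  if (model$use_fusion) {
    kin <- if (cfg$mcpa_input == "dfs") xt else x
    Kt <- hybrid_kernel(pr$mcpa_W_b, impulse_kernel(cfg$kernel_size), pr$mcpa_alpha)
    Sim <- waveform_similarity(kin, Kt)
    wa <- waveform_attention(kin, Sim, scale_preserving = cfg$scale_preserving)
    cache$Kt <- Kt; cache$Sim <- Sim; cache$Aw <- wa$attention
    cache$kin <- kin; cache$Xe <- wa$enhanced
    cache$Xi <- cache$dP <- cache$G <- cache$Fi <- vector("list", length(scales))
    pp <- structure(list(W1 = pr$ph_W1, b1 = pr$ph_b1, W2 = pr$ph_W2,
                         b2 = pr$ph_b2, embed_dim = D), class = "phase_params")
    cache$pp <- pp
    for (i in seq_along(scales)) {
      Pp <- wa$enhanced %*% model$pool[[i]]
      Xi <- scale_embed(Pp, pr[[paste0("align_w_", i)]], pr[[paste0("align_b_", i)]])
      dP <- phase_difference(cache$A[[i]], Xi, pp)
      fg <- phase_gate_fuse(cache$A[[i]], Xi, dP)
      cache$Pp[[i]] <- Pp; cache$Xi[[i]] <- Xi
      cache$dP[[i]] <- dP; cache$G[[i]] <- fg$gate; cache$Fi[[i]] <- fg$fused
    }
    head_in <- cache$Fi
  } else {
    head_in <- cache$A
  }

  hd <- classify_head(head_in, pr$head_W_y, pr$head_b_y, cfg$head_reduction)
  cache$head_features <- hd$features
  cache$prob <- hd$prob
  list(prob = hd$prob, logits = hd$logits, cache = cache)
}

# ---------------------------------------------------------------------------
# Backward pass. dlogits: B x 2 gradient on the pre-softmax head output.
# Returns a flat named list of gradients matching model$params.

model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  pr <- model$params
  scales <- model$scales
  D <- cfg$embed_dim
  B <- nrow(cache$x)
  L <- cfg$segment_length
  g <- lapply(pr, function(p) p * 0)

  # head
  M <- cache$head_features
  g$head_W_y <- crossprod(M, dlogits)
  g$head_b_y <- colSums(dlogits)
  dM <- tcrossprod(dlogits, pr$head_W_y)

  # split dM back into per-scale feature gradients
  dFeat <- vector("list", length(scales))
  off <- 0L
  for (i in seq_along(scales)) {
    s <- scales[i]
    if (cfg$head_reduction == "mean") {
      dmi <- dM[, off + seq_len(D), drop = FALSE]        # B x D
      dFeat[[i]] <- array(rep(dmi / s, each = 1), dim = c(B, 1, D))[, rep(1, s), , drop = FALSE]
      off <- off + D
    } else {
      dFeat[[i]] <- array(dM[, off + seq_len(s * D), drop = FALSE], dim = c(B, s, D))
      off <- off + s * D
    }
  }

  dA <- vector("list", length(scales))   # gradient on attended features
  dXe <- matrix(0, B, L)                 # gradient on enhanced signal

  if (model$use_fusion) {
    pp <- cache$pp
    d_ph_W1 <- array(0, dim = dim(pr$ph_W1)); d_ph_b1 <- numeric(length(pr$ph_b1))
    d_ph_W2 <- numeric(length(pr$ph_W2)); d_ph_b2 <- 0
    for (i in seq_along(scales)) {
      s <- scales[i]
      dF <- dFeat[[i]]
      A_i <- cache$A[[i]]; Xi <- cache$Xi[[i]]; G <- cache$G[[i]]
      Garr <- array(rep(G, D), dim = c(B, s, D))
      dG <- matrix(rowSums(matrix(dF * (A_i - Xi), B * s, D)), B, s)
      dAi <- Garr * dF
      dXi <- (1 - Garr) * dF
      # phase net
      ddp <- dG * G * (1 - G)                          # B x s
      Dm <- matrix(A_i - Xi, B * s, D)
      Z <- sweep(Dm %*% pp$W1, 2, pp$b1, "+")
      T1 <- tanh(Z)
      v <- as.vector(ddp)
      d_ph_W2 <- d_ph_W2 + drop(t(T1) %*% v)
      d_ph_b2 <- d_ph_b2 + sum(v)
      dT1 <- outer(v, pp$W2)
      dZ <- dT1 * (1 - T1^2)
      d_ph_W1 <- d_ph_W1 + crossprod(Dm, dZ)
      d_ph_b1 <- d_ph_b1 + colSums(dZ)
      dDm <- tcrossprod(dZ, pp$W1)
      dDelta <- array(dDm, dim = c(B, s, D))
      dAi <- dAi + dDelta
      dXi <- dXi - dDelta
      dA[[i]] <- dAi
      # align embedding
      dXi_m <- matrix(dXi, B * s, D)
      aw <- pr[[paste0("align_w_", i)]]
      g[[paste0("align_w_", i)]] <- drop(t(dXi_m) %*% as.vector(cache$Pp[[i]]))
      g[[paste0("align_b_", i)]] <- colSums(dXi_m)
      dPp <- matrix(dXi_m %*% aw, B, s)
      dXe <- dXe + tcrossprod(dPp, model$pool[[i]])
    }
    g$ph_W1 <- d_ph_W1; g$ph_b1 <- d_ph_b1; g$ph_W2 <- d_ph_W2; g$ph_b2 <- d_ph_b2

    # waveform attention: Xe = kin * Aw * gain
    gain <- if (cfg$scale_preserving) L else 1
    kin <- cache$kin; Aw <- cache$Aw
    dkin <- dXe * Aw * gain
    dAw <- dXe * kin * gain
    dSim <- row_softmax_vjp(Aw, dAw)
    # correlation adjoint
    k <- cfg$kernel_size; p <- k %/% 2L
    xp <- cbind(kin[, rep(1L, p), drop = FALSE], kin, kin[, rep(L, p), drop = FALSE])
    dKt <- numeric(k)
    dxp <- matrix(0, B, L + 2L * p)
    Kt <- cache$Kt
    for (j in seq_len(k)) {
      cols <- j:(j + L - 1L)
      dKt[j] <- sum(xp[, cols] * dSim)
      dxp[, cols] <- dxp[, cols] + Kt[j] * dSim
    }
    dkin[, 1] <- dkin[, 1] + rowSums(dxp[, seq_len(p), drop = FALSE])
    dkin <- dkin + dxp[, (p + 1L):(p + L), drop = FALSE]
    dkin[, L] <- dkin[, L] + rowSums(dxp[, (p + L + 1L):(L + 2L * p), drop = FALSE])
    # hybrid kernel
    a <- clamp01(pr$mcpa_alpha)
    th <- tanh(pr$mcpa_W_b)
    K0 <- impulse_kernel(k)
    dKraw <- vec_softmax_vjp(Kt, dKt)
    g$mcpa_W_b <- dKraw * a * (1 - th^2)
    g$mcpa_alpha <- if (pr$mcpa_alpha > 0 && pr$mcpa_alpha < 1) {
      sum(dKraw * (th - K0))
    } else 0
    dxt_fusion <- dkin          # routed below depending on mcpa_input
  } else {
    for (i in seq_along(scales)) dA[[i]] <- dFeat[[i]]
    dxt_fusion <- NULL
  }

  # attention + embedding + pooling, per scale
  dxt <- matrix(0, B, L)
  for (i in seq_along(scales)) {
    ab <- attn_backward(dA[[i]], cache$attn, cache$Hemb[[i]], cache$attn_cache[[i]])
    g$attn_W_qkv <- g$attn_W_qkv + ab$W_qkv
    g$attn_lambda <- g$attn_lambda + ab$lambda
    g$attn_W_o <- g$attn_W_o + ab$W_o
    g$attn_b_o <- g$attn_b_o + ab$b_o
    s <- scales[i]
    dH_m <- matrix(ab$dH, B * s, D)
    ew <- pr[[paste0("emb_w_", i)]]
    g[[paste0("emb_w_", i)]] <- drop(t(dH_m) %*% as.vector(cache$P[[i]]))
    g[[paste0("emb_b_", i)]] <- colSums(dH_m)
    dP <- matrix(dH_m %*% ew, B, s)
    dxt <- dxt + tcrossprod(dP, model$pool[[i]])
  }

  if (!is.null(dxt_fusion)) {
    if (cfg$mcpa_input == "dfs") dxt <- dxt + dxt_fusion
    # "raw" input: fusion gradient terminates at the data
  }

  if (cfg$use_dfs) {
    dg <- dfs_backward(dxt, cache$dfs_params, cache$dfs_state)
    g$dfs_W1 <- dg$W1; g$dfs_b1 <- dg$b1; g$dfs_W2 <- dg$W2; g$dfs_b2 <- dg$b2
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class probabilities or labels for new segments
#'
#' Inference runs the deterministic (noise-free) spectral mask.
#'
#' @param object A `seizenet_model`.
#' @param x Segments (`eeg_batch` or matrix).
#' @param type `"prob"` for the `B x 2` class-probability matrix (columns:
#'   class 0, class 1) or `"class"` for hard 0/1 labels.
#' @param ... Unused.
#' @return Matrix of probabilities or integer vector of labels.
#' @export
predict.seizenet_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- model_forward(object, x, training = FALSE)$prob
  colnames(pr) <- c("0", "1")
  if (type == "prob") pr else as.integer(pr[, 2] > pr[, 1])
}

#' Mean learned spectral mask over a dataset
#'
#' Runs the deterministic DFS stage over all segments and averages the
#' per-segment masks, giving the interpretable frequency-selection profile.
#'
#' @param model A `seizenet_model` with `use_dfs = TRUE`.
#' @param x Segments.
#' @return Tibble from [export_mask()]: `bin_index`, `frequency_hz`,
#'   `mean_weight`.
#' @export
dfs_mask_profile <- function(model, x) {
  if (!model$config$use_dfs) stop("Model was built without the DFS stage.", call. = FALSE)
  out <- model_forward(model, x, training = FALSE)
  export_mask(out$cache$dfs_state$mask,
              sampling_rate = model$config$sampling_rate,
              segment_length = model$config$segment_length)
}
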