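# Training loop (Adam on the analytic gradients), loss, and fitted-model
# methods.

cross_entropy <- function(prob, y, weights = NULL) {
  B <- nrow(prob)
  p_true <- prob[cbind(seq_len(B), y + 1L)]
  w <- if (is.null(weights)) rep(1, B) else weights[y + 1L]
  -sum(w * log(pmax(p_true, 1e-12))) / B
}

# dlogits for (optionally weighted) mean cross-entropy over the batch.
cross_entropy_grad <- function(prob, y, weights = NULL) {
  B <- nrow(prob)
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  w <- if (is.null(weights)) rep(1, B) else weights[y + 1L]
  (prob - Y) * w / B
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    step <- lr * mh / (sqrt(vh) + eps)
    if (weight_decay > 0) step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

#' Train a model on labeled segments
#'
#' Minibatch Adam on the analytic gradients of the mean cross-entropy.
#' During training the spectral mask uses fresh Gumbel noise each step;
#' validation metrics (when a validation set is supplied) are computed with
#' the deterministic noise-free mask. Fully reproducible for a fixed
#' `(config$seed, seed)` pair.
#'
#' @param model A `seizenet_model` from [build_model()].
#' @param x Training segments (`eeg_batch` with labels, or matrix).
#' @param y Binary labels (omit when `x` is a labeled `eeg_batch`).
#' @param validation Optional list `list(x =, y =)` evaluated once per epoch.
#' @param epochs,batch_size,learning_rate Override the config defaults.
#' @param seed Seed for shuffling and Gumbel noise. Default `config$seed`.
#' @param verbose Print per-epoch loss.
#' @return Object of class `seizenet_fit`: list with the trained `model` and
#'   a per-epoch `history` tibble (`epoch`, `loss`, plus validation metrics
#'   when available).
#' @export
train_model <- function(model, x, y = NULL, validation = NULL,
                        epochs = NULL, batch_size = NULL, learning_rate = NULL,
                        seed = NULL, verbose = FALSE) {
  cfg <- model$config
  if (inherits(x, "eeg_batch")) {
    if (is.null(y)) y <- x$labels
    x <- x$data
  }
  if (is.null(y)) stop("Training requires labels.", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("Label/segment count mismatch.", call. = FALSE)
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  seed <- seed %||% cfg$seed
  weights <- NULL
  if (isTRUE(cfg$class_weights)) {
    freq <- c(sum(y == 0L), sum(y == 1L)) / length(y)
    weights <- 1 / pmax(freq, 1e-12)
    weights <- weights / mean(weights)
  }
  set.seed(seed)
  opt <- adam_init(model$params)
  n <- nrow(x)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (st in starts) {
      idx <- ord[st:min(st + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- model_forward(model, xb, training = TRUE)
      loss <- cross_entropy(fw$prob, yb, weights)
      if (!is.finite(loss)) {
        stop(sprintf("Non-finite loss at epoch %d (batch starting %d); aborting.",
                     ep, st), call. = FALSE)
      }
      gr <- model_backward(model, fw$cache, cross_entropy_grad(fw$prob, yb, weights))
      upd <- adam_step(model$params, gr, opt, lr,
                       weight_decay = cfg$weight_decay %||% 0)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
    }
    row <- list(epoch = ep, loss = ep_loss / n)
    if (!is.null(validation)) {
      pred <- predict(model, validation$x, type = "class")
      vm <- evaluate_metrics(pred, validation$y,
                             positive_class = cfg$positive_class)
      row$val_acc <- vm$acc; row$val_sens <- vm$sens
      row$val_spec <- vm$spec; row$val_f1 <- vm$f1
    }
    history[[ep]] <- tibble::as_tibble(row)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f%s", ep, epochs, row$loss,
                      if (!is.null(row$val_acc)) sprintf("  val acc %.3f", row$val_acc) else ""))
    }
  }
  structure(list(model = model, history = do.call(rbind, history),
                 seed = seed, config_hash = config_hash(cfg)),
            class = "seizenet_fit")
}

#' @export
print.seizenet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<seizenet_fit> %d epoch(s), final loss %.4f (config %s, seed %d)\n",
              nrow(h), h$loss[nrow(h)], substr(x$config_hash, 1, 8), x$seed))
  invisible(x)
}

#' Per-epoch training history of a fit
#' @param x A `seizenet_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @method tidy seizenet_fit
#' @export
tidy.seizenet_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x A `seizenet_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs, final loss, parameter count, seed.
#' @method glance seizenet_fit
#' @export
glance.seizenet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), final_loss = h$loss[nrow(h)],
                 n_params = n_params(x$model), seed = x$seed,
                 config_hash = x$config_hash)
}

#' @export
predict.seizenet_fit <- function(object, x, type = c("prob", "class"), ...) {
  predict(object$model, x, type = match.arg(type), ...)
}
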