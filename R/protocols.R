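# Experimental protocols: stratified/plain splits, repeated mixed-split
# generalization, ablation variants, and control-variable sensitivity sweeps.

#' Stratified train/test split indices
#'
#' Splits per class so a low-prevalence positive class cannot vanish from
#' either side. Indices are disjoint and cover all samples.
#'
#' @param labels Binary label vector.
#' @param train_frac Fraction assigned to training (strictly in (0, 1)).
#' @param seed RNG seed.
#' @param stratified Stratify by label (default) or split uniformly.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed = 1L,
                             stratified = TRUE) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly in (0, 1).", call. = FALSE)
  }
  n <- length(labels)
  set.seed(seed)
  if (stratified) {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, round(length(idx) * train_frac)))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, round(n * train_frac)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Train on a split of a dataset and evaluate on the held-out part
#'
#' The standard single-experiment protocol: stratified 80/20 split, fit,
#' deterministic evaluation on the test side.
#'
#' @param config A [model_config()].
#' @param dataset An `eeg_dataset` (or list with `segments`, `labels`).
#' @param train_frac Training fraction. Default 0.8.
#' @param seed Seed for the split, initialization, and training noise
#'   (overrides `config$seed`).
#' @param epochs,batch_size,learning_rate Optional training overrides.
#' @param stratified Stratify the split by label. Default `TRUE`.
#' @return List: `metrics` (one-row tibble from [evaluate_metrics()]),
#'   `fit` (the `seizenet_fit`), `split` (index list).
#' @export
evaluate_on_split <- function(config, dataset, train_frac = 0.8,
                              seed = config$seed, epochs = NULL,
                              batch_size = NULL, learning_rate = NULL,
                              stratified = TRUE) {
  sp <- stratified_split(dataset$labels, train_frac, seed, stratified)
  cfg <- config
  cfg$seed <- as.integer(seed)
  model <- build_model(cfg)
  fit <- train_model(model,
                     dataset$segments[sp$train, , drop = FALSE],
                     dataset$labels[sp$train],
                     epochs = epochs, batch_size = batch_size,
                     learning_rate = learning_rate, seed = seed)
  pred <- predict(fit, dataset$segments[sp$test, , drop = FALSE], type = "class")
  metrics <- evaluate_metrics(pred, dataset$labels[sp$test],
                              positive_class = config$positive_class)
  list(metrics = metrics, fit = fit, split = sp)
}

#' Configuration for an ablation variant
#'
#' `"ORI"` is the full model; `"AB1"` removes dynamic frequency selection
#' (multi-scale pooling acts on the raw signal); `"AB2"` removes multi-scale
#' extraction (one full-resolution attention branch, no fusion); `"AB3"`
#' removes phase-aware fusion (attended features feed the head directly).
#'
#' @param base A [model_config()].
#' @param variant One of `"ORI"`, `"AB1"`, `"AB2"`, `"AB3"`.
#' @return A [model_config()] with the corresponding flag cleared.
#' @export
ablation_config <- function(base, variant = c("ORI", "AB1", "AB2", "AB3")) {
  variant <- match.arg(variant)
  cfg <- unclass(base)
  cfg$use_dfs <- variant != "AB1"
  cfg$use_mcfe <- variant != "AB2"
  cfg$use_mcpa <- variant != "AB3"
  do.call(model_config, cfg)
}

#' Repeated mixed-split generalization protocol
#'
#' Merges the given datasets, then repeatedly (default 20 times) shuffles the
#' pool and splits it at the preset ratio (default 8:2), training and
#' evaluating once per repeat. Every repeat's split is disjoint and covers
#' all samples.
#'
#' @param datasets One `eeg_dataset` or a list of them (merged).
#' @param config A [model_config()] used by the default trainer.
#' @param n_repeats Number of shuffles. Default 20.
#' @param train_frac Training fraction. Default 0.8.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param trainer Function `(x_train, y_train, x_test, seed)` returning
#'   predicted labels for the test segments. Defaults to building and
#'   training `config` via [train_model()]. Injectable so the protocol can
#'   be exercised with cheap classifiers.
#' @param epochs,batch_size Overrides forwarded to the default trainer.
#' @return List of class `mixed_split_result`: `per_repeat` (tibble with one
#'   row of metrics per repeat), `splits` (list of index lists), `summary`
#'   (tibble of mean and sd per metric).
#' @export
mixed_split_generalization <- function(datasets, config = NULL, n_repeats = 20,
                                       train_frac = 0.8, seed = 1L,
                                       trainer = NULL, epochs = NULL,
                                       batch_size = NULL) {
  if (inherits(datasets, "eeg_dataset")) datasets <- list(datasets)
  if (length(datasets) < 1) stop("At least one dataset is required.", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly in (0, 1).", call. = FALSE)
  }
  segments <- do.call(rbind, lapply(datasets, function(d) d$segments))
  labels <- unlist(lapply(datasets, function(d) d$labels))
  if (is.null(trainer)) {
    if (is.null(config)) stop("Provide `config` or a custom `trainer`.", call. = FALSE)
    trainer <- function(x_train, y_train, x_test, s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      fit <- train_model(build_model(cfg), x_train, y_train,
                         epochs = epochs, batch_size = batch_size, seed = s)
      predict(fit, x_test, type = "class")
    }
  }
  pos <- if (!is.null(config)) config$positive_class else 1L
  rows <- vector("list", n_repeats)
  splits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- seed + r
    sp <- stratified_split(labels, train_frac, seed = s, stratified = FALSE)
    pred <- trainer(segments[sp$train, , drop = FALSE], labels[sp$train],
                    segments[sp$test, , drop = FALSE], s)
    m <- evaluate_metrics(pred, labels[sp$test], positive_class = pos)
    rows[[r]] <- tibble::tibble(repeat_id = r, seed = s,
                                n_train = length(sp$train),
                                n_test = length(sp$test), m)
    splits[[r]] <- sp
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("acc", "sens", "spec", "f1")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(cl) mean(per_repeat[[cl]]), numeric(1))),
    sd = unname(vapply(metric_cols, function(cl) stats::sd(per_repeat[[cl]]), numeric(1)))
  )
  structure(list(per_repeat = per_repeat, splits = splits, summary = summary),
            class = "mixed_split_result")
}

#' Control-variable sensitivity sweep
#'
#' Varies one hyperparameter at a time over the supplied grids while holding
#' every other key at its base value. Grid values producing an invalid
#' configuration (e.g. scales that do not divide the segment length without
#' interpolation) are recorded as failed rows; the sweep continues.
#'
#' @param base_config A [model_config()].
#' @param grid Named list mapping a config key to a vector (or, for list
#'   valued keys such as `scales`, a list) of values to try.
#' @param evaluate_fn Optional function `(config) -> one-row tibble/list of
#'   metrics` appended to each valid row (e.g. a wrapper around
#'   [evaluate_on_split()]). `NULL` performs a dry validation sweep.
#' @return Tibble with one row per grid point: `param`, `value` (deparsed),
#'   `status` (`"ok"`/`"error"`), `message`, `base_hash` (hash of all
#'   non-swept keys), and any metric columns.
#' @export
sensitivity_sweep <- function(base_config, grid, evaluate_fn = NULL) {
  stopifnot(inherits(base_config, "model_config"))
  rows <- list()
  for (param in names(grid)) {
    if (!param %in% names(base_config)) {
      stop(sprintf("Unknown config key `%s` in grid.", param), call. = FALSE)
    }
    base_rest <- unclass(base_config)
    base_rest[[param]] <- NULL
    base_hash <- rlang::hash(base_rest[sort(names(base_rest))])
    values <- grid[[param]]
    if (!is.list(values)) values <- as.list(values)
    for (v in values) {
      cfg_list <- unclass(base_config)
      cfg_list[[param]] <- v
      row <- tibble::tibble(param = param,
                            value = paste(deparse(v), collapse = ""),
                            status = "ok", message = "", base_hash = base_hash)
      cfg <- tryCatch(do.call(model_config, cfg_list), error = identity)
      if (inherits(cfg, "error")) {
        row$status <- "error"
        row$message <- conditionMessage(cfg)
      } else if (!is.null(evaluate_fn)) {
        met <- tryCatch(tibble::as_tibble(evaluate_fn(cfg)), error = identity)
        if (inherits(met, "error")) {
          row$status <- "error"
          row$message <- conditionMessage(met)
        } else {
          row <- tibble::tibble(row, met)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(param = character(), value = character(),
                          status = character(), message = character(),
                          base_hash = character()))
  }
  # pad differing columns (failed rows lack metrics)
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  do.call(rbind, rows)
}
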