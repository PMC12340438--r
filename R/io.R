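# Readers and writers: CSV segment matrices (full-precision, so round trips
# are bitwise), JSON manifests and metrics, YAML run configuration, and a
# JSON model format so trained models can move between CLI subcommands.

#' Write a segment matrix (and labels) to CSV
#'
#' Values are written with 17 significant digits, so reading the file back
#' reproduces the doubles bitwise. Columns are `s1..sL` plus, when labels
#' are present, a final `label` column.
#'
#' @param x Segments (`eeg_batch`, `eeg_dataset`, or matrix).
#' @param path Output path.
#' @param labels Optional binary labels (taken from `x` when it carries
#'   them).
#' @param manifest Optional list written as JSON next to `path`
#'   (`<path>.manifest.json`).
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path, labels = NULL, manifest = NULL) {
  if (inherits(x, "eeg_dataset")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(manifest)) manifest <- unclass(x$manifest)
    x <- x$segments
  } else if (inherits(x, "eeg_batch")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$data
  }
  L <- ncol(x)
  header <- paste0("s", seq_len(L))
  body <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(labels)) {
    header <- c(header, "label")
    body <- paste(body, as.integer(labels), sep = ",")
  }
  writeLines(c(paste(header, collapse = ","), body), path)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a segment matrix from CSV
#'
#' Expects the layout written by [write_segments()]: a header of `s1..sL`
#' (optionally followed by `label`) and one comma-separated row per segment.
#' Ragged or non-numeric rows raise an error naming the offending row.
#'
#' @param path Input path.
#' @param format Only `"csv"` is supported.
#' @param sampling_rate Hz recorded on the returned batch. Default 256.
#' @param require_labels Error when no label column is present.
#' @return An [eeg_batch()] (with labels when the file has them).
#' @export
read_segments <- function(path, format = "csv", sampling_rate = 256,
                          require_labels = FALSE) {
  if (format != "csv") {
    stop(sprintf("Unsupported format \"%s\"; segments are read from CSV.", format),
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("Empty input: no segment rows found.", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_labels <- header[length(header)] == "label"
  ncols <- length(header)
  L <- ncols - has_labels
  if (require_labels && !has_labels) {
    stop("Labeled mode requested but the file has no `label` column.", call. = FALSE)
  }
  n <- length(lines) - 1L
  data <- matrix(0, n, L)
  labels <- if (has_labels) integer(n) else NULL
  for (i in seq_len(n)) {
    tok <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(tok) != ncols) {
      stop(sprintf("Ragged row %d: expected %d fields, found %d.",
                   i, ncols, length(tok)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) {
      stop(sprintf("Non-numeric value in row %d.", i), call. = FALSE)
    }
    data[i, ] <- vals[seq_len(L)]
    if (has_labels) labels[i] <- as.integer(vals[ncols])
  }
  eeg_batch(data, sampling_rate = sampling_rate, labels = labels)
}

#' Serialize a (trained) model to JSON
#'
#' Stores the configuration and every parameter array (with its shape) at
#' full precision, so CLI subcommands can hand trained models to one
#' another as plain text.
#'
#' @param model A `seizenet_model` or `seizenet_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model_json <- function(model, path) {
  if (inherits(model, "seizenet_fit")) model <- model$model
  params <- lapply(model$params, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.vector(p))
  })
  jsonlite::write_json(list(config = unclass(model$config), params = params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model_json()]
#' @param path Input path.
#' @return A `seizenet_model`.
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_list <- obj$config
  cfg_list$scales <- as.integer(unlist(cfg_list$scales))
  cfg <- do.call(model_config, cfg_list)
  model <- build_model(cfg)
  for (nm in names(model$params)) {
    p <- obj$params[[nm]]
    if (is.null(p)) stop(sprintf("Missing parameter `%s` in %s.", nm, path), call. = FALSE)
    v <- as.numeric(p$data)
    dm <- as.integer(unlist(p$dim))
    model$params[[nm]] <- if (length(dm) > 1) array(v, dim = dm) else v
  }
  model
}

#' Write a run configuration to YAML (versioned schema)
#'
#' @param config A [model_config()] or [synth_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  type <- if (inherits(config, "synth_config")) "synth" else "model"
  yaml::write_yaml(list(schema_version = 1L, type = type,
                        config = unclass(config)), path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Unknown keys are errors, not warnings, so configuration typos cannot
#' silently fall back to defaults.
#'
#' @param path Input path.
#' @return A validated [model_config()] or [synth_config()].
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("Unsupported or missing config schema_version (expected 1).", call. = FALSE)
  }
  ctor <- switch(obj$type %||% "model", model = model_config,
                 synth = synth_config,
                 stop("Config `type` must be \"model\" or \"synth\".", call. = FALSE))
  cfg <- obj$config
  known <- names(formals(ctor))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(cfg$scales)) cfg$scales <- as.integer(unlist(cfg$scales))
  if (!is.null(cfg$band)) cfg$band <- as.numeric(unlist(cfg$band))
  if (!is.null(cfg$rhythms)) cfg$rhythms <- lapply(cfg$rhythms, as.numeric)
  do.call(ctor, cfg)
}
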