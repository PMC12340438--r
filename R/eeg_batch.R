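#' Construct a batch of fixed-length EEG segments
#'
#' An `eeg_batch` bundles a real-valued segment matrix (one row per segment)
#' with its sampling rate and, optionally, binary class labels
#' (1 = seizure, 0 = non-seizure by convention; see [evaluate_metrics()] for
#' how the positive class is chosen at evaluation time).
#'
#' @param data Numeric matrix, `B x L` (segments in rows). A single segment
#'   may be given as a vector and is promoted to a one-row matrix.
#' @param sampling_rate Sampling rate in Hz. Default 256.
#' @param labels Optional binary vector of length `B` with values in `{0, 1}`.
#' @return An object of class `eeg_batch`: a list with elements `data`,
#'   `sampling_rate`, `labels`.
#' @examples
#' x <- eeg_batch(matrix(rnorm(4 * 64), 4, 64))
#' dim(x$data)
#' @export
eeg_batch <- function(data, sampling_rate = 256, labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (segments in rows).", call. = FALSE)
  }
  if (ncol(data) < 2) stop("Segment length L must be at least 2.", call. = FALSE)
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("Non-finite value in segment %d, sample %d.", bad[1], bad[2]),
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive scalar (Hz).", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(data)) {
      stop("`labels` must have one entry per segment.", call. = FALSE)
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("`labels` must be binary (0/1).", call. = FALSE)
    }
  }
  structure(
    list(data = unname(data), sampling_rate = sampling_rate, labels = labels),
    class = "eeg_batch"
  )
}

#' @export
print.eeg_batch <- function(x, ...) {
  cat(sprintf("<eeg_batch> %d segment(s) x %d samples @ %g Hz",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  if (!is.null(x$labels)) {
    cat(sprintf(" | %d positive / %d total", sum(x$labels), length(x$labels)))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.eeg_batch <- function(x) dim(x$data)

# Coerce an eeg_batch or bare matrix/vector to a validated segment matrix.
as_segment_matrix <- function(x) {
  if (inherits(x, "eeg_batch")) return(x$data)
  eeg_batch(x)$data
}
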