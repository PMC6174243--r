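#' Construct a multichannel EEG recording
#'
#' The basic container for a resting-state recording: a time-by-channel
#' numeric matrix in microvolts, a sampling rate, timed condition
#' annotations, and the electrode montage. Annotations use half-open
#' intervals `[onset, onset + duration)` in seconds.
#'
#' @param samples Numeric matrix, time points in rows, channels in columns;
#'   column names are the channel labels (microvolts).
#' @param rate Sampling rate in Hz (> 0).
#' @param annotations Tibble/data frame with columns `label`, `onset` (s)
#'   and `duration` (s); may have zero rows.
#' @param montage Electrode montage as returned by [standard_montage()];
#'   must contain every channel label.
#' @param subject_id Identifier string carried through the pipeline.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate,
                          annotations = empty_annotations(),
                          montage = standard_montage(colnames(samples)),
                          subject_id = "unknown") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (time x channels)")
  }
  if (is.null(colnames(samples))) {
    abort("`samples` must have channel labels as column names")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number")
  }
  annotations <- as_tibble(annotations)
  dur_s <- nrow(samples) / rate
  if (nrow(annotations) > 0) {
    if (any(annotations$onset < 0) ||
        any(annotations$onset + annotations$duration > dur_s + 1e-9)) {
      abort("annotations must lie within the recording")
    }
  }
  colnames(samples) <- toupper(colnames(samples))
  montage <- as_tibble(montage)
  if (!all(colnames(samples) %in% montage$label)) {
    abort("every channel must be present in the montage")
  }
  structure(
    list(samples = samples, rate = rate, annotations = annotations,
         montage = montage, subject_id = subject_id),
    class = "eeg_recording"
  )
}

empty_annotations <- function() {
  tibble(label = character(), onset = numeric(), duration = numeric())
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels x %.1f s @ %g Hz, %d annotation(s)\n",
    x$subject_id, ncol(x$samples), nrow(x$samples) / x$rate, x$rate,
    nrow(x$annotations)))
  cat("  channels:", paste(colnames(x$samples), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.eeg_recording <- function(x, ...) {
  tb <- as_tibble(x$samples)
  tb$time <- (seq_len(nrow(x$samples)) - 1) / x$rate
  tidyr::pivot_longer(tb, cols = -"time",
                      names_to = "channel", values_to = "uv")
}

n_channels <- function(rec) ncol(rec$samples)
channel_labels <- function(rec) colnames(rec$samples)
rec_duration <- function(rec) nrow(rec$samples) / rec$rate

# replace the sample matrix, keeping all metadata
set_samples <- function(rec, samples) {
  stopifnot(identical(dim(samples), dim(rec$samples)))
  dimnames(samples) <- dimnames(rec$samples)
  rec$samples <- samples
  rec
}
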