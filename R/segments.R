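#' Extract eyes-closed / eyes-open condition segments
#'
#' Matches the recording's annotations against a configurable label map
#' (case-insensitive) and returns the eyes-closed (EC) and eyes-open (EO)
#' intervals. Intervals are half-open `[start, end)` in seconds; each is
#' trimmed down to a whole number of 1-s analysis windows and dropped
#' entirely if shorter than one window.
#'
#' @param rec An [eeg_recording()] with condition annotations.
#' @param label_map Named list with elements `ec` and `eo`, each a
#'   character vector of annotation labels to accept for that condition.
#' @param min_window Minimum (and trimming) window length in seconds
#'   (default 1).
#'
#' @return A tibble with columns `condition` ("EC"/"EO"), `start`, `end`
#'   (seconds).
#' @export
segment_conditions <- function(rec,
                               label_map = list(
                                 ec = c("EC", "eyes closed"),
                                 eo = c("EO", "eyes open")),
                               min_window = 1) {
  ann <- rec$annotations
  lab <- tolower(trimws(ann$label))
  cond <- rep(NA_character_, length(lab))
  cond[lab %in% tolower(label_map$ec)] <- "EC"
  cond[lab %in% tolower(label_map$eo)] <- "EO"
  segs <- tibble(condition = cond,
                 start = ann$onset,
                 end = ann$onset + ann$duration) %>%
    filter(!is.na(.data$condition))
  # trim sub-window remainders, drop segments shorter than one window
  segs <- segs %>%
    mutate(end = .data$start +
             floor((.data$end - .data$start) / min_window) * min_window) %>%
    filter(.data$end - .data$start >= min_window) %>%
    arrange(.data$condition, .data$start)
  if (!any(segs$condition == "EC") || !any(segs$condition == "EO")) {
    abort(paste("recording lacks eyes-closed or eyes-open intervals;",
                "cannot compute difference spectrum"),
          class = "alphanorm_no_conditions")
  }
  segs
}
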