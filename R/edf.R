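# Minimal EDF+ (16-bit European Data Format with annotations) IO.
# Only the subset needed here: continuous recordings (EDF+C), one
# annotation signal holding condition markers, equal sampling rate on all
# data signals, 1-second data records.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x) {
  # shortest decimal representation that round-trips to 8 ascii chars
  s <- formatC(x, format = "fg", digits = 7, width = 1)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s
}

tal_time <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  paste0(ifelse(x < 0, "", "+"), s)
}

#' Write a recording to an EDF+ file
#'
#' Serializes an [eeg_recording()] as a continuous EDF+ file: one 16-bit
#' data signal per channel (microvolts) plus an `EDF Annotations` signal
#' carrying the condition annotations as time-stamped annotation lists.
#' Data records are 1 s long; the recording is zero-padded to a whole
#' number of records if needed.
#'
#' @param rec An [eeg_recording()]. The sampling rate must be a whole
#'   number of samples per second.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_edfplus <- function(rec, path) {
  fs <- rec$rate
  if (abs(fs - round(fs)) > 1e-9) abort("sampling rate must be integer Hz")
  fs <- as.integer(round(fs))
  x <- rec$samples
  nch <- ncol(x)
  n_rec <- as.integer(ceiling(nrow(x) / fs))
  if (nrow(x) < n_rec * fs) {
    x <- rbind(x, matrix(0, n_rec * fs - nrow(x), nch))
  }

  pmax_ <- max(1, ceiling(max(abs(x))))
  pmin_ <- -pmax_
  dmin <- -32768L
  dmax <- 32767L
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round((x - pmin_) / gain) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"

  # one TAL stream per record: record-keeping timestamp, then any
  # annotation whose onset falls inside that record
  ann <- rec$annotations
  tals <- lapply(seq_len(n_rec) - 1L, function(t0) {
    parts <- paste0(tal_time(t0), "\x14\x14")
    if (nrow(ann) > 0) {
      in_rec <- which(floor(ann$onset) == t0)
      for (i in in_rec) {
        parts <- c(parts, paste0(
          tal_time(ann$onset[i]), "\x15",
          sub("^\\+", "", tal_time(ann$duration[i])),
          "\x14", ann$label[i], "\x14"))
      }
    }
    # each TAL is terminated by a nul byte
    do.call(c, lapply(parts, function(p) c(charToRaw(p), as.raw(0))))
  })
  ann_bytes <- max(60L, max(vapply(tals, length, 1L)) + 1L)
  if (ann_bytes %% 2L == 1L) ann_bytes <- ann_bytes + 1L
  ann_ns <- ann_bytes %/% 2L

  ns <- nch + 1L
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(edf_pad(s, w)), con)

  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr("EDF+C", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)

  labels <- c(colnames(rec$samples), "EDF Annotations")
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num(pmin_) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num(pmax_) else "1", 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(if (i <= nch) fs else ann_ns, 8)
  for (i in seq_len(ns)) wr("", 32)                       # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      writeBin(dig[idx, ch], con, size = 2L, endian = "little")
    }
    tal <- tals[[r]]
    writeBin(c(tal, raw(ann_bytes - length(tal))), con)
  }
  invisible(path)
}

#' Read an EDF+ file into a recording
#'
#' Reads a continuous EDF/EDF+ file, converts data signals to physical
#' units (expected microvolts) and parses the `EDF Annotations` signal
#' into timed condition annotations. Channels are matched to the montage
#' by label, case-insensitively and ignoring an `EEG ` prefix; channels
#' absent from the montage are dropped with a warning.
#'
#' @param path Path to an EDF+ file.
#' @param montage Montage tibble; defaults to [standard_montage()].
#' @param subject_id Subject identifier; defaults to the file name.
#'
#' @return An [eeg_recording()].
#' @export
read_edfplus <- function(path, montage = standard_montage(),
                         subject_id = sub("\\.edf$", "", basename(path),
                                          ignore.case = TRUE)) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))

  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)                                  # reserved / EDF+C
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) abort("not a valid EDF file")

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  seek(con, header_bytes)

  is_ann <- grepl("^EDF Annotations", labels)
  data_idx <- which(!is_ann)
  if (length(unique(nsamp[data_idx])) > 1) {
    abort("sampling rate differs across data channels")
  }
  fs <- nsamp[data_idx[1]] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)

  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        sig[[i]][[r]] <- readBin(con, "raw", nsamp[i] * 2L)
      } else {
        d <- readBin(con, "integer", nsamp[i], size = 2L, endian = "little")
        sig[[i]][[r]] <- pmin_[i] + (d - dmin[i]) * gain[i]
      }
    }
  }

  samples <- do.call(cbind, lapply(data_idx, function(i) unlist(sig[[i]])))
  raw_labels <- toupper(trimws(sub("^EEG[ .]*", "", labels[data_idx],
                                   ignore.case = TRUE)))
  colnames(samples) <- raw_labels

  known <- raw_labels %in% montage$label
  if (!all(known)) {
    warn(paste0("dropping channel(s) absent from montage: ",
                paste(raw_labels[!known], collapse = ", ")))
    samples <- samples[, known, drop = FALSE]
  }

  ann <- empty_annotations()
  if (any(is_ann)) {
    bytes <- do.call(c, sig[[which(is_ann)[1]]])
    ann <- parse_tals(bytes)
  }

  eeg_recording(samples, fs, ann,
                montage = montage[montage$label %in% colnames(samples), ],
                subject_id = subject_id)
}

parse_tals <- function(bytes) {
  bytes[bytes == as.raw(0)] <- as.raw(10)   # TAL separator -> newline
  tals <- unlist(strsplit(rawToChar(bytes), "\n", fixed = TRUE))
  out <- list()
  for (t in tals) {
    if (!nzchar(t)) next
    parts <- unlist(strsplit(t, "\x14", fixed = TRUE))
    if (length(parts) < 2) next                       # timestamp-only TAL
    head_ <- parts[1]
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    if (length(labs) == 0) next
    if (grepl("\x15", head_, fixed = TRUE)) {
      od <- unlist(strsplit(head_, "\x15", fixed = TRUE))
      onset <- as.numeric(od[1]); dur <- as.numeric(od[2])
    } else {
      onset <- as.numeric(head_); dur <- 0
    }
    for (l in labs) {
      out[[length(out) + 1]] <- tibble(label = l, onset = onset,
                                       duration = dur)
    }
  }
  if (length(out) == 0) empty_annotations() else bind_rows(out)
}
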