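# Sliding-window spectral estimation and alpha-peak detection.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# gather window start samples (0-based) from half-open segments
window_starts <- function(segs, rate, window_s, overlap) {
  step <- window_s * (1 - overlap)
  starts <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    s <- segs$start[i]; e <- segs$end[i]
    if (e - s < window_s) return(numeric(0))
    seq(s, e - window_s, by = step)
  }))
  round(starts * rate)
}

#' Average power spectrum over sliding windows
#'
#' Computes the per-channel power spectral density by averaging
#' Hann-tapered, zero-padded periodograms over 1-s sliding windows taken
#' from the given segments, and expresses it in dB. With the defaults
#' (500 Hz, 1-s windows, 4x zero padding) the frequency grid has 0.25 Hz
#' spacing.
#'
#' @param rec An [eeg_recording()].
#' @param segments Tibble with `start`/`end` columns in seconds (e.g. one
#'   condition's rows from [segment_conditions()]).
#' @param window_s Window length in seconds (default 1).
#' @param overlap Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param pad Zero-padding factor (default 4).
#' @param condition Optional condition tag stored on the result.
#'
#' @return An `eeg_spectrum`: list with `freqs` (Hz), `power_db`
#'   (channels x freqs matrix), `psd` (linear, same shape), `n_windows`,
#'   `channels`, `condition`.
#' @export
compute_spectrum <- function(rec, segments, window_s = 1, overlap = 0.5,
                             pad = 4, condition = NA_character_) {
  fs <- rec$rate
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  starts <- window_starts(segments, fs, window_s, overlap)
  if (length(starts) == 0) abort("no segment is long enough for one window")
  n <- round(window_s * fs)
  nfft <- pad * n
  w <- hann_window(n)
  scale <- 1 / (fs * sum(w^2))
  nkeep <- nfft / 2 + 1

  acc <- matrix(0, n_channels(rec), nkeep)
  for (s0 in starts) {
    seg <- rec$samples[(s0 + 1):(s0 + n), , drop = FALSE]
    tapered <- seg * w
    X <- stats::mvfft(rbind(tapered, matrix(0, nfft - n, ncol(seg))))
    p <- (Mod(X[1:nkeep, , drop = FALSE])^2) * scale
    p[2:(nkeep - 1), ] <- 2 * p[2:(nkeep - 1), ]      # one-sided
    acc <- acc + t(p)
  }
  psd <- acc / length(starts)
  structure(
    list(freqs = (0:(nkeep - 1)) * fs / nfft,
         power_db = 10 * log10(pmax(psd, 1e-300)),
         psd = psd,
         n_windows = length(starts),
         channels = channel_labels(rec),
         condition = condition),
    class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum%s> %d channels, %.2f-%.2f Hz (step %.3g), %d window(s)\n",
              if (is.na(x$condition)) "" else paste0(" ", x$condition),
              length(x$channels), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.eeg_spectrum <- function(x, ...) {
  tibble(channel = rep(x$channels, times = length(x$freqs)),
         freq = rep(x$freqs, each = length(x$channels)),
         power_db = as.vector(x$power_db),
         condition = x$condition)
}

#' Eyes-closed minus eyes-open difference spectrum
#'
#' @param ec,eo `eeg_spectrum` objects on identical frequency grids with
#'   identical channel order.
#'
#' @return An `eeg_spectrum` whose `power_db` is the element-wise dB
#'   difference EC - EO (its linear `psd` field is dropped).
#' @export
difference_spectrum <- function(ec, eo) {
  if (!isTRUE(all.equal(ec$freqs, eo$freqs))) {
    abort("frequency grids differ between conditions")
  }
  if (!identical(ec$channels, eo$channels)) {
    abort("channel sets or order differ between conditions")
  }
  structure(
    list(freqs = ec$freqs,
         power_db = ec$power_db - eo$power_db,
         psd = NULL,
         n_windows = min(ec$n_windows, eo$n_windows),
         channels = ec$channels,
         condition = "EC-EO"),
    class = "eeg_spectrum")
}

#' Detect the individual alpha peak on the difference spectrum
#'
#' Searches the EC-EO difference spectrum over posterior candidate
#' channels for the largest local maximum inside the alpha search band.
#' The peak frequency is refined by quadratic interpolation through the
#' three bins around the maximum; peak power is the interpolated dB
#' difference at the refined frequency. Prominence is the peak value
#' minus the higher of the two minima flanking it within the band. Ties
#' across channels resolve to the earlier candidate.
#'
#' @param diff_spec Difference spectrum from [difference_spectrum()].
#' @param ec Optional EC spectrum; if given, the absolute EC power at the
#'   peak is reported as `power_ec`.
#' @param candidates Channel labels to search (default the posterior set
#'   O1, O2, T5, T6).
#' @param band Search band in Hz (default `c(8, 12)`).
#' @param min_prominence Minimum peak prominence in dB (default 0.5);
#'   below it a condition of class `alphanorm_no_peak` is signalled.
#'
#' @return One-row tibble: `channel`, `frequency` (Hz), `power` (dB,
#'   EC-EO at peak), `prominence` (dB), `power_ec` (dB or NA),
#'   `band_lo`, `band_hi`.
#' @export
detect_alpha_peak <- function(diff_spec, ec = NULL,
                              candidates = c("O1", "O2", "T5", "T6"),
                              band = c(8, 12), min_prominence = 0.5) {
  candidates <- toupper(candidates)
  if (length(candidates) == 0) abort("`candidates` must be non-empty")
  if (!all(candidates %in% diff_spec$channels)) {
    abort("some candidate channels are absent from the spectrum")
  }
  f <- diff_spec$freqs
  in_band <- which(f >= band[1] & f <= band[2])
  if (length(in_band) < 3) abort("search band too narrow for the grid")

  best <- NULL
  for (ch in candidates) {
    y <- diff_spec$power_db[match(ch, diff_spec$channels), ]
    yb <- y[in_band]
    # interior local maxima of the in-band curve
    loc <- which(diff(sign(diff(yb))) < 0) + 1L
    loc <- loc[loc > 1 & loc < length(yb)]
    if (length(loc) == 0) next
    for (i in loc) {
      left_min <- min(yb[1:i])
      right_min <- min(yb[i:length(yb)])
      prom <- yb[i] - max(left_min, right_min)
      if (prom < min_prominence) next
      gi <- in_band[i]
      # quadratic refinement on the native grid around the maximum
      y0 <- y[gi - 1]; y1 <- y[gi]; y2 <- y[gi + 1]
      denom <- y0 - 2 * y1 + y2
      delta <- if (abs(denom) < 1e-15) 0 else 0.5 * (y0 - y2) / denom
      delta <- max(min(delta, 0.5), -0.5)
      df <- f[2] - f[1]
      freq <- f[gi] + delta * df
      val <- y1 - 0.25 * (y0 - y2) * delta
      cand <- list(channel = ch, frequency = freq, power = val,
                   prominence = prom, grid_index = gi)
      if (is.null(best) || cand$power > best$power) best <- cand
    }
  }
  if (is.null(best)) {
    abort("no alpha peak above the prominence threshold in the search band",
          class = "alphanorm_no_peak")
  }
  power_ec <- NA_real_
  if (!is.null(ec)) {
    power_ec <- ec$power_db[match(best$channel, ec$channels),
                            best$grid_index]
  }
  tibble(channel = best$channel, frequency = best$frequency,
         power = best$power, prominence = best$prominence,
         power_ec = power_ec, band_lo = band[1], band_hi = band[2])
}

#' Cross-check the FFT spectrum against a direct DFT
#'
#' Recomputes the sliding-window spectrum of a short recording with a
#' brute-force discrete Fourier transform (an explicit complex-exponential
#' matrix product, no FFT) under identical windowing, padding and
#' averaging conventions, and reports the maximum absolute dB discrepancy
#' per channel. Spectral analysis backends have been observed to disagree
#' on identical data; this check pins the package's backend to the
#' definition of the DFT.
#'
#' @param rec A short [eeg_recording()] (about a minute at most).
#' @param segments Segments tibble as for [compute_spectrum()].
#' @inheritParams compute_spectrum
#'
#' @return List with `max_abs_db` (worst-case |difference| in dB),
#'   `fft` and `direct` spectra.
#' @export
spectral_oracle_check <- function(rec, segments, window_s = 1,
                                  overlap = 0.5, pad = 4) {
  sp_fft <- compute_spectrum(rec, segments, window_s, overlap, pad)

  fs <- rec$rate
  starts <- window_starts(segments, fs, window_s, overlap)
  n <- round(window_s * fs)
  nfft <- pad * n
  w <- hann_window(n)
  scale <- 1 / (fs * sum(w^2))
  nkeep <- nfft / 2 + 1
  # one-sided DFT matrix; padded samples beyond n contribute nothing
  W <- exp(-2i * pi * outer(0:(nkeep - 1), 0:(n - 1)) / nfft)

  acc <- matrix(0, n_channels(rec), nkeep)
  for (s0 in starts) {
    seg <- rec$samples[(s0 + 1):(s0 + n), , drop = FALSE]
    X <- W %*% (seg * w)
    p <- (Mod(X)^2) * scale
    p[2:(nkeep - 1), ] <- 2 * p[2:(nkeep - 1), ]
    acc <- acc + t(p)
  }
  psd <- acc / length(starts)
  direct_db <- 10 * log10(pmax(psd, 1e-300))

  list(max_abs_db = max(abs(direct_db - sp_fft$power_db)),
       fft = sp_fft,
       direct = structure(
         list(freqs = sp_fft$freqs, power_db = direct_db, psd = psd,
              n_windows = length(starts), channels = sp_fft$channels,
              condition = sp_fft$condition),
         class = "eeg_spectrum"))
}
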