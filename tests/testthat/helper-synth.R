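# shared fixtures, all generated in code

# a recording with every channel equal to `x` (or a custom matrix)
flat_recording <- function(x, rate = 500, annotations = NULL) {
  m <- standard_montage()
  samples <- if (is.matrix(x)) x else matrix(rep(x, 10), ncol = 10)
  colnames(samples) <- m$label[seq_len(ncol(samples))]
  if (is.null(annotations)) {
    annotations <- tibble::tibble(label = character(), onset = numeric(),
                                  duration = numeric())
  }
  eeg_recording(samples, rate, annotations, subject_id = "fixture")
}

rms <- function(x) sqrt(mean(x^2))

# single-segment tibble covering [0, dur)
whole_segment <- function(dur) {
  tibble::tibble(condition = "EC", start = 0, end = dur)
}

# hand-built spectrum object on the package's default grid
make_spectrum <- function(power_db, freqs, channels, condition = "EC") {
  structure(list(freqs = freqs, power_db = power_db, psd = NULL,
                 n_windows = 1L, channels = channels,
                 condition = condition),
            class = "eeg_spectrum")
}

default_grid <- function() seq(0, 250, by = 0.25)

# one ground-truth subject row with controllable fields
one_truth <- function(freq = 10, power = 10, reactivity = 4, seed = 99,
                      bad = character(0), id = "S1", age = 120) {
  tibble::tibble(id = id, group = factor("TD", levels = c("TD", "ASD")),
                 age = age, sex = "M", true_alpha_freq = freq,
                 true_alpha_power_ec = power, reactivity = reactivity,
                 bad_channels = list(bad), rating_a = 1L, rating_b = 1L,
                 seed = seed)
}
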