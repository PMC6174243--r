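# Synthetic cohort generator with known ground truth: age trajectories of
# the alpha peak, per-subject truths, multichannel EEG recordings with
# EC/EO structure, and brain-volume tables.

#' Age-trajectory and dispersion parameters for the synthetic cohort
#'
#' The developmental trajectory of the posterior alpha peak is modelled
#' as a saturating-exponential rise of peak frequency with age and a
#' piecewise-linear decline of eyes-closed peak power that plateaus at
#' `plateau_age`. Typically developing subjects scatter around the
#' trajectory with the stated SDs; the autistic group uses the same
#' trajectory but SDs inflated by `heterogeneity_ratio`.
#'
#' All values are configurable stand-ins: they are chosen to look like
#' plausible school-age resting EEG, not estimated from any dataset.
#'
#' @param freq_asymptote Adult alpha frequency asymptote (Hz).
#' @param freq_gain Total frequency rise from birth to asymptote (Hz).
#' @param freq_timescale Exponential time constant of the rise (months).
#' @param power_baseline Peak power over background at age 0 (dB).
#' @param power_slope Power change per month up to the plateau (dB/month,
#'   must be <= 0).
#' @param plateau_age Age at which power stops declining (months).
#' @param td_freq_sd Between-subject SD of peak frequency in the TD
#'   group (Hz, > 0).
#' @param td_power_sd Between-subject SD of peak power in the TD group
#'   (dB, > 0).
#' @param heterogeneity_ratio Multiplier (>= 1) applied to both SDs in
#'   the ASD group.
#'
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(freq_asymptote = 10.5,
                              freq_gain = 3.5,
                              freq_timescale = 40,
                              power_baseline = 14,
                              power_slope = -0.05,
                              plateau_age = 120,
                              td_freq_sd = 0.7,
                              td_power_sd = 1.5,
                              heterogeneity_ratio = 1) {
  if (td_freq_sd <= 0 || td_power_sd <= 0) {
    abort("trajectory SDs must be positive")
  }
  if (heterogeneity_ratio < 1) abort("`heterogeneity_ratio` must be >= 1")
  if (power_slope > 0) abort("`power_slope` must be <= 0")
  if (freq_gain < 0 || freq_timescale <= 0 || plateau_age <= 0) {
    abort("frequency trajectory parameters must be positive")
  }
  structure(
    list(freq_asymptote = freq_asymptote, freq_gain = freq_gain,
         freq_timescale = freq_timescale, power_baseline = power_baseline,
         power_slope = power_slope, plateau_age = plateau_age,
         td_freq_sd = td_freq_sd, td_power_sd = td_power_sd,
         heterogeneity_ratio = heterogeneity_ratio),
    class = "trajectory_params")
}

#' Evaluate the generating age trajectory
#'
#' @param params A [trajectory_params()] object.
#' @param age Ages in months.
#'
#' @return Tibble with `age`, `freq` (Hz) and `power` (dB over
#'   background): the noise-free trajectory.
#' @export
alpha_trajectory <- function(params, age) {
  tibble(
    age = age,
    freq = params$freq_asymptote -
      params$freq_gain * exp(-age / params$freq_timescale),
    power = params$power_baseline +
      params$power_slope * pmin(age, params$plateau_age))
}

#' Simulate ground-truth subjects for a case-control cohort
#'
#' Draws ages uniformly over `age_range`, places each subject's true
#' alpha peak frequency and eyes-closed peak power on the age trajectory
#' plus Gaussian scatter (inflated by `heterogeneity_ratio` in the ASD
#' group), and attaches per-subject nuisance truth: EC-EO reactivity,
#' occasional bad channels, QC ratings from two simulated raters, and a
#' private seed for recording synthesis. Identical seeds give identical
#' cohorts.
#'
#' @param n_td,n_asd Group sizes (>= 0).
#' @param age_range Age range in months, `c(low, high)` with low < high.
#' @param params A [trajectory_params()].
#' @param seed Integer seed controlling the whole draw.
#' @param p_male Proportion of males (default 0.75).
#' @param p_bad_channel Probability that a subject has one bad channel
#'   (default 0.1).
#' @param reactivity_mean,reactivity_sd EC-EO alpha attenuation
#'   distribution (dB, truncated below at 1).
#' @param p_unusable Probability a rater scores a spectrum 4 (unusable).
#'
#' @return Tibble, one row per subject: `id`, `group`, `age`, `sex`,
#'   `true_alpha_freq`, `true_alpha_power_ec`, `reactivity`,
#'   `bad_channels` (list-column), `rating_a`, `rating_b`, `seed`.
#' @export
simulate_subject_truth <- function(n_td, n_asd, age_range = c(60, 192),
                                   params = trajectory_params(),
                                   seed = 1,
                                   p_male = 0.75,
                                   p_bad_channel = 0.1,
                                   reactivity_mean = 4,
                                   reactivity_sd = 1,
                                   p_unusable = 0.05) {
  if (n_td < 0 || n_asd < 0) abort("group sizes must be >= 0")
  if (age_range[1] >= age_range[2]) abort("`age_range` must satisfy low < high")
  n <- n_td + n_asd
  set.seed(seed)
  group <- c(rep("TD", n_td), rep("ASD", n_asd))
  mult <- ifelse(group == "ASD", params$heterogeneity_ratio, 1)
  age <- runif(n, age_range[1], age_range[2])
  traj <- alpha_trajectory(params, age)
  freq <- traj$freq + rnorm(n, 0, params$td_freq_sd) * mult
  power <- traj$power + rnorm(n, 0, params$td_power_sd) * mult
  labels <- standard_montage()$label
  bad <- lapply(seq_len(n), function(i) {
    if (runif(1) < p_bad_channel) sample(labels, 1) else character(0)
  })
  # two raters agree most of the time; unusable recordings are rare
  base_rating <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  base_rating[runif(n) < p_unusable] <- 4L
  jitter_b <- sample(c(-1L, 0L, 0L, 0L, 1L), n, replace = TRUE)
  rating_b <- pmin(pmax(base_rating + jitter_b, 1L), 4L)

  tibble(
    id = sprintf("%s%03d", group, c(seq_len(n_td), seq_len(n_asd))),
    group = factor(group, levels = c("TD", "ASD")),
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(p_male, 1 - p_male)),
    true_alpha_freq = pmin(pmax(freq, 6), 14),
    true_alpha_power_ec = pmax(power, 0.5),
    reactivity = pmax(rnorm(n, reactivity_mean, reactivity_sd), 1),
    bad_channels = bad,
    rating_a = as.integer(base_rating),
    rating_b = as.integer(rating_b),
    seed = sample.int(.Machine$integer.max %/% 2L, n))
}

#' Default desk-scale recording protocol
#'
#' A shortened version of the clinical resting protocol: a 60-s
#' eyes-closed block followed by three alternating 10-s eyes-open /
#' eyes-closed pairs. The full clinical durations (10-min EC plus a 1-min
#' alternation block) are available by changing the arguments.
#'
#' @param ec_block Length of the initial EC block in seconds.
#' @param alt_pair Length of each EO and EC interval in the alternation
#'   block (seconds).
#' @param n_alt Number of EO/EC pairs.
#'
#' @return Tibble with `label`, `onset`, `duration` (seconds).
#' @export
default_protocol <- function(ec_block = 60, alt_pair = 10, n_alt = 3) {
  label <- c("EC", rep(c("EO", "EC"), n_alt))
  duration <- c(ec_block, rep(alt_pair, 2 * n_alt))
  tibble(label = label,
         onset = cumsum(c(0, duration[-length(duration)])),
         duration = duration)
}

noise_params <- function(background_rms = 10, slope = 1.3,
                         line_amp = 5, bad_channel_rms_mult = 10) {
  list(background_rms = background_rms, slope = slope,
       line_amp = line_amp, bad_channel_rms_mult = bad_channel_rms_mult)
}

# 1/f^slope-shaped Gaussian background, scaled to a target RMS
pink_noise <- function(n, fs, slope, rms) {
  x <- rnorm(n)
  X <- fft(x)
  k <- 0:(n - 1)
  k <- pmin(k, n - k)                         # fold negative frequencies
  k[k == 0] <- 1                              # guard DC
  X <- X * (k * fs / n)^(-slope / 2)
  y <- Re(fft(X, inverse = TRUE)) / n
  if (rms == 0) return(numeric(n))
  y * rms / sd(y)
}

# Welch PSD of a vector at one frequency (1-s Hann windows, 50% overlap)
psd_at <- function(x, fs, f0, half_bw = 1) {
  n <- fs
  starts <- seq(1, length(x) - n + 1, by = n / 2)
  w <- hann_window(n)
  scale <- 1 / (fs * sum(w^2))
  freqs <- (0:(n / 2)) * fs / n
  sel <- which(freqs >= f0 - half_bw & freqs <= f0 + half_bw)
  p <- sapply(starts, function(s) {
    X <- fft(x[s:(s + n - 1)] * w)
    2 * Mod(X[sel])^2 * scale
  })
  mean(p)
}

#' Synthesize a multichannel EEG recording for one subject
#'
#' Builds the subject's signal as 1/f-shaped Gaussian background plus
#' powerline interference (line frequency and one harmonic) plus a
#' posterior-dominant alpha oscillation at the subject's true frequency.
#' The alpha amplitude is calibrated against the realized background so
#' that the eyes-closed spectral peak at O1 sits `true_alpha_power_ec`
#' dB above the background, and is attenuated by `reactivity` dB during
#' eyes-open intervals. Bad channels are replaced by high-variance white
#' noise. Annotations mark the EC/EO protocol.
#'
#' @param truth One subject: a one-row tibble (or list) as produced by
#'   [simulate_subject_truth()].
#' @param protocol Annotation plan from [default_protocol()]; must
#'   contain at least one EC and one EO interval.
#' @param noise Background/noise parameters from `noise_params()`.
#' @param line_freq Powerline frequency in Hz (0 disables it).
#' @param rate Sampling rate in Hz (default 500).
#' @param alpha_gains Named spatial gain vector of the alpha source over
#'   the montage (posterior-dominant by default).
#' @param am Depths of the two slow amplitude-modulation components of
#'   the alpha oscillation (waxing/waning); `c(0, 0)` gives a constant
#'   envelope.
#'
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(truth,
                               protocol = default_protocol(),
                               noise = noise_params(),
                               line_freq = 50,
                               rate = 500,
                               am = c(0.25, 0.15),
                               alpha_gains = c(FP1 = 0.15, FP2 = 0.15,
                                               F7 = 0.15, F8 = 0.15,
                                               T5 = 0.6, T6 = 0.6,
                                               O1 = 1, O2 = 1,
                                               C3 = 0.4, C4 = 0.4)) {
  if (is.data.frame(truth)) truth <- as.list(truth[1, ])
  if (is.list(truth$bad_channels)) truth$bad_channels <- truth$bad_channels[[1]]
  if (!any(toupper(protocol$label) == "EC") ||
      !any(toupper(protocol$label) == "EO")) {
    abort("protocol must contain both EC and EO time")
  }
  set.seed(truth$seed)
  montage <- standard_montage(names(alpha_gains))
  total_s <- sum(protocol$duration)
  nsamp <- round(total_s * rate)
  t <- (0:(nsamp - 1)) / rate

  # eyes-open mask from the protocol
  eo_mask <- rep(FALSE, nsamp)
  for (i in which(toupper(protocol$label) == "EO")) {
    i0 <- round(protocol$onset[i] * rate) + 1
    i1 <- round((protocol$onset[i] + protocol$duration[i]) * rate)
    eo_mask[i0:i1] <- TRUE
  }

  nch <- nrow(montage)
  bg <- vapply(seq_len(nch), function(i) {
    pink_noise(nsamp, rate, noise$slope, noise$background_rms)
  }, numeric(nsamp))
  colnames(bg) <- montage$label

  # calibrate the alpha amplitude against the realized O1 background:
  # a sinusoid of amplitude A has Hann-window peak PSD A^2 (sum w)^2 /
  # (2 fs sum w^2); choose A so peak/background = 10^(p/10) - 1
  f0 <- truth$true_alpha_freq
  pbg <- psd_at(bg[, "O1"], rate, f0)
  w <- hann_window(rate)
  sine_peak_psd_unit <- sum(w)^2 / (2 * rate * sum(w^2))
  ratio <- 10^(truth$true_alpha_power_ec / 10) - 1
  A_ec <- if (pbg > 0) {
    sqrt(ratio * pbg / sine_peak_psd_unit)
  } else {
    10                      # noise-free degenerate case: fixed amplitude
  }
  A_eo <- A_ec * 10^(-truth$reactivity / 20)

  # slowly amplitude-modulated alpha oscillation (waxing/waning)
  env <- 1 + am[1] * sin(2 * pi * 0.11 * t + runif(1, 0, 2 * pi)) +
    am[2] * sin(2 * pi * 0.043 * t + runif(1, 0, 2 * pi))
  osc <- env * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
  amp <- ifelse(eo_mask, A_eo, A_ec)
  alpha <- osc * amp

  line <- 0
  if (line_freq > 0) {
    line <- noise$line_amp * sin(2 * pi * line_freq * t + runif(1, 0, 2 * pi))
    if (2 * line_freq < rate / 2) {
      line <- line + noise$line_amp / 3 *
        sin(2 * pi * 2 * line_freq * t + runif(1, 0, 2 * pi))
    }
  }

  samples <- bg + outer(alpha, unname(alpha_gains[montage$label])) + line
  for (b in truth$bad_channels) {
    samples[, b] <- rnorm(nsamp, 0,
                          noise$bad_channel_rms_mult * noise$background_rms)
  }
  eeg_recording(samples, rate, annotations = protocol,
                montage = montage, subject_id = truth$id)
}

#' Canonical brain-structure labels of the volume table
#'
#' @return Character vector of snake_case structure column names.
#' @export
volume_structures <- function() {
  bilateral <- c("thalamus", "caudate", "putamen", "pallidum",
                 "hippocampus", "amygdala", "accumbens")
  lobar <- as.vector(outer(
    c("frontal", "parietal", "occipital", "temporal", "subcortical"),
    c("gray", "white"), paste, sep = "_"))
  c("intracranial_volume", "total_brain_volume",
    as.vector(outer(c("left", "right"), c(bilateral, lobar),
                    paste, sep = "_")))
}

.volume_means <- function() {
  base <- c(intracranial_volume = 1.4e6, total_brain_volume = 1.15e6,
            thalamus = 7000, caudate = 3800, putamen = 5100,
            pallidum = 1600, hippocampus = 3600, amygdala = 1500,
            accumbens = 550,
            frontal_gray = 95000, parietal_gray = 60000,
            occipital_gray = 42000, temporal_gray = 72000,
            subcortical_gray = 32000,
            frontal_white = 85000, parietal_white = 55000,
            occipital_white = 38000, temporal_white = 62000,
            subcortical_white = 90000)
  out <- numeric(0)
  for (s in volume_structures()) {
    key <- sub("^(left|right)_", "", s)
    out[s] <- base[[key]]
  }
  out
}

#' Simulate a per-subject brain-volume table
#'
#' Generates plausible-magnitude volumes (mm^3) for the canonical
#' structure set. If `coupled_structure` is given, that column is
#' generated so the subjects' true alpha frequency is an exact linear
#' function of it plus optional Gaussian noise, giving a known ground
#' truth for regression tests; all other columns are independent of the
#' alpha truth.
#'
#' @param subjects Tibble from [simulate_subject_truth()] (non-empty).
#' @param coupled_structure Optional structure label from
#'   [volume_structures()].
#' @param slope Coupling slope in Hz per mm^3 (ignored unless coupled).
#' @param noise_sd SD of the Hz-scale noise in the coupling (default 0).
#' @param rel_sd Relative between-subject SD of every volume
#'   (default 0.08).
#' @param seed Integer seed.
#'
#' @return Tibble with `id` plus one column per structure, all positive.
#' @export
simulate_volume_table <- function(subjects, coupled_structure = NULL,
                                  slope = 1e-3, noise_sd = 0,
                                  rel_sd = 0.08, seed = 1) {
  if (nrow(subjects) == 0) abort("`subjects` must be non-empty")
  structures <- volume_structures()
  if (!is.null(coupled_structure) &&
      !coupled_structure %in% structures) {
    abort(paste0("unknown structure label: ", coupled_structure))
  }
  set.seed(seed)
  n <- nrow(subjects)
  means <- .volume_means()
  vols <- sapply(structures, function(s) {
    abs(rnorm(n, means[[s]], rel_sd * means[[s]]))
  })
  if (!is.null(coupled_structure)) {
    if (slope == 0) abort("`slope` must be non-zero for a coupled structure")
    f <- subjects$true_alpha_freq
    mu <- means[[coupled_structure]]
    sf2 <- var(f)
    se2 <- noise_sd^2
    if (se2 >= sf2) {
      abort("`noise_sd` must be smaller than the SD of true_alpha_freq")
    }
    # draw the volume jointly normal with the frequency so that the
    # population regression of frequency on volume has exactly the
    # requested slope and residual SD (plain OLS is then consistent)
    cc <- (sf2 - se2) / (slope * sf2)
    s_eta <- sqrt((sf2 - se2) * se2 / (slope^2 * sf2))
    vols[, coupled_structure] <- mu + cc * (f - mean(f)) +
      rnorm(n, 0, s_eta)
  }
  out <- as_tibble(vols)
  out$id <- subjects$id
  dplyr::relocate(out, "id")
}
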