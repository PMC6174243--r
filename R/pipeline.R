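# End-to-end orchestration: synthetic cohort export, per-subject
# processing, normative scoring, cohort statistics, and reporting.

#' Write a synthetic cohort to disk
#'
#' Renders every subject of a ground-truth cohort as an EDF+ recording
#' and writes the cohort table (and optionally a brain-volume table) as
#' CSV, producing exactly the input layout [run_pipeline()] consumes.
#'
#' @param truth Cohort tibble from [simulate_subject_truth()].
#' @param dir Output directory (created if needed).
#' @param protocol,noise,line_freq Passed to [simulate_recording()].
#' @param volumes Optional volume table from [simulate_volume_table()].
#'
#' @return Invisibly, a list with `edf_dir`, `cohort_csv`, `volume_csv`.
#' @export
write_synthetic_cohort <- function(truth, dir,
                                   protocol = default_protocol(),
                                   noise = noise_params(),
                                   line_freq = 50,
                                   volumes = NULL) {
  edf_dir <- file.path(dir, "edf")
  dir.create(edf_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(truth))) {
    rec <- simulate_recording(truth[i, ], protocol = protocol,
                              noise = noise, line_freq = line_freq)
    write_edfplus(rec, file.path(edf_dir, paste0(truth$id[i], ".edf")))
  }
  cohort_csv <- file.path(dir, "cohort.csv")
  cohort <- tibble(id = truth$id, group = as.character(truth$group),
                   age_months = truth$age, sex = truth$sex,
                   rating_a = truth$rating_a, rating_b = truth$rating_b)
  write.csv(cohort, cohort_csv, row.names = FALSE)
  volume_csv <- NULL
  if (!is.null(volumes)) {
    volume_csv <- file.path(dir, "volumes.csv")
    write.csv(volumes, volume_csv, row.names = FALSE)
  }
  invisible(list(edf_dir = edf_dir, cohort_csv = cohort_csv,
                 volume_csv = volume_csv))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#'
#' @param edf_dir Directory of per-subject EDF+ files named `<id>.edf`.
#' @param cohort_csv Cohort CSV with columns id, group, age_months, sex,
#'   rating_a, rating_b.
#' @param out_dir Output directory for result files.
#' @param volume_csv Optional brain-volume CSV (id + structure columns).
#' @param line_freq Mains frequency for the comb filter (Hz).
#' @param band Alpha search band in Hz.
#' @param candidates Posterior candidate channels for peak detection.
#' @param bad_threshold Bad-channel threshold in standard errors.
#' @param min_prominence Minimum peak prominence (dB).
#' @param bandwidth Normative kernel half-width (months).
#' @param outlier_z Normative outlier threshold on |z|.
#' @param label_map Annotation label map for [segment_conditions()].
#' @param reference,case Group labels (reference trains the model).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edf_dir, cohort_csv, out_dir,
                            volume_csv = NULL,
                            line_freq = 50,
                            band = c(8, 12),
                            candidates = c("O1", "O2", "T5", "T6"),
                            bad_threshold = 3,
                            min_prominence = 0.5,
                            bandwidth = 24,
                            outlier_z = 1.96,
                            label_map = list(ec = c("EC", "eyes closed"),
                                             eo = c("EO", "eyes open")),
                            reference = "TD", case = "ASD") {
  structure(
    list(edf_dir = edf_dir, cohort_csv = cohort_csv, out_dir = out_dir,
         volume_csv = volume_csv, line_freq = line_freq, band = band,
         candidates = candidates, bad_threshold = bad_threshold,
         min_prominence = min_prominence, bandwidth = bandwidth,
         outlier_z = outlier_z, label_map = label_map,
         reference = reference, case = case),
    class = "pipeline_config")
}

#' Process one recording to an alpha peak
#'
#' The per-subject chain: band-pass 1-120 Hz, powerline comb filter,
#' bad-channel detection and spherical-spline interpolation, EC/EO
#' segmentation, sliding-window spectra, difference spectrum, peak
#' detection.
#'
#' @param rec An [eeg_recording()].
#' @param config A [pipeline_config()] (paths are ignored here).
#'
#' @return One-row tibble: id, channel, freq_hz, power_db, prominence,
#'   power_ec_db, n_bad_channels, bad_channels, status.
#' @export
process_recording <- function(rec, config = pipeline_config("", "", "")) {
  rec <- eeg_bandpass(rec)
  rec <- eeg_comb_filter(rec, line_freq = config$line_freq)
  bad <- detect_bad_channels(rec, threshold_se = config$bad_threshold)
  rec <- spline_interpolate(rec, bad)
  segs <- segment_conditions(rec, label_map = config$label_map)
  ec <- compute_spectrum(rec, segs[segs$condition == "EC", ], condition = "EC")
  eo <- compute_spectrum(rec, segs[segs$condition == "EO", ], condition = "EO")
  pk <- detect_alpha_peak(difference_spectrum(ec, eo), ec = ec,
                          candidates = config$candidates,
                          band = config$band,
                          min_prominence = config$min_prominence)
  tibble(id = rec$subject_id, channel = pk$channel, freq_hz = pk$frequency,
         power_db = pk$power, prominence = pk$prominence,
         power_ec_db = pk$power_ec, n_bad_channels = length(bad),
         bad_channels = paste(bad, collapse = ";"), status = "ok")
}

failed_peak_row <- function(id, status) {
  tibble(id = id, channel = NA_character_, freq_hz = NA_real_,
         power_db = NA_real_, prominence = NA_real_,
         power_ec_db = NA_real_, n_bad_channels = NA_integer_,
         bad_channels = NA_character_, status = status)
}

# stable 31-bit polynomial hash of the config, for the run manifest
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full alpha-biomarker pipeline
#'
#' Executes the whole analysis for a cohort: per-subject preprocessing
#' and alpha-peak extraction, quality-control gating with inter-rater
#' agreement, age-normative modeling of peak frequency and power on the
#' reference group, deviation scores and heterogeneity statistics, raw
#' case-control summaries, age/status ANOVA, and (when a volume table is
#' given) alpha-vs-brain-volume regressions. Per-subject failures are
#' recorded in the peaks table, never silently dropped. Results are
#' written as CSV plus a JSON manifest and a plain-text summary; reruns
#' with the same inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with tibbles `peaks`, `kept`, `excluded`,
#'   `scores`, `tests`, `volume_tests`, the fitted `models`, the
#'   agreement statistic `agreement_b` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$edf_dir)) abort("EDF directory does not exist")
  if (!file.exists(config$cohort_csv)) abort("cohort CSV does not exist")
  cohort <- as_tibble(read.csv(config$cohort_csv,
                               stringsAsFactors = FALSE))
  if (nrow(cohort) == 0) abort("cohort table is empty")
  edfs <- file.path(config$edf_dir, paste0(cohort$id, ".edf"))
  if (!any(file.exists(edfs))) abort("no EDF+ file matches the cohort ids")

  peaks <- bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    if (!file.exists(edfs[i])) {
      return(failed_peak_row(cohort$id[i], "missing_edf"))
    }
    tryCatch({
      rec <- read_edfplus(edfs[i], subject_id = cohort$id[i])
      process_recording(rec, config)
    },
    alphanorm_no_peak = function(e) failed_peak_row(cohort$id[i], "no_peak"),
    error = function(e) {
      failed_peak_row(cohort$id[i],
                      paste0("error: ", conditionMessage(e)))
    })
  }))

  records <- left_join(cohort, peaks, by = "id")
  qc <- qc_exclude(records)
  b_stat <- bangdiwala_b(rating_table(records))

  kept <- qc$kept
  ok <- kept[kept$status == "ok" & is.finite(kept$freq_hz), ]
  metrics <- c(frequency = "freq_hz", power = "power_db")
  models <- list()
  scores <- list()
  tests <- list()
  for (m in names(metrics)) {
    col <- metrics[[m]]
    train <- ok[as.character(ok$group) == config$reference, ]
    if (nrow(train) < 5) {
      tests[[paste0(m, "_skipped")]] <- tibble(
        name = paste0("normative_", m), statistic = NA_real_,
        p.value = NA_real_, note = "too few reference subjects")
      next
    }
    mod <- fit_normative(train, age_months, !!rlang::sym(col), metric = m,
                         bandwidth = config$bandwidth)
    models[[m]] <- mod
    sc <- score_normative(mod, ok, age_months, !!rlang::sym(col),
                          outlier_z = config$outlier_z)
    # reference subjects trained the model: use their cross-validated
    # (leave-one-out) deviation scores so both groups are out-of-sample
    ref_rows <- which(as.character(ok$group) == config$reference)
    sc$z[ref_rows] <- mod$train_z_loo
    sc$is_outlier <- !is.na(sc$z) & abs(sc$z) > config$outlier_z
    sc$metric <- m
    scores[[m]] <- sc %>%
      select(all_of(c("id", "group", "age_months", "metric", col,
                      "z", "is_outlier", "supported"))) %>%
      rename(value = all_of(col))
    g <- as.character(sc$group)
    vt <- variance_ratio_test(sc$z[g == config$case],
                              sc$z[g == config$reference],
                              name = paste0("variance_z_", m))
    ot <- outlier_proportion_test(
      sum(sc$is_outlier[g == config$case]),
      sum(g == config$case & sc$supported),
      sum(sc$is_outlier[g == config$reference]),
      sum(g == config$reference & sc$supported),
      name = paste0("outlier_fisher_", m))
    gs <- group_summary(ok, !!rlang::sym(col),
                        case = config$case, reference = config$reference)
    an <- anova_age_status(ok, !!rlang::sym(col), age = age_months,
                           case = config$case)
    tests[[m]] <- bind_rows(
      select(vt, all_of(c("name", "statistic", "p.value"))),
      select(ot, all_of(c("name", "statistic", "p.value"))),
      tibble(name = paste0("welch_t_raw_", m), statistic = gs$t_statistic,
             p.value = gs$t_p),
      tibble(name = paste0("variance_raw_", m), statistic = gs$f_statistic,
             p.value = gs$f_p),
      tibble(name = paste0("anova_", m, "_", an$term),
             statistic = an$statistic, p.value = an$p.value))
  }
  scores <- bind_rows(scores)
  tests <- bind_rows(tests)
  tests <- bind_rows(tests,
                     tibble(name = "bangdiwala_b", statistic = b_stat,
                            p.value = NA_real_))

  volume_tests <- NULL
  if (!is.null(config$volume_csv) && file.exists(config$volume_csv)) {
    volumes <- as_tibble(read.csv(config$volume_csv,
                                  stringsAsFactors = FALSE))
    volume_tests <- bind_rows(
      mutate(volume_regressions(ok, volumes, freq_hz), metric = "frequency"),
      mutate(volume_regressions(ok, volumes, power_db), metric = "power"))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    peaks = file.path(config$out_dir, "peaks.csv"),
    scores = file.path(config$out_dir, "scores.csv"),
    tests = file.path(config$out_dir, "tests.csv"),
    volume_tests = file.path(config$out_dir, "volume_tests.csv"),
    manifest = file.path(config$out_dir, "manifest.json"),
    summary = file.path(config$out_dir, "summary.txt"))
  write.csv(records, paths$peaks, row.names = FALSE)
  write.csv(scores, paths$scores, row.names = FALSE)
  write.csv(tests, paths$tests, row.names = FALSE)
  if (!is.null(volume_tests)) {
    write.csv(volume_tests, paths$volume_tests, row.names = FALSE)
  } else {
    paths$volume_tests <- NULL
  }

  manifest <- list(
    package = "alphanorm",
    package_version = as.character(utils::packageVersion("alphanorm")),
    config_hash = config_hash(config),
    config = unclass(config),
    n_subjects = nrow(cohort),
    n_kept = nrow(kept),
    n_excluded = nrow(qc$excluded),
    n_peaks_ok = sum(peaks$status == "ok"),
    failures = as.list(table(peaks$status[peaks$status != "ok"])))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  lines <- c(
    "alphanorm pipeline summary",
    sprintf("subjects: %d (kept %d, excluded %d)",
            nrow(cohort), nrow(kept), nrow(qc$excluded)),
    sprintf("alpha peaks detected: %d", sum(peaks$status == "ok")),
    sprintf("inter-rater agreement B = %.3f", b_stat),
    "",
    utils::capture.output(print(as.data.frame(tests), row.names = FALSE)))
  writeLines(lines, paths$summary)

  invisible(list(peaks = records, kept = kept, excluded = qc$excluded,
                 scores = scores, tests = tests,
                 volume_tests = volume_tests, models = models,
                 agreement_b = b_stat, paths = paths))
}
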