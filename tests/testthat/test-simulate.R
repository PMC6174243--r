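test_that("trajectory is monotone: frequency rises, power falls then plateaus", {
  p <- trajectory_params()
  ages <- seq(0, 240, by = 1)
  tr <- alpha_trajectory(p, ages)
  expect_true(all(diff(tr$freq) >= 0))
  pre <- tr$power[ages <= p$plateau_age]
  post <- tr$power[ages >= p$plateau_age]
  expect_true(all(diff(pre) <= 0))
  expect_true(all(abs(diff(post)) < 1e-12))

  expect_error(trajectory_params(td_freq_sd = 0), "positive")
  expect_error(trajectory_params(heterogeneity_ratio = 0.8), ">= 1")
  expect_error(trajectory_params(power_slope = 0.1), "<= 0")
})

test_that("cohort generation is deterministic and respects group sizes", {
  a <- simulate_subject_truth(10, 8, seed = 42)
  b <- simulate_subject_truth(10, 8, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$group == "TD"), 10)
  expect_equal(sum(a$group == "ASD"), 8)
  expect_true(all(a$true_alpha_freq >= 6 & a$true_alpha_freq <= 14))
  expect_true(all(a$reactivity > 0))
  expect_true(all(a$rating_a %in% 1:4 & a$rating_b %in% 1:4))

  c <- simulate_subject_truth(10, 8, seed = 43)
  expect_false(identical(a$true_alpha_freq, c$true_alpha_freq))

  expect_error(simulate_subject_truth(-1, 5), ">= 0")
  expect_error(simulate_subject_truth(5, 5, age_range = c(100, 100)),
               "low < high")
})

test_that("heterogeneity ratio scales the ASD dispersion around the trajectory", {
  resid_sd <- function(tr, params) {
    traj <- alpha_trajectory(params, tr$age)
    tapply(tr$true_alpha_freq - traj$freq, tr$group, sd)
  }
  p1 <- trajectory_params(heterogeneity_ratio = 1)
  t1 <- simulate_subject_truth(2000, 2000, params = p1, seed = 7)
  s1 <- resid_sd(t1, p1)
  expect_lt(abs(s1[["ASD"]] / s1[["TD"]] - 1), 0.08)

  p15 <- trajectory_params(heterogeneity_ratio = 1.5)
  t15 <- simulate_subject_truth(2000, 2000, params = p15, seed = 7)
  s15 <- resid_sd(t15, p15)
  expect_lt(abs(s15[["ASD"]] / s15[["TD"]] - 1.5), 0.05)
})

test_that("noise-free recording is a pure sinusoid at the true frequency", {
  tr <- one_truth(freq = 10, seed = 5)
  rec <- simulate_recording(tr, noise = noise_params(background_rms = 0,
                                                     line_amp = 0),
                            line_freq = 0, am = c(0, 0))
  seg <- rec$samples[1:(20 * 500), "O1"]           # inside the EC block
  t <- (0:(length(seg) - 1)) / 500
  fit <- lm(seg ~ sin(2 * pi * 10 * t) + cos(2 * pi * 10 * t))
  expect_gt(summary(fit)$r.squared, 1 - 1e-9)
  expect_gt(sd(seg), 0)
})

test_that("full chain recovers the injected frequency", {
  errs <- vapply(c(21, 22, 23, 24, 25), function(seed) {
    tr <- one_truth(freq = 10, power = 10, seed = seed)
    pk <- process_recording(simulate_recording(tr))
    expect_equal(pk$status, "ok")
    abs(pk$freq_hz - 10)
  }, numeric(1))
  expect_lt(median(errs), 0.25)
})

test_that("eyes-open alpha is attenuated by the reactivity in dB", {
  tr <- one_truth(freq = 10, power = 12, reactivity = 4, seed = 31)
  rec <- simulate_recording(tr)
  segs <- segment_conditions(rec)
  ec <- compute_spectrum(rec, segs[segs$condition == "EC", ])
  eo <- compute_spectrum(rec, segs[segs$condition == "EO", ])
  band <- ec$freqs >= 9.5 & ec$freqs <= 10.5
  o1 <- match("O1", ec$channels)
  drop_db <- 10 * log10(sum(ec$psd[o1, band]) / sum(eo$psd[o1, band]))
  expect_lt(abs(drop_db - tr$reactivity), 1)
})

test_that("bad channels are rendered as high-variance noise", {
  tr <- one_truth(seed = 8, bad = "C3")
  rec <- simulate_recording(tr)
  v <- apply(rec$samples, 2, var)
  expect_gt(v[["C3"]] / median(v), 20)
})

test_that("recording protocol is annotated and posterior-dominant", {
  tr <- one_truth(seed = 13)
  rec <- simulate_recording(tr)
  expect_equal(nrow(rec$samples), 120 * 500)
  expect_equal(sum(rec$annotations$duration), 120)
  expect_true(all(c("EC", "EO") %in% rec$annotations$label))

  segs <- segment_conditions(rec)
  ec <- compute_spectrum(rec, segs[segs$condition == "EC", ])
  band <- ec$freqs >= 9 & ec$freqs <= 11
  alpha_power <- rowSums(ec$psd[, band])
  names(alpha_power) <- ec$channels
  expect_gt(min(alpha_power[c("O1", "O2")]), max(alpha_power[c("FP1", "FP2")]))

  expect_error(
    simulate_recording(tr, protocol = tibble::tibble(
      label = "EC", onset = 0, duration = 60)),
    "EC and EO")
})

test_that("background spectrum is log-log linear once alpha is excluded", {
  tr <- one_truth(seed = 17)
  rec <- simulate_recording(tr, noise = noise_params(line_amp = 0),
                            line_freq = 0, am = c(0, 0),
                            alpha_gains = c(FP1 = 0, FP2 = 0, F7 = 0,
                                            F8 = 0, T5 = 0, T6 = 0,
                                            O1 = 0, O2 = 0, C3 = 0,
                                            C4 = 0))
  sp <- compute_spectrum(rec, whole_segment(120))
  sel <- sp$freqs >= 2 & sp$freqs <= 40
  fit <- lm(log10(colMeans(sp$psd)[sel]) ~ log10(sp$freqs[sel]))
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_lt(abs(coef(fit)[2] + 1.3), 0.15)
})

test_that("volume tables couple a chosen structure and nothing else", {
  tr <- simulate_subject_truth(50, 50, seed = 3)
  expect_error(simulate_volume_table(tr, coupled_structure = "left_spleen"),
               "unknown structure")
  expect_error(simulate_volume_table(tr[0, ]), "non-empty")

  v0 <- simulate_volume_table(tr, seed = 4)
  expect_true(all(as.matrix(v0[, -1]) > 0))
  expect_setequal(setdiff(names(v0), "id"), volume_structures())

  # uncoupled: no structure explains the alpha frequency
  r0 <- volume_regressions(cbind(tr, freq = tr$true_alpha_freq), v0, freq)
  expect_true(all(r0$q.value[r0$status == "ok"] > 0.05))

  # noiseless coupling: exact linear relation
  v1 <- simulate_volume_table(tr, coupled_structure = "left_putamen",
                              slope = 1e-3, noise_sd = 0, seed = 4)
  r1 <- volume_regressions(cbind(tr, freq = tr$true_alpha_freq), v1, freq)
  expect_equal(r1$r.squared[r1$structure == "left_putamen"], 1,
               tolerance = 1e-9)

  # noisy coupling at n = 500: slope recovered within 2 SE
  tr5 <- simulate_subject_truth(250, 250, seed = 5)
  v2 <- simulate_volume_table(tr5, coupled_structure = "left_putamen",
                              slope = 1e-3, noise_sd = 0.4, seed = 6)
  fit <- lm(tr5$true_alpha_freq ~ v2$left_putamen)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est[["Estimate"]] - 1e-3), 2 * est[["Std. Error"]])
})
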