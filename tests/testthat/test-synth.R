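# Rhythm simulator: label rules, RR statistics, pulse and trace rendering.

test_that("rhythm labels enforce the group/subtype rules", {
  expect_identical(rhythm_label("AF")$group, "AF")
  expect_identical(rhythm_label("OTHER", "APC")$subtype, "APC")
  expect_error(rhythm_label("OTHER"), "subtype")
  expect_error(rhythm_label("NSR", "APC"), "only valid")
  expect_error(rhythm_label("OTHER", "VTACH"))
})

test_that("NSR intervals have the configured mean rate and low variability", {
  stats <- vapply(1:100, function(s) {
    rr <- simulate_rr("NSR", mean_hr = 60, duration = 60, seed = s)
    c(mean(rr$intervals), stats::sd(rr$intervals) / mean(rr$intervals),
      length(rr$intervals))
  }, numeric(3))
  expect_gt(mean(stats[1, ]), 0.97)
  expect_lt(mean(stats[1, ]), 1.03)
  expect_lt(mean(stats[2, ]), 0.06)
  expect_true(all(abs(stats[3, ] - 60) <= 3))
})

test_that("AF intervals are heavy-variability and serially independent", {
  stats <- vapply(1:100, function(s) {
    rr <- simulate_rr("AF", mean_hr = 75, duration = 300, seed = s)
    x <- rr$intervals
    c(stats::sd(x) / mean(x), stats::cor(x[-1], x[-length(x)]), length(x))
  }, numeric(3))
  expect_gt(mean(stats[1, ]), 0.18)
  expect_lt(mean(stats[1, ]), 0.30)
  expect_true(all(stats[3, ] >= 200))
  # serial independence: lag-1 autocorrelation centered on zero with the
  # sampling spread expected of an i.i.d. series (sd ~ 1/sqrt(n_beats))
  expect_lt(abs(mean(stats[2, ])), 0.05)
  expect_lt(mean(abs(stats[2, ])), 0.15)
  expect_gt(mean(abs(stats[2, ]) < 0.15), 0.95)
})

test_that("RR variability orders AF > sinus arrhythmia > NSR by >= 2x", {
  cv_of <- function(lbl) mean(vapply(1:100, function(s) {
    rr <- simulate_rr(lbl, mean_hr = 70, duration = 120, seed = s)
    stats::sd(rr$intervals) / mean(rr$intervals)
  }, numeric(1)))
  cv_af <- cv_of("AF")
  cv_sa <- cv_of("OTHER/SINUS_ARRHYTHMIA")
  cv_nsr <- cv_of("NSR")
  expect_gte(cv_af, 2 * cv_sa)
  expect_gte(cv_sa, 2 * cv_nsr)
})

test_that("NSR tachogram carries the respiratory modulation frequency", {
  rr <- simulate_rr("NSR", mean_hr = 60, duration = 300, seed = 4,
                    resp_freq = 0.25)
  # resample the tachogram onto a uniform grid and locate its peak
  fs_t <- 4
  grid <- seq(0, max(rr$onsets), by = 1 / fs_t)
  tach <- stats::approx(rr$onsets, rr$intervals, xout = grid)$y
  tach <- tach - mean(tach)
  spec <- Mod(stats::fft(tach))^2
  freq <- (seq_along(spec) - 1) * fs_t / length(spec)
  keep <- freq > 0.05 & freq < 0.5
  f_peak <- freq[keep][which.max(spec[keep])]
  expect_lt(abs(f_peak - 0.25), 0.05)
})

test_that("rhythm subtypes produce their defining signatures", {
  # fixed-rate subtypes override the requested rate
  tachy <- simulate_rr("OTHER/SINUS_TACHY", mean_hr = 75, duration = 60,
                       seed = 1)
  brady <- simulate_rr("OTHER/SINUS_BRADY", mean_hr = 75, duration = 60,
                       seed = 1)
  expect_lt(abs(60 / mean(tachy$intervals) - 110), 5)
  expect_lt(abs(60 / mean(brady$intervals) - 50), 5)
  # flutter alternates between 2:1 (0.4 s) and 4:1 (0.8 s) conduction
  fl <- simulate_rr("OTHER/FLUTTER", mean_hr = 75, duration = 300, seed = 2)
  near <- function(x, v) abs(x - v) < 0.05
  expect_true(all(near(fl$intervals, 0.4) | near(fl$intervals, 0.8)))
  expect_true(any(near(fl$intervals, 0.4)) && any(near(fl$intervals, 0.8)))
  # ectopic beats are premature with reduced pulse amplitude
  apc <- simulate_rr("OTHER/APC", mean_hr = 60, duration = 300, seed = 3)
  expect_gt(sum(apc$beat_amp < 1), 0)
  expect_true(all(apc$beat_amp %in% c(0.8, 1)))
})

test_that("RR generation respects duration, bounds and reproducibility", {
  expect_length(simulate_rr("NSR", 60, duration = 0.5, seed = 0)$intervals, 0)
  expect_error(simulate_rr("NSR", 60, duration = -1), "duration")
  expect_error(simulate_rr("NSR", mean_hr = 10, duration = 60), "mean_hr")
  rr <- simulate_rr("AF", 75, 300, seed = 9)
  expect_true(all(rr$intervals >= 0.25 & rr$intervals <= 3))
  expect_lte(sum(rr$intervals), 300)
  rr2 <- simulate_rr("AF", 75, 300, seed = 9)
  expect_identical(rr$intervals, rr2$intervals)
})

test_that("pulse rendering places beats at the configured rate", {
  rr <- simulate_rr("NSR", mean_hr = 60, duration = 10, seed = 1,
                    resp_depth = 0, jitter_cv = 0)
  pw <- render_pulse(rr, fs = 84)
  expect_length(pw$samples, 840)
  expect_lte(max(abs(pw$samples)), 1)
  spec <- Mod(stats::fft(c(pw$samples - mean(pw$samples),
                           numeric(4096 - 840))))^2
  freq <- (seq_along(spec) - 1) * 84 / length(spec)
  keep <- freq >= 0.5 & freq <= 3
  expect_lt(abs(freq[keep][which.max(spec[keep])] - 1.0), 0.05)
})

test_that("an empty RR series renders a zero wave of the right length", {
  rr <- simulate_rr("NSR", 60, duration = 0.5, seed = 0)
  rr$target_duration <- 5
  pw <- render_pulse(rr, fs = 84)
  expect_length(pw$samples, 420)
  expect_true(all(pw$samples == 0))
})

test_that("RGB rendering follows the skin-reflection observation model", {
  rr <- simulate_rr("NSR", 60, duration = 10, seed = 1)
  pw <- render_pulse(rr, 84)
  quiet <- list(illum_drift_amp = 0, white_noise_sd = 0, artifact_rate = 0)
  # no pulse, no noise: constant channels at baseline
  flat <- pw; flat$samples <- numeric(length(pw$samples))
  tr0 <- render_rgb_trace(flat, baseline = c(150, 110, 90),
                          noise_params = quiet, seed = 1)
  expect_true(all(tr0$r == 150) && all(tr0$g == 110) && all(tr0$b == 90))
  # green carries the strongest pulsatile signature
  tr <- render_rgb_trace(pw, baseline = c(150, 110, 90),
                         noise_params = quiet, seed = 1)
  expect_gt(stats::var(tr$g), stats::var(tr$r))
  expect_gt(stats::var(tr$g), stats::var(tr$b))
  expect_length(tr$r, length(pw$samples))
  expect_identical(tr$fs, pw$fs)
  expect_error(render_rgb_trace(pw, noise_params = list(white_noise_sd = -1)),
               "non-negative")
  expect_error(render_rgb_trace(pw, baseline = c(0, 110, 90)), "baseline")
})

test_that("frame rendering fills the skin rectangle with the trace", {
  rr <- simulate_rr("NSR", 60, duration = 2, seed = 1)
  pw <- render_pulse(rr, 84)
  tr <- render_rgb_trace(pw, noise_params = list(white_noise_sd = 0,
                                                 illum_drift_amp = 0,
                                                 artifact_rate = 0))
  fr <- render_frames(tr, frame_size = c(16, 16),
                      skin_rect = list(row = 3, col = 3, height = 10,
                                       width = 10),
                      pixel_noise_sd = 0)
  expect_identical(dim(fr$frames)[4], length(tr$r))
  expect_true(all(fr$frames[3, 3, 1, ] == tr$r))
  expect_true(all(fr$frames[1, 1, 1, ] == 60))  # background
  expect_error(render_frames(tr, frame_size = c(8, 8),
                             skin_rect = list(row = 5, col = 5, height = 10,
                                              width = 10)),
               "exceeds")
  expect_error(render_frames(tr, skin_rect = list(row = 1, col = 1,
                                                  height = 0, width = 0)),
               "non-empty")
})

test_that("ROI averaging over noisy frames recovers the generating trace", {
  rr <- simulate_rr("NSR", 72, duration = 3, seed = 2)
  pw <- render_pulse(rr, 84)
  tr <- render_rgb_trace(pw, noise_params = list(white_noise_sd = 0,
                                                 illum_drift_amp = 0,
                                                 artifact_rate = 0))
  sd_pix <- 3
  fr <- render_frames(tr, frame_size = c(24, 24),
                      skin_rect = list(row = 5, col = 5, height = 16,
                                       width = 16),
                      pixel_noise_sd = sd_pix, seed = 4)
  rec <- roi_mean_rgb(fr)
  tol <- 5 * sd_pix / sqrt(16 * 16)  # law of large numbers
  expect_lt(max(abs(rec$g - tr$g)), tol)
})

test_that("subject simulation is deterministic and propagates its label", {
  rec <- simulate_subject("NSR", duration = 600, seed = 3)
  expect_length(rec$trace$r, 50400)  # 600 s x 84 Hz
  rec2 <- simulate_subject("NSR", duration = 600, seed = 3)
  expect_identical(rec$trace, rec2$trace)
  expect_identical(rec$label$group, "NSR")
  af <- simulate_subject("AF", duration = 60, seed = 5)
  expect_identical(af$label$group, "AF")
  expect_error(simulate_subject("NSR", duration = 10, seed = 1), "duration")
  expect_error(simulate_subject("NSR", duration = 1000, seed = 1),
               "duration")
})

test_that("cohort generation matches the requested composition exactly", {
  spec <- cohort_spec(n_af = 105, n_nsr = 116,
                      duration_range = c(30, 30), master_seed = 2)
  expect_identical(105L + 116L + as.integer(sum(spec$n_other)), 453L)
  cohort <- simulate_cohort(spec)
  groups <- vapply(cohort, function(r) r$label$group, character(1))
  expect_identical(sum(groups == "AF"), 105L)
  expect_identical(sum(groups == "NSR"), 116L)
  expect_identical(sum(groups == "OTHER"), 232L)
})

test_that("cohorts are reproducible and reject degenerate specs", {
  spec <- cohort_spec(n_af = 1, n_nsr = 1, n_other = c(APC = 0),
                      duration_range = c(30, 60), master_seed = 7)
  c1 <- simulate_cohort(spec)
  expect_length(c1, 2L)
  c2 <- simulate_cohort(spec)
  expect_identical(c1[[1]]$trace, c2[[1]]$trace)
  expect_identical(c1[[2]]$rr$intervals, c2[[2]]$rr$intervals)
  expect_error(cohort_spec(n_af = 0, n_nsr = 0, n_other = c(APC = 0)),
               ">= 1 subject")
})
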