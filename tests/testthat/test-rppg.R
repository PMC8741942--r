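# rPPG extraction: ROI averaging, chrominance projection, bandpass design
# and application, heart-rate estimation, quality control.

quiet_noise <- list(illum_drift_amp = 0, white_noise_sd = 0,
                    artifact_rate = 0)

# Noise-free trace whose pulse is a pure tone at `f_hz`.
tone_trace <- function(f_hz, duration = 30, fs = 84, depth = 0.005) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  pw <- structure(list(samples = sin(2 * pi * f_hz * t), fs = fs,
                       beat_onsets = integer(0)), class = "pulse_wave")
  render_rgb_trace(pw, noise_params = c(quiet_noise,
                                        list(pulse_strength = depth)),
                   seed = 1)
}

dominant_freq <- function(sig) {
  pg <- rppgaf:::band_periodogram(sig$samples, sig$fs, 0.3, 3.5)
  pg$freq[which.max(pg$power)]
}

test_that("roi_mean_rgb averages exactly over the requested rectangle", {
  frames <- structure(list(
    frames = array(rep(c(100, 150, 200), each = 16),
                   dim = c(4, 4, 3, 2)),
    fs = 84, skin_rect = list(row = 1, col = 1, height = 4, width = 4),
    subject_id = "x"), class = "frame_stack")
  tr <- roi_mean_rgb(frames)
  expect_equal(tr$r, c(100, 100))
  expect_equal(tr$g, c(150, 150))
  expect_equal(tr$b, c(200, 200))
  one <- roi_mean_rgb(frames, roi = list(row = 2, col = 3, height = 1,
                                         width = 1))
  expect_equal(one$b, as.numeric(frames$frames[2, 3, 3, ]))
  expect_error(roi_mean_rgb(frames, roi = list(row = 3, col = 3, height = 4,
                                               width = 4)),
               "exceeds")
})

test_that("chrominance projection cancels constants and keeps the pulse", {
  flat <- structure(list(r = rep(120, 840), g = rep(90, 840),
                         b = rep(70, 840), fs = 84, subject_id = "x"),
                    class = "rgb_trace")
  for (m in c("CHROM", "POS", "GREEN"))
    expect_true(all(abs(chrominance_project(flat, m)$samples) < 1e-9))
  tr <- tone_trace(1.2)
  expect_lt(abs(dominant_freq(chrominance_project(tr, "CHROM")) - 1.2), 0.05)
  expect_lt(abs(dominant_freq(chrominance_project(tr, "POS")) - 1.2), 0.05)
  expect_lt(abs(dominant_freq(chrominance_project(tr, "GREEN")) - 1.2), 0.05)
  short <- structure(list(r = rep(120, 50), g = rep(90, 50), b = rep(70, 50),
                          fs = 84, subject_id = "x"), class = "rgb_trace")
  expect_error(chrominance_project(short), "shorter")
})

test_that("chrominance output suppresses pure intensity modulation", {
  # pulsatile modulation (per-channel skin signature) vs the same depth
  # applied identically to all channels (motion/illumination)
  t <- (seq_len(30 * 84) - 1) / 84
  mod <- 0.005 * sin(2 * pi * 1.2 * t)
  base <- c(150, 110, 90)
  k <- c(0.33, 0.77, 0.53)
  pulsatile <- structure(list(r = base[1] * (1 + k[1] * mod),
                              g = base[2] * (1 + k[2] * mod),
                              b = base[3] * (1 + k[3] * mod),
                              fs = 84, subject_id = "p"),
                         class = "rgb_trace")
  intensity <- structure(list(r = base[1] * (1 + mod),
                              g = base[2] * (1 + mod),
                              b = base[3] * (1 + mod),
                              fs = 84, subject_id = "i"),
                         class = "rgb_trace")
  p_pulse <- stats::var(chrominance_project(pulsatile)$samples)
  p_int <- stats::var(chrominance_project(intensity)$samples)
  expect_lte(p_int, 0.1 * p_pulse)
})

test_that("chrominance projection is invariant to global gain and tolerant to offsets", {
  tr <- tone_trace(1.0)
  out <- chrominance_project(tr)$samples
  gained <- tr
  gained$r <- 1.7 * tr$r; gained$g <- 1.7 * tr$g; gained$b <- 1.7 * tr$b
  expect_equal(chrominance_project(gained)$samples, out, tolerance = 1e-12)
  shifted <- tr
  shifted$r <- tr$r + 2; shifted$g <- tr$g + 2; shifted$b <- tr$b + 2
  out2 <- chrominance_project(shifted)$samples
  expect_gt(stats::cor(out, out2), 0.99)
})

test_that("the Chebyshev-II bandpass meets its attenuation contract", {
  spec <- design_bandpass(84, 0.5, 3.0, 4, 40)
  expect_lte(freq_response_db(spec$b, spec$a, 0.05, 84), -40)
  expect_lte(freq_response_db(spec$b, spec$a, 10, 84), -40)
  expect_gte(freq_response_db(spec$b, spec$a, 1.75, 84), -1)
  expect_lt(max(Mod(polyroot(rev(spec$a)))), 1)
  expect_error(design_bandpass(84, 3.0, 0.5, 4, 40), "band")
  expect_error(design_bandpass(84, 0.5, 50, 4, 40), "band")
})

test_that("zero-phase filtering preserves in-band tones and kills out-of-band", {
  spec <- design_bandpass(84)
  fs <- 84
  t <- (seq_len(40 * fs) - 1) / fs
  edge <- 3 * fs
  mid <- (edge + 1):(length(t) - edge)
  zero <- rppgaf:::new_rppg_signal(numeric(length(t)), fs, "RAW")
  expect_true(all(apply_bandpass(zero, spec)$samples == 0))
  inband <- rppgaf:::new_rppg_signal(sin(2 * pi * 1.2 * t), fs, "RAW")
  y <- apply_bandpass(inband, spec)$samples
  expect_gte(max(abs(y[mid])), 0.9)
  low <- rppgaf:::new_rppg_signal(sin(2 * pi * 0.1 * t), fs, "RAW")
  y_lo <- apply_bandpass(low, spec)$samples
  expect_lte(max(abs(y_lo[mid])), 10^(-40 / 20) * 2)
  bad <- rppgaf:::new_rppg_signal(sin(t), 30, "RAW")
  expect_error(apply_bandpass(bad, spec), "mismatch")
})

test_that("filtering is idempotent for in-band content", {
  spec <- design_bandpass(84)
  fs <- 84
  t <- (seq_len(60 * fs) - 1) / fs
  x <- rppgaf:::new_rppg_signal(sin(2 * pi * 1.2 * t), fs, "RAW")
  once <- apply_bandpass(x, spec)
  twice <- apply_bandpass(once, spec)
  mid <- (3 * fs):(length(t) - 3 * fs)
  a1 <- max(abs(once$samples[mid]))
  a2 <- max(abs(twice$samples[mid]))
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("heart-rate estimation recovers known rates", {
  fs <- 84
  t <- (seq_len(60 * fs) - 1) / fs
  pure <- rppgaf:::new_rppg_signal(sin(2 * pi * 1.0 * t), fs, "FILTERED")
  expect_lt(abs(estimate_hr(pure) - 60), 0.5)
  short <- rppgaf:::new_rppg_signal(sin(2 * pi * t[1:100]), fs, "FILTERED")
  expect_error(estimate_hr(short), "10 s")
  # end-to-end on noisy synthetic subjects
  errs <- vapply(1:5, function(s) {
    rec <- simulate_subject("NSR", duration = 60, seed = s, mean_hr = 72)
    abs(estimate_hr(extract_rppg(rec)) - 60 / mean(rec$rr$intervals))
  }, numeric(1))
  expect_lt(mean(errs), 2)
  # AF: estimated rate tracks the RR-derived mean rate; the spectral peak
  # of an irregular pulse train scatters around the mean rate, so the
  # check is on the seed-ensemble median
  af_err <- vapply(1:10, function(s) {
    rec <- simulate_subject("AF", duration = 120, seed = 100 + s,
                            mean_hr = 75)
    abs(estimate_hr(extract_rppg(rec)) - 60 / mean(rec$rr$intervals))
  }, numeric(1))
  expect_lt(stats::median(af_err), 5)
})

test_that("quality check passes clean pulses and fails noise", {
  rec <- simulate_subject("NSR", duration = 60, seed = 2,
                          noise_params = quiet_noise)
  qc <- quality_check(extract_rppg(rec))
  expect_true(qc$pass)
  spec <- design_bandpass(84)
  noise <- rppgaf:::with_seed(9, stats::rnorm(60 * 84))
  nqc <- quality_check(apply_bandpass(
    rppgaf:::new_rppg_signal(noise, 84, "RAW"), spec))
  expect_false(nqc$pass)
  zqc <- quality_check(rppgaf:::new_rppg_signal(numeric(60 * 84), 84,
                                                "FILTERED"))
  expect_false(zqc$pass)
  expect_true(zqc$undefined)
})

test_that("frame-based and trace-based extraction agree", {
  rec <- simulate_subject("NSR", duration = 30, seed = 6,
                          noise_params = quiet_noise)
  sd_pix <- 1
  fr <- render_frames(rec$trace, frame_size = c(24, 24),
                      skin_rect = list(row = 5, col = 5, height = 16,
                                       width = 16),
                      pixel_noise_sd = sd_pix, seed = 2)
  spec <- design_bandpass(84)
  from_frames <- apply_bandpass(chrominance_project(roi_mean_rgb(fr)),
                                spec)$samples
  from_trace <- apply_bandpass(chrominance_project(rec$trace),
                               spec)$samples
  expect_gt(stats::cor(from_frames, from_trace), 0.95)
  # residual per-pixel noise averages down by sqrt(n_pixels); the
  # chrominance units are intensity/baseline, hence the 1/90 scale
  tol <- 2 * sd_pix / sqrt(16 * 16) / 90
  expect_lt(sqrt(mean((from_frames - from_trace)^2)), tol)
})
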