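# Synthetic cardiac rhythm and facial-color simulator.
#
# The generator produces the ground truth the rest of the pipeline tries to
# recover: a beat-to-beat (RR) interval process with a rhythm label, a pulse
# waveform rendered from it, and a three-channel facial RGB trace whose skin
# color is modulated by the pulse plus illumination drift, sensor noise and
# sparse motion artifacts.

RHYTHM_GROUPS <- c("AF", "NSR", "OTHER")
OTHER_SUBTYPES <- c("APC", "VPC", "SINUS_ARRHYTHMIA", "SINUS_TACHY",
                    "SINUS_BRADY", "FLUTTER")

RR_MIN <- 0.25  # s, physiological floor (240 bpm)
RR_MAX <- 3.0   # s, physiological ceiling (20 bpm)

#' Rhythm label
#'
#' A rhythm class label with a coarse group (`AF`, `NSR`, `OTHER`) and, for
#' the `OTHER` group, a closed set of subtypes covering ectopy, sinus
#' arrhythmia, rate abnormalities and atrial flutter.
#'
#' @param group One of `"AF"`, `"NSR"`, `"OTHER"`.
#' @param subtype For `group = "OTHER"`, one of `"APC"`, `"VPC"`,
#'   `"SINUS_ARRHYTHMIA"`, `"SINUS_TACHY"`, `"SINUS_BRADY"`, `"FLUTTER"`;
#'   must be `"NONE"` otherwise.
#' @return An object of class `rhythm_label`.
#' @export
rhythm_label <- function(group, subtype = "NONE") {
  group <- match.arg(group, RHYTHM_GROUPS)
  subtype <- match.arg(subtype, c("NONE", OTHER_SUBTYPES))
  if (group == "OTHER" && subtype == "NONE")
    stopf("group 'OTHER' requires a subtype (one of %s)",
          paste(OTHER_SUBTYPES, collapse = ", "))
  if (group != "OTHER" && subtype != "NONE")
    stopf("subtype '%s' is only valid for group 'OTHER'", subtype)
  structure(list(group = group, subtype = subtype), class = "rhythm_label")
}

#' @export
format.rhythm_label <- function(x, ...) {
  if (x$subtype == "NONE") x$group else paste0(x$group, "/", x$subtype)
}

#' @export
print.rhythm_label <- function(x, ...) {
  cat("<rhythm_label>", format(x), "\n")
  invisible(x)
}

as_rhythm_label <- function(x) {
  if (inherits(x, "rhythm_label")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1L && parts %in% OTHER_SUBTYPES)
      return(rhythm_label("OTHER", parts))
    return(rhythm_label(parts[1], if (length(parts) > 1L) parts[2] else "NONE"))
  }
  stopf("cannot interpret '%s' as a rhythm label", paste(x, collapse = "/"))
}

#' Simulate a beat-to-beat (RR) interval series
#'
#' Generates a sequence of RR intervals with the serial structure of the
#' requested rhythm. Normal sinus rhythm is a low-variability process with
#' sinusoidal respiratory modulation; atrial fibrillation draws intervals
#' independently from a heavy-variability Gamma distribution (the
#' "irregularly irregular" signature with no serial correlation); the
#' `OTHER` subtypes cover premature complexes with compensatory pauses,
#' exaggerated sinus arrhythmia, rate abnormalities and atrial flutter with
#' abrupt conduction-block switches.
#'
#' Beats are accepted while the cumulative time stays within
#' `duration`; every interval is clipped to the physiological range
#' \[0.25, 3\] s. Generation is fully reproducible from `(label, mean_hr,
#' duration, seed)`.
#'
#' @param label A [rhythm_label()] (or a string such as `"AF"`,
#'   `"OTHER/APC"`).
#' @param mean_hr Target mean heart rate in beats per minute, in
#'   \[30, 220\]. Ignored for the fixed-rate subtypes `SINUS_TACHY`
#'   (110 bpm), `SINUS_BRADY` (50 bpm) and `FLUTTER` (atrial 300/min with
#'   2:1 or 4:1 block).
#' @param duration Target recording duration in seconds (> 0).
#' @param seed Integer RNG seed.
#' @param resp_freq Respiratory modulation frequency in Hz (sinus rhythms).
#' @param resp_depth Fractional modulation depth for NSR (sinus arrhythmia
#'   uses 0.15 regardless).
#' @param jitter_cv Coefficient of variation of the multiplicative Gaussian
#'   beat-to-beat jitter for sinus rhythms.
#' @param af_cv Coefficient of variation of the AF Gamma interval
#'   distribution.
#' @param ectopy_prob Per-beat probability of a premature complex for the
#'   `APC`/`VPC` subtypes.
#' @return An object of class `rr_series`: list with `intervals` (seconds),
#'   `onsets` (cumulative beat onset times, seconds), `beat_amp` (relative
#'   pulse amplitude per beat; premature complexes eject less blood),
#'   `label`, `seed`, `target_duration`.
#' @export
simulate_rr <- function(label, mean_hr = 75, duration = 300, seed = 1,
                        resp_freq = 0.25, resp_depth = 0.03,
                        jitter_cv = 0.02, af_cv = 0.24, ectopy_prob = 0.1) {
  label <- as_rhythm_label(label)
  if (!is_scalar_num(duration) || duration <= 0)
    stopf("duration must be a positive number of seconds, got %s",
          format(duration))
  if (!is_scalar_num(mean_hr) || mean_hr < 30 || mean_hr > 220)
    stopf("mean_hr must lie in [30, 220] bpm, got %s", format(mean_hr))

  kind <- if (label$group == "OTHER") label$subtype else label$group
  hr <- switch(kind, SINUS_TACHY = 110, SINUS_BRADY = 50, mean_hr)
  base <- 60 / hr

  intervals <- numeric(0)
  amps <- numeric(0)
  with_seed(seed, {
    t <- 0
    if (kind == "AF") {
      shape <- 1 / af_cv^2
      repeat {
        x <- stats::rgamma(1L, shape = shape, scale = base / shape)
        x <- min(max(x, 0.3), 2.0)
        x <- min(max(x, RR_MIN), RR_MAX)
        if (t + x > duration) break
        intervals <- c(intervals, x)
        amps <- c(amps, 1)
        t <- t + x
      }
    } else if (kind == "FLUTTER") {
      # Atrial rate 300/min; ventricular response at 2:1 (0.4 s) or 4:1
      # (0.8 s) block, switching abruptly every ~30 s.
      atrial <- 60 / 300
      block <- 2L
      next_switch <- stats::runif(1L, 20, 40)
      repeat {
        x <- block * atrial * (1 + stats::rnorm(1L, 0, 0.01))
        x <- min(max(x, RR_MIN), RR_MAX)
        if (t + x > duration) break
        intervals <- c(intervals, x)
        amps <- c(amps, 1)
        t <- t + x
        if (t >= next_switch) {
          block <- if (block == 2L) 4L else 2L
          next_switch <- t + stats::runif(1L, 20, 40)
        }
      }
    } else {
      # Sinus-family rhythms: respiratory sinusoid + multiplicative jitter,
      # optionally interrupted by premature complexes with a compensatory
      # pause.
      depth <- switch(kind, SINUS_ARRHYTHMIA = 0.15, resp_depth)
      ect <- switch(kind, APC = ectopy_prob, VPC = ectopy_prob, 0)
      prem_frac <- switch(kind, VPC = 0.5, 0.6)
      comp_frac <- switch(kind, VPC = 1.5, 1.4)
      prem_amp <- switch(kind, VPC = 0.5, 0.8)
      pending <- character(0)  # queued beat kinds after an ectopic trigger
      repeat {
        sinus <- base * (1 + depth * sin(2 * pi * resp_freq * t)) *
          (1 + stats::rnorm(1L, 0, jitter_cv))
        if (length(pending)) {
          role <- pending[1]; pending <- pending[-1]
          x <- sinus * if (role == "prem") prem_frac else comp_frac
          a <- if (role == "prem") prem_amp else 1
        } else {
          x <- sinus
          a <- 1
          if (ect > 0 && stats::runif(1L) < ect)
            pending <- c("prem", "comp")
        }
        x <- min(max(x, RR_MIN), RR_MAX)
        if (t + x > duration) break
        intervals <- c(intervals, x)
        amps <- c(amps, a)
        t <- t + x
      }
    }
  })

  structure(list(
    intervals = intervals,
    onsets = if (length(intervals)) cumsum(c(0, intervals[-length(intervals)]))
             else numeric(0),
    beat_amp = amps,
    label = label,
    seed = as.integer(seed),
    target_duration = duration
  ), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s: %d beats over %.1f s (mean RR %.3f s, CV %.3f)\n",
              format(x$label), length(x$intervals), x$target_duration,
              mean(x$intervals),
              stats::sd(x$intervals) / mean(x$intervals)))
  invisible(x)
}

#' Render a pulse waveform from an RR interval series
#'
#' Places one pulse template per beat at its onset: a systolic Gaussian peak
#' at 30% of the local RR interval (width 0.08 s, unit amplitude) plus a
#' dicrotic Gaussian at 55% (width 0.1 s, amplitude 0.35), scaled by the
#' beat's relative amplitude (premature complexes eject less). The summed
#' waveform is normalized to unit peak amplitude.
#'
#' @param rr An `rr_series`.
#' @param fs Sampling rate in Hz; must exceed twice the highest beat
#'   frequency implied by the series.
#' @return An object of class `pulse_wave`: list with `samples` (length
#'   `round(target_duration * fs)`), `fs`, `beat_onsets` (1-based sample
#'   indices).
#' @export
render_pulse <- function(rr, fs = 84) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be positive")
  n <- round(rr$target_duration * fs)
  samples <- numeric(n)
  if (length(rr$intervals)) {
    if (fs <= 2 / min(rr$intervals))
      stopf("fs = %g Hz undersamples the fastest beat (RR %.3f s)",
            fs, min(rr$intervals))
    tgrid <- (seq_len(n) - 1) / fs
    for (i in seq_along(rr$intervals)) {
      o <- rr$onsets[i]; w <- rr$intervals[i]; a <- rr$beat_amp[i]
      lo <- max(1L, floor(o * fs) + 1L)
      hi <- min(n, ceiling((o + w + 0.4) * fs) + 1L)
      if (lo > hi) next
      tt <- tgrid[lo:hi] - o
      samples[lo:hi] <- samples[lo:hi] +
        a * (exp(-(tt - 0.30 * w)^2 / (2 * 0.08^2)) +
             0.35 * exp(-(tt - 0.55 * w)^2 / (2 * 0.10^2)))
    }
    peak <- max(abs(samples))
    if (peak > 0) samples <- samples / peak
  }
  structure(list(
    samples = samples,
    fs = fs,
    beat_onsets = if (length(rr$onsets)) pmin(n, round(rr$onsets * fs) + 1L)
                  else integer(0)
  ), class = "pulse_wave")
}

#' Default observation-noise parameters
#'
#' Noise model applied when turning a pulse wave into an RGB trace:
#' `pulse_strength` is the fractional skin-color modulation depth of the
#' pulse (0.5% of baseline); `illum_drift_amp` the standard deviation of a
#' 0.1-Hz band-limited illumination random walk (fraction of baseline);
#' `white_noise_sd` per-channel sensor noise in intensity units;
#' `artifact_rate` sparse motion transients per second (each a 0.5-s
#' triangular ramp of `artifact_amp` intensity units on all channels).
#'
#' @return Named list of noise parameters.
#' @export
default_noise_params <- function() {
  list(pulse_strength = 0.005, illum_drift_amp = 0.01,
       white_noise_sd = 0.2, artifact_rate = 1 / 60, artifact_amp = 5)
}

merge_noise_params <- function(noise_params) {
  def <- default_noise_params()
  if (is.null(noise_params)) return(def)
  unknown <- setdiff(names(noise_params), names(def))
  if (length(unknown))
    stopf("unknown noise parameter(s): %s", paste(unknown, collapse = ", "))
  def[names(noise_params)] <- noise_params
  bad <- vapply(def, function(v) !is_scalar_num(v) || v < 0, logical(1))
  if (any(bad))
    stopf("noise parameters must be non-negative numbers: %s",
          paste(names(def)[bad], collapse = ", "))
  def
}

#' Render a facial RGB trace from a pulse wave
#'
#' Inverts the rPPG observation model: each channel is its skin baseline
#' modulated multiplicatively by the pulse (with the green channel carrying
#' the strongest pulsatile signature, per the standard skin-reflection
#' ratios), a common-mode illumination drift, additive sensor noise, and
#' sparse common-mode motion artifacts.
#'
#' Channel model:
#' `c(t) = baseline_c * (1 + k_c * pulse_strength * pulse(t) + drift(t)) +
#'  white(t) + artifact(t)`
#' with relative pulsatile signature `(k_r, k_g, k_b) = (0.33, 0.77, 0.53)`.
#'
#' @param pulse A `pulse_wave`.
#' @param baseline Length-3 numeric, mean skin color (R, G, B) on the 0-255
#'   scale, each strictly inside (0, 255).
#' @param noise_params Partial or full list as in [default_noise_params()].
#' @param seed Integer RNG seed.
#' @param subject_id Identifier stored on the trace.
#' @return An object of class `rgb_trace`: list with `r`, `g`, `b`, `fs`,
#'   `subject_id`.
#' @export
render_rgb_trace <- function(pulse, baseline = c(150, 110, 90),
                             noise_params = NULL, seed = 1,
                             subject_id = "anon") {
  stopifnot(inherits(pulse, "pulse_wave"))
  if (length(baseline) != 3L || any(baseline <= 0) || any(baseline >= 255))
    stopf("baseline must be three values strictly inside (0, 255)")
  np <- merge_noise_params(noise_params)
  k <- c(r = 0.33, g = 0.77, b = 0.53)
  n <- length(pulse$samples)
  fs <- pulse$fs

  drift <- numeric(n)
  white <- matrix(0, n, 3L)
  artifact <- numeric(n)
  with_seed(seed, {
    if (np$illum_drift_amp > 0 && n > 12L) {
      w <- cumsum(stats::rnorm(n))
      lp <- signal::butter(2, min(0.1 / (fs / 2), 0.99), type = "low")
      w <- signal::filtfilt(lp$b, lp$a, w)
      s <- stats::sd(w)
      drift <- if (s > 0) np$illum_drift_amp * (w - mean(w)) / s else drift
    }
    if (np$white_noise_sd > 0)
      white <- matrix(stats::rnorm(3L * n, 0, np$white_noise_sd), n, 3L)
    if (np$artifact_rate > 0) {
      n_art <- stats::rpois(1L, np$artifact_rate * n / fs)
      if (n_art > 0) {
        onsets <- stats::runif(n_art, 0, max(0, n / fs - 0.5))
        half <- max(1L, round(0.25 * fs))
        bump <- np$artifact_amp *
          c(seq_len(half) / half, rev(seq_len(half)) / half)
        for (o in onsets) {
          i0 <- floor(o * fs) + 1L
          idx <- i0:min(n, i0 + length(bump) - 1L)
          artifact[idx] <- artifact[idx] + bump[seq_along(idx)]
        }
      }
    }
  })

  chans <- lapply(1:3, function(j) {
    baseline[j] * (1 + k[j] * np$pulse_strength * pulse$samples + drift) +
      white[, j] + artifact
  })
  structure(list(r = chans[[1]], g = chans[[2]], b = chans[[3]],
                 fs = fs, subject_id = subject_id), class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> %s: %d samples at %g Hz (%.1f s)\n",
              x$subject_id, length(x$r), x$fs, length(x$r) / x$fs))
  invisible(x)
}

#' Render synthetic video frames from an RGB trace
#'
#' Produces a stack of flat synthetic frames: pixels inside the skin
#' rectangle carry the trace value of that frame plus independent per-pixel
#' noise; everything outside is a constant background. Frame `t` encodes
#' trace sample `t`. This stands in for real face video so that the
#' ROI-averaging front end can be exercised end-to-end.
#'
#' @param trace An `rgb_trace`.
#' @param frame_size `c(height, width)` in pixels.
#' @param skin_rect List with `row`, `col`, `height`, `width` (1-based,
#'   inside the frame, non-empty).
#' @param pixel_noise_sd Per-pixel independent Gaussian noise, intensity
#'   units.
#' @param background Length-3 background color.
#' @param seed Integer RNG seed.
#' @return An object of class `frame_stack`: list with `frames` (array
#'   `height x width x 3 x n`), `fs`, `skin_rect`, `subject_id`.
#' @export
render_frames <- function(trace, frame_size = c(24, 24),
                          skin_rect = list(row = 7, col = 7,
                                           height = 12, width = 12),
                          pixel_noise_sd = 2, background = c(60, 60, 60),
                          seed = 1) {
  stopifnot(inherits(trace, "rgb_trace"))
  h <- frame_size[1]; w <- frame_size[2]
  sr <- skin_rect
  if (sr$height < 1 || sr$width < 1) stopf("skin_rect must be non-empty")
  if (sr$row < 1 || sr$col < 1 || sr$row + sr$height - 1 > h ||
      sr$col + sr$width - 1 > w)
    stopf("skin_rect exceeds the %d x %d frame", h, w)
  n <- length(trace$r)
  frames <- array(0, dim = c(h, w, 3L, n))
  for (j in 1:3) frames[, , j, ] <- background[j]
  rows <- sr$row:(sr$row + sr$height - 1L)
  cols <- sr$col:(sr$col + sr$width - 1L)
  npix <- length(rows) * length(cols)
  chans <- list(trace$r, trace$g, trace$b)
  with_seed(seed, {
    for (j in 1:3) {
      vals <- rep(chans[[j]], each = npix)
      if (pixel_noise_sd > 0)
        vals <- vals + stats::rnorm(length(vals), 0, pixel_noise_sd)
      frames[rows, cols, j, ] <- vals
    }
  })
  structure(list(frames = frames, fs = trace$fs, skin_rect = sr,
                 subject_id = trace$subject_id), class = "frame_stack")
}

#' Simulate one subject's recording
#'
#' Composes [simulate_rr()], [render_pulse()] and [render_rgb_trace()] into
#' a single subject record carrying the ground-truth rhythm and RR series
#' alongside the camera-facing RGB trace.
#'
#' @param label A [rhythm_label()] (or string).
#' @param duration Recording length in seconds, in \[30, 600\].
#' @param noise_params As in [render_rgb_trace()].
#' @param seed Integer seed; all subject randomness (heart rate draw, RR
#'   process, observation noise) derives from it.
#' @param fs Sampling rate (frames per second), default 84.
#' @param mean_hr Mean heart rate in bpm; if `NULL`, drawn from a
#'   rhythm-appropriate range (NSR 55-85, AF 70-110, other 55-95).
#' @param subject_id Identifier; autogenerated from the seed if `NULL`.
#' @return An object of class `subject_record`: list with `subject_id`,
#'   `label`, `rr`, `trace`, `duration`, `fs`, `mean_hr`, `seed`.
#' @export
simulate_subject <- function(label, duration = 300, noise_params = NULL,
                             seed = 1, fs = 84, mean_hr = NULL,
                             subject_id = NULL) {
  label <- as_rhythm_label(label)
  if (!is_scalar_num(duration) || duration < 30 || duration > 600)
    stopf("duration must lie in [30, 600] s, got %s", format(duration))
  if (is.null(subject_id)) subject_id <- sprintf("subj%08d", seed %% 1e8)
  if (is.null(mean_hr)) {
    rng <- switch(label$group, NSR = c(55, 85), AF = c(70, 110), c(55, 95))
    mean_hr <- with_seed(derive_seed(seed, 101L),
                         stats::runif(1L, rng[1], rng[2]))
  }
  rr <- simulate_rr(label, mean_hr = mean_hr, duration = duration,
                    seed = derive_seed(seed, 1L))
  pulse <- render_pulse(rr, fs = fs)
  trace <- render_rgb_trace(pulse, noise_params = noise_params,
                            seed = derive_seed(seed, 2L),
                            subject_id = subject_id)
  structure(list(subject_id = subject_id, label = label, rr = rr,
                 trace = trace, duration = duration, fs = fs,
                 mean_hr = mean_hr, seed = as.integer(seed)),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s [%s]: %.0f s at %g Hz, mean HR %.1f bpm\n",
              x$subject_id, format(x$label), x$duration, x$fs, x$mean_hr))
  invisible(x)
}

#' Cohort specification
#'
#' Defines the composition and generation parameters of a synthetic cohort.
#' The default composition mirrors a mixed hospital population: 105 atrial
#' fibrillation, 116 normal sinus rhythm and 232 other-abnormality subjects
#' spread over the closed subtype list.
#'
#' @param n_af,n_nsr Subject counts for the AF and NSR groups.
#' @param n_other Named integer vector of counts per `OTHER` subtype
#'   (missing subtypes count 0).
#' @param duration_range Recording durations are drawn uniformly from this
#'   range (seconds, within \[30, 600\]).
#' @param fs Sampling rate, default 84 frames per second.
#' @param noise_params As in [default_noise_params()].
#' @param master_seed Integer seed from which every per-subject seed is
#'   derived.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_af = 105, n_nsr = 116,
                        n_other = c(APC = 56, VPC = 44,
                                    SINUS_ARRHYTHMIA = 52, SINUS_TACHY = 40,
                                    SINUS_BRADY = 20, FLUTTER = 20),
                        duration_range = c(300, 600), fs = 84,
                        noise_params = NULL, master_seed = 1) {
  if (!is_count(n_af) || !is_count(n_nsr) ||
      (length(n_other) && (!all(vapply(n_other, is_count, logical(1))))))
    stopf("subject counts must be non-negative integers")
  if (length(n_other)) {
    unknown <- setdiff(names(n_other), OTHER_SUBTYPES)
    if (length(unknown) || is.null(names(n_other)))
      stopf("n_other must be named with subtypes from: %s",
            paste(OTHER_SUBTYPES, collapse = ", "))
  }
  if (n_af + n_nsr + sum(n_other) < 1) stopf("cohort must contain >= 1 subject")
  if (length(duration_range) != 2L || duration_range[1] > duration_range[2] ||
      duration_range[1] < 30 || duration_range[2] > 600)
    stopf("duration_range must be within [30, 600] s")
  structure(list(n_af = as.integer(n_af), n_nsr = as.integer(n_nsr),
                 n_other = n_other, duration_range = duration_range,
                 fs = fs, noise_params = merge_noise_params(noise_params),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of subjects
#'
#' Generates one [simulate_subject()] record per requested subject. Each
#' subject's seed is derived deterministically from the master seed and the
#' subject index, so the same specification always yields a bit-identical
#' cohort; durations are drawn uniformly from the spec's range.
#'
#' @param spec A [cohort_spec()].
#' @return List of `subject_record`s (class `cohort`), ordered AF, NSR,
#'   then the `OTHER` subtypes.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- c(
    rep(list(rhythm_label("AF")), spec$n_af),
    rep(list(rhythm_label("NSR")), spec$n_nsr),
    unlist(lapply(names(spec$n_other), function(st)
      rep(list(rhythm_label("OTHER", st)), spec$n_other[[st]])),
      recursive = FALSE)
  )
  records <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sseed <- derive_seed(spec$master_seed, i)
    dur <- floor(with_seed(derive_seed(sseed, 7L),
                           stats::runif(1L, spec$duration_range[1],
                                        spec$duration_range[2])))
    records[[i]] <- simulate_subject(
      labels[[i]], duration = dur, noise_params = spec$noise_params,
      seed = sseed, fs = spec$fs,
      subject_id = sprintf("S%04d_%s", i,
                           if (labels[[i]]$group == "OTHER")
                             labels[[i]]$subtype else labels[[i]]$group))
  }
  structure(records, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, function(r) r$label$group, character(1))
  cat(sprintf("<cohort> %d subjects (AF %d, NSR %d, OTHER %d)\n",
              length(x), sum(groups == "AF"), sum(groups == "NSR"),
              sum(groups == "OTHER")))
  invisible(x)
}
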