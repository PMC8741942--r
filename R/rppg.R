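# rPPG extraction: ROI averaging, chrominance projection, Chebyshev-II
# bandpass filtering, heart-rate estimation and signal quality control.

new_rppg_signal <- function(samples, fs, stage, subject_id = "anon") {
  stopifnot(stage %in% c("RAW", "FILTERED"), all(is.finite(samples)))
  structure(list(samples = samples, fs = fs, stage = stage,
                 subject_id = subject_id), class = "rppg_signal")
}

#' @export
print.rppg_signal <- function(x, ...) {
  cat(sprintf("<rppg_signal> %s [%s]: %d samples at %g Hz\n",
              x$subject_id, x$stage, length(x$samples), x$fs))
  invisible(x)
}

#' Average the RGB values over a region of interest
#'
#' Reduces a frame stack to a three-channel trace by taking, per frame, the
#' arithmetic mean of each color channel over the ROI pixels.
#'
#' @param frames A `frame_stack` from [render_frames()].
#' @param roi List with `row`, `col`, `height`, `width`; defaults to the
#'   stack's skin rectangle.
#' @return An `rgb_trace`.
#' @export
roi_mean_rgb <- function(frames, roi = NULL) {
  stopifnot(inherits(frames, "frame_stack"))
  if (is.null(roi)) roi <- frames$skin_rect
  d <- dim(frames$frames)
  if (roi$height < 1 || roi$width < 1) stopf("roi must be non-empty")
  if (roi$row < 1 || roi$col < 1 || roi$row + roi$height - 1 > d[1] ||
      roi$col + roi$width - 1 > d[2])
    stopf("roi exceeds the %d x %d frame", d[1], d[2])
  rows <- roi$row:(roi$row + roi$height - 1L)
  cols <- roi$col:(roi$col + roi$width - 1L)
  npix <- length(rows) * length(cols)
  chan_mean <- function(j) {
    colMeans(matrix(frames$frames[rows, cols, j, ], nrow = npix))
  }
  structure(list(r = chan_mean(1), g = chan_mean(2), b = chan_mean(3),
                 fs = frames$fs, subject_id = frames$subject_id),
            class = "rgb_trace")
}

# Window starts covering 1..n with hop = len/2; a final window is anchored
# at the end so every sample is covered.
ola_starts <- function(n, len) {
  hop <- max(1L, len %/% 2L)
  starts <- seq.int(1L, n - len + 1L, by = hop)
  if (starts[length(starts)] + len - 1L < n) starts <- c(starts, n - len + 1L)
  starts
}

#' Project an RGB trace onto a pulse signal
#'
#' Demixes the pulsatile skin-color component from the three camera
#' channels. The default chrominance (CHROM) method normalizes each channel
#' by its short-window mean and combines the fixed chrominance signals
#' `X = 3*r - 2*g` and `Y = 1.5*r + g - 1.5*b` as `X - (sd(X)/sd(Y)) * Y`,
#' which cancels intensity (motion/illumination) modulation while retaining
#' the pulse. Windows of `window_s` seconds with 50% overlap are blended by
#' a raised-cosine overlap-add. `POS` (plane-orthogonal-to-skin) and the
#' plain mean-centered `GREEN` channel are provided for comparison.
#'
#' @param trace An `rgb_trace`.
#' @param method `"CHROM"` (default), `"POS"` or `"GREEN"`.
#' @param window_s Analysis window length in seconds (default 1.6).
#' @return An `rppg_signal` with stage `"RAW"`, same length as the trace.
#' @export
chrominance_project <- function(trace, method = c("CHROM", "POS", "GREEN"),
                                window_s = 1.6) {
  stopifnot(inherits(trace, "rgb_trace"))
  method <- match.arg(method)
  n <- length(trace$r)
  fs <- trace$fs
  if (method == "GREEN") {
    return(new_rppg_signal(trace$g - mean(trace$g), fs, "RAW",
                           trace$subject_id))
  }
  len <- round(window_s * fs)
  if (n < len)
    stopf("trace (%d samples) shorter than one %g-s analysis window",
          n, window_s)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  out <- numeric(n)
  wsum <- numeric(n)
  norm1 <- function(x) {
    m <- mean(x)
    if (abs(m) < 1e-12) rep(1, length(x)) else x / m
  }
  for (s in ola_starts(n, len)) {
    idx <- s:(s + len - 1L)
    rn <- norm1(trace$r[idx]); gn <- norm1(trace$g[idx])
    bn <- norm1(trace$b[idx])
    if (method == "CHROM") {
      X <- 3 * rn - 2 * gn
      Y <- 1.5 * rn + gn - 1.5 * bn
      sy <- stats::sd(Y)
      S <- if (sy < 1e-12) X else X - (stats::sd(X) / sy) * Y
    } else {  # POS
      S1 <- gn - bn
      S2 <- gn + bn - 2 * rn
      s2 <- stats::sd(S2)
      S <- if (s2 < 1e-12) S1 else S1 + (stats::sd(S1) / s2) * S2
    }
    S <- S - mean(S)
    out[idx] <- out[idx] + taper * S
    wsum[idx] <- wsum[idx] + taper
  }
  pos <- wsum > 1e-12
  out[pos] <- out[pos] / wsum[pos]
  new_rppg_signal(out, fs, "RAW", trace$subject_id)
}

#' Design the pulse bandpass filter
#'
#' Chebyshev type-II bandpass (flat passband, equiripple stopband) with the
#' conventional pulse band of 0.5-3 Hz (30-180 bpm). The cutoffs are the
#' stopband edges at which the response first reaches the requested
#' attenuation. Stability (all poles strictly inside the unit circle) is
#' verified at design time.
#'
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param order Prototype filter order (default 4).
#' @param stopband_db Stopband attenuation in dB (default 40).
#' @return An object of class `filter_spec` with numerator `b` and
#'   denominator `a` coefficients.
#' @export
design_bandpass <- function(fs = 84, f_lo = 0.5, f_hi = 3.0, order = 4,
                            stopband_db = 40) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be positive")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2))
    stopf("band must satisfy 0 < f_lo < f_hi < fs/2 (got %g-%g Hz at fs %g)",
          f_lo, f_hi, fs)
  if (!is_count(order) || order < 1) stopf("order must be a positive integer")
  flt <- signal::cheby2(order, stopband_db, c(f_lo, f_hi) / (fs / 2),
                        type = "pass")
  poles <- polyroot(rev(flt$a))
  if (any(Mod(poles) >= 1))
    stopf("designed filter is unstable (pole modulus %.6f)",
          max(Mod(poles)))
  structure(list(family = "Chebyshev-II", order = order,
                 band = c(f_lo, f_hi), stopband_db = stopband_db, fs = fs,
                 b = as.numeric(flt$b), a = as.numeric(flt$a)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s order %d bandpass %g-%g Hz at fs %g Hz (%g dB stopband)\n",
              x$family, x$order, x$band[1], x$band[2], x$fs, x$stopband_db))
  invisible(x)
}

#' Apply the bandpass filter with zero phase distortion
#'
#' Runs the filter forward and backward (`signal::filtfilt`) so that beat
#' timing is preserved exactly; the effective magnitude response is the
#' squared design response. Output length equals input length.
#'
#' @param sig An `rppg_signal`.
#' @param spec A [design_bandpass()] specification with matching sampling
#'   rate.
#' @return The filtered `rppg_signal` (stage `"FILTERED"`).
#' @export
apply_bandpass <- function(sig, spec) {
  stopifnot(inherits(sig, "rppg_signal"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(sig$fs, spec$fs)))
    stopf("sampling-rate mismatch: signal %g Hz vs filter %g Hz",
          sig$fs, spec$fs)
  y <- signal::filtfilt(spec$b, spec$a, sig$samples)
  new_rppg_signal(y, sig$fs, "FILTERED", sig$subject_id)
}

# Zero-padded periodogram restricted to [f_lo, f_hi]; returns freq/power.
band_periodogram <- function(x, fs, f_lo = 0.5, f_hi = 3.0) {
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n, 2) * 4))
  X <- stats::fft(c(x - mean(x), numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  freq <- (half - 1) * fs / nfft
  power <- Mod(X[half])^2
  keep <- freq >= f_lo & freq <= f_hi
  list(freq = freq[keep], power = power[keep])
}

# Welch-averaged band periodogram: Hann-tapered windows with 50% overlap,
# averaged power. Stabilizes the spectral peak for irregular rhythms, where
# a single full-length periodogram fragments into many narrow lines.
welch_band_periodogram <- function(x, fs, f_lo = 0.5, f_hi = 3.0,
                                   win_s = 20) {
  n <- length(x)
  len <- min(n, round(win_s * fs))
  hop <- max(1L, len %/% 2L)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  nfft <- 2^ceiling(log2(len * 4))
  half <- seq_len(nfft %/% 2 + 1L)
  freq <- (half - 1) * fs / nfft
  keep <- freq >= f_lo & freq <= f_hi
  acc <- numeric(sum(keep))
  nwin <- 0L
  for (s in ola_starts(n, len)) {
    seg <- x[s:(s + len - 1L)]
    seg <- (seg - mean(seg)) * taper
    X <- stats::fft(c(seg, numeric(nfft - len)))
    acc <- acc + Mod(X[half][keep])^2
    nwin <- nwin + 1L
  }
  list(freq = freq[keep], power = acc / nwin)
}

#' Estimate heart rate from a filtered rPPG signal
#'
#' Takes 60 times the frequency of the Welch-averaged periodogram maximum
#' over the pulse band (0.5-3 Hz, i.e. 30-180 bpm). Spectral averaging over
#' overlapping windows keeps the peak on the mean rate even for irregular
#' (AF) rhythms.
#'
#' @param sig A filtered `rppg_signal` of at least 10 s.
#' @param f_lo,f_hi Search band in Hz.
#' @return Heart rate in beats per minute.
#' @export
estimate_hr <- function(sig, f_lo = 0.5, f_hi = 3.0) {
  stopifnot(inherits(sig, "rppg_signal"))
  if (length(sig$samples) / sig$fs < 10)
    stopf("need >= 10 s of signal to estimate heart rate")
  pg <- welch_band_periodogram(sig$samples, sig$fs, f_lo, f_hi)
  60 * pg$freq[which.max(pg$power)]
}

#' Signal quality check
#'
#' Computes an in-band signal-to-noise ratio: the power within 0.1 Hz of
#' the dominant pulse-band peak and of its first harmonic, against the
#' remaining pulse-band power, in dB. Recordings below the threshold are
#' flagged for exclusion, the analog of discarding clinically unreadable
#' rPPG traces.
#'
#' @param sig A filtered `rppg_signal` of at least 30 s.
#' @param threshold_db Pass threshold in dB (default 2).
#' @return List with `pass`, `snr_db` (`NA` with `undefined = TRUE` for an
#'   all-zero signal).
#' @export
quality_check <- function(sig, threshold_db = 2) {
  stopifnot(inherits(sig, "rppg_signal"))
  if (length(sig$samples) / sig$fs < 30)
    stopf("need >= 30 s of signal for the quality check")
  if (all(sig$samples == 0))
    return(list(pass = FALSE, snr_db = NA_real_, undefined = TRUE))
  pg <- band_periodogram(sig$samples, sig$fs)
  f0 <- pg$freq[which.max(pg$power)]
  sig_mask <- abs(pg$freq - f0) <= 0.1 | abs(pg$freq - 2 * f0) <= 0.1
  p_sig <- sum(pg$power[sig_mask])
  p_noise <- sum(pg$power[!sig_mask])
  snr <- 10 * log10(p_sig / max(p_noise, .Machine$double.xmin))
  list(pass = snr >= threshold_db, snr_db = snr, undefined = FALSE)
}

#' Extract the filtered rPPG signal from a subject record
#'
#' Convenience wrapper composing [chrominance_project()] and
#' [apply_bandpass()] on a subject's RGB trace.
#'
#' @param record A `subject_record` (or an `rgb_trace`).
#' @param method Projection method, see [chrominance_project()].
#' @param spec Optional pre-designed `filter_spec`; defaults to the
#'   standard 4th-order Chebyshev-II 0.5-3 Hz design at the trace rate.
#' @return A filtered `rppg_signal`.
#' @export
extract_rppg <- function(record, method = "CHROM", spec = NULL) {
  trace <- if (inherits(record, "subject_record")) record$trace else record
  stopifnot(inherits(trace, "rgb_trace"))
  if (is.null(spec)) spec <- design_bandpass(fs = trace$fs)
  apply_bandpass(chrominance_project(trace, method = method), spec)
}
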