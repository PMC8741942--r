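# Shared fixtures, built in code at test time.

# A small convolutional architecture for fast training tests; same layer
# pattern as the default, fewer channels.
small_arch <- function(input_length = 2520) {
  arch_config(input_length = input_length,
              channel_widths = c(8, 8, 16, 16, 32),
              pool_after = 1:5, pool_size = 3, dropout_rate = 0.5)
}

# Deterministic toy segment: pulse waveform of a regular (NSR) or
# irregular (AF) rhythm, z-scored, `seg_len` seconds at 84 Hz.
toy_segment <- function(irregular, seed, seg_len = 30, fs = 84) {
  rr <- simulate_rr(if (irregular) "AF" else "NSR", mean_hr = 75,
                    duration = seg_len + 1, seed = seed)
  x <- render_pulse(rr, fs)$samples[seq_len(round(seg_len * fs))]
  (x - mean(x)) / stats::sd(x)
}

# A linearly separable toy dataset in task_dataset form.
toy_dataset <- function(n_per_class = 30, seg_len = 30, fs = 84) {
  X <- cbind(
    vapply(seq_len(n_per_class), function(s) toy_segment(FALSE, s, seg_len),
           numeric(round(seg_len * fs))),
    vapply(seq_len(n_per_class), function(s)
      toy_segment(TRUE, 10000 + s, seg_len), numeric(round(seg_len * fs))))
  structure(list(
    task = "AF_vs_NSR", X = X,
    subject_id = paste0("T", rep(seq_len(2 * n_per_class))),
    segment_index = rep(0L, 2 * n_per_class),
    label01 = rep(c(0L, 1L), each = n_per_class),
    group = rep(c("NSR", "AF"), each = n_per_class),
    seg_len = seg_len, fs = fs), class = "task_dataset")
}

# Hand-built prepared-subject entries (the assemble_dataset input) without
# running the signal chain: `spec` is a named vector group -> count; each
# subject gets `n_seg` trivial segments.
fake_subjects <- function(spec, n_seg = 3, seg_len = 30, fs = 4) {
  L <- round(seg_len * fs)
  out <- list()
  i <- 0L
  for (g in names(spec)) for (j in seq_len(spec[[g]])) {
    i <- i + 1L
    sid <- sprintf("F%03d", i)
    segs <- lapply(seq_len(n_seg) - 1L, function(k) {
      structure(list(samples = sin(seq_len(L) + i + k), subject_id = sid,
                     segment_index = k, label01 = NA_integer_,
                     seg_len = seg_len, fs = fs, degenerate = FALSE),
                class = "rppg_segment")
    })
    lab <- if (g %in% c("AF", "NSR")) rhythm_label(g)
           else rhythm_label("OTHER", "APC")
    out[[i]] <- list(subject_id = sid, label = lab,
                     group = lab$group, segments = segs, excluded = FALSE,
                     snr_db = NA_real_)
  }
  out
}

# Mann-Whitney concordance AUC: fraction of positive/negative pairs with
# the positive scored higher, ties counted half. O(n_pos * n_neg) oracle.
mw_auc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Direct evaluation of a digital filter's frequency response at `f` Hz,
# independent of the signal package.
freq_response_db <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(b) - 1))
    num <- sum(b * z)
    den <- sum(a * exp(-1i * wi * (seq_along(a) - 1)))
    abs(num / den)
  }, numeric(1))
  20 * log10(H)
}
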