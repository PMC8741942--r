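# Segmentation of filtered rPPG signals into fixed-length normalized clips
# and assembly of the binary classification datasets.

TASKS <- c("AF_vs_NSR", "AF_vs_Others", "AF_vs_NonAF")

#' Cut a signal into fixed-length segments
#'
#' Non-overlapping consecutive windows of `seg_len` seconds, anchored at
#' the first sample; the trailing remainder shorter than `seg_len` is
#' discarded, so a recording of duration `D` yields `floor(D / seg_len)`
#' segments (a 10-min recording gives twenty 30-s segments).
#'
#' @param sig A filtered `rppg_signal`.
#' @param seg_len Segment length in seconds (> 0), default 30.
#' @return List of `rppg_segment` objects (possibly empty), each with
#'   `samples`, `subject_id`, `segment_index` (0-based), `seg_len`, `fs`,
#'   `label01 = NA`.
#' @export
segment_signal <- function(sig, seg_len = 30) {
  stopifnot(inherits(sig, "rppg_signal"))
  if (!is_scalar_num(seg_len) || seg_len <= 0)
    stopf("seg_len must be a positive number of seconds")
  L <- round(seg_len * sig$fs)
  n_seg <- length(sig$samples) %/% L
  lapply(seq_len(n_seg), function(i) {
    structure(list(
      samples = sig$samples[((i - 1L) * L + 1L):(i * L)],
      subject_id = sig$subject_id,
      segment_index = i - 1L,
      label01 = NA_integer_,
      seg_len = seg_len,
      fs = sig$fs,
      degenerate = FALSE
    ), class = "rppg_segment")
  })
}

#' Z-normalize a segment
#'
#' Centers and scales a segment to zero mean and unit variance, making the
#' classifier input invariant to the arbitrary amplitude units of rPPG. A
#' (near-)constant segment cannot be scaled and is returned as all zeros
#' with `degenerate = TRUE`. The operation is idempotent.
#'
#' @param seg An `rppg_segment`.
#' @return The normalized segment.
#' @export
normalize_segment <- function(seg) {
  stopifnot(inherits(seg, "rppg_segment"))
  s <- stats::sd(seg$samples)
  if (!is.finite(s) || s < 1e-12) {
    seg$samples <- numeric(length(seg$samples))
    seg$degenerate <- TRUE
  } else {
    seg$samples <- (seg$samples - mean(seg$samples)) / s
    seg$degenerate <- FALSE
  }
  seg
}

#' Extract, filter and segment a whole cohort
#'
#' Runs the rPPG front end ([extract_rppg()]) on every subject, optionally
#' drops subjects failing the [quality_check()], and cuts each filtered
#' signal into z-normalized segments.
#'
#' @param cohort List of `subject_record`s.
#' @param seg_len Segment length in seconds.
#' @param method Projection method for [chrominance_project()].
#' @param quality_threshold_db If non-`NULL`, subjects with in-band SNR
#'   below this value are excluded (marked, not silently dropped).
#' @return List of per-subject entries: `subject_id`, `label`, `group`,
#'   `segments` (list), `excluded` (logical), `snr_db`.
#' @export
prepare_segments <- function(cohort, seg_len = 30, method = "CHROM",
                             quality_threshold_db = NULL) {
  spec <- design_bandpass(fs = cohort[[1]]$fs)
  lapply(cohort, function(rec) {
    sig <- extract_rppg(rec, method = method, spec = spec)
    snr <- NA_real_
    excluded <- FALSE
    if (!is.null(quality_threshold_db)) {
      qc <- quality_check(sig, threshold_db = quality_threshold_db)
      snr <- qc$snr_db
      excluded <- !qc$pass
    }
    segs <- if (excluded) list() else
      lapply(segment_signal(sig, seg_len), normalize_segment)
    list(subject_id = rec$subject_id, label = rec$label,
         group = rec$label$group, segments = segs, excluded = excluded,
         snr_db = snr)
  })
}

task_label01 <- function(group, task) {
  switch(task,
    AF_vs_NSR = if (group == "AF") 1L else if (group == "NSR") 0L else NA_integer_,
    AF_vs_Others = if (group == "AF") 1L else if (group == "OTHER") 0L else NA_integer_,
    AF_vs_NonAF = if (group == "AF") 1L else 0L)
}

#' Assemble a binary task dataset
#'
#' Filters subjects by task ("AF vs NSR" excludes other abnormalities,
#' "AF vs Others" excludes normal sinus rhythm, "AF vs Non-AF" keeps all)
#' and labels every segment with its subject's group: AF segments are 1 in
#' every task, all segments of one subject share one label.
#'
#' @param subjects Output of [prepare_segments()] (excluded subjects are
#'   skipped).
#' @param task One of `"AF_vs_NSR"`, `"AF_vs_Others"`, `"AF_vs_NonAF"`.
#' @return An object of class `task_dataset`: `task`, `X` (samples x
#'   segments matrix), `subject_id`, `segment_index`, `label01`, `group`
#'   (per-segment vectors), `seg_len`, `fs`.
#' @export
assemble_dataset <- function(subjects, task = c("AF_vs_NonAF", "AF_vs_NSR",
                                                "AF_vs_Others")) {
  task <- match.arg(task)
  keep <- Filter(function(s) {
    !isTRUE(s$excluded) && !is.na(task_label01(s$group, task))
  }, subjects)
  if (!length(keep)) stopf("no subjects left after task filtering")
  n_empty <- sum(vapply(keep, function(s) length(s$segments) == 0L,
                        logical(1)))
  if (n_empty > 0)
    stopf("%d subject(s) have no segments; every subject needs >= 1", n_empty)
  seg_list <- list(); sid <- character(0); sidx <- integer(0)
  lab <- integer(0); grp <- character(0)
  for (s in keep) {
    l01 <- task_label01(s$group, task)
    for (seg in s$segments) {
      seg_list[[length(seg_list) + 1L]] <- seg$samples
      sid <- c(sid, s$subject_id)
      sidx <- c(sidx, seg$segment_index)
      lab <- c(lab, l01)
      grp <- c(grp, s$group)
    }
  }
  if (length(unique(lab)) < 2L)
    stopf("task '%s' needs both classes present (got only label %d)",
          task, unique(lab))
  first <- keep[[1]]$segments[[1]]
  structure(list(task = task, X = do.call(cbind, seg_list),
                 subject_id = sid, segment_index = sidx, label01 = lab,
                 group = grp, seg_len = first$seg_len, fs = first$fs),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> %s: %d segments (%d positive) from %d subjects, %g-s windows at %g Hz\n",
              x$task, ncol(x$X), sum(x$label01), length(unique(x$subject_id)),
              x$seg_len, x$fs))
  invisible(x)
}

# Restrict a dataset to a subset of segment columns.
subset_dataset <- function(ds, idx) {
  ds$X <- ds$X[, idx, drop = FALSE]
  ds$subject_id <- ds$subject_id[idx]
  ds$segment_index <- ds$segment_index[idx]
  ds$label01 <- ds$label01[idx]
  ds$group <- ds$group[idx]
  ds
}
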