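# Trace file I/O, run configuration, metrics-report serialization and the
# end-to-end pipeline driver.

#' Save / load an RGB trace
#'
#' Delimited-text trace format: comma-separated with the exact header
#' `time_s,r,g,b`, one row per sample. Values are written with 17
#' significant digits so a save-load round trip reproduces them exactly;
#' on load, the sampling rate is inferred from the time column, which must
#' be strictly increasing with a constant interval (to 1e-9 s).
#'
#' @param trace An `rgb_trace`.
#' @param path File path.
#' @param subject_id Identifier attached to the loaded trace.
#' @return `load_trace` returns an `rgb_trace`; `save_trace` returns
#'   `path` invisibly.
#' @export
save_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rgb_trace"))
  n <- length(trace$r)
  time_s <- (seq_len(n) - 1) / trace$fs
  lines <- c("time_s,r,g,b",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     time_s, trace$r, trace$g, trace$b))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_trace
#' @export
load_trace <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stopf("trace file '%s' does not exist", path)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("time_s", "r", "g", "b")
  if (!identical(names(df), expected)) {
    bad <- which(names(df) != expected)[1]
    stopf("trace header mismatch at column %d: expected '%s', found '%s'",
          bad, expected[bad],
          if (bad <= length(names(df))) names(df)[bad] else "<missing>")
  }
  if (nrow(df) < 2) stopf("trace needs >= 2 samples")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stopf("time column must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stopf("sampling interval varies by %.3g s (> 1e-9 s tolerance)",
          max(dt) - min(dt))
  fs <- 1 / mean(dt)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(r = df$r, g = df$g, b = df$b, fs = fs,
                 subject_id = subject_id), class = "rgb_trace")
}

#' Save / load an rPPG signal
#'
#' Delimited text `time_s,value` plus a JSON sidecar (`<path>.meta.json`)
#' recording the processing stage, sampling rate and subject id.
#'
#' @param sig An `rppg_signal`.
#' @param path File path for the signal table.
#' @return `load_rppg` returns an `rppg_signal`; `save_rppg` returns
#'   `path` invisibly.
#' @export
save_rppg <- function(sig, path) {
  stopifnot(inherits(sig, "rppg_signal"))
  n <- length(sig$samples)
  writeLines(c("time_s,value",
               sprintf("%.17g,%.17g", (seq_len(n) - 1) / sig$fs,
                       sig$samples)), path)
  jsonlite::write_json(list(stage = sig$stage, fs = sig$fs,
                            subject_id = sig$subject_id),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_rppg
#' @export
load_rppg <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time_s", "value")))
    stopf("expected header 'time_s,value' in '%s'", path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  new_rppg_signal(df$value, meta$fs, meta$stage, meta$subject_id)
}

#' Save a cohort's traces and manifest
#'
#' Writes every subject's RGB trace as delimited text plus a cohort
#' manifest `subject_id,group,subtype,duration_s,trace_path,seed`.
#'
#' @param cohort List of `subject_record`s.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(cohort, function(rec) {
    f <- paste0(rec$subject_id, ".csv")
    save_trace(rec$trace, file.path(dir, f))
    sprintf("%s,%s,%s,%g,%s,%d", rec$subject_id, rec$label$group,
            rec$label$subtype, rec$duration, f, rec$seed)
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("subject_id,group,subtype,duration_s,trace_path,seed", rows),
             manifest)
  invisible(manifest)
}

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with the conventional defaults:
#' 84 Hz sampling, 4th-order Chebyshev-II 0.5-3 Hz bandpass, 30-s
#' segments, 10 folds, strict 0.5 vote threshold, 15-300 s sweep lengths.
#' The default cohort is small (12 subjects) so the full pipeline runs in
#' minutes; scale `simulate` up for cohort-sized experiments.
#'
#' @return Nested configuration list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    simulate = list(n_af = 4L, n_nsr = 4L,
                    n_other = list(APC = 2L, SINUS_ARRHYTHMIA = 2L),
                    duration_range = c(120, 300), fs = 84,
                    noise = default_noise_params(), master_seed = 1L),
    extract = list(method = "CHROM", f_lo = 0.5, f_hi = 3.0, order = 4L,
                   stopband_db = 40, quality_threshold_db = NULL),
    segment = list(seg_len = 30, task = "AF_vs_NonAF"),
    train = list(epochs = 10L, batch_size = 32L, lr = 1e-3,
                 val_fraction = 0, patience = 10L, augment = TRUE,
                 class_weights = "auto", seed = 1L),
    folds = list(k = 4L, grouping = "SUBJECT_LEVEL", seed = 1L),
    vote = list(call_threshold = 0.5, vote_threshold = 0.5),
    sweep = list(enabled = FALSE, lengths = c(15, 30, 60, 120, 240, 300),
                 k = 3L)
  ), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stopf("unknown configuration key '%s'", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stopf("configuration key '%s' must be a section", key)
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys
#' are rejected with the offending key path.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), user)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$segment$seg_len <= 0) stopf("segment.seg_len must be > 0")
  if (!cfg$segment$task %in% TASKS)
    stopf("segment.task must be one of: %s", paste(TASKS, collapse = ", "))
  if (cfg$extract$f_lo <= 0 || cfg$extract$f_lo >= cfg$extract$f_hi ||
      cfg$extract$f_hi >= cfg$simulate$fs / 2)
    stopf("extract band must satisfy 0 < f_lo < f_hi < fs/2")
  if (cfg$folds$k < 2) stopf("folds.k must be >= 2")
  invisible(cfg)
}

#' Serialize a cross-validation metrics report
#'
#' Machine-readable JSON holding the task id, grouping mode, fold-wise
#' segment metrics, pooled confusion counts and rates (with undefined
#' ratios marked explicitly, never zeroed), AUCs and the subject vote
#' table. `read_metrics_report` restores it.
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @param path Destination `.json` file.
#' @return `read_metrics_report` returns the report list;
#'   `write_metrics_report` returns `path` invisibly.
#' @export
write_metrics_report <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  needed <- c("task", "grouping", "k", "segment", "subject")
  missing <- setdiff(needed, names(cv))
  if (length(missing))
    stopf("incomplete report: missing %s", paste(missing, collapse = ", "))
  pooled_block <- function(m) list(
    tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
    sensitivity = m$sensitivity, specificity = m$specificity,
    ppv = m$ppv, accuracy = m$accuracy,
    undefined = as.list(m$undefined))
  obj <- list(
    format = "rppgaf-metrics", version = 1L,
    task = cv$task, grouping = cv$grouping, k = cv$k,
    segment = list(per_fold = cv$segment$per_fold,
                   pooled = pooled_block(cv$segment$pooled),
                   auc = cv$segment$roc$auc),
    subject = list(votes = cv$subject$votes,
                   per_fold = cv$subject$per_fold,
                   pooled = pooled_block(cv$subject$pooled),
                   auc = if (!is.null(cv$subject$roc)) cv$subject$roc$auc
                         else NULL)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rppgaf-metrics"))
    stopf("'%s' is not a metrics report", path)
  obj
}

#' Run the full pipeline
#'
#' Simulate a cohort, extract and filter rPPG signals, segment, assemble
#' the configured task dataset, cross-validate the classifier, vote
#' subjects, and write every result (plus the configuration itself, for
#' provenance) into `out_dir`. The run is deterministic: the same
#' configuration always produces bit-identical metrics files.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @param out_dir Output directory (created; existing files overwritten).
#' @return The `cv_result`, invisibly; side effect: `config.yaml`,
#'   `metrics.json`, `segment_folds.csv`, `subject_votes.csv`,
#'   `roc_segments.csv`, `roc_subjects.csv`, optional `sweep.csv`, and
#'   `pipeline.log` in `out_dir`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  logmsg <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                stage, sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))

  cohort <- run_stage("simulate", {
    spec <- cohort_spec(
      n_af = cfg$simulate$n_af, n_nsr = cfg$simulate$n_nsr,
      n_other = unlist(cfg$simulate$n_other),
      duration_range = cfg$simulate$duration_range, fs = cfg$simulate$fs,
      noise_params = cfg$simulate$noise,
      master_seed = cfg$simulate$master_seed)
    simulate_cohort(spec)
  })
  logmsg("simulate", "%d subjects generated", length(cohort))

  subjects <- run_stage("extract", {
    prepare_segments(cohort, seg_len = cfg$segment$seg_len,
                     method = cfg$extract$method,
                     quality_threshold_db = cfg$extract$quality_threshold_db)
  })
  n_excl <- sum(vapply(subjects, function(s) isTRUE(s$excluded), logical(1)))
  logmsg("extract", "%d subjects extracted, %d excluded by quality check",
         length(subjects) - n_excl, n_excl)

  ds <- run_stage("segment", assemble_dataset(subjects, cfg$segment$task))
  logmsg("segment", "%s: %d segments (%d AF) from %d subjects",
         ds$task, ncol(ds$X), sum(ds$label01),
         length(unique(ds$subject_id)))

  cv <- run_stage("evaluate", {
    folds <- make_folds(ds, k = cfg$folds$k, grouping = cfg$folds$grouping,
                        seed = cfg$folds$seed)
    tcfg <- train_config(epochs = cfg$train$epochs,
                         batch_size = cfg$train$batch_size,
                         lr = cfg$train$lr, seed = cfg$train$seed,
                         val_fraction = cfg$train$val_fraction,
                         patience = cfg$train$patience,
                         augment = cfg$train$augment,
                         class_weights = cfg$train$class_weights)
    cross_validate(ds, folds, tcfg,
                   call_threshold = cfg$vote$call_threshold,
                   vote_threshold = cfg$vote$vote_threshold)
  })
  logmsg("evaluate", "segment acc %.4f, subject acc %.4f",
         cv$segment$pooled$accuracy, cv$subject$pooled$accuracy)

  write_metrics_report(cv, file.path(out_dir, "metrics.json"))
  utils::write.csv(cv$segment$per_fold,
                   file.path(out_dir, "segment_folds.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$subject$votes,
                   file.path(out_dir, "subject_votes.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$segment$roc$points,
                   file.path(out_dir, "roc_segments.csv"),
                   row.names = FALSE)
  if (!is.null(cv$subject$roc))
    utils::write.csv(cv$subject$roc$points,
                     file.path(out_dir, "roc_subjects.csv"),
                     row.names = FALSE)

  if (isTRUE(cfg$sweep$enabled)) {
    sw <- run_stage("sweep", {
      tcfg <- train_config(epochs = cfg$train$epochs,
                           batch_size = cfg$train$batch_size,
                           lr = cfg$train$lr, seed = cfg$train$seed,
                           val_fraction = cfg$train$val_fraction,
                           augment = cfg$train$augment,
                           class_weights = cfg$train$class_weights)
      segment_length_sweep(cohort, lengths = cfg$sweep$lengths, cfg = tcfg,
                           task = cfg$segment$task, k = cfg$sweep$k,
                           method = cfg$extract$method,
                           seed = cfg$folds$seed)
    })
    utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    logmsg("sweep", "%d lengths evaluated", nrow(sw))
  }
  logmsg("done", "outputs written to %s", out_dir)
  invisible(cv)
}
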