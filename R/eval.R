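# Cross-validation, segment-voting subject prediction, confusion-matrix
# metrics, ROC/AUC, and the segment-length sensitivity sweep.

#' Stratified k-fold assignment
#'
#' Partitions a task dataset into `k` folds stratified by the binary
#' label. Under `SUBJECT_LEVEL` grouping (the default) the unit is the
#' subject, so no subject's segments ever span folds - the leakage-safe
#' mode. `SEGMENT_LEVEL` partitions segments directly, mirroring protocols
#' that split the segment pool into equal-sized sets at the cost of
#' possible subject leakage.
#'
#' Units of each class are shuffled (seeded) and dealt round-robin, so fold
#' sizes differ by at most one unit.
#'
#' @param ds A `task_dataset`.
#' @param k Number of folds (default 10).
#' @param grouping `"SUBJECT_LEVEL"` or `"SEGMENT_LEVEL"`.
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: `k`, `grouping`, `fold`
#'   (fold id per segment), `seed`.
#' @export
make_folds <- function(ds, k = 10, grouping = c("SUBJECT_LEVEL",
                                                "SEGMENT_LEVEL"),
                       seed = 1) {
  stopifnot(inherits(ds, "task_dataset"))
  grouping <- match.arg(grouping)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  k <- as.integer(k)
  n_seg <- ncol(ds$X)
  fold <- integer(n_seg)

  if (grouping == "SEGMENT_LEVEL") {
    if (k > n_seg) stopf("k = %d exceeds the %d segments", k, n_seg)
    with_seed(seed, {
      offset <- 0L
      for (cls in c(1L, 0L)) {
        idx <- sample(which(ds$label01 == cls))
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- offset + length(idx)
      }
    })
  } else {
    subj <- unique(ds$subject_id)
    subj_lab <- ds$label01[match(subj, ds$subject_id)]
    if (k > length(subj))
      stopf("k = %d exceeds the %d subjects", k, length(subj))
    subj_fold <- integer(length(subj)); names(subj_fold) <- subj
    with_seed(seed, {
      offset <- 0L
      for (cls in c(1L, 0L)) {
        idx <- sample(which(subj_lab == cls))
        subj_fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- offset + length(idx)
      }
    })
    fold <- unname(subj_fold[ds$subject_id])
  }
  structure(list(k = as.integer(k), grouping = grouping, fold = fold,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Segment-vote subject prediction
#'
#' Aggregates per-segment AF calls into one subject decision: the AF score
#' is the fraction of segments called AF, and the subject is predicted AF
#' only when the score strictly exceeds the threshold (a score of exactly
#' 0.5 is a non-AF call).
#'
#' @param segment_calls Logical (or 0/1) vector of per-segment AF calls;
#'   at least one segment.
#' @param subject_id Optional identifier.
#' @param threshold Vote threshold (default 0.5, strict inequality).
#' @return An object of class `subject_prediction`: `subject_id`,
#'   `af_score`, `predicted_af`, `n_segments`.
#' @export
vote_subject <- function(segment_calls, subject_id = NA_character_,
                         threshold = 0.5) {
  if (length(segment_calls) == 0L)
    stopf("cannot vote on zero segments")
  calls <- as.logical(segment_calls)
  if (anyNA(calls)) stopf("segment calls must be TRUE/FALSE")
  score <- mean(calls)
  structure(list(subject_id = subject_id, af_score = score,
                 predicted_af = score > threshold,
                 n_segments = length(calls)),
            class = "subject_prediction")
}

#' Confusion-matrix metrics
#'
#' Counts true/false positives and negatives and derives sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), positive predictive value
#' TP/(TP+FP) and accuracy (TP+TN)/n. A ratio with a zero denominator is
#' returned as `NA` with an explicit `undefined` flag rather than being
#' silently zeroed.
#'
#' @param pred,truth Logical (or 0/1) vectors of equal length >= 1.
#' @return An object of class `metrics_report` with counts, the four
#'   rates, and an `undefined` character vector naming any undefined
#'   rates.
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stopf("pred (%d) and truth (%d) differ in length",
          length(pred), length(truth))
  if (length(pred) < 1L) stopf("need at least one prediction")
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (anyNA(pred) || anyNA(truth)) stopf("predictions must be TRUE/FALSE")
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              ppv = rate(tp, tp + fp),
              accuracy = (tp + tn) / length(pred))
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity",
                                            "ppv")], is.na, logical(1))))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("<metrics_report> TP %d FP %d TN %d FN %d | sens %s spec %s ppv %s acc %s\n",
              x$tp, x$fp, x$tn, x$fn, fmt(x$sensitivity),
              fmt(x$specificity), fmt(x$ppv), fmt(x$accuracy)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a "predict positive if score >=
#' threshold" operating point, with tied scores grouped, and integrates
#' the curve by the trapezoidal rule. With ties counted half, the AUC
#' equals the Mann-Whitney concordance probability that a random positive
#' scores above a random negative.
#'
#' @param scores Numeric scores, higher = more AF-like.
#' @param truth Logical (or 0/1) vector; both classes must be present.
#' @return List of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, first row the all-negative operating point) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stopf("length mismatch")
  if (anyNA(scores) || anyNA(truth)) stopf("scores/truth must be complete")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(as.numeric(t), grp, sum)
  fp_g <- tapply(as.numeric(!t), grp, sum)
  tpr <- c(0, cumsum(tp_g) / n_pos)
  fpr <- c(0, cumsum(fp_g) / n_neg)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d operating points\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

mean_sd <- function(x) {
  x <- x[!is.na(x)]
  c(mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) > 1) stats::sd(x) else 0)
}

#' K-fold cross-validation of the segment classifier
#'
#' For each fold, trains on the remaining `k - 1` folds and evaluates on
#' the hold-out, so every segment receives exactly one out-of-fold
#' probability. Reports segment-level metrics per fold (mean and sample
#' SD across folds) plus pooled out-of-fold results, and aggregates the
#' out-of-fold segment calls into per-subject votes.
#'
#' @param ds A `task_dataset`.
#' @param folds A [make_folds()] assignment for `ds`.
#' @param cfg A [train_config()].
#' @param arch Optional [arch_config()]; defaults to the standard
#'   architecture at the dataset's segment length.
#' @param call_threshold Probability threshold turning a segment
#'   probability into a binary AF call (default 0.5).
#' @param vote_threshold Subject vote threshold (strict; default 0.5).
#' @return An object of class `cv_result`; see the elements `segment`
#'   (per-fold data.frame, pooled metrics, pooled AUC, out-of-fold
#'   probabilities) and `subject` (vote table, pooled metrics, vote-score
#'   AUC).
#' @export
cross_validate <- function(ds, folds, cfg = train_config(), arch = NULL,
                           call_threshold = 0.5, vote_threshold = 0.5) {
  stopifnot(inherits(ds, "task_dataset"), inherits(folds, "fold_assignment"))
  if (length(folds$fold) != ncol(ds$X))
    stopf("fold assignment does not match the dataset")
  k <- folds$k
  oof_prob <- rep(NA_real_, ncol(ds$X))
  fold_rows <- list()
  for (f in seq_len(k)) {
    tr <- which(folds$fold != f)
    te <- which(folds$fold == f)
    if (length(unique(ds$label01[tr])) < 2L)
      stopf("fold %d leaves a single-class training set", f)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, f)
    model <- train_model(subset_dataset(ds, tr), fold_cfg, arch = arch)
    p <- predict_proba(model, ds$X[, te, drop = FALSE])
    oof_prob[te] <- p
    calls <- p > call_threshold
    truth <- ds$label01[te] == 1L
    m <- confusion_metrics(calls, truth)
    auc_f <- if (length(unique(truth)) == 2L) roc_auc(p, truth)$auc
             else NA_real_
    fold_rows[[f]] <- data.frame(
      fold = f, n_segments = length(te), auc = auc_f,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, accuracy = m$accuracy)
  }
  per_fold <- do.call(rbind, fold_rows)

  seg_truth <- ds$label01 == 1L
  seg_calls <- oof_prob > call_threshold
  seg_pooled <- confusion_metrics(seg_calls, seg_truth)
  seg_auc <- roc_auc(oof_prob, seg_truth)

  subj <- unique(ds$subject_id)
  votes <- do.call(rbind, lapply(subj, function(sid) {
    idx <- which(ds$subject_id == sid)
    v <- vote_subject(seg_calls[idx], subject_id = sid,
                      threshold = vote_threshold)
    data.frame(subject_id = sid, af_score = v$af_score,
               predicted_af = v$predicted_af,
               truth_af = ds$label01[idx[1]] == 1L,
               n_segments = v$n_segments,
               fold = if (folds$grouping == "SUBJECT_LEVEL")
                 folds$fold[idx[1]] else NA_integer_)
  }))
  subj_pooled <- confusion_metrics(votes$predicted_af, votes$truth_af)
  subj_auc <- if (length(unique(votes$truth_af)) == 2L)
    roc_auc(votes$af_score, votes$truth_af) else NULL

  subj_per_fold <- NULL
  if (folds$grouping == "SUBJECT_LEVEL") {
    subj_per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
      vf <- votes[votes$fold == f, ]
      m <- confusion_metrics(vf$predicted_af, vf$truth_af)
      data.frame(fold = f, n_subjects = nrow(vf),
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 ppv = m$ppv, accuracy = m$accuracy)
    }))
  }

  structure(list(
    task = ds$task, grouping = folds$grouping, k = k,
    segment = list(per_fold = per_fold,
                   mean_sd = sapply(per_fold[, -(1:2)], mean_sd),
                   pooled = seg_pooled, roc = seg_auc,
                   oof_prob = oof_prob, call = seg_calls,
                   truth = seg_truth, fold = folds$fold),
    subject = list(votes = votes, per_fold = subj_per_fold,
                   pooled = subj_pooled, roc = subj_auc)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold (%s)\n", x$task, x$k, x$grouping))
  cat(sprintf("  segment: acc %.3f (pooled), AUC %.3f; per-fold acc %.3f +/- %.3f\n",
              x$segment$pooled$accuracy, x$segment$roc$auc,
              x$segment$mean_sd["mean", "accuracy"],
              x$segment$mean_sd["sd", "accuracy"]))
  cat(sprintf("  subject: acc %.3f over %d subjects%s\n",
              x$subject$pooled$accuracy, nrow(x$subject$votes),
              if (!is.null(x$subject$roc))
                sprintf(", vote-score AUC %.3f", x$subject$roc$auc) else ""))
  invisible(x)
}

# Rebind a trained model to a different input length (the convolutional
# weights are length-agnostic; the global max-pool absorbs the change).
change_input_length <- function(model, input_length) {
  arch <- model$arch
  arch$input_length <- as.integer(input_length)
  arch$layer_lengths <- layer_lengths(arch)
  model$arch <- arch
  model
}

#' Segment-length sensitivity sweep
#'
#' Re-runs segmentation, cross-validation and subject voting for each
#' requested segment length and records the subject-level accuracy,
#' emitting one row per length. Lengths exceeding the shortest recording
#' are flagged (accuracy `NA`), not silently dropped. By default each
#' length is trained from scratch; `reuse_model = TRUE` instead trains
#' once at `reuse_train_len` and applies those weights to every length
#' (cheaper, but the evaluation lengths then differ from the training
#' length).
#'
#' @param cohort List of `subject_record`s.
#' @param lengths Segment lengths in seconds, each within \[15, 300\].
#' @param cfg A [train_config()].
#' @param task Which binary task to evaluate.
#' @param k Folds for the per-length cross-validation.
#' @param method rPPG projection method.
#' @param seed Seed for fold assignment.
#' @param reuse_model If `TRUE`, train a single model at `reuse_train_len`
#'   seconds and reuse it across lengths.
#' @param reuse_train_len Training segment length for the reuse mode.
#' @return data.frame with `seg_len_s`, `subject_accuracy`, `n_subjects`,
#'   `flagged`.
#' @export
segment_length_sweep <- function(cohort, lengths = c(15, 30, 60, 120, 240,
                                                     300),
                                 cfg = train_config(), task = "AF_vs_NonAF",
                                 k = 10, method = "CHROM", seed = 1,
                                 reuse_model = FALSE, reuse_train_len = 30) {
  if (any(lengths < 15 | lengths > 300))
    stopf("segment lengths must lie within [15, 300] s")
  min_dur <- min(vapply(cohort, function(r) r$duration, numeric(1)))

  shared_model <- NULL
  if (reuse_model) {
    subs <- prepare_segments(cohort, seg_len = reuse_train_len,
                             method = method)
    ds <- assemble_dataset(subs, task)
    shared_model <- train_model(ds, cfg)
  }

  rows <- lapply(lengths, function(len) {
    if (len > min_dur)
      return(data.frame(seg_len_s = len, subject_accuracy = NA_real_,
                        n_subjects = NA_integer_, flagged = TRUE))
    subs <- prepare_segments(cohort, seg_len = len, method = method)
    ds <- assemble_dataset(subs, task)
    if (reuse_model) {
      model <- change_input_length(shared_model, nrow(ds$X))
      p <- predict_proba(model, ds)
      calls <- p > 0.5
      subj <- unique(ds$subject_id)
      pred <- vapply(subj, function(sid)
        vote_subject(calls[ds$subject_id == sid])$predicted_af, logical(1))
      truth <- vapply(subj, function(sid)
        ds$label01[ds$subject_id == sid][1] == 1L, logical(1))
      acc <- confusion_metrics(pred, truth)$accuracy
      n_subj <- length(subj)
    } else {
      folds <- make_folds(ds, k = k, seed = seed)
      cv <- cross_validate(ds, folds, cfg)
      acc <- cv$subject$pooled$accuracy
      n_subj <- nrow(cv$subject$votes)
    }
    data.frame(seg_len_s = len, subject_accuracy = acc,
               n_subjects = n_subj, flagged = FALSE)
  })
  do.call(rbind, rows)
}
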