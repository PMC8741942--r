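# Sample-level 1-D deep convolutional binary classifier.
#
# The network maps a fixed-length normalized rPPG segment (one input
# channel) to an AF probability. It follows the sample-level design used in
# raw-waveform audio classification: small (size-3) kernels, repeated
# max-pooling, batch normalization and ReLU after every convolution, a
# global max-pool, dropout, and a single fully-connected output unit -
# 11 convolutional layers plus the head, 12 weight layers in total.
#
# All linear algebra is expressed as BLAS matrix products (im2col
# convolutions), so training a cohort-scale model is practical on one CPU.
# Activations are stored as (channels x (length * batch)) matrices with
# columns ordered time-major within each batch element.

#' Network architecture configuration
#'
#' @param input_length Segment length in samples (default 2520 = 30 s at
#'   84 Hz). Any length that survives the pooling schedule is accepted; the
#'   global max-pool before the head absorbs the remaining temporal extent.
#'   For other segment lengths, [default_arch()] adapts the pooling depth
#'   automatically.
#' @param channel_widths Output channels of the 11 convolutional layers.
#' @param kernel_size Convolution kernel size (odd; default 3).
#' @param pool_after Indices of convolutional layers followed by a
#'   max-pool.
#' @param pool_size Max-pool window (default 3, floor semantics).
#' @param global_pool How the final temporal extent is collapsed before
#'   the head: `"mean"` (default) averages the deep feature maps over
#'   time, so the head sees the *density* of locally detected patterns —
#'   the statistic that separates constant irregularity (AF) from
#'   occasional ectopy; `"max"` keeps only the strongest activation
#'   (existence semantics).
#' @param dropout_rate Dropout on the pooled feature vector before the
#'   fully-connected head (training only).
#' @param conv_dropout Channel-wise (spatial) dropout applied after each
#'   convolutional block during training; regularizes against
#'   subject-level memorization on small cohorts.
#' @param batchnorm Whether to batch-normalize after every convolution.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_length = 2520,
                        channel_widths = c(16, 16, 32, 32, 64, 64, 64,
                                           128, 128, 128, 256),
                        kernel_size = 3, pool_after = 1:5, pool_size = 3,
                        global_pool = c("mean", "max"),
                        dropout_rate = 0.5, conv_dropout = 0,
                        batchnorm = TRUE) {
  if (kernel_size %% 2 != 1) stopf("kernel_size must be odd")
  if (length(channel_widths) < 1) stopf("need at least one conv layer")
  global_pool <- match.arg(global_pool)
  arch <- structure(list(
    input_length = as.integer(input_length),
    channel_widths = as.integer(channel_widths),
    n_conv_layers = length(channel_widths),
    kernel_size = as.integer(kernel_size),
    pool_after = as.integer(pool_after),
    pool_size = as.integer(pool_size),
    global_pool = global_pool,
    dropout_rate = dropout_rate,
    conv_dropout = conv_dropout,
    batchnorm = isTRUE(batchnorm)
  ), class = "arch_config")
  arch$layer_lengths <- layer_lengths(arch)  # validates the schedule
  arch
}

#' Standard architecture for a given segment length
#'
#' The default layer stack with the pooling depth adapted so the schedule
#' never exhausts the temporal extent: up to seven max-pools, fewer for
#' short segments. This is what [train_model()] builds when no explicit
#' architecture is supplied, and what the segment-length sweep uses across
#' window lengths.
#'
#' @param input_length Segment length in samples.
#' @return An [arch_config()].
#' @export
default_arch <- function(input_length) {
  n_pool <- min(5L, max(1L, floor(log(input_length / 10) / log(3))))
  arch_config(input_length = input_length, pool_after = seq_len(n_pool))
}

# Temporal length entering each conv layer (and, last element, the length
# entering the global max-pool). Errors if pooling exhausts the signal.
layer_lengths <- function(arch) {
  L <- arch$input_length
  lens <- integer(arch$n_conv_layers + 1L)
  for (l in seq_len(arch$n_conv_layers)) {
    lens[l] <- L
    if (l %in% arch$pool_after) {
      L <- L %/% arch$pool_size
      if (L < 1L)
        stopf("pooling schedule exhausts the temporal length at layer %d (input_length %d too short)",
              l, arch$input_length)
    }
  }
  lens[arch$n_conv_layers + 1L] <- L
  lens
}

#' Number of weight-layer parameters
#'
#' Convolution weights and biases plus the fully-connected head:
#' `sum(k * c_in * c_out + c_out) + (c_last + 1)`. Batch-normalization
#' scale/shift parameters are reported separately.
#'
#' @param arch An `arch_config` (or an `afib_net` model).
#' @return List with `conv_fc` (weight-layer parameters) and `batchnorm`.
#' @export
n_weight_params <- function(arch) {
  if (inherits(arch, "afib_net")) arch <- arch$arch
  c_in <- c(1L, arch$channel_widths[-arch$n_conv_layers])
  c_out <- arch$channel_widths
  conv <- sum(arch$kernel_size * c_in * c_out + c_out)
  head <- c_out[arch$n_conv_layers] + 1L
  bn <- if (arch$batchnorm) 2L * sum(c_out) else 0L
  list(conv_fc = conv + head, batchnorm = bn)
}

#' Build an untrained model
#'
#' Initializes the 12 weight layers (11 convolutional + 1 fully-connected)
#' with He-normal weights, zero biases, and identity batch-norm, all
#' deterministically from `init_seed`.
#'
#' @param arch An [arch_config()].
#' @param init_seed Integer seed for the weight initialization.
#' @return An object of class `afib_net` with `trained = FALSE`.
#' @export
build_model <- function(arch = arch_config(), init_seed = 42) {
  stopifnot(inherits(arch, "arch_config"))
  k <- arch$kernel_size
  c_in <- c(1L, arch$channel_widths[-arch$n_conv_layers])
  c_out <- arch$channel_widths
  params <- with_seed(init_seed, {
    p <- list()
    for (l in seq_len(arch$n_conv_layers)) {
      fan_in <- k * c_in[l]
      p[[paste0("conv", l, ".W")]] <-
        matrix(stats::rnorm(c_out[l] * fan_in, 0, sqrt(2 / fan_in)),
               c_out[l], fan_in)
      p[[paste0("conv", l, ".b")]] <- numeric(c_out[l])
      if (arch$batchnorm) {
        p[[paste0("conv", l, ".gamma")]] <- rep(1, c_out[l])
        p[[paste0("conv", l, ".beta")]] <- numeric(c_out[l])
      }
    }
    nc <- c_out[arch$n_conv_layers]
    p[["fc.w"]] <- stats::rnorm(nc, 0, sqrt(1 / nc))
    p[["fc.b"]] <- 0
    p
  })
  running <- list()
  for (l in seq_len(arch$n_conv_layers)) {
    running[[paste0("conv", l, ".mean")]] <- numeric(c_out[l])
    running[[paste0("conv", l, ".var")]] <- rep(1, c_out[l])
  }
  structure(list(arch = arch, params = params, running = running,
                 init_seed = as.integer(init_seed), trained = FALSE,
                 log = NULL),
            class = "afib_net")
}

#' @export
print.afib_net <- function(x, ...) {
  np <- n_weight_params(x$arch)
  cat(sprintf("<afib_net> %d weight layers, %d conv+fc parameters (%s), input length %d\n",
              x$arch$n_conv_layers + 1L, np$conv_fc,
              if (x$trained) "trained" else "untrained",
              x$arch$input_length))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Forward pass over a batch. X: (input_length x B). Returns probabilities
# and, when `train`, the caches required for the backward pass. Running
# batch-norm statistics are updated in place via the `state` environment
# when training.
nn_forward <- function(model, X, train = FALSE, state = NULL,
                       dropout = FALSE) {
  arch <- model$arch
  p <- model$params
  B <- ncol(X)
  lens <- arch$layer_lengths
  A <- matrix(as.vector(X), nrow = 1L)  # 1 x (L*B), time-major per element
  caches <- if (train) vector("list", arch$n_conv_layers) else NULL

  zero <- numeric(0)
  for (l in seq_len(arch$n_conv_layers)) {
    L <- lens[l]
    has_pool <- l %in% arch$pool_after
    bn <- arch$batchnorm
    fw <- cpp_conv_fwd(
      A, p[[paste0("conv", l, ".W")]], p[[paste0("conv", l, ".b")]],
      if (bn) p[[paste0("conv", l, ".gamma")]] else zero,
      if (bn) p[[paste0("conv", l, ".beta")]] else zero,
      if (bn) model$running[[paste0("conv", l, ".mean")]] else zero,
      if (bn) model$running[[paste0("conv", l, ".var")]] else zero,
      train, bn, has_pool, arch$pool_size, arch$kernel_size, L, B, BN_EPS)
    if (train && bn && !is.null(state)) {
      km <- paste0("conv", l, ".mean"); kv <- paste0("conv", l, ".var")
      state$running[[km]] <- (1 - BN_MOMENTUM) * state$running[[km]] +
        BN_MOMENTUM * as.numeric(fw$mu)
      state$running[[kv]] <- (1 - BN_MOMENTUM) * state$running[[kv]] +
        BN_MOMENTUM * as.numeric(fw$var)
    }
    A_next <- fw$out
    cmask <- NULL
    if (train && dropout && arch$conv_dropout > 0) {
      # channel-wise dropout: whole feature maps dropped per batch element
      keep <- 1 - arch$conv_dropout
      L_out <- ncol(A_next) / B
      mC <- (matrix(stats::runif(nrow(A_next) * B), nrow(A_next), B) <
               keep) / keep
      cmask <- mC[, rep(seq_len(B), each = L_out), drop = FALSE]
      A_next <- A_next * cmask
    }
    if (train)
      caches[[l]] <- list(A_in = A, A_out = A_next, xhat = fw$xhat,
                          invstd = as.numeric(fw$invstd),
                          pidx = fw$pidx, has_pool = has_pool, L = L,
                          cmask = cmask)
    A <- A_next
  }

  # Global pool over the remaining temporal extent: mean (density
  # semantics) or max (existence semantics).
  Lg <- lens[arch$n_conv_layers + 1L]
  C <- nrow(A)
  gmask <- NULL
  if (Lg == 1L) {
    Fmat <- A
  } else if (arch$global_pool == "mean") {
    Fmat <- vapply(seq_len(B), function(b)
      .rowMeans(A[, ((b - 1L) * Lg + 1L):(b * Lg), drop = FALSE], C, Lg),
      numeric(C))
    if (C == 1L) Fmat <- matrix(Fmat, 1L, B)
  } else {
    block <- (0:(B - 1L)) * Lg
    cols <- lapply(seq_len(Lg), function(t) block + t)
    parts <- lapply(cols, function(cc) A[, cc, drop = FALSE])
    Fmat <- do.call(pmax.int, parts)
    dim(Fmat) <- dim(parts[[1]])
    if (train) {
      gmask <- vector("list", Lg)
      cum <- matrix(FALSE, C, B)
      for (t in seq_len(Lg)) {
        m <- (parts[[t]] == Fmat) & !cum
        gmask[[t]] <- m
        cum <- cum | m
      }
    }
  }

  dmask <- NULL
  if (train && dropout && arch$dropout_rate > 0) {
    keep <- 1 - arch$dropout_rate
    dmask <- (matrix(stats::runif(C * B), C, B) < keep) / keep
    Fmat <- Fmat * dmask
  }

  z <- colSums(Fmat * p[["fc.w"]]) + p[["fc.b"]]
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, z = z, Fmat = Fmat, gmask = gmask, dmask = dmask,
       caches = caches, B = B, C = C, Lg = Lg)
}

# Backward pass; `dz` is dLoss/dz (length B). Returns gradients named like
# the parameters.
nn_backward <- function(model, fwd, dz) {
  arch <- model$arch
  p <- model$params
  B <- fwd$B
  grads <- list()
  grads[["fc.w"]] <- as.vector(fwd$Fmat %*% dz)
  grads[["fc.b"]] <- sum(dz)
  dF <- outer(p[["fc.w"]], dz)
  if (!is.null(fwd$dmask)) dF <- dF * fwd$dmask

  Lg <- fwd$Lg
  if (Lg == 1L) {
    dA <- dF
  } else if (arch$global_pool == "mean") {
    dA <- dF[, rep(seq_len(B), each = Lg), drop = FALSE] / Lg
  } else {
    dA <- matrix(0, fwd$C, Lg * B)
    block <- (0:(B - 1L)) * Lg
    for (t in seq_len(Lg)) {
      cc <- block + t
      dA[, cc] <- dF * fwd$gmask[[t]]
    }
  }

  zero <- numeric(0)
  empty_m <- matrix(0, 0, 0)
  for (l in rev(seq_len(arch$n_conv_layers))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$cmask)) dA <- dA * cache$cmask
    bn <- arch$batchnorm
    bw <- cpp_conv_bwd(
      dA, cache$A_in, cache$A_out, p[[paste0("conv", l, ".W")]],
      if (bn) p[[paste0("conv", l, ".gamma")]] else zero,
      if (bn) cache$xhat else empty_m,
      if (bn) cache$invstd else zero,
      cache$pidx, bn, cache$has_pool, arch$pool_size,
      arch$kernel_size, cache$L, B)
    grads[[paste0("conv", l, ".W")]] <- bw$dW
    grads[[paste0("conv", l, ".b")]] <- as.numeric(bw$db)
    if (bn) {
      grads[[paste0("conv", l, ".gamma")]] <- as.numeric(bw$dgamma)
      grads[[paste0("conv", l, ".beta")]] <- as.numeric(bw$dbeta)
    }
    dA <- bw$dA
  }
  grads
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate (initial; decays to a tenth over the run
#'   under the cosine schedule).
#' @param lr_schedule `"cosine"` (default) or `"constant"`.
#' @param seed Integer seed; fully determines initialization, shuffling,
#'   dropout and the validation split.
#' @param val_fraction Fraction of the training pool held out (stratified;
#'   whole subjects when subject ids are available, so validation measures
#'   cross-subject generalization) for early stopping; 0 disables it.
#' @param patience Early-stop patience in epochs (on validation loss).
#' @param weight_decay Decoupled L2 penalty on convolution and head
#'   weights (not biases or batch-norm parameters).
#' @param augment If `TRUE`, apply random tempo-compression augmentation to
#'   every training batch: each segment is resampled at a random factor
#'   from `stretch_range` (with a random crop offset) and re-standardized.
#'   A subject's apparent heart rate then varies from epoch to epoch, which
#'   prevents the network from memorizing per-subject rate signatures and
#'   forces it onto rate-invariant rhythm features. Validation and test
#'   segments are never augmented.
#' @param stretch_range Tempo-compression factors (both <= 1; a factor `s`
#'   multiplies the apparent rate by `1/s`).
#' @param class_weights `NULL` (uniform), `"auto"` (inverse class
#'   frequency), or a length-2 numeric `c(w0, w1)`.
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, lr = 1e-3,
                         lr_schedule = c("cosine", "constant"), seed = 1,
                         val_fraction = 0.1, patience = 10,
                         weight_decay = 1e-4, augment = TRUE,
                         stretch_range = c(0.85, 1),
                         class_weights = NULL, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = match.arg(lr_schedule),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 patience = as.integer(patience),
                 weight_decay = weight_decay, augment = isTRUE(augment),
                 stretch_range = stretch_range,
                 class_weights = class_weights, verbose = isTRUE(verbose)),
            class = "train_config")
}

# Random tempo compression of a batch: segment j is read at stride s_j < 1
# from a random offset (linear interpolation) and re-standardized, so the
# rhythm pattern is preserved while the apparent rate scales by 1/s_j.
augment_stretch <- function(Xb, range) {
  L <- nrow(Xb)
  for (j in seq_len(ncol(Xb))) {
    s <- stats::runif(1L, range[1], range[2])
    span <- (L - 1) * s
    start <- stats::runif(1L, 0, L - 1 - span)
    pos <- start + s * (0:(L - 1))
    i0 <- pmin(floor(pos), L - 2)
    frac <- pos - i0
    x <- Xb[, j]
    v <- x[i0 + 1L] * (1 - frac) + x[i0 + 2L] * frac
    sd_ <- stats::sd(v)
    Xb[, j] <- if (sd_ > 1e-12) (v - mean(v)) / sd_ else v - mean(v)
  }
  Xb
}

bce_loss <- function(prob, y, wt) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(wt * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Train the segment classifier
#'
#' Minimizes (optionally class-weighted) binary cross-entropy with Adam.
#' Deterministic under a fixed `cfg$seed`: initialization, minibatch order,
#' dropout masks and the validation split are all drawn from it. When
#' `val_fraction > 0`, training stops once the validation loss has not
#' improved for `patience` epochs and the best-validation weights are
#' restored.
#'
#' @param ds A `task_dataset` (or any list with `X` samples-by-segments
#'   matrix and `label01` vector) containing both classes.
#' @param cfg A [train_config()].
#' @param arch An [arch_config()]; defaults to the standard architecture at
#'   the dataset's segment length.
#' @return A trained `afib_net` with a per-epoch training log.
#' @export
train_model <- function(ds, cfg = train_config(), arch = NULL) {
  X <- ds$X; y <- ds$label01
  if (is.null(X) || length(y) == 0L) stopf("empty training data")
  if (length(unique(y)) < 2L)
    stopf("training data must contain both classes")
  if (is.null(arch)) arch <- default_arch(nrow(X))
  if (nrow(X) != arch$input_length)
    stopf("segment length %d does not match architecture input_length %d",
          nrow(X), arch$input_length)

  model <- build_model(arch, init_seed = cfg$seed)
  state <- new.env(parent = emptyenv())
  state$running <- model$running

  wt_class <- c(1, 1)
  if (identical(cfg$class_weights, "auto")) {
    n <- length(y)
    wt_class <- c(n / (2 * sum(y == 0)), n / (2 * sum(y == 1)))
  } else if (is.numeric(cfg$class_weights) &&
             length(cfg$class_weights) == 2L) {
    wt_class <- cfg$class_weights
  }
  wt_all <- wt_class[y + 1L]

  log_rows <- list()
  best <- list(loss = Inf, params = NULL, running = NULL, epoch = 0L)
  adam_m <- lapply(model$params, function(x) x * 0)
  adam_v <- lapply(model$params, function(x) x * 0)
  adam_t <- 0L

  with_seed(cfg$seed, {
    n <- length(y)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0) {
      if (!is.null(ds$subject_id) &&
          length(unique(ds$subject_id)) > 3L) {
        # hold out whole subjects so validation loss measures
        # cross-subject generalization, not within-subject recall
        subj <- unique(ds$subject_id)
        subj_lab <- y[match(subj, ds$subject_id)]
        for (cls in c(0L, 1L)) {
          sc <- subj[subj_lab == cls]
          nv <- floor(cfg$val_fraction * length(sc))
          if (nv >= 1 && nv < length(sc))
            val_idx <- c(val_idx,
                         which(ds$subject_id %in% sample(sc, nv)))
        }
      } else {
        for (cls in c(0L, 1L)) {
          ic <- which(y == cls)
          nv <- floor(cfg$val_fraction * length(ic))
          if (nv >= 1 && nv < length(ic))
            val_idx <- c(val_idx, sample(ic, nv))
        }
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr_idx])) < 2L ||
        (length(val_idx) && length(unique(y[val_idx])) < 2L)) {
      tr_idx <- seq_len(n); val_idx <- integer(0)
    }

    for (epoch in seq_len(cfg$epochs)) {
      lr_now <- if (cfg$lr_schedule == "cosine" && cfg$epochs > 1)
        cfg$lr * (0.1 + 0.45 * (1 + cos(pi * (epoch - 1) /
                                          (cfg$epochs - 1))))
      else cfg$lr
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        Xb <- X[, bi, drop = FALSE]
        if (cfg$augment) Xb <- augment_stretch(Xb, cfg$stretch_range)
        yb <- y[bi]; wb <- wt_all[bi]
        fwd <- nn_forward(model, Xb, train = TRUE, state = state,
                          dropout = TRUE)
        loss <- bce_loss(fwd$prob, yb, wb)
        dz <- wb * (fwd$prob - yb) / length(yb)
        grads <- nn_backward(model, fwd, dz)
        adam_t <- adam_t + 1L
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * g
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * g * g
          mhat <- adam_m[[nm]] / (1 - 0.9^adam_t)
          vhat <- adam_v[[nm]] / (1 - 0.999^adam_t)
          step <- mhat / (sqrt(vhat) + 1e-8)
          if (cfg$weight_decay > 0 && grepl("\\.(W|w)$", nm))
            step <- step + cfg$weight_decay * model$params[[nm]]
          model$params[[nm]] <- model$params[[nm]] - lr_now * step
        }
        ep_loss <- ep_loss + loss * length(bi)
        ep_n <- ep_n + length(bi)
        ep_correct <- ep_correct + sum((fwd$prob > 0.5) == (yb == 1))
      }
      model$running <- state$running

      val_loss <- NA_real_; val_acc <- NA_real_
      if (length(val_idx)) {
        pv <- predict_proba(model, X[, val_idx, drop = FALSE])
        val_loss <- bce_loss(pv, y[val_idx], wt_all[val_idx])
        val_acc <- mean((pv > 0.5) == (y[val_idx] == 1))
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n,
        train_acc = ep_correct / ep_n, val_loss = val_loss,
        val_acc = val_acc)
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f acc %.3f  val %.4f/%.3f",
                        epoch, ep_loss / ep_n, ep_correct / ep_n,
                        val_loss, val_acc))

      if (length(val_idx)) {
        if (val_loss < best$loss - 1e-6) {
          best$loss <- val_loss
          best$params <- model$params
          best$running <- model$running
          best$epoch <- epoch
        } else if (epoch - best$epoch >= cfg$patience) break
      }
    }
  })

  if (!is.null(best$params)) {
    model$params <- best$params
    model$running <- best$running
  }
  model$trained <- TRUE
  model$cfg <- cfg
  model$log <- do.call(rbind, log_rows)
  model
}

#' Predict AF probabilities for segments
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no
#' dropout); one probability in \[0, 1\] per segment, independent of batch
#' composition.
#'
#' @param model A (trained) `afib_net`.
#' @param segs A samples-by-segments matrix, a `task_dataset`, a list of
#'   `rppg_segment`s, or a single segment.
#' @param batch_size Internal evaluation batch size.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, segs, batch_size = 256L) {
  stopifnot(inherits(model, "afib_net"))
  X <- if (is.matrix(segs)) segs
  else if (inherits(segs, "task_dataset")) segs$X
  else if (inherits(segs, "rppg_segment")) matrix(segs$samples, ncol = 1L)
  else if (is.list(segs))
    do.call(cbind, lapply(segs, function(s)
      if (inherits(s, "rppg_segment")) s$samples else s))
  else matrix(segs, ncol = 1L)
  if (nrow(X) != model$arch$input_length)
    stopf("segment length %d does not match model input_length %d",
          nrow(X), model$arch$input_length)
  out <- numeric(ncol(X))
  for (b0 in seq(1, ncol(X), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, ncol(X))
    out[bi] <- nn_forward(model, X[, bi, drop = FALSE], train = FALSE)$prob
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file, version-stamped container holding the architecture,
#' parameters, running statistics and training log. A load-save round trip
#' reproduces predictions bit-identically.
#'
#' @param model A trained `afib_net`.
#' @param path Destination file.
#' @return `load_model` returns the `afib_net`; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "afib_net"))
  obj <- list(format = "rppgaf-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rppgaf-checkpoint"))
    stopf("'%s' is not a model checkpoint", path)
  obj$model
}
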