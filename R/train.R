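#' Soft Jaccard loss
#'
#' Per channel `c`, `J_c = (sum(p*t) + eps) / (sum(p) + sum(t) - sum(p*t)
#' + eps)`; the loss is `1 - mean_c(J_c)`, bounded in `[0, 1]`, zero
#' exactly when a binary prediction equals the target.
#'
#' @param pred Probability mask: matrix (samples x 3) or array
#'   (samples x 3 x batch), values in `[0, 1]`.
#' @param target Binary mask of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss.
#' @export
jaccard_loss <- function(pred, target, eps = 1) {
  pred <- unclass(pred); target <- unclass(target)
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  if (is.matrix(pred)) {
    pred <- array(pred, c(dim(pred), 1L))
    target <- array(target, c(dim(target), 1L))
  }
  C <- dim(pred)[2]
  j <- numeric(C)
  for (c in seq_len(C)) {
    p <- pred[, c, ]; t <- target[, c, ]
    inter <- sum(p * t)
    j[c] <- (inter + eps) / (sum(p) + sum(t) - inter + eps)
  }
  1 - mean(j)
}

## Gradient of the soft Jaccard loss w.r.t. the predicted probabilities.
## Works on a (samples x C) matrix or a (samples x C x batch) array.
jaccard_loss_grad <- function(pred, target, eps = 1) {
  C <- dim(pred)[2]
  g <- array(0, dim(pred))
  is_mat <- length(dim(pred)) == 2L
  for (c in seq_len(C)) {
    p <- if (is_mat) pred[, c] else pred[, c, ]
    t <- if (is_mat) target[, c] else target[, c, ]
    inter <- sum(p * t)
    u <- sum(p) + sum(t) - inter + eps
    ## dJ/dp = (t * u - (inter + eps) * (1 - t)) / u^2 ; dloss = -dJ / C
    val <- -(t * u - (inter + eps) * (1 - t)) / (u^2 * C)
    if (is_mat) g[, c] <- val else g[, c, ] <- val
  }
  g
}

#' Subject-wise cross-validation folds
#'
#' Randomly shuffles the subject ids and partitions them into `k`
#' near-equal test sets; every lead and beat of a subject stays on one side
#' of each fold, making subject leakage impossible by construction.
#'
#' @param subject_ids Character vector of unique subject/record ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return An object of class `fold_split`: a list of `k` folds, each with
#'   `train` and `test` id sets.
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1234L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < k)
    stop("need at least k = ", k, " subjects, got ", length(subject_ids))
  set.seed(seed)
  shuffled <- sample(subject_ids)
  groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  folds <- lapply(seq_len(k), function(i) {
    list(train = sort(setdiff(shuffled, groups[[i]])),
         test = sort(groups[[i]]))
  })
  structure(list(k = k, seed = seed, folds = folds), class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d folds, seed %d\n", x$k, x$seed))
  for (i in seq_len(x$k))
    cat(sprintf("  fold %d: %d train / %d test subjects\n", i,
                length(x$folds[[i]]$train), length(x$folds[[i]]$test)))
  invisible(x)
}

#' Training settings
#'
#' @param strategy `"single_lead"` (each lead is an independent training
#'   sample through a 1-channel model) or `"multi_lead"` (leads stacked as
#'   input channels).
#' @param epochs Training epochs.
#' @param batch_size Windows per optimization step.
#' @param lr Adam learning rate.
#' @param window Training window length in samples (must be divisible by
#'   `pool_size^(levels-1)`).
#' @param windows_per_record Random windows drawn per record (per lead for
#'   single-lead) per epoch.
#' @param augmentation An [augmentation_policy()] applied to training
#'   windows, or `NULL` for none.
#' @param seed Seed for the whole training run (default 1234).
#' @param verbose Print the loss each epoch.
#' @return An object of class `train_control`.
#' @export
train_control <- function(strategy = c("single_lead", "multi_lead"),
                          epochs = 50L, batch_size = 16L, lr = 1e-3,
                          window = 512L, windows_per_record = 4L,
                          augmentation = NULL, seed = 1234L,
                          verbose = FALSE) {
  strategy <- match.arg(strategy)
  structure(
    list(strategy = strategy, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), lr = lr,
         window = as.integer(window),
         windows_per_record = as.integer(windows_per_record),
         augmentation = augmentation, seed = as.integer(seed),
         verbose = verbose),
    class = "train_control"
  )
}

adam_init <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_step <- function(opt, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

## Per-lead z-normalization: puts every lead on a common scale so that
## batch statistics are homogeneous across leads and records. Constant
## leads pass through unchanged.
normalize_lead_matrix <- function(sig) {
  for (l in seq_len(ncol(sig))) {
    s <- stats::sd(sig[, l])
    if (s > 0) sig[, l] <- (sig[, l] - mean(sig[, l])) / s
  }
  sig
}

## One training example: a record/lead view plus its full-length mask.
build_training_units <- function(records, fiducials, control, in_channels) {
  units <- list()
  for (id in names(records)) {
    rec <- records[[id]]
    fid <- fiducials[[id]]
    if (is.null(fid)) stop("no annotations for record ", id)
    n <- n_samples(rec)
    if (control$strategy == "single_lead") {
      for (l in seq_len(ncol(rec$signal))) {
        lname <- min(l, length(fid$leads))
        mask <- fiducials_to_mask(fid, n, lead = lname)
        qrs <- lead_waves(fid, lname, "QRS")$on
        units[[length(units) + 1L]] <- list(
          sig = normalize_lead_matrix(rec$signal[, l, drop = FALSE]),
          mask = unclass(mask),
          fs = rec$fs, qrs_on = qrs, id = id)
      }
    } else {
      if (ncol(rec$signal) != in_channels)
        stop("multi_lead model expects ", in_channels, " leads; record ",
             id, " has ", ncol(rec$signal))
      mask <- fiducials_to_mask(fid, n, lead = 1L)
      qrs <- lead_waves(fid, 1L, "QRS")$on
      units[[length(units) + 1L]] <- list(
        sig = normalize_lead_matrix(rec$signal), mask = unclass(mask),
        fs = rec$fs,
        qrs_on = qrs, id = id)
    }
  }
  units
}

#' Fit a U-Net delineator
#'
#' Trains the network on full-record annotations by sampling random
#' fixed-length windows per epoch, optionally augmenting each window with
#' SNR-calibrated noise (labels are noise-invariant), and minimizing the
#' soft Jaccard loss with Adam. The entire run is driven by one seeded RNG
#' stream, so identical inputs and control give bit-identical histories
#' and weights.
#'
#' @param records Named list of [ecg_record()] (names = record ids).
#' @param fiducials Named list of [fiducial_set()] keyed like `records`.
#' @param config A [unet_config()]; `in_channels` must match the strategy.
#' @param control A [train_control()].
#' @param init Optional `ecg_unet` whose weights warm-start training
#'   (e.g. a model pre-trained on low-quality labels).
#' @return A trained `ecg_unet` with a `history` data frame
#'   (epoch, loss).
#' @export
fit_delineator <- function(records, fiducials, config = unet_config(),
                           control = train_control(), init = NULL) {
  stopifnot(inherits(config, "unet_config"),
            inherits(control, "train_control"))
  if (!length(records)) stop("empty training set")
  if (is.null(names(records)) || is.null(names(fiducials)))
    stop("records and fiducials must be named by record id")
  check_input_length(config, control$window)
  if (control$strategy == "single_lead" && config$in_channels != 1L)
    stop("single_lead training requires in_channels = 1")
  model <- if (is.null(init)) build_unet(config) else {
    m <- init; m$config <- config; m
  }
  units <- build_training_units(records, fiducials, control,
                                config$in_channels)
  set.seed(control$seed)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  W <- control$window
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (epoch in seq_len(control$epochs)) {
    ## draw all windows for this epoch
    draws <- list()
    for (u in units) {
      n <- nrow(u$sig)
      for (r in seq_len(control$windows_per_record)) {
        start <- if (n > W) sample.int(n - W + 1L, 1L) else 1L
        draws[[length(draws) + 1L]] <- list(unit = u, start = start)
      }
    }
    draws <- draws[sample.int(length(draws))]
    batches <- split(seq_along(draws),
                     ceiling(seq_along(draws) / control$batch_size))
    epoch_loss <- 0
    for (bi in seq_along(batches)) {
      sel <- batches[[bi]]
      B <- length(sel)
      ## row-blocked batch matrices: window b occupies rows (b-1)*W+1 .. b*W
      X <- matrix(0, W * B, model$config$in_channels)
      Yt <- matrix(0, W * B, 3L)
      for (b in seq_len(B)) {
        dr <- draws[[sel[b]]]
        u <- dr$unit
        idx <- dr$start:(dr$start + W - 1L)
        sig <- u$sig
        if (nrow(sig) < W) {
          sig <- rbind(sig, matrix(0, W - nrow(sig), ncol(sig)))
          idx <- 1:W
        }
        win <- sig[idx, , drop = FALSE]
        if (!is.null(control$augmentation)) {
          qrs_local <- u$qrs_on - (dr$start - 1L)
          qrs_local <- qrs_local[qrs_local >= 0 & qrs_local < W]
          for (ch in seq_len(ncol(win))) {
            win[, ch] <- augment_lead(win[, ch], u$fs,
                                      control$augmentation,
                                      qrs_onsets = qrs_local)
          }
        }
        rows <- ((b - 1L) * W + 1L):(b * W)
        X[rows, ] <- win
        msk <- u$mask
        if (nrow(msk) < W)
          msk <- rbind(msk, matrix(0, W - nrow(msk), 3L))
        Yt[rows, ] <- msk[idx, , drop = FALSE]
      }
      fw <- unet_fwd_mat(model, X, B, training = TRUE)
      model$state <- fw$state
      loss <- jaccard_loss(fw$out, Yt)
      dOut <- jaccard_loss_grad(fw$out, Yt)
      grads <- unet_bwd(model, fw$cache, dOut)
      gflat <- flatten_params(grads)
      stp <- adam_step(opt, theta, gflat, control$lr)
      opt <- stp$opt; theta <- stp$theta
      model$params <- unflatten_params(model$params, theta)
      epoch_loss <- epoch_loss + loss * B
    }
    epoch_loss <- epoch_loss / length(draws)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss))
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f", epoch, epoch_loss))
  }
  model$trained <- TRUE
  model$history <- history
  model$control <- control
  model
}

#' Subject-wise cross-validated training
#'
#' Trains one model per fold on that fold's training subjects only.
#'
#' @param records,fiducials Named lists as in [fit_delineator()].
#' @param folds A [make_folds()] split over `names(records)`.
#' @param config,control As in [fit_delineator()].
#' @param init Optional named list of per-fold warm-start models.
#' @return A list of per-fold fits: each with `model`, `test_ids`,
#'   `train_ids`.
#' @export
cv_delineator <- function(records, fiducials, folds,
                          config = unet_config(),
                          control = train_control(), init = NULL) {
  stopifnot(inherits(folds, "fold_split"))
  lapply(seq_len(folds$k), function(i) {
    f <- folds$folds[[i]]
    if (!length(f$train)) stop("empty training fold ", i)
    warm <- if (is.null(init)) NULL else init[[i]]$model
    model <- fit_delineator(records[f$train], fiducials[f$train], config,
                            control, init = warm)
    list(model = model, train_ids = f$train, test_ids = f$test)
  })
}

#' Semi-supervised pre-training followed by fine-tuning
#'
#' Stage 1 trains each fold's model from scratch on low-quality labels
#' without data augmentation; stage 2 continues from the stage-1 weights on
#' high-quality labels (optionally with augmentation). Fold assignments are
#' identical across both stages.
#'
#' @param records Named list of [ecg_record()].
#' @param high_fiducials,low_fiducials Named lists of high-/low-quality
#'   [fiducial_set()].
#' @param folds A [make_folds()] split.
#' @param config A [unet_config()].
#' @param pre_control,fine_control [train_control()]s for the two stages;
#'   any augmentation policy on `pre_control` is rejected.
#' @return A list of per-fold fits as in [cv_delineator()], with the
#'   stage-1 models attached as `pretrained`.
#' @export
pretrain_then_finetune <- function(records, high_fiducials, low_fiducials,
                                   folds, config = unet_config(),
                                   pre_control = train_control(),
                                   fine_control = train_control()) {
  if (!is.null(pre_control$augmentation))
    stop("no data augmentation is applied during semi-supervised ",
         "pre-training")
  stage1 <- cv_delineator(records, low_fiducials, folds, config,
                          pre_control)
  stage2 <- cv_delineator(records, high_fiducials, folds, config,
                          fine_control, init = stage1)
  for (i in seq_along(stage2)) stage2[[i]]$pretrained <- stage1[[i]]$model
  stage2
}

#' Evaluate cross-validated fits on their held-out subjects
#'
#' @param fits Output of [cv_delineator()] or [pretrain_then_finetune()].
#' @param records,fiducials Full dataset (test subjects are selected per
#'   fold).
#' @param window,overlap,threshold,min_duration_ms Prediction and decoding
#'   settings.
#' @return A list with the pooled [evaluate_delineation()] report and the
#'   per-fold reports.
#' @export
cv_evaluate <- function(fits, records, fiducials, window = 512L,
                        overlap = 0.5, threshold = 0.5,
                        min_duration_ms = 20) {
  per_fold <- vector("list", length(fits))
  pooled_pred <- list(); pooled_truth <- list()
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    strategy <- fit$model$control$strategy
    preds <- list()
    for (id in fit$test_ids) {
      rec <- records[[id]]
      pm <- predict(fit$model, rec, strategy = strategy, window = window,
                    overlap = overlap)
      preds[[id]] <- decode_prediction(pm, rec, threshold, min_duration_ms)
    }
    per_fold[[i]] <- evaluate_delineation(preds, fiducials[fit$test_ids],
                                          strategy = strategy)
    pooled_pred <- c(pooled_pred, preds)
    pooled_truth <- c(pooled_truth, fiducials[fit$test_ids])
  }
  strategy <- fits[[1]]$model$control$strategy
  pooled <- evaluate_delineation(pooled_pred, pooled_truth,
                                 strategy = strategy)
  list(pooled = pooled, per_fold = per_fold)
}

#' Decode predicted probability masks into per-lead wave tables
#'
#' Thresholds each predicted mask and extracts wave onsets, peaks and
#' offsets, using the record's signal to place peaks at the extremal
#' sample of each decoded interval.
#'
#' @param pred_masks A [seg_mask()] (multi-lead prediction) or list of
#'   per-lead masks.
#' @param record The predicted [ecg_record()].
#' @param threshold Binarization threshold.
#' @param min_duration_ms Minimum decoded wave duration in ms.
#' @return A list of per-lead wave tables.
#' @export
decode_prediction <- function(pred_masks, record, threshold = 0.5,
                              min_duration_ms = 20) {
  if (inherits(pred_masks, "seg_mask")) pred_masks <- list(pred_masks)
  lapply(seq_along(pred_masks), function(l) {
    bm <- binarize(pred_masks[[l]], threshold)
    sig_lead <- min(l, ncol(record$signal))
    mask_to_fiducials(bm, signal = record$signal[, sig_lead],
                      min_duration_ms = min_duration_ms)
  })
}

#' Run a small experiment grid
#'
#' Desk-scale counterpart of a model-selection sweep: for every row of the
#' grid, a cross-validated model is trained and evaluated on its held-out
#' subjects, producing one result row per configuration per fold.
#'
#' @param records,fiducials Named dataset lists.
#' @param folds A [make_folds()] split.
#' @param grid Data frame; recognized columns: `block_type`, `levels`,
#'   `blocks_per_level`, `base_width`, `spatial_dropout_p`, `augment`
#'   (logical), `pretrain` (logical). Missing columns use the base
#'   config/control.
#' @param base_config,base_control Defaults for unspecified axes.
#' @param low_fiducials Low-quality labels (required when any `pretrain`).
#' @param window Evaluation window.
#' @return Data frame with one row per (configuration, fold): F1 and
#'   onset/offset error summaries per wave.
#' @export
run_experiment_grid <- function(records, fiducials, folds, grid,
                                base_config = unet_config(),
                                base_control = train_control(),
                                low_fiducials = NULL, window = 512L) {
  results <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    ctl <- base_control
    row <- grid[g, , drop = FALSE]
    for (f in intersect(names(row),
                        c("block_type", "levels", "blocks_per_level",
                          "base_width", "spatial_dropout_p"))) {
      cfg[[f]] <- if (is.factor(row[[f]])) as.character(row[[f]])
                  else row[[f]]
    }
    cfg <- do.call(unet_config, unclass(cfg))
    if (!is.null(row$augment) && isTRUE(row$augment))
      ctl$augmentation <- augmentation_policy()
    use_pre <- !is.null(row$pretrain) && isTRUE(row$pretrain)
    fits <- if (use_pre) {
      if (is.null(low_fiducials)) stop("pretrain requested without ",
                                       "low_fiducials")
      pre_ctl <- ctl; pre_ctl$augmentation <- NULL
      pretrain_then_finetune(records, fiducials, low_fiducials, folds,
                             cfg, pre_ctl, ctl)
    } else {
      cv_delineator(records, fiducials, folds, cfg, ctl)
    }
    ev <- cv_evaluate(fits, records, fiducials, window = window)
    for (i in seq_along(ev$per_fold)) {
      tab <- ev$per_fold[[i]]$waves
      for (w in tab$wave) {
        r <- tab[tab$wave == w, ]
        results[[length(results) + 1L]] <- data.frame(
          grid_row = g, fold = i, wave = w,
          block_type = cfg$block_type, levels = cfg$levels,
          blocks_per_level = cfg$blocks_per_level,
          spatial_dropout_p = cfg$spatial_dropout_p,
          augment = isTRUE(row$augment), pretrain = use_pre,
          precision = r$precision, recall = r$recall, f1 = r$f1,
          on_mean_ms = r$on_mean_ms, on_sd_ms = r$on_sd_ms,
          off_mean_ms = r$off_mean_ms, off_sd_ms = r$off_sd_ms,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, results)
}
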