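#' Correspondence matrix between true and predicted waves
#'
#' `H[i, j] = 1` iff any predicted fiducial (onset, peak or offset) of wave
#' `j` lies in the closed true interval `[on_i, off_i]`, or any true
#' fiducial of wave `i` lies in the closed predicted interval
#' `[on_j, off_j]`.
#'
#' @param true_waves,pred_waves Wave tables (single wave type), ordered by
#'   onset.
#' @return A binary matrix with one row per true wave and one column per
#'   predicted wave.
#' @export
correspondence_matrix <- function(true_waves, pred_waves) {
  for (df in list(true_waves, pred_waves)) {
    if (nrow(df) > 1L && is.unsorted(df$on))
      stop("wave tables must be ordered by onset")
  }
  M <- nrow(true_waves); Mh <- nrow(pred_waves)
  H <- matrix(0L, M, Mh)
  if (M == 0L || Mh == 0L) return(H)
  for (i in seq_len(M)) {
    t_on <- true_waves$on[i]; t_off <- true_waves$off[i]
    t_f <- c(t_on, true_waves$peak[i], t_off)
    for (j in seq_len(Mh)) {
      p_on <- pred_waves$on[j]; p_off <- pred_waves$off[j]
      p_f <- c(p_on, pred_waves$peak[j], p_off)
      if (any(p_f >= t_on & p_f <= t_off) ||
          any(t_f >= p_on & t_f <= p_off)) H[i, j] <- 1L
    }
  }
  H
}

#' Fuse per-lead correspondence matrices with a logical OR
#'
#' @param H_list List of equally sized binary matrices, one per lead.
#' @return The elementwise OR.
#' @export
fuse_leads <- function(H_list) {
  if (!length(H_list)) stop("empty matrix list")
  dims <- vapply(H_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("correspondence matrices differ in dimension across leads")
  out <- H_list[[1]]
  for (H in H_list[-1]) out <- pmax(out, H)
  out
}

#' Detection counts and rates from a fused correspondence matrix
#'
#' TP is the number of matched true waves (rows with at least one 1), FP
#' the number of unmatched predicted waves, FN the number of unmatched
#' true waves. Precision and recall use the convention 0/0 = 1 (an empty
#' prediction against an empty truth is perfect).
#'
#' @param H Fused binary correspondence matrix (rows: truth, columns:
#'   predictions).
#' @param M,M_hat True/predicted wave counts (default from `dim(H)`).
#' @return A one-row data frame with TP, FP, FN, precision, recall, f1.
#' @export
detection_counts <- function(H, M = nrow(H), M_hat = ncol(H)) {
  matched_rows <- if (M) sum(rowSums(H) > 0) else 0L
  matched_cols <- if (M_hat) sum(colSums(H) > 0) else 0L
  TP <- matched_rows
  FP <- M_hat - matched_cols
  FN <- M - matched_rows
  if (TP < 0 || FP < 0 || FN < 0) stop("negative detection count (internal)")
  rates_from_counts(TP, FP, FN)
}

rates_from_counts <- function(TP, FP, FN) {
  precision <- if (TP + FP == 0) 1 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.frame(TP = TP, FP = FP, FN = FN, precision = precision,
             recall = recall, f1 = f1)
}

#' Onset/offset delineation errors over matched waves
#'
#' For each matched true wave, the signed difference (true - predicted, in
#' ms) with minimal absolute value over all matched predictions and leads
#' is taken, separately for onsets and offsets.
#'
#' @param true_waves Canonical truth wave table (one wave type).
#' @param pred_waves_per_lead List of per-lead predicted wave tables.
#' @param H_list The per-lead correspondence matrices against
#'   `true_waves`.
#' @param fs Sampling frequency (Hz) for ms conversion.
#' @return List with vectors `on_err_ms`, `off_err_ms` (one entry per
#'   matched true wave).
#' @export
delineation_errors <- function(true_waves, pred_waves_per_lead, H_list,
                               fs) {
  ms <- 1000 / fs
  on_err <- numeric(0); off_err <- numeric(0)
  M <- nrow(true_waves)
  if (M == 0L) return(list(on_err_ms = numeric(0), off_err_ms = numeric(0)))
  for (i in seq_len(M)) {
    best_on <- NA_real_; best_off <- NA_real_
    for (l in seq_along(H_list)) {
      js <- which(H_list[[l]][i, ] == 1L)
      for (j in js) {
        d_on <- (true_waves$on[i] - pred_waves_per_lead[[l]]$on[j]) * ms
        d_off <- (true_waves$off[i] - pred_waves_per_lead[[l]]$off[j]) * ms
        if (is.na(best_on) || abs(d_on) < abs(best_on)) best_on <- d_on
        if (is.na(best_off) || abs(d_off) < abs(best_off)) best_off <- d_off
      }
    }
    if (!is.na(best_on)) {
      on_err <- c(on_err, best_on); off_err <- c(off_err, best_off)
    }
  }
  list(on_err_ms = on_err, off_err_ms = off_err)
}

#' Dice overlap between two binary masks
#'
#' @param mask_a,mask_b Binary [seg_mask()]s (or plain matrices) of equal
#'   shape.
#' @return Named per-channel vector `2|A∩B| / (|A| + |B|)`; 1 when both
#'   channels are empty.
#' @export
dice_score <- function(mask_a, mask_b) {
  a <- unclass(mask_a); b <- unclass(mask_b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (any(!(a %in% c(0, 1))) || any(!(b %in% c(0, 1))))
    stop("dice_score requires binary masks")
  vapply(seq_len(ncol(a)), function(c) {
    sa <- sum(a[, c]); sb <- sum(b[, c])
    if (sa + sb == 0) return(1)
    2 * sum(a[, c] * b[, c]) / (sa + sb)
  }, numeric(1)) -> d
  names(d) <- colnames(a)
  d
}

## ---- record-level scoring ----------------------------------------------

## Score one record and one wave type. pred_list: per-lead wave tables
## (length 1 under multi-lead prediction); truth_list: per-lead tables.
## When all leads agree on the true wave count the per-lead matrices share
## rows and are fused (OR); otherwise each lead is scored separately and
## counts are summed.
score_record_wave <- function(truth_list, pred_list, fs) {
  Ms <- vapply(truth_list, nrow, integer(1))
  shared <- length(unique(Ms)) == 1L
  if (shared) {
    H_list <- vector("list", 0)
    k <- 0L
    for (l in seq_along(truth_list)) {
      for (p in seq_along(pred_list)) {
        ## single-lead: match lead l's truth with lead l's prediction only
        if (length(pred_list) == length(truth_list) && p != l) next
        k <- k + 1L
        H_list[[k]] <- correspondence_matrix(truth_list[[l]],
                                             pred_list[[p]])
      }
    }
    pred_used <- if (length(pred_list) == length(truth_list)) pred_list
                 else rep(pred_list, length(truth_list))
    M <- Ms[1]
    matched_rows <- rep(FALSE, M)
    FP <- 0L; Mhat_total <- 0L
    for (H in H_list) {
      if (M) matched_rows <- matched_rows | (rowSums(H) > 0)
      Mhat_total <- Mhat_total + ncol(H)
      FP <- FP + ncol(H) - (if (ncol(H)) sum(colSums(H) > 0) else 0L)
    }
    TP <- sum(matched_rows)
    FN <- M - TP
    err <- delineation_errors(truth_list[[1]], pred_used, H_list, fs)
    list(TP = TP, FP = FP, FN = FN,
         on_err_ms = err$on_err_ms, off_err_ms = err$off_err_ms)
  } else {
    TP <- 0L; FP <- 0L; FN <- 0L
    on_err <- numeric(0); off_err <- numeric(0)
    for (l in seq_along(truth_list)) {
      p <- min(l, length(pred_list))
      H <- correspondence_matrix(truth_list[[l]], pred_list[[p]])
      cnt <- detection_counts(H)
      TP <- TP + cnt$TP; FP <- FP + cnt$FP; FN <- FN + cnt$FN
      err <- delineation_errors(truth_list[[l]], pred_list[p], list(H), fs)
      on_err <- c(on_err, err$on_err_ms)
      off_err <- c(off_err, err$off_err_ms)
    }
    list(TP = TP, FP = FP, FN = FN, on_err_ms = on_err,
         off_err_ms = off_err)
  }
}

#' Score predicted fiducials against ground truth
#'
#' Pools detection counts over all records and leads (micro-averaging) and
#' summarizes onset/offset errors over all matched waves per wave type.
#'
#' @param predictions Named list (by record id) of per-lead wave-table
#'   lists, as produced by decoding predicted masks. For multi-lead
#'   prediction each entry holds a single wave table.
#' @param truth Named list of [fiducial_set()] keyed like `predictions`.
#' @param strategy Prediction strategy used (informational).
#' @param dice Optional named per-wave Dice vector to attach.
#' @return An object of class `delineation_report` with a per-wave table
#'   of counts, precision/recall/F1 and error moments.
#' @export
evaluate_delineation <- function(predictions, truth,
                                 strategy = c("single_lead", "multi_lead"),
                                 dice = NULL) {
  strategy <- match.arg(strategy)
  ids <- names(predictions)
  if (!all(ids %in% names(truth)))
    stop("record mismatch between predictions and truth")
  acc <- lapply(WAVE_TYPES, function(w)
    list(TP = 0L, FP = 0L, FN = 0L, on = c(), off = c()))
  names(acc) <- WAVE_TYPES
  for (id in ids) {
    fid <- truth[[id]]
    pred <- predictions[[id]]
    if (inherits(pred, "data.frame")) pred <- list(pred)
    for (w in WAVE_TYPES) {
      truth_list <- lapply(seq_along(fid$leads), function(l)
        lead_waves(fid, l, w))
      pred_list <- lapply(pred, function(df)
        df[df$wave == w, , drop = FALSE])
      sc <- score_record_wave(truth_list, pred_list, fid$fs)
      acc[[w]]$TP <- acc[[w]]$TP + sc$TP
      acc[[w]]$FP <- acc[[w]]$FP + sc$FP
      acc[[w]]$FN <- acc[[w]]$FN + sc$FN
      acc[[w]]$on <- c(acc[[w]]$on, sc$on_err_ms)
      acc[[w]]$off <- c(acc[[w]]$off, sc$off_err_ms)
    }
  }
  waves <- do.call(rbind, lapply(WAVE_TYPES, function(w) {
    a <- acc[[w]]
    r <- rates_from_counts(a$TP, a$FP, a$FN)
    data.frame(wave = w, r,
               on_mean_ms = mean_or_na(a$on), on_sd_ms = sd_or_na(a$on),
               off_mean_ms = mean_or_na(a$off),
               off_sd_ms = sd_or_na(a$off),
               n_err = length(a$on), stringsAsFactors = FALSE)
  }))
  structure(list(waves = waves, strategy = strategy, dice = dice),
            class = "delineation_report")
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else
  if (length(x) == 1L) 0 else NA_real_

#' @export
print.delineation_report <- function(x, ...) {
  cat(sprintf("<delineation_report> (%s)\n", x$strategy))
  tab <- x$waves
  tab$precision <- round(100 * tab$precision, 2)
  tab$recall <- round(100 * tab$recall, 2)
  tab$f1 <- round(100 * tab$f1, 2)
  for (col in c("on_mean_ms", "on_sd_ms", "off_mean_ms", "off_sd_ms"))
    tab[[col]] <- round(tab[[col]], 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$dice))
    cat("Dice:", paste(sprintf("%s=%.4f", names(x$dice), x$dice),
                       collapse = " "), "\n")
  invisible(x)
}

## ---- observer bias ------------------------------------------------------

#' Inter-observer annotation bias
#'
#' Matches the two observers' waves with the correspondence-matrix rule
#' and summarizes the signed onset/offset differences (observer 1 -
#' observer 2) per wave type. A wave type annotated by only one observer
#' is skipped (`n = 0`).
#'
#' @param obs1,obs2 [fiducial_set()]s over the same record.
#' @return A data frame per wave type: onset/offset mean and SD (ms) and
#'   the number of matched pairs.
#' @export
interobserver_bias <- function(obs1, obs2) {
  stopifnot(inherits(obs1, "fiducial_set"), inherits(obs2, "fiducial_set"))
  fs <- obs1$fs
  ms <- 1000 / fs
  out <- list()
  n_leads <- min(length(obs1$leads), length(obs2$leads))
  for (w in WAVE_TYPES) {
    d_on <- c(); d_off <- c()
    any1 <- FALSE; any2 <- FALSE
    for (l in seq_len(n_leads)) {
      w1 <- lead_waves(obs1, l, w); w2 <- lead_waves(obs2, l, w)
      any1 <- any1 || nrow(w1) > 0; any2 <- any2 || nrow(w2) > 0
      if (!nrow(w1) || !nrow(w2)) next
      H <- correspondence_matrix(w1, w2)
      idx <- which(H == 1L, arr.ind = TRUE)
      if (nrow(idx)) {
        d_on <- c(d_on, (w1$on[idx[, 1]] - w2$on[idx[, 2]]) * ms)
        d_off <- c(d_off, (w1$off[idx[, 1]] - w2$off[idx[, 2]]) * ms)
      }
    }
    skipped <- !(any1 && any2)
    out[[w]] <- data.frame(
      wave = w, on_mean_ms = mean_or_na(d_on), on_sd_ms = sd_or_na(d_on),
      off_mean_ms = mean_or_na(d_off), off_sd_ms = sd_or_na(d_off),
      n = length(d_on), skipped = skipped, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Normalized cross-correlation of two segments over all overlapping lags;
## normalization uses full-segment energies so the autocorrelation of a
## segment with itself equals 1 at zero displacement.
ncc_best <- function(a, b) {
  na <- length(a); nb <- length(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) return(list(peak = 0, lag = 0L))
  best <- -Inf; best_lag <- 0L
  for (lag in (-(nb - 1L)):(na - 1L)) {
    ## b shifted by `lag`: b's sample n contributes at position n + lag
    lo <- max(1L, 1L + lag); hi <- min(na, nb + lag)
    if (hi < lo) next
    v <- sum(a[lo:hi] * b[(lo - lag):(hi - lag)]) / denom
    if (v > best) { best <- v; best_lag <- lag }
  }
  list(peak = best, lag = best_lag)
}

#' Intra-observer annotation bias
#'
#' Estimates how consistently one observer delineates morphologically
#' near-identical waves: every delineated wave segment is extended by
#' `window_ms` on both sides, all pairs of same-type waves are compared by
#' normalized running cross-correlation over all overlapping positions,
#' and pairs whose correlation peak reaches `threshold` contribute their
#' aligned onset/offset differences (best-lag shift removed).
#'
#' @param fiducials A [fiducial_set()].
#' @param record The matching [ecg_record()].
#' @param window_ms Segment extension in ms (default 40).
#' @param threshold Similarity threshold (default 0.99).
#' @param max_pairs Optional cap on the number of pairs examined per lead
#'   and wave type (earliest pairs kept), to bound runtime.
#' @return A data frame per wave type: onset/offset mean, SD (ms), and
#'   matched pair count.
#' @export
intraobserver_bias <- function(fiducials, record, window_ms = 40,
                               threshold = 0.99, max_pairs = 2000L) {
  stopifnot(inherits(fiducials, "fiducial_set"),
            inherits(record, "ecg_record"))
  fs <- record$fs
  ms <- 1000 / fs
  w_s <- as.integer(round(window_ms * fs / 1000))
  n <- n_samples(record)
  out <- list()
  for (w in WAVE_TYPES) {
    d_on <- c(); d_off <- c()
    for (l in seq_len(ncol(record$signal))) {
      waves <- lead_waves(fiducials, min(l, length(fiducials$leads)), w)
      if (nrow(waves) < 2L) next
      segs <- lapply(seq_len(nrow(waves)), function(i) {
        s0 <- max(0L, waves$on[i] - w_s)
        s1 <- min(n - 1L, waves$off[i] + w_s)
        if (s1 - s0 < 1L) return(NULL)
        list(x = record$signal[(s0 + 1L):(s1 + 1L), l], start = s0,
             on = waves$on[i], off = waves$off[i])
      })
      keep <- !vapply(segs, is.null, logical(1))
      segs <- segs[keep]
      if (length(segs) < 2L) next
      pairs <- utils::combn(length(segs), 2L)
      if (ncol(pairs) > max_pairs) pairs <- pairs[, seq_len(max_pairs)]
      for (pcol in seq_len(ncol(pairs))) {
        i <- pairs[1, pcol]; j <- pairs[2, pcol]
        cc <- ncc_best(segs[[i]]$x, segs[[j]]$x)
        if (cc$peak < threshold) next
        ## map annotations into segment coordinates and remove the lag
        on_i <- segs[[i]]$on - segs[[i]]$start
        on_j <- segs[[j]]$on - segs[[j]]$start
        off_i <- segs[[i]]$off - segs[[i]]$start
        off_j <- segs[[j]]$off - segs[[j]]$start
        d_on <- c(d_on, (on_i - on_j - cc$lag) * ms)
        d_off <- c(d_off, (off_i - off_j - cc$lag) * ms)
      }
    }
    out[[w]] <- data.frame(
      wave = w, on_mean_ms = mean_or_na(d_on), on_sd_ms = sd_or_na(d_on),
      off_mean_ms = mean_or_na(d_off), off_sd_ms = sd_or_na(d_off),
      n = length(d_on), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
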