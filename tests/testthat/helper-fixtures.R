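## Shared fixtures, built in code at test time.

## One short two-lead record with known truth.
fixture_record <- function(seed = 42, duration = 20, ...) {
  spec <- sim_spec(duration = duration, seed = seed, ...)
  generate_record(spec, "fix001")
}

## A random wave table with non-overlapping same-channel waves, for codec
## and evaluation property tests. Returns 0-based fiducials within
## n_samples.
random_wave_df <- function(n_samples, n_waves = NULL) {
  if (is.null(n_waves)) n_waves <- sample(0:6, 1)
  if (n_waves == 0) {
    return(data.frame(beat = integer(0), wave = character(0),
                      on = integer(0), peak = integer(0), off = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (w in c("P", "QRS", "T")) {
    pos <- 0L
    for (k in seq_len(n_waves)) {
      gap <- sample(2:20, 1)
      len <- sample(3:25, 1)
      on <- pos + gap
      off <- on + len
      if (off >= n_samples) break
      peak <- on + sample.int(len + 1, 1) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        beat = k, wave = w, on = on, peak = peak, off = off,
        stringsAsFactors = FALSE)
      pos <- off + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(beat = integer(0), wave = character(0),
                      on = integer(0), peak = integer(0), off = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$on), ]
}

## Literal per-sample membership oracle for the mask encoding: sample n is
## one iff it lies inside some [on, off] of that wave type.
brute_force_mask <- function(waves, n_samples) {
  m <- matrix(0, n_samples, 3)
  for (n in 0:(n_samples - 1)) {
    for (ci in 1:3) {
      w <- c("P", "QRS", "T")[ci]
      sub <- waves[waves$wave == w, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        if (n >= sub$on[k] && n <= sub$off[k]) m[n + 1, ci] <- 1
      }
    }
  }
  m
}

## Tiny architecture used by network tests (below the model-selection
## sweep sizes, so instantiation warns).
tiny_config <- function(...) {
  suppressWarnings(unet_config(levels = 4, blocks_per_level = 2,
                               base_width = 2, ...))
}

## Literal transcription of the membership rule: H[i, j] = 1 iff a
## predicted fiducial of wave j lies in the true closed interval i, or a
## true fiducial of wave i lies in the predicted closed interval j.
brute_force_H <- function(true_df, pred_df) {
  H <- matrix(0L, nrow(true_df), nrow(pred_df))
  for (i in seq_len(nrow(true_df))) {
    for (j in seq_len(nrow(pred_df))) {
      hit <- FALSE
      for (fid in c("on", "peak", "off")) {
        if (pred_df[[fid]][j] >= true_df$on[i] &&
            pred_df[[fid]][j] <= true_df$off[i]) hit <- TRUE
        if (true_df[[fid]][i] >= pred_df$on[j] &&
            true_df[[fid]][i] <= pred_df$off[j]) hit <- TRUE
      }
      if (hit) H[i, j] <- 1L
    }
  }
  H
}

one_wave <- function(on, peak, off, wave = "QRS") {
  data.frame(beat = seq_along(on), wave = wave, on = as.integer(on),
             peak = as.integer(peak), off = as.integer(off),
             stringsAsFactors = FALSE)
}

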