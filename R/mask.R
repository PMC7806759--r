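#' Three-channel wave segmentation mask
#'
#' A samples-by-3 matrix with channels `P`, `QRS`, `T`, either binary
#' (values in \{0, 1\}) or probabilistic (values in \[0, 1\]). Row `n + 1`
#' corresponds to 0-based sample `n`.
#'
#' @param values Numeric samples x 3 matrix.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `seg_mask` (a classed matrix).
#' @export
seg_mask <- function(values, fs) {
  if (!is.matrix(values) || ncol(values) != 3L)
    stop("mask must be a samples x 3 matrix (channels P, QRS, T)")
  if (any(values < 0 | values > 1))
    stop("mask values must lie in [0, 1]")
  colnames(values) <- WAVE_TYPES
  structure(values, fs = fs, class = c("seg_mask", "matrix", "array"))
}

#' @export
print.seg_mask <- function(x, ...) {
  kind <- if (is_binary_mask(x)) "binary" else "probabilistic"
  cat(sprintf("<seg_mask> %d samples x 3 channels (%s) @ %g Hz\n",
              nrow(x), kind, attr(x, "fs")))
  cov <- colMeans(unclass(x))
  cat(sprintf("  coverage: P=%.3f QRS=%.3f T=%.3f\n", cov[1], cov[2], cov[3]))
  invisible(x)
}

#' @export
is_binary_mask <- function(mask) all(mask == 0 | mask == 1)

#' Encode fiducials as a binary segmentation mask
#'
#' Channel `w` is 1 exactly on the union of the closed sample intervals
#' `[on, off]` of the waves of type `w`, and 0 elsewhere. The three
#' channels are independent; overlap across channels is permitted.
#'
#' @param waves A wave table (one lead's view; see [lead_waves()]) or a
#'   [fiducial_set()], in which case `lead` selects the lead.
#' @param n_samples Mask length in samples; all fiducials must be
#'   `< n_samples`.
#' @param fs Sampling frequency (taken from the fiducial set if available).
#' @param lead Lead selector when `waves` is a `fiducial_set`.
#' @return A binary [seg_mask()].
#' @export
fiducials_to_mask <- function(waves, n_samples, fs = NULL, lead = 1L) {
  if (inherits(waves, "fiducial_set")) {
    if (is.null(fs)) fs <- waves$fs
    waves <- lead_waves(waves, lead)
  }
  if (is.null(fs)) stop("fs required when passing a bare wave table")
  waves <- validate_wave_df(waves)
  if (nrow(waves) > 0L && any(waves$off >= n_samples))
    stop("fiducial beyond mask length (", n_samples, " samples)")
  m <- matrix(0, n_samples, 3L)
  for (k in seq_len(nrow(waves))) {
    ch <- match(waves$wave[k], WAVE_TYPES)
    m[(waves$on[k] + 1L):(waves$off[k] + 1L), ch] <- 1
  }
  seg_mask(m, fs)
}

#' Threshold a probabilistic mask
#'
#' Values greater than or equal to `threshold` map to 1, others to 0;
#' idempotent on binary masks.
#'
#' @param mask A [seg_mask()].
#' @param threshold Decision threshold, strictly inside (0, 1).
#' @return A binary [seg_mask()].
#' @export
binarize <- function(mask, threshold = 0.5) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  seg_mask((unclass(mask) >= threshold) * 1, attr(mask, "fs"))
}

#' Decode a binary mask back to fiducials
#'
#' Each maximal run of ones per channel becomes one wave with `on` the
#' first and `off` the last sample of the run; runs shorter than
#' `min_duration_ms` are discarded. The peak is the sample of maximum
#' absolute signal amplitude within `[on, off]` when `signal` is given,
#' otherwise the interval midpoint `floor((on + off) / 2)`.
#'
#' @param mask A binary [seg_mask()] (binarize probabilistic masks first).
#' @param signal Optional single-lead numeric vector aligned with the mask.
#' @param min_duration_ms Minimum wave duration in ms (default 20 ms,
#'   i.e. 5 samples at 250 Hz).
#' @return A wave table sorted by onset, with beats assigned by QRS
#'   anchoring.
#' @export
mask_to_fiducials <- function(mask, signal = NULL, min_duration_ms = 20) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!is_binary_mask(mask))
    stop("mask_to_fiducials requires a binary mask; call binarize() first")
  fs <- attr(mask, "fs")
  min_len <- max(1L, as.integer(round(min_duration_ms * fs / 1000)))
  if (!is.null(signal) && length(signal) != nrow(mask))
    stop("signal length must match mask length")
  rows <- list()
  for (ch in 1:3) {
    v <- unclass(mask)[, ch]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onesel <- which(r$values == 1 & r$lengths >= min_len)
    for (k in onesel) {
      on <- starts[k] - 1L; off <- ends[k] - 1L
      peak <- if (!is.null(signal)) {
        seg <- signal[(on + 1L):(off + 1L)]
        on + which.max(abs(seg)) - 1L
      } else (on + off) %/% 2L
      rows[[length(rows) + 1L]] <- data.frame(
        beat = NA_integer_, wave = WAVE_TYPES[ch], on = on,
        peak = peak, off = off, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_wave_df())
  df <- do.call(rbind, rows)
  df <- assign_beats(df)
  validate_wave_df(df, n_samples = nrow(mask))
}
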