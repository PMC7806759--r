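#' Multi-lead ECG record
#'
#' Container for a sampled multi-lead ECG signal. The signal is stored as a
#' samples-by-leads matrix in millivolts. Sample indices used throughout the
#' package (fiducials, masks) are 0-based, following the WFDB convention;
#' sample `n` lives in matrix row `n + 1`.
#'
#' @param record_id Character scalar; subject/recording identity.
#' @param signal Numeric matrix, samples x leads, in mV. A vector is treated
#'   as a single lead.
#' @param fs Sampling frequency in Hz.
#' @param lead_names Optional character vector of lead names; defaults to
#'   `"lead1"`, `"lead2"`, ...
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs, lead_names = NULL) {
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id))
    stop("record_id must be a non-empty character scalar")
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric matrix (samples x leads)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(signal)))
  if (length(lead_names) != ncol(signal))
    stop("lead_names length must equal the number of leads")
  colnames(signal) <- lead_names
  structure(
    list(record_id = record_id, fs = fs, signal = signal,
         lead_names = lead_names),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples x %d lead(s) @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}

#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.ecg_record <- function(x) nrow(x$signal)

WAVE_TYPES <- c("P", "QRS", "T")

empty_wave_df <- function() {
  data.frame(beat = integer(0), wave = character(0), on = integer(0),
              peak = integer(0), off = integer(0), stringsAsFactors = FALSE)
}

#' Validate one lead's wave table
#'
#' A wave table is a data frame with columns `beat`, `wave` (one of
#' `"P"`, `"QRS"`, `"T"`), and 0-based integer sample columns `on`, `peak`,
#' `off`. Within a wave `on <= peak <= off` must hold; waves are kept sorted
#' by onset.
#'
#' @param df A wave table.
#' @param n_samples Optional record length; fiducials must lie in
#'   `[0, n_samples - 1]`.
#' @return The validated, onset-sorted data frame (invisibly the same data).
#' @keywords internal
validate_wave_df <- function(df, n_samples = NULL) {
  req <- c("beat", "wave", "on", "peak", "off")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("wave table must have columns beat, wave, on, peak, off")
  if (nrow(df) == 0L) return(empty_wave_df())
  if (!all(df$wave %in% WAVE_TYPES))
    stop("wave must be one of ", paste(WAVE_TYPES, collapse = ", "))
  for (col in c("on", "peak", "off")) df[[col]] <- as.integer(df[[col]])
  if (any(df$on > df$peak) || any(df$peak > df$off))
    stop("fiducial ordering violated: need on <= peak <= off within each wave")
  if (any(df$on < 0L)) stop("fiducials must be non-negative sample indices")
  if (!is.null(n_samples) && any(df$off >= n_samples))
    stop("fiducial beyond record length (", n_samples, " samples)")
  df <- df[order(df$on), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-record fiducial annotations
#'
#' Holds, per lead, a wave table (see [validate_wave_df()]) of up to nine
#' fiducials per beat: onset/peak/offset for each of the P, QRS and T waves.
#'
#' @param record_id Character scalar matching the annotated record.
#' @param leads Named list of wave tables, one per lead.
#' @param fs Sampling frequency in Hz (carried for ms conversions).
#' @param n_samples Optional record length used for range validation.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(record_id, leads, fs, n_samples = NULL) {
  if (!is.list(leads) || is.null(names(leads)) || any(!nzchar(names(leads))))
    stop("leads must be a named list of wave tables")
  leads <- lapply(leads, validate_wave_df, n_samples = n_samples)
  structure(
    list(record_id = record_id, fs = fs, leads = leads,
         n_samples = n_samples),
    class = "fiducial_set"
  )
}

#' @export
print.fiducial_set <- function(x, ...) {
  counts <- vapply(x$leads, function(df) {
    vapply(WAVE_TYPES, function(w) sum(df$wave == w), integer(1))
  }, integer(3))
  cat(sprintf("<fiducial_set> %s: %d lead(s)\n", x$record_id, length(x$leads)))
  for (i in seq_along(x$leads))
    cat(sprintf("  %s: P=%d QRS=%d T=%d\n", names(x$leads)[i],
                counts[1, i], counts[2, i], counts[3, i]))
  invisible(x)
}

#' Extract one lead's waves of one type
#'
#' @param fiducials A `fiducial_set`.
#' @param lead Lead name or index.
#' @param wave Optional wave type filter (`"P"`, `"QRS"`, `"T"`).
#' @return A wave table sorted by onset.
#' @export
lead_waves <- function(fiducials, lead = 1L, wave = NULL) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  df <- fiducials$leads[[lead]]
  if (is.null(df)) stop("no such lead: ", lead)
  if (!is.null(wave)) {
    wave <- match.arg(wave, WAVE_TYPES)
    df <- df[df$wave == wave, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

## Group an onset-sorted wave table into beats: each QRS anchors a beat; a P
## ending before the QRS onset (and after the previous beat's QRS) and the
## first T following the QRS offset (before the next QRS onset) join it.
## Waves that fit no beat get fresh beat indices at the end.
assign_beats <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$on), , drop = FALSE]
  df$beat <- NA_integer_
  qrs_idx <- which(df$wave == "QRS")
  beat <- 0L
  prev_qrs_off <- -1L
  for (k in seq_along(qrs_idx)) {
    i <- qrs_idx[k]
    beat <- beat + 1L
    df$beat[i] <- beat
    next_qrs_on <- if (k < length(qrs_idx)) df$on[qrs_idx[k + 1L]] else Inf
    p_cand <- which(df$wave == "P" & is.na(df$beat) &
                      df$off <= df$on[i] & df$on > prev_qrs_off)
    if (length(p_cand)) df$beat[p_cand[length(p_cand)]] <- beat
    t_cand <- which(df$wave == "T" & is.na(df$beat) &
                      df$on >= df$off[i] & df$on < next_qrs_on)
    if (length(t_cand)) df$beat[t_cand[1L]] <- beat
    prev_qrs_off <- df$off[i]
  }
  orphan <- which(is.na(df$beat))
  if (length(orphan)) {
    df$beat[orphan] <- beat + seq_along(orphan)
  }
  rownames(df) <- NULL
  df
}
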