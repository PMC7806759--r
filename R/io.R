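## Minimal WFDB-dialect storage: a text .hea header plus a format-16
## (16-bit little-endian integer) .dat signal file, and per-beat wave
## annotations as an rdann-style whitespace table. This covers the subset
## of the format family needed for delineation work; EDF/DICOM and the
## binary MIT annotation format are out of scope.

PEAK_SYMBOLS <- c(P = "p", QRS = "N", T = "t")

#' Write an ECG record as WFDB-style .hea/.dat files
#'
#' Signals are stored as 16-bit integers with gain and baseline recorded in
#' the header (`adc = round(mV * gain) + baseline`), so a write/read
#' round-trip is exact to 1/gain mV.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param gain ADC units per mV.
#' @return The header path, invisibly.
#' @export
write_record <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- record$record_id
  dat_name <- paste0(base, ".dat")
  n <- nrow(record$signal); nl <- ncol(record$signal)
  adc <- round(record$signal * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds 16-bit range at gain ", gain)
  adc <- matrix(as.integer(adc), n, nl)
  checksum <- (colSums(adc) %% 65536 + 65536) %% 65536
  hea <- c(
    sprintf("%s %d %g %d", base, nl, record$fs, n),
    sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 %s", dat_name, gain,
            adc[1, ], as.integer(checksum), record$lead_names)
  )
  writeLines(hea, file.path(dir, paste0(base, ".hea")))
  con <- file(file.path(dir, dat_name), "wb")
  on.exit(close(con))
  ## interleave samples across leads, little-endian int16
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(base, ".hea")))
}

#' Read an ECG record from WFDB-style .hea/.dat files
#'
#' @param path Path to the `.hea` header (or its basename without
#'   extension).
#' @return An [ecg_record()] with the signal in mV.
#' @export
read_record <- function(path) {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  if (!file.exists(path)) stop("header file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed header: ", path)
  base <- top[1]; nl <- as.integer(top[2]); fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (length(lines) < 1L + nl) stop("header lists ", nl, " leads but has ",
                                    length(lines) - 1L, " signal lines: ", path)
  gains <- numeric(nl); baselines <- numeric(nl); leads <- character(nl)
  dat_name <- NULL
  for (l in seq_len(nl)) {
    f <- strsplit(trimws(lines[1L + l]), "\\s+")[[1]]
    dat_name <- f[1]
    if (f[2] != "16") stop("unsupported signal format ", f[2], " in ", path)
    gspec <- f[3]
    g <- as.numeric(sub("^([0-9.eE+-]+).*", "\\1", gspec))
    b <- if (grepl("\\(", gspec))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gspec)) else 0
    gains[l] <- g; baselines[l] <- b
    leads[l] <- if (length(f) >= 9L) paste(f[-(1:8)], collapse = " ")
                else paste0("lead", l)
  }
  dat_path <- file.path(dirname(path), dat_name)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "integer", n = n * nl, size = 2L, signed = TRUE,
                      endian = "little")
  if (length(raw_vals) < n * nl)
    stop("signal file truncated: ", dat_path, " (expected ", n * nl,
         " samples, got ", length(raw_vals), ")")
  adc <- matrix(raw_vals, nrow = n, ncol = nl, byrow = TRUE)
  sig <- sweep(sweep(adc, 2, baselines, "-"), 2, gains, "/")
  ecg_record(base, sig, fs, leads)
}

#' Write wave annotations as an rdann-style text table
#'
#' One row per annotation event with columns `sample`, `symbol`, `chan`
#' (0-based lead index): `(` marks a wave onset, `)` an offset, and `p`,
#' `N`, `t` the P, QRS and T peaks.
#'
#' @param fiducials A [fiducial_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  rows <- list()
  for (l in seq_along(fiducials$leads)) {
    df <- fiducials$leads[[l]]
    for (k in seq_len(nrow(df))) {
      sym <- PEAK_SYMBOLS[[df$wave[k]]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = c(df$on[k], df$peak[k], df$off[k]),
        symbol = c("(", sym, ")"),
        chan = l - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$chan, tab$sample), ]
  } else {
    tab <- data.frame(sample = integer(0), symbol = character(0),
                      chan = integer(0))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, sep = "\t")
  invisible(path)
}

#' Read wave annotations from an rdann-style text table
#'
#' Waves are assembled per lead by grouping onset/peak/offset symbol runs:
#' a `(` opens a wave, the following peak symbol types it, and `)` closes
#' it. Waves missing their onset or offset (isolated delineations) are
#' dropped, as they are unusable for training. Unknown symbols are skipped
#' with a warning.
#'
#' @param path Annotation file path.
#' @param record The matching [ecg_record()] (for length validation and
#'   lead naming).
#' @return A [fiducial_set()].
#' @export
read_annotations <- function(path, record) {
  stopifnot(inherits(record, "ecg_record"))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  n <- n_samples(record)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character", "integer"),
                           quote = "", comment.char = "")
  leads <- stats::setNames(
    rep(list(empty_wave_df()), length(record$lead_names)),
    record$lead_names)
  if (nrow(tab)) {
    if (any(tab$sample < 0 | tab$sample >= n))
      stop("annotation sample index out of record range in ", path)
    unknown <- !(tab$symbol %in% c("(", ")", PEAK_SYMBOLS))
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " unknown annotation symbol(s) in ",
              path)
      tab <- tab[!unknown, , drop = FALSE]
    }
    for (l in sort(unique(tab$chan))) {
      sub <- tab[tab$chan == l, , drop = FALSE]
      sub <- sub[order(sub$sample), , drop = FALSE]
      waves <- list()
      pending_on <- NA_integer_
      open_wave <- NULL  # list(wave, on, peak) awaiting ')'
      for (k in seq_len(nrow(sub))) {
        sym <- sub$symbol[k]; smp <- sub$sample[k]
        if (sym == "(") {
          pending_on <- smp
        } else if (sym %in% PEAK_SYMBOLS) {
          open_wave <- list(
            wave = names(PEAK_SYMBOLS)[match(sym, PEAK_SYMBOLS)],
            on = pending_on, peak = smp)
          pending_on <- NA_integer_
        } else if (sym == ")") {
          if (!is.null(open_wave)) {
            if (!is.na(open_wave$on)) {
              waves[[length(waves) + 1L]] <- data.frame(
                beat = NA_integer_, wave = open_wave$wave,
                on = open_wave$on, peak = open_wave$peak, off = smp,
                stringsAsFactors = FALSE)
            }
            open_wave <- NULL
          }
        }
      }
      if (length(waves)) {
        df <- assign_beats(do.call(rbind, waves))
        if (l + 1L <= length(leads)) leads[[l + 1L]] <- df
      }
    }
  }
  fiducial_set(record$record_id, leads, record$fs, n_samples = n)
}

#' Write the true fiducials as a JSON sidecar
#'
#' @param fiducials A [fiducial_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fiducials_json <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  payload <- list(record_id = fiducials$record_id, fs = fiducials$fs,
                  n_samples = fiducials$n_samples, leads = fiducials$leads)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fiducial JSON sidecar
#'
#' @param path Sidecar path.
#' @return A [fiducial_set()].
#' @export
read_fiducials_json <- function(path) {
  if (!file.exists(path)) stop("fiducial sidecar not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  leads <- lapply(p$leads, function(df) {
    if (is.null(df) || !length(df) || !NROW(df)) return(empty_wave_df())
    as.data.frame(df, stringsAsFactors = FALSE)
  })
  fiducial_set(p$record_id, leads, p$fs,
               n_samples = if (is.null(p$n_samples)) NULL else p$n_samples)
}

#' Build a dataset manifest
#'
#' @param record_id Character vector of record ids.
#' @param signal Paths to the signal headers.
#' @param annotation Paths to the annotation files.
#' @param quality Label quality tags, `"high"` or `"low"`.
#' @param check_paths Verify that the listed files exist.
#' @return A `dataset_manifest` data frame.
#' @export
dataset_manifest <- function(record_id, signal, annotation, quality,
                             check_paths = TRUE) {
  if (!all(quality %in% c("high", "low")))
    stop("quality must be 'high' or 'low'")
  m <- data.frame(record_id = record_id, signal = signal,
                  annotation = annotation, quality = quality,
                  stringsAsFactors = FALSE)
  if (check_paths) {
    missing <- c(m$signal[!file.exists(m$signal)],
                 m$annotation[!file.exists(m$annotation)])
    if (length(missing))
      stop("manifest paths do not exist: ",
           paste(missing, collapse = ", "))
  }
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return The parsed configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
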