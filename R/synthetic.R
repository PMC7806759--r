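#' Beat morphology template
#'
#' Parametric description of a single ECG beat as a sum of Gaussian
#' deflections: one for the P wave, three alternating-sign components (Q, R,
#' S) for the QRS complex, and one wider deflection for the T wave. Widths
#' are the on-to-off spans at the 5% amplitude threshold used to define
#' onsets and offsets, in milliseconds. `pq_interval` is the gap between the
#' P offset and the QRS onset; `st_interval` the gap between the QRS offset
#' and the T onset.
#'
#' @param p_amp,qrs_amps,t_amp Amplitudes in mV. `qrs_amps` is a Q/R/S
#'   triple (usually signs -/+/-). Set `p_amp = 0` for a beat without a P
#'   wave.
#' @param p_width,qrs_width,t_width Wave widths in ms (must be > 0).
#' @param pq_interval,st_interval Inter-wave gaps in ms (must be >= 0).
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(p_amp = 0.15, p_width = 90,
                          qrs_amps = c(-0.15, 1.0, -0.25), qrs_width = 90,
                          t_amp = 0.35, t_width = 180,
                          pq_interval = 50, st_interval = 110) {
  tpl <- list(p_amp = p_amp, p_width = p_width, qrs_amps = qrs_amps,
              qrs_width = qrs_width, t_amp = t_amp, t_width = t_width,
              pq_interval = pq_interval, st_interval = st_interval)
  validate_template(tpl)
  structure(tpl, class = "beat_template")
}

validate_template <- function(tpl) {
  widths <- c(tpl$p_width, tpl$qrs_width, tpl$t_width)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("beat template: widths must be positive")
  if (tpl$pq_interval < 0 || tpl$st_interval < 0)
    stop("beat template: intervals must be non-negative")
  if (length(tpl$qrs_amps) != 3L)
    stop("beat template: qrs_amps must be a Q/R/S triple")
  if (all(tpl$qrs_amps == 0))
    stop("beat template: QRS amplitude cannot be all zero")
  if (tpl$t_amp == 0) stop("beat template: T amplitude cannot be zero")
  invisible(tpl)
}

## Fraction of a deflection's own peak that defines its onset/offset.
ONOFF_THRESHOLD <- 0.05

## sigma such that |amp| * exp(-x^2 / (2 sigma^2)) crosses
## ONOFF_THRESHOLD * |amp| at x = +/- width/2.
width_to_sigma <- function(width_s) {
  width_s / (2 * sqrt(2 * log(1 / ONOFF_THRESHOLD)))
}

gauss_bump <- function(t, center, sigma, amp) {
  amp * exp(-((t - center)^2) / (2 * sigma^2))
}

## Measured fiducials of one wave component on the sample grid (0-based).
component_fiducials <- function(comp) {
  pk <- max(abs(comp))
  if (pk == 0) return(NULL)
  idx <- which(abs(comp) >= ONOFF_THRESHOLD * pk)
  c(on = idx[1L] - 1L, peak = which.max(abs(comp)) - 1L,
    off = idx[length(idx)] - 1L)
}

#' Generate one synthetic beat with exactly known fiducials
#'
#' Builds a beat waveform as a sum of smooth Gaussian deflections and
#' measures each wave's onset, peak and offset on the sample grid: onset and
#' offset are the first and last samples where the wave's own component
#' exceeds 5% of its own peak magnitude, the peak is the extremal sample.
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency in Hz.
#' @return A list with `waveform` (numeric vector, mV), `fiducials` (wave
#'   table; no P rows when `p_amp = 0`), and `n` (number of samples).
#' @export
generate_beat <- function(template, fs) {
  if (!inherits(template, "beat_template")) {
    template <- do.call(beat_template, template)
  }
  validate_template(template)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  ms <- function(x) x / 1000
  pad <- 0.03
  p_w <- ms(template$p_width); q_w <- ms(template$qrs_width)
  t_w <- ms(template$t_width)
  p_center <- pad + p_w / 2
  qrs_on_nom <- pad + p_w + ms(template$pq_interval)
  qrs_center <- qrs_on_nom + q_w / 2
  t_on_nom <- qrs_on_nom + q_w + ms(template$st_interval)
  t_center <- t_on_nom + t_w / 2
  dur <- t_on_nom + t_w + 0.05
  n <- ceiling(dur * fs)
  t_axis <- (seq_len(n) - 1L) / fs

  p_comp <- if (template$p_amp != 0)
    gauss_bump(t_axis, p_center, width_to_sigma(p_w), template$p_amp)
  else rep(0, n)
  ## QRS: three narrow Gaussians; sub-width chosen so the summed complex
  ## crosses its 5% threshold close to the nominal qrs_width span.
  qa <- template$qrs_amps
  offs <- c(-0.28, 0, 0.28) * q_w
  sub_sigma <- width_to_sigma(q_w) * 0.45
  qrs_comp <- rep(0, n)
  for (k in 1:3) {
    if (qa[k] != 0)
      qrs_comp <- qrs_comp +
        gauss_bump(t_axis, qrs_center + offs[k], sub_sigma, qa[k])
  }
  t_comp <- gauss_bump(t_axis, t_center, width_to_sigma(t_w), template$t_amp)

  fids <- list(P = component_fiducials(p_comp),
               QRS = component_fiducials(qrs_comp),
               T = component_fiducials(t_comp))
  rows <- lapply(names(fids), function(w) {
    f <- fids[[w]]
    if (is.null(f)) return(NULL)
    data.frame(beat = 1L, wave = w, on = f[["on"]], peak = f[["peak"]],
               off = f[["off"]], stringsAsFactors = FALSE)
  })
  fdf <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  fdf <- validate_wave_df(fdf, n_samples = n)
  ## wave ordering must hold for any valid template
  wv <- fdf[order(fdf$on), ]
  if (nrow(wv) > 1L && any(utils::head(wv$off, -1) > utils::tail(wv$on, -1)))
    stop("beat template produces overlapping waves; widen intervals")
  list(waveform = p_comp + qrs_comp + t_comp, fiducials = fdf, n = n)
}

#' Simulation settings for a synthetic ECG dataset
#'
#' Defines the conditions under which synthetic multi-lead records are
#' generated: quasi-periodic beat trains with per-beat RR jitter, per-beat
#' template perturbation, occasional missing P waves, and leads formed as
#' scaled/sign-flipped projections of one source train plus small
#' independent noise (emulating correlated two-lead ambulatory recordings).
#'
#' @param n_subjects Number of records (one subject each).
#' @param n_leads Leads per record.
#' @param fs Sampling frequency (Hz).
#' @param duration Record duration in seconds.
#' @param heart_rate Mean heart rate in bpm.
#' @param rr_jitter Fractional standard deviation of per-beat RR intervals.
#' @param template_variability Fractional SD of per-beat multiplicative
#'   perturbation of template amplitudes and widths.
#' @param missing_p_probability Probability that a beat has no P wave.
#' @param lead_gains Optional numeric vector of per-lead projection gains
#'   (length `n_leads`); defaults to `1` for lead 1 and alternating damped
#'   sign-flips for further leads.
#' @param noise_sd Per-lead additive Gaussian noise SD in mV.
#' @param template Base [beat_template()].
#' @param seed Integer seed; identical specs yield identical datasets.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects = 1L, n_leads = 2L, fs = 250, duration = 30,
                     heart_rate = 60, rr_jitter = 0.05,
                     template_variability = 0.1,
                     missing_p_probability = 0.1, lead_gains = NULL,
                     noise_sd = 0.01, template = beat_template(),
                     seed = 1234L) {
  if (fs <= 0) stop("fs must be > 0")
  for (p in c(template_variability, missing_p_probability, rr_jitter)) {
    if (p < 0 || p > 1) stop("probabilities/fractions must lie in [0, 1]")
  }
  if (is.null(lead_gains)) {
    lead_gains <- c(1, -0.6, 0.8, -0.4, 0.5)[seq_len(n_leads)]
    lead_gains[is.na(lead_gains)] <- 0.5
  }
  if (length(lead_gains) != n_leads)
    stop("lead_gains must have length n_leads")
  structure(
    list(n_subjects = as.integer(n_subjects), n_leads = as.integer(n_leads),
         fs = fs, duration = duration, heart_rate = heart_rate,
         rr_jitter = rr_jitter, template_variability = template_variability,
         missing_p_probability = missing_p_probability,
         lead_gains = lead_gains, noise_sd = noise_sd, template = template,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

perturb_template <- function(tpl, variability) {
  if (variability <= 0) return(tpl)
  jig <- function(x) x * pmax(0.3, 1 + stats::rnorm(length(x), 0, variability))
  tpl$p_amp <- jig(tpl$p_amp)
  tpl$qrs_amps <- tpl$qrs_amps * pmax(0.3, 1 + stats::rnorm(1, 0, variability))
  tpl$t_amp <- jig(tpl$t_amp)
  tpl$p_width <- jig(tpl$p_width)
  tpl$qrs_width <- jig(tpl$qrs_width)
  tpl$t_width <- jig(tpl$t_width)
  tpl
}

#' Generate one synthetic multi-lead ECG record
#'
#' Places beats at RR intervals drawn around the spec's heart rate, perturbs
#' the beat template per beat, optionally drops P waves, and projects the
#' resulting source train onto `n_leads` leads with per-lead gains and small
#' independent Gaussian noise. All leads share the same fiducial timing.
#'
#' @param spec A [sim_spec()].
#' @param record_id Record identifier.
#' @return A list with elements `record` ([ecg_record()]) and `fiducials`
#'   ([fiducial_set()]).
#' @export
generate_record <- function(spec, record_id = "synt001") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  generate_record_impl(spec, record_id)
}

## RNG-stream version used by simulate_dataset (seeded once at dataset level)
generate_record_impl <- function(spec, record_id) {
  n <- round(spec$duration * spec$fs)
  rr_mean <- 60 / spec$heart_rate
  src <- rep(0, n)
  all_fids <- list()
  onset <- 0L
  beat_i <- 0L
  repeat {
    tpl <- perturb_template(unclass(spec$template), spec$template_variability)
    if (stats::runif(1) < spec$missing_p_probability) tpl$p_amp <- 0
    tpl <- structure(tpl, class = "beat_template")
    beat <- generate_beat(tpl, spec$fs)
    if (onset + beat$n > n) break
    beat_i <- beat_i + 1L
    idx <- onset + seq_len(beat$n)
    src[idx] <- src[idx] + beat$waveform
    f <- beat$fiducials
    f$beat <- beat_i
    f$on <- f$on + onset; f$peak <- f$peak + onset; f$off <- f$off + onset
    all_fids[[beat_i]] <- f
    rr <- rr_mean * (1 + stats::rnorm(1, 0, spec$rr_jitter))
    rr <- max(rr, 0.3)
    onset <- onset + as.integer(round(rr * spec$fs))
  }
  if (beat_i == 0L)
    stop("duration too short for a single beat at the given template")
  fdf <- do.call(rbind, all_fids)
  sig <- matrix(0, n, spec$n_leads)
  leads <- list()
  lead_names <- paste0("lead", seq_len(spec$n_leads))
  for (l in seq_len(spec$n_leads)) {
    sig[, l] <- spec$lead_gains[l] * src +
      stats::rnorm(n, 0, spec$noise_sd)
    leads[[lead_names[l]]] <- fdf
  }
  rec <- ecg_record(record_id, sig, spec$fs, lead_names)
  fids <- fiducial_set(record_id, leads, spec$fs, n_samples = n)
  list(record = rec, fiducials = fids)
}

#' Generate a synthetic dataset of independent subjects
#'
#' @param spec A [sim_spec()]; `spec$n_subjects` records are generated from
#'   one seeded RNG stream, so the whole dataset is reproducible from the
#'   spec alone.
#' @param id_prefix Prefix for record identifiers.
#' @return A list with `records` (named list of [ecg_record()]) and
#'   `fiducials` (named list of [fiducial_set()]), keyed by record id.
#' @export
simulate_dataset <- function(spec, id_prefix = "synt") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  records <- list(); fiducials <- list()
  for (i in seq_len(spec$n_subjects)) {
    id <- sprintf("%s%03d", id_prefix, i)
    out <- generate_record_impl(spec, id)
    records[[id]] <- out$record
    fiducials[[id]] <- out$fiducials
  }
  list(records = records, fiducials = fiducials)
}

#' Degrade annotations into a low-quality label set
#'
#' Emulates automatically produced single-lead labels: wave boundaries are
#' jittered with Gaussian noise, waves are randomly dropped, and spurious
#' short waves are occasionally inserted. Ordering invariants
#' (`on <= peak <= off`, indices in range) are restored by clipping.
#'
#' @param fiducials A [fiducial_set()].
#' @param onset_noise_sd Boundary jitter SD in ms (applied to onsets,
#'   peaks and offsets independently).
#' @param miss_rate Probability of dropping each wave.
#' @param false_rate Expected number of spurious waves per true wave.
#' @param seed Integer seed.
#' @return A degraded [fiducial_set()].
#' @export
degrade_labels <- function(fiducials, onset_noise_sd = 8, miss_rate = 0.05,
                           false_rate = 0.02, seed = 1L) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  if (miss_rate < 0 || miss_rate > 1 || false_rate < 0)
    stop("rates must lie in [0, 1]")
  fs <- fiducials$fs
  n_total <- fiducials$n_samples
  set.seed(seed)
  leads <- lapply(fiducials$leads, function(df) {
    if (nrow(df) == 0L) return(df)
    keep <- stats::runif(nrow(df)) >= miss_rate
    df <- df[keep, , drop = FALSE]
    if (nrow(df) > 0L && onset_noise_sd > 0) {
      jit <- function(x) x + as.integer(round(
        stats::rnorm(length(x), 0, onset_noise_sd) * fs / 1000))
      df$on <- jit(df$on); df$peak <- jit(df$peak); df$off <- jit(df$off)
      ## restore invariants by clipping
      swap <- df$off < df$on
      if (any(swap)) {
        tmp <- df$on[swap]; df$on[swap] <- df$off[swap]; df$off[swap] <- tmp
      }
      df$peak <- pmin(pmax(df$peak, df$on), df$off)
      df$on <- pmax(df$on, 0L)
      df$peak <- pmax(df$peak, df$on)
      if (!is.null(n_total)) {
        df$off <- pmin(df$off, n_total - 1L)
        df$peak <- pmin(df$peak, df$off)
        df$on <- pmin(df$on, df$off)
      }
    }
    n_false <- stats::rpois(1, false_rate * max(1L, nrow(df)))
    if (n_false > 0L && !is.null(n_total)) {
      width <- as.integer(round(0.06 * fs))
      ons <- as.integer(floor(stats::runif(n_false, 0, n_total - width - 1)))
      fake <- data.frame(beat = NA_integer_,
                         wave = sample(WAVE_TYPES, n_false, replace = TRUE),
                         on = ons, peak = ons + width %/% 2L,
                         off = ons + width, stringsAsFactors = FALSE)
      df <- rbind(df, fake)
    }
    df <- df[order(df$on), , drop = FALSE]
    df <- assign_beats(df)
    rownames(df) <- NULL
    df
  })
  fiducial_set(fiducials$record_id, leads, fs, n_samples = n_total)
}
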