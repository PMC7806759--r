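## ECG-tailored additive noise sources, each calibrated to a requested
## signal-to-noise ratio: the noise power is P_n = P_s / 10^(SNR/10) with
## P_s = mean(x^2) the input signal power. Every generator returns an
## additive noise sequence of the same length as its input.

signal_power <- function(x) mean(x^2)

noise_power <- function(x, snr_db) {
  ps <- signal_power(x)
  if (!length(x)) stop("input signal is empty")
  if (ps == 0) stop("SNR undefined for an all-zero signal")
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  ps / 10^(snr_db / 10)
}

#' Additive white Gaussian noise at a target SNR
#'
#' @param x Single-lead signal (mV).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional integer seed for reproducible draws.
#' @return Noise vector of `length(x)` with i.i.d. N(0, P_n) samples.
#' @export
noise_awgn <- function(x, snr_db, seed = NULL) {
  pn <- noise_power(x, snr_db)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(length(x), 0, sqrt(pn))
}

## 5-tap pacemaker-like spike shape stamped by the random-spikes source.
SPIKE_TEMPLATE <- c(0, 0.15, 1.5, -0.25, 0.15)

#' Periodic random spikes at a target SNR
#'
#' Stamps the 5-tap spike template (plus, by default, fresh uniform
#' U(-0.25, 0.25) noise per tap per spike), scaled by `sqrt(P_n / f)`, at
#' intervals of `1/f` seconds with a random phase offset.
#'
#' @param x Single-lead signal (mV).
#' @param snr_db Target SNR in dB.
#' @param f Spike repetition rate in events per second; must satisfy
#'   `0 < f < fs/2`.
#' @param fs Sampling frequency (Hz).
#' @param seed Optional seed.
#' @param tap_jitter Add per-tap uniform noise to the template (disable for
#'   exact-template testing).
#' @param phase Optional fixed phase offset in samples (drawn uniformly on
#'   `[0, fs/f)` when `NULL`).
#' @return Noise vector of `length(x)`.
#' @export
noise_random_spikes <- function(x, snr_db, f, fs, seed = NULL,
                                tap_jitter = TRUE, phase = NULL) {
  if (f <= 0 || f >= fs / 2)
    stop("spike rate f must satisfy 0 < f < fs/2")
  pn <- noise_power(x, snr_db)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  period <- fs / f
  if (is.null(phase)) phase <- stats::runif(1, 0, period)
  starts <- if (phase > n - 1) numeric(0) else seq(phase, n - 1, by = period)
  noise <- rep(0, n)
  amp <- sqrt(pn / f)
  for (s in starts) {
    taps <- SPIKE_TEMPLATE
    if (tap_jitter) taps <- taps + stats::runif(5, -0.25, 0.25)
    idx0 <- round(s) + seq_along(taps) - 1L
    ok <- idx0 >= 0 & idx0 < n
    noise[idx0[ok] + 1L] <- noise[idx0[ok] + 1L] + amp * taps[ok]
  }
  noise
}

#' Amplifier saturation
#'
#' Clips the signal to `[-S_v, S_v]` with saturation value
#' `S_v = p * max(|x|)`; the returned noise is the additive correction, zero
#' wherever `|x| < S_v`.
#'
#' @param x Single-lead signal (mV).
#' @param p Saturation proportion in (0, 1].
#' @return Noise vector such that `x + noise = pmin(pmax(x, -S_v), S_v)`.
#' @export
noise_amplifier_saturation <- function(x, p) {
  if (p <= 0 || p > 1) stop("saturation proportion p must lie in (0, 1]")
  sv <- p * max(abs(x))
  noise <- rep(0, length(x))
  hi <- x >= sv; lo <- x <= -sv
  noise[hi] <- -x[hi] + sv
  noise[lo] <- -x[lo] - sv
  noise
}

#' Sinusoidal noise (powerline / baseline wander) at a target SNR
#'
#' Deterministic cosine `sqrt(2 P_n) * cos(2 pi f n / fs)` over 0-based
#' sample indices. Serves powerline noise with `f = 50` Hz and baseline
#' wander with `f = 0.5` Hz.
#'
#' @param x Single-lead signal (mV).
#' @param snr_db Target SNR in dB.
#' @param f Frequency in Hz, `0 < f < fs/2`.
#' @param fs Sampling frequency (Hz).
#' @return Noise vector of `length(x)`.
#' @export
noise_sinusoid <- function(x, snr_db, f, fs) {
  if (f <= 0 || f >= fs / 2) stop("f must satisfy 0 < f < fs/2")
  pn <- noise_power(x, snr_db)
  n0 <- seq_along(x) - 1L
  sqrt(2 * pn) * cos(2 * pi * f * n0 / fs)
}

#' Pacemaker spikes ahead of QRS onsets
#'
#' Places a constant value `sqrt(P_n / f)` on a small neighbourhood
#' immediately before each QRS onset (default width 1 sample), zero
#' elsewhere.
#'
#' @param x Single-lead signal (mV).
#' @param snr_db Target SNR in dB.
#' @param f Nominal spike rate used in the amplitude normalization.
#' @param qrs_onsets 0-based QRS onset sample indices.
#' @param width Neighbourhood width in samples.
#' @return Noise vector of `length(x)`.
#' @export
noise_pacemaker_spikes <- function(x, snr_db, f, qrs_onsets, width = 1L) {
  if (f <= 0) stop("f must be positive")
  if (length(qrs_onsets) && (any(qrs_onsets < 0) ||
                             any(qrs_onsets >= length(x))))
    stop("QRS onsets must lie within the record")
  pn <- noise_power(x, snr_db)
  noise <- rep(0, length(x))
  amp <- sqrt(pn / f)
  for (on in qrs_onsets) {
    idx0 <- (on - width):(on - 1L)
    idx0 <- idx0[idx0 >= 0]
    noise[idx0 + 1L] <- amp
  }
  noise
}

#' Jitter a noise hyperparameter
#'
#' Adds a uniform draw on `(-snr_db/10, +snr_db/10)` to a generator
#' hyperparameter, maximizing input variability across augmentation calls.
#'
#' @param value Hyperparameter value.
#' @param snr_db SNR (dB) governing the jitter half-width.
#' @param enabled Return `value` unchanged when `FALSE`.
#' @return Jittered value.
#' @export
jitter_hyperparameter <- function(value, snr_db, enabled = TRUE) {
  if (!enabled) return(value)
  value + stats::runif(length(value), -snr_db / 10, snr_db / 10)
}

#' Training-time augmentation policy
#'
#' A list of noise sources, each applied independently with a given
#' probability (capped at `max_concurrent` sources per call). SNRs are
#' drawn uniformly from `snr_range` per invocation; frequency-like
#' hyperparameters receive uniform jitter scaled by SNR/10 when
#' `jitter = TRUE`.
#'
#' @param kinds Character vector among `"AWGN"`, `"RS"`, `"AS"`, `"PN"`,
#'   `"BW"`, `"PS"`.
#' @param prob Per-source application probability (recycled).
#' @param snr_range SNR draw range in dB.
#' @param max_concurrent Maximum number of sources applied at once.
#' @param jitter Enable hyperparameter jitter.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(kinds = c("AWGN", "RS", "AS", "PN", "BW", "PS"),
                                prob = 0.25, snr_range = c(5, 30),
                                max_concurrent = 3L, jitter = TRUE) {
  kinds <- match.arg(kinds, c("AWGN", "RS", "AS", "PN", "BW", "PS"),
                     several.ok = TRUE)
  prob <- rep_len(prob, length(kinds))
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  structure(
    list(kinds = kinds, prob = prob, snr_range = snr_range,
         max_concurrent = as.integer(max_concurrent), jitter = jitter),
    class = "augmentation_policy"
  )
}

## Default per-source hyperparameters: powerline 50 Hz, baseline wander
## 0.5 Hz, random/pacemaker spikes around 2 events/s, saturation at 80% of
## the signal range.
default_source_params <- function(kind) {
  switch(kind,
         PN = list(f = 50), BW = list(f = 0.5),
         RS = list(f = 2), PS = list(f = 2),
         AS = list(p = 0.8), AWGN = list())
}

#' Apply an augmentation policy to one lead
#'
#' Draws, for each source in the policy, an application coin flip and an
#' SNR, generates the corresponding noise and adds it to the signal. Labels
#' are noise-invariant: the fiducials are returned untouched.
#'
#' @param x Single-lead signal (mV).
#' @param fs Sampling frequency (Hz).
#' @param policy An [augmentation_policy()]; `NULL` is the identity.
#' @param qrs_onsets 0-based QRS onset samples (needed by the pacemaker
#'   source; skipped when empty).
#' @param seed Optional integer seed.
#' @return The augmented signal (same length).
#' @export
augment_lead <- function(x, fs, policy, qrs_onsets = integer(0),
                         seed = NULL) {
  if (is.null(policy)) return(x)
  stopifnot(inherits(policy, "augmentation_policy"))
  if (!is.null(seed)) set.seed(seed)
  if (signal_power(x) == 0) return(x)
  applied <- 0L
  out <- x
  for (i in seq_along(policy$kinds)) {
    if (applied >= policy$max_concurrent) break
    if (stats::runif(1) >= policy$prob[i]) next
    kind <- policy$kinds[i]
    snr <- stats::runif(1, policy$snr_range[1], policy$snr_range[2])
    par <- default_source_params(kind)
    if (policy$jitter && !is.null(par$f)) {
      par$f <- max(jitter_hyperparameter(par$f, snr), 0.05)
      par$f <- min(par$f, fs / 2 - 1e-6)
    }
    if (policy$jitter && !is.null(par$p)) {
      par$p <- min(max(jitter_hyperparameter(par$p, snr) , 0.05), 1)
    }
    noise <- switch(kind,
      AWGN = noise_awgn(x, snr),
      RS   = noise_random_spikes(x, snr, par$f, fs),
      AS   = noise_amplifier_saturation(x, par$p),
      PN   = noise_sinusoid(x, snr, par$f, fs),
      BW   = noise_sinusoid(x, snr, par$f, fs),
      PS   = if (length(qrs_onsets))
               noise_pacemaker_spikes(x, snr, par$f, qrs_onsets)
             else rep(0, length(x)))
    out <- out + noise
    applied <- applied + 1L
  }
  out
}
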