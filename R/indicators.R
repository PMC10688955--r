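#' Trial window for indicator extraction
#'
#' Indicators are computed from the moment the pedestrian begins to cross
#' until 3 s after it has passed, the extra 3 s accounting for the latency
#' between a stimulus and the corresponding skin-conductance response. Both
#' boundaries are inclusive.
#'
#' @param start Window start (s).
#' @param end Window end (s), normally pass time + 3.
#' @return A `trial_window` list.
#' @export
trial_window <- function(start, end) {
  if (!(end > start)) stop("window end must exceed start")
  structure(list(start = start, end = end), class = "trial_window")
}

#' Preprocess an electrodermal-activity trace
#'
#' Applies, in order: resampling to 50 Hz (linear interpolation), a centred
#' 1-s moving median, and a 1-Hz low-pass filter (2nd-order Butterworth,
#' applied forward and backward so the phase is preserved). Constants pass
#' through unchanged away from the edges; single-sample artefacts are
#' removed by the median stage; components above 1 Hz are strongly
#' attenuated.
#'
#' @param trace A data.frame with columns `t` (seconds, uniformly spaced)
#'   and `value` (microsiemens); input rate must be at least 50 Hz.
#' @param out_rate Output sampling rate (Hz).
#' @return A data.frame `t`, `value` at `out_rate`.
#' @export
preprocess_eda <- function(trace, out_rate = 50) {
  t <- trace$t
  if (length(t) < 2) stop("trace too short")
  dt <- diff(t)
  rate_in <- 1 / stats::median(dt)
  if (rate_in < out_rate - 1e-9) stop("input rate must be at least ", out_rate, " Hz")
  span <- t[length(t)] - t[1]
  if (span < 1) stop("trace must span at least 1 s")
  tt <- seq(t[1], t[length(t)], by = 1 / out_rate)
  v <- stats::approx(t, trace$value, xout = tt)$y
  k <- 2 * floor(out_rate / 2) + 1   # 1-s centred window, odd length
  v <- stats::runmed(v, k = k, endrule = "median")
  bf <- signal::butter(2, 1 / (out_rate / 2), type = "low")
  v <- signal::filtfilt(bf, v)
  data.frame(t = tt, value = as.numeric(v))
}

#' Detect skin-conductance responses in a phasic trace
#'
#' Scans the trace for trough-to-peak excursions: each local maximum is
#' paired with the preceding local minimum, and the excursion becomes an
#' event when the rise exceeds the amplitude threshold. The event onset is
#' the trough time and the amplitude the trough-to-peak rise.
#'
#' The default threshold is 0.05 microsiemens, a conventional minimum
#' response amplitude for phasic skin-conductance analysis; it is a tunable
#' parameter of the pipeline.
#'
#' @param phasic A data.frame `t`, `value` (phasic conductance).
#' @param amplitude_threshold Minimum trough-to-peak rise (microsiemens).
#' @return A data.frame of events sorted by onset: `onset`, `amplitude`.
#' @export
detect_scrs <- function(phasic, amplitude_threshold = 0.05) {
  v <- phasic$value
  t <- phasic$t
  n <- length(v)
  if (n < 3) return(data.frame(onset = numeric(0), amplitude = numeric(0)))
  rising <- diff(v) > 0
  # a peak is a sample where the trace stops rising (incl. a rising last sample)
  peaks <- which(rising[-(n - 1)] & !rising[-1]) + 1L
  if (rising[n - 1]) peaks <- c(peaks, n)
  onset <- amp <- numeric(0)
  seg_start <- 1L  # search for the trough from the last accepted peak onward
  for (pk in peaks) {
    trough <- seg_start - 1L + which.min(v[seg_start:pk])
    rise <- v[pk] - v[trough]
    if (rise >= amplitude_threshold) {
      onset <- c(onset, t[trough])
      amp <- c(amp, rise)
      seg_start <- pk
    }
  }
  data.frame(onset = onset, amplitude = amp)
}

## samples of a trace falling in a closed window, with boundary interpolation
window_trace <- function(trace, window) {
  inw <- trace$t >= window$start - 1e-12 & trace$t <= window$end + 1e-12
  if (!any(inw)) stop("trial window does not overlap the trace")
  trace[inw, , drop = FALSE]
}

#' Area under the assessed-risk curve (iSA)
#'
#' Trapezoidal integral of the subjective-assessment trace over the trial
#' window; reflects the dynamics of the risk assessment.
#'
#' @param trace A data.frame `t`, `value`.
#' @param window A [trial_window()].
#' @return Non-negative area (value x seconds).
#' @export
compute_isa <- function(trace, window) {
  w <- window_trace(trace, window)
  if (nrow(w) < 2) stop("trial window contains fewer than two samples")
  sum(diff(w$t) * (w$value[-1] + w$value[-nrow(w)]) / 2)
}

#' Maximum assessed risk (mSA)
#'
#' Maximum of the subjective-assessment samples within the trial window.
#'
#' @inheritParams compute_isa
#' @return The in-window maximum.
#' @export
compute_msa <- function(trace, window) {
  w <- window_trace(trace, window)
  max(w$value)
}

#' Count and maximum amplitude of windowed SCRs
#'
#' Counts the skin-conductance responses whose onset falls in the closed
#' trial window and returns the maximum amplitude among them (`nSCR`,
#' `mSCR`); `mSCR` is 0 when no response occurred.
#'
#' @param events A data.frame `onset`, `amplitude`, sorted by onset.
#' @param window A [trial_window()].
#' @return Named numeric vector `c(nSCR, mSCR)`.
#' @export
count_and_max_scr <- function(events, window) {
  inw <- events$onset >= window$start & events$onset <= window$end
  c(nSCR = sum(inw),
    mSCR = if (any(inw)) max(events$amplitude[inw]) else 0)
}

#' Transform specification for the indicator table
#'
#' @param isa_power,msa_power Skewness-correction exponents for iSA and mSA.
#' @param standardize Centre and scale the subjective indicators per
#'   participant (collision trials excluded from the statistics).
#' @param scr_scale Scale the SCR indicators per participant (divide by the
#'   participant's mean non-zero value); no centring, preserving the
#'   non-negativity the compound Poisson-gamma law requires.
#' @return A `transform_spec` list.
#' @export
transform_spec <- function(isa_power = 1 / 2, msa_power = 1 / 3,
                           standardize = TRUE, scr_scale = TRUE) {
  stopifnot(isa_power > 0, isa_power <= 1, msa_power > 0, msa_power <= 1)
  structure(list(isa_power = isa_power, msa_power = msa_power,
                 standardize = standardize, scr_scale = scr_scale),
            class = "transform_spec")
}

#' Apply skewness corrections and per-participant normalisation
#'
#' Raises iSA and mSA to their correction powers (1/2 and 1/3), then centres
#' and scales them to mean 0 and standard deviation 1 within each
#' participant; SCR indicators are divided by the participant's mean
#' non-zero value. All per-participant statistics are computed on
#' non-collision trials only. A participant with zero variance on a
#' subjective indicator (or no non-zero SCR value) keeps scale 1 and is
#' listed in the `flagged` attribute.
#'
#' @param table An indicator table as produced by
#'   [simulate_indicator_table()] (raw scale).
#' @param spec A [transform_spec()].
#' @return The table with transformed indicator columns; attribute
#'   `flagged` lists degenerate participants.
#' @export
apply_transforms <- function(table, spec = transform_spec()) {
  tab <- table
  tab$iSA <- tab$iSA^spec$isa_power
  tab$mSA <- tab$mSA^spec$msa_power
  flagged <- character(0)
  for (pid in unique(tab$participant_id)) {
    ix <- tab$participant_id == pid
    ref <- ix & !tab$is_collision
    if (sum(ref) < 2) stop("participant ", pid, " has fewer than 2 non-collision trials")
    if (spec$standardize) {
      for (col in c("iSA", "mSA")) {
        m <- mean(tab[[col]][ref]); s <- sd(tab[[col]][ref])
        if (!is.finite(s) || s < 1e-12) { s <- 1; flagged <- c(flagged, pid) }
        tab[[col]][ix] <- (tab[[col]][ix] - m) / s
      }
    }
    if (spec$scr_scale) {
      for (col in c("nSCR", "mSCR")) {
        v <- tab[[col]][ref]
        s <- if (any(v > 0)) mean(v[v > 0]) else 1
        if (!any(v > 0)) flagged <- c(flagged, pid)
        tab[[col]][ix] <- tab[[col]][ix] / s
      }
    }
  }
  attr(tab, "flagged") <- unique(flagged)
  attr(tab, "transform_spec") <- spec
  tab
}
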