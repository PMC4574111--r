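# Onset marking for continuous drum-trigger / stimulus channels:
# amplitude threshold plus refractory period.

#' Default extraction parameters
#'
#' The amplitude threshold defaults to 5 times the channel's median absolute
#' amplitude (a reproducible stand-in for the per-participant manual tuning a
#' human operator would do); if that is zero (clean synthetic impulse trains
#' are mostly silent) it falls back to half the channel's peak. The
#' refractory period defaults to 50 ms, well below any stimulus IOI in the
#' battery but longer than the ringing of a single drum hit.
#'
#' @param signal Amplitude vector used for the adaptive threshold (optional).
#' @param amp_threshold Override for the amplitude threshold.
#' @param refractory_ms Refractory period in ms.
#' @return List with `amp_threshold` and `refractory_ms`.
#' @export
extraction_params <- function(signal = NULL, amp_threshold = NULL,
                              refractory_ms = 50) {
  if (is.null(amp_threshold)) {
    if (is.null(signal)) stop("either a signal or an explicit threshold is required")
    amp_threshold <- 5 * stats::median(abs(signal))
    if (amp_threshold <= 0) amp_threshold <- max(abs(signal)) / 2
    if (amp_threshold <= 0) amp_threshold <- 1  # silent channel: no onsets
  }
  if (!is.finite(amp_threshold) || amp_threshold <= 0)
    stop("amp_threshold must be a positive finite number")
  if (!is.finite(refractory_ms) || refractory_ms <= 0)
    stop("refractory_ms must be a positive finite number")
  list(amp_threshold = amp_threshold, refractory_ms = refractory_ms)
}

#' Mark onsets in a continuous channel
#'
#' A sample is marked as an onset iff its absolute amplitude exceeds the
#' threshold and no sample in the preceding `refractory_ms` (open interval)
#' exceeded it. The refractory period prevents the many adjacent
#' high-amplitude samples produced by a single drum hit from being marked as
#' several hits. Times are reported at sample precision in ms; the recorded
#' amplitude is the peak absolute amplitude within the refractory window
#' after the crossing.
#'
#' @param channel Amplitude vector.
#' @param sample_rate_hz Sampling rate.
#' @param params List from [extraction_params()]; built from the channel if
#'   omitted.
#' @return data.frame with `time_ms` (strictly increasing) and `amplitude`.
#' @export
mark_onsets <- function(channel, sample_rate_hz, params = NULL) {
  if (length(channel) && any(!is.finite(channel)))
    stop("non-finite samples in channel")
  if (!length(channel))
    return(data.frame(time_ms = numeric(0), amplitude = numeric(0)))
  if (is.null(params)) params <- extraction_params(channel)
  thr <- params$amp_threshold
  refr_samples <- params$refractory_ms * sample_rate_hz / 1000
  a <- abs(channel)
  above <- which(a > thr)
  if (!length(above))
    return(data.frame(time_ms = numeric(0), amplitude = numeric(0)))
  # marked iff first supra-threshold sample, or preceded by a supra-threshold
  # gap of at least the refractory period
  gap <- diff(above)
  keep <- c(TRUE, gap >= refr_samples)
  idx <- above[keep]
  amp <- vapply(idx, function(i) {
    j <- min(length(a), i + ceiling(refr_samples) - 1)
    max(a[i:j])
  }, numeric(1))
  data.frame(time_ms = (idx - 1) * 1000 / sample_rate_hz, amplitude = amp)
}

#' Extract onsets from a two-channel recording
#'
#' @param recording List with `sample_rate_hz`, `stimulus` and `drum`
#'   amplitude vectors of equal length (as returned by [read_wav()]).
#' @param stim_params,drum_params Optional per-channel extraction parameter
#'   lists; adaptive defaults otherwise.
#' @return List of two onset data.frames (`stimulus`, `drum`) plus the
#'   parameters used, for audit.
#' @export
extract_recording <- function(recording, stim_params = NULL,
                              drum_params = NULL) {
  stopifnot(length(recording$stimulus) == length(recording$drum))
  sp <- if (is.null(stim_params)) extraction_params(recording$stimulus) else stim_params
  dp <- if (is.null(drum_params)) extraction_params(recording$drum) else drum_params
  list(stimulus = mark_onsets(recording$stimulus, recording$sample_rate_hz, sp),
       drum = mark_onsets(recording$drum, recording$sample_rate_hz, dp),
       params = list(stimulus = sp, drum = dp))
}

#' Split battery-timeline onsets into per-trial series
#'
#' Assigns each onset to the trial whose `[start_ms, end_ms)` window contains
#' it and checks that the stimulus-channel onsets in each trial match the
#' scheduled count. Mismatching trials are flagged for manual review (the
#' continuous-recording workflow assumes marked onsets are visually checked
#' against the raw signal).
#'
#' @param stim_onsets,drum_onsets Onset data.frames with `time_ms` on the
#'   battery timeline.
#' @param plan A [battery_plan()].
#' @return List of per-trial records: `test`, `trial`, `stimulus` and `drum`
#'   onset times relative to trial start, and `flagged`.
#' @export
split_by_trial <- function(stim_onsets, drum_onsets, plan) {
  stopifnot(inherits(plan, "battery_plan"))
  out <- list()
  for (test in c("metronome", "adaptation", "drumalong", "memory")) {
    for (tr in plan[[test]]) {
      in_win <- function(t) t >= tr$start_ms & t < tr$end_ms
      st <- stim_onsets$time_ms[in_win(stim_onsets$time_ms)] - tr$start_ms
      dr <- drum_onsets$time_ms[in_win(drum_onsets$time_ms)] - tr$start_ms
      out[[length(out) + 1L]] <- list(
        test = test, trial = tr$trial, stimulus = st, drum = dr,
        flagged = length(st) != length(tr$onset_times_ms))
    }
  }
  out
}
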