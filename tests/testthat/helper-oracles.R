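# Independent brute-force oracles and small fixtures used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal per-sample scan of the onset definition: a sample is an onset iff
# it exceeds the threshold and no sample in the preceding refractory window
# (open interval) exceeded it.
oracle_mark_onsets <- function(channel, sample_rate_hz, thr, refr_ms) {
  refr_samples <- refr_ms * sample_rate_hz / 1000
  marks <- integer(0)
  for (i in seq_along(channel)) {
    if (abs(channel[i]) <= thr) next
    lo <- max(1, ceiling(i - refr_samples + 1e-9))
    prior <- if (lo <= i - 1) any(abs(channel[lo:(i - 1)]) > thr) else FALSE
    if (!prior) marks <- c(marks, i)
  }
  (marks - 1) * 1000 / sample_rate_hz
}

# Window-occupancy oracle for the hit/rest grid: slot p is hit iff any drum
# onset lies in [t_p - 100, t_p + 100).
oracle_drum_grid <- function(drum_times, grid_times) {
  sapply(grid_times, function(t) {
    hit <- FALSE
    for (d in drum_times) if (d >= t - 100 && d < t + 100) hit <- TRUE
    as.integer(hit)
  })
}

# Align the columns of a recovered loading matrix to a reference, over
# column permutations and sign flips; returns the best-aligned matrix.
align_loadings <- function(L, ref) {
  stopifnot(ncol(L) == ncol(ref))
  perms <- if (ncol(L) == 2) list(1:2, 2:1) else list(seq_len(ncol(L)))
  best <- NULL; best_err <- Inf
  for (pm in perms) {
    Lp <- L[, pm, drop = FALSE]
    for (j in seq_len(ncol(Lp)))
      if (sum((Lp[, j] - ref[, j])^2) > sum((-Lp[, j] - ref[, j])^2))
        Lp[, j] <- -Lp[, j]
    err <- sum((Lp - ref)^2)
    if (err < best_err) { best <- Lp; best_err <- err }
  }
  best
}

# A deterministic perfect drummer: taps exactly at the stimulus onsets.
perfect_taps <- function(trial) trial$onset_times_ms

# Tiny impulse-train channel: amplitude `amp` spikes at the given times.
impulse_channel <- function(times_ms, sr, dur_ms, amp = 1) {
  x <- numeric(ceiling(dur_ms * sr / 1000))
  x[round(times_ms * sr / 1000) + 1] <- amp
  x
}
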