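# The four test-scoring procedures. Drum data enter as numeric onset-time
# vectors (ms, relative to trial start); trials are the schedule objects
# from battery-schedule.R.

GRID_HALF_WINDOW_MS <- 100

# Nearest-onset matching of taps to scheduled beats: a tap is assigned to a
# beat if it is the closest tap and lies within half an IOI of it; each tap
# is used at most once (closest beat wins).
.match_taps <- function(taps, beat_times, half_window) {
  if (!length(taps)) return(rep(NA_real_, length(beat_times)))
  assigned <- rep(NA_integer_, length(beat_times))
  dist <- abs(outer(beat_times, taps, `-`))
  repeat {
    i <- which.min(dist)
    if (!length(i) || dist[i] > half_window) break
    b <- (i - 1) %% length(beat_times) + 1
    t <- (i - 1) %/% length(beat_times) + 1
    assigned[b] <- t
    dist[b, ] <- Inf
    dist[, t] <- Inf
  }
  ifelse(is.na(assigned), NA_real_, taps[assigned])
}

# Produced inter-tap intervals between taps assigned to consecutive beats of
# the analyzed window.
.analyzed_intervals <- function(drum_times, trial, n_analyzed) {
  beats <- utils::tail(trial$onset_times_ms, n_analyzed)
  matched <- .match_taps(drum_times, beats, trial$ioi_ms / 2)
  ok <- which(!is.na(matched))
  if (length(ok) < 3) return(NULL)
  consec <- which(diff(ok) == 1)
  iv <- matched[ok[consec + 1]] - matched[ok[consec]]
  if (length(iv) < 2) NULL else iv
}

#' Metronome-trial tapping variability
#'
#' The standard deviation (sample, n-1 denominator) of the participant's
#' produced inter-tap intervals over the last `n_analyzed` beats of the
#' trial, divided by the stimulus IOI — a dimensionless consistency measure
#' invariant to the trial tempo. Taps are matched to beats by
#' nearest-neighbour within half an IOI; unmatched taps are dropped.
#'
#' @param drum_times Tap onset times (ms, trial-relative).
#' @param trial A `metronome_trial`.
#' @param n_analyzed Number of final beats analyzed (default 20; the earlier
#'   beats give the participant time to lock in).
#' @return Normalized variability, or `NA` if fewer than 3 taps match.
#' @export
metronome_trial_variability <- function(drum_times, trial, n_analyzed = 20) {
  iv <- .analyzed_intervals(drum_times, trial, n_analyzed)
  if (is.null(iv)) return(NA_real_)
  stats::sd(iv) / trial$ioi_ms
}

#' Metronome-trial mean tempo deviation
#'
#' Absolute difference between the mean produced inter-tap interval (over
#' the analyzed beats) and the stimulus IOI, in ms. Used by the exclusion
#' rule for participants who drummed at their own tempo.
#' @inheritParams metronome_trial_variability
#' @export
metronome_trial_tempo_dev <- function(drum_times, trial, n_analyzed = 20) {
  iv <- .analyzed_intervals(drum_times, trial, n_analyzed)
  if (is.null(iv)) return(NA_real_)
  abs(mean(iv) - trial$ioi_ms)
}

#' Participant-level metronome score
#'
#' Mean of the available per-trial variabilities; missing trials are
#' reported, and an all-missing participant gets `NA`.
#' @param trial_values Vector of per-trial variabilities (may contain `NA`).
#' @return List with `score` and `n_missing`.
#' @export
metronome_score <- function(trial_values) {
  n_missing <- sum(is.na(trial_values))
  score <- if (n_missing == length(trial_values)) NA_real_
           else mean(trial_values, na.rm = TRUE)
  list(score = score, n_missing = n_missing)
}

#' Tempo-adaptation error of one shifted trial
#'
#' For the last two inter-tap intervals the participant produced in the
#' trial (up to one post-shift IOI past the final scheduled onset), the
#' absolute difference between the post-shift target IOI and the produced
#' interval, averaged over the two.
#'
#' @param drum_times Tap onset times (ms, trial-relative).
#' @param trial A shifted `adaptation_trial`.
#' @return Error in ms, or `NA` if fewer than 3 usable post-shift taps.
#' @export
adaptation_trial_error <- function(drum_times, trial) {
  if (!isTRUE(trial$shifted))
    stop("adaptation error is defined for shifted trials only")
  onsets <- trial$onset_times_ms
  shift_time <- onsets[trial$n_base]          # last base-tempo onset
  t_max <- onsets[length(onsets)] + trial$post_ioi_ms  # one IOI of grace
  taps <- drum_times[drum_times > shift_time - trial$post_ioi_ms / 2 &
                     drum_times <= t_max]
  if (length(taps) < 3) return(NA_real_)
  iv <- utils::tail(diff(sort(taps)), 2)
  mean(abs(trial$post_ioi_ms - iv))
}

#' Participant-level tempo-adaptation score
#'
#' Mean error over the fifty shifted trials (available ones if some are
#' missing).
#' @param trial_errors Vector of per-trial errors in ms (may contain `NA`).
#' @return List with `score` and `n_missing`.
#' @export
adaptation_score <- function(trial_errors) {
  n_missing <- sum(is.na(trial_errors))
  score <- if (n_missing == length(trial_errors)) NA_real_
           else mean(trial_errors, na.rm = TRUE)
  list(score = score, n_missing = n_missing)
}

#' Convert drum onsets to a hit/rest grid
#'
#' Grid slot `p` is 1 iff at least one drum onset lies within 100 ms of the
#' slot's start time, i.e. in the half-open window `[t_p - 100, t_p + 100)`;
#' adjacent 200-ms windows tile time exactly, so a tap at +100 ms belongs to
#' the next slot.
#'
#' @param drum_times Drum onset times (ms).
#' @param grid_times_ms Start times of the 200-ms slots.
#' @return Integer 0/1 vector, one bit per slot.
#' @export
drum_grid <- function(drum_times, grid_times_ms) {
  vapply(grid_times_ms, function(t)
    as.integer(any(drum_times >= t - GRID_HALF_WINDOW_MS &
                   drum_times < t + GRID_HALF_WINDOW_MS)),
    integer(1))
}

#' Positional agreement of two hit/rest grids
#'
#' The percentage of slots whose bits match: e.g. stimulus `[0 1 1 0]`
#' against drumming `[1 1 1 0]` scores 75%. Extra hits on rest slots and
#' missed hits are penalized identically through the mismatch count.
#'
#' @param stim,drum Equal-length 0/1 vectors.
#' @return Percentage in [0, 100].
#' @export
grid_agreement <- function(stim, drum) {
  if (length(stim) != length(drum)) stop("grids must have equal length")
  100 * mean(as.integer(stim) == as.integer(drum))
}

#' Score one drum-along trial
#'
#' The stimulus cycle's hit/rest grid is compared slot-by-slot with the
#' participant's drum grid over repetitions 2 through `n_reps` (the first
#' repetition is a listening pass and is excluded).
#'
#' @param drum_times Tap onset times (ms, trial-relative).
#' @param trial A `drumalong_trial`.
#' @param reps Repetitions scored (default 2:10).
#' @return Agreement percentage.
#' @export
drumalong_trial_score <- function(drum_times, trial, reps = NULL) {
  seqc <- trial$sequence
  if (is.null(reps)) reps <- 2:trial$n_reps
  slot_times <- as.vector(vapply(reps, function(r)
    trial$lead_in_ms + (r - 1) * seqc$cycle_ms +
      GRID_RES_MS * (seq_along(seqc$grid) - 1),
    numeric(length(seqc$grid))))
  stim_bits <- rep(seqc$grid, length(reps))
  grid_agreement(stim_bits, drum_grid(drum_times, slot_times))
}

#' Participant-level drum-along score
#' @param trial_scores Vector of per-trial agreement percentages.
#' @return List with `score` and `n_missing`.
#' @export
drumalong_score <- function(trial_scores) {
  n_missing <- sum(is.na(trial_scores))
  score <- if (n_missing == length(trial_scores)) NA_real_
           else mean(trial_scores, na.rm = TRUE)
  list(score = score, n_missing = n_missing)
}

#' Score one sequence-memory trial
#'
#' The participant reproduces the sequence during a silent pause as if it
#' had repeated a fourth time; the drum grid is built over the virtual
#' fourth repetition's slot times (same 200-ms windows) and compared with
#' the stimulus grid.
#'
#' @param drum_times Tap onset times (ms, trial-relative).
#' @param trial A `memory_trial`.
#' @return Agreement percentage.
#' @export
memory_trial_score <- function(drum_times, trial) {
  seqc <- trial$sequence
  slot_times <- trial$lead_in_ms + trial$n_reps * seqc$cycle_ms +
    GRID_RES_MS * (seq_along(seqc$grid) - 1)
  grid_agreement(seqc$grid, drum_grid(drum_times, slot_times))
}

#' Participant-level sequence-memory score
#' @param trial_scores Vector of per-trial agreement percentages.
#' @return List with `score` and `n_missing`.
#' @export
memory_score <- function(trial_scores) {
  n_missing <- sum(is.na(trial_scores))
  score <- if (n_missing == length(trial_scores)) NA_real_
           else mean(trial_scores, na.rm = TRUE)
  list(score = score, n_missing = n_missing)
}

#' Score a participant's full battery
#'
#' @param trials List with elements `metronome`, `adaptation`, `drumalong`,
#'   `memory`; each a list of records `list(trial = <schedule trial>,
#'   drum = <tap times>)` (a `NULL` record marks a lost trial).
#' @param verbal Optional named vector/list with `awm` and `digits_reversed`.
#' @param participant Participant identifier.
#' @return One-row data.frame with the four rhythm scores, verbal scores,
#'   the mean tempo deviation, and missing-trial counts.
#' @export
score_participant <- function(trials, verbal = NULL, participant = 1L) {
  per <- function(recs, f) vapply(recs, function(r)
    if (is.null(r)) NA_real_ else f(r$drum, r$trial), numeric(1))
  met_v <- per(trials$metronome, metronome_trial_variability)
  met_d <- per(trials$metronome, metronome_trial_tempo_dev)
  ada <- per(Filter(function(r) is.null(r) || isTRUE(r$trial$shifted),
                    trials$adaptation), adaptation_trial_error)
  dal <- per(trials$drumalong, drumalong_trial_score)
  mem <- per(trials$memory, memory_trial_score)
  m <- metronome_score(met_v); a <- adaptation_score(ada)
  d <- drumalong_score(dal); r <- memory_score(mem)
  data.frame(
    participant = participant,
    metronome_variability = m$score,
    adaptation_error_ms = a$score,
    drumalong_pct = d$score,
    memory_pct = r$score,
    awm = if (is.null(verbal)) NA_real_ else as.numeric(verbal[["awm"]]),
    digits_reversed = if (is.null(verbal)) NA_real_
                      else as.numeric(verbal[["digits_reversed"]]),
    mean_tempo_dev_ms = mean(met_d, na.rm = TRUE),
    n_missing_trials = m$n_missing + a$n_missing + d$n_missing + r$n_missing)
}

#' Write a score table to CSV
#' @param scores data.frame as built by [score_participant()]/[score_cohort()].
#' @param path Output CSV path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read a score table from CSV
#' @param path CSV path with the columns `metronome_variability`,
#'   `adaptation_error_ms`, `drumalong_pct`, `memory_pct`, `awm`,
#'   `digits_reversed`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("metronome_variability", "adaptation_error_ms",
            "drumalong_pct", "memory_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table lacks columns: ", paste(miss, collapse = ", "))
  df
}
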