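# Stimulus schedules for the four-test rhythm battery. All times in ms,
# relative to trial start unless a trial carries a start_ms offset.

SEQ_IOI_MULTISET <- c(200, 200, 200, 200, 200, 400, 400, 600, 800)
SEQ_CYCLE_MS <- 3200
GRID_RES_MS <- 200

#' Metronome trials of the synchronization test
#'
#' Builds the six isochronous metronome trials: two each at inter-onset
#' intervals (IOIs) of 667, 500 and 333 ms (1.5, 2 and 3 Hz), always in that
#' order, each with 40 snare onsets.
#'
#' @param lead_in_ms Silence before the first onset of each trial (ms).
#' @return A list of six `metronome_trial` objects with fields `ioi_ms`,
#'   `n_beats` and `onset_times_ms`.
#' @export
make_metronome_trials <- function(lead_in_ms = 1000) {
  iois <- c(667, 667, 500, 500, 333, 333)
  lapply(seq_along(iois), function(i) {
    ioi <- iois[i]
    structure(
      list(test = "metronome", trial = i, ioi_ms = ioi, n_beats = 40L,
           rate_hz = 1000 / ioi,
           onset_times_ms = lead_in_ms + ioi * (0:39)),
      class = c("metronome_trial", "battery_trial"))
  })
}

#' Tempo-adaptation trials
#'
#' Builds the 55 tempo-adaptation trials: a 500-ms-IOI conga pulse repeated
#' between 6 and 10 times (uniformly at random), followed by five more
#' presentations at a post-shift IOI drawn from 450--550 ms in 10-ms steps.
#' Five trials use each post IOI, so 50 of the 55 trials are shifted
#' (post IOI different from 500 ms) and five are catch trials. Trial order is
#' shuffled under the seed.
#'
#' @param seed Integer seed controlling the per-trial base-repetition counts
#'   and the trial order.
#' @param lead_in_ms Silence before the first onset of each trial (ms).
#' @return A list of 55 `adaptation_trial` objects with fields `base_ioi_ms`,
#'   `n_base`, `post_ioi_ms`, `shifted` and `onset_times_ms`.
#' @export
make_adaptation_trials <- function(seed = 1L, lead_in_ms = 1000) {
  post_iois <- rep(seq(450, 550, by = 10), each = 5)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  post_iois <- sample(post_iois)
  n_bases <- sample(6:10, length(post_iois), replace = TRUE)
  lapply(seq_along(post_iois), function(i) {
    n_base <- n_bases[i]
    post <- post_iois[i]
    onsets <- lead_in_ms + cumsum(c(0, rep(500, n_base - 1), rep(post, 5)))
    structure(
      list(test = "adaptation", trial = i, base_ioi_ms = 500, n_base = n_base,
           post_ioi_ms = post, shifted = post != 500, n_post = 5L,
           onset_times_ms = onsets),
      class = c("adaptation_trial", "battery_trial"))
  })
}

#' Construct a rhythmic sequence from an IOI ordering
#'
#' A sequence is one 3.2-s four-measure cycle whose nine onsets are separated
#' by a fixed multiset of IOIs: five of 200 ms, two of 400 ms, one of 600 ms
#' and one of 800 ms (the last IOI closes the cycle). Orderings differ in
#' where the onsets fall on the 200-ms grid, which determines how strongly
#' metrical the pattern is.
#'
#' @param ioi_order_ms Ordered IOIs; with `strict = TRUE` they must be a
#'   permutation of the canonical multiset.
#' @param metricality `"strong"` or `"weak"`.
#' @param strict Enforce the canonical multiset (default). With
#'   `strict = FALSE` any IOIs that are positive multiples of 200 ms are
#'   accepted (toy sequences for testing).
#' @return A `rhythm_sequence` with the onset times within the cycle and the
#'   hit/rest grid.
#' @export
make_sequence <- function(ioi_order_ms, metricality = c("strong", "weak"),
                          strict = TRUE) {
  metricality <- match.arg(metricality)
  ioi_order_ms <- as.numeric(ioi_order_ms)
  if (strict) {
    if (!identical(sort(ioi_order_ms), sort(as.numeric(SEQ_IOI_MULTISET))))
      stop("invalid sequence: IOIs must be a permutation of {200x5, 400x2, 600, 800}")
  } else {
    if (any(ioi_order_ms <= 0) || any(ioi_order_ms %% GRID_RES_MS != 0))
      stop("invalid sequence: IOIs must be positive multiples of 200 ms")
  }
  cycle <- sum(ioi_order_ms)
  onsets <- cumsum(c(0, ioi_order_ms))[seq_along(ioi_order_ms)]
  grid <- integer(cycle / GRID_RES_MS)
  grid[onsets / GRID_RES_MS + 1] <- 1L
  structure(
    list(ioi_order_ms = ioi_order_ms, metricality = metricality,
         cycle_ms = cycle, onset_times_ms = onsets, grid = grid),
    class = "rhythm_sequence")
}

#' Hit/rest grid of a sequence
#'
#' The cycle is divided into 200-ms slots; slot `p` (0-based) is 1 iff an
#' onset falls at time `200 * p`. Slot 0 is always a hit (every cycle starts
#' with an onset).
#'
#' @param seq A `rhythm_sequence`.
#' @return Integer 0/1 vector (length 16 for protocol sequences).
#' @export
grid_from_sequence <- function(seq) {
  stopifnot(inherits(seq, "rhythm_sequence"))
  seq$grid
}

#' Recover a sequence from its hit/rest grid
#'
#' Inverse of [grid_from_sequence()]: onset positions become IOIs, the final
#' IOI wrapping to the end of the cycle.
#'
#' @param grid 0/1 vector starting with a 1.
#' @param metricality Label to attach.
#' @param strict Passed to [make_sequence()].
#' @export
sequence_from_grid <- function(grid, metricality = "strong", strict = TRUE) {
  grid <- as.integer(grid)
  if (!length(grid) || grid[1] != 1L || !all(grid %in% 0:1))
    stop("grid must be a 0/1 vector beginning with a hit")
  pos <- (which(grid == 1L) - 1L) * GRID_RES_MS
  iois <- diff(c(pos, length(grid) * GRID_RES_MS))
  make_sequence(iois, metricality, strict = strict)
}

# Enumerate all distinct orderings of the IOI multiset, classify by how many
# of the four 800-ms beat positions (grid slots 0, 4, 8, 12) carry an onset,
# and keep a deterministic (lexicographic) bank of strongly metrical
# sequences (all four beats marked) and weakly metrical ones (at most two).
# Cached after first use.
.seq_bank_env <- new.env(parent = emptyenv())

.multiset_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (p in .multiset_perms(rest)) out[[length(out) + 1L]] <- c(u, p)
  }
  out
}

#' Deterministic bank of strongly and weakly metrical sequences
#'
#' All 1512 orderings of the IOI multiset are enumerated; an ordering is
#' strongly metrical if all four beat positions of the 3.2-s cycle (0, 800,
#' 1600, 2400 ms) carry an onset, weakly metrical if at most two do (more
#' rests in metrically strong positions, i.e. more syncopation). The first
#' `n_strong`/`n_weak` of each class in lexicographic IOI order are returned.
#'
#' @param n_strong,n_weak Number of sequences of each class.
#' @return List with `strong` and `weak` lists of `rhythm_sequence` objects.
#' @export
sequence_bank <- function(n_strong = 17, n_weak = 17) {
  if (is.null(.seq_bank_env$all)) {
    pp <- .multiset_perms(SEQ_IOI_MULTISET)
    ord <- do.call(order, as.data.frame(do.call(rbind, pp)))
    pp <- pp[ord]
    beat_hits <- vapply(pp, function(io) {
      pos <- cumsum(c(0, io))[1:9]
      sum(c(0, 800, 1600, 2400) %in% pos)
    }, numeric(1))
    .seq_bank_env$all <- pp
    .seq_bank_env$beat_hits <- beat_hits
  }
  strong_idx <- which(.seq_bank_env$beat_hits == 4)
  weak_idx <- which(.seq_bank_env$beat_hits <= 2)
  if (n_strong > length(strong_idx) || n_weak > length(weak_idx))
    stop("requested more sequences than the bank contains")
  list(
    strong = lapply(.seq_bank_env$all[strong_idx[seq_len(n_strong)]],
                    make_sequence, metricality = "strong"),
    weak = lapply(.seq_bank_env$all[weak_idx[seq_len(n_weak)]],
                  make_sequence, metricality = "weak"))
}

.sequence_trial <- function(seq, test, trial, n_reps, pause_cycles = 0,
                            lead_in_ms = 1000) {
  rep_starts <- lead_in_ms + seq$cycle_ms * (seq_len(n_reps) - 1)
  onsets <- as.vector(outer(seq$onset_times_ms, rep_starts, `+`))
  structure(
    list(test = test, trial = trial, sequence = seq, n_reps = n_reps,
         pause_ms = pause_cycles * seq$cycle_ms, lead_in_ms = lead_in_ms,
         onset_times_ms = sort(onsets)),
    class = c(paste0(test, "_trial"), "battery_trial"))
}

#' Drum-along trials
#'
#' Four trials, each one sequence repeated ten times (two strongly and two
#' weakly metrical sequences).
#' @param sequences Optional list of 4 `rhythm_sequence` objects (2 strong
#'   then 2 weak); defaults to the head of [sequence_bank()].
#' @param lead_in_ms Silence before the first onset (ms).
#' @export
make_drumalong_trials <- function(sequences = NULL, lead_in_ms = 1000) {
  if (is.null(sequences)) {
    bank <- sequence_bank(2, 2)
    sequences <- c(bank$strong, bank$weak)
  }
  stopifnot(length(sequences) == 4)
  lapply(1:4, function(i)
    .sequence_trial(sequences[[i]], "drumalong", i, n_reps = 10,
                    lead_in_ms = lead_in_ms))
}

#' Sequence-memory trials
#'
#' Thirty trials, each one sequence repeated three times followed by a silent
#' pause of one cycle during which the participant reproduces the sequence as
#' if it had repeated a fourth time. The first 15 trials are strongly
#' metrical, the last 15 weakly metrical.
#' @param sequences Optional list of 30 `rhythm_sequence` objects (15 strong
#'   then 15 weak); defaults to [sequence_bank()] entries not used by the
#'   drum-along test.
#' @param lead_in_ms Silence before the first onset (ms).
#' @export
make_memory_trials <- function(sequences = NULL, lead_in_ms = 1000) {
  if (is.null(sequences)) {
    bank <- sequence_bank(17, 17)
    sequences <- c(bank$strong[3:17], bank$weak[3:17])
  }
  stopifnot(length(sequences) == 30)
  lapply(seq_along(sequences), function(i)
    .sequence_trial(sequences[[i]], "memory", i, n_reps = 3,
                    pause_cycles = 1, lead_in_ms = lead_in_ms))
}

#' Full battery plan
#'
#' Assembles the four tests into one plan: 6 metronome trials, 55
#' tempo-adaptation trials (50 shifted), 4 drum-along trials and 30
#' sequence-memory trials. Trials are laid out on one continuous timeline
#' with `gap_ms` of silence between trials, so the plan can drive both
#' simulation and the splitting of continuous recordings.
#'
#' @param seed Seed for the adaptation-schedule randomization.
#' @param lead_in_ms Within-trial silence before the first onset (ms).
#' @param gap_ms Silence between consecutive trials (ms).
#' @return A `battery_plan`: lists `metronome`, `adaptation`, `drumalong`,
#'   `memory`, each trial annotated with its absolute `start_ms`.
#' @export
battery_plan <- function(seed = 1L, lead_in_ms = 1000, gap_ms = 2000) {
  plan <- list(metronome = make_metronome_trials(lead_in_ms),
               adaptation = make_adaptation_trials(seed, lead_in_ms),
               drumalong = make_drumalong_trials(lead_in_ms = lead_in_ms),
               memory = make_memory_trials(lead_in_ms = lead_in_ms))
  t0 <- 0
  for (test in names(plan)) {
    for (i in seq_along(plan[[test]])) {
      tr <- plan[[test]][[i]]
      dur <- max(tr$onset_times_ms) + if (!is.null(tr$pause_ms)) tr$pause_ms else 0
      tr$start_ms <- t0
      tr$end_ms <- t0 + dur + gap_ms
      t0 <- tr$end_ms
      plan[[test]][[i]] <- tr
    }
  }
  structure(c(plan, list(seed = seed, lead_in_ms = lead_in_ms,
                         gap_ms = gap_ms, total_ms = t0)),
            class = "battery_plan")
}

#' Flatten a plan to a schedule table
#'
#' @param plan A `battery_plan`.
#' @param absolute Report onset times on the battery timeline (default) or
#'   relative to trial start.
#' @return data.frame with columns `trial_id`, `test`, `condition`,
#'   `onset_time_ms`.
#' @export
schedule_to_df <- function(plan, absolute = TRUE) {
  stopifnot(inherits(plan, "battery_plan"))
  rows <- list()
  for (test in c("metronome", "adaptation", "drumalong", "memory")) {
    for (tr in plan[[test]]) {
      cond <- switch(test,
        metronome = paste0("ioi", tr$ioi_ms),
        adaptation = paste0("post", tr$post_ioi_ms),
        paste0(tr$sequence$metricality))
      off <- if (absolute) tr$start_ms else 0
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = paste0(test, "_", tr$trial), test = test, condition = cond,
        onset_time_ms = round(off + tr$onset_times_ms, 3))
    }
  }
  do.call(rbind, rows)
}

#' Write a schedule to CSV or JSON
#' @param plan A `battery_plan`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @export
write_schedule <- function(plan, path) {
  df <- schedule_to_df(plan)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# Preserve caller RNG state around seeded schedule construction.
.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
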