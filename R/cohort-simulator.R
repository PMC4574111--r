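# Synthetic cohort generator. Each participant is two independent latent
# abilities (beat, memory) plus a verbal component; tapping is generated by
# a first-order linear phase-correction model with Wing-Kristofferson-style
# two-source noise and a first-order period-correction update, sequence
# drumming by a probabilistic recall model on the 200-ms grid.

#' Simulator configuration
#'
#' Defaults define the study conditions: a cohort of 65, independent
#' latents, and latent-to-parameter maps calibrated once so the score
#' marginals are plausible for young non-musician adults (median normalized
#' metronome variability near 0.043, adaptation errors in the low tens of
#' ms, grid scores spanning roughly 60--95%).
#'
#' @param cohort_size Number of participants.
#' @param latent_cor Correlation imposed between the beat and memory
#'   latents (0 = the dissociation hypothesis; 0.9 = the single-competence
#'   control).
#' @param beat_task_loading,memory_task_loading Loading of the shared latent
#'   on each test's effective ability; the remainder is test-specific.
#' @param verbal_loading Loading of the memory latent on the two verbal
#'   memory scores.
#' @param verbal_shared Loading of a verbal-specific shared factor on both
#'   verbal scores (memory they share with each other but not with rhythm).
#' @param lead_in_ms,gap_ms Battery layout parameters.
#' @param ... Overrides for the latent-to-parameter map constants (see
#'   [latent_to_params()]).
#' @return A config list.
#' @export
sim_config <- function(cohort_size = 65, latent_cor = 0,
                       beat_task_loading = 0.75, memory_task_loading = 0.85,
                       verbal_loading = 0.4, verbal_shared = 0.6,
                       lead_in_ms = 1000, gap_ms = 2000, ...) {
  cfg <- list(
    cohort_size = cohort_size, latent_cor = latent_cor,
    beat_task_loading = beat_task_loading,
    memory_task_loading = memory_task_loading,
    verbal_loading = verbal_loading, verbal_shared = verbal_shared,
    lead_in_ms = lead_in_ms, gap_ms = gap_ms,
    # latent -> parameter map constants
    timekeeper_sd_mid = 12.5, timekeeper_slope = 0.35,
    motor_sd_mid = 6, motor_slope = 0.2,
    alpha_base = 0.5, alpha_range = 0.45, alpha_slope = 1.2, alpha_shift = 0.5,
    period_gain_scale = 0.22, period_gain_slope = 0.9, period_gain_shift = 0.2,
    mean_asynchrony_ms = -25,
    fidelity_drumalong_mid = 1.3, fidelity_memory_mid = 0.5,
    fidelity_slope = 0.9,
    jitter_mid = 30, jitter_slope = 0.25,
    false_rate_mid = -3, false_rate_slope = 0.3,
    verbal_mean = 100, verbal_sd = 15)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Deterministic latent-to-parameter map
#'
#' Monotone squashing maps from effective (per-test) abilities to model
#' parameters: higher beat ability gives lower timekeeper and motor noise, a
#' phase-correction gain closer to its optimum of 1 and a faster period
#' correction; higher memory ability gives higher recall fidelity, lower
#' motor jitter and a lower false-tap rate. All parameters stay in their
#' valid ranges for any real-valued ability.
#'
#' @param beat_ability,memory_ability Effective abilities (z-scale).
#' @param config From [sim_config()].
#' @return List with `tapping` (`alpha`, `period_gain`, `timekeeper_sd_ms`,
#'   `motor_sd_ms`, `mean_asynchrony_ms`) and `sequence`
#'   (`recall_fidelity_drumalong`, `recall_fidelity_memory`, `jitter_sd_ms`,
#'   `false_tap_rate`).
#' @export
latent_to_params <- function(beat_ability, memory_ability,
                             config = sim_config()) {
  cfg <- config
  list(
    tapping = list(
      alpha = cfg$alpha_base + cfg$alpha_range *
        stats::plogis(cfg$alpha_slope * beat_ability + cfg$alpha_shift),
      period_gain = cfg$period_gain_scale *
        stats::plogis(cfg$period_gain_slope * beat_ability + cfg$period_gain_shift),
      timekeeper_sd_ms = cfg$timekeeper_sd_mid *
        exp(-cfg$timekeeper_slope * beat_ability),
      motor_sd_ms = cfg$motor_sd_mid * exp(-cfg$motor_slope * beat_ability),
      mean_asynchrony_ms = cfg$mean_asynchrony_ms),
    sequence = list(
      recall_fidelity_drumalong =
        stats::plogis(cfg$fidelity_drumalong_mid + cfg$fidelity_slope * memory_ability),
      recall_fidelity_memory =
        stats::plogis(cfg$fidelity_memory_mid + cfg$fidelity_slope * memory_ability),
      jitter_sd_ms = cfg$jitter_mid * exp(-cfg$jitter_slope * memory_ability),
      false_tap_rate =
        stats::plogis(cfg$false_rate_mid - cfg$false_rate_slope * memory_ability)))
}

#' Per-test parameters and verbal scores for one latent profile
#'
#' Each of the four tests gets its own effective ability: the shared latent
#' scaled by the task loading plus an independent test-specific component,
#' so the two tests within a cluster correlate strongly but not perfectly.
#' Verbal scores load on the memory latent plus a verbal-specific factor
#' the two verbal tests share with each other but not with the rhythm
#' tests (scaled to a mean-100, SD-15 standard-score metric).
#'
#' Uses the current RNG stream for the task-specific components and the
#' verbal noise; seed the stream before calling for reproducibility.
#'
#' @param profile List/vector with `beat_ability`, `memory_ability`,
#'   `verbal_loading` (the latter defaulting to the config value).
#' @param config From [sim_config()].
#' @return List with per-test parameter sets `metronome`, `adaptation`
#'   (tapping), `drumalong`, `memory` (sequence), and `verbal` scores.
#' @export
params_from_profile <- function(profile, config = sim_config()) {
  lb <- config$beat_task_loading; lm <- config$memory_task_loading
  vl <- if (!is.null(profile$verbal_loading)) profile$verbal_loading
        else config$verbal_loading
  eff <- function(shared, loading)
    loading * shared + sqrt(1 - loading^2) * stats::rnorm(1)
  a_met <- eff(profile$beat_ability, lb)
  a_ada <- eff(profile$beat_ability, lb)
  a_dal <- eff(profile$memory_ability, lm)
  a_mem <- eff(profile$memory_ability, lm)
  vs <- config$verbal_shared
  verbal_common <- stats::rnorm(1)
  verbal_z <- vl * profile$memory_ability + vs * verbal_common +
    sqrt(max(0, 1 - vl^2 - vs^2)) * stats::rnorm(2)
  list(
    metronome = latent_to_params(a_met, 0, config)$tapping,
    adaptation = latent_to_params(a_ada, 0, config)$tapping,
    drumalong = latent_to_params(0, a_dal, config)$sequence,
    memory = latent_to_params(0, a_mem, config)$sequence,
    verbal = c(awm = config$verbal_mean + config$verbal_sd * verbal_z[1],
               digits_reversed = config$verbal_mean + config$verbal_sd * verbal_z[2]))
}

#' Simulate taps to a pacing stimulus
#'
#' Linear phase- and period-correction model. With asynchrony
#' `A_k = tap_k - stim_k`, the next tap is
#' `tap_{k+1} = tap_k + P_{k+1} - alpha * A_k + T_k + (M_{k+1} - M_k)`,
#' where `P` is the internal period estimate relaxed toward each observed
#' stimulus IOI with gain `period_gain`, `T` is timekeeper (central clock)
#' noise and `M` is motor implementation noise. The first tap falls at the
#' first stimulus onset plus the mean asynchrony. With zero noise and a
#' constant IOI the asynchrony decays geometrically as `(1 - alpha)^k`; with
#' timekeeper noise only, its stationary variance is
#' `sigma_T^2 / (1 - (1 - alpha)^2)`.
#'
#' @param trial A `metronome_trial` or `adaptation_trial` (any trial with
#'   `onset_times_ms`).
#' @param params Tapping parameter list (`alpha`, `period_gain`,
#'   `timekeeper_sd_ms`, `motor_sd_ms`, `mean_asynchrony_ms`).
#' @param seed Optional integer seed; if `NULL` the current stream is used.
#' @return Numeric vector of tap times (ms), one per stimulus onset.
#' @export
simulate_metronome_taps <- function(trial, params, seed = NULL) {
  if (!is.null(seed)) { old <- .save_seed(); on.exit(.restore_seed(old)); set.seed(seed) }
  stim <- trial$onset_times_ms
  n <- length(stim)
  alpha <- params$alpha
  if (abs(1 - alpha) >= 1) stop("stationarity requires |1 - alpha| < 1")
  gam <- if (is.null(params$period_gain)) 1 else params$period_gain
  tk <- if (params$timekeeper_sd_ms > 0)
    stats::rnorm(n, 0, params$timekeeper_sd_ms) else numeric(n)
  mo <- if (params$motor_sd_ms > 0)
    stats::rnorm(n, 0, params$motor_sd_ms) else numeric(n)
  taps <- numeric(n)
  period <- stim[2] - stim[1]   # base tempo, established before the trial
  taps[1] <- stim[1] + params$mean_asynchrony_ms + mo[1]
  for (k in seq_len(n - 1)) {
    # causal period correction: only gaps already heard (up to onset k) can
    # update the internal tempo estimate, so a tempo shift is first absorbed
    # as an asynchrony and corrected over the following taps
    if (k >= 2) period <- period + gam * ((stim[k] - stim[k - 1]) - period)
    asyn <- taps[k] - stim[k]
    taps[k + 1] <- taps[k] + period - alpha * asyn + tk[k] + mo[k + 1] - mo[k]
  }
  taps
}

#' Simulate drumming to a rhythmic sequence
#'
#' For each grid slot of the scored span, a stimulus hit is reproduced with
#' probability `recall_fidelity` at the slot time plus Gaussian jitter; a
#' rest slot spawns a false tap with probability `false_tap_rate`. In
#' `drumalong` mode emission spans all repetitions; in `memory` mode it is
#' confined to the silent virtual fourth repetition.
#'
#' @param trial A `drumalong_trial` or `memory_trial`.
#' @param mparams Sequence parameter list (`recall_fidelity_drumalong`,
#'   `recall_fidelity_memory`, `jitter_sd_ms`, `false_tap_rate`).
#' @param mode `"drumalong"` or `"memory"`.
#' @param seed Optional integer seed.
#' @return Sorted tap-time vector (ms, trial-relative).
#' @export
simulate_sequence_taps <- function(trial, mparams,
                                   mode = c("drumalong", "memory"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) { old <- .save_seed(); on.exit(.restore_seed(old)); set.seed(seed) }
  seqc <- trial$sequence
  reps <- if (mode == "drumalong") seq_len(trial$n_reps) else trial$n_reps + 1
  fidelity <- if (mode == "drumalong") mparams$recall_fidelity_drumalong
              else mparams$recall_fidelity_memory
  grid_bits <- rep(seqc$grid, length(reps))
  slot_times <- as.vector(vapply(reps, function(r)
    trial$lead_in_ms + (r - 1) * seqc$cycle_ms +
      GRID_RES_MS * (seq_along(seqc$grid) - 1),
    numeric(length(seqc$grid))))
  p_emit <- ifelse(grid_bits == 1, fidelity, mparams$false_tap_rate)
  emit <- stats::runif(length(p_emit)) < p_emit
  taps <- slot_times[emit] +
    stats::rnorm(sum(emit), 0, mparams$jitter_sd_ms)
  taps <- sort(taps[taps >= 0])
  # collapse physically impossible double hits (< 30 ms apart)
  if (length(taps) > 1) taps <- taps[c(TRUE, diff(taps) >= 30)]
  taps
}

.participant_seed <- function(seed, i) {
  (as.numeric(seed) * 1000003 + i * 7919) %% 2147483629
}

#' Simulate a cohort's full battery
#'
#' Draws latent profiles (independent standard normals, or correlated via
#' `latent_cor`), converts them to per-test model parameters, and generates
#' raw tap onsets for every trial of the battery. Deterministic under
#' `seed`; each participant has a derived sub-seed so individuals are
#' reproducible in isolation.
#'
#' @param n Cohort size (>= 4).
#' @param seed Master integer seed.
#' @param config From [sim_config()].
#' @return A `rhythm_cohort`: `participants` (each with `id`, `profile`,
#'   `params`, `verbal` and per-test trial records `list(trial, drum)`),
#'   the shared `plan`, and a `truth` data.frame of latent profiles.
#' @export
simulate_cohort <- function(n = 65, seed = 1L, config = sim_config()) {
  if (n < 4) stop("cohort size must be at least 4")
  plan <- battery_plan(seed = seed, lead_in_ms = config$lead_in_ms,
                       gap_ms = config$gap_ms)
  shifted_adapt <- Filter(function(tr) tr$shifted, plan$adaptation)
  participants <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    old <- .save_seed()
    set.seed(.participant_seed(seed, i))
    z <- stats::rnorm(2)
    rho <- config$latent_cor
    profile <- list(beat_ability = z[1],
                    memory_ability = rho * z[1] + sqrt(1 - rho^2) * z[2],
                    verbal_loading = config$verbal_loading)
    params <- params_from_profile(profile, config)
    sim_tap_recs <- function(trials, p) lapply(trials, function(tr)
      list(trial = tr, drum = simulate_metronome_taps(tr, p)))
    sim_seq_recs <- function(trials, p, mode) lapply(trials, function(tr)
      list(trial = tr, drum = simulate_sequence_taps(tr, p, mode)))
    participants[[i]] <- list(
      id = i, profile = profile, params = params, verbal = params$verbal,
      trials = list(
        metronome = sim_tap_recs(plan$metronome, params$metronome),
        adaptation = sim_tap_recs(shifted_adapt, params$adaptation),
        drumalong = sim_seq_recs(plan$drumalong, params$drumalong, "drumalong"),
        memory = sim_seq_recs(plan$memory, params$memory, "memory")))
    truth[[i]] <- data.frame(
      participant = i, beat_ability = profile$beat_ability,
      memory_ability = profile$memory_ability,
      verbal_loading = profile$verbal_loading,
      awm = params$verbal[["awm"]],
      digits_reversed = params$verbal[["digits_reversed"]])
    .restore_seed(old)
  }
  structure(list(participants = participants, plan = plan,
                 truth = do.call(rbind, truth), seed = seed, config = config),
            class = "rhythm_cohort")
}

#' Score a simulated cohort
#'
#' Runs the four scoring procedures on every participant's raw onsets and
#' binds the verbal scores, giving the per-participant score table the
#' statistical pipeline consumes.
#'
#' @param cohort A `rhythm_cohort` from [simulate_cohort()].
#' @return data.frame with one row per participant and the columns
#'   `metronome_variability`, `adaptation_error_ms`, `drumalong_pct`,
#'   `memory_pct`, `awm`, `digits_reversed`, `mean_tempo_dev_ms`,
#'   `n_missing_trials`.
#' @export
score_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "rhythm_cohort"))
  do.call(rbind, lapply(cohort$participants, function(p)
    score_participant(p$trials, verbal = p$verbal, participant = p$id)))
}

#' Simulate and score a cohort in one call
#' @inheritParams simulate_cohort
#' @return Score table as from [score_cohort()].
#' @export
simulate_scores <- function(n = 65, seed = 1L, config = sim_config()) {
  score_cohort(simulate_cohort(n, seed, config))
}

#' Flatten a cohort's raw onsets to the onset CSV dialect
#'
#' One row per onset, battery-timeline times: `participant`, `trial_id`,
#' `test`, `channel` (stimulus/drum), `time_ms`. The same dialect the
#' extraction path emits, so scoring is source-agnostic.
#'
#' @param cohort A `rhythm_cohort`.
#' @param path Optional CSV path; if given the table is also written there.
#' @export
cohort_onsets_df <- function(cohort, path = NULL) {
  rows <- list()
  for (p in cohort$participants) {
    for (test in names(p$trials)) {
      for (rec in p$trials[[test]]) {
        tr <- rec$trial
        id <- paste0(test, "_", tr$trial)
        add <- function(channel, times) {
          if (!length(times)) return()
          rows[[length(rows) + 1L]] <<- data.frame(
            participant = rep(p$id, length(times)), trial_id = id,
            test = test, channel = channel, time_ms = round(times, 3))
        }
        add("stimulus", tr$start_ms + tr$onset_times_ms)
        add("drum", tr$start_ms + rec$drum)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
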