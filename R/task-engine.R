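#' Configuration of the serial probabilistic reversal learning task
#'
#' The task presents two abstract stimuli; one is designated correct and is
#' rewarded except on a small fraction of misleading trials, where a correct
#' choice receives spurious negative feedback. Once the cumulative number of
#' correct choices within the current sequence reaches a criterion (drawn
#' uniformly between `criterion_min` and `criterion_max`), the contingency
#' reverses and a new sequence begins. A run ends when its last sequence
#' completes, or after `max_trials_per_run` trials. The defaults give two
#' runs of ten sequences, i.e. 18 reversals for an agent that always reaches
#' criterion.
#'
#' @param n_runs Number of runs per session.
#' @param sequences_per_run Sequences (contingency blocks) per run.
#' @param criterion_min,criterion_max Bounds of the uniform integer
#'   cumulative-correct criterion.
#' @param p_misleading Probability that a correct choice receives negative
#'   feedback; must be in `[0, 0.5)`.
#' @param max_trials_per_run Hard cap on trials within one run.
#' @param rng_seed Optional integer seed recorded with the config; used when
#'   no explicit seed is given to [generate_session()].
#' @return An object of class `prl_task_config`.
#' @export
task_config <- function(n_runs = 2L, sequences_per_run = 10L,
                        criterion_min = 10L, criterion_max = 15L,
                        p_misleading = 0.15, max_trials_per_run = 200L,
                        rng_seed = NULL) {
  cfg <- list(n_runs = as.integer(n_runs),
              sequences_per_run = as.integer(sequences_per_run),
              criterion_min = as.integer(criterion_min),
              criterion_max = as.integer(criterion_max),
              p_misleading = as.numeric(p_misleading),
              max_trials_per_run = as.integer(max_trials_per_run),
              rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  counts <- c(cfg$n_runs, cfg$sequences_per_run, cfg$criterion_min,
              cfg$criterion_max, cfg$max_trials_per_run)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("task_config: all counts must be positive integers", call. = FALSE)
  if (cfg$criterion_min > cfg$criterion_max)
    stop("task_config: criterion_min must not exceed criterion_max",
         call. = FALSE)
  if (is.na(cfg$p_misleading) || cfg$p_misleading < 0 || cfg$p_misleading >= 0.5)
    stop("task_config: p_misleading must lie in [0, 0.5)", call. = FALSE)
  structure(cfg, class = "prl_task_config")
}

new_session <- function(df, reversal_points, criteria_used, config) {
  structure(df,
            reversal_points = as.integer(reversal_points),
            criteria_used = as.integer(criteria_used),
            task_config = config,
            class = c("prl_session", "data.frame"))
}

#' @export
print.prl_session <- function(x, ...) {
  cat(sprintf("<prl_session> %d trials, %d reversals, subject %s (%s, %s)\n",
              nrow(x), length(attr(x, "reversal_points")),
              x$subject_id[1], x$group[1], x$drug[1]))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Generate one task session from a choice policy
#'
#' Runs the serial PRL task against a choice policy and returns the full
#' trial log with ground-truth annotations (the correct stimulus, sequence
#' and run indices, reversal points and the criteria drawn per sequence).
#' All randomness (stimulus side assignment, choice sampling, misleading
#' feedback, criterion draws) comes from R's RNG; fixing `seed` makes the
#' session fully reproducible.
#'
#' The policy is called with the trial context and must return the
#' probabilities of choosing the left and right option (summing to one); the
#' engine then samples the choice and informs the policy of the outcome. See
#' [prl_policy()].
#'
#' @param policy A [prl_policy()] object (e.g. [policy_oracle()],
#'   [policy_from_model()]).
#' @param config A [task_config()].
#' @param seed Optional integer seed; defaults to `config$rng_seed` when set.
#' @param subject_id,group,drug Metadata stamped on every trial row.
#' @return A `prl_session`: a data frame with one row per trial (columns
#'   `subject_id, group, drug, run, sequence, trial, stim_left, stim_right,
#'   correct_stim, chosen_stim, chosen_side, reinforcement, misleading`) and
#'   attributes `reversal_points` (0-based session trial indices of the
#'   first trial under each new contingency) and `criteria_used`.
#' @export
generate_session <- function(policy, config = task_config(), seed = NULL,
                             subject_id = "s01", group = "HC",
                             drug = "placebo") {
  if (!inherits(policy, "prl_policy"))
    stop("policy must be a prl_policy object", call. = FALSE)
  if (!inherits(config, "prl_task_config"))
    stop("config must come from task_config()", call. = FALSE)
  if (is.null(seed)) seed <- config$rng_seed
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(policy$reset)) policy$reset()

  cap <- config$n_runs * config$max_trials_per_run
  run <- seq_v <- stim_l <- cor_v <- cho_v <- side_v <- rf_v <- integer(cap)
  ml_v <- logical(cap)
  revpts <- integer(0)
  crits <- integer(0)
  rng_crit <- function() {
    u <- runif(1)
    config$criterion_min +
      min(config$criterion_max - config$criterion_min,
          as.integer(u * (config$criterion_max - config$criterion_min + 1L)))
  }
  t_all <- 0L
  for (r in seq_len(config$n_runs)) {
    cor <- if (runif(1) < 0.5) 1L else 2L        # index into STIMS
    s <- 1L
    crit <- rng_crit()
    crits <- c(crits, crit)
    cum <- 0L
    t_run <- 0L
    repeat {
      sl <- if (runif(1) < 0.5) 1L else 2L
      sr <- 3L - sl
      ctx <- list(stim_left = STIMS[sl], stim_right = STIMS[sr],
                  correct_stim = STIMS[cor], run = r, sequence = s,
                  trial = t_all)
      pr <- policy$choose(ctx)
      if (!is.numeric(pr) || length(pr) != 2L || anyNA(pr) || any(pr < 0) ||
          abs(sum(pr) - 1) > 1e-8)
        stop("invalid policy: choose() must return two nonnegative ",
             "probabilities summing to 1", call. = FALSE)
      ch_side <- if (runif(1) < pr[1]) 1L else 2L
      cs <- if (ch_side == 1L) sl else sr
      R <- 0L
      ml <- FALSE
      if (cs == cor) {
        if (runif(1) < config$p_misleading) ml <- TRUE else R <- 1L
      }
      t_all <- t_all + 1L
      t_run <- t_run + 1L
      run[t_all] <- r; seq_v[t_all] <- s; stim_l[t_all] <- sl
      cor_v[t_all] <- cor; cho_v[t_all] <- cs; side_v[t_all] <- ch_side
      rf_v[t_all] <- R; ml_v[t_all] <- ml
      if (!is.null(policy$learn))
        policy$learn(STIMS[cs], SIDES[ch_side], R)
      if (cs == cor) cum <- cum + 1L
      if (cum >= crit) {
        if (s == config$sequences_per_run) break
        if (t_run >= config$max_trials_per_run) break
        cor <- 3L - cor
        revpts <- c(revpts, t_all)       # 0-based index of next trial
        s <- s + 1L
        crit <- rng_crit()
        crits <- c(crits, crit)
        cum <- 0L
      } else if (t_run >= config$max_trials_per_run) break
    }
  }
  idx <- seq_len(t_all)
  df <- data.frame(
    subject_id = subject_id, group = group, drug = drug,
    run = run[idx] - 1L, sequence = seq_v[idx] - 1L, trial = idx - 1L,
    stim_left = STIMS[stim_l[idx]], stim_right = STIMS[3L - stim_l[idx]],
    correct_stim = STIMS[cor_v[idx]], chosen_stim = STIMS[cho_v[idx]],
    chosen_side = SIDES[side_v[idx]], reinforcement = rf_v[idx],
    misleading = ml_v[idx], stringsAsFactors = FALSE)
  new_session(df, revpts, crits, config)
}

#' Check a session against the task invariants
#'
#' Violations are reported, not raised: an empty report means the session is
#' consistent with the task rules (distinct stimuli per trial, choices among
#' the presented stimuli, misleading trials being correct choices with
#' negative feedback, incorrect choices never rewarded, strictly increasing
#' reversal points, criteria within bounds, per-run trial counts within the
#' cap).
#'
#' @param session A `prl_session` (or a bare trial data frame).
#' @param config The [task_config()] to validate against; defaults to the
#'   config stored in the session.
#' @return A data frame with columns `rule`, `trial` and `detail`, one row
#'   per violation (zero rows when the session is valid).
#' @export
validate_session <- function(session, config = NULL) {
  if (is.null(config)) config <- attr(session, "task_config")
  if (is.null(config)) config <- task_config()
  df <- as.data.frame(session)
  bad <- function(rule, trial, detail)
    data.frame(rule = rule, trial = trial, detail = detail,
               stringsAsFactors = FALSE)
  out <- list()
  i <- which(df$stim_left == df$stim_right)
  if (length(i)) out[[length(out) + 1L]] <-
    bad("distinct_stimuli", df$trial[i], "stim_left equals stim_right")
  i <- which(df$chosen_stim != df$stim_left & df$chosen_stim != df$stim_right)
  if (length(i)) out[[length(out) + 1L]] <-
    bad("chosen_presented", df$trial[i], "chosen_stim not presented")
  i <- which(df$misleading & !(df$chosen_stim == df$correct_stim &
                                 df$reinforcement == 0))
  if (length(i)) out[[length(out) + 1L]] <-
    bad("misleading_semantics", df$trial[i],
        "misleading trial must be a correct choice with R = 0")
  i <- which(df$chosen_stim != df$correct_stim & df$reinforcement != 0)
  if (length(i)) out[[length(out) + 1L]] <-
    bad("no_spurious_reward", df$trial[i], "incorrect choice with R = 1")
  rp <- attr(session, "reversal_points")
  if (!is.null(rp) && length(rp) > 1 && any(diff(rp) <= 0))
    out[[length(out) + 1L]] <-
      bad("reversals_increasing", NA_integer_,
          "reversal_points not strictly increasing")
  cu <- attr(session, "criteria_used")
  if (!is.null(cu)) {
    j <- which(cu < config$criterion_min | cu > config$criterion_max)
    if (length(j)) out[[length(out) + 1L]] <-
      bad("criterion_bounds", NA_integer_,
          sprintf("criterion %d outside [%d, %d]", cu[j][1],
                  config$criterion_min, config$criterion_max))
  }
  per_run <- table(df$run)
  if (any(per_run > config$max_trials_per_run))
    out[[length(out) + 1L]] <-
      bad("run_cap", NA_integer_, "run exceeds max_trials_per_run")
  if (length(out)) do.call(rbind, out)
  else data.frame(rule = character(), trial = integer(),
                  detail = character(), stringsAsFactors = FALSE)
}
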