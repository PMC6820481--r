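test_that("perseverative errors are counted from the second post-reversal trial", {
  # Sequence 0: A correct, criterion reached; reversal at trial 3 -> B correct.
  # Post-reversal choices: A (excluded), A (counted), B (streak ends).
  df <- toy_trials(chosen  = c("A", "A", "A", "A", "A", "B", "B"),
                   reinf   = c(1, 1, 1, 0, 0, 1, 1),
                   correct = c("A", "A", "A", "B", "B", "B", "B"),
                   sequence = c(0, 0, 0, 1, 1, 1, 1))
  s <- as_toy_session(df, reversal_points = 3L, criteria_used = c(3L, 3L))
  pe <- perseverative_errors(s)
  expect_identical(pe$count, 1L)
  expect_identical(pe$rate, 1)
  # streak broken on the first post-reversal trial: no error at all
  df2 <- toy_trials(chosen  = c("A", "A", "A", "B", "A", "B"),
                    reinf   = c(1, 1, 1, 1, 0, 1),
                    correct = c("A", "A", "A", "B", "B", "B"),
                    sequence = c(0, 0, 0, 1, 1, 1))
  s2 <- as_toy_session(df2, reversal_points = 3L)
  expect_identical(perseverative_errors(s2)$count, 0L)
  expect_identical(perseverative_errors(s2)$rate, 0)
})

test_that("oracle sessions have no perseverative, probabilistic or spontaneous errors", {
  s <- generate_session(policy_oracle(), seed = 3)
  m <- session_measures(s)
  expect_identical(m$perseverative_errors, 0L)
  expect_identical(m$perseverative_error_rate, 0)
  expect_equal(m$probabilistic_switches, 0)
  expect_equal(m$spontaneous_errors, 0)
  # the oracle switches stimulus only at reversals, so its stay rates are
  # near-perfect but not exactly 1
  expect_gt(m$win_stay, 0.9)
  expect_lt(m$lose_shift, 0.1)
})

test_that("sessions without reversals yield zero counts and defined rate", {
  s <- generate_session(policy_antioracle(), seed = 3)
  m <- session_measures(s)
  expect_identical(m$perseverative_errors, 0L)
  expect_identical(m$perseverative_error_rate, 0)
})

test_that("probabilistic switches count misleading-then-switch events", {
  # trial 1 misleading, trial 2 switches to incorrect B
  df <- toy_trials(chosen  = c("A", "A", "B", "A"),
                   reinf   = c(1, 0, 0, 1),
                   misleading = c(FALSE, TRUE, FALSE, FALSE))
  s <- as_toy_session(df)
  expect_identical(probabilistic_switches(s), 1L)
  # an always-switch-after-loss agent: count equals misleading trials
  # followed by another trial in the same run
  set.seed(8)
  e <- new.env(); e$last <- NULL
  pol <- prl_policy(
    choose = function(ctx) {
      if (is.null(e$last)) return(c(.5, .5))
      want <- if (e$last$R == 0) setdiff(c("A", "B"), e$last$stim) else e$last$stim
      if (ctx$stim_left == want) c(1, 0) else c(0, 1)
    },
    learn = function(stim, side, R) e$last <- list(stim = stim, R = R),
    reset = function() e$last <- NULL)
  ses <- generate_session(pol, seed = 17)
  df2 <- as.data.frame(ses)
  n <- nrow(df2)
  prev <- seq_len(n - 1)
  manual <- sum(df2$misleading[prev] & df2$run[prev + 1] == df2$run[prev] &
                  df2$chosen_stim[prev + 1] != df2$correct_stim[prev + 1] &
                  df2$chosen_stim[prev + 1] != df2$chosen_stim[prev])
  expect_identical(probabilistic_switches(ses), as.integer(manual))
  # no misleading feedback, no probabilistic switches
  s0 <- generate_session(policy_random(), task_config(p_misleading = 0),
                         seed = 2)
  expect_identical(probabilistic_switches(s0), 0L)
})

test_that("spontaneous errors are rewarded-then-switch events and complement win-stay", {
  df <- toy_trials(chosen = c("A", "B", "A", "A"),
                   reinf  = c(1, 0, 1, 1))
  s <- as_toy_session(df)
  expect_identical(spontaneous_errors(s), 1L)
  ses <- generate_session(policy_random(), seed = 31)
  m <- session_measures(ses)
  df2 <- as.data.frame(ses)
  n <- nrow(df2)
  prev <- seq_len(n - 1)
  keep <- df2$reinforcement[prev] == 1 & df2$run[prev + 1] == df2$run[prev]
  spont_prop <- sum(keep & df2$chosen_stim[prev + 1] != df2$chosen_stim[prev] &
                      df2$chosen_stim[prev + 1] != df2$correct_stim[prev + 1]) /
    sum(keep)
  # rewarded trials are always correct choices, so a switch is an
  # immediate spontaneous error except across a reversal boundary
  expect_equal(1 - m$win_stay,
               sum(keep & df2$chosen_stim[prev + 1] != df2$chosen_stim[prev]) /
                 sum(keep))
  expect_lte(spont_prop, 1 - m$win_stay)
})

test_that("measures are invariant to left/right relabelling", {
  ses <- fixture_session(seed = 23)
  df <- as.data.frame(ses)
  flipped <- df
  flipped$stim_left <- df$stim_right
  flipped$stim_right <- df$stim_left
  flipped$chosen_side <- ifelse(df$chosen_side == "left", "right", "left")
  fses <- as_toy_session(flipped, attr(ses, "reversal_points"),
                         attr(ses, "criteria_used"))
  a <- session_measures(ses)
  b <- session_measures(fses)
  expect_equal(a[, -1], b[, -1])
})

test_that("stats harness matches textbook F and t on a fixture table", {
  set.seed(99)
  meas <- data.frame(
    subject_id = sprintf("s%02d", 1:30),
    group = rep(c("HC", "SUD", "OCD"), each = 10),
    drug = "placebo",
    trials_per_sequence = c(rnorm(10, 12), rnorm(10, 14), rnorm(10, 12.5)),
    perseverative_error_rate = runif(30),
    probabilistic_switches = rpois(30, 4),
    spontaneous_errors = rpois(30, 3))
  rep <- stats_harness(meas)
  y <- meas$trials_per_sequence
  g <- factor(meas$group)
  k <- nlevels(g); n <- length(y)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fman <- (ssb / (k - 1)) / (ssw / (n - k))
  got <- rep[rep$measure == "trials_per_sequence" &
               rep$effect == "group (placebo)", ]
  expect_equal(got$value, Fman, tolerance = 1e-10)
  expect_identical(c(got$df1, got$df2), c(2, 27))
  # Welch t against the direct formula
  a <- y[g == "HC"]; b <- y[g == "SUD"]
  tman <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  gt <- rep[rep$measure == "trials_per_sequence" &
              rep$effect == "HC vs SUD (placebo)", ]
  expect_equal(gt$value, tman, tolerance = 1e-10)
  # identical samples give t = 0
  meas2 <- meas
  meas2$trials_per_sequence <- rep(meas$trials_per_sequence[1:10], 3)
  rep2 <- stats_harness(meas2)
  t0 <- rep2[rep2$measure == "trials_per_sequence" &
               rep2$effect == "HC vs SUD (placebo)", ]
  expect_equal(t0$value, 0)
})

test_that("group effect type-I error is near the nominal 5% under the null", {
  set.seed(123)
  reps <- 300
  hits <- 0
  for (i in seq_len(reps)) {
    y <- rnorm(60)
    g <- factor(rep(c("HC", "SUD", "OCD"), each = 20))
    p <- summary(stats::aov(y ~ g))[[1]]$`Pr(>F)`[1]
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.04)
})

test_that("elevated stimulus stickiness raises the perseverative error rate", {
  lo <- vapply(1:6, function(i) {
    s <- simulate_model_session("M4c", c(alpha_rew = .4, alpha_pun = .4,
                                         tau_reinf = 5.5, tau_stim = 0.2,
                                         tau_loc = .3), seed = 100 + i)
    session_measures(s)$perseverative_error_rate
  }, numeric(1))
  hi <- vapply(1:6, function(i) {
    s <- simulate_model_session("M4c", c(alpha_rew = .4, alpha_pun = .4,
                                         tau_reinf = 5.5, tau_stim = 2.5,
                                         tau_loc = .3), seed = 200 + i)
    session_measures(s)$perseverative_error_rate
  }, numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("parameter-measure correlations recover an induced association", {
  set.seed(5)
  n <- 40
  params <- data.frame(subject_id = sprintf("s%02d", 1:n), drug = "placebo",
                       tau_stim = runif(n, 0, 2))
  meas <- data.frame(subject_id = params$subject_id, drug = "placebo",
                     perseverative_error_rate = 2 * params$tau_stim +
                       rnorm(n, 0, .3),
                     probabilistic_switches = rpois(n, 4),
                     spontaneous_errors = rpois(n, 3),
                     trials_per_sequence = rnorm(n, 12))
  out <- measure_parameter_correlations(params, meas,
                                        parameters = "tau_stim")
  r <- out[out$measure == "perseverative_error_rate", ]
  expect_gt(r$r, 0.8)
  expect_lt(r$p, 1e-6)
})
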