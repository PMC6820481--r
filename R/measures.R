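#' Conventional reversal-learning measures for one session
#'
#' * **Perseverative errors**: consecutive choices of the previously
#'   correct stimulus immediately after a reversal, excluding the error on
#'   the first post-reversal trial (which cannot count but can start a
#'   perseverative streak; the streak ends at the first choice of the newly
#'   correct stimulus). The **rate** divides the total count by the number
#'   of post-reversal sequences containing at least one such error, and is
#'   0 when there are none.
#' * **Probabilistic switches**: trials whose previous trial was a correct
#'   choice with misleading negative feedback and whose choice switches to
#'   the (currently) incorrect stimulus.
#' * **Spontaneous errors**: switches to the incorrect stimulus immediately
#'   after a veraciously rewarded correct choice.
#' * **Trials per sequence**: mean number of trials over the sequences of
#'   the session (incomplete, cap-terminated sequences included).
#' * **Win-stay / lose-shift**: probability of repeating the previous
#'   stimulus choice after reinforcement, and of switching after
#'   nonreinforcement.
#'
#' Consecutive-trial measures never cross run boundaries.
#'
#' @param session A `prl_session` or trial data frame for one session.
#' @return One-row data frame with columns `subject_id, group, drug,
#'   n_trials, n_reversals, perseverative_errors, perseverative_error_rate,
#'   probabilistic_switches, spontaneous_errors, trials_per_sequence,
#'   win_stay, lose_shift`.
#' @export
session_measures <- function(session) {
  df <- as.data.frame(session)
  df <- df[order(df$trial), , drop = FALSE]
  n <- nrow(df)
  rp <- attr(session, "reversal_points")
  if (is.null(rp)) {
    # reconstruct: first trial of every within-run sequence change
    chg <- which(diff(df$sequence) != 0 & diff(df$run) == 0)
    rp <- df$trial[chg + 1L]
  }
  pers_total <- 0L
  seq_with_err <- 0L
  for (r in rp) {
    i <- match(r, df$trial)
    if (is.na(i) || i == 1L) next
    prev_cor <- df$correct_stim[i - 1L]
    this_run <- df$run[i]
    k <- 0L
    j <- i
    while (j <= n && df$run[j] == this_run && df$chosen_stim[j] == prev_cor) {
      k <- k + 1L
      j <- j + 1L
    }
    err <- max(0L, k - 1L)   # first post-reversal trial excluded
    pers_total <- pers_total + err
    if (err > 0L) seq_with_err <- seq_with_err + 1L
  }
  pers_rate <- if (seq_with_err > 0L) pers_total / seq_with_err else 0
  prev <- seq_len(n - 1L)
  cur <- prev + 1L
  same_run <- df$run[cur] == df$run[prev]
  switched <- df$chosen_stim[cur] != df$chosen_stim[prev]
  to_incorrect <- df$chosen_stim[cur] != df$correct_stim[cur]
  prev_misleading <- df$misleading[prev]
  prev_rewarded <- df$reinforcement[prev] == 1
  prob_sw <- sum(same_run & prev_misleading & switched & to_incorrect)
  spont <- sum(same_run & prev_rewarded & switched & to_incorrect)
  ws_den <- sum(same_run & prev_rewarded)
  ls_den <- sum(same_run & !prev_rewarded)
  win_stay <- if (ws_den > 0) sum(same_run & prev_rewarded & !switched) / ws_den else NA_real_
  lose_shift <- if (ls_den > 0) sum(same_run & !prev_rewarded & switched) / ls_den else NA_real_
  tps <- mean(table(paste(df$run, df$sequence)))
  data.frame(subject_id = df$subject_id[1], group = df$group[1],
             drug = df$drug[1], n_trials = n, n_reversals = length(rp),
             perseverative_errors = pers_total,
             perseverative_error_rate = pers_rate,
             probabilistic_switches = prob_sw,
             spontaneous_errors = spont,
             trials_per_sequence = unname(tps),
             win_stay = win_stay, lose_shift = lose_shift,
             stringsAsFactors = FALSE)
}

#' Perseverative error count and rate
#'
#' @param session A `prl_session`.
#' @return List with `count` and `rate`.
#' @export
perseverative_errors <- function(session) {
  m <- session_measures(session)
  list(count = m$perseverative_errors, rate = m$perseverative_error_rate)
}

#' Probabilistic switch count
#' @param session A `prl_session`.
#' @return Integer count.
#' @export
probabilistic_switches <- function(session) {
  session_measures(session)$probabilistic_switches
}

#' Spontaneous error count
#' @param session A `prl_session`.
#' @return Integer count.
#' @export
spontaneous_errors <- function(session) {
  session_measures(session)$spontaneous_errors
}

#' Behavioural measures for every session of a cohort
#'
#' @param cohort A [prl_cohort()] or a stacked trial data frame.
#' @return Data frame with one row per session (see [session_measures()]).
#' @export
cohort_measures <- function(cohort) {
  sess <- if (inherits(cohort, "prl_cohort")) cohort_sessions(cohort)
          else cohort_sessions(prl_cohort(cohort))
  out <- do.call(rbind, lapply(sess, session_measures))
  rownames(out) <- NULL
  out
}

#' Classical statistical harness over cohort measures
#'
#' Reproduces the analysis style applied to simulated behaviour: per
#' measure, a one-way between-group ANOVA on the placebo sessions, pairwise
#' Welch t-tests between groups on placebo, and -- when several drug
#' conditions are present -- a group-by-drug two-way ANOVA with main
#' effects and interaction. Degenerate (zero-variance) measures are
#' reported with a flag rather than an error.
#'
#' @param measures Data frame from [cohort_measures()].
#' @param which_measures Character vector of measure columns to analyse.
#' @return Data frame with columns `measure, effect, statistic, df1, df2,
#'   value, p, note`.
#' @export
stats_harness <- function(measures,
                          which_measures = c("perseverative_error_rate",
                                             "probabilistic_switches",
                                             "spontaneous_errors",
                                             "trials_per_sequence")) {
  measures$group <- factor(measures$group, levels = GROUPS)
  measures$drug <- factor(measures$drug, levels = DRUGS)
  measures <- droplevels(measures)
  if (nlevels(measures$group) < 2)
    stop("stats_harness needs at least 2 groups", call. = FALSE)
  plc <- measures[measures$drug == "placebo", , drop = FALSE]
  multi_drug <- nlevels(measures$drug) > 1
  rows <- list()
  add <- function(measure, effect, statistic, df1, df2, value, p, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, effect = effect, statistic = statistic,
      df1 = df1, df2 = df2, value = value, p = p, note = note,
      stringsAsFactors = FALSE)
  for (m in which_measures) {
    y <- plc[[m]]
    if (length(unique(y[!is.na(y)])) < 2) {
      add(m, "group (placebo)", "F", NA, NA, NA, NA, "degenerate variance")
    } else {
      fit <- stats::aov(y ~ group, data = data.frame(y = y, group = plc$group))
      s <- summary(fit)[[1]]
      add(m, "group (placebo)", "F", s$Df[1], s$Df[2], s$`F value`[1],
          s$`Pr(>F)`[1])
      for (pair in list(c("HC", "SUD"), c("HC", "OCD"), c("SUD", "OCD"))) {
        a <- y[plc$group == pair[1]]
        b <- y[plc$group == pair[2]]
        if (stats::var(a) + stats::var(b) == 0) {
          add(m, sprintf("%s vs %s (placebo)", pair[1], pair[2]), "t",
              NA, NA, 0, 1, "degenerate variance")
        } else {
          tt <- stats::t.test(a, b)
          add(m, sprintf("%s vs %s (placebo)", pair[1], pair[2]), "t",
              1, unname(tt$parameter), unname(tt$statistic), tt$p.value)
        }
      }
    }
    if (multi_drug) {
      y2 <- measures[[m]]
      if (length(unique(y2[!is.na(y2)])) >= 2) {
        fit2 <- stats::aov(y ~ group * drug,
                           data = data.frame(y = y2, group = measures$group,
                                             drug = measures$drug))
        s2 <- summary(fit2)[[1]]
        terms <- trimws(rownames(s2))
        for (eff in c("group", "drug", "group:drug")) {
          i <- match(eff, terms)
          if (!is.na(i))
            add(m, eff, "F", s2$Df[i], s2$Df[nrow(s2)], s2$`F value`[i],
                s2$`Pr(>F)`[i])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations between model parameters and behavioural measures
#'
#' Product-moment correlations between per-session parameter values (e.g.
#' generating ground truth or posterior means) and behavioural measures.
#'
#' @param params Data frame with `subject_id`, `drug` and parameter
#'   columns.
#' @param measures Data frame from [cohort_measures()].
#' @param parameters,which_measures Columns to correlate.
#' @return Data frame with `parameter, measure, r, df, p`.
#' @export
measure_parameter_correlations <- function(params, measures,
                                           parameters = NULL,
                                           which_measures = c(
                                             "perseverative_error_rate",
                                             "probabilistic_switches",
                                             "spontaneous_errors",
                                             "trials_per_sequence")) {
  if (is.null(parameters))
    parameters <- setdiff(names(params), c("subject_id", "group", "drug"))
  dat <- merge(params, measures, by = c("subject_id", "drug"))
  rows <- list()
  for (p in parameters) for (m in which_measures) {
    x <- dat[[p]]
    y <- dat[[m]]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 3 || var(x[keep]) == 0 || var(y[keep]) == 0) next
    ct <- stats::cor.test(x[keep], y[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, measure = m, r = unname(ct$estimate),
      df = unname(ct$parameter), p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(parameter = character(),
                                       measure = character(), r = numeric(),
                                       df = numeric(), p = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
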