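# Independent naive oracles used across the test files. These are written
# directly from the model equations as plain loops, deliberately sharing no
# code with the package implementation.

# Naive trial-loop log-likelihood oracle for all seven models.
naive_loglik <- function(model, pars, df) {
  V <- c(A = 0.5, B = 0.5)
  nw <- c(A = 1, B = 1)
  prev_stim <- ""
  prev_side <- ""
  ll <- 0
  for (t in seq_len(nrow(df))) {
    q <- c(left = 0, right = 0)
    stim_of <- c(left = df$stim_left[t], right = df$stim_right[t])
    for (side in c("left", "right")) {
      st <- stim_of[[side]]
      q[side] <- switch(model,
        M1 = , M2 = , M3 = , M4a = , M4b = , M4c = pars[["tau_reinf"]] * V[[st]],
        M5 = V[[st]])
      if (model %in% c("M2", "M4b", "M4c") && st == prev_stim)
        q[side] <- q[side] + pars[["tau_stim"]]
      if (model %in% c("M4a", "M4c") && side == prev_side)
        q[side] <- q[side] + pars[["tau_loc"]]
    }
    b <- if (model == "M5") pars[["beta"]] else 1
    pch <- exp(b * q) / sum(exp(b * q))
    ll <- ll + log(pch[[df$chosen_side[t]]])
    ch <- df$chosen_stim[t]
    R <- df$reinforcement[t]
    if (model == "M5") {
      n_old <- nw[[ch]]
      n_new <- n_old * pars[["rho"]] + 1
      V[[ch]] <- (pars[["phi"]] * n_old * V[[ch]] + R) / n_new
      nw[[ch]] <- n_new
    } else {
      lr <- if (model %in% c("M1", "M2")) pars[["alpha_reinf"]]
            else if (R == 1) pars[["alpha_rew"]] else pars[["alpha_pun"]]
      V[[ch]] <- V[[ch]] + lr * (R - V[[ch]])
    }
    prev_stim <- ch
    prev_side <- df$chosen_side[t]
  }
  ll
}

# Draw a random valid parameter vector for a model.
random_params <- function(model) {
  full <- c(alpha_reinf = runif(1), alpha_rew = runif(1),
            alpha_pun = runif(1), tau_reinf = rgamma(1, 4.82, 0.88),
            tau_stim = rnorm(1), tau_loc = rnorm(1),
            rho = runif(1), phi = runif(1), beta = rgamma(1, 4.82, 0.88))
  full[revlearn::model_spec(model)$free_parameters]
}

# A small session simulated from a mid-range agent, reused as a fixture.
fixture_session <- function(seed = 11, model = "M4c",
                            params = c(alpha_rew = 0.45, alpha_pun = 0.35,
                                       tau_reinf = 5, tau_stim = 1,
                                       tau_loc = 0.3)) {
  revlearn::simulate_model_session(model, params, seed = seed)
}

# Hand-built four-trial session: stimulus A correct throughout, A always
# left; used for hand-enumerated measure checks.
toy_trials <- function(chosen, reinf, misleading = rep(FALSE, length(chosen)),
                       correct = rep("A", length(chosen)),
                       sequence = rep(0L, length(chosen)),
                       run = rep(0L, length(chosen))) {
  n <- length(chosen)
  data.frame(subject_id = "t01", group = "HC", drug = "placebo",
             run = run, sequence = sequence, trial = seq_len(n) - 1L,
             stim_left = "A", stim_right = "B", correct_stim = correct,
             chosen_stim = chosen,
             chosen_side = ifelse(chosen == "A", "left", "right"),
             reinforcement = reinf, misleading = misleading,
             stringsAsFactors = FALSE)
}

# Attach session attributes to a toy trial table.
as_toy_session <- function(df, reversal_points = integer(0),
                           criteria_used = integer(0)) {
  structure(df, reversal_points = as.integer(reversal_points),
            criteria_used = as.integer(criteria_used),
            task_config = revlearn::task_config(),
            class = c("prl_session", "data.frame"))
}
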