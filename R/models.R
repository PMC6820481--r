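#' The seven reinforcement-learning models
#'
#' All models share one interface: a latent state holding one value `V` per
#' stimulus (initialised at 0.5, the midpoint of the binary outcome range),
#' a delta-rule or experience-weighted update applied to the chosen
#' stimulus, an option-level quantity `Q` that may add stimulus- and
#' side-stickiness bonuses for the previously chosen stimulus/side, and a
#' softmax choice rule. The softmax inverse temperature is fixed at 1 for
#' models M1-M4c (their `tau` weights then act directly as softmax-exponent
#' weights); the experience-weighted attraction model M5 frees it.
#'
#' * **M1** single learning rate: `alpha_reinf`, `tau_reinf`
#' * **M2** M1 + stimulus stickiness: `+ tau_stim`
#' * **M3** separate reward/punishment rates: `alpha_rew`, `alpha_pun`,
#'   `tau_reinf`
#' * **M4a** M3 + side stickiness: `+ tau_loc`
#' * **M4b** M3 + stimulus stickiness: `+ tau_stim`
#' * **M4c** M3 + both stickiness terms (five free parameters)
#' * **M5** experience-weighted attraction: `rho`, `phi`, `beta`
#'
#' @param name One of `"M1", "M2", "M3", "M4a", "M4b", "M4c", "M5"`.
#' @return An object of class `model_spec` with elements `name`,
#'   `free_parameters` and the internal model code.
#' @export
model_spec <- function(name = c("M1", "M2", "M3", "M4a", "M4b", "M4c", "M5")) {
  name <- match.arg(name)
  free <- MODEL_PARAMS[[name]]
  structure(list(name = name, free_parameters = free,
                 code = match(name, names(MODEL_PARAMS))),
            class = "model_spec")
}

MODEL_PARAMS <- list(
  M1  = c("alpha_reinf", "tau_reinf"),
  M2  = c("alpha_reinf", "tau_reinf", "tau_stim"),
  M3  = c("alpha_rew", "alpha_pun", "tau_reinf"),
  M4a = c("alpha_rew", "alpha_pun", "tau_reinf", "tau_loc"),
  M4b = c("alpha_rew", "alpha_pun", "tau_reinf", "tau_stim"),
  M4c = c("alpha_rew", "alpha_pun", "tau_reinf", "tau_stim", "tau_loc"),
  M5  = c("rho", "phi", "beta"))

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %s>\n", x$name,
              paste(x$free_parameters, collapse = ", ")))
  invisible(x)
}

#' Names of the models in the family
#' @return Character vector of the seven model names.
#' @export
model_names <- function() names(MODEL_PARAMS)

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) x else model_spec(x)
}

# validate and order a named parameter vector for a model
check_params <- function(spec, params) {
  spec <- as_model_spec(spec)
  if (is.list(params)) params <- unlist(params)
  miss <- setdiff(spec$free_parameters, names(params))
  if (length(miss))
    stop(sprintf("missing parameters for %s: %s", spec$name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  p <- params[spec$free_parameters]
  rates <- intersect(c("alpha_rew", "alpha_pun", "alpha_reinf", "rho", "phi"),
                     spec$free_parameters)
  if (any(p[rates] < 0 | p[rates] > 1))
    stop("learning-rate/decay parameters must lie in [0, 1]", call. = FALSE)
  pos <- intersect(c("tau_reinf", "beta"), spec$free_parameters)
  if (any(p[pos] < 0))
    stop("tau_reinf and beta must be nonnegative", call. = FALSE)
  p
}

effective_beta <- function(spec, params) {
  if (spec$name == "M5") unname(params[["beta"]]) else 1
}

#' Initial latent state
#'
#' Both stimulus values start at 0.5 (symmetric, so first-trial choice
#' probabilities are 0.5/0.5), stickiness indicators are all-zero, and the
#' experience weights of the EWA model start at 1 per stimulus.
#'
#' @param spec A [model_spec()].
#' @return A list with elements `V`, `prev_stim`, `prev_side`, and (for M5)
#'   `ewa_n`, each named by stimulus (`A`, `B`) or side.
#' @export
init_state <- function(spec) {
  spec <- as_model_spec(spec)
  st <- list(V = c(A = 0.5, B = 0.5), prev_stim = NA_character_,
             prev_side = NA_character_)
  if (spec$name == "M5") st$ewa_n <- c(A = 1, B = 1)
  st
}

#' Latent-state update after one trial
#'
#' For M1/M2 the chosen stimulus's value moves toward the outcome at rate
#' `alpha_reinf`; for M3/M4a/M4b/M4c the rate is `alpha_rew` after reward
#' and `alpha_pun` after nonreward. The EWA model (M5) first decays and
#' increments the chosen stimulus's experience weight, `n' = n * rho + 1`,
#' then mixes the old value with the payoff, `V' = (phi * n * V + R) / n'`.
#' Unchosen stimuli are untouched. Stickiness indicators become one-hot at
#' the chosen stimulus and side.
#'
#' @param spec A [model_spec()].
#' @param params Named parameter vector.
#' @param state State from [init_state()] or a previous update.
#' @param chosen_stim `"A"` or `"B"`.
#' @param chosen_side `"left"` or `"right"`.
#' @param reinforcement 0 or 1.
#' @return The updated state.
#' @export
update_state <- function(spec, params, state, chosen_stim, chosen_side,
                         reinforcement) {
  spec <- as_model_spec(spec)
  if (!reinforcement %in% c(0, 1))
    stop("reinforcement must be 0 or 1", call. = FALSE)
  R <- as.numeric(reinforcement)
  cs <- chosen_stim
  if (spec$name == "M5") {
    n_old <- state$ewa_n[[cs]]
    n_new <- n_old * params[["rho"]] + 1
    state$V[[cs]] <- (params[["phi"]] * n_old * state$V[[cs]] + R) / n_new
    state$ewa_n[[cs]] <- n_new
  } else {
    lr <- if (spec$name %in% c("M1", "M2")) params[["alpha_reinf"]]
          else if (R == 1) params[["alpha_rew"]] else params[["alpha_pun"]]
    state$V[[cs]] <- state$V[[cs]] + lr * (R - state$V[[cs]])
  }
  state$prev_stim <- cs
  state$prev_side <- chosen_side
  state
}

#' Option-level softmax-exponent quantities
#'
#' Computes `Q` for the left and right option of a trial:
#' `Q = tau_reinf * V_stim + tau_stim * [stim == previous stimulus] +
#' tau_loc * [side == previous side]`, including only the components the
#' model owns. M5 uses `Q = V` (its weighting is carried by the free
#' softmax `beta`).
#'
#' @inheritParams update_state
#' @param layout Named character vector `c(left = , right = )` mapping sides
#'   to stimulus identifiers.
#' @return Named numeric vector `c(left = , right = )`.
#' @export
option_quantities <- function(spec, params, state, layout) {
  spec <- as_model_spec(spec)
  q <- c(left = 0, right = 0)
  for (side in c("left", "right")) {
    stim <- layout[[side]]
    q[[side]] <- if (spec$name == "M5") state$V[[stim]]
                 else params[["tau_reinf"]] * state$V[[stim]]
    if ("tau_stim" %in% spec$free_parameters &&
        isTRUE(state$prev_stim == stim))
      q[[side]] <- q[[side]] + params[["tau_stim"]]
    if ("tau_loc" %in% spec$free_parameters &&
        isTRUE(state$prev_side == side))
      q[[side]] <- q[[side]] + params[["tau_loc"]]
  }
  q
}

#' Softmax choice probabilities
#'
#' `P(a) = exp(beta * Q_a) / sum_k exp(beta * Q_k)`, computed with
#' max-subtraction so large `Q` cannot overflow.
#'
#' @param q Numeric vector of option quantities.
#' @param beta Inverse temperature (1 for models M1-M4c).
#' @return Probabilities in the same order as `q`, summing to one.
#' @export
choice_probability <- function(q, beta = 1) {
  if (any(!is.finite(q))) stop("non-finite Q values", call. = FALSE)
  z <- beta * q
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

#' Session log-likelihood of observed choices
#'
#' Sums `log P(chosen option)` over the trials of a session, updating the
#' latent state after each trial, exactly as the generative model walks the
#' data. The default engine is compiled; `engine = "r"` runs the same
#' computation through the R-level primitives ([option_quantities()],
#' [choice_probability()], [update_state()]).
#'
#' @param spec A [model_spec()].
#' @param params Named parameter vector.
#' @param session A `prl_session` or trial data frame.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return The log-likelihood (a finite scalar).
#' @export
session_log_likelihood <- function(spec, params, session,
                                   engine = c("cpp", "r")) {
  spec <- as_model_spec(spec)
  params <- check_params(spec, params)
  engine <- match.arg(engine)
  v <- validate_session(session)
  if (nrow(v) > 0)
    stop("invalid session: ", v$rule[1], " (", v$detail[1], ")",
         call. = FALSE)
  df <- as.data.frame(session)
  if (engine == "cpp") {
    return(cpp_session_loglik(spec$code, unname(params),
                              match(df$stim_left, STIMS) - 1L,
                              match(df$chosen_stim, STIMS) - 1L,
                              as.integer(df$reinforcement)))
  }
  state <- init_state(spec)
  beta <- effective_beta(spec, params)
  ll <- 0
  for (t in seq_len(nrow(df))) {
    q <- option_quantities(spec, params, state,
                           layout = c(left = df$stim_left[t],
                                      right = df$stim_right[t]))
    p <- choice_probability(q, beta)
    ll <- ll + log(p[[df$chosen_side[t]]])
    state <- update_state(spec, params, state, df$chosen_stim[t],
                          df$chosen_side[t], df$reinforcement[t])
  }
  ll
}

#' Simulate a model agent performing the task (fast path)
#'
#' Compiled equivalent of `generate_session(policy_from_model(spec,
#' params), config)`: both consume the RNG stream in the same order, so the
#' two paths produce identical sessions under the same seed. This is the
#' engine behind the cohort-scale simulation experiments.
#'
#' @inheritParams generate_session
#' @param spec A [model_spec()].
#' @param params Named parameter vector.
#' @return A `prl_session`.
#' @export
simulate_model_session <- function(spec, params, config = task_config(),
                                   seed = NULL, subject_id = "s01",
                                   group = "HC", drug = "placebo") {
  spec <- as_model_spec(spec)
  params <- check_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  sim <- cpp_simulate_session(spec$code, unname(params), config$n_runs,
                              config$sequences_per_run, config$criterion_min,
                              config$criterion_max, config$p_misleading,
                              config$max_trials_per_run)
  nt <- length(sim$run)
  df <- data.frame(
    subject_id = subject_id, group = group, drug = drug,
    run = sim$run, sequence = sim$sequence - 1L, trial = seq_len(nt) - 1L,
    stim_left = STIMS[sim$stim_left + 1L],
    stim_right = STIMS[2L - sim$stim_left],
    correct_stim = STIMS[sim$correct_stim + 1L],
    chosen_stim = STIMS[sim$chosen_stim + 1L],
    chosen_side = SIDES[sim$chosen_side + 1L],
    reinforcement = sim$reinforcement,
    misleading = sim$misleading, stringsAsFactors = FALSE)
  new_session(df, sim$reversal_points, sim$criteria_used, config)
}
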