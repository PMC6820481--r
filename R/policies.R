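#' Choice policies for the task engine
#'
#' A policy bundles three callbacks: `choose(ctx)` returns the probability
#' of choosing the left and the right option given the trial context
#' (`ctx$stim_left`, `ctx$stim_right`, `ctx$correct_stim`, `ctx$run`,
#' `ctx$sequence`, `ctx$trial`); `learn(chosen_stim, chosen_side,
#' reinforcement)` lets stateful policies update after feedback; `reset()`
#' is called at session start. Policies must be deterministic given their
#' state: the engine itself samples the choice, so that all randomness flows
#' through one seeded stream.
#'
#' @param choose Function of one argument (the context list) returning a
#'   numeric vector `c(p_left, p_right)`.
#' @param learn Optional function `(chosen_stim, chosen_side,
#'   reinforcement)`.
#' @param reset Optional zero-argument function.
#' @param name Label used in printing.
#' @return An object of class `prl_policy`.
#' @export
prl_policy <- function(choose, learn = NULL, reset = NULL, name = "policy") {
  stopifnot(is.function(choose))
  structure(list(choose = choose, learn = learn, reset = reset, name = name),
            class = "prl_policy")
}

#' @export
print.prl_policy <- function(x, ...) {
  cat(sprintf("<prl_policy: %s>\n", x$name))
  invisible(x)
}

#' Reference policies
#'
#' `policy_oracle()` always chooses the currently correct stimulus (an upper
#' performance bound: every sequence completes in exactly its criterion
#' number of trials). `policy_antioracle()` always chooses the incorrect
#' stimulus, so no sequence ever completes and each run stops at the trial
#' cap. `policy_random()` chooses both sides with probability one half.
#'
#' @return A [prl_policy()].
#' @export
policy_oracle <- function() {
  prl_policy(function(ctx) {
    if (ctx$stim_left == ctx$correct_stim) c(1, 0) else c(0, 1)
  }, name = "oracle")
}

#' @rdname policy_oracle
#' @export
policy_antioracle <- function() {
  prl_policy(function(ctx) {
    if (ctx$stim_left == ctx$correct_stim) c(0, 1) else c(1, 0)
  }, name = "anti-oracle")
}

#' @rdname policy_oracle
#' @export
policy_random <- function() {
  prl_policy(function(ctx) c(0.5, 0.5), name = "random")
}

#' Turn a reinforcement-learning model into a task policy
#'
#' Creates a stateful policy whose choice probabilities come from the
#' model's softmax rule and whose latent state (stimulus values, stickiness
#' indicators, experience weights) is updated after every trial. Used with
#' [generate_session()] this simulates a model agent performing the task in
#' silico; [simulate_model_session()] is a fast equivalent that produces
#' draw-for-draw identical sessions under the same seed.
#'
#' @param spec A [model_spec()].
#' @param params Named parameter vector (the model's free parameters).
#' @return A [prl_policy()].
#' @export
policy_from_model <- function(spec, params) {
  spec <- as_model_spec(spec)
  params <- check_params(spec, params)
  e <- new.env(parent = emptyenv())
  e$state <- init_state(spec)
  prl_policy(
    choose = function(ctx) {
      q <- option_quantities(spec, params, e$state,
                             layout = c(left = ctx$stim_left,
                                        right = ctx$stim_right))
      choice_probability(q, beta = effective_beta(spec, params))
    },
    learn = function(chosen_stim, chosen_side, reinforcement) {
      e$state <- update_state(spec, params, e$state, chosen_stim,
                              chosen_side, reinforcement)
    },
    reset = function() e$state <- init_state(spec),
    name = paste0("model-", spec$name))
}
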