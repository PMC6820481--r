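#' Build the hierarchical group-by-drug cell-means model
#'
#' Each free model parameter gets nine cell means (3 groups x 3 drug
#' conditions) carrying the [prior_spec()] priors, one inter-subject
#' standard deviation with a half-Normal prior, and one deviation per
#' subject drawn from `Normal(0, sigma)` and shared across that subject's
#' sessions. The parameter value entering a session's likelihood is
#' `mu[group, drug] + delta[subject]`, truncated to the parameter's
#' support. The joint log density is the sum of all prior terms plus the
#' per-session choice log-likelihoods.
#'
#' @param spec A [model_spec()].
#' @param cohort A [prl_cohort()].
#' @param priors A [prior_spec()]; defaults to the standard priors.
#' @return An object of class `prl_hmodel` with, among others, a
#'   `log_density(theta)` function over the full latent vector and the
#'   parameter-vector layout (`par_names`).
#' @export
build_hierarchical_model <- function(spec, cohort, priors = NULL) {
  spec <- as_model_spec(spec)
  if (!inherits(cohort, "prl_cohort")) stop("cohort must be a prl_cohort",
                                            call. = FALSE)
  if (is.null(priors)) priors <- prior_spec(spec)
  if (!all(spec$free_parameters %in% priors$parameter))
    stop("priors do not cover all free parameters", call. = FALSE)
  priors <- priors[match(spec$free_parameters, priors$parameter), ,
                   drop = FALSE]
  subjects <- cohort$design$subject_id
  groups <- cohort$design$group
  sess <- cohort_sessions(cohort)
  sess_subj <- vapply(sess, function(d) match(d$subject_id[1], subjects),
                      integer(1))
  sess_cell <- vapply(sess, function(d) cell_index(d$group[1], d$drug[1]),
                      integer(1))
  if (anyNA(sess_subj))
    stop("design error: session references unknown subject", call. = FALSE)
  dat <- list(
    model = spec$code,
    P = length(spec$free_parameters),
    S = length(subjects),
    C = 9L,
    family = match(priors$family, c("beta", "gamma", "normal")) - 1L,
    h1 = priors$h1, h2 = priors$h2,
    lo = priors$lo, hi = priors$hi,
    sigma_scale = priors$sigma_scale,
    sessions = lapply(sess, function(d) list(
      stim_left = match(d$stim_left, STIMS) - 1L,
      chosen_stim = match(d$chosen_stim, STIMS) - 1L,
      reinf = as.integer(d$reinforcement))),
    sess_subj = sess_subj - 1L,
    sess_cell = sess_cell - 1L)
  P <- dat$P
  cells <- cell_labels()
  pn <- spec$free_parameters
  par_names <- c(
    as.vector(t(outer(pn, cells, function(p, c) sprintf("mu[%s,%s]", p, c)))),
    as.vector(t(outer(pn, subjects,
                      function(p, s) sprintf("delta[%s,%s]", p, s)))),
    sprintf("sigma[%s]", pn))
  structure(list(
    spec = spec, priors = priors, dat = dat, subjects = subjects,
    groups = groups, cells = cells, par_names = par_names,
    D = P * 9L + P * dat$S + P,
    session_keys = names(sess),
    log_density = function(theta) cpp_joint_logdens(theta, dat),
    log_density_mat = function(thetas) cpp_joint_logdens_mat(thetas, dat)),
    class = "prl_hmodel")
}

#' @export
print.prl_hmodel <- function(x, ...) {
  cat(sprintf("<prl_hmodel %s: %d subjects, %d sessions, %d latent quantities>\n",
              x$spec$name, x$dat$S, length(x$dat$sessions), x$D))
  invisible(x)
}

# index helpers into the flat latent vector
idx_mu <- function(model, p, cell) (p - 1L) * 9L + cell
idx_delta <- function(model, p, s)
  model$dat$P * 9L + (p - 1L) * model$dat$S + s
idx_sigma <- function(model, p) model$dat$P * (9L + model$dat$S) + p

# one overdispersed chain initialisation
init_chain <- function(model) {
  P <- model$dat$P
  S <- model$dat$S
  th <- numeric(model$D)
  st <- numeric(model$D)
  for (p in seq_len(P)) {
    row <- model$priors[p, ]
    mu0 <- prior_draw(row, 9)
    if (row$family == "beta") mu0 <- pmin(pmax(mu0, 0.05), 0.95)
    if (row$family == "gamma") mu0 <- pmax(mu0, 0.1)
    th[idx_mu(model, p, 1:9)] <- mu0
    th[idx_delta(model, p, seq_len(S))] <- 0
    th[idx_sigma(model, p)] <- abs(rnorm(1, 0, row$sigma_scale / 2)) +
      0.05 * row$sigma_scale
    st[idx_mu(model, p, 1:9)] <- switch(row$family, beta = 0.1, gamma = 0.5,
                                        normal = 0.3)
    st[idx_delta(model, p, seq_len(S))] <- max(0.02, row$sigma_scale / 2)
    st[idx_sigma(model, p)] <- row$sigma_scale / 2
  }
  list(theta = th, step = st)
}

#' Draw from the hierarchical posterior
#'
#' Runs `chains` independent chains of an adaptive random-walk
#' Metropolis-within-Gibbs sampler over all latent quantities (cell means,
#' subject deviations, inter-subject SDs). Step sizes adapt during warmup
#' toward a 0.44 per-coordinate acceptance rate and are then frozen. Chains
#' are initialised overdispersed (cell means drawn from their priors) and
#' seeded deterministically from `seed`, so runs are exactly reproducible.
#'
#' @param model A [build_hierarchical_model()] object.
#' @param chains Number of chains (at least 2, required for R-hat).
#' @param warmup,draws Iterations discarded / retained per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @return A `prl_posterior`: per-chain draw matrices (columns named as in
#'   `model$par_names`), split-chain R-hat per stored quantity, and the
#'   sampler settings.
#' @export
sample_posterior <- function(model, chains = 4, warmup = 1000, draws = 1000,
                             thin = 1, seed = 1) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  ch <- vector("list", chains)
  for (i in seq_len(chains)) {
    set.seed(seed + i - 1L)
    ini <- init_chain(model)
    res <- cpp_sample_chain(model$dat, as.integer(warmup), as.integer(draws),
                            as.integer(thin), ini$theta, ini$step)
    m <- res$draws
    colnames(m) <- model$par_names
    if (any(!is.finite(m)))
      stop("sampling failed: non-finite draws (acceptance rates: ",
           paste(round(range(res$accept_rate), 3), collapse = "-"), ")",
           call. = FALSE)
    ch[[i]] <- m
  }
  rhat <- vapply(seq_along(model$par_names), function(j) {
    split_rhat(sapply(ch, function(m) m[, j]))
  }, numeric(1))
  names(rhat) <- model$par_names
  structure(list(chains = ch, model = model, rhat = rhat,
                 settings = list(chains = chains, warmup = warmup,
                                 draws = draws, thin = thin, seed = seed)),
            class = "prl_posterior")
}

#' @export
print.prl_posterior <- function(x, ...) {
  cat(sprintf(
    "<prl_posterior %s: %d chains x %d draws, %d quantities, max R-hat %.3f>\n",
    x$model$spec$name, length(x$chains), nrow(x$chains[[1]]),
    length(x$rhat), max(x$rhat)))
  invisible(x)
}

#' Pooled posterior draws
#'
#' @param posterior A `prl_posterior`.
#' @param quantities Optional character vector of quantity names.
#' @return Matrix of pooled (chain-concatenated) draws.
#' @export
posterior_draws <- function(posterior, quantities = NULL) {
  m <- do.call(rbind, posterior$chains)
  if (!is.null(quantities)) {
    miss <- setdiff(quantities, colnames(m))
    if (length(miss)) stop("unknown quantities: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    m <- m[, quantities, drop = FALSE]
  }
  m
}

#' Cell-mean draws of one parameter
#'
#' @param posterior A `prl_posterior`.
#' @param parameter Free-parameter name, e.g. `"tau_stim"`.
#' @return Matrix of pooled draws, one column per design cell.
#' @export
posterior_cell_means <- function(posterior, parameter) {
  cells <- posterior$model$cells
  cols <- sprintf("mu[%s,%s]", parameter, cells)
  m <- posterior_draws(posterior, cols)
  colnames(m) <- cells
  m
}

#' Tidy draws table
#'
#' @param posterior A `prl_posterior`.
#' @return Data frame with columns `chain`, `draw`, `quantity`, `value`.
#' @export
posterior_tidy <- function(posterior) {
  out <- lapply(seq_along(posterior$chains), function(i) {
    m <- posterior$chains[[i]]
    data.frame(chain = i, draw = rep(seq_len(nrow(m)), ncol(m)),
               quantity = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Posterior summary table
#'
#' @param posterior A `prl_posterior`.
#' @return Data frame with mean, SD, split R-hat and 95%/90% HDIs per
#'   stored quantity.
#' @export
posterior_summary <- function(posterior) {
  m <- posterior_draws(posterior)
  h95 <- apply(m, 2, hdi, mass = 0.95)
  h90 <- apply(m, 2, hdi, mass = 0.90)
  data.frame(quantity = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, sd), rhat = posterior$rhat[colnames(m)],
             hdi95_lower = h95[1, ], hdi95_upper = h95[2, ],
             hdi90_lower = h90[1, ], hdi90_upper = h90[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
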