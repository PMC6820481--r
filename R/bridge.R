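logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# forward/inverse transforms to the unconstrained scale, with log-Jacobian
# of the inverse (added to the joint density on the unconstrained scale)
unc_forward <- function(x, type) {
  switch(type, identity = x, log = log(x), logit = qlogis(x))
}
unc_inverse <- function(y, type) {
  switch(type, identity = y, log = exp(y), logit = plogis(y))
}
unc_logjac <- function(y, type) {
  switch(type,
         identity = 0 * y,
         log = y,
         logit = {p <- plogis(y); log(p) + log1p(-p)})
}

#' Bridge-sampling estimate of a log marginal likelihood
#'
#' Implements the iterative (optimal-bridge) estimator: posterior draws are
#' mapped to an unconstrained scale (log for positive parameters, logit for
#' unit-interval ones), one half of the draws fits a moment-matched
#' multivariate normal proposal, the other half and fresh proposal draws
#' enter the bridge identity, which is iterated in log space to a fixed
#' point. The returned standard error uses the independence approximation
#' to the estimator's relative mean-squared error.
#'
#' @param samples Matrix of posterior draws on the original (constrained)
#'   scale, one column per quantity.
#' @param log_joint Function taking such a matrix and returning the
#'   unnormalised joint log density (log prior + log likelihood) per row.
#' @param types Character vector per column: `"identity"`, `"log"` or
#'   `"logit"` (unit interval).
#' @param tol Convergence tolerance on the iterative update.
#' @param max_iter Maximum number of bridge iterations.
#' @param ridge Diagonal inflation of the proposal covariance, as a
#'   fraction of the mean diagonal, guarding near-degenerate draws.
#' @return List with `logml`, `se`, `niter`, `converged`.
#' @export
bridge_log_ml <- function(samples, log_joint, types = NULL, tol = 1e-10,
                          max_iter = 1000, ridge = 1e-8) {
  samples <- as.matrix(samples)
  D <- ncol(samples)
  if (is.null(types)) types <- rep("identity", D)
  if (length(types) == 1) types <- rep(types, D)
  stopifnot(length(types) == D)
  N <- nrow(samples)
  if (N < 20) stop("too few posterior draws for bridge sampling",
                   call. = FALSE)
  Y <- samples
  for (j in seq_len(D)) Y[, j] <- unc_forward(samples[, j], types[j])
  if (any(!is.finite(Y)))
    stop("draws on the boundary of their support cannot be transformed",
         call. = FALSE)
  fit_i <- seq(1, N, by = 2)
  est_i <- seq(2, N, by = 2)
  Y1 <- Y[fit_i, , drop = FALSE]
  Y2 <- Y[est_i, , drop = FALSE]
  mu <- colMeans(Y1)
  S <- stats::cov(Y1)
  diag(S) <- diag(S) + ridge * mean(diag(S))
  L <- chol(S)
  log_g <- function(Ym) {
    Z <- forwardsolve(t(L), t(Ym) - mu)
    -0.5 * D * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(Z^2)
  }
  M <- nrow(Y2)
  Yg <- matrix(rnorm(M * D), M, D) %*% L + matrix(mu, M, D, byrow = TRUE)
  log_q_unc <- function(Ym) {
    X <- Ym
    lj <- numeric(nrow(Ym))
    for (j in seq_len(D)) {
      X[, j] <- unc_inverse(Ym[, j], types[j])
      lj <- lj + unc_logjac(Ym[, j], types[j])
    }
    log_joint(X) + lj
  }
  l1 <- log_q_unc(Y2) - log_g(Y2)   # posterior half
  l2 <- log_q_unc(Yg) - log_g(Yg)   # proposal draws
  lstar <- stats::median(l1)
  l1 <- l1 - lstar
  l2 <- l2 - lstar
  s1 <- M / (M + M)   # equal sizes: both 1/2
  s2 <- 1 - s1
  logr <- 0
  converged <- FALSE
  niter <- 0
  for (it in seq_len(max_iter)) {
    niter <- it
    num <- l2 - apply(cbind(log(s1) + l2, log(s2) + logr), 1, logsumexp)
    den <- -apply(cbind(log(s1) + l1, log(s2) + logr), 1, logsumexp)
    logr_new <- (logsumexp(num) - log(M)) - (logsumexp(den) - log(length(l1)))
    if (!is.finite(logr_new))
      stop("bridge estimator diverged (non-finite update)", call. = FALSE)
    if (abs(logr_new - logr) <= tol * max(1, abs(logr_new))) {
      logr <- logr_new
      converged <- TRUE
      break
    }
    logr <- logr_new
  }
  if (!converged)
    stop(sprintf("bridge estimator did not converge in %d iterations (last delta %.3g)",
                 max_iter, abs(logr_new - logr)), call. = FALSE)
  r <- exp(logr)
  f1 <- 1 / (s1 * exp(l1) + s2 * r)
  f2 <- exp(l2) / (s1 * exp(l2) + s2 * r)
  relvar <- var(f2) / (M * mean(f2)^2) + var(f1) / (length(f1) * mean(f1)^2)
  list(logml = logr + lstar, se = sqrt(relvar), niter = niter,
       converged = converged)
}

#' Bridge-sampling evidence of a fitted hierarchical model
#'
#' Applies [bridge_log_ml()] to the full hierarchical joint: all latent
#' quantities (cell means, subject deviations, inter-subject SDs) are
#' integrated over their posterior draws, with log transforms for the SDs
#' and positive parameters and logit transforms for unit-interval
#' parameters.
#'
#' @param posterior A `prl_posterior` from [sample_posterior()].
#' @param seed Seed for the proposal draws.
#' @param ... Passed to [bridge_log_ml()].
#' @return List with `logml`, `se`, `niter`, `converged`.
#' @export
bridge_log_marginal_likelihood <- function(posterior, seed = 1, ...) {
  model <- posterior$model
  m <- posterior_draws(posterior)
  P <- model$dat$P
  S <- model$dat$S
  fam <- model$priors$family
  types <- c(rep(ifelse(fam == "beta", "logit",
                        ifelse(fam == "gamma", "log", "identity")), each = 9),
             rep("identity", P * S),
             rep("log", P))
  set.seed(seed)
  bridge_log_ml(m, model$log_density_mat, types = types, ...)
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' `log P(model | data) = log prior + log ML - logsumexp(log prior + log
#' ML)` across the family; models are ranked by log marginal likelihood
#' (larger, i.e. less negative, is better).
#'
#' @param log_mls Named numeric vector of log marginal likelihoods.
#' @param prior_probs Prior model probabilities (default equal); must sum
#'   to one.
#' @return Data frame with columns `rank`, `model`,
#'   `log_marginal_likelihood`, `log_posterior_probability`,
#'   `posterior_probability`, ordered by rank.
#' @export
posterior_model_probabilities <- function(log_mls,
                                          prior_probs = NULL) {
  k <- length(log_mls)
  if (is.null(prior_probs)) prior_probs <- rep(1 / k, k)
  if (length(prior_probs) != k)
    stop("log_mls and prior_probs lengths differ", call. = FALSE)
  if (abs(sum(prior_probs) - 1) > 1e-8)
    stop("prior_probs must sum to 1", call. = FALSE)
  if (any(!is.finite(log_mls)))
    stop("all log marginal likelihoods must be finite", call. = FALSE)
  nm <- names(log_mls)
  if (is.null(nm)) nm <- paste0("model", seq_len(k))
  lp <- log(prior_probs) + log_mls
  lpost <- lp - logsumexp(lp)
  out <- data.frame(model = nm, log_marginal_likelihood = unname(log_mls),
                    log_posterior_probability = unname(lpost),
                    posterior_probability = exp(unname(lpost)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log_marginal_likelihood), ]
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}

#' Fit and compare a family of models on one cohort
#'
#' Fits each model with [sample_posterior()], estimates its evidence with
#' [bridge_log_marginal_likelihood()], and ranks the family by log marginal
#' likelihood under equal prior model probabilities. A model whose fit or
#' evidence estimation fails is kept in the table with `NA` entries and the
#' error message in `note`; probabilities are renormalised over the models
#' that succeeded.
#'
#' @param cohort A [prl_cohort()].
#' @param specs List of [model_spec()]s or model names.
#' @param chains,warmup,draws,thin,seed Passed to [sample_posterior()].
#' @return Data frame with columns `rank`, `model`, `parameters`,
#'   `log_marginal_likelihood`, `log_posterior_probability`,
#'   `posterior_probability`, `max_rhat`, `note`.
#' @export
compare_family <- function(cohort, specs = model_names(), chains = 4,
                           warmup = 1000, draws = 1000, thin = 1, seed = 1) {
  specs <- lapply(specs, as_model_spec)
  res <- lapply(specs, function(sp) {
    out <- list(model = sp$name,
                parameters = paste(sp$free_parameters, collapse = ", "),
                logml = NA_real_, max_rhat = NA_real_, note = "")
    tryCatch({
      hm <- build_hierarchical_model(sp, cohort)
      post <- sample_posterior(hm, chains = chains, warmup = warmup,
                               draws = draws, thin = thin, seed = seed)
      br <- bridge_log_marginal_likelihood(post, seed = seed)
      out$logml <- br$logml
      out$max_rhat <- max(post$rhat)
    }, error = function(e) out$note <<- conditionMessage(e))
    out
  })
  tab <- data.frame(
    model = vapply(res, `[[`, "", "model"),
    parameters = vapply(res, `[[`, "", "parameters"),
    log_marginal_likelihood = vapply(res, `[[`, 0, "logml"),
    max_rhat = vapply(res, `[[`, 0, "max_rhat"),
    note = vapply(res, `[[`, "", "note"), stringsAsFactors = FALSE)
  ok <- is.finite(tab$log_marginal_likelihood)
  tab$log_posterior_probability <- NA_real_
  tab$posterior_probability <- NA_real_
  if (any(ok)) {
    pp <- posterior_model_probabilities(
      setNames(tab$log_marginal_likelihood[ok], tab$model[ok]))
    i <- match(tab$model[ok], pp$model)
    tab$log_posterior_probability[ok] <- pp$log_posterior_probability[i]
    tab$posterior_probability[ok] <- pp$posterior_probability[i]
  }
  tab <- tab[order(-ifelse(ok, tab$log_marginal_likelihood, -Inf)), ]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab[, c("rank", "model", "parameters", "log_marginal_likelihood",
          "log_posterior_probability", "posterior_probability",
          "max_rhat", "note")]
}
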