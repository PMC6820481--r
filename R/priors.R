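#' Prior specification for the hierarchical model
#'
#' Cell-level means carry the model-parameter priors: Beta(1.2, 1.2) for
#' learning rates and EWA decay factors, Gamma(shape 4.82, rate 0.88) for
#' the reinforcement sensitivity and the EWA inverse temperature, and
#' Normal(0, 1) for the stickiness weights. Inter-subject standard
#' deviations carry half-Normal priors: scale 0.05 for the unit-interval
#' parameters and the side-stickiness weight, scale 1 for `tau_reinf`,
#' `beta` and `tau_stim` (the stimulus-stickiness SD prior is not pinned
#' down elsewhere; the wide scale used for the other unbounded weights is
#' adopted). Identical priors apply to every group and drug cell.
#'
#' @param spec A [model_spec()].
#' @param overrides Optional named list of per-parameter replacement
#'   entries, each a list with any of `family` (`"beta"`, `"gamma"`,
#'   `"normal"`), `h1`, `h2`, `sigma_scale`.
#' @return An object of class `prior_spec`: one row per free parameter with
#'   columns `parameter, family, h1, h2, lo, hi, sigma_scale`.
#' @export
prior_spec <- function(spec, overrides = NULL) {
  spec <- as_model_spec(spec)
  base <- list(
    alpha_rew   = list(family = "beta",   h1 = 1.2,  h2 = 1.2,  sigma_scale = 0.05),
    alpha_pun   = list(family = "beta",   h1 = 1.2,  h2 = 1.2,  sigma_scale = 0.05),
    alpha_reinf = list(family = "beta",   h1 = 1.2,  h2 = 1.2,  sigma_scale = 0.05),
    rho         = list(family = "beta",   h1 = 1.2,  h2 = 1.2,  sigma_scale = 0.05),
    phi         = list(family = "beta",   h1 = 1.2,  h2 = 1.2,  sigma_scale = 0.05),
    tau_reinf   = list(family = "gamma",  h1 = 4.82, h2 = 0.88, sigma_scale = 1),
    beta        = list(family = "gamma",  h1 = 4.82, h2 = 0.88, sigma_scale = 1),
    tau_loc     = list(family = "normal", h1 = 0,    h2 = 1,    sigma_scale = 0.05),
    tau_stim    = list(family = "normal", h1 = 0,    h2 = 1,    sigma_scale = 1))
  rows <- lapply(spec$free_parameters, function(p) {
    e <- base[[p]]
    if (!is.null(overrides[[p]]))
      e <- utils::modifyList(e, overrides[[p]])
    sup <- switch(e$family, beta = c(0, 1), gamma = c(0, Inf),
                  normal = c(-Inf, Inf))
    data.frame(parameter = p, family = e$family, h1 = e$h1, h2 = e$h2,
               lo = sup[1], hi = sup[2], sigma_scale = e$sigma_scale,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("prior_spec", "data.frame"))
}

# log density / sampler / mean of one cell-mean prior
prior_logdens <- function(row, x) {
  switch(row$family,
         beta   = dbeta(x, row$h1, row$h2, log = TRUE),
         gamma  = dgamma(x, shape = row$h1, rate = row$h2, log = TRUE),
         normal = dnorm(x, row$h1, row$h2, log = TRUE))
}

prior_draw <- function(row, n = 1) {
  switch(row$family,
         beta   = rbeta(n, row$h1, row$h2),
         gamma  = rgamma(n, shape = row$h1, rate = row$h2),
         normal = rnorm(n, row$h1, row$h2))
}

prior_mean <- function(row) {
  switch(row$family,
         beta   = row$h1 / (row$h1 + row$h2),
         gamma  = row$h1 / row$h2,
         normal = row$h1)
}

prior_cdf <- function(row, q) {
  switch(row$family,
         beta   = stats::pbeta(q, row$h1, row$h2),
         gamma  = stats::pgamma(q, shape = row$h1, rate = row$h2),
         normal = stats::pnorm(q, row$h1, row$h2))
}
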