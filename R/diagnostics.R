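#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor is computed over the resulting half-chains, comparing between- and
#' within-chain variance. Values near 1 indicate convergence; 1.1 is the
#' stringent and 1.2 the conventional guideline. Chains with zero variance
#' everywhere (a degenerate but converged case) return exactly 1.
#'
#' @param draws Matrix with one column per chain (or a list of equal-length
#'   numeric vectors).
#' @return The R-hat scalar.
#' @export
split_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("at least 2 chains are required", call. = FALSE)
  n <- nrow(draws)
  if (n < 4) stop("at least 4 draws per chain are required", call. = FALSE)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  W <- mean(apply(sub, 2, var))
  if (!is.finite(W) || W == 0) return(1)
  B <- half * var(colMeans(sub))
  vhat <- (half - 1) / half * W + B / half
  sqrt(vhat / W)
}

#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws -- the Bayesian credible interval used to flag contrasts
#' whose posterior excludes zero.
#'
#' @param draws Numeric vector of posterior draws (at least 20 for a
#'   meaningful interval; a point mass yields a zero-width interval).
#' @param mass Probability mass in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n == 0) stop("no draws supplied", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k):n] - x[seq_len(n - k + 1)]
  i <- which.min(w)
  c(x[i], x[i + k - 1])
}

#' Posterior contrasts between design cells
#'
#' For one model parameter, computes draw-wise differences of cell means:
#' between-group differences on placebo (SUD-HC, OCD-HC, SUD-OCD),
#' within-group drug effects (drug minus placebo, per group and drug), and
#' group differences in drug effects,
#' `(patient_drug - patient_placebo) - (HC_drug - HC_placebo)`. Each
#' contrast is summarised by its posterior mean and 95% and 90% HDIs, with
#' flags for intervals excluding zero.
#'
#' @param posterior A `prl_posterior`.
#' @param parameter Free-parameter name.
#' @return Data frame of contrast summaries, with the draw-wise contrast
#'   matrix attached as attribute `"draws"`.
#' @export
cell_contrasts <- function(posterior, parameter) {
  cm <- posterior_cell_means(posterior, parameter)
  cell <- function(g, d) cm[, paste(g, d, sep = ":")]
  draws <- list()
  for (pair in list(c("SUD", "HC"), c("OCD", "HC"), c("SUD", "OCD")))
    draws[[sprintf("%s-%s (placebo)", pair[1], pair[2])]] <-
      cell(pair[1], "placebo") - cell(pair[2], "placebo")
  for (g in GROUPS) for (d in DRUGS[-1])
    draws[[sprintf("%s: %s-placebo", g, d)]] <- cell(g, d) - cell(g, "placebo")
  for (g in c("SUD", "OCD")) for (d in DRUGS[-1])
    draws[[sprintf("(%s-HC) x %s effect", g, d)]] <-
      (cell(g, d) - cell(g, "placebo")) - (cell("HC", d) - cell("HC", "placebo"))
  dm <- do.call(cbind, draws)
  h95 <- apply(dm, 2, hdi, mass = 0.95)
  h90 <- apply(dm, 2, hdi, mass = 0.90)
  out <- data.frame(
    parameter = parameter, contrast = colnames(dm), mean = colMeans(dm),
    hdi95_lower = h95[1, ], hdi95_upper = h95[2, ],
    hdi90_lower = h90[1, ], hdi90_upper = h90[2, ],
    excl95 = h95[1, ] > 0 | h95[2, ] < 0,
    excl90 = h90[1, ] > 0 | h90[2, ] < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "draws") <- dm
  out
}
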