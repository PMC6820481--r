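#' Preset generating cell means
#'
#' The clinical study's fitted posterior means are not published, so the
#' presets encode qualitative group patterns at chosen magnitudes, for use
#' as generating ground truth in simulation experiments:
#'
#' * `"placebo_pattern"` -- the placebo-group pattern for the winning
#'   five-parameter model: relative to healthy controls, the stimulant-use
#'   group has a lower reward learning rate, a higher punishment learning
#'   rate and stronger stimulus stickiness; the OCD group has a higher
#'   punishment learning rate and weaker stimulus stickiness. Drug cells
#'   repeat each group's placebo values (drug effects are not part of the
#'   preset).
#' * `"stickiness_only"` -- all cells identical except for `tau_stim`,
#'   which differs by group; isolates stimulus stickiness as the sole
#'   driver of group differences, the setting used by the fixed-parameter
#'   ablation experiments.
#' * `"spread"` -- cell means spread widely over each parameter's support
#'   (each parameter permuted differently across the nine cells); used by
#'   parameter-recovery experiments, where well-separated truths are
#'   needed.
#'
#' @param preset Preset name.
#' @param model Model name (presets are defined for `"M4c"`).
#' @return Data frame with columns `group`, `drug` and one column per free
#'   parameter (nine rows, one per design cell).
#' @export
preset_cells <- function(preset = c("placebo_pattern", "stickiness_only",
                                    "spread"), model = "M4c") {
  preset <- match.arg(preset)
  spec <- as_model_spec(model)
  if (spec$name != "M4c")
    stop("presets are defined for the winning model M4c", call. = FALSE)
  grid <- expand.grid(drug = DRUGS, group = GROUPS,
                      stringsAsFactors = FALSE)[, c("group", "drug")]
  base <- c(alpha_rew = 0.40, alpha_pun = 0.40, tau_reinf = 5.5,
            tau_stim = 1.0, tau_loc = 0.3)
  cells <- as.data.frame(matrix(rep(base, each = 9), nrow = 9,
                                dimnames = list(NULL, names(base))))
  if (preset == "placebo_pattern") {
    sud <- grid$group == "SUD"
    ocd <- grid$group == "OCD"
    cells$alpha_rew[sud] <- 0.12
    cells$alpha_pun[sud] <- 0.60
    cells$tau_stim[sud] <- 1.8
    cells$alpha_pun[ocd] <- 0.55
    cells$tau_stim[ocd] <- 0.35
  } else if (preset == "stickiness_only") {
    cells$tau_stim[grid$group == "SUD"] <- 2.2
    cells$tau_stim[grid$group == "OCD"] <- 0.2
  } else {
    perm <- list(alpha_rew = c(1, 4, 7, 2, 5, 8, 3, 6, 9),
                 alpha_pun = c(9, 3, 6, 1, 7, 4, 8, 2, 5),
                 tau_reinf = c(5, 1, 8, 3, 9, 2, 7, 4, 6),
                 tau_stim = c(2, 7, 4, 9, 1, 6, 3, 8, 5),
                 tau_loc = c(6, 2, 9, 5, 3, 8, 1, 7, 4))
    levels <- list(alpha_rew = seq(0.15, 0.65, length.out = 9),
                   alpha_pun = seq(0.15, 0.65, length.out = 9),
                   tau_reinf = seq(3, 8, length.out = 9),
                   tau_stim = seq(-0.5, 2.5, length.out = 9),
                   tau_loc = seq(-1, 1, length.out = 9))
    for (p in names(perm)) cells[[p]] <- levels[[p]][perm[[p]]]
  }
  cbind(grid, cells)
}

#' Specification of a synthetic cohort
#'
#' @param model Model name or [model_spec()].
#' @param cell_means Data frame as returned by [preset_cells()] (columns
#'   `group`, `drug`, and the model's free parameters). Cells may be
#'   omitted; subjects then contribute no session for the missing drug.
#' @param sds Named vector of inter-subject SDs per parameter (0 = all
#'   subjects in a cell identical).
#' @param n_per_group Subjects per group (scalar or named by group);
#'   defaults to the study-sized 19/18/19 split for HC/SUD/OCD.
#' @param config A [task_config()].
#' @param seed Integer seed driving every random element of the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(model = "M4c", cell_means = preset_cells(),
                        sds = NULL, n_per_group = c(HC = 19, SUD = 18,
                                                    OCD = 19),
                        config = task_config(), seed = 1) {
  spec <- as_model_spec(model)
  need <- c("group", "drug", spec$free_parameters)
  miss <- setdiff(need, names(cell_means))
  if (length(miss))
    stop("cell_means lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(sds))
    sds <- setNames(ifelse(grepl("^alpha|^rho|^phi", spec$free_parameters),
                           0.04, 0.25), spec$free_parameters)
  sds <- sds[spec$free_parameters]
  if (anyNA(sds) || any(sds < 0))
    stop("sds must be nonnegative and cover all free parameters",
         call. = FALSE)
  pr <- prior_spec(spec)
  for (p in spec$free_parameters) {
    row <- pr[pr$parameter == p, ]
    v <- cell_means[[p]]
    if (any(v < row$lo | v > row$hi))
      stop(sprintf("cell mean for %s outside its support", p), call. = FALSE)
  }
  if (length(n_per_group) == 1)
    n_per_group <- setNames(rep(n_per_group, 3), GROUPS)
  structure(list(spec = spec, cell_means = cell_means, sds = sds,
                 n_per_group = n_per_group, config = config,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' For every subject, one deviation per parameter is drawn from
#' `Normal(0, sd)` and shared across that subject's sessions; the
#' session-level parameter is the cell mean plus the deviation, truncated
#' to the parameter's support -- exactly the structure assumed by the
#' hierarchical fitter, so recovery failures indicate estimation problems
#' rather than model mismatch. Sessions are simulated with the model agent
#' via the compiled task simulator.
#'
#' @param spec A [cohort_spec()].
#' @return A [prl_cohort()] whose `ground_truth` holds the generating cell
#'   means, SDs, subject deviations and realised per-session parameters.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ms <- spec$spec
  pr <- prior_spec(ms)
  pars <- ms$free_parameters
  subjects <- unlist(lapply(GROUPS, function(g)
    sprintf("%s%02d", tolower(g), seq_len(spec$n_per_group[[g]]))))
  design <- data.frame(
    subject_id = subjects,
    group = rep(GROUPS, times = vapply(GROUPS,
                                       function(g) spec$n_per_group[[g]],
                                       numeric(1))),
    stringsAsFactors = FALSE)
  deltas <- matrix(rnorm(nrow(design) * length(pars)) *
                     rep(spec$sds, each = nrow(design)),
                   nrow = nrow(design),
                   dimnames = list(subjects, pars))
  trials <- list()
  truth <- list()
  for (i in seq_len(nrow(design))) {
    g <- design$group[i]
    for (d in DRUGS) {
      row <- spec$cell_means[spec$cell_means$group == g &
                               spec$cell_means$drug == d, , drop = FALSE]
      if (nrow(row) == 0) next
      p <- unlist(row[1, pars])
      p <- p + deltas[i, pars]
      for (k in pars) {
        pri <- pr[pr$parameter == k, ]
        p[k] <- min(max(p[k], pri$lo), pri$hi)
      }
      ses <- simulate_model_session(ms, p, spec$config,
                                    subject_id = design$subject_id[i],
                                    group = g, drug = d)
      trials[[length(trials) + 1L]] <- as.data.frame(ses)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = design$subject_id[i], group = g, drug = d,
        t(p), stringsAsFactors = FALSE)
    }
  }
  prl_cohort(do.call(rbind, trials), design = design,
             ground_truth = list(cell_means = spec$cell_means,
                                 sds = spec$sds,
                                 deltas = as.data.frame(deltas),
                                 session_params = do.call(rbind, truth),
                                 cohort_spec = spec))
}

#' Posterior-predictive simulation with identical virtual subjects
#'
#' Simulates `n_subjects` identical agents per design cell (no
#' inter-subject variability and no within-subject structure, so that the
#' only variability is the stochastic mapping from choice probabilities to
#' choices and the random stimulus-side assignment), computes the
#' behavioural measures and runs the classical statistical harness.
#'
#' @param cell_params Data frame of per-cell parameters (e.g.
#'   [preset_cells()] or fitted posterior cell means).
#' @param model Model name or spec.
#' @param n_subjects Virtual subjects per cell.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return List with `measures` (one row per virtual session), `stats`
#'   (harness report) and `cell_params`.
#' @export
posterior_mean_simulation <- function(cell_params, model = "M4c",
                                      n_subjects = 100,
                                      config = task_config(), seed = 1) {
  spec <- as_model_spec(model)
  pars <- spec$free_parameters
  set.seed(seed)
  meas <- list()
  for (r in seq_len(nrow(cell_params))) {
    g <- cell_params$group[r]
    d <- cell_params$drug[r]
    p <- unlist(cell_params[r, pars])
    for (i in seq_len(n_subjects)) {
      ses <- simulate_model_session(spec, p, config,
                                    subject_id = sprintf("%s_%s_%03d", g, d, i),
                                    group = g, drug = d)
      meas[[length(meas) + 1L]] <- session_measures(ses)
    }
  }
  measures <- do.call(rbind, meas)
  rownames(measures) <- NULL
  list(measures = measures, stats = stats_harness(measures),
       cell_params = cell_params)
}

#' Ablation: fix one parameter at its overall mean across cells
#'
#' Replaces the named parameter in every cell by the mean of its nine
#' per-cell values (the "overall posterior mean" convention), re-simulates
#' the virtual cohort and re-runs the statistical harness. Comparing the
#' resulting report with the unablated one shows which group and drug
#' effects depend on between-cell variation of that parameter.
#'
#' @param parameter Parameter to fix (e.g. `"tau_stim"` or `"tau_loc"`).
#' @param cell_params Data frame of per-cell parameters.
#' @inheritParams posterior_mean_simulation
#' @return As [posterior_mean_simulation()], with the ablated `cell_params`.
#' @export
fixed_parameter_ablation <- function(parameter, cell_params, model = "M4c",
                                     n_subjects = 100,
                                     config = task_config(), seed = 1) {
  spec <- as_model_spec(model)
  if (!parameter %in% spec$free_parameters)
    stop(sprintf("parameter %s is not free in model %s", parameter,
                 spec$name), call. = FALSE)
  if (!parameter %in% names(cell_params))
    stop("parameter column missing from cell_params", call. = FALSE)
  cp <- cell_params
  cp[[parameter]] <- mean(cp[[parameter]])
  posterior_mean_simulation(cp, model = model, n_subjects = n_subjects,
                            config = config, seed = seed)
}

#' Parameter-recovery experiment
#'
#' Generates a cohort from known cell means, fits the hierarchical model,
#' and reports truth versus posterior mean per cell mean, 95% HDI coverage
#' of the truths, and the Spearman rank correlation between generating and
#' recovered cell means across the nine cells, per parameter.
#'
#' @param spec A [cohort_spec()] (the generating model defaults to M4c).
#' @param chains,warmup,draws,thin,seed Fit settings, passed to
#'   [sample_posterior()].
#' @return List with `table` (per-cell-mean recovery rows), `rank_cor`
#'   (per-parameter Spearman correlation), `coverage` (overall 95% HDI
#'   coverage of cell-mean truths), `posterior` and `cohort`.
#' @export
parameter_recovery_experiment <- function(spec = cohort_spec(
                                            cell_means = preset_cells("spread"),
                                            n_per_group = 6),
                                          chains = 4, warmup = 1000,
                                          draws = 1000, thin = 1, seed = 1) {
  cohort <- generate_cohort(spec)
  hm <- build_hierarchical_model(spec$spec, cohort)
  post <- sample_posterior(hm, chains = chains, warmup = warmup,
                           draws = draws, thin = thin, seed = seed)
  pars <- spec$spec$free_parameters
  cm <- spec$cell_means
  rows <- list()
  for (p in pars) {
    dm <- posterior_cell_means(post, p)
    for (r in seq_len(nrow(cm))) {
      cellname <- paste(cm$group[r], cm$drug[r], sep = ":")
      dr <- dm[, cellname]
      h <- hdi(dr, 0.95)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, cell = cellname, truth = cm[[p]][r],
        estimate = mean(dr), hdi95_lower = h[1], hdi95_upper = h[2],
        covered = cm[[p]][r] >= h[1] & cm[[p]][r] <= h[2],
        rhat = post$rhat[sprintf("mu[%s,%s]", p, cellname)],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rank_cor <- vapply(pars, function(p) {
    d <- tab[tab$parameter == p, ]
    stats::cor(d$truth, d$estimate, method = "spearman")
  }, numeric(1))
  list(table = tab, rank_cor = rank_cor, coverage = mean(tab$covered),
       posterior = post, cohort = cohort)
}
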