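# small two-subject cohort reused across hierarchy tests
tiny_cohort <- function(seed = 41, n_per_group = 2,
                        config = task_config(n_runs = 1,
                                             sequences_per_run = 4)) {
  generate_cohort(cohort_spec(cell_means = preset_cells("placebo_pattern"),
                              n_per_group = n_per_group, config = config,
                              seed = seed))
}

test_that("joint density decomposes into prior plus session log-likelihoods", {
  co <- tiny_cohort()
  hm <- build_hierarchical_model("M4c", co)
  pr <- hm$priors
  set.seed(1)
  theta <- numeric(hm$D)
  P <- nrow(pr); S <- hm$dat$S
  for (p in seq_len(P)) {
    theta[(p - 1) * 9 + 1:9] <- prior_draw(pr[p, ], 9)
    theta[P * 9 + (p - 1) * S + 1:S] <- rnorm(S, 0, 0.02)
    theta[P * (9 + S) + p] <- abs(rnorm(1, 0, pr$sigma_scale[p])) + 0.01
  }
  # independent recomputation in R
  lp <- 0
  for (p in seq_len(P)) {
    sig <- theta[P * (9 + S) + p]
    lp <- lp + sum(prior_logdens(pr[p, ], theta[(p - 1) * 9 + 1:9])) +
      log(2) + dnorm(sig, 0, pr$sigma_scale[p], log = TRUE) +
      sum(dnorm(theta[P * 9 + (p - 1) * S + 1:S], 0, sig, log = TRUE))
  }
  sess <- cohort_sessions(co)
  for (k in seq_along(sess)) {
    d <- sess[[k]]
    ci <- cell_index(d$group[1], d$drug[1])
    si <- match(d$subject_id[1], co$design$subject_id)
    pars <- vapply(seq_len(P), function(p) {
      v <- theta[(p - 1) * 9 + ci] + theta[P * 9 + (p - 1) * S + si]
      min(max(v, pr$lo[p]), pr$hi[p])
    }, numeric(1))
    names(pars) <- pr$parameter
    lp <- lp + naive_loglik("M4c", pars, d)
  }
  expect_equal(hm$log_density(theta), lp, tolerance = 1e-8)
})

test_that("with all data removed the joint density is the prior density", {
  co <- tiny_cohort()
  co0 <- prl_cohort(co$trials[0, ], design = co$design)
  hm0 <- build_hierarchical_model("M4c", co0)
  pr <- hm0$priors
  set.seed(2)
  theta <- numeric(hm0$D)
  P <- nrow(pr); S <- hm0$dat$S
  lp <- 0
  for (p in seq_len(P)) {
    theta[(p - 1) * 9 + 1:9] <- prior_draw(pr[p, ], 9)
    theta[P * 9 + (p - 1) * S + 1:S] <- rnorm(S, 0, 0.01)
    sig <- abs(rnorm(1, 0, pr$sigma_scale[p])) + 0.01
    theta[P * (9 + S) + p] <- sig
    lp <- lp + sum(prior_logdens(pr[p, ], theta[(p - 1) * 9 + 1:9])) +
      log(2) + dnorm(sig, 0, pr$sigma_scale[p], log = TRUE) +
      sum(dnorm(theta[P * 9 + (p - 1) * S + 1:S], 0, sig, log = TRUE))
  }
  expect_equal(hm0$log_density(theta), lp, tolerance = 1e-8)
})

test_that("design errors are caught", {
  co <- tiny_cohort()
  tr <- co$trials
  expect_error(prl_cohort(tr, design = data.frame(subject_id = "zz",
                                                  group = "HC")),
               "design error")
  dd <- rbind(co$design, data.frame(subject_id = co$design$subject_id[1],
                                    group = "OCD"))
  expect_error(prl_cohort(tr, design = dd), "more than one group")
})

test_that("split R-hat behaves at its edge cases", {
  expect_equal(split_rhat(cbind(rep(1, 100), rep(1, 100))), 1)
  set.seed(3)
  x <- matrix(rnorm(4e4), ncol = 4)
  expect_lt(split_rhat(x), 1.01)
  y <- cbind(rnorm(5000, 0), rnorm(5000, 10))
  expect_gt(split_rhat(y), 1.2)
  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("hdi matches closed forms", {
  expect_equal(hdi(rep(3.2, 50)), c(3.2, 3.2))
  set.seed(4)
  z <- rnorm(1e6)
  h <- hdi(z, 0.95)
  # endpoints of a sample HDI carry selection noise beyond the order-stat
  # standard error; width concentrates faster than location
  expect_lt(max(abs(h - c(-1.96, 1.96))), 0.03)
  expect_lt(abs(diff(h) - 2 * 1.96), 0.02)
  u <- runif(1e5)
  hu <- hdi(u, 0.9)
  expect_lt(abs(diff(hu) - 0.9), 0.02)
  expect_error(hdi(numeric(0)), "no draws")
  expect_error(hdi(rnorm(50), mass = 1.2), "mass")
})

test_that("sampler is seed-deterministic and prior-calibrated without data", {
  co <- tiny_cohort()
  co0 <- prl_cohort(co$trials[0, ], design = co$design)
  hm0 <- build_hierarchical_model("M4c", co0)
  a <- sample_posterior(hm0, chains = 2, warmup = 200, draws = 200, seed = 9)
  b <- sample_posterior(hm0, chains = 2, warmup = 200, draws = 200, seed = 9)
  expect_identical(a$chains, b$chains)
  expect_error(sample_posterior(hm0, chains = 1), "2 chains")
  # prior-predictive: cell-mean draws reproduce the stated priors
  post <- sample_posterior(hm0, chains = 4, warmup = 500, draws = 2500,
                           thin = 2, seed = 5)
  pr <- hm0$priors
  for (p in c("alpha_rew", "tau_reinf", "tau_stim")) {
    dr <- posterior_draws(post, sprintf("mu[%s,%s]", p, "SUD:placebo"))[, 1]
    row <- pr[pr$parameter == p, ]
    # rejected MH proposals duplicate draws; ties only affect the exact
    # p-value computation, not the asymptotic one used here
    ks <- suppressWarnings(stats::ks.test(dr, function(q) prior_cdf(row, q)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("delta fixed at zero makes subject parameters equal their cell means", {
  co <- tiny_cohort()
  hm <- build_hierarchical_model("M4c", co)
  pr <- hm$priors
  P <- nrow(pr); S <- hm$dat$S
  set.seed(6)
  theta <- numeric(hm$D)
  for (p in seq_len(P)) {
    theta[(p - 1) * 9 + 1:9] <- prior_draw(pr[p, ], 9)
    theta[P * (9 + S) + p] <- 0.05
  }
  # likelihood part must equal summing session LLs at the raw cell means
  ll_model <- hm$log_density(theta)
  prior_part <- 0
  for (p in seq_len(P)) {
    sig <- theta[P * (9 + S) + p]
    prior_part <- prior_part +
      sum(prior_logdens(pr[p, ], theta[(p - 1) * 9 + 1:9])) +
      log(2) + dnorm(sig, 0, pr$sigma_scale[p], log = TRUE) +
      S * dnorm(0, 0, sig, log = TRUE)
  }
  ll_sessions <- 0
  for (d in cohort_sessions(co)) {
    ci <- cell_index(d$group[1], d$drug[1])
    pars <- setNames(theta[(seq_len(P) - 1) * 9 + ci], pr$parameter)
    ll_sessions <- ll_sessions +
      session_log_likelihood("M4c", pars, as_toy_session(d))
  }
  expect_equal(ll_model, prior_part + ll_sessions, tolerance = 1e-8)
})

test_that("contrasts are draw-wise differences with nested HDIs", {
  co <- tiny_cohort()
  hm <- build_hierarchical_model("M4c", co)
  post <- sample_posterior(hm, chains = 2, warmup = 300, draws = 300, seed = 2)
  ct <- cell_contrasts(post, "tau_stim")
  expect_identical(nrow(ct), 13L)
  # sample HDIs at two masses are nested up to order-statistic noise
  slack <- 0.05 * (ct$hdi95_upper - ct$hdi95_lower)
  expect_true(all(ct$hdi90_lower >= ct$hdi95_lower - slack))
  expect_true(all(ct$hdi90_upper <= ct$hdi95_upper + slack))
  # independent tabular recomputation of one contrast
  cm <- posterior_cell_means(post, "tau_stim")
  manual <- cm[, "SUD:placebo"] - cm[, "HC:placebo"]
  expect_equal(unname(attr(ct, "draws")[, "SUD-HC (placebo)"]),
               unname(manual))
  # chain permutation leaves contrast HDIs unchanged
  post2 <- post
  post2$chains <- rev(post2$chains)
  ct2 <- cell_contrasts(post2, "tau_stim")
  expect_equal(ct$hdi95_lower, ct2$hdi95_lower)
  # identical cells give null contrasts containing zero
  dm <- attr(ct, "draws")
  nullc <- cm[, "HC:amisulpride"] - cm[, "HC:amisulpride"]
  expect_true(all(nullc == 0))
  h <- hdi(nullc + 0, 0.95)
  expect_true(h[1] <= 0 && h[2] >= 0)
  # a +1 shifted contrast excludes zero
  h1 <- hdi(nullc + 1, 0.95)
  expect_true(h1[1] > 0)
})

test_that("subject-level estimates shrink from the session ML fit toward the cell mean", {
  # single-cell cohort (placebo only) so each subject has one session and
  # the subject-level value is cell mean + own deviation
  cm <- preset_cells("placebo_pattern")
  cs <- cohort_spec("M4c", cell_means = cm, n_per_group = 8, seed = 14,
                    sds = c(alpha_rew = 0.08, alpha_pun = 0.08,
                            tau_reinf = 0.8, tau_stim = 0.5, tau_loc = 0.2))
  co <- generate_cohort(cs)
  keep <- co$trials$drug == "placebo" & co$trials$group == "HC"
  co1 <- prl_cohort(co$trials[keep, ],
                    design = co$design[co$design$group == "HC", ])
  spec <- model_spec("M1")
  hm <- build_hierarchical_model(spec, co1)
  post <- sample_posterior(hm, chains = 2, warmup = 600, draws = 800,
                           seed = 4)
  subs <- co1$design$subject_id
  cellmean <- colMeans(posterior_draws(
    post, sprintf("mu[%s,HC:placebo]", spec$free_parameters)))
  names(cellmean) <- spec$free_parameters
  sess <- cohort_sessions(co1)
  ok <- 0L; total <- 0L
  for (s in subs) {
    d <- sess[[paste(s, "placebo", sep = ":")]]
    ml <- stats::optim(c(0, log(5)), function(th) {
      -naive_loglik("M1", c(alpha_reinf = plogis(th[1]),
                            tau_reinf = exp(th[2])), d)
    })$par
    ml <- c(alpha_reinf = plogis(ml[1]), tau_reinf = exp(ml[2]))
    for (p in spec$free_parameters) {
      est <- cellmean[[p]] + mean(posterior_draws(
        post, sprintf("delta[%s,%s]", p, s)))
      lohi <- range(c(ml[[p]], cellmean[[p]]))
      # tolerance for Monte-Carlo noise when the ML fit and the cell mean
      # nearly coincide: ~1% of the parameter's magnitude
      tol <- 0.02 * diff(lohi) + 0.01 * max(abs(cellmean[[p]]), 0.1)
      ok <- ok + (est >= lohi[1] - tol && est <= lohi[2] + tol)
      total <- total + 1L
    }
  }
  expect_gte(ok / total, 0.9)
})

test_that("posterior summaries expose R-hat and HDIs for every quantity", {
  co <- tiny_cohort()
  hm <- build_hierarchical_model("M4c", co)
  post <- sample_posterior(hm, chains = 2, warmup = 200, draws = 200, seed = 3)
  sm <- posterior_summary(post)
  expect_identical(nrow(sm), hm$D)
  expect_true(all(is.finite(sm$rhat)))
  expect_true(all(sm$hdi95_lower <= sm$hdi95_upper))
  td <- posterior_tidy(post)
  expect_identical(nrow(td), 2L * 200L * hm$D)
  expect_identical(sort(unique(td$quantity)), sort(hm$par_names))
})
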