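# Hierarchical Bayesian fit: determinism, shrinkage, credible differences,
# and posterior-predictive checks. Recovery at full study size lives in
# test-acceptance.R; fits here use small settings to probe structure.

mu_2c <- function(pr1 = 0.5, pf1 = 0.7, pr2 = pr1, pf2 = pf1) {
  m <- rbind(Pr = c(pr1, pr2), Pf = c(pf1, pf2))
  colnames(m) <- c("CORRECTED_1X", "CORRECTED_3X")
  m
}

test_that("identical seeds give identical draws; different seeds differ", {
  cnt <- simulate_mpt_counts(20, 15, mu_2c(), seed = 1)
  f1 <- quick_fit(cnt)
  f2 <- quick_fit(cnt)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mpt(cnt, chains = 2, iter = 400, warmup = 200, seed = 43)
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("input validation catches malformed count tables", {
  cnt <- simulate_mpt_counts(10, 15, mu_2c(), seed = 2)
  expect_error(fit_mpt(cnt[, -3]), "missing columns")
  expect_error(fit_mpt(cnt[cnt$participant_id == "S0001", ]), "2 participants")
  # participants missing one condition are dropped with a warning
  drop_one <- cnt[!(cnt$participant_id == "S0001" &
                      cnt$condition == "CORRECTED_3X"), ]
  expect_warning(f <- quick_fit(drop_one), "every condition")
  expect_equal(length(f$participant_ids), 9)
})

test_that("participant estimates shrink toward the group mean", {
  set.seed(3)
  cnt <- simulate_mpt_counts(40, 15, mu_2c(), seed = 3)
  fit <- quick_fit(cnt)
  # raw per-participant moment estimates are noisier than posterior means
  raw <- do.call(rbind, lapply(c("CORRECTED_1X", "CORRECTED_3X"), function(cond) {
    m <- as.matrix(cnt[cnt$condition == cond, c("n_real", "n_fake", "n_novel")])
    mpt_moments(m / rowSums(m))
  }))
  post_sd <- sd(fit$theta_prob_mean[, "Pr_CORRECTED_1X"])
  raw_sd <- sd(raw$pr[seq_len(40)])
  expect_lt(post_sd, raw_sd)
})

test_that("posterior uncertainty of the group mean shrinks with sample size", {
  sds <- vapply(c(15, 60), function(n) {
    cnt <- simulate_mpt_counts(n, 15, mu_2c(), seed = 4)
    fit <- quick_fit(cnt)
    sd(parameter_draws(fit, "Pr_CORRECTED_1X"))
  }, numeric(1))
  expect_lt(sds[2], sds[1])
})

test_that("credible differences summarize aligned draws correctly", {
  x <- rnorm(1000)
  same <- credible_difference(x, x)
  expect_equal(same$mean, 0)
  expect_false(same$credible)
  shift <- credible_difference(x, x - 1)
  expect_equal(shift$mean, 1)
  expect_true(shift$credible)
  expect_error(credible_difference(x, x[-1]), "equal length")
})

test_that("summary layout exposes estimates, intervals and the repetition effect", {
  cnt <- simulate_mpt_counts(30, 15, mu_2c(pf2 = 0.8), seed = 5)
  fit <- quick_fit(cnt)
  s <- summary(fit)
  expect_true(all(c("Pr_CORRECTED_1X", "Pf_diff_CORRECTED_3X-CORRECTED_1X") %in%
                    s$parameter))
  expect_true(all(s$ci_lo <= s$mean & s$mean <= s$ci_hi))
  co <- coef(fit)
  expect_equal(dim(co), c(2, 2))
  expect_true(all(co > 0 & co < 1))
  # simulate() returns replicate tables with the observed totals
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_equal(sum(reps[[1]][, c("n_real", "n_fake", "n_novel")]),
               sum(cnt[, c("n_real", "n_fake", "n_novel")]))
})

test_that("posterior-predictive checks are calibrated under the null and
           flag injected misfit", {
  # model-generated data: T1 should stay non-extreme in most replicates
  inside <- vapply(1:8, function(s) {
    cnt <- simulate_mpt_counts(30, 15, mu_2c(), seed = 100 + s)
    fit <- fit_mpt(cnt, chains = 1, iter = 600, warmup = 300, seed = s)
    pp <- ppc_fit(fit, n_rep = 200, seed = s)
    pp$t1_ppp >= 0.05 && pp$t1_ppp <= 0.95
  }, logical(1))
  expect_gte(mean(inside), 7 / 8)
  # gross misfit: shifting mass into the novel category breaks the means
  cnt <- simulate_mpt_counts(60, 15, mu_2c(), seed = 200)
  fit <- fit_mpt(cnt, chains = 1, iter = 600, warmup = 300, seed = 1)
  distorted <- lapply(fit$counts_list, function(m) {
    shift <- pmin(m[, "real"], 3L)
    m[, "real"] <- m[, "real"] - shift
    m[, "novel"] <- m[, "novel"] + shift
    m
  })
  fit_bad <- fit
  fit_bad$counts_list <- distorted
  pp_bad <- ppc_fit(fit_bad, n_rep = 200, seed = 2)
  expect_true(pp_bad$t1_ppp < 0.05 || pp_bad$t1_ppp > 0.95)
})

test_that("degenerate covariance data trip the T2 warning path", {
  cnt <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:6), each = 2),
    condition = rep(c("CORRECTED_1X", "CORRECTED_3X"), 6),
    n_real = 10L, n_fake = 3L, n_novel = 2L,
    stringsAsFactors = FALSE
  )
  fit <- fit_mpt(cnt, chains = 1, iter = 200, warmup = 100, seed = 1)
  expect_warning(pp <- ppc_fit(fit, n_rep = 50, seed = 1), "constant across")
  expect_true(pp$t2_ppp >= 0 && pp$t2_ppp <= 1)
})
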