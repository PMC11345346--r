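# The dual-process response tree: category probabilities, closed-form
# inversion, and the multinomial likelihood.

test_that("category probabilities match hand-evaluated tree polynomials", {
  # pure recollection
  expect_equal(unname(mpt_probs(1, 0.3)[1, ]), c(1, 0, 0))
  # familiarity only: equal split between seen details
  expect_equal(unname(mpt_probs(0, 1)[1, ]), c(0.5, 0.5, 0))
  # pure guessing
  expect_equal(unname(mpt_probs(0, 0)[1, ]), rep(1 / 3, 3))
  # interior point, hand evaluation: 17/24, 5/24, 2/24
  expect_equal(unname(mpt_probs(0.5, 0.5)[1, ]), c(17, 5, 2) / 24)
  # sequential-halves guessing reading: 0.5 / 0.25 / 0.25 at no memory
  expect_equal(unname(mpt_probs(0, 0, branching = "sequential")[1, ]),
               c(0.5, 0.25, 0.25))
  expect_error(mpt_probs(1.2, 0.5), "0, 1")
})

test_that("probabilities are normalized and monotone on a dense grid", {
  g <- seq(0, 1, length.out = 101)
  grid <- expand.grid(pr = g, pf = g)
  for (br in c("uniform", "sequential")) {
    p <- mpt_probs(grid$pr, grid$pf, branching = br)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
    expect_true(all(p >= 0))
  }
  # p_real strictly increasing in pr at fixed pf; p_novel decreasing in both
  p_fix <- mpt_probs(g, rep(0.4, 101))
  expect_true(all(diff(p_fix[, "real"]) > 0))
  expect_true(all(diff(p_fix[, "novel"]) < 0))
  p_pf <- mpt_probs(rep(0.4, 101), g)
  expect_true(all(diff(p_pf[, "novel"]) < 0))
})

test_that("moment estimator inverts the tree on the interior grid", {
  g <- seq(0.02, 0.98, length.out = 49)
  grid <- expand.grid(pr = g, pf = g)
  for (br in c("uniform", "sequential")) {
    est <- mpt_moments(mpt_probs(grid$pr, grid$pf, branching = br), branching = br)
    expect_lt(max(abs(est$pr - grid$pr)), 1e-9)
    expect_lt(max(abs(est$pf - grid$pf)), 1e-9)
    expect_false(any(est$boundary))
  }
})

test_that("moment estimator flags boundary and inconsistent data", {
  # pure guessing maps back to the origin
  expect_equal(unlist(mpt_moments(c(1, 1, 1) / 3)[c("pr", "pf")]),
               c(pr = 0, pf = 0))
  # Pr = 1 leaves familiarity unidentified
  est <- mpt_moments(c(1, 0, 0))
  expect_equal(est$pr, 1)
  expect_true(est$boundary)
  # p_fake < p_novel is outside the model interior
  est2 <- mpt_moments(c(0.5, 0.1, 0.4))
  expect_true(est2$boundary)
  expect_error(mpt_moments(c(0.5, 0.4, 0.3)), "sum to 1")
})

test_that("log-likelihood agrees with an independent multinomial pmf", {
  # oracle: stats::dmultinom (the implementation uses its own lgamma form)
  cases <- list(
    list(n = c(5, 3, 2), pr = 0.5, pf = 0.5),
    list(n = c(15, 0, 0), pr = 0.9, pf = 0.2),
    list(n = c(4, 4, 4), pr = 0.1, pf = 0.3)
  )
  for (cs in cases) {
    p <- mpt_probs(cs$pr, cs$pf)[1, ]
    expect_equal(mpt_loglik(cs$n, cs$pr, cs$pf),
                 dmultinom(cs$n, prob = p, log = TRUE))
  }
  # certain datum under pure recollection
  expect_equal(mpt_loglik(c(1, 0, 0), 1, 0.5), 0)
  # impossible datum flags -Inf
  expect_warning(ll <- mpt_loglik(c(0, 0, 1), 1, 0.5), "zero model probability")
  expect_identical(ll, -Inf)
})

test_that("count tabulation and CSV round trip preserve the category counts", {
  trials <- simulate_study(tiny_config(n_per_group = 4), seed = 9)
  cnt <- mpt_counts(trials)
  expect_setequal(unique(cnt$condition), c("CORRECTED_1X", "CORRECTED_3X"))
  expect_true(all(cnt$n_real + cnt$n_fake + cnt$n_novel == 3))
  expect_equal(nrow(cnt), 8 * 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mpt_counts(cnt, path)
  back <- read_mpt_counts(path)
  expect_equal(back$n_real, cnt$n_real)
  bad <- cnt
  bad$n_fake[3] <- -1L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_mpt_counts(path), "rows: 3")
})
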