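# Generative behaviour of the three phase simulators and trial-table IO.

test_that("participant sampling honours the covariance and the seed", {
  p <- flat_params()
  # degenerate covariance: everyone sits at the group mean
  prof <- sample_participants(p, 5, seed = 1)
  theta <- as.matrix(prof[, p$theta_names])
  expect_true(all(apply(theta, 2, sd) == 0))
  expect_equal(unname(pnorm(theta[1, "th_Pr_CORRECTED_1X"])), 0.4)
  # law of large numbers under an identity covariance
  p2 <- gen_params("YOUNGER", sigma = diag(6))
  prof2 <- sample_participants(p2, 10000, seed = 2)
  th2 <- as.matrix(prof2[, p2$theta_names])
  expect_lt(max(abs(colMeans(th2) - as.vector(p2$mu_probit))), 0.05)
  # seed reproducibility
  expect_identical(sample_participants(p2, 50, seed = 7),
                   sample_participants(p2, 50, seed = 7))
  expect_error(gen_params(sigma = matrix(-1, 6, 6)), "positive semi-definite")
  expect_error(sample_participants(p, 0), "at least 1")
})

test_that("repetition raises familiarity ratings only when the shift is positive", {
  cfg <- design_config(n_per_group = 120)
  d <- study_design(cfg, seed = 5)
  mean_by_cycle <- function(shift) {
    p <- flat_params(familiarity_shift_per_exposure = shift)
    prof <- sample_participants(p, 120, seed = 3)
    rows <- simulate_phase1(prof, d, p, seed = 4)
    fam <- rows[rows$phase == "P1_FAMILIARITY" & rows$condition == "CORRECTED_3X", ]
    tapply(fam$rating, fam$presentation_index, mean)
  }
  m0 <- mean_by_cycle(0)
  expect_lt(abs(m0[[2]] - m0[[1]]), 0.12)         # null effect, MC error only
  m1 <- mean_by_cycle(0.5)
  expect_gt(m1[[2]], m1[[1]])                      # repetition effect direction
})

test_that("saturated cutpoints force a single rating category", {
  cfg <- tiny_config()
  d <- study_design(cfg, seed = 1)
  p <- flat_params(rating_thresholds = c(-100, -99, -98, -97, -96))
  prof <- sample_participants(p, 4, seed = 1)
  rows <- simulate_phase1(prof, d, p, seed = 2)
  expect_true(all(rows$rating == 6L))
})

test_that("real news draws higher accuracy ratings than fake news", {
  cfg <- design_config(n_per_group = 60)
  d <- study_design(cfg, seed = 8)
  p <- flat_params()
  prof <- sample_participants(p, 60, seed = 8)
  rows <- simulate_phase1(prof, d, p, seed = 9)
  acc <- rows[rows$phase == "P1_ACCURACY", ]
  shown_fake <- acc$condition %in% c("CORRECTED_1X", "CORRECTED_3X")
  expect_gt(mean(acc$rating[!shown_fake]), mean(acc$rating[shown_fake]))
})

test_that("detection rates follow the closed-form SDT convention", {
  cfg <- design_config(n_per_group = 200)
  d <- study_design(cfg, seed = 11)
  p <- flat_params(detect_dprime = c(CORRECTED_1X = 2, CORRECTED_3X = 2),
                   detect_criterion = 0)
  prof <- sample_participants(p, 200, seed = 12)
  rows <- simulate_phase2(prof, d, p, seed = 13)
  rate <- tapply(rows$detect_yes, rows$condition, mean)
  expect_lt(abs(rate[["CORRECTED_1X"]] - pnorm(1)), 0.02)
  expect_lt(abs(rate[["CORRECTED_3X"]] - pnorm(1)), 0.02)
  expect_lt(abs(rate[["AFFIRMED_REAL"]] - pnorm(-1)), 0.02)
  # d' = 0: no discrimination between corrections and affirmations
  p0 <- flat_params(detect_dprime = c(CORRECTED_1X = 0, CORRECTED_3X = 0),
                    detect_criterion = 0)
  prof0 <- sample_participants(p0, 200, seed = 14)
  r0 <- simulate_phase2(prof0, d, p0, seed = 15)
  rate0 <- tapply(r0$detect_yes, r0$condition, mean)
  expect_lt(max(abs(rate0 - 0.5)), 0.03)
  # extreme conservative criterion: nobody says yes
  pc <- flat_params(detect_criterion = 50)
  profc <- sample_participants(pc, 10, seed = 16)
  rc <- simulate_phase2(profc, d, pc, seed = 17)
  expect_true(all(rc$detect_yes == 0L))
})

test_that("Phase-3 choice frequencies converge to the tree probabilities", {
  # 50,000 correction trials at fixed (Pr, Pf) = (0.4, 0.6)
  cfg <- design_config(n_per_group = 500, items_per_condition = 50,
                       n_fillers = 50)
  d <- study_design(cfg, seed = 21)
  p <- flat_params(pr = 0.4, pf = 0.6)
  prof <- sample_participants(p, 500, seed = 22)
  p2 <- simulate_phase2(prof, d, p, seed = 23)
  p3 <- simulate_phase3(prof, d, p, p2, seed = 24)
  corr <- p3[p3$condition %in% c("CORRECTED_1X", "CORRECTED_3X"), ]
  expect_gte(nrow(corr), 50000)
  freq <- prop.table(table(factor(corr$p3_choice, c("REAL", "FAKE", "NOVEL"))))
  expect_lt(max(abs(freq - mpt_probs(0.4, 0.6)[1, ])), 0.01)
})

test_that("pure-parameter extremes force the expected choices and gating", {
  cfg <- tiny_config(n_per_group = 20)
  d <- study_design(cfg, seed = 31)
  p <- flat_params(pr = 1 - 1e-12, pf = 0.5)
  prof <- sample_participants(p, 20, seed = 32)
  p2 <- simulate_phase2(prof, d, p, seed = 33)
  p3 <- simulate_phase3(prof, d, p, p2, seed = 34)
  corr <- p3$condition %in% c("CORRECTED_1X", "CORRECTED_3X")
  expect_true(all(p3$p3_choice[corr] == "REAL"))
  # gating is exact
  expect_identical(sum(p3$fake_retrieved != "NOT_ASKED"),
                   sum(p3$remember_yes == 1L))
  expect_true(all(p3$fake_retrieved[p3$remember_yes == 0L] == "NOT_ASKED"))
  # missing Phase-2 rows are an error
  expect_error(simulate_phase3(prof, d, p, p2[0, ], seed = 35), "missing Phase-2")
})

test_that("a full cohort is deterministic under the seed and round-trips", {
  cfg <- tiny_config()
  a <- simulate_study(cfg, seed = 77)
  b <- simulate_study(cfg, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  validate_trials(a)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, path2)
  expect_identical(readLines(path), readLines(path2))  # byte-identical output
  back <- read_trials(path)
  expect_equal(back, a[, corrmem:::trial_cols], ignore_attr = TRUE)
})

test_that("schema violations are rejected with row numbers", {
  a <- simulate_study(tiny_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, path)
  x <- read.csv(path, na.strings = "")
  bad_row <- which(!is.na(x$rating))[1]
  x$rating[bad_row] <- 7L
  write.csv(x, path, row.names = FALSE, na = "")
  expect_error(read_trials(path), paste0("rows: ", bad_row))
  # empty table round-trips as a valid header-only file
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_trials(a[0, ], path3)
  empty <- read_trials(path3)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), corrmem:::trial_cols)
})
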