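# Conditionalization, cell weights, belief accuracy and the cluster
# bootstrap.

toy_trials <- function() {
  # one participant, 10 Phase-2-detected correction trials:
  # 6 with the fake detail retrieved (5 of them real-correct),
  # 4 without (1 real-correct)
  choice <- c(rep("REAL", 5), "FAKE", "REAL", rep("FAKE", 3))
  fake_ret <- c(rep("CORRECT_FAKE", 6), rep("OTHER", 4))
  p3 <- data.frame(
    participant_id = "P01", age_group = "YOUNGER",
    topic_id = sprintf("T%02d", 1:10), condition = "CORRECTED_1X",
    phase = "P3_TEST", presentation_index = 1L, rating = NA_integer_,
    detect_yes = NA_integer_, p3_choice = choice,
    p3_accuracy_rating = ifelse(choice == "REAL", 6L, 1L),
    remember_yes = 1L, fake_retrieved = fake_ret,
    stringsAsFactors = FALSE
  )
  p2 <- p3
  p2$phase <- "P2_DETECTION"
  p2$detect_yes <- 1L
  p2$p3_choice <- NA_character_
  p2$p3_accuracy_rating <- NA_integer_
  p2$remember_yes <- NA_integer_
  p2$fake_retrieved <- NA_character_
  rbind(p2, p3)
}

test_that("the toy table reproduces hand-enumerated cells and weights", {
  cells <- conditionalize(toy_trials(), "real_correct", "fake_retrieved")
  ret <- cells[cells$status == "FAKE_RETRIEVED", ]
  not <- cells[cells$status == "FAKE_NOT_RETRIEVED", ]
  expect_equal(ret$prop_pooled, 5 / 6)
  expect_equal(not$prop_pooled, 1 / 4)
  expect_equal(ret$weight, 0.6)
  expect_equal(not$weight, 0.4)
  expect_equal(ret$n_obs, 6L)
  expect_true(not$sparse)   # 4 < default min_n of 5
})

test_that("a constant conditioner collapses to one full-weight cell", {
  tt <- toy_trials()
  tt$fake_retrieved[tt$phase == "P3_TEST"] <- "CORRECT_FAKE"
  cells <- conditionalize(tt, "real_correct", "fake_retrieved")
  expect_equal(nrow(cells), 1)
  expect_equal(cells$weight, 1)
})

test_that("law of total probability holds exactly on random tables", {
  for (s in 1:25) {
    tab <- random_p3_table(n_participants = sample(2:8, 1),
                           trials_per_cond = sample(3:12, 1), seed = s)
    for (tg in c("real_correct", "fake_error")) {
      for (cd in c("fake_retrieved", "correction_remembered")) {
        cells <- conditionalize(tab, tg, cd, min_n = 1)
        p3 <- corrmem:::conditional_frame(tab)
        tgt <- if (tg == "real_correct") p3$p3_choice == "REAL" else
          p3$p3_choice == "FAKE"
        for (cond in unique(cells$condition)) {
          sub <- cells[cells$condition == cond, ]
          marginal <- mean(tgt[p3$condition == cond])
          expect_equal(sum(sub$weight * sub$prop_pooled), marginal)
          expect_equal(sum(sub$weight), 1)
        }
      }
    }
  }
})

test_that("classification tables give per-cell proportions with CIs", {
  trials <- simulate_study(tiny_config(n_per_group = 10), seed = 12)
  ct <- classification_table(trials, "P2_DETECTION", B = 300, seed = 1)
  expect_equal(nrow(ct$participant), 10 * 2 * 3)
  expect_true(all(ct$group$ci_lo <= ct$group$prop + 1e-12))
  # all-yes degenerates to proportion 1 everywhere
  allyes <- trials
  allyes$detect_yes[allyes$phase == "P2_DETECTION"] <- 1L
  ct2 <- classification_table(allyes, "P2_DETECTION", B = 300, seed = 1)
  expect_true(all(ct2$participant$prop == 1))
})

test_that("overall retrieval respects the gating bound on correct-fake", {
  trials <- simulate_study(tiny_config(n_per_group = 10), seed = 13)
  ov <- overall_retrieval(trials)
  p3 <- trials[trials$phase == "P3_TEST", ]
  for (i in which(ov$measure == "correct_fake_after_remembering")) {
    sel <- p3$age_group == ov$age_group[i] & p3$condition == ov$condition[i]
    expect_lte(ov$prop_pooled[i] * sum(sel), sum(p3$remember_yes[sel] == 1L))
  }
  # degenerate: all choices REAL
  forced <- trials
  forced$p3_choice[forced$phase == "P3_TEST"] <- "REAL"
  ov2 <- overall_retrieval(forced)
  expect_true(all(ov2$prop[ov2$measure == "correct_real"] == 1))
  expect_true(all(ov2$prop[ov2$measure == "erroneous_fake"] == 0))
})

test_that("belief accuracy is the exact rating difference and hits extremes", {
  tt <- toy_trials()
  ba <- belief_accuracy(tt, strata = "overall")
  expect_equal(ba$belief_accuracy, 5)   # ratings 6 vs 1 by construction
  tt$p3_accuracy_rating[tt$phase == "P3_TEST"] <- 4L
  ba0 <- belief_accuracy(tt, strata = "overall")
  expect_equal(ba0$belief_accuracy, 0)
  expect_equal(ba0$mean_rating_correct_real - ba0$mean_rating_erroneous_fake,
               ba0$belief_accuracy)
})

test_that("recollection-linked belief shifts surface in the conditional strata", {
  cfg <- design_config(n_per_group = 60)
  trials <- simulate_study(cfg, seed = 14)
  # retrieving the fake detail marks mostly recollection-generated trials, so
  # ratings of correctly retrieved real news are higher in that stratum
  # (the erroneous-fake side is structurally empty there: a trial whose fake
  # detail was identified cannot also have chosen the fake as real)
  ba <- suppressWarnings(belief_accuracy(trials, strata = "fake_retrieved"))
  wide <- reshape(ba[, c("age_group", "condition", "status",
                         "mean_rating_correct_real")],
                  direction = "wide", idvar = c("age_group", "condition"),
                  timevar = "status")
  expect_true(all(wide[["mean_rating_correct_real.FAKE_RETRIEVED"]] >
                    wide[["mean_rating_correct_real.FAKE_NOT_RETRIEVED"]]))
  # and overall belief accuracy is positive in every cell
  ov <- belief_accuracy(trials, strata = "overall")
  expect_true(all(ov$belief_accuracy > 0))
})

test_that("cluster bootstrap is deterministic, degenerate-safe and shrinks", {
  x <- rnorm(40)
  ci1 <- cluster_bootstrap_ci(x, B = 500, seed = 9)
  ci2 <- cluster_bootstrap_ci(x, B = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_warning(ci0 <- cluster_bootstrap_ci(rep(2, 10), B = 200), "degenerate")
  expect_equal(ci0, c(2, 2))
  set.seed(11)
  widths <- vapply(c(25, 100, 400), function(n) {
    ci <- cluster_bootstrap_ci(rnorm(n), B = 2000)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  ratio <- widths[1] / widths[3]
  expect_gt(ratio, 2)      # ~ sqrt(16) = 4 expected, loose band
  expect_lt(ratio, 8)
  expect_error(cluster_bootstrap_ci(1), "2 participants")
  expect_error(cluster_bootstrap_ci(rnorm(10), B = 50), "at least 100")
})
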