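# Shared fixtures, built in code at test time.

# a small but structurally complete design
tiny_config <- function(n_per_group = 8, items = 3) {
  design_config(n_per_group = n_per_group, items_per_condition = items,
                n_fillers = items)
}

# deterministic-participant parameters: no heterogeneity anywhere
flat_params <- function(age_group = "YOUNGER", pr = 0.4, pf = 0.6, ...) {
  mu <- rbind(Pr = rep(pr, 3), Pf = rep(pf, 3))
  colnames(mu) <- c("AFFIRMED_REAL", "CORRECTED_1X", "CORRECTED_3X")
  gen_params(age_group, mu_prob = mu, sigma = matrix(0, 6, 6),
             sd_dprime = 0, sd_criterion = 0, rating_intercept_sd = 0, ...)
}

# random trial tables (Phase 2 + Phase 3 only) for conditionalization
# property tests; respects the gating invariant by construction
random_p3_table <- function(n_participants, trials_per_cond, seed) {
  set.seed(seed)
  conds <- c("CORRECTED_1X", "CORRECTED_3X")
  rows <- expand.grid(
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    condition = conds,
    trial = seq_len(trials_per_cond),
    stringsAsFactors = FALSE
  )
  n <- nrow(rows)
  topic <- paste0(rows$condition, "_t", rows$trial)
  remember <- rbinom(n, 1, runif(1, 0.3, 0.9))
  p3 <- data.frame(
    participant_id = rows$participant_id, age_group = "YOUNGER",
    topic_id = topic, condition = rows$condition, phase = "P3_TEST",
    presentation_index = 1L, rating = NA_integer_, detect_yes = NA_integer_,
    p3_choice = sample(c("REAL", "FAKE", "NOVEL"), n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    p3_accuracy_rating = sample.int(6, n, replace = TRUE),
    remember_yes = remember,
    fake_retrieved = ifelse(remember == 1L,
                            sample(c("CORRECT_FAKE", "OTHER"), n, replace = TRUE),
                            "NOT_ASKED"),
    stringsAsFactors = FALSE
  )
  p2 <- p3
  p2$phase <- "P2_DETECTION"
  p2$detect_yes <- rbinom(n, 1, 0.8)
  p2$p3_choice <- NA_character_
  p2$p3_accuracy_rating <- NA_integer_
  p2$remember_yes <- NA_integer_
  p2$fake_retrieved <- NA_character_
  rbind(p2, p3)
}

# fast MCMC settings for structural (non-recovery) fit tests
quick_fit <- function(counts, ...) {
  fit_mpt(counts, chains = 2, iter = 400, warmup = 200, seed = 42, ...)
}
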