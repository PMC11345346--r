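# Phase-level simulators. All three emit rows of the common trial table;
# simulate_study() chains them for a full two-group cohort.

trial_cols <- c("participant_id", "age_group", "topic_id", "condition", "phase",
                "presentation_index", "rating", "detect_yes", "p3_choice",
                "p3_accuracy_rating", "remember_yes", "fake_retrieved")

# internal: empty trial-table skeleton with the fixed column set
trial_skeleton <- function(n) {
  data.frame(
    participant_id = character(n), age_group = character(n),
    topic_id = character(n), condition = character(n), phase = character(n),
    presentation_index = integer(n), rating = NA_integer_,
    detect_yes = NA_integer_, p3_choice = NA_character_,
    p3_accuracy_rating = NA_integer_, remember_yes = NA_integer_,
    fake_retrieved = NA_character_, stringsAsFactors = FALSE
  )
}

# internal: cumulative-probit rating from latent means (unit normal noise)
draw_rating <- function(latent_mean, thresholds) {
  z <- latent_mean + stats::rnorm(length(latent_mean))
  findInterval(z, thresholds) + 1L
}

#' Simulate Phase 1: familiarity and accuracy ratings
#'
#' Block A rows carry familiarity ratings for each presentation of the
#' thrice-presented fake news and the real fillers; the latent rating mean
#' grows by `familiarity_shift_per_exposure` per prior presentation. Block B
#' rows carry accuracy ratings; fake-news latent accuracy grows by
#' `illusory_truth_shift` per prior exposure (the illusory truth effect) and
#' real news has a higher latent mean than fake news.
#'
#' @param profiles participant profiles from [sample_participants()].
#' @param design a [study_design()]; must offer every `format_id` present in
#'   `profiles`.
#' @param params the [gen_params()] used to draw `profiles`.
#' @param seed integer seed.
#' @return Trial-table rows with phases `P1_FAMILIARITY` and `P1_ACCURACY`.
#' @export
simulate_phase1 <- function(profiles, design, params, seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(params, "gen_params"))
  if (!is.null(seed)) set.seed(seed)
  th <- params$rating_thresholds
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    prof <- profiles[i, ]
    sched <- design$schedule[[prof$format_id]]
    p1 <- sched[sched$phase %in% c("P1_FAMILIARITY", "P1_ACCURACY"), ]
    lat <- numeric(nrow(p1))
    fam <- p1$phase == "P1_FAMILIARITY"
    lat[fam] <- params$fam_base +
      params$familiarity_shift_per_exposure * (p1$presentation_index[fam] - 1L)
    acc <- !fam
    is_fake <- acc & p1$shown == "FAKE"
    lat[acc & !is_fake] <- params$acc_base_real
    lat[is_fake] <- params$acc_base_fake +
      params$illusory_truth_shift * (p1$presentation_index[is_fake] - 1L)
    rows <- trial_skeleton(nrow(p1))
    rows$participant_id <- prof$participant_id
    rows$age_group <- prof$age_group
    rows$topic_id <- p1$topic_id
    rows$condition <- p1$condition
    rows$phase <- p1$phase
    rows$presentation_index <- p1$presentation_index
    rows$rating <- draw_rating(lat + prof$rating_intercept, th)
    rows
  })
  do.call(rbind, out)
}

#' Simulate Phase 2: correction detection
#'
#' Detection follows the equal-variance Gaussian signal-detection convention:
#' a correction trial in condition `c` elicits "yes" with probability
#' `pnorm(d_c / 2 - crit)`, an affirmed-real trial with probability
#' `pnorm(-dbar / 2 - crit)` where `dbar` averages the participant's
#' condition sensitivities (with equal sensitivities across conditions this
#' is exactly the convention inverted by [sdt_estimate()]).
#'
#' @inheritParams simulate_phase1
#' @return Trial-table rows with phase `P2_DETECTION` and `detect_yes` set.
#' @export
simulate_phase2 <- function(profiles, design, params, seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(params, "gen_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    prof <- profiles[i, ]
    sched <- design$schedule[[prof$format_id]]
    p2 <- sched[sched$phase == "P2_DETECTION", ]
    d1 <- prof$detect_d_CORRECTED_1X
    d3 <- prof$detect_d_CORRECTED_3X
    crit <- prof$detect_c
    p_yes <- ifelse(
      p2$condition == "CORRECTED_1X", stats::pnorm(d1 / 2 - crit),
      ifelse(p2$condition == "CORRECTED_3X", stats::pnorm(d3 / 2 - crit),
             stats::pnorm(-(d1 + d3) / 4 - crit))
    )
    rows <- trial_skeleton(nrow(p2))
    rows$participant_id <- prof$participant_id
    rows$age_group <- prof$age_group
    rows$topic_id <- p2$topic_id
    rows$condition <- p2$condition
    rows$phase <- "P2_DETECTION"
    rows$presentation_index <- 1L
    rows$detect_yes <- as.integer(stats::runif(nrow(p2)) < p_yes)
    rows
  })
  do.call(rbind, out)
}

#' Simulate Phase 3: retrieval, remembering corrections, and beliefs
#'
#' The test choice (real / fake / novel) is sampled from the dual-process
#' tree ([mpt_probs()]) at the participant's condition-specific parameters.
#' The correction-remembering question follows the signal-detection process
#' with an extra latent boost on recollection-generated trials; the
#' fake-identification question is asked only after a "yes" (otherwise
#' `fake_retrieved = "NOT_ASKED"`), and its success probability depends on
#' the generating branch. Belief ratings come from the cumulative-probit
#' rating process with a latent shift for real-news choices and a further
#' shift on recollected trials.
#'
#' @inheritParams simulate_phase1
#' @param phase2 Phase-2 rows for the same cohort; every correction-condition
#'   test trial must have a matching detection row.
#' @return Trial-table rows with phase `P3_TEST`.
#' @export
simulate_phase3 <- function(profiles, design, params, phase2, seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(params, "gen_params"))
  if (!is.null(seed)) set.seed(seed)
  th <- params$rating_thresholds
  p2key <- paste(phase2$participant_id, phase2$topic_id)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    prof <- profiles[i, ]
    sched <- design$schedule[[prof$format_id]]
    p3 <- sched[sched$phase == "P3_TEST", ]
    n <- nrow(p3)
    corrected <- p3$condition %in% c("CORRECTED_1X", "CORRECTED_3X")
    missing_p2 <- corrected &
      !(paste(prof$participant_id, p3$topic_id) %in% p2key)
    if (any(missing_p2)) {
      stop("missing Phase-2 detection rows for correction trials of participant ",
           prof$participant_id, call. = FALSE)
    }
    pr <- stats::pnorm(unlist(prof[paste0("th_Pr_", p3$condition)], use.names = FALSE))
    pf <- stats::pnorm(unlist(prof[paste0("th_Pf_", p3$condition)], use.names = FALSE))
    u <- stats::runif(n)
    recollected <- u < pr
    familiar <- !recollected & (stats::runif(n) < pf)
    branch <- ifelse(recollected, "recollect", ifelse(familiar, "familiar", "guess"))
    choice <- character(n)
    choice[recollected] <- "REAL"
    nf <- sum(familiar)
    if (nf) choice[familiar] <- sample(c("REAL", "FAKE"), nf, replace = TRUE)
    ng <- sum(branch == "guess")
    if (ng) {
      choice[branch == "guess"] <- if (params$branching == "uniform") {
        sample(c("REAL", "FAKE", "NOVEL"), ng, replace = TRUE)
      } else {
        sample(c("REAL", "FAKE", "NOVEL"), ng, replace = TRUE,
               prob = c(0.5, 0.25, 0.25))
      }
    }
    d1 <- prof$remember_d_CORRECTED_1X
    d3 <- prof$remember_d_CORRECTED_3X
    crit <- prof$remember_c
    evid <- ifelse(
      p3$condition == "CORRECTED_1X", d1 / 2 - crit,
      ifelse(p3$condition == "CORRECTED_3X", d3 / 2 - crit,
             -(d1 + d3) / 4 - crit)
    )
    evid <- evid + params$remember_boost_recollected * (recollected & corrected)
    # familiarity without recollection suppresses correction attribution:
    # a chosen fake detail lowers the remember evidence per prior exposure
    n_expo <- ifelse(p3$condition == "CORRECTED_3X", 3L,
                     ifelse(p3$condition == "CORRECTED_1X", 1L, 0L))
    evid <- evid - params$remember_suppression_fake * n_expo * (choice == "FAKE")
    remember <- as.integer(stats::runif(n) < stats::pnorm(evid))
    # gated fake-identification question
    fake_ret <- rep("NOT_ASKED", n)
    asked <- remember == 1L
    if (any(asked)) {
      # in the affirmed condition no fake detail was studied, so identifying
      # the would-have-been fake is knowledge/guessing regardless of branch
      p_id <- ifelse(corrected[asked], params$p_fake_id[branch[asked]],
                     params$p_fake_id[["guess"]])
      hit <- stats::runif(sum(asked)) < p_id
      fake_ret[asked] <- ifelse(choice[asked] == "FAKE", "OTHER",
                                ifelse(hit, "CORRECT_FAKE", "OTHER"))
    }
    lat <- params$belief_base_real * (choice == "REAL") +
      params$belief_shift_recollected * recollected + prof$rating_intercept
    rows <- trial_skeleton(n)
    rows$participant_id <- prof$participant_id
    rows$age_group <- prof$age_group
    rows$topic_id <- p3$topic_id
    rows$condition <- p3$condition
    rows$phase <- "P3_TEST"
    rows$presentation_index <- 1L
    rows$p3_choice <- choice
    rows$p3_accuracy_rating <- draw_rating(lat, th)
    rows$remember_yes <- remember
    rows$fake_retrieved <- fake_ret
    rows
  })
  do.call(rbind, out)
}

#' Simulate a complete two-group cohort of the correction paradigm
#'
#' Convenience wrapper: builds the counterbalanced design, samples younger
#' and older participant profiles, and runs all three phases. The generating
#' parameters and profiles are attached as attributes `"params"` and
#' `"profiles"` so recovery analyses can compare estimates against ground
#' truth.
#'
#' @param config a [design_config()].
#' @param params_younger,params_older [gen_params()] for the two groups.
#' @param seed integer seed governing design, profiles and all phases.
#' @return A trial table (data frame) spanning the three phases for both
#'   groups, ordered by participant, phase, topic.
#' @examples
#' trials <- simulate_study(design_config(n_per_group = 6), seed = 1)
#' table(trials$phase)
#' @export
simulate_study <- function(config = design_config(),
                           params_younger = gen_params("YOUNGER"),
                           params_older = gen_params("OLDER"),
                           seed = 1) {
  set.seed(seed)
  design <- study_design(config)
  groups <- list(
    list(params = params_younger, prefix = "Y"),
    list(params = params_older, prefix = "O")
  )
  all_rows <- lapply(groups, function(g) {
    prof <- sample_participants(g$params, config$n_per_group,
                                n_formats = config$n_formats,
                                id_prefix = g$prefix)
    p1 <- simulate_phase1(prof, design, g$params)
    p2 <- simulate_phase2(prof, design, g$params)
    p3 <- simulate_phase3(prof, design, g$params, p2)
    list(profiles = prof, rows = rbind(p1, p2, p3))
  })
  trials <- do.call(rbind, lapply(all_rows, `[[`, "rows"))
  rownames(trials) <- NULL
  attr(trials, "params") <- list(YOUNGER = params_younger, OLDER = params_older)
  attr(trials, "profiles") <- do.call(rbind, lapply(all_rows, `[[`, "profiles"))
  attr(trials, "design") <- design
  trials
}

#' Validate a trial table
#'
#' Checks the structural invariants of the trial-table schema: the fixed
#' column set, rating and binary ranges, the categorical levels, the exact
#' gating of the fake-identification question on `remember_yes`, and that no
#' participant sees a topic twice in the Phase-3 test. Violations are
#' reported with their row numbers.
#'
#' @param trials a data frame.
#' @return `trials`, invisibly, if valid; otherwise an error.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(trial_cols, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad_rows <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      stop(what, " at rows: ", paste(utils::head(which(idx), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_rows(!is.na(trials$rating) & !(trials$rating %in% 1:6),
           "rating outside 1-6")
  bad_rows(!is.na(trials$p3_accuracy_rating) & !(trials$p3_accuracy_rating %in% 1:6),
           "p3_accuracy_rating outside 1-6")
  bad_rows(!is.na(trials$detect_yes) & !(trials$detect_yes %in% 0:1),
           "detect_yes not 0/1")
  bad_rows(!is.na(trials$remember_yes) & !(trials$remember_yes %in% 0:1),
           "remember_yes not 0/1")
  bad_rows(!is.na(trials$p3_choice) & !(trials$p3_choice %in% c("REAL", "FAKE", "NOVEL")),
           "unknown p3_choice")
  bad_rows(!is.na(trials$fake_retrieved) &
             !(trials$fake_retrieved %in% c("CORRECT_FAKE", "OTHER", "NOT_ASKED")),
           "unknown fake_retrieved")
  p3 <- trials$phase == "P3_TEST"
  bad_rows(p3 & !is.na(trials$remember_yes) & trials$remember_yes == 0L &
             trials$fake_retrieved != "NOT_ASKED",
           "fake_retrieved recorded without remember_yes = 1")
  bad_rows(p3 & !is.na(trials$remember_yes) & trials$remember_yes == 1L &
             trials$fake_retrieved == "NOT_ASKED",
           "fake question skipped despite remember_yes = 1")
  key <- paste(trials$participant_id, trials$topic_id)[p3]
  if (anyDuplicated(key)) {
    dup <- which(p3)[duplicated(key)]
    stop("duplicate Phase-3 test trials at rows: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  invisible(trials)
}

#' Write / read a trial table as tidy CSV
#'
#' The on-disk format is a UTF-8 CSV with a header row and the documented
#' column order; the round trip is lossless. Reading validates the schema and
#' reports offending row numbers.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials()` returns the validated trial table.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, trial_cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       colClasses = c(
                         participant_id = "character", age_group = "character",
                         topic_id = "character", condition = "character",
                         phase = "character", presentation_index = "integer",
                         rating = "integer", detect_yes = "integer",
                         p3_choice = "character", p3_accuracy_rating = "integer",
                         remember_yes = "integer", fake_retrieved = "character"
                       ))
  validate_trials(x)
  x
}
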