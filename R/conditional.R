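# Descriptive and conditional analysis chain: classification tables, overall
# retrieval proportions, conditionalized accuracy with cell weights, and
# belief-accuracy summaries. Proportions are computed per participant then
# averaged (default) and trial-pooled; both aggregations are reported because
# group plots can be read either way.

# internal: mean of per-participant means and pooled proportion for a 0/1
# vector grouped by participant id
two_way_prop <- function(x, id) {
  per <- tapply(x, id, mean)
  c(participant = mean(per), pooled = mean(x))
}

#' Per-participant "yes" proportions for correction classifications
#'
#' Tabulates the proportion of "yes" responses to the correction question:
#' Phase-2 detection (`detect_yes`) or the Phase-3 remembering question
#' (`remember_yes`). "Yes" responses are hits in the correction conditions
#' and false alarms in the affirmed-real condition.
#'
#' @param trials a trial table.
#' @param phase `"P2_DETECTION"` or `"P3_TEST"`.
#' @param B bootstrap resamples for the group CIs.
#' @param seed integer seed for the bootstrap.
#' @return A list with `participant` (one row per participant x condition:
#'   `prop`, `n_trials`) and `group` (per age group x condition: participant-
#'   mean and pooled proportions with cluster-bootstrap 95% CIs).
#' @export
classification_table <- function(trials, phase = c("P2_DETECTION", "P3_TEST"),
                                 B = 2000, seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  rows <- trials[trials$phase == phase, ]
  yes <- if (phase == "P2_DETECTION") rows$detect_yes else rows$remember_yes
  keep <- !is.na(yes)
  rows <- rows[keep, ]
  yes <- yes[keep]
  if (!nrow(rows)) stop("no classified trials in phase ", phase, call. = FALSE)
  key <- paste(rows$participant_id, rows$condition, sep = "\x1f")
  prop <- tapply(yes, key, mean)
  ntr <- tapply(yes, key, length)
  ids <- do.call(rbind, strsplit(names(prop), "\x1f", fixed = TRUE))
  participant <- data.frame(
    participant_id = ids[, 1],
    age_group = rows$age_group[match(ids[, 1], rows$participant_id)],
    condition = ids[, 2],
    prop = as.numeric(prop), n_trials = as.integer(ntr),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cells <- unique(participant[, c("age_group", "condition")])
  group <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- participant[participant$age_group == cells$age_group[i] &
                         participant$condition == cells$condition[i], ]
    pooled_rows <- rows$age_group == cells$age_group[i] &
      rows$condition == cells$condition[i]
    ci <- cluster_bootstrap_ci(sub$prop, B = B)
    data.frame(
      age_group = cells$age_group[i], condition = cells$condition[i],
      n_participants = nrow(sub),
      prop = mean(sub$prop), ci_lo = ci[1], ci_hi = ci[2],
      prop_pooled = mean(yes[pooled_rows]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(group) <- NULL
  list(participant = participant, group = group)
}

#' Overall Phase-3 retrieval proportions
#'
#' The three headline retrieval measures per age group x condition: correct
#' retrieval of real news (test choice = real), erroneous retrieval of fake
#' news (test choice = fake), and correct retrieval of the fake detail after
#' remembering a correction (trials with `remember_yes = 1` and
#' `fake_retrieved = "CORRECT_FAKE"`, as a proportion of all test trials in
#' the cell).
#'
#' @param trials a trial table.
#' @return A long data frame: `age_group`, `condition`, `measure`,
#'   `prop` (participant-mean), `prop_pooled`, `n_trials`.
#' @export
overall_retrieval <- function(trials) {
  p3 <- trials[trials$phase == "P3_TEST", ]
  if (!nrow(p3)) stop("no Phase-3 rows", call. = FALSE)
  measures <- list(
    correct_real = p3$p3_choice == "REAL",
    erroneous_fake = p3$p3_choice == "FAKE",
    correct_fake_after_remembering =
      p3$remember_yes == 1L & p3$fake_retrieved == "CORRECT_FAKE"
  )
  cells <- unique(p3[, c("age_group", "condition")])
  cells <- cells[order(cells$age_group, cells$condition), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- p3$age_group == cells$age_group[i] & p3$condition == cells$condition[i]
    do.call(rbind, lapply(names(measures), function(m) {
      x <- as.integer(measures[[m]][sel])
      tw <- two_way_prop(x, p3$participant_id[sel])
      data.frame(age_group = cells$age_group[i], condition = cells$condition[i],
                 measure = m, prop = unname(tw["participant"]),
                 prop_pooled = unname(tw["pooled"]), n_trials = sum(sel),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# internal: restrict Phase-3 correction trials to those whose correction was
# detected in Phase 2 and attach the target / conditioning variables
conditional_frame <- function(trials, gate_detected = TRUE) {
  p3 <- trials[trials$phase == "P3_TEST" &
                 trials$condition %in% c("CORRECTED_1X", "CORRECTED_3X"), ]
  if (!nrow(p3)) stop("no correction-condition Phase-3 rows", call. = FALSE)
  if (gate_detected) {
    p2 <- trials[trials$phase == "P2_DETECTION", ]
    det <- p2$detect_yes[match(paste(p3$participant_id, p3$topic_id),
                               paste(p2$participant_id, p2$topic_id))]
    if (anyNA(det)) stop("Phase-2 detection rows missing for some test trials",
                         call. = FALSE)
    p3 <- p3[det == 1L, ]
  }
  p3
}

#' Conditionalized retrieval proportions with cell weights
#'
#' Computes a Phase-3 retrieval measure within strata defined by another
#' Phase-3 response, restricted (by default) to correction trials whose
#' correction was detected in Phase 2. Two analyses are supported:
#'
#' * `target = "real_correct"`, `conditioner = "fake_retrieved"`: correct
#'   real-news retrieval conditional on whether the fake detail was also
#'   retrieved (remembered correction with `fake_retrieved = CORRECT_FAKE`
#'   vs. everything else).
#' * `target = "fake_error"`, `conditioner = "correction_remembered"`:
#'   erroneous fake-news retrieval conditional on remembering the correction.
#'
#' Each cell carries its observation count and its weight (share of the
#' gated observations within age group x condition), so the law of total
#' probability `sum(weight * pooled proportion) = marginal pooled proportion`
#' holds exactly. Cells with fewer than `min_n` observations are flagged
#' sparse, not dropped.
#'
#' @param trials a trial table.
#' @param target `"real_correct"` or `"fake_error"`.
#' @param conditioner `"fake_retrieved"` or `"correction_remembered"`.
#' @param gate_detected restrict to Phase-2-detected corrections (default).
#' @param min_n sparse-cell threshold.
#' @return A data frame of conditional cells: `age_group`, `condition`,
#'   `status`, `prop` (participant-mean), `prop_pooled`, `n_obs`, `weight`,
#'   `sparse`.
#' @export
conditionalize <- function(trials,
                           target = c("real_correct", "fake_error"),
                           conditioner = c("fake_retrieved", "correction_remembered"),
                           gate_detected = TRUE,
                           min_n = 5) {
  target <- match.arg(target)
  conditioner <- match.arg(conditioner)
  p3 <- conditional_frame(trials, gate_detected)
  tgt <- switch(target,
    real_correct = as.integer(p3$p3_choice == "REAL"),
    fake_error = as.integer(p3$p3_choice == "FAKE")
  )
  status <- switch(conditioner,
    fake_retrieved = ifelse(
      p3$remember_yes == 1L & p3$fake_retrieved == "CORRECT_FAKE",
      "FAKE_RETRIEVED", "FAKE_NOT_RETRIEVED"),
    correction_remembered = ifelse(p3$remember_yes == 1L,
                                   "CORRECTION_REMEMBERED",
                                   "CORRECTION_NOT_REMEMBERED")
  )
  cells <- unique(data.frame(age_group = p3$age_group, condition = p3$condition,
                             status = status, stringsAsFactors = FALSE))
  cells <- cells[order(cells$age_group, cells$condition, cells$status), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    in_margin <- p3$age_group == cells$age_group[i] &
      p3$condition == cells$condition[i]
    sel <- in_margin & status == cells$status[i]
    per <- tapply(tgt[sel], p3$participant_id[sel], mean)
    data.frame(
      age_group = cells$age_group[i], condition = cells$condition[i],
      status = cells$status[i],
      prop = mean(per), prop_pooled = mean(tgt[sel]),
      n_obs = sum(sel), weight = sum(sel) / sum(in_margin),
      sparse = sum(sel) < min_n,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Belief accuracy of retrieved details
#'
#' Belief accuracy is the difference between the mean Phase-3 accuracy
#' rating for correctly retrieved real news and the mean rating for
#' erroneously retrieved fake news; larger values mean retrieved real
#' details were believed more than retrieved fake details. Reported overall
#' and within conditional strata (fake detail retrieved / correction
#' remembered), per age group x condition, on Phase-2-detected correction
#' trials.
#'
#' @param trials a trial table.
#' @param strata any of `"overall"`, `"fake_retrieved"`,
#'   `"correction_remembered"`.
#' @param gate_detected restrict to Phase-2-detected corrections.
#' @return A data frame: `age_group`, `condition`, `stratum`, `status`,
#'   `mean_rating_correct_real`, `mean_rating_erroneous_fake`,
#'   `belief_accuracy`, and the two cell sizes. Empty cells yield `NA` with
#'   a warning.
#' @export
belief_accuracy <- function(trials,
                            strata = c("overall", "fake_retrieved",
                                       "correction_remembered"),
                            gate_detected = TRUE) {
  strata <- match.arg(strata, several.ok = TRUE)
  p3 <- conditional_frame(trials, gate_detected)
  stat_frames <- list()
  for (st in strata) {
    status <- switch(st,
      overall = rep("ALL", nrow(p3)),
      fake_retrieved = ifelse(
        p3$remember_yes == 1L & p3$fake_retrieved == "CORRECT_FAKE",
        "FAKE_RETRIEVED", "FAKE_NOT_RETRIEVED"),
      correction_remembered = ifelse(p3$remember_yes == 1L,
                                     "CORRECTION_REMEMBERED",
                                     "CORRECTION_NOT_REMEMBERED")
    )
    cells <- unique(data.frame(age_group = p3$age_group,
                               condition = p3$condition,
                               status = status, stringsAsFactors = FALSE))
    cells <- cells[order(cells$age_group, cells$condition, cells$status), ]
    stat_frames[[st]] <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- p3$age_group == cells$age_group[i] &
        p3$condition == cells$condition[i] & status == cells$status[i]
      real_sel <- sel & p3$p3_choice == "REAL"
      fake_sel <- sel & p3$p3_choice == "FAKE"
      if (!any(real_sel) || !any(fake_sel)) {
        warning("empty belief-accuracy stratum: ",
                paste(cells[i, ], collapse = " / "), call. = FALSE)
      }
      m_real <- if (any(real_sel)) mean(p3$p3_accuracy_rating[real_sel]) else NA_real_
      m_fake <- if (any(fake_sel)) mean(p3$p3_accuracy_rating[fake_sel]) else NA_real_
      data.frame(
        age_group = cells$age_group[i], condition = cells$condition[i],
        stratum = st, status = cells$status[i],
        mean_rating_correct_real = m_real,
        mean_rating_erroneous_fake = m_fake,
        belief_accuracy = m_real - m_fake,
        n_correct_real = sum(real_sel), n_erroneous_fake = sum(fake_sel),
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- do.call(rbind, stat_frames)
  rownames(out) <- NULL
  out
}

#' Percentile cluster-bootstrap confidence interval
#'
#' Resamples participants (the per-participant statistics) with replacement
#' and returns a percentile interval for the mean. Deterministic for a fixed
#' seed; a degenerate (constant) statistic yields a zero-width interval with
#' a warning.
#'
#' @param x per-participant statistics.
#' @param B number of resamples (>= 100).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
cluster_bootstrap_ci <- function(x, B = 2000, level = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("at least 2 participants are required", call. = FALSE)
  if (B < 100) stop("`B` must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (stats::sd(x) == 0) {
    warning("degenerate statistic: zero-width interval", call. = FALSE)
    return(c(x[1], x[1]))
  }
  n <- length(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  means <- rowMeans(matrix(x[idx], nrow = B))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
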