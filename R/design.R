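#' Configuration of the three-phase correction paradigm
#'
#' Captures the design constants of the paradigm: a set of critical headline
#' topics rotated through three headline-type conditions across experimental
#' formats, real-news filler items used in Phase 1 Block A, and the Phase-3
#' test mode.
#'
#' The three conditions are `AFFIRMED_REAL` (real news in Phase 1, repeated in
#' Phase 2), `CORRECTED_1X` (fake news once in Phase 1, corrected in Phase 2)
#' and `CORRECTED_3X` (fake news three times in Phase 1, corrected in
#' Phase 2).
#'
#' @param n_per_group participants per age group.
#' @param items_per_condition critical topics per condition within a format.
#' @param n_formats number of counterbalancing formats; the number of critical
#'   topics is `items_per_condition * 3` and each topic must visit every
#'   condition exactly once across formats, so `n_formats` must equal the
#'   number of conditions (3) or a multiple of it.
#' @param n_fillers real-news filler items interleaved with the repeated fake
#'   news in Phase 1 Block A; defaults to `items_per_condition` so Block A is
#'   balanced (and the run-length constraint stays satisfiable).
#' @param test_mode Phase-3 test, `"RECOGNITION_3AFC"` or `"CUED_RECALL"`.
#'   Cued-recall responses are emitted pre-scored into the same three
#'   categories (other errors and omissions pool into `NOVEL`).
#' @param max_run_length maximum number of consecutive same-condition items in
#'   any presentation schedule.
#' @param retention_hours nominal Phase 2 to Phase 3 retention interval;
#'   metadata only, not modelled.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_per_group = 102,
                          items_per_condition = 15,
                          n_formats = 3,
                          n_fillers = items_per_condition,
                          test_mode = c("RECOGNITION_3AFC", "CUED_RECALL"),
                          max_run_length = 3,
                          retention_hours = 48) {
  test_mode <- match.arg(test_mode)
  conditions <- c("AFFIRMED_REAL", "CORRECTED_1X", "CORRECTED_3X")
  if (n_per_group < 1 || items_per_condition < 1) {
    stop("`n_per_group` and `items_per_condition` must be positive", call. = FALSE)
  }
  if (n_formats %% length(conditions) != 0) {
    stop("`n_formats` must be a multiple of the number of conditions (3) so that ",
         "every topic appears in every condition equally often across formats",
         call. = FALSE)
  }
  if (max_run_length < 1) stop("`max_run_length` must be at least 1", call. = FALSE)
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_critical_topics = as.integer(items_per_condition * length(conditions)),
      items_per_condition = as.integer(items_per_condition),
      n_formats = as.integer(n_formats),
      n_fillers = as.integer(n_fillers),
      conditions = conditions,
      test_mode = test_mode,
      max_run_length = as.integer(max_run_length),
      retention_hours = retention_hours
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("Three-phase correction paradigm design\n")
  cat(sprintf("  %d critical topics (%d per condition), %d fillers, %d formats\n",
              x$n_critical_topics, x$items_per_condition, x$n_fillers, x$n_formats))
  cat(sprintf("  test mode: %s; max same-condition run: %d; retention: %s h\n",
              x$test_mode, x$max_run_length, format(x$retention_hours)))
  invisible(x)
}

# internal: shuffle `labels` (a character vector) so that no more than
# max_run identical labels are consecutive. Rejection sampling with a
# greedy fallback; with balanced condition sets a random shuffle succeeds
# almost immediately.
shuffle_max_run <- function(labels, max_run, max_tries = 200L) {
  n <- length(labels)
  if (n <= max_run) return(sample(labels))
  ok <- function(x) {
    r <- rle(x)
    all(r$lengths <= max_run)
  }
  for (i in seq_len(max_tries)) {
    cand <- sample(labels)
    if (ok(cand)) return(cand)
  }
  # greedy: repeatedly place the most frequent label allowed at this slot
  pool <- sort(labels)
  out <- character(n)
  run <- 0L
  last <- ""
  for (i in seq_len(n)) {
    tab <- sort(table(pool), decreasing = TRUE)
    cand <- names(tab)
    if (run >= max_run) cand <- setdiff(cand, last)
    if (!length(cand)) stop("cannot satisfy the run-length constraint", call. = FALSE)
    pick <- cand[[1]]
    out[i] <- pick
    pool <- pool[-match(pick, pool)]
    run <- if (identical(pick, last)) run + 1L else 1L
    last <- pick
  }
  out
}

# internal: order item indices so their condition labels satisfy the run cap.
order_by_condition <- function(items, cond_of, max_run) {
  labs <- shuffle_max_run(cond_of[items], max_run)
  # assign concrete items to the label sequence, randomising within label
  out <- integer(length(items))
  for (lab in unique(labs)) {
    slots <- which(labs == lab)
    members <- items[cond_of[items] == lab]
    out[slots] <- sample(members)
  }
  out
}

#' Build a counterbalanced study design with presentation schedules
#'
#' Assigns every critical topic to a condition within each format by rotating
#' the topic sets through the conditions (a Latin-square rotation, so that
#' across formats each topic appears in each condition exactly once), and
#' draws presentation schedules for all phases under the constraint that no
#' more than `max_run_length` same-condition items appear consecutively.
#'
#' Phase 1 runs in two seamless blocks. Block A interleaves the first two
#' presentations of the thrice-presented fake news with real-news fillers in
#' two full cycles (every item once per cycle). Block B contains the third
#' fake presentation, the once-presented fake news, the to-be-affirmed real
#' news, and a filler repetition.
#'
#' @param config a [design_config()].
#' @param seed integer seed for the schedule randomisation.
#' @return An object of class `study_design`: a list with `assignment`
#'   (topic x format condition map) and `schedule` (one data frame per format
#'   with columns `phase`, `block`, `cycle`, `slot`, `topic_id`, `item_class`,
#'   `condition`, `shown`, `presentation_index`).
#' @export
study_design <- function(config = design_config(), seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  conds <- config$conditions
  k <- length(conds)
  m <- config$items_per_condition
  topics <- sprintf("T%02d", seq_len(config$n_critical_topics))
  sets <- split(topics, rep(seq_len(k), each = m))   # three sets of m topics
  assignment <- do.call(rbind, lapply(seq_len(config$n_formats), function(f) {
    rot <- ((seq_len(k) + f - 2) %% k) + 1           # cyclic rotation
    data.frame(
      format_id = f,
      topic_id = unlist(sets, use.names = FALSE),
      condition = rep(conds[rot], each = m),
      stringsAsFactors = FALSE
    )
  }))
  fillers <- if (config$n_fillers > 0) sprintf("F%02d", seq_len(config$n_fillers)) else character()
  schedule <- lapply(seq_len(config$n_formats), function(f) {
    amap <- assignment[assignment$format_id == f, ]
    cond_of <- setNames(amap$condition, amap$topic_id)
    cond_of[fillers] <- "FILLER"
    fake3 <- amap$topic_id[amap$condition == "CORRECTED_3X"]
    fake1 <- amap$topic_id[amap$condition == "CORRECTED_1X"]
    affirmed <- amap$topic_id[amap$condition == "AFFIRMED_REAL"]

    rows <- list()
    add <- function(phase, block, cycle, ids, shown, pres) {
      rows[[length(rows) + 1L]] <<- data.frame(
        phase = phase, block = block, cycle = cycle,
        slot = seq_along(ids), topic_id = ids,
        item_class = ifelse(grepl("^F", ids), "FILLER", "CRITICAL"),
        condition = unname(cond_of[ids]),
        shown = shown, presentation_index = pres,
        stringsAsFactors = FALSE
      )
    }

    # Phase 1, Block A: two cycles over fake (3x) items + real fillers
    block_a_items <- c(fake3, fillers)
    for (cyc in 1:2) {
      ord <- order_by_condition(seq_along(block_a_items),
                                cond_of[block_a_items], config$max_run_length)
      ids <- block_a_items[ord]
      add("P1_FAMILIARITY", "A", cyc, ids,
          shown = ifelse(grepl("^F", ids), "REAL", "FAKE"), pres = cyc)
    }
    # Phase 1, Block B: 3rd fake(3x) presentation, fake(1x), affirmed real,
    # filler repetition; accuracy ratings
    block_b_items <- c(fake3, fake1, affirmed, fillers)
    ord <- order_by_condition(seq_along(block_b_items),
                              cond_of[block_b_items], config$max_run_length)
    ids <- block_b_items[ord]
    pres <- ifelse(ids %in% fake3, 3L, ifelse(ids %in% fillers, 3L, 1L))
    shown <- ifelse(ids %in% c(affirmed, fillers), "REAL", "FAKE")
    add("P1_ACCURACY", "B", 1L, ids, shown, pres)

    # Phase 2: all critical topics, real headlines (affirmation or correction)
    crit <- amap$topic_id
    ord <- order_by_condition(seq_along(crit), cond_of[crit], config$max_run_length)
    add("P2_DETECTION", NA_character_, 1L, crit[ord], shown = "REAL", pres = 1L)

    # Phase 3: all critical topics, test trials
    ord <- order_by_condition(seq_along(crit), cond_of[crit], config$max_run_length)
    add("P3_TEST", NA_character_, 1L, crit[ord], shown = NA_character_, pres = 1L)

    do.call(rbind, rows)
  })
  structure(
    list(config = config, assignment = assignment, schedule = schedule),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Counterbalanced study design:", x$config$n_critical_topics, "topics x",
      x$config$n_formats, "formats\n")
  tab <- table(x$assignment$format_id, x$assignment$condition)
  print(tab)
  invisible(x)
}
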