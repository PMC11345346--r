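#' Corrected hit and false-alarm rates
#'
#' Converts hit/false-alarm counts into rates strictly inside (0, 1) so the
#' probit transform is defined. The default log-linear rule adds 0.5 to each
#' count and 1 to each trial total and is applied to every cell (not only
#' extreme ones), avoiding a discontinuity between extreme and non-extreme
#' data. The `"onehalf"` rule replaces only 0 and 1 proportions by
#' `1/(2N)` and `1 - 1/(2N)`; `"none"` leaves raw proportions and errors on
#' extremes.
#'
#' @param hits,misses signal-trial counts.
#' @param false_alarms,correct_rejections noise-trial counts.
#' @param rule `"loglinear"` (default), `"onehalf"`, or `"none"`.
#' @return A list with components `H` and `F`.
#' @examples
#' corrected_rates(15, 0, 0, 15)           # H = 15.5/16, F = 0.5/16
#' corrected_rates(8, 8, 8, 8)             # symmetric: H = F = 0.5
#' @export
corrected_rates <- function(hits, misses, false_alarms, correct_rejections,
                            rule = c("loglinear", "onehalf", "none")) {
  rule <- match.arg(rule)
  counts <- cbind(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (any(n_sig < 1) || any(n_noise < 1)) {
    stop("at least one signal and one noise trial are required", call. = FALSE)
  }
  H <- switch(rule,
    loglinear = (hits + 0.5) / (n_sig + 1),
    onehalf = {
      h <- hits / n_sig
      ifelse(h == 0, 1 / (2 * n_sig), ifelse(h == 1, 1 - 1 / (2 * n_sig), h))
    },
    none = hits / n_sig
  )
  F <- switch(rule,
    loglinear = (false_alarms + 0.5) / (n_noise + 1),
    onehalf = {
      f <- false_alarms / n_noise
      ifelse(f == 0, 1 / (2 * n_noise), ifelse(f == 1, 1 - 1 / (2 * n_noise), f))
    },
    none = false_alarms / n_noise
  )
  if (rule == "none" && (any(H <= 0 | H >= 1) || any(F <= 0 | F >= 1))) {
    stop("proportion of 0 or 1 with rule = \"none\"; choose a correction rule",
         call. = FALSE)
  }
  list(H = H, F = F)
}

#' Equal-variance signal-detection estimates
#'
#' Sensitivity and criterion from hit and false-alarm rates:
#' `d' = qnorm(H) - qnorm(F)` and `c = -(qnorm(H) + qnorm(F)) / 2`. Higher
#' `c` is a more conservative criterion (fewer "yes" responses); `c = 0` is
#' unbiased. This is the exact inverse of the generative convention
#' `H = pnorm(d'/2 - c)`, `F = pnorm(-d'/2 - c)` used by the simulator.
#'
#' @param H,F hit and false-alarm rates strictly inside (0, 1); vectorised.
#' @return A data frame with columns `H`, `F`, `d_prime`, `criterion_c`.
#' @examples
#' sdt_estimate(0.85, 0.18)   # d' ~ 1.95, c ~ -0.06
#' @export
sdt_estimate <- function(H, F) {
  if (any(H <= 0 | H >= 1 | F <= 0 | F >= 1)) {
    stop("`H` and `F` must lie strictly inside (0, 1)", call. = FALSE)
  }
  zh <- stats::qnorm(H)
  zf <- stats::qnorm(F)
  data.frame(H = H, F = F, d_prime = zh - zf, criterion_c = -(zh + zf) / 2)
}

#' Per-participant SDT estimates for correction classifications
#'
#' Builds hit/false-alarm counts from the trial table and returns one
#' signal-detection estimate per participant x correction condition. "Yes"
#' responses in each correction condition are separate hit rates; "yes"
#' responses in the affirmed-real condition are the shared false-alarm
#' source. Raw (uncorrected) proportions are reported alongside the
#' corrected rates.
#'
#' @param trials a trial table.
#' @param phase `"P2_DETECTION"` (detection question) or `"P3_TEST"`
#'   (correction-remembering question, `remember_yes`).
#' @param rule extreme-proportion correction rule, see [corrected_rates()].
#' @return A data frame with one row per participant x correction condition:
#'   counts, raw proportions (`hit_raw`, `fa_raw`), corrected `H`/`F`,
#'   `d_prime` and `criterion_c`. Participants without both signal and noise
#'   trials are excluded with a warning.
#' @export
sdt_by_cell <- function(trials, phase = c("P2_DETECTION", "P3_TEST"),
                        rule = c("loglinear", "onehalf", "none")) {
  phase <- match.arg(phase)
  rule <- match.arg(rule)
  rows <- trials[trials$phase == phase, ]
  yes <- if (phase == "P2_DETECTION") rows$detect_yes else rows$remember_yes
  keep <- !is.na(yes)
  rows <- rows[keep, ]
  yes <- yes[keep]
  noise <- rows$condition == "AFFIRMED_REAL"
  if (!any(noise)) stop("no affirmed-real trials: the noise distribution is missing",
                        call. = FALSE)
  fa_tab <- tapply(yes[noise], rows$participant_id[noise], sum)
  nn_tab <- tapply(yes[noise], rows$participant_id[noise], length)
  out <- list()
  for (cond in c("CORRECTED_1X", "CORRECTED_3X")) {
    sig <- rows$condition == cond
    if (!any(sig)) next
    hit <- tapply(yes[sig], rows$participant_id[sig], sum)
    ns <- tapply(yes[sig], rows$participant_id[sig], length)
    ids <- intersect(names(hit), names(fa_tab))
    dropped <- setdiff(union(names(hit), names(fa_tab)), ids)
    if (length(dropped)) {
      warning("excluding participants missing a cell in ", cond, ": ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    cr <- corrected_rates(hit[ids], ns[ids] - hit[ids],
                          fa_tab[ids], nn_tab[ids] - fa_tab[ids], rule)
    est <- sdt_estimate(cr$H, cr$F)
    out[[cond]] <- data.frame(
      participant_id = ids,
      age_group = rows$age_group[match(ids, rows$participant_id)],
      condition = cond,
      n_signal = as.integer(ns[ids]), n_noise = as.integer(nn_tab[ids]),
      hits = as.integer(hit[ids]), false_alarms = as.integer(fa_tab[ids]),
      hit_raw = as.numeric(hit[ids] / ns[ids]),
      fa_raw = as.numeric(fa_tab[ids] / nn_tab[ids]),
      H = est$H, F = est$F,
      d_prime = est$d_prime, criterion_c = est$criterion_c,
      correction_rule = rule,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (!length(out)) stop("no correction-condition trials in phase ", phase, call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group summary of per-participant SDT estimates
#'
#' @param cell_estimates output of [sdt_by_cell()].
#' @param B bootstrap resamples for the group confidence intervals.
#' @param seed integer seed for the bootstrap.
#' @return A data frame per age group x condition with mean `d_prime` and
#'   `criterion_c` and percentile cluster-bootstrap 95% CIs.
#' @export
sdt_summary <- function(cell_estimates, B = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  split_by <- interaction(cell_estimates$age_group, cell_estimates$condition,
                          drop = TRUE)
  res <- lapply(split(cell_estimates, split_by), function(g) {
    ci_d <- cluster_bootstrap_ci(g$d_prime, B = B)
    ci_c <- cluster_bootstrap_ci(g$criterion_c, B = B)
    data.frame(
      age_group = g$age_group[1], condition = g$condition[1],
      n = nrow(g),
      d_prime = mean(g$d_prime), d_lo = ci_d[1], d_hi = ci_d[2],
      criterion_c = mean(g$criterion_c), c_lo = ci_c[1], c_hi = ci_c[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
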