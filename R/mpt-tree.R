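#' Dual-process MPT category probabilities
#'
#' Maps the two latent dual-process parameters onto the probabilities of the
#' three Phase-3 response categories for a corrected headline topic: choosing
#' the real news detail, erroneously choosing the fake news detail seen before
#' the correction, or choosing the novel foil.
#'
#' The processing tree: with probability `pr` the correction episode is
#' recollected and the real detail is retrieved. When recollection fails
#' (`1 - pr`), with probability `pf` the previously seen details are familiar,
#' and the real and fake details are then chosen with equal probability (the
#' familiarity guess is fixed at 0.5 and never estimated). Without familiarity,
#' the participant guesses among the alternatives.
#'
#' Two readings of the final guessing stage are supported. `"uniform"`
#' (default) guesses with equal probability among all three response types.
#' `"sequential"` applies two successive 0.5 splits (real vs. not, then fake
#' vs. novel), yielding 0.5/0.25/0.25.
#'
#' @param pr recollection probability (vectorised, values in \[0, 1\]).
#' @param pf familiarity probability (vectorised, values in \[0, 1\]).
#' @param branching `"uniform"` or `"sequential"` guessing at the final stage.
#' @return A numeric matrix with one row per parameter pair and columns
#'   `real`, `fake`, `novel`; rows sum to 1 exactly.
#' @examples
#' mpt_probs(0.5, 0.5)            # (17, 5, 2) / 24
#' mpt_probs(0, 1)                # familiarity only: (.5, .5, 0)
#' mpt_probs(0, 0)                # pure guessing: thirds
#' @seealso [mpt_moments()] for the closed-form inverse, [fit_mpt()] for the
#'   hierarchical Bayesian fit.
#' @export
mpt_probs <- function(pr, pf, branching = c("uniform", "sequential")) {
  branching <- match.arg(branching)
  if (length(pr) != length(pf)) {
    k <- max(length(pr), length(pf))
    pr <- rep_len(pr, k)
    pf <- rep_len(pf, k)
  }
  if (anyNA(pr) || anyNA(pf) || any(pr < 0 | pr > 1) || any(pf < 0 | pf > 1)) {
    stop("`pr` and `pf` must lie in [0, 1]", call. = FALSE)
  }
  fam <- (1 - pr) * pf * 0.5
  if (branching == "uniform") {
    guess <- (1 - pr) * (1 - pf)
    p_real  <- pr + fam + guess / 3
    p_fake  <- fam + guess / 3
    p_novel <- guess / 3
  } else {
    guess <- (1 - pr) * (1 - pf)
    p_real  <- pr + fam + guess * 0.5
    p_fake  <- fam + guess * 0.25
    p_novel <- guess * 0.25
  }
  cbind(real = p_real, fake = p_fake, novel = p_novel)
}

#' Closed-form moment estimator of the dual-process parameters
#'
#' Inverts [mpt_probs()] analytically from observed category proportions.
#' Under the default uniform-thirds guessing stage the tree implies
#' `(1 - Pr)(1 - Pf) = 3 p_novel` and `(1 - Pr) Pf = 2 (p_fake - p_novel)`,
#' which identify both parameters whenever the proportions lie in the model
#' interior. Used as a fast point estimator and as an independent oracle for
#' the Bayesian fit.
#'
#' Estimates falling outside \[0, 1\] are clipped and flagged via the
#' `boundary` column: `p_fake < p_novel` is inconsistent with the tree
#' interior, and at `Pr = 1` familiarity is unidentified (`pf` is `NA`).
#'
#' @param p matrix (or vector of length 3) of category proportions with
#'   columns ordered real, fake, novel; each row must sum to 1.
#' @param branching guessing-stage variant, as in [mpt_probs()].
#' @return A data frame with columns `pr`, `pf`, `boundary`.
#' @examples
#' mpt_moments(mpt_probs(0.5, 0.5))   # recovers (0.5, 0.5)
#' mpt_moments(c(1, 1, 1) / 3)        # pure guessing: (0, 0)
#' @export
mpt_moments <- function(p, branching = c("uniform", "sequential")) {
  branching <- match.arg(branching)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3) stop("`p` must have three columns (real, fake, novel)", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-8)) {
    stop("category proportions must sum to 1", call. = FALSE)
  }
  if (branching == "uniform") {
    no_mem <- 3 * p[, 3]                 # (1-Pr)(1-Pf)
    fam    <- 2 * (p[, 2] - p[, 3])      # (1-Pr)Pf
  } else {
    no_mem <- 4 * p[, 3]
    fam    <- 2 * (p[, 2] - p[, 3])
  }
  one_minus_pr <- no_mem + fam
  pr <- 1 - one_minus_pr
  pf <- ifelse(one_minus_pr > 1e-12, fam / one_minus_pr, NA_real_)
  boundary <- (p[, 2] < p[, 3] - 1e-12) | pr < -1e-12 | pr > 1 + 1e-12 |
    (!is.na(pf) & (pf < -1e-12 | pf > 1 + 1e-12)) | is.na(pf)
  data.frame(
    pr = unname(pmin(pmax(pr, 0), 1)),
    pf = unname(pmin(pmax(pf, 0), 1)),
    boundary = unname(boundary)
  )
}

#' Multinomial log-likelihood of category counts under the tree
#'
#' @param n matrix (or length-3 vector) of counts with columns real, fake,
#'   novel.
#' @param pr,pf dual-process parameters, recycled against rows of `n`.
#' @param branching guessing-stage variant, as in [mpt_probs()].
#' @return Numeric vector of log-likelihood contributions, one per row.
#'   A category with zero probability but a nonzero count yields `-Inf`
#'   (with a warning).
#' @export
mpt_loglik <- function(n, pr, pf, branching = c("uniform", "sequential")) {
  branching <- match.arg(branching)
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  if (ncol(n) != 3) stop("`n` must have three columns (real, fake, novel)", call. = FALSE)
  if (any(n < 0) || any(n != round(n))) stop("counts must be non-negative integers", call. = FALSE)
  p <- mpt_probs(rep_len(pr, nrow(n)), rep_len(pf, nrow(n)), branching)
  ll <- lgamma(rowSums(n) + 1) - rowSums(lgamma(n + 1)) +
    rowSums(ifelse(n == 0, 0, n * log(p)))
  if (any(!is.finite(ll))) {
    warning("zero model probability for an observed category; log-likelihood is -Inf",
            call. = FALSE)
  }
  ll
}

# internal: log-likelihood for count matrix given probit-scale params,
# constant terms dropped. theta_pr, theta_pf on the probit scale.
mpt_loglik_probit <- function(n, theta_pr, theta_pf, branching = "uniform") {
  p <- mpt_probs(stats::pnorm(theta_pr), stats::pnorm(theta_pf), branching)
  rowSums(ifelse(n == 0, 0, n * log(pmax(p, 1e-300))))
}

#' Tabulate Phase-3 category counts for the MPT model
#'
#' Reduces a trial table to per participant x condition counts of the three
#' Phase-3 response categories. Only the fake-news correction conditions enter
#' the MPT; the affirmed-real condition is excluded by design (no fake detail
#' appeared before Phase 3 there).
#'
#' @param trials a trial table (see [simulate_study()] / [read_trials()]).
#' @param conditions correction conditions to keep.
#' @return A data frame with columns `participant_id`, `age_group`,
#'   `condition`, `n_real`, `n_fake`, `n_novel`.
#' @export
mpt_counts <- function(trials,
                       conditions = c("CORRECTED_1X", "CORRECTED_3X")) {
  stopifnot(is.data.frame(trials))
  p3 <- trials[trials$phase == "P3_TEST" & trials$condition %in% conditions, ]
  if (nrow(p3) == 0) stop("no Phase-3 rows in the requested conditions", call. = FALSE)
  key <- paste(p3$participant_id, p3$condition, sep = "\x1f")
  tab <- table(key, factor(p3$p3_choice, levels = c("REAL", "FAKE", "NOVEL")))
  ids <- do.call(rbind, strsplit(rownames(tab), "\x1f", fixed = TRUE))
  age <- p3$age_group[match(ids[, 1], p3$participant_id)]
  out <- data.frame(
    participant_id = ids[, 1],
    age_group = age,
    condition = ids[, 2],
    n_real = as.integer(tab[, "REAL"]),
    n_fake = as.integer(tab[, "FAKE"]),
    n_novel = as.integer(tab[, "NOVEL"]),
    stringsAsFactors = FALSE
  )
  out[order(out$participant_id, out$condition), , drop = FALSE]
}

#' Read / write MPT category-count tables
#'
#' Plain-CSV interchange format for per participant x condition category
#' counts, e.g. to refit the model on externally deposited data.
#'
#' @param path file path.
#' @param counts a data frame as produced by [mpt_counts()].
#' @return `read_mpt_counts()` returns the validated data frame.
#' @export
read_mpt_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "n_real", "n_fake", "n_novel")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("counts file missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  bad <- which(x$n_real < 0 | x$n_fake < 0 | x$n_novel < 0)
  if (length(bad)) stop("negative counts at rows: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x
}

#' @rdname read_mpt_counts
#' @export
write_mpt_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
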