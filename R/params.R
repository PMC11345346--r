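#' Group-level generative parameters for the paradigm simulator
#'
#' Bundles everything the simulator needs to generate one age group's data:
#' probit-scale group means and a covariance matrix for the participant-level
#' dual-process parameters (recollection `Pr` and familiarity `Pf`, one pair
#' per headline-type condition), equal-variance signal-detection parameters
#' for the Phase-2 correction-detection and Phase-3 correction-remembering
#' processes, cumulative-probit cutpoints for the 1-6 rating scales, and the
#' latent-mean shifts that produce repetition-driven familiarity, the illusory
#' truth effect, and recollection-dependent belief ratings.
#'
#' Defaults emulate the magnitudes observed in the recognition experiment of
#' the three-phase correction paradigm (younger adults unless `age_group =
#' "OLDER"`): dual-process means around `Pr ~ 0.47` and `Pf ~ 0.70` in the
#' correction conditions with a familiarity repetition benefit, detection
#' sensitivity near `d' ~ 1.9` with an unbiased criterion, and remembering
#' sensitivity near `d' ~ 1.4`.
#'
#' @param age_group `"YOUNGER"` or `"OLDER"`; switches the default means.
#' @param mu_prob 2 x 3 matrix of group mean `Pr` (row 1) and `Pf` (row 2) on
#'   the probability scale, columns `AFFIRMED_REAL`, `CORRECTED_1X`,
#'   `CORRECTED_3X`. Internally converted to the probit scale.
#' @param sigma 6 x 6 covariance of the participant probit effects, parameter
#'   order `(Pr, Pf)` within condition, conditions in the column order of
#'   `mu_prob`. Must be symmetric positive semi-definite.
#' @param detect_dprime,detect_criterion group detection sensitivity per
#'   correction condition and shared criterion (probit units).
#' @param remember_dprime,remember_criterion same for the Phase-3
#'   correction-remembering question.
#' @param remember_boost_recollected latent-evidence increment on the
#'   remembering question for trials whose Phase-3 choice was generated by
#'   recollection.
#' @param remember_suppression_fake latent-evidence decrement on the
#'   remembering question, per prior fake-news exposure, on correction trials
#'   where the fake detail was (erroneously) chosen at test: familiarity of
#'   the fake detail without recollection suppresses attribution of a
#'   correction, so repeated fake news piles errors into the
#'   correction-not-remembered stratum.
#' @param sd_dprime,sd_criterion between-participant SDs of the detection and
#'   remembering parameters.
#' @param rating_thresholds five strictly increasing cutpoints mapping the
#'   latent standard normal to the 1-6 ordinal scale.
#' @param fam_base latent mean of first-presentation familiarity.
#' @param familiarity_shift_per_exposure latent familiarity increment per
#'   prior presentation.
#' @param acc_base_real,acc_base_fake latent accuracy-rating means for real
#'   and once-seen fake headlines (`acc_base_real` must exceed
#'   `acc_base_fake`).
#' @param illusory_truth_shift latent accuracy increment per prior fake-news
#'   exposure (the illusory truth effect).
#' @param belief_base_real latent belief-rating increment for real-news
#'   choices at test.
#' @param belief_shift_recollected latent belief-rating increment when the
#'   test choice was recollection-generated.
#' @param p_fake_id probability of correctly identifying the Phase-1 fake
#'   detail when asked, by generating branch (`recollect`, `familiar`,
#'   `guess`).
#' @param rating_intercept_sd SD of a participant random intercept shared by
#'   all rating scales.
#' @param branching guessing-stage variant of the response tree, see
#'   [mpt_probs()].
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(age_group = c("YOUNGER", "OLDER"),
                       mu_prob = NULL,
                       sigma = NULL,
                       detect_dprime = c(CORRECTED_1X = 1.9, CORRECTED_3X = 2.0),
                       detect_criterion = 0,
                       remember_dprime = c(CORRECTED_1X = 1.3, CORRECTED_3X = 1.5),
                       remember_criterion = 0,
                       remember_boost_recollected = 0.75,
                       remember_suppression_fake = 0.5,
                       sd_dprime = 0.4,
                       sd_criterion = 0.3,
                       rating_thresholds = c(-1.5, -0.75, 0, 0.75, 1.5),
                       fam_base = NULL,
                       familiarity_shift_per_exposure = 0.15,
                       acc_base_real = NULL,
                       acc_base_fake = NULL,
                       illusory_truth_shift = 0.08,
                       belief_base_real = 0.3,
                       belief_shift_recollected = 0.8,
                       p_fake_id = c(recollect = 0.9, familiar = 0.6, guess = 0.5),
                       rating_intercept_sd = 0.3,
                       branching = c("uniform", "sequential")) {
  age_group <- match.arg(age_group)
  branching <- match.arg(branching)
  conds <- c("AFFIRMED_REAL", "CORRECTED_1X", "CORRECTED_3X")
  if (is.null(mu_prob)) {
    mu_prob <- if (age_group == "YOUNGER") {
      rbind(Pr = c(0.65, 0.47, 0.49), Pf = c(0.70, 0.70, 0.73))
    } else {
      rbind(Pr = c(0.62, 0.46, 0.44), Pf = c(0.68, 0.61, 0.70))
    }
    colnames(mu_prob) <- conds
  }
  if (!all(dim(mu_prob) == c(2, 3)) || any(mu_prob <= 0) || any(mu_prob >= 1)) {
    stop("`mu_prob` must be a 2 x 3 matrix of probabilities strictly inside (0, 1)",
         call. = FALSE)
  }
  if (is.null(sigma)) {
    sigma <- matrix(0.3 * 0.4^2, 6, 6)
    diag(sigma) <- 0.4^2
  }
  check_psd(sigma, 6)
  if (is.unsorted(rating_thresholds, strictly = TRUE)) {
    stop("`rating_thresholds` must be strictly increasing", call. = FALSE)
  }
  if (length(rating_thresholds) != 5) {
    stop("exactly five cutpoints are needed for the 1-6 scale", call. = FALSE)
  }
  if (is.null(fam_base)) fam_base <- if (age_group == "YOUNGER") -0.2 else -0.5
  if (is.null(acc_base_real)) acc_base_real <- if (age_group == "YOUNGER") 0.25 else 0.0
  if (is.null(acc_base_fake)) acc_base_fake <- if (age_group == "YOUNGER") -0.05 else -0.35
  if (acc_base_real <= acc_base_fake) {
    stop("real news latent accuracy mean must exceed the fake news mean", call. = FALSE)
  }
  theta_names <- as.vector(t(outer(conds, c("Pr", "Pf"),
                                   function(c, p) paste0("th_", p, "_", c))))
  dimnames(sigma) <- list(theta_names, theta_names)
  structure(
    list(
      age_group = age_group,
      conditions = conds,
      mu_prob = mu_prob,
      mu_probit = stats::qnorm(mu_prob),
      sigma = sigma,
      theta_names = theta_names,
      detect_dprime = detect_dprime,
      detect_criterion = detect_criterion,
      remember_dprime = remember_dprime,
      remember_criterion = remember_criterion,
      remember_boost_recollected = remember_boost_recollected,
      remember_suppression_fake = remember_suppression_fake,
      sd_dprime = sd_dprime,
      sd_criterion = sd_criterion,
      rating_thresholds = rating_thresholds,
      fam_base = fam_base,
      familiarity_shift_per_exposure = familiarity_shift_per_exposure,
      acc_base_real = acc_base_real,
      acc_base_fake = acc_base_fake,
      illusory_truth_shift = illusory_truth_shift,
      belief_base_real = belief_base_real,
      belief_shift_recollected = belief_shift_recollected,
      p_fake_id = p_fake_id,
      rating_intercept_sd = rating_intercept_sd,
      branching = branching
    ),
    class = "gen_params"
  )
}

#' @export
print.gen_params <- function(x, ...) {
  cat("Generative parameters (", x$age_group, ")\n", sep = "")
  cat("  group Pr/Pf (probability scale):\n")
  print(round(x$mu_prob, 3))
  cat(sprintf("  detection d' = (%s), c = %.2f; remembering d' = (%s), c = %.2f\n",
              paste(format(x$detect_dprime), collapse = ", "), x$detect_criterion,
              paste(format(x$remember_dprime), collapse = ", "), x$remember_criterion))
  invisible(x)
}

# internal: symmetric PSD check with a small tolerance
check_psd <- function(sigma, p) {
  if (!is.matrix(sigma) || !all(dim(sigma) == c(p, p))) {
    stop("covariance must be a ", p, " x ", p, " matrix", call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > 1e-8) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance must be positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}

# internal: MVN draws tolerating a singular (PSD) covariance
rmvnorm_psd <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  a <- e$vectors %*% (t(e$vectors) * sqrt(lam))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% t(a), 2, mu, "+")
}

#' Draw participant profiles from the group generative model
#'
#' Participant dual-process parameters are drawn on the probit scale from a
#' multivariate normal with mean `qnorm(mu_prob)` and covariance `sigma`;
#' detection and remembering parameters get independent normal participant
#' effects. Formats are assigned in rotation so each counterbalancing format
#' is used (near-)equally often.
#'
#' @param params a [gen_params()] object.
#' @param n number of participants (>= 1).
#' @param n_formats number of formats to rotate through.
#' @param seed integer seed.
#' @param id_prefix prefix for participant identifiers.
#' @return A data frame with one row per participant: identifiers, format,
#'   probit-scale `th_Pr_*` / `th_Pf_*` columns, detection and remembering
#'   parameters, and a rating intercept.
#' @export
sample_participants <- function(params, n, n_formats = 3, seed = NULL,
                                id_prefix = substr(params$age_group, 1, 1)) {
  stopifnot(inherits(params, "gen_params"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- as.vector(params$mu_probit)          # column-major: (Pr, Pf) within condition
  theta <- rmvnorm_psd(n, mu, params$sigma)
  colnames(theta) <- params$theta_names
  out <- data.frame(
    participant_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    age_group = params$age_group,
    format_id = ((seq_len(n) - 1L) %% n_formats) + 1L,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(theta))
  for (cond in names(params$detect_dprime)) {
    out[[paste0("detect_d_", cond)]] <-
      params$detect_dprime[[cond]] + stats::rnorm(n, 0, params$sd_dprime)
    out[[paste0("remember_d_", cond)]] <-
      params$remember_dprime[[cond]] + stats::rnorm(n, 0, params$sd_dprime)
  }
  out$detect_c <- params$detect_criterion + stats::rnorm(n, 0, params$sd_criterion)
  out$remember_c <- params$remember_criterion + stats::rnorm(n, 0, params$sd_criterion)
  out$rating_intercept <- stats::rnorm(n, 0, params$rating_intercept_sd)
  out
}
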