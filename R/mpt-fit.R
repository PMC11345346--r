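#' MCMC settings profiles
#'
#' `"desk"` is the default working profile (4 chains of 5,000 retained
#' iterations after 1,000 warm-up, no thinning). `"paper"` mirrors the full
#' published settings for the paradigm (4 chains of 100,000 iterations with
#' 20,000 adaptation + 2,000 burn-in discarded and a thinning factor of 5).
#'
#' @param profile `"desk"` or `"paper"`.
#' @return A list with `chains`, `iter` (retained, pre-thinning), `warmup`,
#'   `thin`.
#' @export
mcmc_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    list(chains = 4L, iter = 5000L, warmup = 1000L, thin = 1L)
  } else {
    list(chains = 4L, iter = 78000L, warmup = 22000L, thin = 5L)
  }
}

# internal: per-condition multinomial log-lik for probit params, counts n x 3
ll_cond <- function(n3, th_pr, th_pf, branching) {
  p <- mpt_probs(stats::pnorm(th_pr), stats::pnorm(th_pf), branching)
  rowSums(ifelse(n3 == 0, 0, n3 * log(pmax(p, 1e-300))))
}

# internal: one MCMC chain of the latent-trait MPT sampler.
# counts_list: list over conditions of n x 3 count matrices (aligned rows).
run_chain <- function(counts_list, branching, iter, warmup, thin,
                      mu_prior_sd, nu0, S0, init, seed,
                      theta_store_max = 200L) {
  set.seed(seed)
  C <- length(counts_list)
  P <- 2L * C
  n <- nrow(counts_list[[1]])
  theta <- init$theta
  mu <- init$mu
  Sigma <- init$Sigma
  Lambda <- chol2inv(chol(Sigma))
  S0_inv_prior <- S0
  step <- rep(0.6, P)
  acc <- integer(P)
  batch <- 0L
  n_keep <- iter %/% thin
  draw_mu <- matrix(NA_real_, n_keep, P)
  draw_sig <- matrix(NA_real_, n_keep, P * (P + 1) / 2)
  theta_prob_sum <- matrix(0, n, P)
  n_store <- min(theta_store_max, n_keep)
  store_at <- unique(round(seq(1, n_keep, length.out = n_store)))
  theta_draws <- array(NA_real_, c(n, P, length(store_at)))
  store_ptr <- 0L
  lower_idx <- which(lower.tri(matrix(0, P, P), diag = TRUE))
  ll <- vapply(seq_len(C), function(ci) {
    ll_cond(counts_list[[ci]], theta[, 2 * ci - 1], theta[, 2 * ci], branching)
  }, numeric(n))
  kept <- 0L
  total_acc <- 0
  total_prop <- 0
  prior_prec_mu <- diag(1 / mu_prior_sd^2, P)
  for (it in seq_len(warmup + iter)) {
    # -- participant parameters, coordinate-wise random-walk Metropolis
    centred <- sweep(theta, 2, mu)
    for (p in seq_len(P)) {
      ci <- (p + 1L) %/% 2L
      is_pr <- p %% 2L == 1L
      prop <- theta[, p] + step[p] * stats::rnorm(n)
      ll_new <- if (is_pr) {
        ll_cond(counts_list[[ci]], prop, theta[, 2 * ci], branching)
      } else {
        ll_cond(counts_list[[ci]], theta[, 2 * ci - 1], prop, branching)
      }
      d <- prop - theta[, p]
      r <- centred %*% Lambda[, p]
      dprior <- -d * as.vector(r) - 0.5 * Lambda[p, p] * d^2
      accept <- log(stats::runif(n)) < (ll_new - ll[, ci] + dprior)
      if (any(accept)) {
        theta[accept, p] <- prop[accept]
        centred[accept, p] <- centred[accept, p] + d[accept]
        ll[accept, ci] <- ll_new[accept]
      }
      acc[p] <- acc[p] + sum(accept)
      if (it > warmup) {
        total_acc <- total_acc + sum(accept)
        total_prop <- total_prop + n
      }
    }
    # -- adapt proposal scales during warm-up only
    if (it <= warmup) {
      if (it %% 50L == 0L) {
        batch <- batch + 1L
        rate <- acc / (50 * n)
        step <- step * exp(pmin(pmax(rate - 0.44, -0.25), 0.25) / sqrt(batch))
        acc[] <- 0L
      }
    }
    # -- group mean, conjugate update
    A <- prior_prec_mu + n * Lambda
    cA <- chol(A)
    b <- Lambda %*% colSums(theta)
    mu_hat <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
    mu <- as.vector(mu_hat + backsolve(cA, stats::rnorm(P)))
    # -- group covariance, conjugate inverse-Wishart update
    centred <- sweep(theta, 2, mu)
    S <- S0_inv_prior + crossprod(centred)
    Lambda <- stats::rWishart(1, nu0 + n, chol2inv(chol(S)))[, , 1]
    Sigma <- chol2inv(chol(Lambda))
    # -- store
    if (it > warmup && (it - warmup) %% thin == 0L) {
      kept <- kept + 1L
      draw_mu[kept, ] <- mu
      draw_sig[kept, ] <- Sigma[lower_idx]
      theta_prob_sum <- theta_prob_sum + stats::pnorm(theta)
      if (store_ptr < length(store_at) && kept == store_at[store_ptr + 1L]) {
        store_ptr <- store_ptr + 1L
        theta_draws[, , store_ptr] <- theta
      }
    }
  }
  list(mu = draw_mu, sigma = draw_sig,
       theta_prob_mean = theta_prob_sum / kept,
       theta_draws = theta_draws,
       accept_rate = total_acc / max(total_prop, 1),
       step = step)
}

#' Fit the hierarchical Bayesian dual-process MPT model
#'
#' Fits the latent-trait multinomial processing tree to per participant x
#' condition category counts. Each participant has a probit-scale parameter
#' vector (recollection and familiarity for every condition) drawn from a
#' group multivariate normal with unknown mean and full covariance, so
#' parameter correlations across conditions are modelled. Priors are weakly
#' informative: independent `N(0, mu_prior_sd^2)` on the probit group means
#' and inverse-Wishart(`P + 2`, `I`) on the covariance.
#'
#' Sampling is Metropolis-within-Gibbs: coordinate-wise random-walk
#' Metropolis updates of the participant parameters (proposal scales adapted
#' toward 44% acceptance during warm-up, then frozen) and exact conjugate
#' Gibbs draws of the group mean and covariance. Runs are deterministic for
#' a fixed `seed` and fixed iteration counts. Convergence is checked with
#' split-chain potential scale reduction (R-hat) on the group means; any
#' R-hat above 1.05 flags the fit prominently but summaries are still
#' returned.
#'
#' @param counts a data frame with columns `participant_id`, `condition`,
#'   `n_real`, `n_fake`, `n_novel` (see [mpt_counts()]). Fit one age group at
#'   a time; see [fit_mpt_groups()] for the per-group convenience wrapper.
#' @param conditions conditions to model; default all present, sorted.
#' @param branching guessing-stage variant, see [mpt_probs()].
#' @param profile an [mcmc_profile()] list; individual components can be
#'   overridden by `chains`, `iter`, `warmup`, `thin`.
#' @param chains,iter,warmup,thin MCMC run lengths; `iter` counts retained
#'   pre-thinning iterations after `warmup`.
#' @param mu_prior_sd prior SD of the probit group means.
#' @param seed integer seed (chain `k` uses `seed + k - 1`).
#' @return An object of class `mpt_fit` with `print`, `summary`, `coef`,
#'   `plot` and `simulate` methods; see also [credible_difference()] and
#'   [ppc_fit()].
#' @examples
#' cnt <- simulate_mpt_counts(n = 30, trials_per_condition = 15,
#'                            mu_prob = cbind(CORRECTED_1X = c(0.5, 0.7)),
#'                            seed = 1)
#' fit <- fit_mpt(cnt, chains = 2, iter = 400, warmup = 200, seed = 1)
#' coef(fit)
#' @export
fit_mpt <- function(counts,
                    conditions = NULL,
                    branching = c("uniform", "sequential"),
                    profile = mcmc_profile("desk"),
                    chains = profile$chains,
                    iter = profile$iter,
                    warmup = profile$warmup,
                    thin = profile$thin,
                    mu_prior_sd = 1,
                    seed = 1) {
  branching <- match.arg(branching)
  need <- c("participant_id", "condition", "n_real", "n_fake", "n_novel")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("`counts` missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(conditions)) conditions <- sort(unique(counts$condition))
  counts <- counts[counts$condition %in% conditions, ]
  ids <- sort(unique(counts$participant_id))
  if (length(ids) < 2) stop("at least 2 participants are required", call. = FALSE)
  complete <- vapply(ids, function(id) {
    all(conditions %in% counts$condition[counts$participant_id == id])
  }, logical(1))
  if (!all(complete)) {
    warning("dropping participants without counts in every condition: ",
            paste(ids[!complete], collapse = ", "), call. = FALSE)
    ids <- ids[complete]
  }
  counts_list <- lapply(conditions, function(cond) {
    sub <- counts[counts$condition == cond, ]
    m <- as.matrix(sub[match(ids, sub$participant_id), c("n_real", "n_fake", "n_novel")])
    if (any(m < 0) || anyNA(m)) stop("invalid counts in condition ", cond, call. = FALSE)
    dimnames(m) <- list(ids, c("real", "fake", "novel"))
    m
  })
  names(counts_list) <- conditions
  C <- length(conditions)
  P <- 2L * C
  n <- length(ids)
  par_names <- as.vector(vapply(conditions, function(cond) {
    c(paste0("Pr_", cond), paste0("Pf_", cond))
  }, character(2)))

  # moment-based initial values, clipped into the interior
  init_theta <- do.call(cbind, lapply(seq_len(C), function(ci) {
    m <- counts_list[[ci]]
    tot <- pmax(rowSums(m), 1)
    est <- mpt_moments(m / tot, branching)
    cbind(stats::qnorm(pmin(pmax(est$pr, 0.05), 0.95)),
          stats::qnorm(pmin(pmax(ifelse(is.na(est$pf), 0.5, est$pf), 0.05), 0.95)))
  }))
  colnames(init_theta) <- par_names

  nu0 <- P + 2
  S0 <- diag(P)
  t0 <- proc.time()[["elapsed"]]
  chains_out <- lapply(seq_len(chains), function(k) {
    set.seed(seed + k - 1L)
    jitter <- matrix(stats::rnorm(n * P, 0, 0.1), n, P)
    init <- list(theta = init_theta + jitter,
                 mu = colMeans(init_theta) + stats::rnorm(P, 0, 0.15),
                 Sigma = diag(0.25, P))
    run_chain(counts_list, branching, iter, warmup, thin,
              mu_prior_sd, nu0, S0, init, seed = seed + 7919L * k)
  })
  elapsed <- proc.time()[["elapsed"]] - t0

  sig_names <- outer(seq_len(P), seq_len(P), function(i, j) {
    paste0("Sigma[", i, ",", j, "]")
  })[lower.tri(matrix(0, P, P), diag = TRUE)]
  draws <- lapply(chains_out, function(ch) {
    m <- cbind(ch$mu, ch$sigma)
    colnames(m) <- c(paste0("mu_", par_names), sig_names)
    m
  })
  mu_mcmc <- coda::mcmc.list(lapply(draws, function(d) {
    coda::mcmc(d[, seq_len(P), drop = FALSE])
  }))
  rhat <- tryCatch(
    coda::gelman.diag(mu_mcmc, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, P)
  )
  ess <- tryCatch(coda::effectiveSize(mu_mcmc), error = function(e) rep(NA_real_, P))
  names(rhat) <- names(ess) <- par_names
  converged <- all(is.na(rhat) | rhat < 1.05)
  theta_prob_mean <- Reduce(`+`, lapply(chains_out, `[[`, "theta_prob_mean")) / chains
  colnames(theta_prob_mean) <- par_names
  rownames(theta_prob_mean) <- ids
  theta_draws <- do.call(abind3, lapply(chains_out, `[[`, "theta_draws"))

  fit <- structure(
    list(
      draws = draws,
      par_names = par_names,
      conditions = conditions,
      branching = branching,
      counts_list = counts_list,
      participant_ids = ids,
      theta_prob_mean = theta_prob_mean,
      theta_draws = theta_draws,
      accept_rate = mean(vapply(chains_out, `[[`, numeric(1), "accept_rate")),
      rhat = rhat,
      ess = ess,
      converged = converged,
      settings = list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                      mu_prior_sd = mu_prior_sd, seed = seed),
      elapsed = elapsed,
      call = match.call()
    ),
    class = "mpt_fit"
  )
  if (!converged) {
    warning("possible non-convergence: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  fit
}

#' Extract pooled posterior draws of a group-level parameter
#'
#' @param fit an `mpt_fit`.
#' @param parameter name, e.g. `"Pr_CORRECTED_1X"` (see `fit$par_names`).
#' @param scale `"prob"` (probability scale, `pnorm` of the probit mean) or
#'   `"probit"`.
#' @return Numeric vector of pooled post-warm-up draws, chains concatenated
#'   in order.
#' @export
parameter_draws <- function(fit, parameter, scale = c("prob", "probit")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "mpt_fit"))
  col <- paste0("mu_", parameter)
  if (!col %in% colnames(fit$draws[[1]])) {
    stop("unknown parameter; available: ", paste(fit$par_names, collapse = ", "),
         call. = FALSE)
  }
  x <- unlist(lapply(fit$draws, function(d) d[, col]), use.names = FALSE)
  if (scale == "prob") stats::pnorm(x) else x
}

#' Summarize a difference of posterior draws
#'
#' Summarizes `drawsA - drawsB` and flags the difference as credible when the
#' central 95% credibility interval excludes 0.
#'
#' @param drawsA,drawsB equal-length aligned draw vectors.
#' @param level credibility level of the central interval.
#' @return A one-row data frame: `mean`, `sd`, `ci_lo`, `ci_hi`, `credible`.
#' @export
credible_difference <- function(drawsA, drawsB, level = 0.95) {
  if (length(drawsA) != length(drawsB)) {
    stop("draw vectors must have equal length", call. = FALSE)
  }
  d <- drawsA - drawsB
  qs <- unname(stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2)))
  data.frame(mean = mean(d), sd = stats::sd(d), ci_lo = qs[1], ci_hi = qs[2],
             credible = qs[1] > 0 | qs[2] < 0)
}

#' @export
print.mpt_fit <- function(x, ...) {
  s <- x$settings
  cat("Hierarchical dual-process MPT fit (latent-trait probit)\n")
  cat(sprintf("  %d participants, conditions: %s; guessing: %s\n",
              length(x$participant_ids), paste(x$conditions, collapse = ", "),
              x$branching))
  cat(sprintf("  %d chains x %d retained (warmup %d, thin %d); accept %.2f; %.1f s\n",
              s$chains, s$iter %/% s$thin, s$warmup, s$thin, x$accept_rate,
              x$elapsed))
  if (!x$converged) {
    cat("  ** WARNING: R-hat > 1.05 for some parameters -- inspect traces **\n")
  }
  cat("\nGroup-level posterior means (probability scale):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Posterior summary in the layout of the parameter table
#'
#' Group-level `Pr` and `Pf` per condition on the probability scale (mean,
#' SD, central 95% CI, R-hat, effective sample size) plus, when exactly two
#' conditions were fitted, the condition difference (repetition effect) per
#' parameter with its credible flag.
#'
#' @param object an `mpt_fit`.
#' @param ... unused.
#' @return A data frame of class `summary.mpt_fit`.
#' @export
summary.mpt_fit <- function(object, ...) {
  rows <- lapply(object$par_names, function(pn) {
    g <- parameter_draws(object, pn)
    qs <- unname(stats::quantile(g, c(0.025, 0.975)))
    data.frame(parameter = pn, mean = mean(g), sd = stats::sd(g),
               ci_lo = qs[1], ci_hi = qs[2],
               rhat = unname(object$rhat[pn]), ess = unname(object$ess[pn]),
               credible = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(object$conditions) == 2) {
    for (par in c("Pr", "Pf")) {
      a <- parameter_draws(object, paste0(par, "_", object$conditions[2]))
      b <- parameter_draws(object, paste0(par, "_", object$conditions[1]))
      cd <- credible_difference(a, b)
      out <- rbind(out, data.frame(
        parameter = paste0(par, "_diff_", object$conditions[2], "-", object$conditions[1]),
        mean = cd$mean, sd = cd$sd, ci_lo = cd$ci_lo, ci_hi = cd$ci_hi,
        rhat = NA_real_, ess = NA_real_, credible = cd$credible,
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("summary.mpt_fit", "data.frame")
  out
}

#' @export
print.summary.mpt_fit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mpt_fit <- function(object, ...) {
  est <- vapply(object$par_names, function(pn) mean(parameter_draws(object, pn)),
                numeric(1))
  matrix(est, nrow = 2, dimnames = list(c("Pr", "Pf"), object$conditions))
}

#' @export
plot.mpt_fit <- function(x, pars = paste0("mu_", x$par_names), ...) {
  P <- length(pars)
  old <- graphics::par(mfrow = c(ceiling(P / 2), min(P, 2)),
                       mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (pn in pars) {
    tr <- vapply(x$draws, function(d) d[, pn], numeric(nrow(x$draws[[1]])))
    graphics::matplot(stats::pnorm(tr), type = "l", lty = 1,
                      main = sub("^mu_", "", pn), xlab = "", ylab = "")
  }
  invisible(x)
}

#' Posterior-predictive replicate count tables
#'
#' For each replicate, draws `(mu, Sigma)` from the pooled posterior, samples
#' a new cohort of participant parameters and generates multinomial category
#' counts with the observed per-cell trial totals.
#'
#' @param object an `mpt_fit`.
#' @param nsim number of replicate tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames in [mpt_counts()] layout.
#' @export
simulate.mpt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pooled <- do.call(rbind, object$draws)
  picks <- sample.int(nrow(pooled), nsim, replace = nsim > nrow(pooled))
  lapply(picks, function(i) ppc_replicate(object, pooled[i, ]))
}

# internal: one replicate counts data frame from a single (mu, Sigma) draw
ppc_replicate <- function(fit, draw) {
  P <- length(fit$par_names)
  mu <- draw[seq_len(P)]
  Sigma <- matrix(0, P, P)
  Sigma[lower.tri(Sigma, diag = TRUE)] <- draw[-seq_len(P)]
  Sigma <- Sigma + t(Sigma) - diag(diag(Sigma))
  n <- length(fit$participant_ids)
  theta <- rmvnorm_psd(n, mu, Sigma)
  out <- lapply(seq_along(fit$conditions), function(ci) {
    tot <- rowSums(fit$counts_list[[ci]])
    p <- mpt_probs(stats::pnorm(theta[, 2 * ci - 1]),
                   stats::pnorm(theta[, 2 * ci]), fit$branching)
    m <- t(vapply(seq_len(n), function(i) {
      as.integer(stats::rmultinom(1, tot[i], p[i, ]))
    }, integer(3)))
    data.frame(participant_id = fit$participant_ids,
               condition = fit$conditions[ci],
               n_real = m[, 1], n_fake = m[, 2], n_novel = m[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# internal: bind arrays along the third margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  array(unlist(arrs), c(d[1], d[2], sum(vapply(arrs, function(a) dim(a)[3],
                                               numeric(1)))))
}

#' Posterior-predictive fit checks for means (T1) and covariances (T2)
#'
#' Discrepancies are conditioned on the participant-level parameter draws
#' retained during sampling. For each stored draw, the expected category
#' proportions per participant are computed, a replicate data set is
#' generated at those same parameters with the observed trial totals, and
#' two discrepancies are compared between observed and replicate data: T1,
#' the summed squared deviation of the per-condition mean category
#' proportions from their expectation; and T2, the same construction on the
#' between-participant covariance matrix of the category proportions (within
#' and across conditions), the check that is sensitive to a misspecified
#' random-effects structure. The reported values are the proportions of
#' draws in which the replicate discrepancy is at least the observed one;
#' values near 0 or 1 indicate misfit.
#'
#' @param fit an `mpt_fit`.
#' @param n_rep number of stored posterior draws to use (at most the number
#'   retained in the fit).
#' @param seed integer seed.
#' @return A list with `t1_ppp` and `t2_ppp` (the latter `NA` with a warning
#'   when fewer than 4 participants make the covariance check meaningless).
#' @export
ppc_fit <- function(fit, n_rep = 500, seed = 1) {
  stopifnot(inherits(fit, "mpt_fit"))
  set.seed(seed)
  n <- length(fit$participant_ids)
  C <- length(fit$conditions)
  totals <- lapply(fit$counts_list, rowSums)
  prop_obs <- lapply(fit$counts_list, function(m) m / pmax(rowSums(m), 1))
  flat_obs <- do.call(cbind, prop_obs)
  m_obs <- unlist(lapply(prop_obs, colMeans), use.names = FALSE)
  do_t2 <- n >= 4
  if (!do_t2) warning("too few participants for the covariance check; T2 omitted",
                      call. = FALSE)
  v_obs <- NULL
  if (do_t2) {
    v <- stats::cov(flat_obs)
    v_obs <- v[lower.tri(v, diag = TRUE)]
    if (all(abs(v_obs) < 1e-12)) {
      warning("category counts are constant across participants; ",
              "covariance discrepancy is degenerate", call. = FALSE)
    }
  }
  S <- dim(fit$theta_draws)[3]
  picks <- if (n_rep >= S) seq_len(S) else sample.int(S, n_rep)
  t1_exceed <- logical(length(picks))
  t2_exceed <- logical(length(picks))
  for (r in seq_along(picks)) {
    theta <- fit$theta_draws[, , picks[r]]
    p_list <- lapply(seq_len(C), function(ci) {
      mpt_probs(stats::pnorm(theta[, 2 * ci - 1]),
                stats::pnorm(theta[, 2 * ci]), fit$branching)
    })
    rep_prop <- lapply(seq_len(C), function(ci) {
      tot <- totals[[ci]]
      y <- t(vapply(seq_len(n), function(i) {
        as.integer(stats::rmultinom(1, tot[i], p_list[[ci]][i, ]))
      }, integer(3)))
      y / pmax(tot, 1)
    })
    # T1: means around the draw-conditional expectation
    e_m <- unlist(lapply(p_list, colMeans), use.names = FALSE)
    m_rep <- unlist(lapply(rep_prop, colMeans), use.names = FALSE)
    t1_exceed[r] <- sum((m_rep - e_m)^2) >= sum((m_obs - e_m)^2)
    if (do_t2) {
      # expected covariance: spread of expected proportions plus the
      # multinomial sampling covariance at the observed totals
      flat_p <- do.call(cbind, p_list)
      e_cov <- stats::cov(flat_p)
      for (ci in seq_len(C)) {
        idx <- (3 * ci - 2):(3 * ci)
        p <- p_list[[ci]]
        tot <- pmax(totals[[ci]], 1)
        within <- matrix(0, 3, 3)
        for (i in seq_len(n)) {
          within <- within + (diag(p[i, ]) - tcrossprod(p[i, ])) / tot[i]
        }
        e_cov[idx, idx] <- e_cov[idx, idx] + within / n
      }
      e_v <- e_cov[lower.tri(e_cov, diag = TRUE)]
      vr <- stats::cov(do.call(cbind, rep_prop))
      v_rep <- vr[lower.tri(vr, diag = TRUE)]
      t2_exceed[r] <- sum((v_rep - e_v)^2) >= sum((v_obs - e_v)^2)
    }
  }
  list(t1_ppp = mean(t1_exceed), t2_ppp = if (do_t2) mean(t2_exceed) else NA_real_)
}

#' Simulate category counts directly from the latent-trait MPT
#'
#' Generates per participant x condition counts from the hierarchical model
#' itself (bypassing the full paradigm simulator): participant probit
#' parameters are drawn from a multivariate normal around `qnorm(mu_prob)`
#' and counts from the category-probability multinomial. Used for parameter
#' recovery and calibration studies.
#'
#' @param n participants.
#' @param trials_per_condition multinomial total per cell.
#' @param mu_prob 2 x C matrix (rows `Pr`, `Pf`; named columns = conditions)
#'   of group means on the probability scale.
#' @param sigma 2C x 2C covariance of probit effects (parameter order `(Pr,
#'   Pf)` within condition); default exchangeable, SD 0.4, correlation 0.3.
#' @param branching guessing-stage variant.
#' @param seed integer seed.
#' @param age_group label attached to the output.
#' @return A data frame in [mpt_counts()] layout.
#' @export
simulate_mpt_counts <- function(n, trials_per_condition, mu_prob,
                                sigma = NULL,
                                branching = c("uniform", "sequential"),
                                seed = NULL, age_group = "YOUNGER") {
  branching <- match.arg(branching)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(mu_prob)) || nrow(mu_prob) != 2) {
    stop("`mu_prob` must be a 2 x C matrix (rows Pr, Pf)", call. = FALSE)
  }
  conds <- colnames(mu_prob)
  if (is.null(conds)) conds <- paste0("COND", seq_len(ncol(mu_prob)))
  C <- ncol(mu_prob)
  P <- 2L * C
  if (is.null(sigma)) {
    sigma <- matrix(0.3 * 0.16, P, P)
    diag(sigma) <- 0.16
  }
  check_psd(sigma, P)
  theta <- rmvnorm_psd(n, as.vector(stats::qnorm(mu_prob)), sigma)
  ids <- sprintf("S%04d", seq_len(n))
  out <- lapply(seq_len(C), function(ci) {
    p <- mpt_probs(stats::pnorm(theta[, 2 * ci - 1]),
                   stats::pnorm(theta[, 2 * ci]), branching)
    m <- t(vapply(seq_len(n), function(i) {
      as.integer(stats::rmultinom(1, trials_per_condition, p[i, ]))
    }, integer(3)))
    data.frame(participant_id = ids, age_group = age_group,
               condition = conds[ci],
               n_real = m[, 1], n_fake = m[, 2], n_novel = m[, 3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "theta") <- theta
  res
}

#' Fit the MPT model separately per age group
#'
#' @param counts a counts data frame including an `age_group` column.
#' @param ... passed to [fit_mpt()].
#' @return A named list of `mpt_fit` objects, one per age group.
#' @export
fit_mpt_groups <- function(counts, ...) {
  stopifnot("age_group" %in% names(counts))
  groups <- sort(unique(counts$age_group))
  fits <- lapply(groups, function(g) fit_mpt(counts[counts$age_group == g, ], ...))
  names(fits) <- groups
  fits
}
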