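## Time-to-first-visit model.  Days to the first visit of a species at a
## carcass follow a discrete-time Weibull: S(t) = exp(-lambda * t^k) with
## log(lambda) = alpha_season + beta * distance_to_farm + transect effect,
## right-censored at the end of monitoring.  beta > 0 means the daily
## hazard (and so the chance of an early first visit) increases with
## distance from the farm boundary.

#' Default priors for the first-visit model
#'
#' Vague priors: Normal(0, 10^2) on intercepts and the distance slope,
#' Gamma(1, 1) on the Weibull shape k, Half-Normal(0, 5^2) on the
#' transect standard deviation.
#'
#' @return named list of prior hyperparameters.
#' @export
first_visit_priors <- function() {
  list(intercept_sd = 10, beta_sd = 10, k_shape = 1, k_rate = 1,
       sigma_sd = 5)
}

fv_lambda <- function(params, site) {
  a <- ifelse(site$season == "spring", params$alpha_spring,
              params$alpha_winter)
  u <- if (is.null(params$transect_effects)) 0 else
    params$transect_effects[site$transect_id]
  exp(a + params$beta * site$distance_to_farm + u)
}

#' Weibull survival function for days to first visit
#'
#' S(t) = exp(-lambda t^k), the probability the carcass is still unvisited
#' after t days, with lambda = exp(alpha_season + beta * distance +
#' transect effect).
#'
#' @param t days since deployment (>= 0).
#' @param params list with `k`, `alpha_spring`, `alpha_winter`, `beta` and
#'   optionally `transect_effects` (named or indexed by transect id).
#' @param site one-row data frame (or list) with `season`,
#'   `distance_to_farm`, `transect_id`.
#' @return survival probability in \[0,1\].
#' @export
fv_survival <- function(t, params, site) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp(-fv_lambda(params, site) * t^params$k)
}

#' Probability the first visit falls on day t
#'
#' P(T = t) = S(t-1) - S(t) for integer day t >= 1 (deployment is day 0,
#' the first possible visit day is 1).  Together with the censoring mass
#' S(horizon) these probabilities sum to one.
#'
#' @param t integer day (>= 1).
#' @inheritParams fv_survival
#' @return probability of first visit on day t.
#' @export
fv_interval_prob <- function(t, params, site) {
  if (any(t < 1)) stop("t must be >= 1", call. = FALSE)
  fv_survival(t - 1, params, site) - fv_survival(t, params, site)
}

## log(S(t-1) - S(t)) computed stably: with A = -lambda (t-1)^k and
## B = -lambda t^k (A > B), log(e^A - e^B) = A + log1p(-exp(B - A)).
fv_loglik_vec <- function(day, censored, k, lambda) {
  A <- -lambda * (day - 1)^k
  B <- -lambda * day^k
  obs <- A + log1p(-exp(B - A))
  ifelse(censored, B, obs)
}

#' Log-likelihood of first-visit data
#'
#' Observed first visits contribute log(S(t-1) - S(t)); carcasses never
#' visited contribute log S(censor day).
#'
#' @param data data frame with one row per carcass: `transect_id`,
#'   `distance_to_farm`, `season`, `day` (first-visit day, or the censor
#'   day for censored rows), `censored` (logical).
#' @param params as in [fv_survival()]; `transect_effects` must cover all
#'   transects in `data`.
#' @return scalar log-likelihood (-Inf if any datum has zero probability).
#' @export
fv_log_likelihood <- function(data, params) {
  stopifnot(all(data$day >= 1))
  lam <- fv_lambda(params, data)
  ll <- fv_loglik_vec(data$day, data$censored, params$k, lam)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

## log_t0 > 0 selects the decorrelating parameterisation used during
## sampling: the stored intercept g relates to the model intercept by
## alpha = g - k * log_t0, so proposals in k leave the hazard near the
## typical first-visit day t0 unchanged (the Jacobian is 1).
fv_theta_to_params <- function(theta, n_transects, season_effect = TRUE,
                               log_t0 = 0) {
  k <- exp(theta[["log_k"]])
  a_spring <- if (season_effect) theta[["a_spring"]] else theta[["a"]]
  a_winter <- if (season_effect) theta[["a_winter"]] else theta[["a"]]
  list(k = k,
       alpha_spring = a_spring - k * log_t0,
       alpha_winter = a_winter - k * log_t0,
       beta = theta[["beta"]],
       transect_effects = unname(theta[paste0("u", seq_len(n_transects))]),
       sigma_transect = exp(theta[["log_sigma_t"]]))
}

#' Fit the first-visit model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs over the Weibull shape (log scale),
#' season intercepts, distance slope, transect random effects (vectorised
#' independent updates) and the transect standard deviation (log scale with
#' Jacobian).  Non-convergence (max R-hat >= 1.05) is flagged with a
#' warning; draws are still returned.
#'
#' @param data as in [fv_log_likelihood()]; transect ids must be 1..T.
#' @param priors from [first_visit_priors()].
#' @param config an [mcmc_config()].
#' @param season_effect if FALSE a single intercept replaces the two
#'   season intercepts (for DIC comparison of season vs no-season).
#' @param compute_dic compute deviance draws and DIC (adds one likelihood
#'   pass per kept draw).
#' @return a `first_visit_fit` (also a `posterior_fit`) with elements
#'   `data`, `season_effect`, `n_transects`, `converged`, and optionally
#'   `dic`, `deviance_draws`.
#' @export
fit_first_visit <- function(data, priors = first_visit_priors(),
                            config = mcmc_config(), season_effect = TRUE,
                            compute_dic = TRUE) {
  stopifnot(is.logical(data$censored), all(data$day >= 1))
  n_t <- max(data$transect_id)
  if (length(unique(data$transect_id)) < 2)
    stop("need >= 2 transects to identify the transect variance",
         call. = FALSE)
  u_names <- paste0("u", seq_len(n_t))
  fixed <- if (season_effect) c("log_k", "a_spring", "a_winter", "beta")
           else c("log_k", "a", "beta")
  log_t0 <- log(stats::median(data$day))

  loglik <- function(theta) {
    p <- fv_theta_to_params(theta, n_t, season_effect, log_t0)
    fv_log_likelihood(data, p)
  }
  log_prior_fixed <- function(theta) {
    k <- exp(theta[["log_k"]])
    p <- fv_theta_to_params(theta, n_t, season_effect, log_t0)
    ints <- if (season_effect) c(p$alpha_spring, p$alpha_winter)
            else p$alpha_spring
    stats::dgamma(k, priors$k_shape, priors$k_rate, log = TRUE) +
      theta[["log_k"]] +
      sum(stats::dnorm(ints, 0, priors$intercept_sd, log = TRUE)) +
      stats::dnorm(theta[["beta"]], 0, priors$beta_sd, log = TRUE)
  }
  log_prior_sigma <- function(theta) {
    s <- exp(theta[["log_sigma_t"]])
    stats::dnorm(s, 0, priors$sigma_sd, log = TRUE) + log(2) +
      theta[["log_sigma_t"]]
  }
  log_posterior <- function(theta) {
    s <- exp(theta[["log_sigma_t"]])
    loglik(theta) + log_prior_fixed(theta) + log_prior_sigma(theta) +
      sum(stats::dnorm(theta[u_names], 0, s, log = TRUE))
  }

  ## local conditionals: transect effects touch only their transect's rows
  by_transect <- split(seq_len(nrow(data)), data$transect_id)
  lp_u <- function(theta) {
    p <- fv_theta_to_params(theta, n_t, season_effect, log_t0)
    lam <- fv_lambda(p, data)
    ll <- fv_loglik_vec(data$day, data$censored, p$k, lam)
    grp <- vapply(by_transect, function(ix) sum(ll[ix]), 0)
    grp + stats::dnorm(theta[u_names], 0, exp(theta[["log_sigma_t"]]),
                       log = TRUE)
  }
  lp_sigma <- function(theta) {
    log_prior_sigma(theta) +
      sum(stats::dnorm(theta[u_names], 0, exp(theta[["log_sigma_t"]]),
                       log = TRUE))
  }

  ## shift move: intercepts + delta, transect effects - delta; the
  ## likelihood is invariant (lambda depends on alpha + u only), so the
  ## acceptance ratio involves just the priors -- this decorrelates the
  ## intercepts from the random-effect mean
  int_names <- fixed[-c(1, length(fixed))]
  lp_shift <- function(theta) log_prior_fixed(theta) +
    sum(stats::dnorm(theta[u_names], 0, exp(theta[["log_sigma_t"]]),
                     log = TRUE))
  propose_shift <- function(theta, sd) {
    delta <- stats::rnorm(1, 0, sd)
    theta[int_names] <- theta[int_names] + delta
    theta[u_names] <- theta[u_names] - delta
    theta
  }
  blocks <- c(
    lapply(fixed, function(p) list(pars = p, type = "joint", step = 0.3)),
    list(list(pars = u_names, type = "indep", lp = lp_u, step = 0.5),
         list(pars = c(int_names, u_names), type = "custom", lp = lp_shift,
              propose = propose_shift, step = 0.5),
         list(pars = "log_sigma_t", type = "joint", lp = lp_sigma,
              step = 0.4))
  )

  init <- lapply(seq_len(config$n_chains), function(ch) {
    set.seed(config$seed + 37L * ch)
    th <- c(stats::rnorm(1, 0.2, 0.3),
            stats::rnorm(length(fixed) - 2, -1, 1.5),
            stats::rnorm(1, 0, 0.3),
            stats::rnorm(n_t, 0, 0.5),
            stats::rnorm(1, 0, 0.5))
    names(th) <- c("log_k", fixed[-1], u_names, "log_sigma_t")
    th
  })

  fit <- mcmc_sample(log_posterior, init, config, blocks)
  ## back-transform the decorrelated intercepts to model-scale alphas
  k_arr <- exp(fit$draws[, , "log_k"])
  for (a in intersect(c("a_spring", "a_winter", "a"), fit$parameters))
    fit$draws[, , a] <- fit$draws[, , a] - k_arr * log_t0
  if (config$n_chains >= 2) fit$rhat <- gelman_rubin(fit$draws)
  fit$data <- data
  fit$season_effect <- season_effect
  fit$n_transects <- n_t
  fit$converged <- max(fit$rhat) < 1.05
  if (!fit$converged)
    warning("first-visit model not converged: max R-hat = ",
            format(max(fit$rhat), digits = 4), call. = FALSE)
  if (compute_dic) {
    m <- as.matrix(fit)   # already on the model (alpha) scale
    ll_alpha <- function(th)
      fv_log_likelihood(data, fv_theta_to_params(th, n_t, season_effect))
    dev <- apply(m, 1, function(th) -2 * ll_alpha(th))
    dev_at_mean <- -2 * ll_alpha(colMeans(m))
    fit$deviance_draws <- dev
    fit$dic <- dic(dev, dev_at_mean)
  }
  class(fit) <- c("first_visit_fit", class(fit))
  fit
}

#' Posterior summary of days to first visit
#'
#' For each posterior draw the Weibull median (log 2 / lambda)^(1/k) is
#' evaluated at the given distance and season, marginal over transect
#' effects (one fresh transect effect drawn per posterior draw from
#' N(0, sigma^2)); the draws are summarised by their median and 95% HPD
#' interval.
#'
#' @param fit a `first_visit_fit`.
#' @param distance distance to farm (km).
#' @param season "spring" or "winter".
#' @param level HPD mass.
#' @param marginal_seed seed for the fresh transect-effect draws.
#' @return list with `median`, `hpd` (lo, hi) in days.
#' @export
first_visit_summary <- function(fit, distance, season, level = 0.95,
                                marginal_seed = 1) {
  m <- as.matrix(fit)
  a <- if (fit$season_effect) {
    if (season == "spring") m[, "a_spring"] else m[, "a_winter"]
  } else m[, "a"]
  set.seed(marginal_seed)
  u <- stats::rnorm(nrow(m), 0, exp(m[, "log_sigma_t"]))
  lambda <- exp(a + m[, "beta"] * distance + u)
  med_days <- (log(2) / lambda)^(1 / exp(m[, "log_k"]))
  list(median = stats::median(med_days), hpd = hpd_interval(med_days, level))
}

#' Posterior predictive check for the first-visit model
#'
#' Discrepancy: counts of carcasses visited by day 7, day 28 and the
#' horizon, as a sum of squared Pearson residuals against their
#' expectations under the drawn parameters.  Replicates are simulated from
#' the fitted model at the observed design.
#'
#' @param fit a `first_visit_fit`.
#' @param n_rep number of replicated datasets (default 5000).
#' @param seed RNG seed.
#' @param check_days days at which cumulative visited counts are compared.
#' @return Bayesian p-value.
#' @export
first_visit_ppp <- function(fit, n_rep = 5000, seed = 1,
                            check_days = NULL) {
  data <- fit$data
  horizon <- max(data$day)
  if (is.null(check_days)) check_days <- unique(c(7, 28, horizon))
  n_t <- fit$n_transects

  expected <- function(theta) {
    p <- fv_theta_to_params(theta, n_t, fit$season_effect)
    sv <- sapply(check_days, function(d) fv_survival(d, p, data))
    pr <- 1 - sv                      # n_sites x n_days visit-by-day probs
    list(mu = colSums(pr), v = colSums(pr * (1 - pr)))
  }
  discrepancy <- function(dat, theta) {
    e <- expected(theta)
    obs <- sapply(check_days, function(d)
      sum(!dat$censored & dat$day <= d))
    sum((obs - e$mu)^2 / pmax(e$v, 1e-8))
  }
  replicate_generator <- function(theta) {
    p <- fv_theta_to_params(theta, n_t, fit$season_effect)
    lam <- fv_lambda(p, data)
    u01 <- stats::runif(nrow(data))
    ## inverse-cdf on the discrete day scale; a common horizon is assumed
    tt <- ceiling((-log(u01) / lam)^(1 / p$k))
    cens <- tt > horizon
    data.frame(day = pmin(tt, horizon), censored = cens)
  }
  posterior_predictive_pvalue(fit, replicate_generator, discrepancy,
                              data[, c("day", "censored")],
                              n_rep = n_rep, seed = seed)
}

#' First-visit data from events and sites
#'
#' Reduces an event table to one row per carcass: the day index (1 = first
#' day after deployment) of the first visit by `species`, right-censored at
#' the end of each carcass's monitored window.
#'
#' @param events validated events table.
#' @param sites validated sites table.
#' @param species one of wild_dog, fox, feral_cat.
#' @return data frame with `carcass_id`, `transect_id`, `distance_to_farm`,
#'   `season`, `day`, `censored`.
#' @export
first_visit_data <- function(events, sites, species) {
  validate_events(events)
  validate_sites(sites)
  ev <- events[events$species == species, , drop = FALSE]
  out <- sites[, c("carcass_id", "transect_id", "distance_to_farm", "season")]
  end_date <- sites$removal_date
  monitored <- as.integer(end_date - sites$deploy_date)
  day <- integer(nrow(sites))
  censored <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    mine <- ev[ev$carcass_id == sites$carcass_id[i], , drop = FALSE]
    if (nrow(mine)) {
      first <- min(mine$start_time)
      d <- as.numeric(difftime(first,
                               as.POSIXct(paste(sites$deploy_date[i], "00:00:00"),
                                          tz = "UTC"), units = "days"))
      day[i] <- max(1L, ceiling(d + 1e-9))
      censored[i] <- FALSE
    } else {
      day[i] <- max(1L, monitored[i])
      censored[i] <- TRUE
    }
  }
  out$day <- day
  out$censored <- censored
  out
}
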