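#' MCMC sampler configuration
#'
#' Defaults mirror common practice for models of this size: 3 chains,
#' 10,000 burn-in iterations, 10,000 further iterations thinned by 10.
#' Proposal standard deviations adapt during burn-in only (Robbins-Monro on
#' the log scale, in batches of `adapt_window`), targeting 0.44 acceptance
#' for scalar blocks and 0.23 for vector blocks; adaptation is frozen after
#' burn-in so the kept draws satisfy detailed balance.
#'
#' @param n_chains number of chains (>= 1; >= 2 for convergence checks).
#' @param n_burnin,n_keep iterations discarded / retained per chain
#'   (`n_keep` counts post-thinning draws).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed controlling all sampler randomness.
#' @param target_accept_scalar,target_accept_vector adaptation targets.
#' @param adapt_window batch size (iterations) for acceptance-rate
#'   adaptation.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 10000, n_keep = 10000,
                        thin = 10, seed = 1,
                        target_accept_scalar = 0.44,
                        target_accept_vector = 0.23,
                        adapt_window = 50) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_keep >= 1, thin >= 1,
            adapt_window >= 1)
  structure(list(n_chains = n_chains, n_burnin = n_burnin, n_keep = n_keep,
                 thin = thin, seed = as.integer(seed),
                 target_accept_scalar = target_accept_scalar,
                 target_accept_vector = target_accept_vector,
                 adapt_window = adapt_window),
            class = "mcmc_config")
}

#' Adaptive random-walk Metropolis-within-Gibbs sampler
#'
#' Samples a user-supplied log-posterior by updating parameter blocks in
#' turn with Gaussian random-walk proposals.  Three block types are
#' supported:
#' \describe{
#'   \item{scalar/joint}{one proposal and one accept/reject step for the
#'     whole block, using `block$lp` if supplied (a function of the full
#'     parameter vector returning the terms of the log-posterior that
#'     depend on this block; constant terms cancel in the Metropolis
#'     ratio), otherwise the global `log_posterior`.}
#'   \item{indep}{a vector of parameters whose full conditionals are
#'     mutually independent given the rest (e.g. random effects across
#'     groups).  `block$lp` must return one log-density contribution per
#'     parameter; all components are proposed and accepted element-wise in
#'     one vectorised step.  Correctness relies on the stated independence,
#'     which is the caller's responsibility.}
#'   \item{custom}{a deterministic symmetric move: `block$propose(theta,
#'     sd)` returns a proposed parameter vector (the proposal must be
#'     symmetric, e.g. a common shift delta ~ N(0, sd) added to some
#'     parameters and subtracted from others); accepted against `block$lp`.
#'     Used to decorrelate intercepts from random-effect means in
#'     hierarchical models.}
#' }
#'
#' @param log_posterior function(theta) -> scalar log-posterior density
#'   (up to a constant); must be finite at every initial point.
#' @param init list with one named numeric vector per chain (over-dispersed
#'   starting values), or a single vector reused for every chain.
#' @param config an [mcmc_config()].
#' @param blocks optional list of block specs, each
#'   `list(pars = <names>, type = "joint"|"indep", lp = <function or NULL>,
#'   step = <initial proposal sd>)`.  Default: every parameter its own
#'   scalar block with the global log-posterior.
#' @return an object of class `posterior_fit`: `draws` (array
#'   iterations x chains x parameters), `parameters`, `rhat`,
#'   `acceptance` (per block per chain), `config`.
#' @export
mcmc_sample <- function(log_posterior, init, config = mcmc_config(),
                        blocks = NULL) {
  if (!is.list(init)) init <- rep(list(init), config$n_chains)
  stopifnot(length(init) == config$n_chains)
  par_names <- names(init[[1]])
  if (is.null(par_names)) stop("initial points must be named vectors")
  n_par <- length(par_names)

  if (is.null(blocks)) {
    blocks <- lapply(par_names, function(p)
      list(pars = p, type = "joint", lp = NULL, step = 0.5))
  }
  blocks <- lapply(blocks, function(b) {
    b$idx <- match(b$pars, par_names)
    if (anyNA(b$idx)) stop("block refers to unknown parameter(s): ",
                           paste(b$pars[is.na(b$idx)], collapse = ", "))
    b$type <- b$type %||% "joint"
    b$step <- b$step %||% 0.5
    if (is.null(b$lp)) b$lp <- log_posterior
    b
  })
  n_blocks <- length(blocks)

  n_iter <- config$n_burnin + config$n_keep * config$thin
  keep_at <- config$n_burnin + seq_len(config$n_keep) * config$thin
  draws <- array(NA_real_,
                 dim = c(config$n_keep, config$n_chains, n_par),
                 dimnames = list(NULL, NULL, par_names))
  acceptance <- matrix(NA_real_, n_blocks, config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    theta <- init[[ch]]
    lp0 <- log_posterior(theta)
    if (!is.finite(lp0))
      stop("log-posterior not finite at initial point of chain ", ch)

    ## per-block state: log step sizes (scalar for joint, vector for indep)
    steps <- lapply(blocks, function(b)
      if (b$type == "indep") rep(log(b$step), length(b$idx)) else log(b$step))
    acc_count <- lapply(blocks, function(b)
      if (b$type == "indep") numeric(length(b$idx)) else 0)
    acc_total <- numeric(n_blocks)
    batch_n <- 0L
    adapt_round <- 0L
    keep_ptr <- 1L

    for (it in seq_len(n_iter)) {
      adapting <- it <= config$n_burnin
      batch_n <- batch_n + 1L
      for (bi in seq_len(n_blocks)) {
        b <- blocks[[bi]]
        idx <- b$idx
        if (b$type == "custom") {
          lp_old <- b$lp(theta)
          prop <- b$propose(theta, exp(steps[[bi]]))
          lp_new <- b$lp(prop)
          if (is.finite(lp_new) &&
              log(stats::runif(1)) < (lp_new - lp_old)) {
            theta <- prop
            acc_count[[bi]] <- acc_count[[bi]] + 1
            acc_total[bi] <- acc_total[bi] + 1
          }
        } else if (b$type == "indep") {
          ## full conditionals independent across components: propose and
          ## accept element-wise in one vectorised pass
          lp_old <- b$lp(theta)
          prop <- theta
          eps <- stats::rnorm(length(idx), 0, exp(steps[[bi]]))
          prop[idx] <- theta[idx] + eps
          lp_new <- b$lp(prop)
          acc <- log(stats::runif(length(idx))) < (lp_new - lp_old)
          acc[!is.finite(lp_new)] <- FALSE
          if (any(acc)) theta[idx[acc]] <- prop[idx[acc]]
          acc_count[[bi]] <- acc_count[[bi]] + acc
          acc_total[bi] <- acc_total[bi] + mean(acc)
        } else {
          lp_old <- b$lp(theta)
          prop <- theta
          prop[idx] <- theta[idx] +
            stats::rnorm(length(idx), 0, exp(steps[[bi]]))
          lp_new <- b$lp(prop)
          if (is.finite(lp_new) &&
              log(stats::runif(1)) < (lp_new - lp_old)) {
            theta <- prop
            acc_count[[bi]] <- acc_count[[bi]] + 1
            acc_total[bi] <- acc_total[bi] + 1
          }
        }
      }

      if (adapting && batch_n == config$adapt_window) {
        adapt_round <- adapt_round + 1L
        gamma <- min(0.25, 1 / sqrt(adapt_round))
        for (bi in seq_len(n_blocks)) {
          target <- if (blocks[[bi]]$type == "custom" ||
                        (blocks[[bi]]$type == "joint" &&
                         length(blocks[[bi]]$idx) == 1))
            config$target_accept_scalar else config$target_accept_vector
          rate <- acc_count[[bi]] / config$adapt_window
          steps[[bi]] <- steps[[bi]] + gamma * (rate - target)
          acc_count[[bi]] <- acc_count[[bi]] * 0
        }
        batch_n <- 0L
      }

      if (keep_ptr <= config$n_keep && it == keep_at[keep_ptr]) {
        draws[keep_ptr, ch, ] <- theta
        keep_ptr <- keep_ptr + 1L
      }
    }
    acceptance[, ch] <- acc_total / n_iter
    if (all(acc_total == 0))
      warning("chain ", ch, ": no proposals accepted", call. = FALSE)
  }

  rhat <- if (config$n_chains >= 2) gelman_rubin(draws) else
    stats::setNames(rep(NA_real_, n_par), par_names)
  structure(list(draws = draws, parameters = par_names, rhat = rhat,
                 acceptance = acceptance, config = config),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("posterior_fit:", dim(x$draws)[1], "draws x", dim(x$draws)[2],
      "chains x", dim(x$draws)[3], "parameters\n")
  cat("max R-hat:", format(max(x$rhat), digits = 4), "\n")
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param x a `posterior_fit`.
#' @param ... unused.
#' @return matrix (chains * iterations) x parameters.
#' @export
as.matrix.posterior_fit <- function(x, ...) {
  d <- x$draws
  m <- matrix(aperm(d, c(1, 2, 3)), dim(d)[1] * dim(d)[2], dim(d)[3])
  colnames(m) <- x$parameters
  m
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) form: with m chains of n draws, within-chain
#' variance W and between-chain variance B (of chain means, times n),
#' R = sqrt(((n-1)/n * W + B/n) / W).  Chains that have converged to the
#' same distribution give R near 1; the conventional convergence gate is
#' max R < 1.05.
#'
#' @param draws array iterations x chains x parameters (or a matrix
#'   iterations x chains for a single parameter).
#' @param split if TRUE, each chain is split in half first (split R-hat).
#' @return named vector of R values, one per parameter.
#' @export
gelman_rubin <- function(draws, split = FALSE) {
  if (length(dim(draws)) == 2) {
    draws <- array(draws, c(dim(draws), 1),
                   dimnames = list(NULL, NULL, "par"))
  }
  if (split) {
    n <- dim(draws)[1]
    half <- floor(n / 2)
    draws <- array(c(draws[seq_len(half), , , drop = FALSE],
                     draws[(n - half + 1):n, , , drop = FALSE]),
                   c(half, 2 * dim(draws)[2], dim(draws)[3]),
                   dimnames = list(NULL, NULL, dimnames(draws)[[3]]))
  }
  m <- dim(draws)[2]
  n <- dim(draws)[1]
  if (m < 2) stop("gelman_rubin requires >= 2 chains", call. = FALSE)
  if (n < 10) stop("gelman_rubin requires >= 10 draws per chain", call. = FALSE)
  out <- apply(draws, 3, function(x) {
    means <- colMeans(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(means)
    if (W < .Machine$double.eps) return(1)
    ## floored at 1: with B = 0 the raw ratio is (n-1)/n < 1, but R < 1
    ## carries no diagnostic meaning
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  })
  stats::setNames(out, dimnames(draws)[[3]])
}

#' Deviance information criterion
#'
#' DIC = mean posterior deviance + pD, with the effective number of
#' parameters pD = mean deviance - deviance at the posterior mean.
#'
#' @param deviance_draws vector of deviance values over posterior draws.
#' @param deviance_at_mean deviance evaluated at the posterior mean of the
#'   parameters.
#' @return list with `dic`, `pd`, `mean_deviance`.
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  stopifnot(all(is.finite(deviance_draws)), is.finite(deviance_at_mean))
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  list(dic = dbar + pd, pd = pd, mean_deviance = dbar)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `level` of the sample: all windows of
#' ceiling(level * n) consecutive order statistics are scanned and the
#' narrowest returned.  Never wider than the equal-tailed interval.
#'
#' @param samples numeric vector (>= 20 values recommended).
#' @param level probability mass, in (0,1).
#' @return c(lo, hi).
#' @export
hpd_interval <- function(samples, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  k <- ceiling(level * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Posterior predictive Bayesian p-value
#'
#' Draws `n_rep` parameter vectors from the posterior, simulates one
#' replicate dataset from each, and reports the proportion of replicates
#' whose discrepancy is greater than or equal to the observed data's
#' discrepancy at the same draw (ties count).  Values near 0 or 1 indicate
#' lack of fit; a well-specified model yields values away from both tails.
#'
#' @param fit a `posterior_fit` (or a draws matrix with named columns).
#' @param replicate_generator function(theta) -> replicated dataset.
#' @param discrepancy function(data, theta) -> scalar discrepancy.
#' @param observed the observed dataset.
#' @param n_rep number of replicated datasets (default 5000).
#' @param seed RNG seed for draw selection and replication.
#' @return the Bayesian p-value in \[0,1\].
#' @export
posterior_predictive_pvalue <- function(fit, replicate_generator, discrepancy,
                                        observed, n_rep = 5000, seed = 1) {
  m <- if (inherits(fit, "posterior_fit")) as.matrix(fit) else fit
  stopifnot(n_rep >= 1)
  set.seed(seed)
  rows <- sample.int(nrow(m), n_rep, replace = n_rep > nrow(m))
  exceed <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    theta <- m[rows[r], ]
    rep_data <- replicate_generator(theta)
    exceed[r] <- discrepancy(rep_data, theta) >= discrepancy(observed, theta)
  }
  mean(exceed)
}
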