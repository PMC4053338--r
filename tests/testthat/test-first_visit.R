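fv_params <- function(k = 1, a = log(0.1), beta = 0, u = 0) {
  list(k = k, alpha_spring = a, alpha_winter = a, beta = beta,
       transect_effects = u)
}
site1 <- function(d = 0) list(season = "spring", distance_to_farm = d,
                              transect_id = 1L)

test_that("Weibull survival and interval probabilities follow closed forms", {
  p <- fv_params()
  expect_equal(fv_survival(0, p, site1()), 1)
  expect_equal(fv_survival(10, p, site1()), exp(-1))
  expect_error(fv_survival(-1, p, site1()), ">= 0")

  ## canonical-parameter evaluation against independent arithmetic:
  ## k = 1.61, alpha = -5.38, beta = 0.38, Dtf = 2, t = 30
  p2 <- fv_params(k = 1.61, a = -5.38, beta = 0.38)
  expect_equal(fv_survival(30, p2, site1(2)),
               exp(-exp(-5.38 + 0.38 * 2) * 30^1.61), tolerance = 1e-12)

  ## day-1 probability telescopes
  expect_equal(fv_interval_prob(1, p, site1()),
               1 - fv_survival(1, p, site1()))

  ## conservation: interval masses plus censoring mass sum to 1 (1e-12)
  for (k in c(0.7, 1, 1.61)) {
    pk <- fv_params(k = k, a = -2.2)
    total <- sum(vapply(1:50, function(t)
      fv_interval_prob(t, pk, site1()), 0)) + fv_survival(50, pk, site1())
    expect_equal(total, 1, tolerance = 1e-12)
  }

  ## monotone decreasing interval probabilities when k <= 1
  pm <- fv_params(k = 0.8, a = -1.5)
  probs <- vapply(1:20, function(t) fv_interval_prob(t, pm, site1()), 0)
  expect_true(all(diff(probs) < 0))
})

test_that("log-likelihood matches a 10-day enumeration oracle", {
  ## one observed day-1 visit, k = 1: log(1 - e^-lambda)
  d1 <- data.frame(transect_id = 1L, distance_to_farm = 0,
                   season = "spring", day = 1L, censored = FALSE)
  lam <- 0.1
  expect_equal(
    fv_log_likelihood(d1, fv_params(a = log(lam))),
    log(1 - exp(-lam)), tolerance = 1e-12)

  ## all censored, lambda -> 0: log-likelihood -> 0
  dc <- data.frame(transect_id = 1L, distance_to_farm = 0,
                   season = "spring", day = 10L, censored = TRUE)
  expect_lt(abs(fv_log_likelihood(dc, fv_params(a = -30))), 1e-8)

  ## enumeration oracle on a 10-day toy with mixed outcomes
  toy <- data.frame(transect_id = c(1L, 1L, 2L, 2L),
                    distance_to_farm = c(0.05, 2, 3, 4),
                    season = c("spring", "spring", "winter", "winter"),
                    day = c(3L, 10L, 7L, 10L),
                    censored = c(FALSE, TRUE, FALSE, TRUE))
  p <- fv_params(k = 1.3, a = -2.5, beta = 0.2, u = c(0.3, -0.4))
  oracle <- 0
  for (i in 1:4) {
    site <- list(season = toy$season[i],
                 distance_to_farm = toy$distance_to_farm[i],
                 transect_id = toy$transect_id[i])
    daily <- vapply(1:10, function(t) fv_interval_prob(t, p, site), 0)
    oracle <- oracle + if (toy$censored[i]) log(1 - sum(daily)) else
      log(daily[toy$day[i]])
  }
  expect_equal(fv_log_likelihood(toy, p), oracle, tolerance = 1e-10)
})

test_that("first-visit fit is reproducible and flags the null", {
  truth <- default_sim_truth()
  sites <- generate_design(8, seed = 61)
  fv <- simulate_first_visits(truth, sites, horizon_days = 100, seed = 62)
  cfg <- small_mcmc(seed = 63, n_burnin = 600, n_keep = 600)
  f1 <- suppressWarnings(fit_first_visit(fv, config = cfg,
                                         compute_dic = FALSE))
  f2 <- suppressWarnings(fit_first_visit(fv, config = cfg,
                                         compute_dic = FALSE))
  expect_identical(f1$draws, f2$draws)

  ## beta truth = 0: posterior interval for beta contains 0
  t0 <- truth
  t0$weibull$wild_dog$beta <- 0
  fv0 <- simulate_first_visits(t0, sites, horizon_days = 100, seed = 64)
  f0 <- suppressWarnings(fit_first_visit(fv0, config = cfg,
                                         compute_dic = FALSE))
  h <- hpd_interval(as.matrix(f0)[, "beta"])
  expect_true(h[1] <= 0 && 0 <= h[2])
})

test_that("posterior first-visit summaries respect season and distance", {
  ## point-mass posterior: k = 1, lambda = log 2 => median day 1
  draws2 <- array(0, c(50, 2, 5),
                  dimnames = list(NULL, NULL,
                                  c("log_k", "a_spring", "a_winter", "beta",
                                    "log_sigma_t")))
  draws2[, , "a_spring"] <- log(log(2))
  draws2[, , "a_winter"] <- log(log(2)) - 1
  draws2[, , "log_sigma_t"] <- -30
  fit2 <- structure(list(draws = draws2,
                         parameters = dimnames(draws2)[[3]],
                         season_effect = TRUE),
                    class = c("first_visit_fit", "posterior_fit"))
  s <- first_visit_summary(fit2, distance = 0, season = "spring")
  expect_equal(s$median, 1, tolerance = 1e-9)
  expect_equal(unname(s$hpd), c(1, 1), tolerance = 1e-9)

  ## lower hazard (winter here) implies later first visits at all distances
  for (d in c(0.05, 2, 4)) {
    ss <- first_visit_summary(fit2, d, "spring")
    sw <- first_visit_summary(fit2, d, "winter")
    expect_lt(ss$median, sw$median)
  }

  ## a positive beta shortens waiting times further away
  draws3 <- draws2
  draws3[, , "beta"] <- 0.4
  fit3 <- structure(list(draws = draws3,
                         parameters = dimnames(draws3)[[3]],
                         season_effect = TRUE),
                    class = c("first_visit_fit", "posterior_fit"))
  s0 <- first_visit_summary(fit3, 0, "spring")
  s4 <- first_visit_summary(fit3, 4, "spring")
  expect_lt(s4$median, s0$median)
})
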